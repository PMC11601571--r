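# shared fixtures and independent oracles

# long-format score rows for one mouse over a window, with selected days set
make_mouse_df <- function(id, window = c(5L, 50L), classic = NULL, ar = NULL,
                          strain = "CC900", sex = "M", cohort = "C1",
                          status = NULL, days = NULL) {
  if (is.null(days)) days <- window[1]:window[2]
  n <- length(days)
  df <- data.frame(mouse_id = id, strain = strain, sex = sex, cohort = cohort,
                   day = days,
                   classic = if (is.null(classic)) 0L else classic,
                   ar = if (is.null(ar)) 0L else ar,
                   status = if (is.null(status)) "alive" else status,
                   stringsAsFactors = FALSE)
  df
}

# score vector with positive values on the named days, zero elsewhere
score_on <- function(days_on, value = 2L, window = c(5L, 50L)) {
  days <- window[1]:window[2]
  s <- integer(length(days))
  s[days %in% days_on] <- as.integer(value)
  s
}

# Independent disease-course oracle: classifies the combined score series
# by regular expressions on the day-presence string rather than run-length
# bookkeeping.
course_oracle <- function(disease_score) {
  b <- paste(ifelse(disease_score > 0, "D", "z"), collapse = "")
  onset <- regexpr("DD", b)
  if (onset < 0) return("none")
  rest <- substring(b, onset)          # starts inside the initial bout
  bout_len <- attr(regexpr("^D+", rest), "match.length")
  tail_str <- substring(rest, bout_len + 1)
  if (grepl("^z+$", tail_str)) return("monophasic")  # >=1 remitted day
  if (grepl("z{3,}.*DD", rest)) return("RR")
  "chronic"
}

# Independent two-regression LOD oracle using stats::lm at each marker
lod_oracle <- function(gp, pheno) {
  idx <- match(pheno$strain, gp$strains)
  y <- pheno$value
  n <- length(y)
  vapply(seq_len(nrow(gp$map)), function(m) {
    D <- gp$probs[, m, ][idx, , drop = FALSE]
    rss0 <- sum((y - mean(y))^2)
    rss1 <- sum(stats::resid(stats::lm(y ~ D[, -1]))^2)
    (n / 2) * log10(rss0 / rss1)
  }, numeric(1))
}

# Independent smallest-mass-interval search for the credible interval
ci_oracle <- function(lod, pos, prob = 0.95) {
  w <- 10^(lod - max(lod)); w <- w / sum(w)
  peak <- which.max(lod)
  best <- NULL; best_width <- Inf; best_k <- Inf
  for (i in seq_len(peak)) for (j in peak:length(w)) {
    if (sum(w[i:j]) >= prob) {
      width <- pos[j] - pos[i]
      if (width < best_width || (width == best_width && (j - i) < best_k)) {
        best <- c(pos[i], pos[j]); best_width <- width; best_k <- j - i
      }
    }
  }
  best
}

# one archetype per named strain, defaults
sim_archetypes <- function(names = c("chronic", "monophasic", "rr",
                                     "progressive", "ar_chronic")) {
  out <- lapply(names, archetype_spec)
  names(out) <- toupper(names)
  out
}
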