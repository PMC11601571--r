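#' Combine classic and axial-rotary scores into a daily disease score
#'
#' The combined daily disease score is the classic score when only the
#' classic scale is positive, the axial-rotary (AR) score when only AR is
#' positive, and the arithmetic mean of the two on days when both scales
#' are positive simultaneously.
#'
#' @param classic,ar integer scores in 0--5 (vectorized).
#' @return Numeric vector of combined daily disease scores.
#' @export
combine_daily <- function(classic, ar) {
  ifelse(classic > 0 & ar > 0, (classic + ar) / 2, classic + ar)
}

#' Cumulative disease scores for one score series
#'
#' CDS is the sum of the combined daily disease score over the window;
#' classic-CDS and AR-CDS sum each raw scale.  Because simultaneous days
#' contribute their mean to CDS, CDS need not equal classic-CDS + AR-CDS.
#'
#' @param classic,ar integer daily scores over the window.
#' @return Named numeric vector `c(cds, classic_cds, ar_cds)`.
#' @export
cumulative_scores <- function(classic, ar) {
  c(cds = sum(combine_daily(classic, ar)),
    classic_cds = sum(classic),
    ar_cds = sum(ar))
}

# run-length encoding of disease presence with first-day bookkeeping
disease_runs <- function(disease_score) {
  r <- rle(disease_score > 0)
  ends <- cumsum(r$lengths)
  data.frame(positive = r$values, len = r$lengths,
             start = ends - r$lengths + 1L, end = ends)
}

#' EAE incidence and onset day
#'
#' A mouse is EAE-incident iff its combined daily disease score is
#' positive for at least 2 consecutive days; onset is the first day of the
#' first qualifying run.
#'
#' @param disease_score numeric combined daily scores.
#' @param days integer day labels aligned with `disease_score`.
#' @return List with `incident` (logical) and `onset_day` (integer or NA).
#' @export
eae_incidence <- function(disease_score, days = seq_along(disease_score)) {
  runs <- disease_runs(disease_score)
  q <- which(runs$positive & runs$len >= 2L)
  if (length(q) == 0L) return(list(incident = FALSE, onset_day = NA_integer_))
  list(incident = TRUE, onset_day = as.integer(days[runs$start[q[1]]]))
}

#' Mutually exclusive EAE subtype assignment
#'
#' Classic-only presentations are `classic`, AR-only are `AR`.  Mice that
#' presented with both scales ("combined type") are assigned by comparing
#' days scored classic-only (classic > 0, AR = 0) against days scored
#' AR-only; simultaneous days are excluded from the comparison.  An exact
#' tie is assigned `classic` with `tie = TRUE`.
#'
#' @param classic,ar integer daily scores.
#' @param incident logical; non-incident mice return `"none"`.
#' @return List with `subtype` in `c("classic", "AR", "none")` and `tie`.
#' @export
subtype_assignment <- function(classic, ar, incident = TRUE) {
  if (!incident) return(list(subtype = "none", tie = FALSE))
  any_classic <- any(classic > 0)
  any_ar <- any(ar > 0)
  if (any_classic && !any_ar) return(list(subtype = "classic", tie = FALSE))
  if (any_ar && !any_classic) return(list(subtype = "AR", tie = FALSE))
  classic_only <- sum(classic > 0 & ar == 0)
  ar_only <- sum(ar > 0 & classic == 0)
  if (classic_only > ar_only) list(subtype = "classic", tie = FALSE)
  else if (ar_only > classic_only) list(subtype = "AR", tie = FALSE)
  else list(subtype = "classic", tie = TRUE)
}

#' Disease-course classification
#'
#' Classifies an incident mouse's combined daily disease-score series as:
#' \describe{
#'   \item{monophasic}{an initial bout (>= 2 consecutive positive days)
#'     followed by zeros for the remainder of the window;}
#'   \item{RR}{(relapsing-remitting) an initial bout, then a remission of
#'     >= 3 consecutive zero days, then a relapse of >= 2 consecutive
#'     positive days;}
#'   \item{chronic}{everything else with disease onset (the catch-all;
#'     in particular, zero-dips shorter than 3 days do not count as
#'     remission).}
#' }
#' Non-incident series return `"none"`.
#'
#' @param disease_score numeric combined daily scores over the window.
#' @return One of `"monophasic"`, `"RR"`, `"chronic"`, `"none"`.
#' @export
course_classification <- function(disease_score) {
  runs <- disease_runs(disease_score)
  onset_run <- which(runs$positive & runs$len >= 2L)[1]
  if (is.na(onset_run)) return("none")
  later <- runs[-seq_len(onset_run), , drop = FALSE]
  # monophasic: nothing after the initial bout but a single zero run
  if (nrow(later) == 1L && !later$positive[1]) return("monophasic")
  if (nrow(later) == 0L) return("chronic")  # bout persists to termination
  remission <- which(!later$positive & later$len >= 3L)[1]
  if (!is.na(remission)) {
    after <- later[-seq_len(remission), , drop = FALSE]
    if (any(after$positive & after$len >= 2L)) return("RR")
  }
  "chronic"
}

#' Derive per-mouse quantitative trait variables
#'
#' Computes, for every non-excluded mouse in a preprocessed cohort (see
#' [apply_endpoint_rules()]), the cumulative disease scores, incidence
#' flag and onset day, mutually exclusive subtype, disease-course class,
#' and humane-endpoint flag.
#'
#' @param table a [cohort_table()], ideally after [apply_endpoint_rules()].
#' @return data.frame with one row per mouse: `mouse_id`, `strain`, `sex`,
#'   `cohort`, `cds`, `classic_cds`, `ar_cds`, `eae_incident`, `subtype`,
#'   `course`, `onset_day`, `endpoint`, `subtype_tie`.
#' @export
derive_qtv <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  mice <- split_mice(table$scores)
  rows <- lapply(mice, function(m) {
    m <- m[order(m$day), , drop = FALSE]
    d <- combine_daily(m$classic, m$ar)
    cs <- cumulative_scores(m$classic, m$ar)
    inc <- eae_incidence(d, m$day)
    sub <- subtype_assignment(m$classic, m$ar, inc$incident)
    course <- if (inc$incident) course_classification(d) else "none"
    data.frame(mouse_id = m$mouse_id[1], strain = m$strain[1], sex = m$sex[1],
               cohort = m$cohort[1],
               cds = unname(cs["cds"]), classic_cds = unname(cs["classic_cds"]),
               ar_cds = unname(cs["ar_cds"]),
               eae_incident = inc$incident, subtype = sub$subtype,
               course = course, onset_day = inc$onset_day,
               endpoint = any(m$status == "endpoint"),
               subtype_tie = sub$tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-strain summaries of the quantitative trait variables
#'
#' Aggregates the per-mouse table to one row per strain: sample size,
#' percent incidence of any EAE and of each mutually exclusive subtype,
#' percent of each disease course, mean cumulative scores, and percent
#' reaching the humane endpoint.  Percentages are over non-excluded mice
#' (excluded mice never enter [derive_qtv()]).
#'
#' @param qtv per-mouse data.frame from [derive_qtv()].
#' @param by_sex if TRUE, summarize strain-by-sex slices instead.
#' @return data.frame with one row per strain (or strain-sex).
#' @export
summarize_strain <- function(qtv, by_sex = FALSE) {
  if (nrow(qtv) == 0L) stop("no mice to summarize")
  key <- if (by_sex) interaction(qtv$strain, qtv$sex, drop = TRUE)
         else qtv$strain
  groups <- split(qtv, key)
  rows <- lapply(groups, function(g) {
    n <- nrow(g)
    data.frame(strain = g$strain[1],
               sex = if (by_sex) g$sex[1] else NA_character_,
               n_mice = n,
               incidence_pct = 100 * mean(g$eae_incident),
               classic_incidence_pct = 100 * mean(g$subtype == "classic"),
               ar_incidence_pct = 100 * mean(g$subtype == "AR"),
               chronic_pct = 100 * mean(g$course == "chronic"),
               rr_pct = 100 * mean(g$course == "RR"),
               mono_pct = 100 * mean(g$course == "monophasic"),
               mean_cds = mean(g$cds),
               mean_classic_cds = mean(g$classic_cds),
               mean_ar_cds = mean(g$ar_cds),
               endpoint_pct = 100 * mean(g$endpoint),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!by_sex) out$sex <- NULL
  rownames(out) <- NULL
  out
}
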