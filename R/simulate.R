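#' Disease-course archetype specification
#'
#' Template parameters for simulated EAE trajectories.  The named
#' archetypes mirror the course profiles observed across the strain panel:
#' near-complete resistance, chronic disease, monophasic disease with full
#' remission, relapsing-remitting (RR) disease, rapidly progressive severe
#' disease reaching the humane endpoint, and chronic axial-rotary (AR)
#' disease.
#'
#' @param name one of `resistant`, `chronic`, `monophasic`, `rr`,
#'   `progressive`, `ar_chronic`.
#' @param onset_mu,onset_sd mean and SD of onset day.
#' @param peak peak clinical score, 1--5.
#' @param remission_day first fully remitted day (monophasic / rr).
#' @param relapse_day first day of the second bout (rr).
#' @param penetrance probability an immunized mouse develops disease.
#' @param subtype_channel which scale carries the trajectory: `classic`,
#'   `ar`, or `both`.
#' @return List of class `archetype_spec`.
#' @export
archetype_spec <- function(name,
                           onset_mu = NULL, onset_sd = NULL, peak = NULL,
                           remission_day = NULL, relapse_day = NULL,
                           penetrance = NULL, subtype_channel = NULL) {
  defaults <- list(
    resistant   = list(onset_mu = 12, onset_sd = 2, peak = 1,
                       remission_day = NA, relapse_day = NA,
                       penetrance = 0, subtype_channel = "classic"),
    chronic     = list(onset_mu = 12, onset_sd = 2, peak = 3,
                       remission_day = NA, relapse_day = NA,
                       penetrance = 0.9, subtype_channel = "classic"),
    monophasic  = list(onset_mu = 12, onset_sd = 2, peak = 3,
                       remission_day = 26, relapse_day = NA,
                       penetrance = 0.8, subtype_channel = "classic"),
    rr          = list(onset_mu = 12, onset_sd = 2, peak = 3,
                       remission_day = 24, relapse_day = 30,
                       penetrance = 0.85, subtype_channel = "classic"),
    progressive = list(onset_mu = 10, onset_sd = 1.5, peak = 5,
                       remission_day = NA, relapse_day = NA,
                       penetrance = 1, subtype_channel = "classic"),
    ar_chronic  = list(onset_mu = 12, onset_sd = 2, peak = 3,
                       remission_day = NA, relapse_day = NA,
                       penetrance = 0.8, subtype_channel = "ar"))
  if (!name %in% names(defaults)) stop("unknown archetype: ", name)
  spec <- defaults[[name]]
  for (f in names(spec)) {
    v <- get(f)
    if (!is.null(v)) spec[[f]] <- v
  }
  if (spec$penetrance < 0 || spec$penetrance > 1)
    stop("penetrance must lie in [0, 1]")
  structure(c(list(name = name), spec), class = "archetype_spec")
}

# Piecewise-linear score template over the window for one incident mouse;
# rounded to integers; ramps rise and fall one point per day.
archetype_template <- function(spec, onset, window) {
  days <- window[1]:window[2]
  s <- numeric(length(days))
  ramp_up <- function(from_day) pmin(pmax(days - from_day + 1, 0), spec$peak)
  if (spec$name %in% c("chronic", "ar_chronic", "progressive")) {
    s <- ramp_up(onset)
  } else if (spec$name == "monophasic") {
    up <- ramp_up(onset)
    down <- pmax(spec$remission_day - days, 0)
    s <- pmin(up, down)
  } else if (spec$name == "rr") {
    up <- ramp_up(onset)
    down <- pmax(spec$remission_day - days, 0)
    bout1 <- pmin(up, down)
    bout2 <- ramp_up(spec$relapse_day)
    s <- pmax(bout1, bout2)
  }
  as.integer(round(pmin(pmax(s, 0), 5)))
}

check_window_fits <- function(spec, window) {
  need <- spec$onset_mu + spec$peak + 2
  if (spec$name == "monophasic") need <- spec$remission_day + 1
  if (spec$name == "rr") need <- spec$relapse_day + 2
  if (spec$name == "progressive") need <- spec$onset_mu + spec$peak + 3
  if (need > window[2])
    stop(sprintf("window [%d, %d] too short for archetype '%s' landmarks",
                 window[1], window[2], spec$name))
}

#' Simulate a cohort of daily clinical-score trajectories
#'
#' Draws, for each strain, `n_per_sex` mice per sex; each mouse is
#' incident with the archetype's penetrance, and incident trajectories
#' follow the archetype's piecewise-linear template anchored at a
#' normally drawn onset day.  Day-level jitter of plus or minus one point
#' is applied at rate `noise_sd` to days the template scores positive
#' (scorer noise on symptomatic days), clipped to 0--5.  The progressive
#' archetype ramps to 5 and holds, so [apply_endpoint_rules()] triggers
#' the 72-hour endpoint.
#'
#' @param archetypes named list: strain -> [archetype_spec()].
#' @param n_per_sex mice per sex per strain (study design: ~5/sex/strain).
#' @param window observation window, closed.
#' @param noise_sd per-day jitter probability on symptomatic days.
#' @param cohorts cohort labels cycled across mice (default C1--C4).
#' @param seed optional integer seed.
#' @return List: `table` (a [cohort_table()]) and `truth` (per-mouse
#'   data.frame with the generating archetype, incidence, expected course
#'   and subtype, and expected endpoint flag).
#' @export
gen_scores <- function(archetypes, n_per_sex = 5, window = c(5L, 50L),
                       noise_sd = 0, cohorts = paste0("C", 1:4),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  window <- as.integer(window)
  rows <- list(); truth <- list()
  mouse_counter <- 0L
  for (strain in names(archetypes)) {
    spec <- archetypes[[strain]]
    stopifnot(inherits(spec, "archetype_spec"))
    if (spec$penetrance > 0) check_window_fits(spec, window)
    for (sex in c("M", "F")) {
      for (k in seq_len(n_per_sex)) {
        mouse_counter <- mouse_counter + 1L
        id <- sprintf("%s_%s%02d", strain, sex, k)
        incident <- stats::runif(1) < spec$penetrance
        days <- window[1]:window[2]
        classic <- integer(length(days)); ar <- integer(length(days))
        if (incident) {
          onset <- round(stats::rnorm(1, spec$onset_mu, spec$onset_sd))
          onset <- min(max(onset, window[1]), window[1] + 10L)
          tmpl <- archetype_template(spec, onset, window)
          if (noise_sd > 0) {
            hit <- tmpl > 0 & stats::runif(length(tmpl)) < noise_sd
            tmpl[hit] <- pmin(pmax(tmpl[hit] +
              sample(c(-1L, 1L), sum(hit), replace = TRUE), 0L), 5L)
          }
          if (spec$subtype_channel %in% c("classic", "both")) classic <- tmpl
          if (spec$subtype_channel %in% c("ar", "both")) ar <- tmpl
        }
        rows[[mouse_counter]] <- data.frame(
          mouse_id = id, strain = strain, sex = sex,
          cohort = cohorts[(mouse_counter - 1L) %% length(cohorts) + 1L],
          day = days, classic = classic, ar = ar, status = "alive",
          stringsAsFactors = FALSE)
        truth[[mouse_counter]] <- data.frame(
          mouse_id = id, strain = strain, sex = sex,
          archetype = spec$name, incident = incident,
          expected_course = if (!incident) "none" else switch(spec$name,
            monophasic = "monophasic", rr = "RR", "chronic"),
          expected_subtype = if (!incident) "none" else
            if (spec$subtype_channel == "ar") "AR" else "classic",
          expected_endpoint = incident && spec$name == "progressive",
          stringsAsFactors = FALSE)
      }
    }
  }
  list(table = cohort_table(do.call(rbind, rows), window = window),
       truth = do.call(rbind, truth))
}

#' Simulate founder-mosaic genomes
#'
#' Per strain and chromosome, founder ancestry follows a Markov chain
#' along the marker grid (uniform initial state, probability
#' `switch_prob` of jumping to a uniformly drawn other founder at each
#' step).  Dosages put `certainty` on the sampled founder and spread the
#' remainder evenly over the other seven.
#'
#' @param n_strains number of strains.
#' @param chroms data.frame with columns `chrom`, `n_markers`,
#'   `length_Mb`.
#' @param switch_prob per-step founder-switch probability, in (0, 1).
#' @param certainty dosage concentration on the sampled founder, in
#'   (0, 1]; 1 gives one-hot dosages.
#' @param seed optional integer seed.
#' @return A [genotype_probs()] object.
#' @export
gen_genomes <- function(n_strains,
                        chroms = data.frame(chrom = c("1", "2", "3"),
                                            n_markers = 100,
                                            length_Mb = 100),
                        switch_prob = 0.1, certainty = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(switch_prob > 0, switch_prob < 1,
            certainty > 0, certainty <= 1)
  strains <- sprintf("S%03d", seq_len(n_strains))
  map <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    nm <- chroms$n_markers[i]
    data.frame(marker = sprintf("m%s_%03d", chroms$chrom[i], seq_len(nm)),
               chrom = chroms$chrom[i],
               pos_Mb = round(seq(1, chroms$length_Mb[i], length.out = nm), 3),
               stringsAsFactors = FALSE)
  }))
  rownames(map) <- NULL
  probs <- array(0, c(n_strains, nrow(map), 8L))
  off <- 0L
  for (i in seq_len(nrow(chroms))) {
    nm <- chroms$n_markers[i]
    for (s in seq_len(n_strains)) {
      state <- sample.int(8L, 1L)
      for (m in seq_len(nm)) {
        if (m > 1L && stats::runif(1) < switch_prob)
          state <- sample(setdiff(1:8, state), 1L)
        probs[s, off + m, ] <- (1 - certainty) / 7
        probs[s, off + m, state] <- certainty
      }
    }
    off <- off + nm
  }
  genotype_probs(probs, map, strains)
}

#' Plant a QTL into simulated genomes and draw phenotypes
#'
#' Each strain's genetic value is `beta` times its summed dosage over the
#' high founders at the planted marker, plus a polygenic term built from
#' random founder effects summed over background markers (scaled so it
#' contributes a fraction `h2_poly` of the non-QTL variance), plus
#' residual noise.  With `n_per_strain > 1`, each mouse adds its own
#' residual around the strain genetic value.  `trait = "incidence"`
#' pushes the strain value through a logistic link to a percentage.
#'
#' @param gp a [genotype_probs()] object.
#' @param marker planted marker id.
#' @param high_founders founder labels (subset of [cc_founders]) whose
#'   alleles raise the trait.
#' @param beta additive effect per unit dosage.
#' @param trait `"quant"` (e.g. CDS-like) or `"incidence"` (per-strain
#'   percentage).
#' @param h2_poly background polygenic fraction of the non-QTL variance,
#'   in `[0, 1)`.
#' @param noise_sd residual standard deviation.
#' @param n_per_strain replicate mice per strain (quant trait only).
#' @param seed optional integer seed.
#' @return List: `pheno` (data.frame `strain`, `value`, plus `mouse_id`
#'   when replicated) and `truth` (planted marker, founders, beta).
#' @export
plant_qtl <- function(gp, marker, high_founders, beta,
                      trait = c("quant", "incidence"), h2_poly = 0,
                      noise_sd = 1, n_per_strain = 1, seed = NULL) {
  trait <- match.arg(trait)
  if (!is.null(seed)) set.seed(seed)
  m <- match(marker, gp$map$marker)
  if (is.na(m)) stop("unknown marker: ", marker)
  hf <- match(high_founders, cc_founders)
  if (anyNA(hf)) stop("unknown founder(s): ",
                      paste(high_founders[is.na(hf)], collapse = ", "))
  stopifnot(h2_poly >= 0, h2_poly < 1)
  S <- length(gp$strains)
  dose <- rowSums(gp$probs[, m, hf, drop = FALSE][, 1, , drop = FALSE])
  dim(dose) <- NULL
  g_qtl <- beta * dose
  g_poly <- rep(0, S)
  if (h2_poly > 0) {
    n_bg <- min(200L, nrow(gp$map))
    bg <- sample(seq_len(nrow(gp$map)), n_bg)
    raw <- rowSums(vapply(bg, function(mm)
      gp$probs[, mm, ] %*% stats::rnorm(8), numeric(S)))
    target_var <- noise_sd^2 * h2_poly / (1 - h2_poly)
    if (stats::sd(raw) > 0)
      g_poly <- (raw - mean(raw)) / stats::sd(raw) * sqrt(target_var)
  }
  g <- g_qtl + g_poly
  truth <- list(marker = marker, high_founders = high_founders, beta = beta,
                chrom = gp$map$chrom[m], pos_Mb = gp$map$pos_Mb[m],
                h2_poly = h2_poly, noise_sd = noise_sd)
  if (trait == "incidence") {
    lin <- (g - mean(g)) / max(stats::sd(g), 1e-12) +
      stats::rnorm(S, 0, noise_sd)
    pheno <- data.frame(strain = gp$strains,
                        value = 100 * stats::plogis(lin))
    return(list(pheno = pheno, truth = truth))
  }
  if (n_per_strain == 1L) {
    pheno <- data.frame(strain = gp$strains,
                        value = g + stats::rnorm(S, 0, noise_sd))
  } else {
    pheno <- data.frame(
      mouse_id = sprintf("%s_%02d", rep(gp$strains, each = n_per_strain),
                         rep(seq_len(n_per_strain), S)),
      strain = rep(gp$strains, each = n_per_strain),
      value = rep(g, each = n_per_strain) +
        stats::rnorm(S * n_per_strain, 0, noise_sd))
  }
  list(pheno = pheno, truth = truth)
}

#' Simulate a gene network with a planted trait module
#'
#' Background gene pairs gain an edge with probability `density` and an
#' exponential weight of mean `w_bg_mean`; pairs inside the planted module
#' gain an edge with probability `in_density` and mean `w_in_mean`.
#' Positives are sampled from the module (the held-out module genes are
#' the planted true candidates); background candidates are sampled from
#' the rest.
#'
#' @param n_genes total genes.
#' @param module_size planted module size (< `n_genes`).
#' @param w_in_mean,w_bg_mean mean edge weight inside / outside the module.
#' @param density background edge probability.
#' @param in_density within-module edge probability.
#' @param frac_positive fraction of module genes used as positives.
#' @param n_bg_candidates background candidates to hold out.
#' @param tissue tissue label for the network.
#' @param seed optional integer seed.
#' @return List: `network` ([gene_network()]), `module`, `positives`,
#'   `candidates_true`, `candidates_bg`, `negative_pool`.
#' @export
gen_network <- function(n_genes = 2000, module_size = 150,
                        w_in_mean = 1, w_bg_mean = 0.1,
                        density = 0.01, in_density = 0.5,
                        frac_positive = 0.6, n_bg_candidates = 50,
                        tissue = "immune", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(module_size < n_genes)
  if (w_in_mean <= w_bg_mean)
    warning("w_in_mean <= w_bg_mean: planted module carries no signal")
  genes <- sprintf("G%05d", seq_len(n_genes))
  module <- genes[seq_len(module_size)]
  pairs <- function(g, p) {
    n <- length(g)
    if (n < 2L || p <= 0) return(NULL)
    # Bernoulli thinning of all pairs via expected count + index sampling
    total <- n * (n - 1) / 2
    k <- stats::rbinom(1, total, p)
    if (k == 0L) return(NULL)
    sel <- sort(sample(total, k))
    # unrank lexicographic pair index -> (i, j), i < j
    i <- ceiling((n - 0.5) - sqrt((n - 0.5)^2 - 2 * sel))
    j <- sel - ((i - 1) * n - (i - 1) * i / 2) + i
    data.frame(gene_a = g[i], gene_b = g[j], stringsAsFactors = FALSE)
  }
  bg <- pairs(genes, density)
  if (!is.null(bg)) bg$weight <- stats::rexp(nrow(bg), rate = 1 / w_bg_mean)
  inm <- pairs(module, in_density)
  if (!is.null(inm)) inm$weight <- stats::rexp(nrow(inm), 1 / w_in_mean)
  edges <- rbind(inm, bg)  # module draw first so it wins collisions
  if (is.null(edges))
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric())
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  edges <- edges[!duplicated(key), , drop = FALSE]
  rownames(edges) <- NULL
  positives <- sample(module, round(frac_positive * module_size))
  candidates_true <- setdiff(module, positives)
  background <- setdiff(genes, module)
  candidates_bg <- sample(background, n_bg_candidates)
  negative_pool <- setdiff(background, candidates_bg)
  list(network = gene_network(edges, tissue = tissue, genes = genes),
       module = module, positives = positives,
       candidates_true = candidates_true, candidates_bg = candidates_bg,
       negative_pool = negative_pool)
}

#' Simulate a variant table with known nonsynonymous segregation counts
#'
#' Rows are placed uniformly in the interval; each row is missense with
#' probability `frac_missense` and segregates between the two named
#' founders with probability `frac_segregating`.  The realized number of
#' qualifying rows (missense AND segregating) is recorded in the truth.
#'
#' @param chrom chromosome label.
#' @param lo_mb,hi_mb interval bounds (Mb, closed).
#' @param genes gene symbols to sample from.
#' @param n_rows number of variant rows.
#' @param frac_missense probability a row is missense.
#' @param frac_segregating probability the two focal founders differ.
#' @param founder_a,founder_b focal founders.
#' @param seed optional integer seed.
#' @return List: `variants` (data.frame ready for [nssnp_segregating()])
#'   and `truth` (`n_qualifying`).
#' @export
gen_variants <- function(chrom, lo_mb, hi_mb, genes, n_rows = 100,
                         frac_missense = 0.3, frac_segregating = 0.5,
                         founder_a = "WSB", founder_b = "NOD",
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(frac_missense >= 0, frac_missense <= 1,
            frac_segregating >= 0, frac_segregating <= 1)
  missense <- stats::runif(n_rows) < frac_missense
  segregating <- stats::runif(n_rows) < frac_segregating
  v <- data.frame(chrom = chrom,
                  pos_Mb = round(stats::runif(n_rows, lo_mb, hi_mb), 4),
                  gene = sample(genes, n_rows, replace = TRUE),
                  consequence = ifelse(missense, "missense_variant",
                                       "synonymous_variant"),
                  stringsAsFactors = FALSE)
  for (f in cc_founders) v[[f]] <- "A"
  v[[founder_b]][segregating] <- "G"
  if (founder_a == founder_b) stop("founder_a and founder_b must differ")
  v <- v[order(v$pos_Mb), , drop = FALSE]
  rownames(v) <- NULL
  list(variants = v,
       truth = list(n_qualifying = sum(missense & segregating),
                    founder_a = founder_a, founder_b = founder_b))
}
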