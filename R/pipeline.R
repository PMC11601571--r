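#' Default pipeline configuration
#'
#' Returns the configuration list [run_pipeline()] consumes, filled with
#' the defaults of a fully synthetic run: simulated score trajectories,
#' founder-mosaic genomes with one planted QTL, a planted-module gene
#' network, and a variant table.  Any field can be overridden, and input
#' paths can replace the simulation blocks to run on real files.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @return Named list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    window = c(5L, 50L),
    alphas = c(0.15, 0.20),
    n_perm = 1000L,
    n_svm = 100L,
    kinship = "none",  # none | overall | loco
    scores_path = NULL, probs_path = NULL, network_path = NULL,
    positives_path = NULL, variants_path = NULL,
    simulate = list(
      n_per_sex = 5L, noise_sd = 0.05,
      n_strains = 40L, switch_prob = 0.08, certainty = 1,
      qtl_marker = "m2_050", qtl_high_founders = c("WSB", "NZO"),
      qtl_beta = 2, qtl_noise_sd = 1,
      network = list(n_genes = 800L, module_size = 80L, w_in_mean = 1,
                     w_bg_mean = 0.1, density = 0.01, in_density = 0.5),
      variants = list(chrom = "2", lo_mb = 40, hi_mb = 60, n_rows = 100L,
                      frac_missense = 0.3, frac_segregating = 0.5)))
}

# derive a reproducible sub-seed (kept well below 2^31)
sub_seed <- function(seed, k) (as.integer(seed) * 97L + k * 1009L) %% 1000000L

#' Run the full pipeline end-to-end
#'
#' Executes the stages scores -> traits -> genome scan -> prioritization
#' in order, writing one TSV per stage plus a JSON manifest (package
#' version, seeds, parameters, input checksums) into `out_dir`.  With the
#' default configuration all inputs are simulated; supplying `*_path`
#' fields reads them from disk instead.  Given identical configuration and
#' seed, outputs are byte-identical across runs.
#'
#' @param config a list as from [default_config()], or a path to a YAML
#'   file holding one (fields merge over the defaults).
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  }
  for (p in c("scores_path", "probs_path", "network_path",
              "positives_path", "variants_path")) {
    if (!is.null(config[[p]]) && !file.exists(config[[p]]))
      stop("stage input missing: ", p, " = ", config[[p]])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  sim <- config$simulate
  outputs <- character(0)
  checksums <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <<- c(outputs, name)
    checksums[[name]] <<- unname(tools::md5sum(path))
    path
  }

  ## stage 1: scores
  if (!is.null(config$scores_path)) {
    ct <- read_scores(config$scores_path, window = config$window)
    truth <- NULL
  } else {
    arch <- list(
      SIM_RESIST = archetype_spec("resistant"),
      SIM_CHRON1 = archetype_spec("chronic"),
      SIM_MONO1 = archetype_spec("monophasic"),
      SIM_RR1 = archetype_spec("rr"),
      SIM_PROG1 = archetype_spec("progressive"),
      SIM_ARCHR1 = archetype_spec("ar_chronic"))
    gs <- gen_scores(arch, n_per_sex = sim$n_per_sex,
                     window = config$window, noise_sd = sim$noise_sd,
                     seed = sub_seed(seed, 1L))
    ct <- gs$table
    truth <- gs$truth
  }
  ct <- apply_endpoint_rules(ct)
  emit(ct$scores, "scores_preprocessed.tsv")

  ## stage 2: traits
  qtv <- derive_qtv(ct)
  emit(qtv, "qtv.tsv")
  summ <- summarize_strain(qtv)
  emit(summ, "strain_summary.tsv")

  ## stage 3: genome scan on a simulated or supplied genome
  if (!is.null(config$probs_path)) {
    gp <- read_genoprobs(config$probs_path)
  } else {
    gp <- gen_genomes(sim$n_strains, switch_prob = sim$switch_prob,
                      certainty = sim$certainty, seed = sub_seed(seed, 2L))
  }
  planted <- plant_qtl(gp, sim$qtl_marker, sim$qtl_high_founders,
                       beta = sim$qtl_beta, noise_sd = sim$qtl_noise_sd,
                       seed = sub_seed(seed, 3L))
  pheno <- planted$pheno
  pheno$value <- rank_z(pheno$value)
  kin <- switch(config$kinship,
                none = NULL,
                overall = compute_kinship(gp),
                loco = compute_kinship(gp, loco = TRUE),
                stop("kinship must be none, overall or loco"))
  scan <- scan_qtl(gp, pheno, kinship = kin)
  emit(scan, "scan.tsv")
  th <- permutation_thresholds(gp, pheno, n_perm = config$n_perm,
                               alphas = config$alphas,
                               seed = sub_seed(seed, 4L), kinship = kin)
  peaks <- find_peaks(scan, threshold = min(th))
  emit(peaks, "peaks.tsv")

  ## stage 4: prioritization on a simulated or supplied network
  if (!is.null(config$network_path)) {
    net <- read_network(config$network_path)
    positives <- readLines(config$positives_path)
    all_genes <- net$genes
    candidates <- setdiff(all_genes, positives)[
      seq_len(min(50L, length(all_genes) - length(positives)))]
    negative_pool <- setdiff(all_genes, c(positives, candidates))
  } else {
    nw <- do.call(gen_network, c(sim$network,
                                 list(seed = sub_seed(seed, 5L))))
    net <- nw$network
    positives <- nw$positives
    candidates <- c(nw$candidates_true, nw$candidates_bg)
    negative_pool <- nw$negative_pool
  }
  feats <- build_features(net, intersect(positives, net$genes),
                          genes_to_score = net$genes)
  positives_kept <- intersect(positives, rownames(feats))
  ens <- train_ensemble(feats, positives_kept,
                        intersect(negative_pool, rownames(feats)),
                        n_svm = config$n_svm, seed = sub_seed(seed, 6L))
  scores <- score_candidates(ens, feats, candidates)
  emit(scores, "prioritization.tsv")

  ## stage 5: variant filter
  if (!is.null(config$variants_path)) {
    variants <- utils::read.table(config$variants_path, header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE)
    vspec <- config$simulate$variants
  } else {
    vspec <- sim$variants
    gv <- do.call(gen_variants,
                  c(vspec[c("chrom", "lo_mb", "hi_mb", "n_rows",
                            "frac_missense", "frac_segregating")],
                    list(genes = utils::head(net$genes, 20),
                         seed = sub_seed(seed, 7L))))
    variants <- gv$variants
  }
  nssnp <- nssnp_segregating(variants, vspec$chrom, vspec$lo_mb,
                             vspec$hi_mb, "WSB", "NOD")
  emit(nssnp, "nssnp_segregating.tsv")

  manifest <- list(
    package = "eaemap",
    version = as.character(utils::packageVersion("eaemap")),
    seed = seed,
    parameters = config[c("window", "alphas", "n_perm", "n_svm", "kinship")],
    thresholds = as.list(th),
    outputs = outputs,
    checksums = checksums)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
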