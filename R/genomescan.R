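#' Eight-founder genotype probabilities for a strain panel
#'
#' Container for per-strain, per-marker founder-ancestry dosages of a
#' multiparent panel.  Each strain-marker cell holds an 8-vector of
#' nonnegative dosages over the founders (order [cc_founders]) summing
#' to 1.
#'
#' @param probs numeric array `strains x markers x 8`.
#' @param map data.frame with columns `marker`, `chrom`, `pos_Mb`;
#'   positions must be nondecreasing within a chromosome.
#' @param strains character strain labels (defaults to dimnames).
#' @return Object of class `genotype_probs`.
#' @export
genotype_probs <- function(probs, map, strains = dimnames(probs)[[1]]) {
  stopifnot(length(dim(probs)) == 3L, dim(probs)[3] == 8L,
            dim(probs)[2] == nrow(map))
  if (is.null(strains)) strains <- paste0("S", seq_len(dim(probs)[1]))
  sums <- rowSums(probs, dims = 2)
  if (any(abs(sums - 1) > 1e-6))
    stop("founder dosages must sum to 1 per strain-marker (max deviation ",
         format(max(abs(sums - 1))), ")")
  if (any(probs < -1e-12)) stop("founder dosages must be nonnegative")
  for (ch in unique(map$chrom)) {
    p <- map$pos_Mb[map$chrom == ch]
    if (is.unsorted(p)) stop("positions not nondecreasing on chromosome ", ch)
  }
  dimnames(probs) <- list(strains, map$marker, cc_founders)
  structure(list(probs = probs, map = map, strains = strains),
            class = "genotype_probs")
}

#' @export
print.genotype_probs <- function(x, ...) {
  cat(sprintf("genotype_probs: %d strains x %d markers on %d chromosome(s)\n",
              length(x$strains), nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

#' Read genotype probabilities from a wide TSV
#'
#' Expects columns `strain`, `chrom`, `pos_Mb`, `marker` and the eight
#' founder dosage columns named as in [cc_founders].
#'
#' @param path file path (tab-separated, header required).
#' @return A [genotype_probs()] object.
#' @export
read_genoprobs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(strain = "character",
                                         chrom = "character",
                                         marker = "character"))
  miss <- setdiff(c("strain", "chrom", "pos_Mb", "marker", cc_founders),
                  names(df))
  if (length(miss) > 0L)
    stop("genotype table lacks column(s): ", paste(miss, collapse = ", "))
  strains <- unique(df$strain)
  map <- unique(df[c("marker", "chrom", "pos_Mb")])
  map <- map[order(match(map$marker, df$marker)), , drop = FALSE]
  rownames(map) <- NULL
  probs <- array(NA_real_, c(length(strains), nrow(map), 8L))
  si <- match(df$strain, strains)
  mi <- match(df$marker, map$marker)
  for (f in seq_along(cc_founders))
    probs[cbind(si, mi, f)] <- df[[cc_founders[f]]]
  if (anyNA(probs)) stop("incomplete strain x marker grid in ", path)
  genotype_probs(probs, map, strains)
}

#' Write genotype probabilities to a wide TSV
#' @param gp a [genotype_probs()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genoprobs <- function(gp, path) {
  rows <- expand.grid(mi = seq_len(nrow(gp$map)),
                      si = seq_along(gp$strains))
  df <- data.frame(strain = gp$strains[rows$si],
                   chrom = gp$map$chrom[rows$mi],
                   pos_Mb = gp$map$pos_Mb[rows$mi],
                   marker = gp$map$marker[rows$mi])
  for (f in seq_along(cc_founders))
    df[[cc_founders[f]]] <- gp$probs[cbind(rows$si, rows$mi, f)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank-based inverse normal (rank-Z) transformation
#'
#' Maps values to normal quantiles of their mid-adjusted fractional ranks,
#' `qnorm((rank - 0.5)/n)`, with average ranks for ties.  The output is
#' invariant to strictly monotone transforms of the input.
#'
#' @param values numeric vector (>= 3 finite values).
#' @return Numeric vector of the same length.
#' @export
rank_z <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3L) stop("rank_z needs at least 3 finite values")
  out <- rep(NA_real_, length(values))
  v <- values[ok]
  if (length(unique(v)) == 1L) {
    warning("all values identical; rank_z returns zeros")
    out[ok] <- 0
    return(out)
  }
  n <- length(v)
  out[ok] <- stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
  out
}

#' Residualize a phenotype on experimental batch
#'
#' Least-squares residuals of the values on batch indicator columns; with
#' a single batch this is centering on the grand mean.  Residuals have
#' zero mean within every batch; a singleton batch therefore gets a zero
#' residual (warned).
#'
#' @param values numeric phenotype vector.
#' @param batch batch labels, same length.
#' @return Numeric residual vector.
#' @export
residualize_batch <- function(values, batch) {
  stopifnot(length(values) == length(batch))
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) return(values - mean(values))
  sizes <- table(batch)
  if (any(sizes == 1L))
    warning("batch(es) with a single observation get zero residuals: ",
            paste(names(sizes)[sizes == 1L], collapse = ", "))
  unname(stats::resid(stats::lm(values ~ batch)))
}

#' Genetic-relationship (kinship) matrix from founder dosages
#'
#' `K = (1/M) * sum_m D_m D_m^T` over markers, where `D_m` is the
#' strains-by-8 dosage matrix, rescaled to unit average diagonal.  With
#' `loco = TRUE` a list of per-chromosome matrices is returned, each
#' computed leaving that chromosome's markers out.
#'
#' @param gp a [genotype_probs()] object.
#' @param loco leave-one-chromosome-out?
#' @return Strain-by-strain matrix, or a named list of them if `loco`.
#' @export
compute_kinship <- function(gp, loco = FALSE) {
  kin_from <- function(markers) {
    if (length(markers) == 0L) stop("no markers available for kinship")
    D <- matrix(gp$probs[, markers, , drop = FALSE],
                nrow = length(gp$strains))
    K <- tcrossprod(D) / length(markers)
    K <- K / mean(diag(K))
    dimnames(K) <- list(gp$strains, gp$strains)
    K
  }
  if (!loco) return(kin_from(seq_len(nrow(gp$map))))
  chroms <- unique(gp$map$chrom)
  out <- lapply(chroms, function(ch) kin_from(which(gp$map$chrom != ch)))
  names(out) <- chroms
  out
}

# Fit the null variance components on an eigendecomposed kinship:
# y = mu + g + e, g ~ N(0, vg K), e ~ N(0, ve I).  Returns the rotation
# (eigenvectors), per-observation weights, and the heritability estimate.
kinship_rotation <- function(y, K) {
  ed <- eigen(K, symmetric = TRUE)
  U <- ed$vectors
  lam <- pmax(ed$values, 0)
  ys <- crossprod(U, y)
  xs <- crossprod(U, rep(1, length(y)))
  n <- length(y)
  negll <- function(h2) {
    w <- h2 * lam + (1 - h2)
    sw <- 1 / sqrt(w)
    r <- stats::lm.fit(xs * sw, ys * sw)$residuals
    s2 <- sum(r^2) / n
    0.5 * (n * log(s2) + sum(log(w)) + n)
  }
  h2 <- stats::optimize(negll, c(0, 0.99))$minimum
  w <- h2 * lam + (1 - h2)
  list(U = U, sqrtw_inv = 1 / sqrt(w), h2 = h2)
}

# Resolve phenotype input into (y, strain index into gp$strains)
resolve_pheno <- function(gp, pheno) {
  if (is.numeric(pheno) && !is.null(names(pheno)))
    pheno <- data.frame(strain = names(pheno), value = unname(pheno))
  stopifnot(all(c("strain", "value") %in% names(pheno)))
  idx <- match(pheno$strain, gp$strains)
  if (anyNA(idx))
    stop("phenotype strain(s) absent from genotypes: ",
         paste(unique(pheno$strain[is.na(idx)]), collapse = ", "))
  list(y = as.numeric(pheno$value), idx = idx)
}

# Core per-marker LOD given a response and design rows; X gains an
# intercept and founder dosage columns 2..8 (one dropped for
# identifiability); rank-deficient designs lose collinear columns via
# pivoted QR rather than failing.
lod_one_marker <- function(y, D, x0 = NULL) {
  n <- length(y)
  if (is.null(x0)) x0 <- matrix(1, n, 1)
  X <- cbind(x0, D[, -1L, drop = FALSE])
  rss0 <- sum(stats::lm.fit(x0, y)$residuals^2)
  fit <- stats::lm.fit(X, y)
  rss1 <- sum(fit$residuals^2)
  floorv <- 1e-12 * rss0
  (n / 2) * log10(max(rss0, floorv) / max(rss1, floorv))
}

#' Single-locus genome scan on founder haplotype dosages
#'
#' At each marker, contrasts the intercept-only model against the model
#' adding the 8 founder dosages (one dropped for identifiability):
#' `LOD = (n/2) * log10(RSS0 / RSS1)`.  The phenotype should already be
#' batch-residualized and rank-Z transformed where applicable.  With a
#' kinship matrix, the contrast is computed after rotating by the kinship
#' eigendecomposition with variance components estimated once under the
#' null (per chromosome when a LOCO list is supplied).
#'
#' @param gp a [genotype_probs()] object.
#' @param pheno data.frame with columns `strain` and `value` (one row per
#'   mouse or per strain), or a named numeric vector keyed by strain.
#' @param kinship optional strain-by-strain matrix from
#'   [compute_kinship()], or a per-chromosome LOCO list.
#' @return data.frame of class `scan_result`: `marker`, `chrom`, `pos_Mb`,
#'   `lod`; attributes `n` and (if kinship used) `h2`.
#' @export
scan_qtl <- function(gp, pheno, kinship = NULL) {
  rp <- resolve_pheno(gp, pheno)
  y <- rp$y; idx <- rp$idx
  n <- length(y)
  M <- nrow(gp$map)
  lod <- numeric(M)
  h2 <- NULL
  if (is.null(kinship)) {
    for (m in seq_len(M))
      lod[m] <- lod_one_marker(y, gp$probs[, m, ][idx, , drop = FALSE])
  } else if (is.matrix(kinship)) {
    rot <- kinship_rotation(y, kinship[idx, idx, drop = FALSE])
    h2 <- rot$h2
    ys <- as.vector(crossprod(rot$U, y)) * rot$sqrtw_inv
    x0 <- crossprod(rot$U, rep(1, n)) * rot$sqrtw_inv
    for (m in seq_len(M)) {
      D <- crossprod(rot$U, gp$probs[, m, ][idx, , drop = FALSE]) *
        rot$sqrtw_inv
      X <- cbind(x0, D[, -1L, drop = FALSE])
      rss0 <- sum(stats::lm.fit(x0, ys)$residuals^2)
      rss1 <- sum(stats::lm.fit(X, ys)$residuals^2)
      floorv <- 1e-12 * rss0
      lod[m] <- (n / 2) * log10(max(rss0, floorv) / max(rss1, floorv))
    }
  } else {  # LOCO list keyed by chromosome
    h2 <- numeric(0)
    for (ch in unique(gp$map$chrom)) {
      mm <- which(gp$map$chrom == ch)
      K <- kinship[[as.character(ch)]]
      if (is.null(K)) stop("no LOCO kinship for chromosome ", ch)
      rot <- kinship_rotation(y, K[idx, idx, drop = FALSE])
      h2 <- c(h2, stats::setNames(rot$h2, as.character(ch)))
      ys <- as.vector(crossprod(rot$U, y)) * rot$sqrtw_inv
      x0 <- crossprod(rot$U, rep(1, n)) * rot$sqrtw_inv
      for (m in mm) {
        D <- crossprod(rot$U, gp$probs[, m, ][idx, , drop = FALSE]) *
          rot$sqrtw_inv
        X <- cbind(x0, D[, -1L, drop = FALSE])
        rss0 <- sum(stats::lm.fit(x0, ys)$residuals^2)
        rss1 <- sum(stats::lm.fit(X, ys)$residuals^2)
        floorv <- 1e-12 * rss0
        lod[m] <- (n / 2) * log10(max(rss0, floorv) / max(rss1, floorv))
      }
    }
  }
  out <- data.frame(marker = gp$map$marker, chrom = gp$map$chrom,
                    pos_Mb = gp$map$pos_Mb, lod = pmax(lod, 0),
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  attr(out, "n") <- n
  attr(out, "h2") <- h2
  out
}

#' Genome-wide significance thresholds by phenotype permutation
#'
#' Permutes phenotype values across strain units (mouse rows move with
#' their strain, preserving within-strain replicate correlation), records
#' the genome-wide maximum LOD of each permutation, and returns the
#' `1 - alpha` quantiles.  With equal per-strain replicate counts and no
#' kinship a vectorized path reuses each marker's projection for all
#' permutations.
#'
#' @inheritParams scan_qtl
#' @param n_perm number of permutations (study convention: 1000).
#' @param alphas genome-wide error rates, each in (0, 1); the study used
#'   relaxed 0.15 and 0.20 thresholds.
#' @param seed optional integer seed for reproducible permutations.
#' @return Named numeric vector of LOD thresholds (names = alphas),
#'   with attribute `max_lods` holding the permutation null sample.
#' @export
permutation_thresholds <- function(gp, pheno, n_perm = 1000,
                                   alphas = c(0.15, 0.20), seed = NULL,
                                   kinship = NULL) {
  if (any(alphas <= 0 | alphas >= 1)) stop("alphas must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  rp <- resolve_pheno(gp, pheno)
  us <- unique(rp$idx)
  sizes <- table(factor(rp$idx, levels = us))
  equal <- length(unique(as.integer(sizes))) == 1L
  n <- length(rp$y)
  M <- nrow(gp$map)

  if (equal && is.null(kinship)) {
    ord <- order(match(rp$idx, us))
    y <- rp$y[ord]
    idx <- rp$idx[ord]
    r <- as.integer(sizes[1])
    S <- length(us)
    yblocks <- matrix(y, nrow = r, ncol = S)  # column s = strain us[s]
    Y <- matrix(0, n, n_perm)
    for (j in seq_len(n_perm))
      Y[, j] <- as.vector(yblocks[, sample.int(S), drop = FALSE])
    csY2 <- colSums(Y^2)
    rss0 <- csY2 - colSums(Y)^2 / n
    maxlod <- rep(0, n_perm)
    for (m in seq_len(M)) {
      X <- cbind(1, gp$probs[, m, ][idx, -1L, drop = FALSE])
      qx <- qr(X)
      # collinear founder columns: keep only the rank-revealing basis
      Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
      rss1 <- pmax(csY2 - colSums(crossprod(Q, Y)^2), 1e-12 * rss0)
      maxlod <- pmax(maxlod, (n / 2) * log10(rss0 / rss1))
    }
  } else {
    strains_here <- gp$strains[us]
    maxlod <- vapply(seq_len(n_perm), function(j) {
      perm <- sample(strains_here)
      ph <- data.frame(
        strain = perm[match(gp$strains[rp$idx], strains_here)],
        value = rp$y)
      max(scan_qtl(gp, ph, kinship = kinship)$lod)
    }, numeric(1))
  }
  th <- stats::quantile(maxlod, probs = 1 - alphas, names = FALSE, type = 7)
  names(th) <- as.character(alphas)
  attr(th, "max_lods") <- maxlod
  th
}

#' Founder allele effects at a marker
#'
#' Least-squares coefficients of the 8 founder dosages, reported as
#' deviations from their mean (sum-to-zero), so positive effects mark
#' founders whose alleles raise the phenotype.  A kinship matrix, if
#' supplied, is applied as in [scan_qtl()].
#'
#' @inheritParams scan_qtl
#' @param marker marker id present in `gp$map`.
#' @return Named numeric vector of 8 effects (order [cc_founders]).
#' @export
founder_effects <- function(gp, pheno, marker, kinship = NULL) {
  m <- match(marker, gp$map$marker)
  if (is.na(m)) stop("unknown marker: ", marker)
  rp <- resolve_pheno(gp, pheno)
  y <- rp$y
  D <- gp$probs[, m, ][rp$idx, , drop = FALSE]
  if (!is.null(kinship)) {
    K <- if (is.matrix(kinship)) kinship
         else kinship[[as.character(gp$map$chrom[m])]]
    rot <- kinship_rotation(y, K[rp$idx, rp$idx, drop = FALSE])
    y <- as.vector(crossprod(rot$U, y)) * rot$sqrtw_inv
    D <- crossprod(rot$U, D) * rot$sqrtw_inv
  }
  co <- stats::lm.fit(D, y)$coefficients
  co[is.na(co)] <- mean(co, na.rm = TRUE)  # collinear founders: no deviation
  eff <- co - mean(co)
  names(eff) <- cc_founders
  eff
}

#' Bayesian credible interval for a QTL peak
#'
#' Normalizes `10^LOD` over one chromosome's markers and returns the
#' smallest closed marker interval containing the peak whose normalized
#' mass reaches `prob`.  Endpoints are marker positions in Mb.
#'
#' @param lod LOD scores of one chromosome's markers (>= 2).
#' @param pos_mb corresponding positions in Mb, nondecreasing.
#' @param prob target interval mass (default 0.95).
#' @return Named numeric `c(lo, hi)` in Mb.
#' @export
credible_interval <- function(lod, pos_mb, prob = 0.95) {
  stopifnot(length(lod) == length(pos_mb), length(lod) >= 2L)
  if (diff(range(lod)) < 1e-12) {
    warning("flat LOD profile; credible interval spans the chromosome")
    return(c(lo = min(pos_mb), hi = max(pos_mb)))
  }
  w <- 10^(lod - max(lod))
  w <- w / sum(w)
  peak <- which.max(lod)
  cw <- cumsum(w)
  mass <- function(i, j) cw[j] - if (i > 1L) cw[i - 1L] else 0
  best <- c(1L, length(w)); best_width <- Inf
  for (i in seq_len(peak)) {
    for (j in peak:length(w)) {
      if (mass(i, j) >= prob) {
        width <- pos_mb[j] - pos_mb[i]
        if (width < best_width ||
            (width == best_width && (j - i) < (best[2] - best[1]))) {
          best <- c(i, j); best_width <- width
        }
        break  # larger j only widens this i's interval
      }
    }
  }
  c(lo = pos_mb[best[1]], hi = pos_mb[best[2]])
}

#' Locate QTL peaks and their credible intervals
#'
#' One row per chromosome whose maximum LOD reaches `threshold` (all
#' chromosomes if `threshold` is NULL).
#'
#' @param scan a `scan_result` from [scan_qtl()].
#' @param threshold minimum genome-wide LOD to report (e.g. a value from
#'   [permutation_thresholds()]).
#' @param prob credible-interval mass.
#' @return data.frame: `chrom`, `marker`, `pos_Mb`, `lod`, `ci_lo`, `ci_hi`.
#' @export
find_peaks <- function(scan, threshold = NULL, prob = 0.95) {
  rows <- lapply(unique(scan$chrom), function(ch) {
    s <- scan[scan$chrom == ch, , drop = FALSE]
    i <- which.max(s$lod)
    if (!is.null(threshold) && s$lod[i] < threshold) return(NULL)
    ci <- if (nrow(s) >= 2L) credible_interval(s$lod, s$pos_Mb, prob)
          else c(lo = s$pos_Mb, hi = s$pos_Mb)
    data.frame(chrom = ch, marker = s$marker[i], pos_Mb = s$pos_Mb[i],
               lod = s$lod[i], ci_lo = unname(ci["lo"]),
               ci_hi = unname(ci["hi"]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chrom = character(), marker = character(),
                      pos_Mb = numeric(), lod = numeric(),
                      ci_lo = numeric(), ci_hi = numeric())
  rownames(out) <- NULL
  out
}

#' Genotype-by-phenotype table at a marker
#'
#' Assigns each strain its maximum-dosage founder at the marker (ties
#' report all tied founders, slash-separated) and joins the strain-level
#' phenotype, sorted by phenotype, descending.
#'
#' @inheritParams founder_effects
#' @param strain_pheno data.frame with `strain` and `value` (one row per
#'   strain), or named numeric vector.
#' @return data.frame: `strain`, `founder`, `value`.
#' @export
genotype_by_phenotype <- function(gp, marker, strain_pheno) {
  m <- match(marker, gp$map$marker)
  if (is.na(m)) stop("unknown marker: ", marker)
  if (is.numeric(strain_pheno) && !is.null(names(strain_pheno)))
    strain_pheno <- data.frame(strain = names(strain_pheno),
                               value = unname(strain_pheno))
  idx <- match(strain_pheno$strain, gp$strains)
  if (anyNA(idx))
    stop("strain(s) absent from genotypes: ",
         paste(strain_pheno$strain[is.na(idx)], collapse = ", "))
  D <- gp$probs[, m, ][idx, , drop = FALSE]
  founder <- apply(D, 1, function(p) {
    top <- which(p >= max(p) - 1e-9)
    paste(cc_founders[top], collapse = "/")
  })
  out <- data.frame(strain = strain_pheno$strain, founder = founder,
                    value = strain_pheno$value, stringsAsFactors = FALSE)
  out[order(-out$value), , drop = FALSE]
}
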