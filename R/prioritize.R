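#' Tissue-specific functional gene network
#'
#' A weighted undirected gene-gene network, stored as an edge list.
#' Self-edges are rejected; weights must be finite and nonnegative.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `weight`.
#' @param tissue free tissue label (e.g. `"immune"`, `"cns"`).
#' @param genes optional full gene universe; isolated genes (no edges)
#'   are kept so downstream trimming can report them.
#' @return Object of class `gene_network`.
#' @export
gene_network <- function(edges, tissue = "unspecified", genes = NULL) {
  stopifnot(all(c("gene_a", "gene_b", "weight") %in% names(edges)))
  if (nrow(edges) > 0L) {
    if (any(edges$gene_a == edges$gene_b)) stop("self-edges are not allowed")
    if (any(!is.finite(edges$weight) | edges$weight < 0))
      stop("edge weights must be finite and nonnegative")
    key <- paste(pmin(edges$gene_a, edges$gene_b),
                 pmax(edges$gene_a, edges$gene_b))
    if (anyDuplicated(key)) stop("duplicate undirected edge(s)")
  }
  structure(list(edges = edges,
                 genes = sort(unique(c(edges$gene_a, edges$gene_b, genes))),
                 tissue = tissue),
            class = "gene_network")
}

#' Read a gene network from a 3-column edge-list TSV
#' @param path file with header columns `gene_a`, `gene_b`, `weight`.
#' @param tissue tissue label to attach.
#' @return A [gene_network()].
#' @export
read_network <- function(path, tissue = "unspecified") {
  gene_network(utils::read.table(path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE), tissue)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network (%s): %d genes, %d edges\n",
              x$tissue, length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Network connection-weight feature vectors
#'
#' The feature vector of a gene is its vector of connection weights to
#' every positive (training) gene: entry j holds the edge weight between
#' the gene and positive j, 0 if unconnected; a positive's own entry
#' against itself is 0.  Genes whose entire vector is zero carry no
#' network information and are trimmed; the trimmed labels are attached
#' as attribute `trimmed`.
#'
#' @param network a [gene_network()].
#' @param positives character vector of positive training genes (must be
#'   present in the network).
#' @param genes_to_score genes to build rows for (default: all network
#'   genes).
#' @return Numeric matrix (rows = retained genes, columns = positives)
#'   with attribute `trimmed`.
#' @export
build_features <- function(network, positives, genes_to_score = NULL) {
  stopifnot(inherits(network, "gene_network"))
  absent <- setdiff(positives, network$genes)
  if (length(absent) > 0L)
    stop("positive gene(s) absent from network: ",
         paste(absent, collapse = ", "))
  if (is.null(genes_to_score)) genes_to_score <- network$genes
  genes <- network$genes
  e <- network$edges
  ia <- match(e$gene_a, genes); ib <- match(e$gene_b, genes)
  W <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                            x = c(e$weight, e$weight),
                            dims = c(length(genes), length(genes)))
  rows <- match(genes_to_score, genes)
  known <- !is.na(rows)
  F <- matrix(0, length(genes_to_score), length(positives),
              dimnames = list(genes_to_score, positives))
  F[known, ] <- as.matrix(W[rows[known], match(positives, genes),
                            drop = FALSE])
  keep <- rowSums(F != 0) > 0
  out <- F[keep, , drop = FALSE]
  attr(out, "trimmed") <- genes_to_score[!keep]
  out
}

# oriented decision values: higher = more positive-like
decision_values <- function(model, X, flip) {
  dv <- attr(stats::predict(model, X, decision.values = TRUE),
             "decision.values")[, 1]
  if (flip) -dv else dv
}

#' Train an ensemble of linear SVMs on network features
#'
#' Each of `n_svm` rounds samples, without replacement and afresh, a set
#' of negatives matched in size to the positives, and fits a linear
#' maximum-margin classifier (cost `C = 1`, no feature scaling: connection
#' weights share one scale within a network) separating positives from the
#' sampled negatives.  Decision functions are oriented so higher values
#' mean more positive-like.
#'
#' @param features feature matrix from [build_features()] covering all
#'   genes involved.
#' @param positives positive training genes (rows of `features`).
#' @param negative_pool genes eligible as negatives; must be at least as
#'   many as the positives and disjoint from them.
#' @param n_svm ensemble size (study convention: 100).
#' @param cost SVM regularization constant.
#' @param seed optional integer seed.
#' @return Object of class `svm_ensemble`.
#' @export
train_ensemble <- function(features, positives, negative_pool, n_svm = 100,
                           cost = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  positives <- intersect(positives, rownames(features))
  negative_pool <- intersect(negative_pool, rownames(features))
  if (length(intersect(positives, negative_pool)) > 0L)
    stop("positives and negative_pool overlap")
  if (length(negative_pool) < length(positives))
    stop(sprintf("negative pool (%d) smaller than positives (%d)",
                 length(negative_pool), length(positives)))
  Xp <- features[positives, , drop = FALSE]
  k <- length(positives)
  rounds <- vector("list", n_svm)
  for (r in seq_len(n_svm)) {
    neg <- sample(negative_pool, k)
    X <- rbind(Xp, features[neg, , drop = FALSE])
    y <- factor(rep(c("pos", "neg"), each = k), levels = c("neg", "pos"))
    model <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(stats::predict(model, X, decision.values = TRUE),
               "decision.values")[, 1]
    flip <- mean(dv[y == "pos"]) < mean(dv[y == "neg"])
    dvo <- if (flip) -dv else dv
    # FPR reference set: a fresh out-of-sample draw of negatives.  Scoring
    # candidates against the round's own training negatives would be
    # anti-conservative: the margin pushes training negatives' decision
    # values down, so any unseen gene outranks them too easily.
    ref_pool <- setdiff(negative_pool, neg)
    ref <- if (length(ref_pool) >= k) sample(ref_pool, k)
           else sample(negative_pool, k)
    rounds[[r]] <- list(
      model = model, negatives = neg, ref_negatives = ref, flip = flip,
      train_acc = mean((dvo > 0) == (y == "pos")),
      neg_decision = decision_values(model,
                                     features[ref, , drop = FALSE], flip))
  }
  structure(list(rounds = rounds, positives = positives,
                 n_features = ncol(features)),
            class = "svm_ensemble")
}

#' @export
print.svm_ensemble <- function(x, ...) {
  cat(sprintf("svm_ensemble: %d rounds, %d positives, %d features; mean training accuracy %.3f\n",
              length(x$rounds), length(x$positives), x$n_features,
              mean(vapply(x$rounds, `[[`, numeric(1), "train_acc"))))
  invisible(x)
}

#' False positive rate of a candidate score against negatives
#'
#' `FPR = FP / (FP + TN)` where FP counts negatives scoring at or above
#' the candidate's score (the candidate sits on the positive side of its
#' own cutoff) and TN the rest.
#'
#' @param candidate_score scalar decision value of the candidate.
#' @param negative_scores decision values of the negative genes (nonempty).
#' @return FPR in `[0, 1]`.
#' @export
fpr <- function(candidate_score, negative_scores) {
  if (length(negative_scores) == 0L) stop("no negative scores")
  mean(negative_scores >= candidate_score)
}

#' Score positional candidate genes against a trained ensemble
#'
#' For every SVM round, each candidate's decision value is converted to an
#' FPR against the decision values of that round's out-of-sample reference
#' negatives (see [train_ensemble()]); the per-gene FPRs are
#' averaged across rounds and the final score is
#' `-log10(max(mean_fpr, floor))` with `floor = 1/(n_svm * m + 1)`
#' (`m` = negatives per round), keeping scores finite when every round
#' returns FPR 0.  Significance is `mean_fpr <= cutoff` (study cutoff
#' 0.05).  Candidates absent from the feature matrix (trimmed for lacking
#' any connection to the positives) are reported as unrankable.
#'
#' @param ensemble an [train_ensemble()] result.
#' @param features the same feature matrix used for training.
#' @param candidates character vector of candidate genes (never part of
#'   training).
#' @param cutoff significance cutoff on the mean FPR.
#' @return data.frame of class `prioritization_scores`: `gene`,
#'   `mean_fpr`, `final_score`, `significant`, `unrankable`; the per-round
#'   FPR matrix is attached as attribute `fpr_matrix`.
#' @export
score_candidates <- function(ensemble, features, candidates, cutoff = 0.05) {
  stopifnot(inherits(ensemble, "svm_ensemble"))
  overlap <- intersect(candidates, ensemble$positives)
  if (length(overlap) > 0L)
    stop("candidate(s) were used in training: ",
         paste(overlap, collapse = ", "))
  rankable <- intersect(candidates, rownames(features))
  unrankable <- setdiff(candidates, rankable)
  n_svm <- length(ensemble$rounds)
  m <- length(ensemble$positives)
  fprs <- matrix(NA_real_, length(rankable), n_svm,
                 dimnames = list(rankable, NULL))
  if (length(rankable) > 0L) {
    Xc <- features[rankable, , drop = FALSE]
    for (r in seq_len(n_svm)) {
      rd <- ensemble$rounds[[r]]
      dvc <- decision_values(rd$model, Xc, rd$flip)
      neg <- rd$neg_decision
      fprs[, r] <- vapply(dvc, function(s) mean(neg >= s), numeric(1))
    }
  }
  mean_fpr <- rowMeans(fprs)
  floorv <- 1 / (n_svm * m + 1)
  out <- data.frame(
    gene = c(rankable, unrankable),
    mean_fpr = c(mean_fpr, rep(NA_real_, length(unrankable))),
    final_score = c(-log10(pmax(mean_fpr, floorv)),
                    rep(NA_real_, length(unrankable))),
    significant = c(mean_fpr <= cutoff, rep(FALSE, length(unrankable))),
    unrankable = c(rep(FALSE, length(rankable)),
                   rep(TRUE, length(unrankable))),
    stringsAsFactors = FALSE)
  out <- out[match(candidates, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("prioritization_scores", "data.frame")
  attr(out, "fpr_matrix") <- fprs
  attr(out, "fpr_floor") <- floorv
  attr(out, "aggregation") <- "-log10(mean over SVMs of FPR)"
  out
}

#' Overlap of QTL genes with reference gene lists via an orthology map
#'
#' Translates mouse QTL genes to human symbols through the supplied
#' two-column orthology table and intersects them with each reference
#' list.
#'
#' @param qtl_genes data.frame with columns `qtl` and `gene` (mouse
#'   symbols).
#' @param ref_lists named list of character vectors of human gene symbols.
#' @param orthology data.frame with columns `mouse`, `human`.
#' @return data.frame: `qtl`, `mouse_gene`, `human_gene`, `list`.
#' @export
overlap_gene_lists <- function(qtl_genes, ref_lists, orthology) {
  stopifnot(all(c("qtl", "gene") %in% names(qtl_genes)),
            all(c("mouse", "human") %in% names(orthology)))
  merged <- merge(qtl_genes, orthology, by.x = "gene", by.y = "mouse")
  rows <- lapply(names(ref_lists), function(nm) {
    hit <- merged[merged$human %in% ref_lists[[nm]], , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    data.frame(qtl = hit$qtl, mouse_gene = hit$gene, human_gene = hit$human,
               list = nm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(qtl = character(), mouse_gene = character(),
                      human_gene = character(), list = character())
  out[order(out$list, out$qtl, out$mouse_gene), , drop = FALSE]
}

#' Nonsynonymous variants segregating between two founders in an interval
#'
#' Keeps variant rows whose consequence is nonsynonymous/missense, whose
#' alleles differ between the two named founders, whose position lies in
#' the closed Mb interval, and (optionally) whose gene is in a subset.
#'
#' @param variants data.frame with columns `chrom`, `pos_Mb`, `gene`,
#'   `consequence` and one allele column per founder ([cc_founders]).
#' @param chrom chromosome label of the interval.
#' @param lo_mb,hi_mb interval bounds in Mb (closed).
#' @param founder_a,founder_b founder labels whose alleles must differ.
#' @param genes optional gene subset.
#' @return The filtered rows of `variants`.
#' @export
nssnp_segregating <- function(variants, chrom, lo_mb, hi_mb,
                              founder_a, founder_b, genes = NULL) {
  for (f in c(founder_a, founder_b))
    if (!f %in% names(variants))
      stop("unknown founder label: ", f)
  cons <- tolower(variants$consequence)
  keep <- cons %in% c("missense", "missense_variant", "nonsynonymous",
                      "nonsynonymous_variant") &
    variants$chrom == chrom &
    variants$pos_Mb >= lo_mb & variants$pos_Mb <= hi_mb &
    variants[[founder_a]] != variants[[founder_b]]
  if (!is.null(genes)) keep <- keep & variants$gene %in% genes
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
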