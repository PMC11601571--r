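test_that("feature vectors are connection weights to positives, trimmed", {
  edges <- data.frame(gene_a = c("p1", "p2", "c1"),
                      gene_b = c("p2", "c1", "b1"),
                      weight = c(0.7, 0.4, 0.2))
  net <- gene_network(edges, genes = c("iso1"))
  F <- build_features(net, positives = c("p1", "p2"))
  expect_equal(unname(F["p1", ]), c(0, 0.7))
  expect_equal(unname(F["p1", "p1"]), 0)       # self-weight is zero
  expect_equal(unname(F["c1", ]), c(0, 0.4))
  expect_false("b1" %in% rownames(F))          # no edge to any positive
  expect_true(all(c("b1", "iso1") %in% attr(F, "trimmed")))
  expect_error(build_features(net, c("p1", "nope")), "nope")
})

test_that("trim report equals a brute-force connectivity scan", {
  set.seed(11)
  nw <- gen_network(n_genes = 200, module_size = 30, density = 0.02,
                    in_density = 0.5, n_bg_candidates = 10, seed = 12)
  F <- build_features(nw$network, nw$positives)
  # brute force: a gene survives iff it has an edge to some positive
  e <- nw$network$edges
  touch <- union(e$gene_b[e$gene_a %in% nw$positives],
                 e$gene_a[e$gene_b %in% nw$positives])
  survivors <- intersect(nw$network$genes, touch)
  expect_setequal(rownames(F), survivors)
  expect_setequal(attr(F, "trimmed"),
                  setdiff(nw$network$genes, survivors))
})

test_that("gene_network rejects malformed edge lists", {
  expect_error(gene_network(data.frame(gene_a = "a", gene_b = "a",
                                       weight = 1)), "self-edges")
  expect_error(gene_network(data.frame(gene_a = "a", gene_b = "b",
                                       weight = -1)), "nonnegative")
  expect_error(gene_network(data.frame(gene_a = c("a", "b"),
                                       gene_b = c("b", "a"),
                                       weight = 1)), "duplicate")
})

test_that("fpr counts ties on the positive side and matches brute force", {
  expect_equal(fpr(10, 1:9), 0)
  expect_equal(fpr(0, 1:9), 1)
  neg <- c(1, 2, 3, 5, 5, 5, 7, 8, 9, 10)
  expect_equal(fpr(5, c(5, 5, 5, 1, 2, 3, 4, 4, 4, 4)), 0.3)
  set.seed(13)
  for (i in 1:300) {
    cand <- rnorm(1); negs <- rnorm(sample(3:40, 1))
    fp <- 0; tn <- 0
    for (v in negs) if (v >= cand) fp <- fp + 1 else tn <- tn + 1
    expect_identical(fpr(cand, negs), fp / (fp + tn))
  }
  # nonincreasing step function of the candidate score
  negs <- rnorm(25)
  grid <- sort(rnorm(60))
  vals <- vapply(grid, fpr, numeric(1), negative_scores = negs)
  expect_true(all(diff(vals) <= 0))
  # invariant under strictly monotone joint transforms
  for (i in 1:50) {
    a <- runif(1, 0.1, 3); b <- rnorm(1)
    f <- function(x) a * x + b
    g <- function(x) exp(a * x)
    expect_equal(fpr(cand, negs), fpr(f(cand), f(negs)))
    expect_equal(fpr(cand, negs), fpr(g(cand), g(negs)))
  }
})

test_that("ensemble separates a linearly separable fixture perfectly", {
  set.seed(14)
  pos <- paste0("p", 1:20); negpool <- paste0("n", 1:60)
  F <- rbind(matrix(runif(20 * 5, 2, 3), 20, 5),
             matrix(runif(60 * 5, 0, 1), 60, 5))
  rownames(F) <- c(pos, negpool)
  ens <- train_ensemble(F, pos, negpool, n_svm = 10, seed = 15)
  accs <- vapply(ens$rounds, `[[`, numeric(1), "train_acc")
  expect_equal(accs, rep(1, 10))
  expect_error(train_ensemble(F, pos, negpool[1:5], n_svm = 5),
               "smaller")
})

test_that("a shuffled-label fixture generalizes at chance", {
  set.seed(16)
  n <- 80
  F <- matrix(rnorm(2 * n * 10), 2 * n, 10)
  rownames(F) <- paste0("g", seq_len(2 * n))
  pos <- rownames(F)[1:n]           # labels carry no feature information
  ens <- train_ensemble(F, pos[1:40], rownames(F)[81:160][1:60],
                        n_svm = 20, seed = 17)
  # held-back genes: 40 "positives" and 40 pool genes never trained on
  held_pos <- pos[41:80]
  held_neg <- rownames(F)[141:160]
  acc <- mean(vapply(ens$rounds, function(rd) {
    dp <- eaemap:::decision_values(rd$model, F[held_pos, ], rd$flip)
    dn <- eaemap:::decision_values(rd$model, F[held_neg, ], rd$flip)
    mean(c(dp > 0, dn <= 0))
  }, numeric(1)))
  expect_gt(acc, 0.3); expect_lt(acc, 0.7)
})

test_that("candidate scoring flags planted-module genes and reconstructs scores", {
  nw <- gen_network(n_genes = 400, module_size = 50, w_in_mean = 1,
                    w_bg_mean = 0.1, density = 0.02, in_density = 0.6,
                    n_bg_candidates = 25, seed = 18)
  F <- build_features(nw$network, nw$positives)
  pos <- intersect(nw$positives, rownames(F))
  ens <- train_ensemble(F, pos, intersect(nw$negative_pool, rownames(F)),
                        n_svm = 25, seed = 19)
  cands <- c(nw$candidates_true, nw$candidates_bg)
  sc <- score_candidates(ens, F, cands)
  expect_error(score_candidates(ens, F, c(cands, pos[1])), "training")
  planted <- sc$gene %in% nw$candidates_true & !sc$unrankable
  bg <- sc$gene %in% nw$candidates_bg & !sc$unrankable
  expect_gt(mean(sc$final_score[planted]), mean(sc$final_score[bg]))
  expect_gt(mean(sc$significant[planted]), 0.9)
  # final score reconstructs from the per-round FPR matrix with the floor
  fm <- attr(sc, "fpr_matrix")
  fl <- attr(sc, "fpr_floor")
  rank_genes <- sc$gene[!sc$unrankable]
  expect_equal(sc$final_score[!sc$unrankable],
               unname(-log10(pmax(rowMeans(fm)[rank_genes], fl))))
  expect_equal(sc$significant[!sc$unrankable],
               unname(rowMeans(fm)[rank_genes] <= 0.05))
  # background-connectivity-only candidates sit near FPR 0.5
  expect_gt(mean(sc$mean_fpr[bg]), 0.2)
  # unrankable candidates are reported, not dropped
  iso <- setdiff(attr(F, "trimmed"), nw$positives)[1]
  sc2 <- score_candidates(ens, F, c(cands[1], iso))
  expect_true(sc2$unrankable[sc2$gene == iso])
  expect_true(is.na(sc2$final_score[sc2$gene == iso]))
})

test_that("gene-list overlap intersects through the orthology map", {
  qtl_genes <- data.frame(qtl = c("Q1", "Q1", "Q2"),
                          gene = c("Abcc4", "Gpc6", "Yap1"))
  orth <- data.frame(mouse = c("Abcc4", "Gpc6", "Yap1"),
                     human = c("ABCC4", "GPC6", "YAP1"))
  out <- overlap_gene_lists(qtl_genes,
                            list(risk = c("GPC6", "YAP1"),
                                 severity = "ABCC4",
                                 empty = "ZZZ9"),
                            orth)
  expect_equal(nrow(out), 3L)
  expect_setequal(out$list[out$qtl == "Q1"], c("risk", "severity"))
  none <- overlap_gene_lists(qtl_genes, list(l = "NOPE"), orth)
  expect_equal(nrow(none), 0L)
})

test_that("nonsynonymous segregation filter applies all four conditions", {
  gv <- gen_variants("9", 4.04, 11.82, c("Yap1", "Birc3", "Dync2h1"),
                     n_rows = 60, frac_missense = 0.4,
                     frac_segregating = 0.5, seed = 20)
  v <- gv$variants
  out <- nssnp_segregating(v, "9", 4.04, 11.82, "WSB", "NOD")
  expect_equal(nrow(out), gv$truth$n_qualifying)
  expect_true(all(out$WSB != out$NOD))
  # same alleles everywhere -> empty
  v2 <- v; v2$NOD <- v2$WSB
  expect_equal(nrow(nssnp_segregating(v2, "9", 4.04, 11.82, "WSB", "NOD")), 0L)
  # synonymous only -> empty
  v3 <- v; v3$consequence <- "synonymous_variant"
  expect_equal(nrow(nssnp_segregating(v3, "9", 4.04, 11.82, "WSB", "NOD")), 0L)
  # gene subset and closed interval bounds
  one <- nssnp_segregating(v, "9", 4.04, 11.82, "WSB", "NOD",
                           genes = "Birc3")
  expect_true(all(one$gene == "Birc3"))
  expect_error(nssnp_segregating(v, "9", 4, 12, "WSB", "XXX"), "unknown")
})
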