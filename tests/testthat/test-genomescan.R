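test_that("rank-Z matches closed-form quantiles and handles ties", {
  expect_equal(rank_z(c(1, 2, 3)),
               qnorm(c(1, 3, 5) / 6), tolerance = 1e-12)
  # rank invariance under a monotone transform
  x <- c(0.3, 5, 2, 11, 7)
  expect_equal(rank_z(x), rank_z(exp(x)))
  # tied minima share the averaged rank
  z <- rank_z(c(1, 1, 4))
  expect_equal(z[1], z[2])
  expect_warning(zz <- rank_z(rep(2, 5)), "identical")
  expect_equal(zz, rep(0, 5))
  expect_error(rank_z(c(1, 2)), "at least 3")
})

test_that("batch residualization zeroes batch means", {
  v <- c(10, 10, 20, 20)
  b <- c("a", "a", "b", "b")
  expect_equal(residualize_batch(v, b), rep(0, 4))
  expect_equal(residualize_batch(c(1, 2, 3), rep("a", 3)),
               c(-1, 0, 1))
  set.seed(5)
  v2 <- rnorm(30); b2 <- sample(c("a", "b", "c"), 30, replace = TRUE)
  r <- residualize_batch(v2, b2)
  for (lev in unique(b2))
    expect_lt(abs(sum(r[b2 == lev])), 1e-8)
})

test_that("kinship is a rescaled dosage cross-product with expected structure", {
  # identical strains: off-diagonal equals diagonal
  map <- data.frame(marker = c("m1", "m2"), chrom = "1", pos_Mb = c(1, 2))
  p <- array(0, c(2, 2, 8)); p[, , 1] <- 1
  K <- compute_kinship(genotype_probs(p, map, c("s1", "s2")))
  expect_equal(K[1, 2], K[1, 1])
  # disjoint fixed founders: off-diagonal zero
  p2 <- array(0, c(2, 2, 8)); p2[1, , 1] <- 1; p2[2, , 2] <- 1
  K2 <- compute_kinship(genotype_probs(p2, map, c("s1", "s2")))
  expect_equal(K2[1, 2], 0)
  # random panel: symmetric PSD with unit average diagonal
  gp <- gen_genomes(15, data.frame(chrom = c("1", "2"), n_markers = 30,
                                   length_Mb = 50),
                    certainty = 0.9, seed = 31)
  K3 <- compute_kinship(gp)
  expect_equal(K3, t(K3))
  expect_gte(min(eigen(K3, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_equal(mean(diag(K3)), 1)
  Kl <- compute_kinship(gp, loco = TRUE)
  expect_named(Kl, c("1", "2"))
})

test_that("scan LOD equals the independent two-regression oracle", {
  gp <- gen_genomes(12, data.frame(chrom = "1", n_markers = 5,
                                   length_Mb = 40),
                    certainty = 0.85, seed = 17)
  set.seed(18)
  pheno <- data.frame(strain = gp$strains, value = rnorm(12))
  s <- scan_qtl(gp, pheno)
  expect_equal(s$lod, lod_oracle(gp, pheno), tolerance = 1e-8)
  # affine transforms of the phenotype leave LOD unchanged
  s2 <- scan_qtl(gp, transform(pheno, value = 3 * value - 7))
  expect_equal(s$lod, s2$lod, tolerance = 1e-8)
})

test_that("perfect genetic signal peaks at the causal marker, capped not infinite", {
  gp <- gen_genomes(20, data.frame(chrom = "1", n_markers = 10,
                                   length_Mb = 40),
                    switch_prob = 0.3, certainty = 0.9, seed = 23)
  m <- 5L
  pheno <- data.frame(strain = gp$strains,
                      value = gp$probs[, m, ] %*% c(1:8))
  s <- scan_qtl(gp, pheno)
  expect_equal(which.max(s$lod), m)
  expect_true(is.finite(max(s$lod)))
})

test_that("mouse-level phenotypes expand by strain and tolerate collinearity", {
  gp <- gen_genomes(10, data.frame(chrom = "1", n_markers = 4,
                                   length_Mb = 10),
                    certainty = 1, seed = 41)  # one-hot: rank-deficient
  set.seed(42)
  pheno <- data.frame(strain = rep(gp$strains, each = 3),
                      value = rnorm(30))
  s <- scan_qtl(gp, pheno)
  expect_equal(attr(s, "n"), 30L)
  expect_true(all(is.finite(s$lod)) && all(s$lod >= 0))
})

test_that("permutation thresholds are seeded, monotone, and block-exchange exact", {
  gp <- gen_genomes(12, data.frame(chrom = c("1", "2"), n_markers = 8,
                                   length_Mb = 30),
                    certainty = 0.9, seed = 51)
  set.seed(52)
  pheno <- data.frame(strain = rep(gp$strains, each = 2), value = rnorm(24))
  th <- permutation_thresholds(gp, pheno, n_perm = 60, seed = 1)
  th_again <- permutation_thresholds(gp, pheno, n_perm = 60, seed = 1)
  expect_identical(th, th_again)
  expect_gte(th[["0.15"]], th[["0.2"]])
  expect_error(permutation_thresholds(gp, pheno, n_perm = 5, alphas = 1.2),
               "alphas")

  # the vectorized path's first permutation equals an explicit scan of the
  # block-permuted phenotype
  th1 <- permutation_thresholds(gp, pheno, n_perm = 1, alphas = 0.5,
                                seed = 99)
  set.seed(99)
  perm <- sample.int(12)
  yb <- matrix(pheno$value, nrow = 2)           # columns = strains, in order
  pheno_perm <- pheno
  pheno_perm$value <- as.vector(yb[, perm])
  expect_equal(unname(attr(th1, "max_lods")),
               max(scan_qtl(gp, pheno_perm)$lod), tolerance = 1e-10)
})

test_that("strain-permutation slow path is exercised for unequal replicates", {
  gp <- gen_genomes(8, data.frame(chrom = "1", n_markers = 6,
                                  length_Mb = 20),
                    certainty = 0.9, seed = 61)
  set.seed(62)
  pheno <- data.frame(strain = rep(gp$strains, times = c(2, 3, 2, 2, 3, 2,
                                                         2, 2)),
                      value = rnorm(18))
  th <- permutation_thresholds(gp, pheno, n_perm = 30, seed = 2)
  expect_true(all(is.finite(th)) && all(th > 0))
  expect_gte(th[["0.15"]], th[["0.2"]])
})

test_that("founder effects recover planted shifts under sum-to-zero", {
  # constant phenotype: all effects zero
  gp <- gen_genomes(24, data.frame(chrom = "1", n_markers = 3,
                                   length_Mb = 10),
                    certainty = 1, seed = 71)
  ph0 <- data.frame(strain = gp$strains, value = rep(2, 24))
  expect_equal(unname(founder_effects(gp, ph0, gp$map$marker[1])),
               rep(0, 8))

  # balanced one-hot panel, one founder's carriers shifted by +delta
  map <- data.frame(marker = "m1", chrom = "1", pos_Mb = 1)
  p <- array(0, c(24, 1, 8))
  f <- rep(1:8, each = 3)
  for (i in 1:24) p[i, 1, f[i]] <- 1
  gpb <- genotype_probs(p, map)
  delta <- 4
  ph <- data.frame(strain = gpb$strains,
                   value = 10 + delta * (f == 8))
  eff <- founder_effects(gpb, ph, "m1")
  expect_equal(unname(eff["WSB"]), delta * 7 / 8, tolerance = 1e-8)
  expect_equal(unname(eff["AJ"]), -delta / 8, tolerance = 1e-8)
  expect_equal(sum(eff), 0, tolerance = 1e-10)
})

test_that("planted WSB/NZO-high NOD-low contrast yields the right sign pattern", {
  gp <- gen_genomes(40, data.frame(chrom = "1", n_markers = 20,
                                   length_Mb = 60),
                    switch_prob = 0.15, certainty = 0.95, seed = 81)
  pq <- plant_qtl(gp, gp$map$marker[10], c("WSB", "NZO"), beta = 3,
                  noise_sd = 0.3, seed = 82)
  eff <- founder_effects(gp, pq$pheno, gp$map$marker[10])
  expect_gt(eff[["WSB"]], 0)
  expect_gt(eff[["NZO"]], 0)
  expect_lt(eff[["NOD"]], 0)
  expect_gt(min(eff[["WSB"]], eff[["NZO"]]), eff[["NOD"]])
})

test_that("credible interval matches brute-force smallest-mass search", {
  # dominant single peak: interval within flanking markers
  lod <- c(0.01, 0.02, 9, 0.02, 0.01)
  pos <- c(2, 4, 6, 8, 10)
  ci <- credible_interval(lod, pos)
  expect_gte(ci[["lo"]], 4); expect_lte(ci[["hi"]], 8)

  expect_warning(ci_flat <- credible_interval(rep(1, 5), pos), "flat")
  expect_equal(unname(ci_flat), c(2, 10))

  set.seed(91)
  for (i in 1:25) {
    lod <- c(runif(10, 0, 2), runif(1, 3, 6), runif(9, 0, 2))
    pos <- sort(runif(20, 0, 100))
    expect_equal(unname(credible_interval(lod, pos)), ci_oracle(lod, pos))
  }
})

test_that("genotype-by-phenotype assigns argmax founders and reports ties", {
  map <- data.frame(marker = "m1", chrom = "1", pos_Mb = 5)
  p <- array(0, c(3, 1, 8))
  p[1, 1, 8] <- 1                      # WSB
  p[2, 1, 4] <- 1                      # NOD
  p[3, 1, c(1, 2)] <- 0.5              # tie AJ/B6
  gp <- genotype_probs(p, map, c("sA", "sB", "sC"))
  tab <- genotype_by_phenotype(gp, "m1",
                               c(sA = 80, sB = 10, sC = 40))
  expect_equal(tab$founder[tab$strain == "sA"], "WSB")
  expect_equal(tab$founder[tab$strain == "sC"], "AJ/B6")
  expect_equal(tab$strain, c("sA", "sC", "sB"))  # sorted by phenotype
})

test_that("kinship-corrected scans stay finite and find strong signals", {
  gp <- gen_genomes(30, data.frame(chrom = c("1", "2"), n_markers = 25,
                                   length_Mb = 60),
                    switch_prob = 0.15, certainty = 0.95, seed = 95)
  pq <- plant_qtl(gp, "m1_013", "CAST", beta = 3, h2_poly = 0.3,
                  noise_sd = 0.5, seed = 96)
  K <- compute_kinship(gp)
  s <- scan_qtl(gp, pq$pheno, kinship = K)
  expect_true(all(is.finite(s$lod)) && all(s$lod >= 0))
  peak <- s$marker[which.max(s$lod)]
  expect_equal(s$chrom[s$marker == peak], "1")
  Kl <- compute_kinship(gp, loco = TRUE)
  sl <- scan_qtl(gp, pq$pheno, kinship = Kl)
  expect_true(all(is.finite(sl$lod)))
  expect_equal(sl$chrom[which.max(sl$lod)], "1")
})
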