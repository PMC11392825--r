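test_that("Reich estimator equals an independent per-locus transcription", {
  set.seed(91)
  n <- 10; L <- 1000   # 1000 random count configurations
  a1 <- matrix(sample(1:2, n * L, TRUE), n, L)
  a2 <- matrix(sample(1:2, n * L, TRUE), n, L)
  miss <- matrix(runif(n * L) < 0.15, n, L)
  a1[miss] <- NA; a2[miss] <- NA
  g <- toy_genotypes(a1, a2, locality = rep(c("A", "B"), each = 5))
  est <- reich_fst(g, min_samples = 4)
  ca <- counts_by_locality(g, "A"); cb <- counts_by_locality(g, "B")
  expect_equal(est$fst["A", "B"], reich_brute(ca$a, ca$n, cb$a, cb$n))
  expect_equal(est$fst, t(est$fst))
  expect_equal(unname(diag(est$fst)), c(0, 0))
})

test_that("Reich estimator hits the boundary cases", {
  # fixed opposite alleles at every locus -> F_ST = 1
  g1 <- toy_genotypes(matrix(rep(c(2L, 1L), each = 3), 6, 20),
                      matrix(rep(c(2L, 1L), each = 3), 6, 20),
                      locality = rep(c("A", "B"), each = 3))
  expect_equal(reich_fst(g1, min_samples = 3)$fst["A", "B"], 1)
  # identical allele frequencies -> estimate near 0
  co <- simulate_cohort_genotypes(
    demographic_model(n_demes = 2, deme_size = 1000, migration_rate = 0.49,
                      n_loci = 3000, n_samples_per_deme = 8,
                      inbreeding_f = 0, missing_rate = 0, seed = 14))
  expect_lt(abs(reich_fst(co$genotypes)$fst[1, 2]), 0.02)
  # localities under the 4-sample floor are excluded
  g2 <- toy_genotypes(matrix(1L, 9, 5), matrix(2L, 9, 5),
                      locality = rep(c("A", "B", "C"), c(4, 4, 1)))
  expect_equal(reich_fst(g2)$localities, c("A", "B"))
  expect_error(reich_fst(g2[1:5, ]), "at least two localities")
})

test_that("F_ST is invariant to allele label swapping per locus", {
  co <- simulate_cohort_genotypes(
    demographic_model(n_demes = 2, n_loci = 300, n_samples_per_deme = 6,
                      missing_rate = 0.05, seed = 15))
  g <- co$genotypes
  f0 <- reich_fst(g)$fst
  swap <- sample(ncol(g$a1), 150)
  g$a1[, swap] <- 3L - g$a1[, swap]
  g$a2[, swap] <- 3L - g$a2[, swap]
  expect_equal(reich_fst(g)$fst, f0)
})

test_that("island-model simulations recover the closed-form F_ST", {
  target <- 0.10
  m_rate <- (1 / target - 1) / 4000       # 1/(1+4Nm) = 0.10 at N = 1000
  ests <- vapply(1:8, function(r) {
    co <- simulate_cohort_genotypes(
      demographic_model(n_demes = 2, deme_size = 1000,
                        migration_rate = m_rate, n_loci = 1500,
                        n_samples_per_deme = 10, inbreeding_f = 0,
                        missing_rate = 0, seed = 500 + r))
    reich_fst(co$genotypes)$fst[1, 2]
  }, numeric(1))
  ci <- mean(ests) + c(-1, 1) * qt(0.975, 7) * sd(ests) / sqrt(8)
  expect_gt(target, ci[1]); expect_lt(target, ci[2])
})

test_that("F_ST standardization is the elementwise F/(1-F)", {
  expect_equal(standardize_fst(matrix(c(0, 0.5, 0.5, 0), 2)),
               matrix(c(0, 1, 1, 0), 2))
  expect_equal(standardize_fst(matrix(c(0, 0.2, 0.2, 0), 2))[1, 2], 0.25)
  expect_error(standardize_fst(matrix(c(0, 1, 1, 0), 2)), "undefined")
  # negative unbiased estimates pass through un-clipped
  expect_lt(standardize_fst(matrix(c(0, -0.01, -0.01, 0), 2))[1, 2], 0)
})

test_that("haversine distances use the great-circle closed form", {
  meta <- data.frame(locality_id = c("a", "b", "c"),
                     latitude = c(0, 0, 45), longitude = c(0, 180, -90))
  d <- haversine_matrix(meta)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(d["a", "b"], pi * 6371.0088, tolerance = 1e-6) # antipodal
  expect_equal(d, t(d))
  expect_error(haversine_matrix(data.frame(locality_id = "x",
                                           latitude = 91, longitude = 0)),
               "out of range")
})

test_that("Mantel test is exact on proportional matrices and label-stable", {
  set.seed(5)
  d1 <- matrix(runif(49), 7, 7); d1 <- d1 + t(d1); diag(d1) <- 0
  dimnames(d1) <- list(letters[1:7], letters[1:7])
  mt <- mantel_test(d1, 2 * d1, n_permutations = 999, seed = 2)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 1000)
  # consistent relabelling of both matrices leaves r unchanged
  p <- sample(7)
  mt2 <- mantel_test(d1[p, p], (2 * d1)[p, p], n_permutations = 99, seed = 2)
  expect_equal(mt2$r, 1)
  expect_error(mantel_test(d1, matrix(1, 7, 7,
                                      dimnames = dimnames(d1)), 99),
               "constant")
})

test_that("Mantel r agrees with vegan's statistic on random matrices", {
  skip_if_not_installed("vegan")
  set.seed(8)
  a <- matrix(runif(64), 8, 8); a <- a + t(a); diag(a) <- 0
  b <- matrix(runif(64), 8, 8); b <- b + t(b); diag(b) <- 0
  dimnames(a) <- dimnames(b) <- list(LETTERS[1:8], LETTERS[1:8])
  ours <- mantel_test(a, b, n_permutations = 999, seed = 3)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic))
  expect_lt(abs(ours$p - ref$signif), 0.1)
})

test_that("genotype PCA separates demes and orders variance", {
  co <- simulate_cohort_genotypes(
    demographic_model(n_demes = 3, deme_size = 1000,
                      migration_rate = (1 / 0.15 - 1) / 4000,
                      n_loci = 600, n_samples_per_deme = 8,
                      inbreeding_f = 0, missing_rate = 0, seed = 16))
  pc <- pca_genotypes(co$genotypes, n_components = 3)
  expect_true(all(diff(pc$explained) <= 1e-12))
  xy <- pc$scores[, 1:2]
  dem <- co$genotypes$samples$locality
  centroids <- apply(xy, 2, tapply, dem, mean)
  within <- unlist(lapply(unique(dem), function(d)
    sqrt(rowSums((xy[dem == d, ] -
                    matrix(centroids[d, ], sum(dem == d), 2,
                           byrow = TRUE))^2))))
  between <- dist(centroids)
  expect_gt(min(between), quantile(within, 0.95))
  # duplicated sample lands on coincident coordinates
  g2 <- co$genotypes[c(1, 1, 2:24), ]
  g2$samples$sample_id <- sprintf("S%03d", 1:25)
  pc2 <- pca_genotypes(g2, n_components = 2)
  expect_equal(pc2$scores[1, ], pc2$scores[2, ], ignore_attr = TRUE)
})

test_that("PCA truncates gracefully beyond the matrix rank", {
  g <- toy_genotypes(matrix(sample(1:2, 4 * 30, TRUE), 4, 30),
                     matrix(sample(1:2, 4 * 30, TRUE), 4, 30))
  expect_warning(pc <- pca_genotypes(g, n_components = 10), "rank")
  expect_lte(ncol(pc$scores), 4)
})

test_that("inbreeding summary reproduces the published locality table", {
  tbl <- read_inbreeding_table(table1_path())
  s <- summarize_inbreeding(tbl)
  expect_equal(s$n_localities, 22L)
  expect_equal(s$min, 0.17)
  expect_equal(s$max, 0.45)
  expect_length(s$flagged, 22)                      # all strictly above 0.1
  # strict "above" at the threshold; clean tables raise no flags
  s2 <- summarize_inbreeding(data.frame(locality_id = 1:3,
                                        inbreeding_coefficient =
                                          c(0.1, 0.05, 0.05)))
  expect_length(s2$flagged, 0)
  expect_error(summarize_inbreeding(
    data.frame(locality_id = 1, inbreeding_coefficient = 1.2)), "0, 1")
})

test_that("stepping-stone cohorts show isolation by distance", {
  hits <- 0L
  for (r in 1:10) {
    co <- simulate_cohort_genotypes(
      demographic_model(n_demes = 6, deme_size = 1000, migration_rate = 0.005,
                        n_loci = 400, n_samples_per_deme = 4,
                        inbreeding_f = 0, missing_rate = 0,
                        structure = "stepping_stone", seed = 700 + r))
    fst <- reich_fst(co$genotypes, min_samples = 4)
    d <- haversine_matrix(co$meta)[fst$localities, fst$localities]
    mt <- mantel_test(d, standardize_fst(fst), n_permutations = 199,
                      seed = r)
    if (mt$r > 0 && mt$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
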