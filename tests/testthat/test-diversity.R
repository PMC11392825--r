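test_that("windowed multiallelic ratios follow the two-allele/two-sample rule", {
  n <- 13; L <- 100
  a1 <- matrix(1L, n, L); a2 <- matrix(1L, n, L)
  # locus 1: allele 2 in two samples -> multiallelic
  a1[1:2, 1] <- 2L
  # locus 2: allele 2 in one sample only -> not multiallelic
  a1[1, 2] <- 2L
  # locus 3: covered by a single sample -> excluded from the denominator
  a1[2:n, 3] <- NA; a2[2:n, 3] <- NA
  g <- toy_genotypes(a1, a2, pos = seq_len(L) * 50L)  # one 10-kb window
  w <- multiallelic_window_ratios(g, "samuelis", subsample = 13, seed = 1)
  expect_equal(nrow(w), 1L)
  expect_equal(w$covered_positions, 99L)
  expect_equal(w$multiallelic_count, 1L)
  expect_equal(w$ratio, 1 / 99)
  # ratio invariant under allele relabelling and sample reordering
  g2 <- g; g2$a1 <- 3L - g2$a1; g2$a2 <- 3L - g2$a2
  expect_equal(multiallelic_window_ratios(g2, "x", subsample = 13,
                                          seed = 1)$ratio, w$ratio)
  g3 <- g[rev(seq_len(n)), ]
  expect_equal(multiallelic_window_ratios(g3, "x", subsample = 13,
                                          seed = 1)$ratio, w$ratio)
  expect_error(multiallelic_window_ratios(g, "fridayi", subsample = 14),
               "fridayi")
})

test_that("per-window subsets are fresh but seed-reproducible", {
  co <- simulate_cohort_genotypes(
    demographic_model(n_demes = 1, n_loci = 400, n_samples_per_deme = 20,
                      missing_rate = 0, seed = 19))
  w1 <- multiallelic_window_ratios(co$genotypes, "s", subsample = 13, seed = 4)
  w2 <- multiallelic_window_ratios(co$genotypes, "s", subsample = 13, seed = 4)
  expect_identical(w1, w2)
  expect_gt(nrow(w1), 1)
})

test_that("single-sample bi-allelic ratio applies the depth floor", {
  a1 <- matrix(1L, 1, 10)
  a2 <- matrix(c(2L, 2L, 2L, rep(1L, 7)), 1, 10)     # 3 het calls
  depth <- matrix(c(rep(10L, 8), 4L, 4L), 1, 10)
  g <- toy_genotypes(a1, a2, depth = depth)
  expect_equal(single_sample_biallelic_ratio(g, "S01", min_depth = 5),
               3 / 8)
  # all-homozygous sample
  g2 <- toy_genotypes(a1, a1, depth = depth)
  expect_equal(single_sample_biallelic_ratio(g2, "S01", min_depth = 5), 0)
  # depth exactly 4 everywhere under the >4 rule: nothing qualifies
  g3 <- toy_genotypes(a1, a2, depth = matrix(4L, 1, 10))
  expect_warning(r <- single_sample_biallelic_ratio(g3, "S01", min_depth = 5),
                 "no position")
  expect_true(is.na(r))
})

test_that("pair matching honours the year and distance constraints", {
  cand <- data.frame(sample_a = c("k1", "k2", "k3"),
                     sample_b = c("k1b", "k2b", "k3b"),
                     year_gap = c(1, 0, 1), distance = c(150, 150, 250),
                     ratio = c(0.01, 0.02, 0.03))
  other <- data.frame(sample_a = "m1", sample_b = "m2", year_gap = 1,
                      distance = 100, ratio = 0.015)
  m <- match_pairs(other, cand)
  expect_equal(m$karner_a, "k1")     # only candidate meeting both rules
  # distance exactly 2d is eligible ("up to twice")
  m2 <- match_pairs(other, data.frame(sample_a = "k", sample_b = "kb",
                                      year_gap = 2, distance = 200,
                                      ratio = 0.01))
  expect_equal(nrow(m2), 1L)
  # a year gap of y - 1 is not
  m3 <- match_pairs(other, data.frame(sample_a = "k", sample_b = "kb",
                                      year_gap = 0, distance = 150,
                                      ratio = 0.01))
  expect_equal(nrow(m3), 0L)
  expect_equal(attr(m3, "dropped"), 1L)
  # tie-break: minimize |distance - d|, then lexicographic ids
  tie <- data.frame(sample_a = c("kb", "ka", "kc"),
                    sample_b = c("x", "x", "x"),
                    year_gap = c(2, 2, 2), distance = c(120, 120, 180),
                    ratio = 0.01)
  expect_equal(match_pairs(other, tie)$karner_a, "ka")
})

test_that("paired one-sided t-test matches the closed form", {
  res <- paired_one_sided_test(c(0.3, 0.5, 0.7), c(0.2, 0.3, 0.4))
  expect_equal(res$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$t, 3.4641, tolerance = 1e-4)
  expect_equal(res$p, pt(res$t, df = 2, lower.tail = FALSE))
  expect_equal(res$p, 0.0371, tolerance = 1e-3)
  expect_equal(res$n, 3L)
  expect_error(paired_one_sided_test(c(1, 2), c(0.5, 1.5)), "zero-variance")
  expect_error(paired_one_sided_test(1, 1), "equal length|two pairs")
})

# Window tables for three species: `base` counts everywhere, with planted
# windows at `low`/`high` counts for the focal/comparison species.
loss_fixture <- function(n_win = 40, covered = 5000, base = 50,
                         planted = c(10, 25), low = 0, high = 150) {
  mk <- function(sp, counts)
    data.frame(species = sp, contig = "ctg1",
               window_start = (seq_len(n_win) - 1) * 10000,
               covered_positions = covered, multiallelic_count = counts,
               ratio = counts / covered)
  k <- rep(base, n_win); k[planted] <- low
  m <- rep(base * 1.3, n_win); m[planted] <- high
  rbind(mk("samuelis", k), mk("melissa", m), mk("fridayi", m))
}

test_that("loss-of-diversity windows require the three-way conjunction", {
  w <- loss_fixture()
  res <- loss_of_diversity_windows(w, alpha = 0.01)
  expect_equal(which(res$flag), c(10L, 25L))
  # the flag matches exact binomial tails against each genome-wide mean
  gm <- sum(w$multiallelic_count[w$species == "samuelis"]) /
    sum(w$covered_positions[w$species == "samuelis"])
  expect_equal(res$p_samuelis[10], pbinom(0, 5000, gm))
  # elevation in only one comparison species is not enough
  w2 <- loss_fixture()
  w2$multiallelic_count[w2$species == "fridayi"] <- 65  # flat everywhere
  expect_false(any(loss_of_diversity_windows(w2, alpha = 0.01)$flag))
  # everything at its genome mean: nothing flagged
  w3 <- loss_fixture(planted = integer(0))
  expect_false(any(loss_of_diversity_windows(w3, alpha = 0.01)$flag))
})

test_that("gene overlap uses padded spans with the 70% rule", {
  regions <- data.frame(contig = "ctg1", window_start = c(0, 10000))
  genes <- data.frame(contig = "ctg1", start = 2000, end = 8000,
                      gene_id = "g1")
  # 6-kb gene padded to [0, 10000): fully inside the flagged window
  hit <- genes_in_regions(genes, regions[1, ], pad = 2000)
  expect_equal(hit$gene_id, "g1")
  expect_equal(hit$overlap_fraction, 1)
  # 12-kb gene padded to 16 kb overlapping one 10-kb window: 62.5% < 70%
  g2 <- data.frame(contig = "ctg1", start = 10000, end = 22000,
                   gene_id = "g2")
  expect_equal(nrow(genes_in_regions(g2, regions[2, ], pad = 2000)), 0L)
  # padding truncated at the contig start shrinks the denominator
  g3 <- data.frame(contig = "ctg1", start = 0, end = 6000, gene_id = "g3")
  hit3 <- genes_in_regions(g3, regions[1, ], pad = 2000)
  expect_equal(hit3$overlap_fraction, 1)
  expect_error(genes_in_regions(
    data.frame(contig = "c", start = 5, end = 5, gene_id = "bad"),
    regions), "line 1")
})
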