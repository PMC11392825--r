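# Small alignment: 10 samples per group over `pat` columns given as strings.
aln_fixture <- function(cols_a, cols_b) {
  stopifnot(length(cols_a) == length(cols_b))
  m <- matrix(NA_character_, 20, length(cols_a),
              dimnames = list(c(sprintf("a%02d", 1:10),
                                sprintf("b%02d", 1:10)), NULL))
  for (j in seq_along(cols_a)) {
    m[1:10, j] <- strsplit(cols_a[j], "")[[1]]
    m[11:20, j] <- strsplit(cols_b[j], "")[[1]]
  }
  m[m == "."] <- NA
  m
}
grp_a <- sprintf("a%02d", 1:10)
grp_b <- sprintf("b%02d", 1:10)

test_that("good positions need strict presence in both groups", {
  m <- aln_fixture(c("AAAAA.....", "AAAAAAAAAA", "....AAAAAA", ".........."),
                   c("AAAAAAAAAA", "AAAA......", "AAAAAAAAAA", ".........."))
  # col 1: 50%/100% in; col 2: 100%/40% out (strict >); col 3: 60%/100% in;
  # col 4: fully missing out
  expect_equal(good_positions(m, grp_a, grp_b, presence = 0.40), c(1L, 3L))
  expect_error(good_positions(m, character(0), grp_b), "non-empty")
})

test_that("divergent positions need >70% distinct consensus in both groups", {
  pan <- protein_panel(
    list(p1 = aln_fixture(
      c("AAAAAAAAGG",    # A 8/10 in group a
        "AAAAAAGGGG",    # A 6/10: below the consensus bar
        "AAAAAAAAAA",    # same consensus in both groups
        "AAAAAGGGGG"),   # 5/5 tie: not divergent
      c("GGGGGGGGGA", "GGGGGGGGGG", "AAAAAAAAAA", "GGGGGGGGGG"))),
    setNames(rep(c("x", "y"), each = 10), c(grp_a, grp_b)))
  div <- protein_divergence(pan, grp_a, grp_b, min_good = 0)
  expect_equal(div$good_positions, 4L)
  expect_equal(div$divergent_positions, 1L)
  expect_equal(div$divergence, 0.25)
})

test_that("protein selection demands above-average divergence in all pairs", {
  rec <- function(v) data.frame(protein_id = paste0("p", seq_along(v)),
                                divergence = v)
  records <- list(rec(c(0.05, 0.01, 0.01)),   # mean 0.0233: p1 above
                  rec(c(0.04, 0.03, 0.01)),   # mean 0.0267: p1, p2 above
                  rec(c(0.05, 0.02, 0.01)))   # mean 0.0267: p1 above
  expect_equal(select_diverged_proteins(records), "p1")
  # above average in only 2 of 3 comparisons is not enough
  records2 <- records; records2[[3]]$divergence <- c(0.01, 0.05, 0.02)
  expect_equal(select_diverged_proteins(records2), character(0))
  # all-equal divergences: nothing is strictly above the mean
  flat <- replicate(3, rec(c(0.02, 0.02, 0.02)), simplify = FALSE)
  expect_equal(select_diverged_proteins(flat), character(0))
})

test_that("SAV screen applies its four criteria with the stated boundaries", {
  pan <- simulate_protein_panel(
    n_proteins = 2, lengths = 60,
    n_samples_per_species = c(samuelis = 20, melissa = 20, fridayi = 20),
    planted_savs = data.frame(protein = 1, position = c(5, 40)), seed = 6)
  # prevalence exactly 95% is inclusive
  pan$alignments$prot001[1, 5] <- "A"        # 19/20 = 0.95 focal 'P'
  # focal residue at exactly 5% of a comparison species is still a candidate
  pan$alignments$prot001[21, 40] <- "P"      # 1/20 melissa
  sav <- find_sav_candidates(pan)
  expect_setequal(sav$position, c(5L, 40L))
  # ... but above the 5% cap it is rejected
  pan$alignments$prot001[22, 40] <- "P"      # 2/20 = 10%
  expect_equal(find_sav_candidates(pan)$position, 5L)
  # and below 95% prevalence it is rejected
  pan$alignments$prot001[2, 5] <- "A"        # 18/20 = 0.90
  expect_equal(nrow(find_sav_candidates(pan)), 0L)
})

test_that("SAV screen skips positions failing the coverage floors", {
  pan <- simulate_protein_panel(
    n_proteins = 1, lengths = 30,
    n_samples_per_species = c(samuelis = 20, melissa = 13),
    planted_savs = data.frame(protein = 1, position = 3), seed = 7)
  # comparison species called in only 5 samples: needs more than
  # max(5, 20% of 13) = 5
  pan$alignments$prot001[26:33, 3] <- NA
  sav <- find_sav_candidates(pan)
  expect_equal(nrow(sav), 0L)
  expect_gte(attr(sav, "skipped_low_coverage"), 1L)
  # focal coverage at exactly 50% also fails (strict >)
  pan2 <- simulate_protein_panel(
    n_proteins = 1, lengths = 30,
    n_samples_per_species = c(samuelis = 20, melissa = 13),
    planted_savs = data.frame(protein = 1, position = 3), seed = 7)
  pan2$alignments$prot001[1:10, 3] <- NA
  expect_equal(nrow(find_sav_candidates(pan2)), 0L)
})

test_that("SAV screen recovers plants and is monotone and order-stable", {
  plants <- data.frame(protein = rep(1:4, each = 10),
                       position = rep(seq(10, 100, 10), 4))
  pan <- simulate_protein_panel(n_proteins = 5, lengths = 120,
                                planted_savs = plants, seed = 8)
  sav <- find_sav_candidates(pan)
  expect_equal(nrow(sav), 40L)                        # recall 1
  expect_equal(anti <- nrow(merge(sav, data.frame(
    protein_id = sprintf("prot%03d", plants$protein),
    position = plants$position))), 40L)               # precision 1
  # under 10% missingness recall stays >= 0.95
  pan_miss <- simulate_protein_panel(n_proteins = 5, lengths = 120,
                                     planted_savs = plants,
                                     missing_rate = 0.10, seed = 9)
  expect_gte(nrow(find_sav_candidates(pan_miss)), 38L)
  # tightening thresholds never adds candidates
  n95 <- nrow(find_sav_candidates(pan_miss, prevalence = 0.95))
  n99 <- nrow(find_sav_candidates(pan_miss, prevalence = 0.99))
  ncap <- nrow(find_sav_candidates(pan_miss, max_other_freq = 0.01))
  expect_lte(n99, n95)
  expect_lte(ncap, n95)
  # sample order is irrelevant
  perm <- sample(nrow(pan$alignments[[1]]))
  pan_perm <- protein_panel(lapply(pan$alignments,
                                   function(m) m[perm, , drop = FALSE]),
                            pan$species)
  expect_equal(find_sav_candidates(pan_perm), sav,
               ignore_attr = TRUE)
})

test_that("burial classification is strict at the 25% RSA cutoff", {
  expect_equal(classify_burial(c(0.30, 0.25, 0.10, NA)),
               c(FALSE, TRUE, TRUE, NA))
  expect_error(classify_burial(1.2), "0, 1")
})

test_that("term enrichment computes exact binomial tails", {
  bg <- sprintf("p%03d", 1:100)
  sel <- bg[1:10]
  tm <- data.frame(protein_id = c(bg[1:5], bg[11:15]), term = "T1")
  res <- enrich_terms(sel, bg, tm)
  # independent tail arithmetic from factorials
  tail_exact <- sum(vapply(5:10, function(k)
    choose(10, k) * 0.1^k * 0.9^(10 - k), numeric(1)))
  expect_equal(res$p_value, tail_exact)
  expect_equal(res$p_value, 1.63e-3, tolerance = 2e-3)
  # equal frequency in selection and background: clearly non-significant
  tm2 <- data.frame(protein_id = c(bg[1:5], bg[11:55]), term = "T2")
  expect_gte(enrich_terms(sel, bg, tm2)$p_value, 0.3)
  # selected == background reduces to the enumeration oracle at small n
  bg8 <- bg[1:8]
  tm3 <- data.frame(protein_id = bg8[1:3], term = "T3")
  res3 <- enrich_terms(bg8, bg8, tm3)
  enum <- sum(vapply(3:8, function(k)
    choose(8, k) * (3 / 8)^k * (5 / 8)^(8 - k), numeric(1)))
  expect_equal(res3$p_value, enum)
  expect_error(enrich_terms(c(sel, "zzz"), bg, tm), "subset")
  expect_warning(enrich_terms(sel, bg, rbind(
    tm, data.frame(protein_id = "zzz", term = "orphan"))), "orphan")
})

test_that("protein panels round-trip through per-protein FASTA", {
  pan <- simulate_protein_panel(n_proteins = 2, lengths = 40,
                                missing_rate = 0.1, seed = 10)
  dir <- withr::local_tempdir()
  files <- write_protein_panel(pan, dir)
  back <- read_protein_panel(files, pan$species)
  expect_equal(back$alignments, pan$alignments)
})
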