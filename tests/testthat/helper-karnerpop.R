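# Shared fixtures and independent oracles, built in code.

# A reference string of the given length (period-4, so substitutions are easy
# to reason about).
ref_seq <- function(len) paste(rep_len(c("A", "C", "G", "T"), len),
                               collapse = "")

# Substitute positions `at` of `s` with a different fixed base.
mutate_at <- function(s, at, to = NULL) {
  x <- strsplit(s, "")[[1]]
  for (p in at) x[p] <- if (is.null(to)) setdiff(c("A", "C", "G", "T"),
                                                 x[p])[1] else to
  paste(x, collapse = "")
}

# Build a genotype_matrix from bare allele matrices.
toy_genotypes <- function(a1, a2, depth = NULL, locality = NULL,
                          pos = NULL, contig = "ctg1") {
  n <- nrow(a1); L <- ncol(a1)
  if (is.null(depth)) depth <- matrix(20L, n, L)
  if (is.null(locality)) locality <- rep("L01", n)
  if (is.null(pos)) pos <- seq_len(L) * 100L
  genotype_matrix(a1, a2, depth,
                  data.frame(contig = contig, pos = pos),
                  data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                             locality = locality))
}

# ---- Independent literal transcription of Protocol A -----------------------
# Written directly from the procedure's prose, with naive data handling, as
# an oracle for the packaged implementation.
protoA_oracle <- function(reads, reference, window_size = 30,
                          step = window_size) {
  count_mm <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    sum(x != y & x != "N" & y != "N")
  }
  bad_ids <- c()
  for (ctg in unique(reads$contig)) {
    rr <- reads[reads$contig == ctg, ]
    clen <- nchar(reference[[ctg]])
    for (ws in seq(0, clen - window_size, by = step)) {
      we <- ws + window_size
      inwin <- rr[rr$start <= ws &
                    rr$start + nchar(rr$sequence) >= we, ]
      if (nrow(inwin) == 0) next
      qwin <- substr(reference[[ctg]], ws + 1, we)
      wseq <- substr(inwin$sequence, ws - inwin$start + 1, we - inwin$start)
      mm <- mapply(count_mm, wseq, qwin)
      # rank by identity high to low, ties by read id
      o <- order(mm, inwin$read_id)
      wseq <- wseq[o]; mm <- mm[o]; ids <- inwin$read_id[o]
      cluster_of <- rep(NA_integer_, length(ids))
      firsts <- c()
      for (i in seq_along(ids)) {
        assigned <- NA
        for (cl in seq_along(firsts)) {
          if (count_mm(wseq[i], wseq[firsts[cl]]) <= 1) { assigned <- cl; break }
        }
        if (is.na(assigned)) { firsts <- c(firsts, i); assigned <- length(firsts) }
        cluster_of[i] <- assigned
      }
      sizes <- tabulate(cluster_of)
      avg <- vapply(seq_along(firsts),
                    function(cl) mean(mm[cluster_of == cl]), numeric(1))
      is_good <- sizes >= max(sizes) / 2 & avg <= min(avg) + 2
      if (sum(is_good) <= 2) {
        bad_ids <- c(bad_ids, ids[!is_good[cluster_of]])
      } else {
        bad_ids <- c(bad_ids, ids)
      }
    }
  }
  reads[!(reads$read_id %in% bad_ids), ]
}

# Random small window fixture for oracle-equivalence checks: up to 8 reads
# spanning a single 30-bp window, with 0-4 random substitutions each.
random_window_reads <- function(seed) {
  set.seed(seed)
  ref <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
  n <- sample.int(8, 1)
  seqs <- vapply(seq_len(n), function(i) {
    k <- sample(0:4, 1)
    if (k == 0) ref else mutate_at(ref, sample.int(30, k))
  }, "")
  list(reads = read_set(sprintf("r%02d", seq_len(n)), "c", 0L, seqs),
       reference = c(c = ref))
}

# ---- Independent transcription of the Reich/Hudson-type estimator ----------
# Scalar per-locus arithmetic, summed explicitly.
reich_brute <- function(a1, n1, a2, n2) {
  num_sum <- den_sum <- 0
  for (l in seq_along(a1)) {
    if (n1[l] < 2 || n2[l] < 2) next
    h1 <- a1[l] * (n1[l] - a1[l]) / (n1[l] * (n1[l] - 1))
    h2 <- a2[l] * (n2[l] - a2[l]) / (n2[l] * (n2[l] - 1))
    N <- (a1[l] / n1[l] - a2[l] / n2[l])^2 - h1 / n1[l] - h2 / n2[l]
    num_sum <- num_sum + N
    den_sum <- den_sum + N + h1 + h2
  }
  num_sum / den_sum
}

# Count derived alleles / called chromosomes per locality from a matrix.
counts_by_locality <- function(g, loc) {
  rows <- g$samples$locality == loc
  a1 <- g$a1[rows, , drop = FALSE]; a2 <- g$a2[rows, , drop = FALSE]
  list(a = colSums(a1 == 2L, na.rm = TRUE) + colSums(a2 == 2L, na.rm = TRUE),
       n = 2 * colSums(!is.na(a1)))
}

# Random sample-pair tables for the matched-pair machinery. Ratios are
# binomial counts over `npos` positions at rate `rate`.
random_pairs <- function(n, rate, npos = 5000, dist_range = c(50, 500),
                        year_range = 0:5, prefix = "p") {
  data.frame(sample_a = sprintf("%s%03da", prefix, seq_len(n)),
             sample_b = sprintf("%s%03db", prefix, seq_len(n)),
             year_gap = sample(year_range, n, replace = TRUE),
             distance = runif(n, dist_range[1], dist_range[2]),
             ratio = rbinom(n, npos, rate) / npos)
}

table1_path <- function() {
  system.file("extdata", "locality_inbreeding.tsv", package = "karnerpop")
}
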