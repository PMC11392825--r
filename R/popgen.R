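#' Reich's small-sample F_ST estimator between localities
#'
#' Pairwise F_ST suited to few individuals per population. For one locus
#' with derived-allele counts `a1, a2` out of `n1, n2` sampled chromosomes,
#' the per-locus components are
#' \deqn{N = (a_1/n_1 - a_2/n_2)^2 - h_1/n_1 - h_2/n_2, \quad
#'       D = N + h_1 + h_2,}
#' with \eqn{h_i = a_i (n_i - a_i) / (n_i (n_i - 1))}, and the pair's
#' estimate is the ratio of sums `sum(N) / sum(D)` across loci. Loci missing
#' in either locality of a pair (fewer than 2 called chromosomes) are
#' skipped for that pair; localities with fewer than `min_samples` sampled
#' individuals are excluded entirely. Estimates may dip slightly below zero
#' (unbiasedness is preserved; no clipping).
#'
#' @param g a [genotype_matrix()] with bi-allelic codes 1/2.
#' @param min_samples minimum individuals per locality (default 4).
#' @return A list of class `fst_matrix`: `fst` (symmetric matrix, zero
#'   diagonal), `n_loci` (loci used per pair) and `localities`.
#' @export
reich_fst <- function(g, min_samples = 4) {
  tab <- table(g$samples$locality)
  localities <- names(tab)[tab >= min_samples]
  if (length(localities) < 2)
    stop("need at least two localities with >= ", min_samples, " samples")
  L <- ncol(g$a1)
  # per-locality derived counts and called chromosomes at each locus
  a <- n <- matrix(0, length(localities), L,
                   dimnames = list(localities, NULL))
  for (k in seq_along(localities)) {
    rows <- g$samples$locality == localities[k]
    a1 <- g$a1[rows, , drop = FALSE]; a2 <- g$a2[rows, , drop = FALSE]
    a[k, ] <- colSums(a1 == 2L, na.rm = TRUE) + colSums(a2 == 2L, na.rm = TRUE)
    n[k, ] <- 2 * colSums(!is.na(a1))
  }
  m <- length(localities)
  fst <- matrix(0, m, m, dimnames = list(localities, localities))
  nl <- matrix(0L, m, m, dimnames = list(localities, localities))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    use <- n[i, ] >= 2 & n[j, ] >= 2
    a1 <- a[i, use]; n1 <- n[i, use]; a2 <- a[j, use]; n2 <- n[j, use]
    h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
    h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
    num <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
    den <- num + h1 + h2
    fst[i, j] <- fst[j, i] <- sum(num) / sum(den)
    nl[i, j] <- nl[j, i] <- sum(use)
  }
  structure(list(fst = fst, n_loci = nl, localities = localities),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat(sprintf("fst_matrix: %d localities (Reich estimator)\n",
              length(x$localities)))
  print(round(x$fst, 4))
  invisible(x)
}

#' Linearized F_ST for isolation-by-distance analysis
#'
#' Applies the monotone transform `F / (1 - F)` elementwise (diagonal stays
#' zero). Defined for `F < 1`; slightly negative unbiased estimates pass
#' through unchanged in sign.
#'
#' @param f an `fst_matrix` or a plain numeric matrix.
#' @return Numeric matrix of standardized values.
#' @export
standardize_fst <- function(f) {
  m <- if (inherits(f, "fst_matrix")) f$fst else as.matrix(f)
  if (any(m >= 1)) stop("F/(1-F) undefined for F >= 1")
  out <- m / (1 - m)
  diag(out) <- 0
  out
}

#' Great-circle distance matrix between localities
#'
#' Haversine distances (IUGG mean Earth radius 6371.0088 km) between the
#' localities of a metadata table; each locality's coordinates are taken
#' from its first record.
#'
#' @param meta metadata data.frame with `locality_id`, `latitude`,
#'   `longitude` (see [read_cohort_meta()]).
#' @param radius_km Earth radius in km.
#' @return Symmetric matrix of distances in km with locality dimnames.
#' @export
haversine_matrix <- function(meta, radius_km = 6371.0088) {
  if (any(abs(meta$latitude) > 90) || any(abs(meta$longitude) > 180))
    stop("coordinates out of range")
  first <- !duplicated(meta$locality_id)
  loc <- meta[first, c("locality_id", "longitude", "latitude")]
  d <- geosphere::distm(loc[, c("longitude", "latitude")],
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2,
                                                   r = radius_km * 1000))
  d <- d / 1000
  dimnames(d) <- list(loc$locality_id, loc$locality_id)
  d
}

#' Mantel permutation test for matrix association
#'
#' Pearson correlation of the upper off-diagonal triangles of two labelled
#' distance matrices, with a one-sided (positive association) permutation
#' null obtained by simultaneously permuting the rows and columns of the
#' second matrix. The p-value follows the add-one rule
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_permutations)`.
#'
#' @param d1,d2 symmetric matrices with matching dimnames (size >= 3).
#' @param n_permutations number of permutations (default 9999).
#' @param seed integer seed for reproducible permutations.
#' @return A list of class `mantel_result` with `r`, `p`, `n_permutations`
#'   and `seed`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 9999, seed = NULL) {
  if (!is.null(dimnames(d2)) && !is.null(dimnames(d1)))
    d2 <- d2[rownames(d1), rownames(d1)]
  n <- nrow(d1)
  if (n < 3) stop("need at least 3 localities")
  ut <- upper.tri(d1)
  x <- d1[ut]; y <- d2[ut]
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant matrix: correlation undefined")
  r <- cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  id <- seq_len(n)
  for (b in seq_len(n_permutations)) {
    p <- sample.int(n)
    while (identical(p, id)) p <- sample.int(n) # identity carries no signal
    if (cor(x, d2[p, p][ut]) >= r) hits <- hits + 1L
  }
  structure(list(r = r, p = (1 + hits) / (1 + n_permutations),
                 n_permutations = n_permutations, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, one-sided p = %.4g (%d permutations)\n",
              x$r, x$p, x$n_permutations))
  invisible(x)
}

#' PCA of genotype dosages
#'
#' Samples x loci dosage matrix (copies of allele code 2), missing entries
#' imputed with the locus mean, centered and scaled by
#' `sqrt(p * (1 - p))` of the locus allele frequency (smartpca-style
#' normalization). Monomorphic loci are dropped.
#'
#' @param g a [genotype_matrix()].
#' @param locus_set optional locus indices (e.g. the `pca` profile of
#'   [select_loci()]).
#' @param n_components components to return; truncated with a warning if the
#'   matrix rank is lower.
#' @return A list with `scores` (samples x components), `explained`
#'   (fractions of variance, non-increasing) and `sdev`.
#' @export
pca_genotypes <- function(g, locus_set = NULL, n_components = 10) {
  if (!is.null(locus_set)) g <- g[, locus_set]
  dos <- (g$a1 == 2L) + (g$a2 == 2L)
  mu <- colMeans(dos, na.rm = TRUE)
  for (j in which(colSums(is.na(dos)) > 0)) dos[is.na(dos[, j]), j] <- mu[j]
  p <- mu / 2
  keep <- p > 0 & p < 1
  dos <- dos[, keep, drop = FALSE]
  z <- scale(dos, center = TRUE, scale = sqrt(p[keep] * (1 - p[keep])))
  pc <- prcomp(z, center = FALSE)
  rank <- sum(pc$sdev > 1e-8)
  if (n_components > rank) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncating")
    n_components <- rank
  }
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)],
       sdev = pc$sdev[seq_len(n_components)])
}

#' Summarize per-locality inbreeding coefficients
#'
#' Reports the range (rounded to two decimals) and the localities whose
#' coefficient is strictly above the "high inbreeding" threshold.
#'
#' @param tbl data.frame with `locality_id` and `inbreeding_coefficient` in
#'   `[0, 1]` (see [read_inbreeding_table()]).
#' @param threshold flag localities strictly above this value (default 0.1).
#' @return List with `min`, `max` (2-decimal rounded), `n_localities` and
#'   `flagged` (character vector of locality ids).
#' @export
summarize_inbreeding <- function(tbl, threshold = 0.1) {
  f <- tbl$inbreeding_coefficient
  if (!length(f)) stop("empty inbreeding table")
  if (any(f < 0 | f > 1)) stop("inbreeding coefficients must lie in [0, 1]")
  list(min = round(min(f), 2), max = round(max(f), 2),
       n_localities = nrow(tbl),
       flagged = as.character(tbl$locality_id[f > threshold]))
}
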