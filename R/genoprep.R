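#' Per-sample genotype completeness
#'
#' Completeness is the fraction of loci with a called genotype,
#' `present / (present + missing)`; samples at or below the threshold are
#' flagged for exclusion. A literal present-to-missing odds ratio is
#' available via `mode = "odds"`.
#'
#' @param g a [genotype_matrix()].
#' @param threshold completeness cutoff; samples are kept iff completeness is
#'   strictly above it.
#' @param mode `"fraction"` (default) or `"odds"` (present / missing).
#' @return data.frame with `sample_id`, `completeness` and logical `keep`.
#' @export
sample_completeness <- function(g, threshold = 0.30,
                                mode = c("fraction", "odds")) {
  mode <- match.arg(mode)
  if (!nrow(g$a1) || !ncol(g$a1)) stop("empty genotype matrix")
  present <- rowSums(!is.na(g$a1))
  total <- ncol(g$a1)
  comp <- if (mode == "fraction") present / total
          else present / pmax(total - present, 1)
  data.frame(sample_id = g$samples$sample_id, completeness = comp,
             keep = comp > threshold, row.names = NULL)
}

# Samples carrying each allele at each locus: list of named counts.
allele_sample_counts <- function(g, j) {
  ok <- !is.na(g$a1[, j])
  if (!any(ok)) return(integer(0))
  a1 <- g$a1[ok, j]; a2 <- g$a2[ok, j]
  alleles <- sort(unique(c(a1, a2)))
  setNames(vapply(alleles, function(al) sum(a1 == al | a2 == al), integer(1)),
           alleles)
}

#' Select loci for PCA or STRUCTURE input
#'
#' A bi-allelic locus is kept iff (1) the fraction of samples covered at
#' depth strictly above 2 strictly exceeds the profile's coverage fraction
#' (0.75 for `pca`, 0.50 for `structure`), and (2) both alleles are each
#' carried by more than four samples (>= 5).
#'
#' @param g a [genotype_matrix()] with depth.
#' @param profile `"pca"` or `"structure"`.
#' @param min_coverage override of the profile coverage fraction.
#' @param min_allele_samples minimum samples per allele (default 5,
#'   i.e. "more than four").
#' @return Integer vector of locus indices with attribute `profile`.
#' @export
select_loci <- function(g, profile = c("pca", "structure"),
                        min_coverage = NULL, min_allele_samples = 5) {
  profile <- match.arg(profile)
  if (is.null(min_coverage))
    min_coverage <- switch(profile, pca = 0.75, structure = 0.50)
  n <- nrow(g$a1)
  keep <- logical(ncol(g$a1))
  for (j in seq_len(ncol(g$a1))) {
    if (mean(g$depth[, j] > 2, na.rm = TRUE) <= min_coverage) next
    cnt <- allele_sample_counts(g, j)
    keep[j] <- length(cnt) == 2 && all(cnt >= min_allele_samples)
  }
  structure(which(keep), profile = profile)
}

#' Select loci for BA3-SNPs inbreeding estimation
#'
#' Keeps loci where (1) every locality has at least two called samples,
#' (2) the locus carries at least two different alleles, and (3) any two
#' kept loci on the same contig are more than `min_spacing` bp apart
#' (left-to-right greedy scan per contig; loci on different contigs always
#' satisfy spacing).
#'
#' @param g a [genotype_matrix()].
#' @param min_spacing minimum spacing in bp (default 50 kb).
#' @return Integer vector of locus indices; empty with a warning when no
#'   locus qualifies.
#' @export
select_ba3_loci <- function(g, min_spacing = 50000) {
  localities <- unique(g$samples$locality)
  ok <- logical(ncol(g$a1))
  for (j in seq_len(ncol(g$a1))) {
    called <- !is.na(g$a1[, j])
    per_loc <- vapply(localities,
                      function(l) sum(called & g$samples$locality == l),
                      integer(1))
    if (any(per_loc < 2)) next
    ok[j] <- length(unique(c(g$a1[called, j], g$a2[called, j]))) >= 2
  }
  idx <- which(ok)
  kept <- integer(0)
  for (contig in unique(g$loci$contig[idx])) {
    ji <- idx[g$loci$contig[idx] == contig]
    ji <- ji[order(g$loci$pos[ji])]
    last <- -Inf
    for (j in ji) {
      if (g$loci$pos[j] - last > min_spacing) {
        kept <- c(kept, j)
        last <- g$loci$pos[j]
      }
    }
  }
  kept <- sort(kept)
  if (!length(kept)) warning("no locus satisfies the BA3 criteria")
  kept
}
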