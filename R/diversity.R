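#' Windowed multiallelic-locus ratios with per-window subsampling
#'
#' For each 10-kb window, a fresh seeded random subset of `subsample`
#' individuals is drawn (equalizing sample size across species). Positions
#' covered (called) in fewer than two subset samples are excluded from the
#' denominator. A position counts as multiallelic iff it carries at least
#' two alleles, each observed in at least two subset samples.
#'
#' @param g a [genotype_matrix()] for one species.
#' @param species species label used in the output and error messages.
#' @param window_size window width in bp (default 10 kb).
#' @param subsample individuals drawn per window (default 13).
#' @param seed integer seed; subsets are reproducible given the seed.
#' @param unit `"window"` (default: fresh subset per window) or `"cohort"`
#'   (one subset reused for all windows).
#' @return data.frame (`species`, `contig`, `window_start`,
#'   `covered_positions`, `multiallelic_count`, `ratio`).
#' @export
multiallelic_window_ratios <- function(g, species = "unknown",
                                       window_size = 10000, subsample = 13,
                                       seed = 1,
                                       unit = c("window", "cohort")) {
  unit <- match.arg(unit)
  n <- nrow(g$a1)
  if (n < subsample)
    stop("species '", species, "' has ", n, " samples; need ", subsample)
  set.seed(seed)
  fixed_subset <- sample.int(n, subsample)
  win <- floor(g$loci$pos / window_size) * window_size
  key <- paste(g$loci$contig, win)
  out <- list()
  for (k in unique(key)) {
    j <- which(key == k)
    rows <- if (unit == "window") sample.int(n, subsample) else fixed_subset
    a1 <- g$a1[rows, j, drop = FALSE]; a2 <- g$a2[rows, j, drop = FALSE]
    called <- colSums(!is.na(a1))
    covered <- called >= 2
    multi <- vapply(seq_along(j), function(jj) {
      if (!covered[jj]) return(FALSE)
      x1 <- a1[, jj]; x2 <- a2[, jj]
      ok <- !is.na(x1)
      alleles <- unique(c(x1[ok], x2[ok]))
      if (length(alleles) < 2) return(FALSE)
      carriers <- vapply(alleles, function(al)
        sum((x1 == al | x2 == al)[ok]), integer(1))
      sum(carriers >= 2) >= 2
    }, logical(1))
    out[[k]] <- data.frame(species = species,
                           contig = g$loci$contig[j[1]],
                           window_start = win[j[1]],
                           covered_positions = sum(covered),
                           multiallelic_count = sum(multi))
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res$ratio <- ifelse(res$covered_positions > 0,
                      res$multiallelic_count / res$covered_positions,
                      NA_real_)
  res
}

#' Single-sample bi-allelic (heterozygous) ratio at a depth floor
#'
#' Fraction of heterozygous calls among positions whose depth strictly
#' exceeds `min_depth - 1` in one sample (the conventional floors are depth
#' > 4 and > 8, i.e. `min_depth` 5 and 9).
#'
#' @param g a [genotype_matrix()].
#' @param sample_id the sample to evaluate.
#' @param min_depth minimum qualifying depth (inclusive).
#' @return Fraction in `[0, 1]`; `NA` with a warning when no position
#'   qualifies.
#' @export
single_sample_biallelic_ratio <- function(g, sample_id, min_depth = 5) {
  i <- match(sample_id, g$samples$sample_id)
  if (is.na(i)) stop("unknown sample: ", sample_id)
  qual <- which(g$depth[i, ] >= min_depth & !is.na(g$a1[i, ]))
  if (!length(qual)) {
    warning("no position with depth >= ", min_depth, " for ", sample_id)
    return(NA_real_)
  }
  mean(g$a1[i, qual] != g$a2[i, qual])
}

#' Match comparison-species sample pairs to Karner-blue pairs
#'
#' For each comparison pair with year gap `y` and distance `d`, selects a
#' Karner pair whose year gap is at least `y` and whose distance lies in
#' `[d, 2d]` ("equal to or up to twice"). Among eligible candidates the one
#' minimizing `|distance - d|` wins, ties broken lexicographically on sample
#' ids; candidate pairs may be reused across comparisons. Comparison pairs
#' with no eligible candidate are dropped and listed in the `dropped`
#' attribute.
#'
#' @param other_pairs data.frame of comparison-species pairs with columns
#'   `sample_a`, `sample_b`, `year_gap`, `distance`, `ratio`.
#' @param karner_pairs candidate Karner pairs, same columns.
#' @return data.frame with the comparison pair columns prefixed `other_` and
#'   the matched candidate columns prefixed `karner_`.
#' @export
match_pairs <- function(other_pairs, karner_pairs) {
  if (!nrow(other_pairs) || !nrow(karner_pairs))
    stop("candidate pools must be non-empty")
  res <- list(); dropped <- integer(0)
  for (i in seq_len(nrow(other_pairs))) {
    y <- other_pairs$year_gap[i]; d <- other_pairs$distance[i]
    ok <- karner_pairs$year_gap >= y &
      karner_pairs$distance >= d & karner_pairs$distance <= 2 * d
    if (!any(ok)) { dropped <- c(dropped, i); next }
    cand <- karner_pairs[ok, , drop = FALSE]
    cand <- cand[order(abs(cand$distance - d), cand$sample_a,
                       cand$sample_b), , drop = FALSE]
    best <- cand[1, ]
    res[[length(res) + 1]] <- data.frame(
      other_a = other_pairs$sample_a[i], other_b = other_pairs$sample_b[i],
      other_year_gap = y, other_distance = d,
      other_ratio = other_pairs$ratio[i],
      karner_a = best$sample_a, karner_b = best$sample_b,
      karner_year_gap = best$year_gap, karner_distance = best$distance,
      karner_ratio = best$ratio)
  }
  out <- if (length(res)) do.call(rbind, c(res, make.row.names = FALSE))
         else data.frame()
  attr(out, "dropped") <- dropped
  out
}

#' One-sided paired t-test of diversity ratios
#'
#' Paired t statistic on the differences `other - karner` with the
#' alternative that comparison-species pairs have the greater diversity.
#'
#' @param other_ratios,karner_ratios equal-length paired numeric vectors
#'   (n >= 2).
#' @return List with `t`, `p` (one-sided upper) and `n`.
#' @export
paired_one_sided_test <- function(other_ratios, karner_ratios) {
  if (length(other_ratios) != length(karner_ratios))
    stop("paired vectors must have equal length")
  n <- length(other_ratios)
  if (n < 2) stop("need at least two pairs")
  if (sd(other_ratios - karner_ratios) == 0)
    stop("zero-variance differences: t undefined")
  ht <- t.test(other_ratios, karner_ratios, paired = TRUE,
               alternative = "greater")
  list(t = unname(ht$statistic), p = ht$p.value, n = n)
}

#' Flag loss-of-diversity windows across species
#'
#' A window is flagged iff, against each species' own genome-wide mean
#' multiallelic ratio (total multiallelic count over total covered
#' positions), an exact binomial test gives one-sided *lower* tail p <
#' `alpha` in the focal species and one-sided *upper* tail p < `alpha` in
#' each comparison species. Windows with zero covered positions in any
#' species are skipped.
#'
#' @param windows data.frame as returned by [multiallelic_window_ratios()],
#'   rows for all species stacked.
#' @param focal focal species label (default `"samuelis"`).
#' @param comparison comparison species labels (default
#'   `c("melissa", "fridayi")`).
#' @param alpha per-test significance level (default 0.01; raw p-values, no
#'   multiplicity correction unless `adjust = TRUE` adds a BH column).
#' @param adjust add Benjamini-Hochberg adjusted p-value columns.
#' @return data.frame of windows shared by all species, with per-species
#'   p-value columns and a logical `flag`.
#' @export
loss_of_diversity_windows <- function(windows, focal = "samuelis",
                                      comparison = c("melissa", "fridayi"),
                                      alpha = 0.01, adjust = FALSE) {
  species <- c(focal, comparison)
  if (!all(species %in% windows$species))
    stop("windows must contain species: ", paste(species, collapse = ", "))
  per <- lapply(species, function(s) windows[windows$species == s, ])
  names(per) <- species
  gmean <- vapply(per, function(w)
    sum(w$multiallelic_count) / sum(w$covered_positions), numeric(1))
  key <- function(w) paste(w$contig, w$window_start)
  shared <- Reduce(intersect, lapply(per, key))
  out <- per[[focal]][match(shared, key(per[[focal]])),
                      c("contig", "window_start")]
  pcols <- matrix(NA_real_, length(shared), length(species),
                  dimnames = list(NULL, paste0("p_", species)))
  usable <- rep(TRUE, length(shared))
  for (s in species) {
    w <- per[[s]][match(shared, key(per[[s]])), ]
    usable <- usable & w$covered_positions > 0
    pcols[, paste0("p_", s)] <- if (s == focal)
      pbinom(w$multiallelic_count, w$covered_positions, gmean[s])
    else
      pbinom(w$multiallelic_count - 1, w$covered_positions, gmean[s],
             lower.tail = FALSE)
  }
  out <- cbind(out, pcols)
  out <- out[usable, , drop = FALSE]
  if (adjust)
    for (s in species)
      out[[paste0("p_adj_", s)]] <- p.adjust(out[[paste0("p_", s)]], "BH")
  out$flag <- rowSums(out[, paste0("p_", species), drop = FALSE] <
                        alpha) == length(species)
  rownames(out) <- NULL
  out
}

#' Genes overlapping flagged loss-of-diversity regions
#'
#' Each gene span is padded by `pad` bp on both sides (truncated at contig
#' ends) and reported iff the padded span overlaps the union of flagged
#' windows by at least `min_overlap` of its own (truncated) length.
#'
#' @param genes data.frame with `contig`, `start`, `end` (0-based half-open)
#'   and `gene_id`.
#' @param regions data.frame of flagged windows with `contig`,
#'   `window_start` (or `start`) and optionally `end`; windows default to
#'   `window_size` bp wide.
#' @param pad padding in bp (default 2000).
#' @param min_overlap minimum overlap fraction (default 0.70).
#' @param window_size width of flagged windows when `regions` has no `end`.
#' @param contig_lengths optional named vector for truncating padding at
#'   contig ends.
#' @return data.frame of reported genes with their overlap fractions.
#' @export
genes_in_regions <- function(genes, regions, pad = 2000, min_overlap = 0.70,
                             window_size = 10000, contig_lengths = NULL) {
  if (is.null(genes$gene_id) || any(is.na(genes$start)) ||
      any(is.na(genes$end)) || any(genes$end <= genes$start)) {
    bad <- which(is.na(genes$start) | is.na(genes$end) |
                   genes$end <= genes$start)
    stop("malformed annotation at line ",
         paste(bad, collapse = ", "))
  }
  if (is.null(regions$start)) regions$start <- regions$window_start
  if (is.null(regions$end)) regions$end <- regions$start + window_size
  frac <- numeric(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    ctg <- genes$contig[i]
    s <- max(0, genes$start[i] - pad)
    e <- genes$end[i] + pad
    if (!is.null(contig_lengths) && ctg %in% names(contig_lengths))
      e <- min(e, contig_lengths[[ctg]])
    r <- regions[regions$contig == ctg, , drop = FALSE]
    if (!nrow(r)) { frac[i] <- 0; next }
    reg <- IRanges::reduce(IRanges::IRanges(r$start + 1L, r$end))
    ov <- IRanges::intersect(IRanges::IRanges(s + 1L, e), reg)
    frac[i] <- sum(IRanges::width(ov)) / (e - s)
  }
  out <- genes[frac >= min_overlap, , drop = FALSE]
  out$overlap_fraction <- frac[frac >= min_overlap]
  rownames(out) <- NULL
  out
}
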