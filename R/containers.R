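#' karnerpop: population genomics of the Karner blue butterfly
#'
#' Implements a reusable, tested version of the computational stages of a
#' range-wide conservation-genomics workflow for the Karner blue butterfly
#' (*Plebejus samuelis*) and its close relatives: cleanup of degraded and
#' contaminated read alignments, depth-based genomic masking, locus selection
#' and export, Reich's small-sample F_ST with Mantel isolation-by-distance
#' testing, cross-species windowed diversity comparison, protein divergence
#' scoring and a screen for fixed single-amino-acid variants. Seeded
#' synthetic-data generators reproduce the statistical structure each stage
#' assumes so the full pipeline runs without external data.
#'
#' All genomic coordinates are 0-based half-open internally; 1-based
#' conventions appear only at VCF/GFF boundaries.
#'
#' @importFrom stats rbeta rbinom rpois runif median cor sd pbinom pt t.test
#'   prcomp p.adjust ks.test quantile setNames
#' @importFrom utils read.delim read.table write.table head packageVersion
#' @keywords internal
"_PACKAGE"

#' Diploid genotype matrix with per-entry depth
#'
#' Container for samples x loci diploid calls. Alleles are coded as small
#' positive integers (1 = reference, 2.. = alternates); a missing genotype has
#' `NA` in both allele matrices and, by convention, depth 0.
#'
#' @param a1,a2 integer matrices (samples x loci) of allele codes; `NA` for
#'   missing calls. Both alleles of a genotype are missing together.
#' @param depth non-negative integer matrix of per-entry sequencing depth, or
#'   `NULL` for unknown (stored as `NA`).
#' @param loci data.frame with columns `contig` and `pos` (0-based).
#' @param samples data.frame with columns `sample_id` and `locality`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(a1, a2, depth = NULL, loci, samples) {
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (!identical(dim(a1), dim(a2)))
    stop("allele matrices must have identical dimensions")
  if (is.null(depth)) depth <- matrix(NA_integer_, nrow(a1), ncol(a1))
  depth <- as.matrix(depth)
  if (!identical(dim(depth), dim(a1)))
    stop("depth matrix dimension mismatch")
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be non-negative")
  loci <- as.data.frame(loci); samples <- as.data.frame(samples)
  if (!all(c("contig", "pos") %in% names(loci)))
    stop("loci must have columns 'contig' and 'pos'")
  if (!all(c("sample_id", "locality") %in% names(samples)))
    stop("samples must have columns 'sample_id' and 'locality'")
  if (nrow(samples) != nrow(a1) || nrow(loci) != ncol(a1))
    stop("loci/samples tables inconsistent with call matrices")
  if (any(is.na(a1) != is.na(a2)))
    stop("alleles of a genotype must be missing together")
  rownames(a1) <- rownames(a2) <- rownames(depth) <- samples$sample_id
  structure(list(a1 = a1, a2 = a2, depth = depth,
                 loci = loci, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci, %d localities\n",
              nrow(x$a1), ncol(x$a1), length(unique(x$samples$locality))))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$a1)

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i sample index (integer, logical or sample_id character).
#' @param j locus index.
#' @param ... ignored.
#' @return A `genotype_matrix` restricted to the requested samples/loci.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$a1))
  if (missing(j)) j <- seq_len(ncol(x$a1))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  genotype_matrix(x$a1[i, j, drop = FALSE], x$a2[i, j, drop = FALSE],
                  x$depth[i, j, drop = FALSE],
                  x$loci[j, , drop = FALSE], x$samples[i, , drop = FALSE])
}

#' Aligned read set
#'
#' A data.frame-backed container for ungapped short-read alignments against a
#' reference: one row per read with `read_id`, `contig`, `start` (0-based) and
#' `sequence`. Per-position mismatch status is computed on demand against a
#' reference supplied as a named character vector of contig sequences, so read
#' records never carry derived state.
#'
#' @param read_id unique character ids.
#' @param contig contig names.
#' @param start 0-based alignment start positions.
#' @param sequence read nucleotide strings (A/C/G/T/N).
#' @return An object of classes `read_set` and `data.frame`.
#' @export
read_set <- function(read_id, contig, start, sequence) {
  if (anyDuplicated(read_id)) stop("read ids must be unique")
  if (any(start < 0)) stop("start must be >= 0")
  structure(data.frame(read_id = as.character(read_id),
                       contig = as.character(contig),
                       start = as.integer(start),
                       sequence = as.character(sequence),
                       stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads on %d contig(s)\n",
              nrow(x), length(unique(x$contig))))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5))
  invisible(x)
}

#' Windowed sequencing-depth track
#'
#' Stores mean per-base depth in fixed-width windows along one or more
#' contigs. The final window of a contig may be shorter than `window_size`;
#' its depth is normalized by its true width.
#'
#' @param depth numeric vector of per-window mean depths (single contig), or a
#'   data.frame with columns `contig`, `start`, `end`, `depth`.
#' @param window_size window width in bp.
#' @param contig contig name used when `depth` is a bare vector.
#' @param contig_length total contig length in bp; defaults to
#'   `length(depth) * window_size`.
#' @return An object of class `depth_track` (a data.frame with columns
#'   `contig`, `start`, `end`, `depth` and a `window_size` attribute).
#' @export
depth_track <- function(depth, window_size = 100, contig = "ctg1",
                        contig_length = NULL) {
  if (is.data.frame(depth)) {
    df <- depth
  } else {
    n <- length(depth)
    if (n < 1) stop("need at least one window")
    if (is.null(contig_length)) contig_length <- n * window_size
    start <- (seq_len(n) - 1L) * window_size
    df <- data.frame(contig = contig, start = start,
                     end = pmin(start + window_size, contig_length),
                     depth = as.numeric(depth))
  }
  if (any(df$depth < 0)) stop("depths must be non-negative")
  if (window_size <= 0) stop("window_size must be positive")
  structure(df, window_size = window_size,
            class = c("depth_track", "data.frame"))
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("depth_track: %d windows of %d bp on %d contig(s), median depth %.2f\n",
              nrow(x), attr(x, "window_size"), length(unique(x$contig)),
              median(x$depth[x$depth > 0])))
  invisible(x)
}

#' Multi-sample amino-acid alignment panel
#'
#' Per-protein amino-acid alignments across samples of several species.
#' Each alignment is a character matrix (rows = samples, columns = residue
#' positions) over the 20 one-letter amino-acid codes, with `NA` for missing
#' (uncovered) positions. All proteins share the same sample universe.
#'
#' @param alignments named list of character matrices with identical rownames.
#' @param species named character vector mapping sample id to species/group
#'   label.
#' @return An object of class `protein_panel`.
#' @export
protein_panel <- function(alignments, species) {
  if (!length(alignments) || is.null(names(alignments)))
    stop("alignments must be a named list")
  samples <- rownames(alignments[[1]])
  for (nm in names(alignments)) {
    m <- alignments[[nm]]
    if (!is.matrix(m) || !identical(rownames(m), samples))
      stop("all alignments must be matrices over the same samples")
  }
  if (!all(samples %in% names(species)))
    stop("every sample needs a species label")
  structure(list(alignments = alignments, species = species[samples]),
            class = "protein_panel")
}

#' @export
print.protein_panel <- function(x, ...) {
  cat(sprintf("protein_panel: %d proteins, %d samples, species: %s\n",
              length(x$alignments), nrow(x$alignments[[1]]),
              paste(sort(unique(x$species)), collapse = ", ")))
  invisible(x)
}

# Count mismatching positions between equal-length sequences. Ambiguous 'N'
# bases are mismatch-neutral: they neither match nor mismatch.
seq_mismatch <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) stop("sequences must have equal length")
  sum(x != y & x != "N" & y != "N")
}

# Identity over comparable (non-N) positions; NA when nothing comparable.
seq_identity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) stop("sequences must have equal length")
  ok <- x != "N" & y != "N"
  if (!any(ok)) return(NA_real_)
  mean(x[ok] == y[ok])
}
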