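#' Windowed mean sequencing depth from aligned reads
#'
#' Computes, for each fixed-width window along each contig, the mean per-base
#' depth: the sum over reads of their overlap length with the window, divided
#' by the window's true width (the final partial window is normalized by its
#' own length).
#'
#' @param reads a [read_set()], sorted by start coordinate within contig.
#' @param contig_lengths named integer vector of contig lengths in bp.
#' @param window_size window width in bp (default 100).
#' @return A [depth_track()] covering every contig in `contig_lengths`.
#' @export
window_depth <- function(reads, contig_lengths, window_size = 100) {
  rows <- list()
  for (contig in names(contig_lengths)) {
    rc <- reads[reads$contig == contig, , drop = FALSE]
    if (nrow(rc) && is.unsorted(rc$start))
      stop("reads must be sorted by coordinate within contig '", contig, "'")
    clen <- contig_lengths[[contig]]
    nwin <- ceiling(clen / window_size)
    ws <- (seq_len(nwin) - 1) * window_size
    we <- pmin(ws + window_size, clen)
    depth <- numeric(nwin)
    if (nrow(rc)) {
      ends <- rc$start + nchar(rc$sequence)
      for (i in seq_len(nrow(rc))) {
        ov_s <- pmax(ws, rc$start[i]); ov_e <- pmin(we, ends[i])
        ov <- pmax(0, ov_e - ov_s)
        depth <- depth + ov / (we - ws)
      }
    }
    rows[[contig]] <- data.frame(contig = contig, start = ws, end = we,
                                 depth = depth)
  }
  depth_track(do.call(rbind, c(rows, make.row.names = FALSE)),
              window_size = window_size)
}

#' Depth-based "good position" segments
#'
#' The median depth is computed over windows with depth > 0 (pooled across
#' contigs, giving one cohort-wide mask); zero-depth windows are excluded
#' from the median so unassembled regions do not depress it, but they still
#' fail the lower bound. A window passes iff its depth lies within
#' `[low, high] x median` (bounds inclusive). Maximal runs of at least
#' `min_consecutive` consecutive passing windows are emitted as 0-based
#' half-open intervals.
#'
#' @param track a [depth_track()].
#' @param low,high multiples of the median bounding acceptable depth.
#' @param min_consecutive minimum run length in windows.
#' @return A data.frame (`contig`, `start`, `end`) of good segments; empty
#'   (with a warning) when every window has zero depth.
#' @export
good_segments <- function(track, low = 0.25, high = 2.5,
                          min_consecutive = 3) {
  if (!nrow(track)) stop("empty depth track")
  pos <- track$depth[track$depth > 0]
  if (!length(pos)) {
    warning("all windows have zero depth; returning empty mask")
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  }
  med <- median(pos)
  pass <- track$depth >= low * med & track$depth <= high * med
  out <- list()
  for (contig in unique(track$contig)) {
    idx <- which(track$contig == contig)
    r <- rle(pass[idx])
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1
    keep <- r$values & r$lengths >= min_consecutive
    if (any(keep))
      out[[contig]] <- data.frame(
        contig = contig,
        start = track$start[idx[starts[keep]]],
        end = track$end[idx[stops[keep]]])
  }
  if (!length(out))
    return(data.frame(contig = character(), start = integer(),
                      end = integer()))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Apply a genomic mask to positions or variants
#'
#' Retains exactly the records whose position falls inside the mask
#' (0-based half-open intervals). Records on contigs absent from the mask are
#' dropped and counted in the `dropped_contigs` attribute with a warning.
#'
#' @param positions data.frame with columns `contig` and `pos`.
#' @param mask data.frame of intervals (`contig`, `start`, `end`).
#' @return The retained rows, with attributes `retained_fraction` and
#'   `dropped_contigs`.
#' @export
apply_mask <- function(positions, mask) {
  keep <- logical(nrow(positions))
  missing_ctg <- setdiff(unique(positions$contig), unique(mask$contig))
  if (length(missing_ctg))
    warning("contig(s) absent from mask, records dropped: ",
            paste(missing_ctg, collapse = ", "))
  for (contig in intersect(unique(positions$contig), unique(mask$contig))) {
    pi <- which(positions$contig == contig)
    mi <- mask[mask$contig == contig, , drop = FALSE]
    ir <- IRanges::IRanges(start = mi$start + 1L, end = mi$end)
    qr <- IRanges::IRanges(start = positions$pos[pi] + 1L, width = 1L)
    keep[pi] <- IRanges::overlapsAny(qr, ir)
  }
  out <- positions[keep, , drop = FALSE]
  attr(out, "retained_fraction") <-
    if (nrow(positions)) mean(keep) else NA_real_
  attr(out, "dropped_contigs") <-
    sum(positions$contig %in% missing_ctg)
  out
}

#' Write a mask as a BED file
#'
#' @param mask data.frame of intervals (`contig`, `start`, `end`).
#' @param file output path.
#' @return The file path, invisibly.
#' @export
write_mask_bed <- function(mask, file) {
  write.table(mask[, c("contig", "start", "end")], file, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a BED file of intervals
#'
#' @param file path to a 3+ column BED file.
#' @return data.frame with columns `contig`, `start`, `end` (plus `name` when
#'   a fourth column is present).
#' @export
read_bed <- function(file) {
  df <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("contig", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df[seq_len(min(4, ncol(df)))]
}
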