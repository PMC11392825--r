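#' Cluster reads within a 30-bp window by seed-sequence similarity
#'
#' Implements the window clustering used by Protocol A. Reads fully spanning
#' the window are ranked by sequence identity of their window sub-sequence to
#' the reference window, from high to low (ties broken by ascending
#' `read_id`). The first read initiates a cluster; each subsequent read joins
#' the first existing cluster whose *first* member's window sequence differs
#' from it by at most one mismatch, else it founds a new cluster.
#'
#' @param reads a [read_set()]; every read must fully span the window.
#' @param reference named character vector of contig sequences.
#' @param window_start,window_end 0-based half-open window bounds.
#' @return A list of clusters, in creation order; each is a list with
#'   `members` (read ids), `seed_sequence`, `size` and `mean_mismatch` (mean
#'   mismatches of members against the reference window).
#' @export
cluster_window_reads <- function(reads, reference, window_start, window_end) {
  if (!nrow(reads)) return(list())
  contig <- unique(reads$contig)
  if (length(contig) != 1) stop("reads must come from a single contig")
  ends <- reads$start + nchar(reads$sequence)
  if (any(reads$start > window_start | ends < window_end))
    stop("every read must fully span the window; pre-filter the input")
  refwin <- substr(reference[[contig]], window_start + 1, window_end)
  sub <- substr(reads$sequence, window_start - reads$start + 1,
                window_end - reads$start)
  mm <- vapply(sub, seq_mismatch, numeric(1), b = refwin, USE.NAMES = FALSE)
  ord <- order(mm, reads$read_id)
  seeds <- character(0)
  members <- list()
  member_mm <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(seeds)) {
      if (seq_mismatch(sub[i], seeds[k]) <= 1) {
        members[[k]] <- c(members[[k]], reads$read_id[i])
        member_mm[[k]] <- c(member_mm[[k]], mm[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, sub[i])
      members[[length(seeds)]] <- reads$read_id[i]
      member_mm[[length(seeds)]] <- mm[i]
    }
  }
  lapply(seq_along(seeds), function(k)
    list(members = members[[k]], seed_sequence = seeds[k],
         size = length(members[[k]]), mean_mismatch = mean(member_mm[[k]])))
}

#' Protocol A: window-cluster cleanup of degraded alignments
#'
#' For each window tiled along every contig, reads fully spanning the window
#' are clustered with [cluster_window_reads()]. A cluster is *good* if its
#' size is at least half the largest cluster size and its mean mismatch count
#' against the reference window is no larger than the minimum cluster mean
#' plus 2. If at most two clusters are good, members of the non-good clusters
#' are marked bad; if more than two clusters are good, *all* reads in the
#' window are marked bad. A read is removed from the output if it was marked
#' bad in any window it fully spans. Reads spanning no complete window are
#' retained (the protocol is only defined for full windows); they are listed
#' in the attached report.
#'
#' @param reads a [read_set()].
#' @param reference named character vector of contig sequences.
#' @param window_size window width in bp (default 30).
#' @param step tiling step; defaults to `window_size` (non-overlapping).
#' @return The retained subset of `reads`, with attribute `report`: a
#'   data.frame (`read_id`, `window`, `reason`) of removals, where reason is
#'   `A:bad_cluster` or `A:too_many_good`.
#' @export
protocol_a <- function(reads, reference, window_size = 30,
                       step = window_size) {
  report <- data.frame(read_id = character(), window = character(),
                       reason = character())
  if (!nrow(reads)) {
    attr(reads, "report") <- report
    return(reads)
  }
  bad <- character(0)
  evaluated <- character(0)
  for (contig in unique(reads$contig)) {
    rc <- reads[reads$contig == contig, , drop = FALSE]
    clen <- nchar(reference[[contig]])
    starts <- seq(0, clen - window_size, by = step)
    for (ws in starts) {
      we <- ws + window_size
      span <- rc$start <= ws & rc$start + nchar(rc$sequence) >= we
      if (!any(span)) next
      evaluated <- union(evaluated, rc$read_id[span])
      cl <- cluster_window_reads(rc[span, , drop = FALSE], reference, ws, we)
      sizes <- vapply(cl, `[[`, numeric(1), "size")
      means <- vapply(cl, `[[`, numeric(1), "mean_mismatch")
      good <- sizes >= max(sizes) / 2 & means <= min(means) + 2
      wid <- sprintf("%s:%d-%d", contig, ws, we)
      if (sum(good) <= 2) {
        newbad <- unlist(lapply(cl[!good], `[[`, "members"))
        if (length(newbad))
          report <- rbind(report, data.frame(read_id = newbad, window = wid,
                                             reason = "A:bad_cluster"))
      } else {
        newbad <- unlist(lapply(cl, `[[`, "members"))
        report <- rbind(report, data.frame(read_id = newbad, window = wid,
                                           reason = "A:too_many_good"))
      }
      bad <- union(bad, newbad)
    }
  }
  out <- reads[!(reads$read_id %in% bad), , drop = FALSE]
  attr(out, "report") <- report
  attr(out, "not_evaluated") <- setdiff(reads$read_id, evaluated)
  class(out) <- class(reads)
  out
}

#' Protocol B: corroboration cleanup by overlapping reads
#'
#' Every read (the target) is compared against all other reads overlapping it
#' in genomic coordinates. An overlapping read is *consistent* with the
#' target if the overlap spans at least `min_overlap` bp and the sequence
#' identity over the overlap exceeds `identity_hi`; it is *inconsistent* if
#' it has at least two mismatches from the target and identity below
#' `identity_hi`. Reads meeting neither clause count as neither. The target
#' is kept iff its consistent count is more than twice its inconsistent
#' count, so isolated reads (0 vs 0) are dropped unless
#' `keep_singletons = TRUE`.
#'
#' @param reads a [read_set()].
#' @param min_overlap minimum overlap in bp for the consistency clause.
#' @param identity_hi identity threshold (exclusive on both clauses).
#' @param keep_singletons retain reads with no overlapping reads at all.
#' @return The retained subset of `reads`, with attribute `report` listing
#'   removals with reason `B:outvoted`.
#' @export
protocol_b <- function(reads, min_overlap = 20, identity_hi = 0.95,
                       keep_singletons = FALSE) {
  n <- nrow(reads)
  keep <- logical(n)
  ends <- reads$start + nchar(reads$sequence)
  for (i in seq_len(n)) {
    ncons <- nincons <- 0L
    nover <- 0L
    for (j in seq_len(n)) {
      if (i == j || reads$contig[j] != reads$contig[i]) next
      os <- max(reads$start[i], reads$start[j])
      oe <- min(ends[i], ends[j])
      if (oe <= os) next
      nover <- nover + 1L
      a <- substr(reads$sequence[i], os - reads$start[i] + 1, oe - reads$start[i])
      b <- substr(reads$sequence[j], os - reads$start[j] + 1, oe - reads$start[j])
      mm <- seq_mismatch(a, b)
      idy <- seq_identity(a, b)
      if (oe - os >= min_overlap && !is.na(idy) && idy > identity_hi) {
        ncons <- ncons + 1L
      } else if (mm >= 2 && !is.na(idy) && idy < identity_hi) {
        nincons <- nincons + 1L
      }
    }
    keep[i] <- ncons > 2 * nincons ||
      (keep_singletons && nover == 0L)
  }
  out <- reads[keep, , drop = FALSE]
  removed <- reads$read_id[!keep]
  attr(out, "report") <- data.frame(read_id = removed,
                                    window = rep(NA_character_,
                                                 length(removed)),
                                    reason = rep("B:outvoted",
                                                 length(removed)))
  class(out) <- class(reads)
  out
}
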