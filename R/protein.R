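# Resolve a group spec (species label or explicit sample ids) to sample ids.
resolve_group <- function(panel, group) {
  samples <- names(panel$species)
  if (length(group) == 1 && group %in% panel$species)
    return(samples[panel$species == group])
  if (!all(group %in% samples)) stop("unknown samples in group")
  group
}

#' Good positions of a pairwise protein comparison
#'
#' Positions with a called residue in strictly more than `presence` of the
#' samples of *both* groups. Good positions need not be contiguous.
#'
#' @param alignment character matrix (samples x positions, `NA` missing).
#' @param group_a,group_b character vectors of row names.
#' @param presence presence fraction threshold (default 0.40, strict).
#' @return Integer vector of 1-based positions.
#' @export
good_positions <- function(alignment, group_a, group_b, presence = 0.40) {
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  fa <- colMeans(!is.na(alignment[group_a, , drop = FALSE]))
  fb <- colMeans(!is.na(alignment[group_b, , drop = FALSE]))
  which(fa > presence & fb > presence)
}

# Most frequent residue among called samples; NA on tie or no calls.
consensus_residue <- function(x, min_freq) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_character_)
  tab <- sort(table(x), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_) # tie
  if (tab[1] / length(x) <= min_freq) return(NA_character_)
  names(tab)[1]
}

#' Between-group percent divergence of proteins
#'
#' For each protein, good positions (see [good_positions()]) are screened
#' for divergence: a position is divergent iff in both groups the most
#' frequent residue among called samples occurs in strictly more than
#' `consensus` of them (ties disqualify) and the two consensus residues
#' differ. Divergence is `divergent / good`; proteins with at most
#' `min_good` good positions are excluded.
#'
#' @param panel a [protein_panel()].
#' @param group_a,group_b species/group labels or sample-id vectors.
#' @param consensus consensus fraction threshold (default 0.70, strict).
#' @param min_good minimum good positions (default 200, strict ">").
#' @param presence presence threshold passed to [good_positions()].
#' @return data.frame (`protein_id`, `good_positions`, `divergent_positions`,
#'   `divergence`), excluded proteins listed in the `excluded` attribute.
#' @export
protein_divergence <- function(panel, group_a, group_b, consensus = 0.70,
                               min_good = 200, presence = 0.40) {
  ga <- resolve_group(panel, group_a)
  gb <- resolve_group(panel, group_b)
  rows <- list(); excluded <- character(0)
  for (pid in names(panel$alignments)) {
    aln <- panel$alignments[[pid]]
    gp <- good_positions(aln, ga, gb, presence)
    if (length(gp) <= min_good) { excluded <- c(excluded, pid); next }
    ndiv <- 0L
    for (p in gp) {
      ca <- consensus_residue(aln[ga, p], consensus)
      cb <- consensus_residue(aln[gb, p], consensus)
      if (!is.na(ca) && !is.na(cb) && ca != cb) ndiv <- ndiv + 1L
    }
    rows[[pid]] <- data.frame(protein_id = pid, good_positions = length(gp),
                              divergent_positions = ndiv,
                              divergence = ndiv / length(gp))
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(protein_id = character(), good_positions = integer(),
                         divergent_positions = integer(),
                         divergence = numeric())
  attr(out, "excluded") <- excluded
  out
}

#' Proteins diverged above average in all pairwise comparisons
#'
#' A protein is selected iff its divergence strictly exceeds the mean
#' divergence of each comparison's record set, in every comparison.
#' Proteins absent from any comparison are excluded.
#'
#' @param records list of data.frames from [protein_divergence()] (one per
#'   group pair, typically three).
#' @return Character vector of selected protein ids.
#' @export
select_diverged_proteins <- function(records) {
  shared <- Reduce(intersect, lapply(records, `[[`, "protein_id"))
  above <- lapply(records, function(r) {
    m <- mean(r$divergence)
    r$protein_id[r$divergence > m]
  })
  sort(intersect(shared, Reduce(intersect, above)))
}

#' Screen for fixed single-amino-acid variants (SAVs)
#'
#' Emits positions satisfying, against every comparison species, all four
#' criteria: (1) the position is called in strictly more than
#' `focal_coverage` of focal samples and, per comparison species, in more
#' than `max(other_min_samples, other_min_frac * n)` samples; (2) at least
#' `prevalence` (inclusive) of called focal samples share one residue, the
#' prevalent residue; (3) each comparison species has a dominant residue
#' (frequency >= `dominant` among its called samples) different from the
#' focal prevalent residue; and (4) the prevalent residue occurs in at most
#' `max_other_freq` (inclusive) of each comparison species' called samples.
#' All frequencies are computed over called (non-missing) samples.
#'
#' @param panel a [protein_panel()].
#' @param focal focal species label (default `"samuelis"`).
#' @param focal_coverage criterion-1 focal coverage fraction (strict >).
#' @param other_min_samples criterion-1 absolute floor; the default 5 with a
#'   strict ">" realizes "more than 5" (>= 6); set 4 to relax to >= 5.
#' @param other_min_frac criterion-1 relative floor (default 0.20).
#' @param prevalence criterion-2 threshold, inclusive (default 0.95).
#' @param dominant criterion-3 threshold, inclusive (default 0.80).
#' @param max_other_freq criterion-4 cap, inclusive (default 0.05).
#' @return data.frame with one row per candidate: `protein_id`, `position`
#'   (1-based), `residue`, `focal_freq`, and per comparison species
#'   `freq_<sp>` (frequency of the focal residue) and `dom_<sp>` (dominant
#'   residue). Positions failing the coverage floor are counted in the
#'   `skipped_low_coverage` attribute.
#' @export
find_sav_candidates <- function(panel, focal = "samuelis",
                                focal_coverage = 0.50,
                                other_min_samples = 5, other_min_frac = 0.20,
                                prevalence = 0.95, dominant = 0.80,
                                max_other_freq = 0.05) {
  species <- setdiff(unique(panel$species), focal)
  if (!length(species)) stop("need at least one comparison species")
  if (!focal %in% panel$species) stop("focal species absent from panel")
  rows <- list(); skipped <- 0L
  foc_samples <- names(panel$species)[panel$species == focal]
  sp_samples <- lapply(species, function(s)
    names(panel$species)[panel$species == s])
  names(sp_samples) <- species
  for (pid in names(panel$alignments)) {
    aln <- panel$alignments[[pid]]
    for (p in seq_len(ncol(aln))) {
      fx <- aln[foc_samples, p]; fx <- fx[!is.na(fx)]
      if (length(fx) <= focal_coverage * length(foc_samples)) {
        skipped <- skipped + 1L; next
      }
      cover_ok <- TRUE
      for (s in species) {
        ns <- sum(!is.na(aln[sp_samples[[s]], p]))
        if (ns <= max(other_min_samples,
                      other_min_frac * length(sp_samples[[s]]))) {
          cover_ok <- FALSE; break
        }
      }
      if (!cover_ok) { skipped <- skipped + 1L; next }
      tab <- sort(table(fx), decreasing = TRUE)
      if (tab[1] / length(fx) < prevalence) next
      res <- names(tab)[1]
      ok <- TRUE
      freqs <- doms <- setNames(rep(NA, length(species)), species)
      for (s in species) {
        sx <- aln[sp_samples[[s]], p]; sx <- sx[!is.na(sx)]
        stab <- sort(table(sx), decreasing = TRUE)
        dom_ok <- length(stab) >= 1 && stab[1] / length(sx) >= dominant &&
          !(length(stab) > 1 && stab[1] == stab[2])
        freqs[s] <- if (res %in% names(stab))
          stab[[res]] / length(sx) else 0
        doms[s] <- if (dom_ok) names(stab)[1] else NA
        if (!dom_ok || names(stab)[1] == res || freqs[s] > max_other_freq) {
          ok <- FALSE; break
        }
      }
      if (!ok) next
      row <- data.frame(protein_id = pid, position = p, residue = res,
                        focal_freq = unname(tab[1] / length(fx)))
      for (s in species) {
        row[[paste0("freq_", s)]] <- unname(freqs[s])
        row[[paste0("dom_", s)]] <- unname(doms[s])
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(protein_id = character(), position = integer(),
                         residue = character(), focal_freq = numeric())
  attr(out, "skipped_low_coverage") <- skipped
  out
}

#' Classify residue burial from relative solvent accessibility
#'
#' DSSP-style relative solvent accessibility (RSA) in `[0, 1]`: a residue is
#' exposed iff RSA is strictly above the cutoff, buried otherwise. Missing
#' RSA leaves the flag undefined (`NA`); such candidates are retained
#' unclassified.
#'
#' @param rsa numeric vector of RSA values (`NA` allowed).
#' @param cutoff exposure threshold (default 0.25).
#' @return Logical vector: `TRUE` = buried, `FALSE` = exposed, `NA` unknown.
#' @export
classify_burial <- function(rsa, cutoff = 0.25) {
  if (any(rsa < 0 | rsa > 1, na.rm = TRUE))
    stop("RSA values must lie in [0, 1]")
  ifelse(is.na(rsa), NA, rsa <= cutoff)
}

#' Binomial term enrichment of a protein selection
#'
#' For each annotation term, computes the one-sided upper binomial tail
#' `P(X >= k | n = |selected|, p = background term frequency)` where `k` is
#' the term's count among selected proteins. Terms annotated only outside
#' the background are skipped with a warning. Raw p-values are reported;
#' `adjust = TRUE` adds a Benjamini-Hochberg column.
#'
#' @param selected character vector of selected protein ids (subset of
#'   `background`).
#' @param background character vector of background protein ids.
#' @param term_map data.frame with columns `protein_id` and `term`.
#' @param adjust add a BH-adjusted p-value column.
#' @return data.frame (`term`, `n_selected`, `n_background`, `bg_freq`,
#'   `p_value`[, `p_adjust`]).
#' @export
enrich_terms <- function(selected, background, term_map, adjust = FALSE) {
  if (!all(selected %in% background))
    stop("selected proteins must be a subset of the background")
  tm <- term_map[term_map$protein_id %in% background, , drop = FALSE]
  orphan <- setdiff(unique(term_map$term), unique(tm$term))
  if (length(orphan))
    warning("term(s) absent from background skipped: ",
            paste(orphan, collapse = ", "))
  n <- length(selected)
  terms <- unique(tm$term)
  rows <- lapply(terms, function(tr) {
    prot <- unique(tm$protein_id[tm$term == tr])
    k <- sum(selected %in% prot)
    p_bg <- length(prot) / length(unique(background))
    data.frame(term = tr, n_selected = k, n_background = length(prot),
               bg_freq = p_bg,
               p_value = pbinom(k - 1, n, p_bg, lower.tail = FALSE))
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (adjust) out$p_adjust <- p.adjust(out$p_value, "BH")
  out[order(out$p_value), ]
}

#' Read per-protein multi-FASTA alignments into a panel
#'
#' Each file holds one protein's alignment, one record per sample, with `X`
#' or `-` treated as missing. Sample ids are the FASTA record names.
#'
#' @param files named character vector of FASTA paths (names = protein ids).
#' @param species named character vector mapping sample id to species.
#' @return A [protein_panel()].
#' @export
read_protein_panel <- function(files, species) {
  aln <- lapply(files, function(f) {
    ss <- Biostrings::readAAStringSet(f)
    m <- do.call(rbind, strsplit(as.character(ss), "", fixed = TRUE))
    rownames(m) <- names(ss)
    m[m %in% c("X", "-")] <- NA_character_
    m
  })
  if (is.null(names(files))) names(aln) <- basename(files)
  protein_panel(aln, species)
}

#' Write a protein panel as per-protein multi-FASTA files
#'
#' Missing residues are written as `X`.
#'
#' @param panel a [protein_panel()].
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_protein_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (pid in names(panel$alignments)) {
    m <- panel$alignments[[pid]]
    m[is.na(m)] <- "X"
    seqs <- apply(m, 1, paste, collapse = "")
    path <- file.path(dir, paste0(pid, ".fasta"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
    paths[pid] <- path
  }
  invisible(paths)
}
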