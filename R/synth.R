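#' Demographic model for synthetic diploid cohorts
#'
#' Parameter bundle for [simulate_cohort_genotypes()]. Demes follow either a
#' symmetric island model, in which the expected differentiation between any
#' two demes is `1 / (1 + 4 N m)` (with `N` the effective deme size and `m`
#' the per-generation migration fraction), or a linear stepping-stone
#' arrangement in which differentiation accumulates with the number of steps
#' separating two demes, yielding isolation by distance.
#'
#' @param n_demes number of demes (localities).
#' @param deme_size effective size `N` of each deme.
#' @param migration_rate per-generation migration fraction `m` in `[0, 1]`.
#' @param inbreeding_f per-deme inbreeding coefficient in `[0, 1]`, recycled
#'   across demes.
#' @param n_loci number of bi-allelic loci.
#' @param n_samples_per_deme diploid samples drawn per deme.
#' @param missing_rate fraction of genotype entries masked as missing.
#' @param mean_depth mean of the Poisson per-entry sequencing depth.
#' @param structure `"island"` or `"stepping_stone"`.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return An object of class `demographic_model`.
#' @export
demographic_model <- function(n_demes = 4, deme_size = 1000,
                              migration_rate = 1e-3, inbreeding_f = 0.3,
                              n_loci = 2000, n_samples_per_deme = 5,
                              missing_rate = 0.05, mean_depth = 20,
                              structure = c("island", "stepping_stone"),
                              seed = 1) {
  structure <- match.arg(structure)
  inbreeding_f <- rep_len(inbreeding_f, n_demes)
  if (n_demes < 1 || deme_size < 1 || n_loci < 1 || n_samples_per_deme < 1)
    stop("all counts and sizes must be positive")
  if (migration_rate < 0 || migration_rate > 1)
    stop("migration_rate must lie in [0, 1]")
  if (any(inbreeding_f < 0) || any(inbreeding_f > 1))
    stop("inbreeding_f must lie in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  out <- list(n_demes = n_demes, deme_size = deme_size,
              migration_rate = migration_rate, inbreeding_f = inbreeding_f,
              n_loci = n_loci, n_samples_per_deme = n_samples_per_deme,
              missing_rate = missing_rate, mean_depth = mean_depth,
              structure = structure, seed = as.integer(seed))
  class(out) <- "demographic_model"
  out
}

#' Expected island-model differentiation
#'
#' Closed-form expectation `F = 1 / (1 + 4 N m)` used as the oracle for the
#' F_ST estimator on island-model cohorts.
#'
#' @param model a [demographic_model()].
#' @return Expected F_ST between two demes.
#' @export
expected_fst <- function(model) {
  if (model$n_demes < 2 || model$structure != "island") return(NA_real_)
  1 / (1 + 4 * model$deme_size * model$migration_rate)
}

# Draw a frequency with intraclass correlation F around ancestral p.
drift_freq <- function(p, f) {
  if (f <= 1e-8) return(p)
  if (f >= 1 - 1e-12) return(as.numeric(runif(length(p)) < p))
  rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a multi-deme diploid SNP cohort with metadata
#'
#' Ancestral allele frequencies are drawn uniformly on `[0.05, 0.95]`; deme
#' frequencies are Beta-distributed around them with intraclass correlation
#' equal to the island-model expectation `1/(1 + 4Nm)` (or accumulate per
#' step under the stepping-stone arrangement). Within a deme, each individual
#' is identical-by-descent at a locus with probability equal to the deme's
#' inbreeding coefficient, in which case a single allele draw is duplicated;
#' otherwise the two allele copies are drawn independently. This makes the
#' within-deme heterozygosity deficit `1 - Ho/He` match `inbreeding_f` in
#' expectation. Depth is Poisson; missing entries get depth 0.
#'
#' @param model a [demographic_model()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]), `meta`
#'   (per-sample metadata data.frame with locality, coordinates in decimal
#'   degrees, collection year and species label) and `expected_fst`.
#' @export
simulate_cohort_genotypes <- function(model) {
  stopifnot(inherits(model, "demographic_model"))
  set.seed(model$seed)
  L <- model$n_loci; D <- model$n_demes; S <- model$n_samples_per_deme
  p0 <- runif(L, 0.05, 0.95)
  fst <- expected_fst(model)
  pd <- matrix(NA_real_, D, L)
  if (model$structure == "island" || D == 1) {
    for (d in seq_len(D)) pd[d, ] <- if (D == 1) p0 else drift_freq(p0, fst)
  } else {
    # stepping stone: per-step drift from the previous deme along a line
    fstep <- 1 / (1 + 4 * model$deme_size * model$migration_rate)
    pd[1, ] <- drift_freq(p0, fstep)
    for (d in seq_len(D)[-1]) pd[d, ] <- drift_freq(pd[d - 1, ], fstep)
  }
  n <- D * S
  a1 <- a2 <- matrix(NA_integer_, n, L)
  locality <- character(n)
  for (d in seq_len(D)) {
    rows <- (d - 1) * S + seq_len(S)
    locality[rows] <- sprintf("L%02d", d)
    p <- matrix(pd[d, ], S, L, byrow = TRUE)
    ibd <- matrix(runif(S * L) < model$inbreeding_f[d], S, L)
    u1 <- matrix(rbinom(S * L, 1, p), S, L)
    u2 <- matrix(rbinom(S * L, 1, p), S, L)
    a1[rows, ] <- 1L + u1
    a2[rows, ] <- 1L + ifelse(ibd, u1, u2)
  }
  depth <- matrix(rpois(n * L, model$mean_depth), n, L)
  if (model$missing_rate > 0) {
    miss <- matrix(runif(n * L) < model$missing_rate, n, L)
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_; depth[miss] <- 0L
  }
  sample_id <- sprintf("S%03d", seq_len(n))
  loci <- data.frame(contig = "ctg1",
                     pos = sort(sample.int(L * 1000L, L)) - 1L)
  g <- genotype_matrix(a1, a2, depth, loci,
                       data.frame(sample_id = sample_id, locality = locality))
  # locality coordinates: stepping-stone demes sit on an east-west line so
  # geographic distance tracks the number of migration steps; island demes
  # are scattered over the species' Great Lakes / New York range box.
  if (model$structure == "stepping_stone") {
    lat <- rep(44, D); lon <- -92 + (seq_len(D) - 1) * 18 / max(1, D - 1)
  } else {
    lat <- runif(D, 41.5, 46); lon <- runif(D, -92.5, -73.5)
  }
  meta <- data.frame(sample_id = sample_id, locality_id = locality,
                     latitude = lat[rep(seq_len(D), each = S)],
                     longitude = lon[rep(seq_len(D), each = S)],
                     collection_year = sample(2010:2012, n, replace = TRUE),
                     species_label = "samuelis")
  list(genotypes = g, meta = meta, expected_fst = fst)
}

#' Wright's heterozygosity-deficit inbreeding estimate
#'
#' Moment estimator `F = 1 - sum(Ho) / sum(He)` over loci within each
#' locality, with `He` the small-sample-corrected expected heterozygosity
#' `2*p*q * 2n/(2n - 1)`.
#'
#' @param g a [genotype_matrix()].
#' @return Named numeric vector of per-locality estimates.
#' @export
wright_f <- function(g) {
  out <- c()
  for (loc in unique(g$samples$locality)) {
    rows <- g$samples$locality == loc
    a1 <- g$a1[rows, , drop = FALSE]; a2 <- g$a2[rows, , drop = FALSE]
    ho <- he <- 0
    for (j in seq_len(ncol(a1))) {
      ok <- !is.na(a1[, j])
      n <- sum(ok)
      if (n < 2) next
      p <- mean(c(a1[ok, j], a2[ok, j]) == 2)
      ho <- ho + mean(a1[ok, j] != a2[ok, j])
      he <- he + 2 * p * (1 - p) * (2 * n) / (2 * n - 1)
    }
    out[loc] <- if (he > 0) 1 - ho / he else NA_real_
  }
  out
}

#' Simulate a read stack with planted contaminant reads
#'
#' Generates full-length reads over a reference window. Native reads are
#' exact copies of the reference; each contaminant read carries exactly
#' `round(contaminant_divergence * nchar(reference_window))` substitutions at
#' uniformly chosen positions, so the planted divergence is deterministic at
#' the stated per-base rate. The native/contaminant truth is returned in a
#' sidecar table and never stored in the read records themselves.
#'
#' @param reference_window non-empty reference sequence string.
#' @param depth number of reads (>= 1).
#' @param contaminant_fraction fraction of reads planted as contaminants.
#' @param contaminant_divergence per-base substitution rate of contaminants.
#' @param seed integer seed.
#' @param contig contig name given to the reads.
#' @return A list with `reads` (a [read_set()]), `truth` (data.frame
#'   `read_id`, `origin`) and `reference` (named character vector).
#' @export
simulate_read_stack <- function(reference_window, depth,
                                contaminant_fraction = 0,
                                contaminant_divergence = 0,
                                seed = 1, contig = "win") {
  if (!nzchar(reference_window)) stop("reference window must be non-empty")
  if (depth < 1) stop("depth must be >= 1")
  if (contaminant_fraction < 0 || contaminant_fraction > 1 ||
      contaminant_divergence < 0 || contaminant_divergence > 1)
    stop("fractions must lie in [0, 1]")
  set.seed(seed)
  len <- nchar(reference_window)
  ref <- strsplit(reference_window, "", fixed = TRUE)[[1]]
  n_cont <- round(depth * contaminant_fraction)
  k <- round(contaminant_divergence * len)
  bases <- c("A", "C", "G", "T")
  seqs <- character(depth)
  origin <- c(rep("contaminant", n_cont), rep("native", depth - n_cont))
  for (i in seq_len(depth)) {
    s <- ref
    if (origin[i] == "contaminant" && k > 0) {
      at <- sample.int(len, k)
      for (j in at) s[j] <- sample(setdiff(bases, s[j]), 1)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  ids <- sprintf("r%03d", seq_len(depth))
  list(reads = read_set(ids, contig, 0L, seqs),
       truth = data.frame(read_id = ids, origin = origin),
       reference = setNames(reference_window, contig))
}

#' Simulate a multi-species protein alignment panel with planted features
#'
#' Background positions carry one residue shared by every sample of every
#' species (exchangeable noise is added with `noise_rate`). Planted SAV
#' positions give all focal-species samples one residue and all other species
#' a different one, satisfying the four fixed-variant criteria by
#' construction. Planted divergent positions give the two groups of
#' `divergent_groups` different fixed residues, satisfying the 70% consensus
#' rule. Missingness is applied uniformly at `missing_rate` (recycled per
#' protein).
#'
#' @param n_proteins number of proteins.
#' @param lengths protein lengths (recycled).
#' @param n_samples_per_species named integer vector, names are species
#'   labels; the first label is the focal species unless `focal` is given.
#' @param planted_savs data.frame with columns `protein` (index or id) and
#'   `position`, or NULL.
#' @param planted_divergent data.frame with columns `protein` and `position`,
#'   or NULL.
#' @param divergent_groups length-2 character vector of species labels
#'   carrying the planted divergent residues.
#' @param missing_rate per-protein missingness fraction, recycled.
#' @param noise_rate per-cell probability of substituting a random residue.
#' @param focal focal species label.
#' @param seed integer seed.
#' @return A [protein_panel()] with attribute `truth` listing the plants.
#' @export
simulate_protein_panel <- function(n_proteins = 10, lengths = 300,
                                   n_samples_per_species =
                                     c(samuelis = 20, melissa = 13,
                                       fridayi = 13, idas = 13, anna = 13),
                                   planted_savs = NULL,
                                   planted_divergent = NULL,
                                   divergent_groups = NULL,
                                   missing_rate = 0, noise_rate = 0,
                                   focal = names(n_samples_per_species)[1],
                                   seed = 1) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNQRSTVWY", "")[[1]]  # 'P' reserved for SAV plants
  lengths <- rep_len(lengths, n_proteins)
  missing_rate <- rep_len(missing_rate, n_proteins)
  species_of <- rep(names(n_samples_per_species), n_samples_per_species)
  samples <- sprintf("%s_%02d", species_of,
                     unlist(lapply(n_samples_per_species, seq_len)))
  species <- setNames(species_of, samples)
  ids <- sprintf("prot%03d", seq_len(n_proteins))
  norm_plant <- function(pl) {
    if (is.null(pl)) return(pl)
    pl <- as.data.frame(pl)
    if (!is.numeric(pl$protein)) pl$protein <- match(pl$protein, ids)
    if (any(pl$position > lengths[pl$protein]))
      stop("planted position beyond protein length")
    pl
  }
  planted_savs <- norm_plant(planted_savs)
  planted_divergent <- norm_plant(planted_divergent)
  if (!is.null(planted_savs) && !is.null(planted_divergent)) {
    clash <- merge(planted_savs, planted_divergent, by = c("protein", "position"))
    if (nrow(clash)) stop("incompatible plants at the same protein position")
  }
  if (is.null(divergent_groups))
    divergent_groups <- head(names(n_samples_per_species), 2)
  aln <- list()
  for (i in seq_len(n_proteins)) {
    L <- lengths[i]
    m <- matrix(sample(aa, L, replace = TRUE), length(samples), L,
                byrow = TRUE, dimnames = list(samples, NULL))
    if (noise_rate > 0) {
      hit <- which(matrix(runif(length(m)) < noise_rate, nrow(m)))
      m[hit] <- sample(aa, length(hit), replace = TRUE)
    }
    if (!is.null(planted_savs))
      for (p in planted_savs$position[planted_savs$protein == i]) {
        m[species == focal, p] <- "P"
        m[species != focal, p] <- "A"
      }
    if (!is.null(planted_divergent))
      for (p in planted_divergent$position[planted_divergent$protein == i]) {
        # 80/20 residue mixtures: both groups clear the 70% consensus rule
        # with distinct consensus residues, yet neither is near-fixed, so a
        # planted divergent position can never double as a fixed variant
        for (grp in 1:2) {
          rows <- which(species == divergent_groups[grp])
          major <- ceiling(0.8 * length(rows))
          m[rows[seq_len(major)], p] <- c("D", "E")[grp]
          m[rows[-seq_len(major)], p] <- c("E", "D")[grp]
        }
      }
    if (missing_rate[i] > 0)
      m[matrix(runif(length(m)) < missing_rate[i], nrow(m))] <- NA_character_
    aln[[ids[i]]] <- m
  }
  out <- protein_panel(aln, species)
  attr(out, "truth") <- list(savs = planted_savs, divergent = planted_divergent,
                             ids = ids)
  out
}

#' Simulate a windowed depth track with planted dropouts and spikes
#'
#' Ordinary windows fluctuate uniformly within 0.8-1.2x the target median;
#' dropout windows sit at 0.05x and spike windows at 5x, guaranteeing they
#' fall outside the `[0.25, 2.5] x median` acceptance band used by
#' [good_segments()] while ordinary windows fall inside it.
#'
#' @param n_windows number of windows (>= 1).
#' @param median_target target median depth of ordinary windows.
#' @param dropout_windows 1-based indices planted as dropouts.
#' @param spike_windows 1-based indices planted as spikes.
#' @param seed integer seed.
#' @param window_size window width in bp.
#' @param contig contig name.
#' @return A [depth_track()].
#' @export
simulate_depth_track <- function(n_windows, median_target = 20,
                                 dropout_windows = integer(),
                                 spike_windows = integer(),
                                 seed = 1, window_size = 100,
                                 contig = "ctg1") {
  if (n_windows < 1) stop("n_windows must be >= 1")
  if (length(intersect(dropout_windows, spike_windows)))
    stop("a window cannot be both dropout and spike")
  set.seed(seed)
  d <- median_target * runif(n_windows, 0.8, 1.2)
  d[dropout_windows] <- median_target * 0.05
  d[spike_windows] <- median_target * 5
  depth_track(d, window_size = window_size, contig = contig)
}
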