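#' Default pipeline configuration
#'
#' All analysis thresholds in one validated block, defaulting to the values
#' the workflow is built around: 100-bp depth windows with the
#' `[0.25, 2.5] x median` band and 3-window minimum run; 30-bp cleanup
#' windows, 20-bp overlap and 0.95 identity; PCA/STRUCTURE coverage
#' fractions 0.75/0.50 with the more-than-four-samples allele rule; 50-kb
#' BA3 locus spacing; 10-kb diversity windows with 13-sample subsets and
#' alpha 0.01; 2000-bp gene padding with the 70% overlap rule; SAV
#' thresholds 0.50/0.95/0.80/0.05 with the 0.25 RSA burial cutoff; and the
#' 0.1 high-inbreeding flag.
#'
#' @param ... named overrides of nested defaults, e.g.
#'   `diversity = list(alpha = 0.05)` (unknown keys warn but are kept, for
#'   forward compatibility).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    stages = list(mask = TRUE, cleanup = TRUE, genoprep = TRUE,
                  popgen = TRUE, diversity = TRUE, loss_regions = TRUE,
                  region_genes = TRUE, protein = TRUE),
    synth = list(n_demes = 4, deme_size = 1000, migration_rate = 1e-3,
                 inbreeding_f = 0.3, n_loci = 2000, n_samples_per_deme = 5,
                 missing_rate = 0.05, n_proteins = 20, protein_length = 300,
                 n_species_samples = 13),
    mask = list(window = 100, low = 0.25, high = 2.5, min_run = 3),
    cleanup = list(window = 30, step = 30, min_overlap = 20,
                   identity = 0.95, keep_singletons = FALSE),
    genoprep = list(completeness = 0.30, pca_coverage = 0.75,
                    structure_coverage = 0.50, min_allele_samples = 5,
                    ba3_spacing = 50000),
    popgen = list(min_samples_per_locality = 4, n_permutations = 999,
                  inbreeding_threshold = 0.1),
    diversity = list(window = 10000, subsample = 13, alpha = 0.01,
                     pad = 2000, min_gene_overlap = 0.70,
                     depth_floor_low = 5, depth_floor_high = 9),
    protein = list(presence = 0.40, consensus = 0.70, min_good = 200,
                   focal_coverage = 0.50, prevalence = 0.95,
                   dominant = 0.80, max_other_freq = 0.05,
                   rsa_cutoff = 0.25))
  over <- list(...)
  known <- names(cfg)
  for (nm in names(over)) {
    if (!nm %in% known) {
      warning("unknown config key '", nm, "' kept for forward compatibility")
      cfg[[nm]] <- over[[nm]]
    } else if (is.list(cfg[[nm]])) {
      for (sub in names(over[[nm]])) {
        if (!sub %in% names(cfg[[nm]]))
          warning("unknown config key '", nm, ".", sub, "'")
        cfg[[nm]][[sub]] <- over[[nm]][[sub]]
      }
    } else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented domain and returns the list
#' of violations (empty when the configuration is valid), each naming the
#' offending key.
#'
#' @param config a [pipeline_config()] or plain nested list.
#' @return Character vector of error messages; `character(0)` when ok.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(cond, key, what) {
    v <- tryCatch(cond, error = function(e) FALSE)
    if (!isTRUE(v)) errs <<- c(errs, paste0(key, ": ", what))
    invisible(NULL)
  }
  frac <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  pos <- function(x) is.numeric(x) && length(x) == 1 && x > 0
  chk(pos(config$mask$window), "mask.window", "must be a positive number")
  chk(pos(config$mask$low) && config$mask$low < config$mask$high,
      "mask.low/high", "need 0 < low < high")
  chk(pos(config$mask$min_run), "mask.min_run", "must be positive")
  chk(pos(config$cleanup$window), "cleanup.window", "must be positive")
  chk(pos(config$cleanup$min_overlap), "cleanup.min_overlap",
      "must be positive")
  chk(frac(config$cleanup$identity), "cleanup.identity",
      "must lie in [0, 1]")
  chk(frac(config$genoprep$completeness), "genoprep.completeness",
      "must lie in [0, 1]")
  chk(frac(config$genoprep$pca_coverage), "genoprep.pca_coverage",
      "must lie in [0, 1]")
  chk(frac(config$genoprep$structure_coverage),
      "genoprep.structure_coverage", "must lie in [0, 1]")
  chk(pos(config$genoprep$ba3_spacing), "genoprep.ba3_spacing",
      "must be positive")
  chk(pos(config$popgen$n_permutations), "popgen.n_permutations",
      "must be positive")
  chk(frac(config$popgen$inbreeding_threshold),
      "popgen.inbreeding_threshold", "must lie in [0, 1]")
  chk(pos(config$diversity$window), "diversity.window", "must be positive")
  chk(pos(config$diversity$subsample), "diversity.subsample",
      "must be positive")
  chk(frac(config$diversity$alpha) && config$diversity$alpha > 0,
      "diversity.alpha", "must lie in (0, 1]")
  chk(frac(config$diversity$min_gene_overlap),
      "diversity.min_gene_overlap", "must lie in [0, 1]")
  chk(config$diversity$pad >= 0, "diversity.pad", "must be >= 0")
  for (key in c("presence", "consensus", "focal_coverage", "prevalence",
                "dominant", "max_other_freq", "rsa_cutoff"))
    chk(frac(config$protein[[key]]), paste0("protein.", key),
        "must lie in [0, 1]")
  chk(pos(config$protein$min_good), "protein.min_good", "must be positive")
  errs
}

#' Read / write a pipeline configuration as YAML
#'
#' @param file YAML path.
#' @return `read_pipeline_config` returns a validated [pipeline_config()];
#'   `write_pipeline_config` returns the path invisibly. The configuration
#'   round-trips through serialization.
#' @export
read_pipeline_config <- function(file) {
  raw <- tryCatch(yaml::read_yaml(file), error = function(e)
    stop("unparseable config file: ", conditionMessage(e)))
  do.call(pipeline_config, raw)
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

# Stage dependency graph of the synthetic demonstration run.
stage_deps <- list(mask = character(), cleanup = character(),
                   genoprep = character(), popgen = "genoprep",
                   diversity = character(), loss_regions = "diversity",
                   region_genes = "loss_regions", protein = character())

#' Run the synthetic demonstration pipeline
#'
#' Generates a seeded synthetic cohort, read stack, depth track and protein
#' panel, then executes the enabled stages in dependency order, writing each
#' stage's tables under `out_dir` plus a `manifest.json` recording the
#' configuration, seeds and MD5 hashes of every output. A rerun with the
#' same configuration and seed reproduces all outputs byte-identically.
#' Stages whose dependencies are disabled are reported as unmet in the
#' manifest and skipped. A stage failure leaves a `FAILED` marker beside the
#' partial outputs and raises an error.
#'
#' @param config a [pipeline_config()] (validated before any stage runs).
#' @param out_dir output directory, created if needed.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  errs <- validate_config(config)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  outputs <- character(0)
  status <- list()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  enabled <- function(s) isTRUE(config$stages[[s]])
  run_stage <- function(name, fun) {
    if (!enabled(name)) { status[[name]] <<- "disabled"; return(invisible()) }
    unmet <- Filter(function(d) !identical(status[[d]], "ok"),
                    stage_deps[[name]])
    if (length(unmet)) {
      status[[name]] <<- paste0("unmet dependency: ",
                                paste(unlist(unmet), collapse = ","))
      return(invisible())
    }
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      writeLines(conditionMessage(e), file.path(out_dir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
    status[[name]] <<- "ok"
  }
  sy <- config$synth
  model <- demographic_model(
    n_demes = sy$n_demes, deme_size = sy$deme_size,
    migration_rate = sy$migration_rate, inbreeding_f = sy$inbreeding_f,
    n_loci = sy$n_loci, n_samples_per_deme = sy$n_samples_per_deme,
    missing_rate = sy$missing_rate, seed = seed)
  cohort <- simulate_cohort_genotypes(model)
  emit(cohort$meta, "cohort_meta.tsv")

  run_stage("mask", function() {
    track <- simulate_depth_track(50, dropout_windows = c(10, 11, 12),
                                  spike_windows = 30, seed = seed,
                                  window_size = config$mask$window)
    seg <- good_segments(track, config$mask$low, config$mask$high,
                         config$mask$min_run)
    emit(seg, "good_segments.bed")
  })
  run_stage("cleanup", function() {
    stack <- simulate_read_stack(paste(rep("ACGT", 15), collapse = ""),
                                 depth = 30, contaminant_fraction = 0.3,
                                 contaminant_divergence = 0.1, seed = seed)
    kept <- protocol_a(stack$reads, stack$reference,
                       config$cleanup$window, config$cleanup$step)
    kept <- protocol_b(kept, config$cleanup$min_overlap,
                       config$cleanup$identity,
                       config$cleanup$keep_singletons)
    emit(as.data.frame(kept), "clean_reads.tsv")
  })
  sel <- NULL
  run_stage("genoprep", function() {
    comp <- sample_completeness(cohort$genotypes,
                                config$genoprep$completeness)
    emit(comp, "sample_completeness.tsv")
    sel <<- select_loci(cohort$genotypes, "pca",
                        min_allele_samples = config$genoprep$min_allele_samples)
    ba3 <- select_ba3_loci(cohort$genotypes, config$genoprep$ba3_spacing)
    export_genotypes(cohort$genotypes, sel, "structure",
                     file.path(out_dir, "genotypes.str"))
    export_genotypes(cohort$genotypes, ba3, "ba3",
                     file.path(out_dir, "genotypes.ba3"))
    outputs <<- c(outputs, file.path(out_dir, c("genotypes.str",
                                                "genotypes.ba3")))
  })
  run_stage("popgen", function() {
    fst <- reich_fst(cohort$genotypes,
                     config$popgen$min_samples_per_locality)
    emit(as.data.frame(fst$fst), "fst.tsv")
    dist <- haversine_matrix(cohort$meta)
    mt <- mantel_test(dist[fst$localities, fst$localities],
                      standardize_fst(fst),
                      config$popgen$n_permutations, seed = seed)
    emit(data.frame(r = mt$r, p = mt$p,
                    n_permutations = mt$n_permutations), "mantel.tsv")
    pc <- pca_genotypes(cohort$genotypes, sel, n_components = 2)
    emit(data.frame(sample_id = rownames(pc$scores), pc$scores),
         "pca_scores.tsv")
  })
  div_windows <- NULL
  run_stage("diversity", function() {
    nper <- sy$n_species_samples
    per_species <- lapply(c(samuelis = 1L, melissa = 2L, fridayi = 3L),
      function(off) {
        m <- demographic_model(n_demes = 1, n_loci = sy$n_loci,
                               n_samples_per_deme = nper,
                               inbreeding_f = 0, missing_rate = 0.02,
                               seed = seed + off)
        simulate_cohort_genotypes(m)$genotypes
      })
    div_windows <<- do.call(rbind, lapply(names(per_species), function(s)
      multiallelic_window_ratios(per_species[[s]], s,
                                 config$diversity$window,
                                 config$diversity$subsample, seed = seed)))
    emit(div_windows, "window_diversity.tsv")
  })
  loss <- NULL
  run_stage("loss_regions", function() {
    loss <<- loss_of_diversity_windows(div_windows,
                                       alpha = config$diversity$alpha)
    emit(loss, "loss_regions.tsv")
  })
  run_stage("region_genes", function() {
    flagged <- loss[loss$flag, , drop = FALSE]
    genes <- data.frame(contig = "ctg1",
                        start = seq(0, 40000, by = 20000),
                        end = seq(6000, 46000, by = 20000),
                        gene_id = sprintf("gene%02d", 1:3))
    hits <- genes_in_regions(genes, flagged, config$diversity$pad,
                             config$diversity$min_gene_overlap,
                             config$diversity$window)
    emit(hits, "region_genes.tsv")
  })
  run_stage("protein", function() {
    panel <- simulate_protein_panel(
      n_proteins = sy$n_proteins, lengths = sy$protein_length,
      planted_savs = data.frame(protein = 1, position = 10), seed = seed)
    savs <- find_sav_candidates(
      panel, focal_coverage = config$protein$focal_coverage,
      prevalence = config$protein$prevalence,
      dominant = config$protein$dominant,
      max_other_freq = config$protein$max_other_freq)
    savs$buried <- classify_burial(rep(0.1, nrow(savs)),
                                   config$protein$rsa_cutoff)
    emit(savs[, c("protein_id", "position", "residue", "focal_freq",
                  "buried")], "sav_candidates.tsv")
  })
  manifest <- list(package = "karnerpop",
                   version = as.character(utils::packageVersion("karnerpop")),
                   seed = seed, config = unclass(config),
                   stages = status,
                   files = as.list(setNames(unname(tools::md5sum(sort(outputs))),
                                            basename(sort(outputs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
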