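#' Export genotypes for downstream population-structure tools
#'
#' Writes the selected loci of a genotype matrix in one of three formats:
#' \describe{
#'   \item{structure}{a locus-label header, then two rows per individual
#'     (`sample locality allele...`), missing coded -9;}
#'   \item{ba3}{BA3-SNPs immanc-style rows `individual locality locus a1 a2`,
#'     missing coded 0;}
#'   \item{eigenstrat}{a `.geno`/`.snp`/`.ind` triplet; `.geno` rows are one
#'     character per sample counting copies of allele code 2 (9 = missing).
#'     Only bi-allelic codes 1/2 are representable.}
#' }
#' Each format round-trips through the matching `read_*` function.
#'
#' @param g a [genotype_matrix()].
#' @param locus_set integer locus indices (e.g. from [select_loci()]).
#' @param format `"structure"`, `"ba3"` or `"eigenstrat"`.
#' @param file output path; for `eigenstrat` a prefix to which `.geno`,
#'   `.snp` and `.ind` are appended.
#' @return The path(s) written, invisibly.
#' @export
export_genotypes <- function(g, locus_set,
                             format = c("structure", "ba3", "eigenstrat"),
                             file) {
  format <- match.arg(format)
  if (length(locus_set) && (min(locus_set) < 1 || max(locus_set) > ncol(g$a1)))
    stop("locus_set outside matrix loci")
  gs <- g[, locus_set]
  switch(format,
         structure = write_structure(gs, file),
         ba3 = write_ba3(gs, file),
         eigenstrat = write_eigenstrat(gs, file))
}

locus_labels <- function(g) sprintf("%s:%d", g$loci$contig, g$loci$pos)

parse_locus_labels <- function(lab) {
  parts <- strsplit(lab, ":", fixed = TRUE)
  data.frame(contig = vapply(parts, `[`, "", 1),
             pos = as.integer(vapply(parts, `[`, "", 2)))
}

write_structure <- function(g, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines(paste(locus_labels(g), collapse = " "), con)
  code <- function(m) { m[is.na(m)] <- -9L; m }
  a1 <- code(g$a1); a2 <- code(g$a2)
  for (i in seq_len(nrow(a1))) {
    pre <- paste(g$samples$sample_id[i], g$samples$locality[i])
    writeLines(paste(pre, paste(a1[i, ], collapse = " ")), con)
    writeLines(paste(pre, paste(a2[i, ], collapse = " ")), con)
  }
  invisible(file)
}

#' Read a STRUCTURE two-rows-per-individual file
#'
#' @param file path written by [export_genotypes()] with
#'   `format = "structure"`.
#' @return A [genotype_matrix()] (depth unknown).
#' @export
read_structure <- function(file) {
  lines <- readLines(file)
  loci <- parse_locus_labels(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  body <- do.call(rbind, strsplit(lines[-1], " ", fixed = TRUE))
  if (nrow(body) %% 2 != 0) stop("malformed STRUCTURE file")
  geno <- matrix(as.integer(body[, -(1:2), drop = FALSE]), nrow(body))
  geno[geno == -9L] <- NA_integer_
  odd <- seq(1, nrow(body), by = 2)
  genotype_matrix(geno[odd, , drop = FALSE], geno[odd + 1, , drop = FALSE],
                  NULL, loci,
                  data.frame(sample_id = body[odd, 1], locality = body[odd, 2]))
}

write_ba3 <- function(g, file) {
  lab <- locus_labels(g)
  code <- function(m) { m[is.na(m)] <- 0L; m }
  a1 <- code(g$a1); a2 <- code(g$a2)
  n <- nrow(a1); L <- ncol(a1)
  df <- data.frame(
    individual = rep(g$samples$sample_id, each = L),
    locality = rep(g$samples$locality, each = L),
    locus = rep(lab, times = n),
    a1 = as.vector(t(a1)), a2 = as.vector(t(a2)))
  write.table(df, file, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Read a BA3-SNPs genotype file
#'
#' @param file path written by [export_genotypes()] with `format = "ba3"`.
#' @return A [genotype_matrix()] (depth unknown).
#' @export
read_ba3 <- function(file) {
  df <- read.table(file, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("individual", "locality", "locus",
                                 "a1", "a2"))
  samples <- unique(df[c("individual", "locality")])
  lab <- unique(df$locus)
  dec <- function(v) { v[v == 0L] <- NA_integer_; v }
  a1 <- matrix(NA_integer_, nrow(samples), length(lab),
               dimnames = list(samples$individual, lab))
  a2 <- a1
  i <- match(df$individual, samples$individual)
  j <- match(df$locus, lab)
  a1[cbind(i, j)] <- dec(df$a1)
  a2[cbind(i, j)] <- dec(df$a2)
  genotype_matrix(a1, a2, NULL, parse_locus_labels(lab),
                  data.frame(sample_id = samples$individual,
                             locality = samples$locality))
}

write_eigenstrat <- function(g, prefix) {
  codes <- c(g$a1, g$a2)
  if (any(!is.na(codes) & !(codes %in% c(1L, 2L))))
    stop("EIGENSTRAT export requires bi-allelic codes 1/2")
  dos <- (g$a1 == 2L) + (g$a2 == 2L)
  dos[is.na(dos)] <- 9L
  geno_lines <- apply(dos, 2, paste, collapse = "")
  writeLines(geno_lines, paste0(prefix, ".geno"))
  snp <- data.frame(id = locus_labels(g), contig = g$loci$contig,
                    gen = 0, pos = g$loci$pos + 1L)
  write.table(snp, paste0(prefix, ".snp"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ind <- data.frame(g$samples$sample_id, "U", g$samples$locality)
  write.table(ind, paste0(prefix, ".ind"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".geno", ".snp", ".ind")))
}

#' Read an EIGENSTRAT geno/snp/ind triplet
#'
#' Heterozygotes are reconstructed in canonical (1,2) order; compare against
#' [canonical_calls()] of the source matrix for round-trip checks.
#'
#' @param prefix common path prefix of the `.geno`, `.snp`, `.ind` files.
#' @return A [genotype_matrix()] (depth unknown).
#' @export
read_eigenstrat <- function(prefix) {
  geno <- readLines(paste0(prefix, ".geno"))
  snp <- read.delim(paste0(prefix, ".snp"), header = FALSE)
  ind <- read.delim(paste0(prefix, ".ind"), header = FALSE)
  dos <- do.call(cbind, lapply(geno, function(l)
    as.integer(strsplit(l, "", fixed = TRUE)[[1]])))
  a1 <- ifelse(dos == 2L, 2L, 1L)
  a2 <- ifelse(dos >= 1L, 2L, 1L)
  a1[dos == 9L] <- NA_integer_; a2[dos == 9L] <- NA_integer_
  genotype_matrix(a1, a2, NULL,
                  data.frame(contig = snp[[2]], pos = snp[[4]] - 1L),
                  data.frame(sample_id = ind[[1]], locality = ind[[3]]))
}

#' Canonical (sorted-allele) view of diploid calls
#'
#' Diploid genotypes are unordered pairs; this returns the matrix pair with
#' each genotype's smaller allele code first, for order-insensitive
#' comparisons.
#'
#' @param g a [genotype_matrix()].
#' @return The same `genotype_matrix` with canonically ordered alleles.
#' @export
canonical_calls <- function(g) {
  genotype_matrix(pmin(g$a1, g$a2), pmax(g$a1, g$a2), g$depth,
                  g$loci, g$samples)
}

#' Write genotypes as VCF
#'
#' Allele codes map to placeholder bases (1 = REF `A`; 2-4 = ALT `C`,`G`,`T`)
#' and per-entry depth is written in the `DP` FORMAT field. The output is
#' bgzipped (`.vcf.gz`) as produced by `vcfR`.
#'
#' @param g a [genotype_matrix()].
#' @param file output path (".vcf.gz").
#' @return The file path, invisibly.
#' @export
write_genotypes_vcf <- function(g, file) {
  base_of <- c("A", "C", "G", "T")
  L <- ncol(g$a1)
  alt <- vapply(seq_len(L), function(j) {
    codes <- sort(unique(c(g$a1[, j], g$a2[, j])))
    codes <- codes[!is.na(codes) & codes > 1]
    if (length(codes)) paste(base_of[codes], collapse = ",") else "."
  }, "")
  fix <- cbind(CHROM = g$loci$contig, POS = as.character(g$loci$pos + 1L),
               ID = locus_labels(g), REF = "A", ALT = alt, QUAL = ".",
               FILTER = "PASS", INFO = ".")
  gt_body <- matrix("", nrow = L, ncol = nrow(g$a1))
  for (i in seq_len(nrow(g$a1))) {
    gt <- ifelse(is.na(g$a1[i, ]), "./.",
                 paste0(g$a1[i, ] - 1L, "/", g$a2[i, ] - 1L))
    gt_body[, i] <- paste0(gt, ":", g$depth[i, ])
  }
  colnames(gt_body) <- g$samples$sample_id
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")))
  v@meta <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">")
  v@fix <- fix
  v@gt <- cbind(FORMAT = "GT:DP", gt_body)
  vcfR::write.vcf(v, file)
  invisible(file)
}

#' Read genotypes from VCF
#'
#' @param file VCF path (.vcf or .vcf.gz).
#' @param localities optional named vector mapping sample_id to locality.
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(file, localities = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  split_gt <- function(k) {
    al <- t(vapply(strsplit(gt, "[/|]"), function(x)
      suppressWarnings(as.integer(x[seq_len(2)])), integer(2)))
    matrix(al[, k] + 1L, nrow = nrow(gt))
  }
  a1 <- t(split_gt(1)); a2 <- t(split_gt(2))
  dp <- t(dp); dp[is.na(dp)] <- 0L
  loci <- data.frame(contig = vcfR::getCHROM(v),
                     pos = as.integer(vcfR::getPOS(v)) - 1L)
  ids <- colnames(gt)
  loc <- if (is.null(localities)) rep(NA_character_, length(ids))
         else unname(localities[ids])
  genotype_matrix(a1, a2, dp, loci,
                  data.frame(sample_id = ids, locality = loc))
}

#' Write aligned reads as SAM text
#'
#' Emits an @HD/@SQ header and one ungapped record per read (flag 0, MAPQ
#' 60, CIGAR `<len>M`, `*` quality).
#'
#' @param reads a [read_set()].
#' @param reference named character vector of contig sequences.
#' @param file output path.
#' @return The file path, invisibly.
#' @export
write_sam <- function(reads, reference, file) {
  con <- file(file, "w"); on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (ctg in names(reference))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ctg, nchar(reference[[ctg]])), con)
  for (i in seq_len(nrow(reads)))
    writeLines(paste(reads$read_id[i], 0, reads$contig[i],
                     reads$start[i] + 1L, 60,
                     paste0(nchar(reads$sequence[i]), "M"),
                     "*", 0, 0, reads$sequence[i], "*", sep = "\t"), con)
  invisible(file)
}

#' Read ungapped alignments from SAM text
#'
#' Only simple `<len>M` CIGARs are consumed (all the cleanup protocols
#' operate on); records with other CIGARs are dropped with a warning.
#'
#' @param file SAM path.
#' @return A [read_set()].
#' @export
read_sam <- function(file) {
  lines <- grep("^@", readLines(file), invert = TRUE, value = TRUE)
  if (!length(lines)) return(read_set(character(), character(),
                                      integer(), character()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  cig <- vapply(f, `[`, "", 6)
  simple <- grepl("^[0-9]+M$", cig)
  if (any(!simple))
    warning(sum(!simple), " record(s) with non-M CIGARs dropped")
  f <- f[simple]
  read_set(vapply(f, `[`, "", 1), vapply(f, `[`, "", 3),
           as.integer(vapply(f, `[`, "", 4)) - 1L,
           vapply(f, `[`, "", 10))
}

#' Read sample metadata
#'
#' Tab-separated metadata with columns `sample_id`, `locality_id`,
#' `latitude`, `longitude`, `collection_year`, `species_label`.
#'
#' @param file TSV path.
#' @return Validated data.frame.
#' @export
read_cohort_meta <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "locality_id", "latitude", "longitude",
            "collection_year", "species_label")
  if (!all(need %in% names(df)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180))
    stop("coordinates out of range")
  df
}

#' Read a per-locality inbreeding coefficient table
#'
#' Two-column TSV (`locality_id`, `inbreeding_coefficient`), e.g. as reported
#' by BA3-SNPs.
#'
#' @param file TSV path.
#' @return data.frame with `locality_id` and `inbreeding_coefficient`.
#' @export
read_inbreeding_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("locality_id", "inbreeding_coefficient") %in% names(df)))
    stop("expected columns locality_id, inbreeding_coefficient")
  df
}
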