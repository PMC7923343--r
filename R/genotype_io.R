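#' Read genotypes from disk
#'
#' Two dialects are supported. `plink_text` reads `<path>.ped` /
#' `<path>.map` (chromosome, snp_id, genetic distance ignored,
#' position_bp; two allele columns per SNP in the .ped, `0 0` missing).
#' `tsv_matrix` is the native format: `<path>_geno.tsv` (header of
#' snp_ids, one row per sample, cells 0/1/2/NA) plus companion
#' `<path>_variants.tsv` and `<path>_samples.tsv`.
#'
#' For `plink_text` the .ped carries no allele-order metadata, so the
#' counted allele (`allele_a`) defaults to the lexicographically smaller
#' of the two alleles observed at each SNP; pass `alleles` to force a
#' coding (e.g. for exact round-trips with arbitrary allele order).
#'
#' @param path file prefix (without extension/suffix).
#' @param format `"plink_text"` or `"tsv_matrix"`.
#' @param alleles optional data.frame `snp_id`, `allele_a`, `allele_b`
#'   fixing the counted allele for `plink_text`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink_text", "tsv_matrix"),
                           alleles = NULL) {
  format <- match.arg(format)
  switch(format,
         plink_text = read_plink_text(path, alleles),
         tsv_matrix = read_tsv_matrix(path))
}

read_plink_text <- function(prefix, alleles = NULL) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  for (p in c(map_path, ped_path))
    if (!file.exists(p)) stop("file not found: ", p)
  map <- utils::read.table(map_path, header = FALSE, sep = "",
                           colClasses = "character")
  if (ncol(map) != 4)
    stop("parse error in ", map_path, ": expected 4 columns, got ", ncol(map))
  variants <- data.frame(
    snp_id = map[[2]], chromosome = map[[1]],
    position_bp = as.integer(map[[4]]),
    allele_a = NA_character_, allele_b = NA_character_,
    stringsAsFactors = FALSE
  )
  if (anyNA(variants$position_bp))
    stop("parse error in ", map_path, ": non-integer position at line ",
         which(is.na(variants$position_bp))[1])
  m <- nrow(variants)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  a1 <- matrix(NA_character_, n, m)
  a2 <- matrix(NA_character_, n, m)
  sample_id <- character(n)
  population <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m)
      stop("parse error in ", ped_path, " at line ", i, ": expected ",
           6 + 2 * m, " fields, got ", length(f))
    population[i] <- f[1]
    sample_id[i] <- f[2]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1, 2 * m, by = 2)]
    a2[i, ] <- al[seq(2, 2 * m, by = 2)]
  }
  half_missing <- xor(a1 == "0", a2 == "0")
  if (any(half_missing)) {
    bad <- which(half_missing, arr.ind = TRUE)[1, ]
    stop("parse error in ", ped_path, " at line ", bad[1],
         ": half-missing genotype at SNP ", variants$snp_id[bad[2]])
  }
  dosage <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- setdiff(unique(c(a1[, j], a2[, j])), "0")
    if (length(obs) > 2)
      stop("parse error in ", ped_path, ": more than two alleles at SNP ",
           variants$snp_id[j], " (", paste(obs, collapse = ","), ")")
    if (!is.null(alleles)) {
      k <- match(variants$snp_id[j], alleles$snp_id)
      if (is.na(k)) stop("no allele coding supplied for SNP ",
                         variants$snp_id[j])
      ab <- c(alleles$allele_a[k], alleles$allele_b[k])
      if (!all(obs %in% ab))
        stop("parse error: observed alleles at SNP ", variants$snp_id[j],
             " not in supplied coding")
    } else {
      ab <- sort(obs)
      if (length(ab) == 0) ab <- c("A", "B")       # all-missing column
      if (length(ab) == 1) ab <- c(ab, setdiff(c("A", "B", "C"), ab)[1])
    }
    variants$allele_a[j] <- ab[1]
    variants$allele_b[j] <- ab[2]
    called <- a1[, j] != "0"
    dosage[called, j] <- (a1[called, j] == ab[1]) + (a2[called, j] == ab[1])
  }
  samples <- data.frame(sample_id = sample_id, population = population,
                        role = "crossbred", stringsAsFactors = FALSE)
  genotype_matrix(dosage, variants, samples)
}

read_tsv_matrix <- function(prefix) {
  gp <- paste0(prefix, "_geno.tsv")
  vp <- paste0(prefix, "_variants.tsv")
  sp <- paste0(prefix, "_samples.tsv")
  for (p in c(gp, vp, sp)) if (!file.exists(p)) stop("file not found: ", p)
  variants <- utils::read.table(vp, header = TRUE, sep = "\t",
                                colClasses = c("character", "character",
                                               "numeric", "character",
                                               "character"))
  samples <- utils::read.table(sp, header = TRUE, sep = "\t",
                               colClasses = "character")
  geno <- utils::read.table(gp, header = TRUE, sep = "\t",
                            check.names = FALSE, na.strings = "NA")
  if (nrow(geno) > 0 && names(geno)[1] != "sample_id")
    stop("parse error in ", gp, ": first column must be sample_id")
  dos <- as.matrix(geno[, -1, drop = FALSE])
  bad <- which(!(dos %in% c(0, 1, 2, NA)))
  if (length(bad))
    stop("parse error in ", gp, ": genotype code outside {0,1,2,NA} at cell ",
         bad[1])
  if (!identical(colnames(dos), variants$snp_id))
    stop("snp_id mismatch between ", gp, " and ", vp)
  if (!identical(as.character(geno$sample_id), samples$sample_id))
    stop("sample_id mismatch between ", gp, " and ", sp)
  genotype_matrix(dos, variants, samples)
}

#' Write genotypes to disk
#'
#' Inverse of [read_genotypes()]; see that help page for the dialects.
#'
#' @param g a `genotype_matrix`.
#' @param path file prefix.
#' @param format `"plink_text"` or `"tsv_matrix"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("plink_text", "tsv_matrix")) {
  format <- match.arg(format)
  validate_genotype_matrix(g)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("I/O error: directory does not exist: ", dir)
  if (format == "plink_text") write_plink_text(g, path)
  else write_tsv_matrix(g, path)
  invisible(path)
}

write_plink_text <- function(g, prefix) {
  op <- options(scipen = 15)          # positions never in scientific form
  on.exit(options(op), add = TRUE)
  v <- g$variants
  utils::write.table(
    data.frame(v$chromosome, v$snp_id, 0, v$position_bp),
    paste0(prefix, ".map"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  n <- nrow(g$dosage); m <- ncol(g$dosage)
  con <- file(paste0(prefix, ".ped"), "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    d <- g$dosage[i, ]
    a1 <- ifelse(is.na(d), "0", ifelse(d >= 1, v$allele_a, v$allele_b))
    a2 <- ifelse(is.na(d), "0", ifelse(d == 2, v$allele_a, v$allele_b))
    al <- character(2 * m)
    if (m > 0) {
      al[seq(1, 2 * m, 2)] <- a1
      al[seq(2, 2 * m, 2)] <- a2
    }
    writeLines(paste(c(g$samples$population[i], g$samples$sample_id[i],
                       "0", "0", "0", "-9", al), collapse = " "), con)
  }
  invisible(prefix)
}

write_tsv_matrix <- function(g, prefix) {
  op <- options(scipen = 15)
  on.exit(options(op), add = TRUE)
  utils::write.table(
    g$variants[c("snp_id", "chromosome", "position_bp",
                 "allele_a", "allele_b")],
    paste0(prefix, "_variants.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(g$samples, paste0(prefix, "_samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  geno <- data.frame(sample_id = g$samples$sample_id,
                     g$dosage, check.names = FALSE,
                     stringsAsFactors = FALSE)
  colnames(geno) <- c("sample_id", g$variants$snp_id)
  utils::write.table(geno, paste0(prefix, "_geno.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(prefix)
}

#' Filter SNPs and samples by call rate
#'
#' Quality control mirroring array pipelines: SNPs whose call rate is not
#' strictly above `snp_threshold` are dropped first, then samples whose
#' call rate on the remaining SNPs is not strictly above
#' `sample_threshold`. The SNP-then-sample order is fixed.
#'
#' @param g a `genotype_matrix`.
#' @param snp_threshold,sample_threshold retain call rates `> threshold`
#'   (default 0.9, i.e. "higher than 90\%").
#' @return a filtered `genotype_matrix` (possibly empty).
#' @export
filter_call_rate <- function(g, snp_threshold = 0.9, sample_threshold = 0.9) {
  stopifnot(snp_threshold >= 0, snp_threshold <= 1,
            sample_threshold >= 0, sample_threshold <= 1)
  called <- !is.na(g$dosage)
  keep_snp <- if (nrow(called)) colMeans(called) > snp_threshold
              else rep(TRUE, ncol(called))
  d <- g$dosage[, keep_snp, drop = FALSE]
  keep_smp <- if (ncol(d)) rowMeans(!is.na(d)) > sample_threshold
              else rep(TRUE, nrow(d))
  genotype_matrix(d[keep_smp, , drop = FALSE],
                  g$variants[keep_snp, , drop = FALSE],
                  g$samples[keep_smp, , drop = FALSE])
}

#' Merge two genotype datasets on their common SNPs
#'
#' Keeps the SNP intersection (in the first dataset's order) and the
#' sample union. Shared SNPs are matched by `snp_id`; when the second
#' dataset counts the opposite allele, its dosages are flipped
#' (`2 - g`). An allele pair that cannot be reconciled by swapping
#' raises a merge error naming the offending SNPs.
#'
#' @param a,b `genotype_matrix` objects with disjoint sample ids.
#' @return a merged `genotype_matrix` coded on `a`'s alleles.
#' @export
merge_on_common_snps <- function(a, b) {
  if (length(intersect(a$samples$sample_id, b$samples$sample_id)))
    stop("sample_id collision between datasets")
  common <- intersect(a$variants$snp_id, b$variants$snp_id)
  ai <- match(common, a$variants$snp_id)
  bi <- match(common, b$variants$snp_id)
  va <- a$variants[ai, , drop = FALSE]
  vb <- b$variants[bi, , drop = FALSE]
  same <- va$allele_a == vb$allele_a & va$allele_b == vb$allele_b
  swapped <- va$allele_a == vb$allele_b & va$allele_b == vb$allele_a
  bad <- !(same | swapped)
  if (any(bad))
    stop("merge error: irreconcilable alleles at SNPs: ",
         paste(common[bad], collapse = ", "))
  db <- b$dosage[, bi, drop = FALSE]
  if (any(swapped))
    db[, swapped] <- 2L - db[, swapped]
  dosage <- rbind(a$dosage[, ai, drop = FALSE], db)
  samples <- rbind(a$samples[intersect(names(a$samples), names(b$samples))],
                   b$samples[intersect(names(a$samples), names(b$samples))])
  genotype_matrix(dosage, va, samples)
}
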