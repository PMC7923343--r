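#' admixpanel: small SNP panels for breed proportion and parentage
#'
#' Design and evaluate small ancestry-informative SNP panels for admixed
#' dairy cattle with three ancestral groups (European taurine, African
#' taurine, indicine): allele-frequency-difference panel selection with
#' stepwise physical-distance pruning, supervised maximum-likelihood
#' admixture estimation, and opposing-homozygote parentage assignment.
#'
#' @keywords internal
"_PACKAGE"

MISSING_DOSAGE <- NA_integer_

#' Construct a genotype matrix
#'
#' The central container of the package: an individuals-by-SNPs dosage
#' matrix holding counts of `allele_a` (0, 1, 2 or `NA` for missing),
#' together with a variant map (chromosome, physical position, alleles)
#' and a sample table (population label, reference/crossbred role).
#'
#' @param dosage integer matrix, `n_samples x n_snps`, entries in
#'   `{0, 1, 2, NA}`; interpreted as the count of `allele_a`.
#' @param variants data.frame with columns `snp_id`, `chromosome`,
#'   `position_bp` (1-based), `allele_a`, `allele_b`.
#' @param samples data.frame with columns `sample_id`, `population` and
#'   optionally `role` (one of `"reference"`, `"crossbred"`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$role)) samples$role <- "crossbred"
  g <- structure(
    list(dosage = dosage, variants = variants, samples = samples),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(g)
  rownames(g$dosage) <- samples$sample_id
  colnames(g$dosage) <- variants$snp_id
  g
}

validate_genotype_matrix <- function(g) {
  v <- g$variants
  s <- g$samples
  need_v <- c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b")
  if (!all(need_v %in% names(v)))
    stop("variants must have columns: ", paste(need_v, collapse = ", "))
  if (!all(c("sample_id", "population") %in% names(s)))
    stop("samples must have columns sample_id, population")
  if (anyDuplicated(v$snp_id))
    stop("validation error: duplicated snp_id: ",
         paste(unique(v$snp_id[duplicated(v$snp_id)]), collapse = ", "))
  if (anyDuplicated(s$sample_id))
    stop("validation error: duplicated sample_id: ",
         paste(unique(s$sample_id[duplicated(s$sample_id)]), collapse = ", "))
  if (nrow(v) > 0 && any(v$position_bp < 1))
    stop("position_bp must be >= 1")
  if (anyDuplicated(paste(v$chromosome, v$position_bp)))
    stop("duplicated (chromosome, position_bp) pair")
  if (nrow(v) > 0 && any(v$allele_a == v$allele_b))
    stop("allele_a must differ from allele_b")
  if (nrow(g$dosage) != nrow(s) || ncol(g$dosage) != nrow(v))
    stop("dosage dimensions inconsistent with samples/variants")
  bad <- !(g$dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    stop("illegal dosage values (must be 0, 1, 2 or NA)")
  invisible(g)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Number of samples / SNPs in a genotype matrix
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_snps <- function(g) ncol(g$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs (%.1f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage),
    if (length(x$dosage)) 100 * mean(is.na(x$dosage)) else 0
  ))
  pops <- table(x$samples$population)
  cat("populations:", paste(sprintf("%s (%d)", names(pops), pops),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param g a `genotype_matrix`.
#' @param samples character vector of sample ids (or NULL to keep all).
#' @param snps character vector of snp ids (or NULL to keep all); the
#'   returned variants follow the order given here.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(g, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(g$dosage)) else {
    i <- match(samples, g$samples$sample_id)
    if (anyNA(i)) stop("unknown sample ids: ",
                       paste(samples[is.na(i)], collapse = ", "))
    i
  }
  vi <- if (is.null(snps)) seq_len(ncol(g$dosage)) else {
    j <- match(snps, g$variants$snp_id)
    if (anyNA(j)) stop("unknown snp ids: ",
                       paste(snps[is.na(j)], collapse = ", "))
    j
  }
  genotype_matrix(g$dosage[si, vi, drop = FALSE],
                  g$variants[vi, , drop = FALSE],
                  g$samples[si, , drop = FALSE])
}
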