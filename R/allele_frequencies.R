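#' Construct an allele-frequency table
#'
#' Per-population, per-SNP frequency of the counted allele (`allele_a`)
#' together with the number of called genotypes behind each estimate.
#' Frequencies are `NA` (flagged undefined) where the call count is 0.
#'
#' @param freq numeric matrix, SNPs x populations, entries in `[0,1]` or
#'   `NA`; rownames are snp_ids, colnames population labels.
#' @param n_called integer matrix of the same shape (may be `NA` for
#'   parametric frequencies, e.g. simulated population parameters).
#' @param variants optional variant map carried along for pruning.
#' @return an object of class `freq_table`.
#' @export
freq_table <- function(freq, n_called = NULL, variants = NULL) {
  freq <- as.matrix(freq)
  if (is.null(n_called))
    n_called <- matrix(NA_integer_, nrow(freq), ncol(freq),
                       dimnames = dimnames(freq))
  stopifnot(all(dim(freq) == dim(n_called)))
  ok <- is.na(freq) | (freq >= 0 & freq <= 1)
  if (!all(ok)) stop("frequencies must lie in [0,1]")
  structure(list(freq = freq, n_called = as.matrix(n_called),
                 variants = variants),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("freq_table: %d SNPs x %d populations (%s)\n",
              nrow(x$freq), ncol(x$freq),
              paste(colnames(x$freq), collapse = ", ")))
  invisible(x)
}

#' Population labels of a frequency table
#' @param freqs a `freq_table`.
#' @return character vector.
#' @export
populations <- function(freqs) colnames(freqs$freq)

get_pop_freq <- function(freqs, population) {
  if (!population %in% colnames(freqs$freq))
    stop("unknown population: ", population)
  freqs$freq[, population]
}

#' Per-population allele frequencies from genotypes
#'
#' The frequency of `allele_a` in each group is the dosage sum over the
#' group's called genotypes divided by twice the call count
#' (individual-level pooling: a group may pool several breeds and each
#' animal contributes its genotypes directly).
#'
#' @param g a [genotype_matrix()].
#' @param grouping named character vector mapping `sample_id` to a group
#'   label; defaults to the sample table's `population` column. Samples
#'   absent from `grouping` are ignored.
#' @return a [freq_table()] carrying `g`'s variant map.
#' @export
population_allele_frequencies <- function(g, grouping = NULL) {
  if (is.null(grouping)) {
    grouping <- stats::setNames(g$samples$population, g$samples$sample_id)
  }
  unknown <- setdiff(names(grouping), g$samples$sample_id)
  if (length(unknown))
    stop("grouped samples not in genotype matrix: ",
         paste(unknown, collapse = ", "))
  groups <- sort(unique(grouping))
  m <- ncol(g$dosage)
  freq <- matrix(NA_real_, m, length(groups),
                 dimnames = list(g$variants$snp_id, groups))
  ncall <- matrix(0L, m, length(groups),
                  dimnames = list(g$variants$snp_id, groups))
  for (grp in groups) {
    ids <- names(grouping)[grouping == grp]
    if (!length(ids)) stop("empty group: ", grp)
    d <- g$dosage[match(ids, g$samples$sample_id), , drop = FALSE]
    called <- colSums(!is.na(d))
    tot <- colSums(d, na.rm = TRUE)
    f <- ifelse(called > 0, tot / (2 * called), NA_real_)
    freq[, grp] <- f
    ncall[, grp] <- as.integer(called)
  }
  freq_table(freq, ncall, variants = g$variants)
}

#' Minor allele frequency for one population
#'
#' `MAF = min(p, 1 - p)`; undefined frequencies propagate as `NA`.
#'
#' @param freqs a `freq_table`.
#' @param population population label.
#' @return named numeric vector in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(freqs, population) {
  p <- get_pop_freq(freqs, population)
  pmin(p, 1 - p)
}

#' Absolute allele-frequency difference between two populations
#'
#' The panel-selection score `|pA_i - pA_j|`: symmetric in the two
#' populations and invariant to which allele is counted. SNPs with an
#' undefined frequency in either population score `NA` and are excluded
#' from ranking.
#'
#' @param freqs a `freq_table`.
#' @param pop_i,pop_j population labels.
#' @return named numeric vector in `[0,1]` (or `NA`).
#' @export
absolute_frequency_difference <- function(freqs, pop_i, pop_j) {
  abs(get_pop_freq(freqs, pop_i) - get_pop_freq(freqs, pop_j))
}

#' Weighted hypothetical ancestral population
#'
#' Combines two ancestral populations into a hypothetical pool with
#' frequency `w * p_a + (1 - w) * p_b` per SNP, e.g. an AFT-BI pool with
#' weightings from 0.1:0.9 to 0.9:0.1.
#'
#' @param freqs a `freq_table`.
#' @param pop_a,pop_b population labels.
#' @param w weight on `pop_a`, in `[0,1]`.
#' @return named numeric frequency vector (NA where either input is NA).
#' @export
weighted_hypothetical_frequency <- function(freqs, pop_a, pop_b, w) {
  stopifnot(w >= 0, w <= 1)
  w * get_pop_freq(freqs, pop_a) + (1 - w) * get_pop_freq(freqs, pop_b)
}

#' Attach a frequency vector to a table as a new population
#'
#' @param freqs a `freq_table`.
#' @param name new population label.
#' @param p numeric frequency vector of length `nrow(freqs$freq)`.
#' @return a `freq_table` with one more column.
#' @export
add_population_frequencies <- function(freqs, name, p) {
  stopifnot(length(p) == nrow(freqs$freq))
  if (name %in% colnames(freqs$freq)) stop("population exists: ", name)
  freq <- cbind(freqs$freq, p)
  colnames(freq)[ncol(freq)] <- name
  nc <- cbind(freqs$n_called, NA_integer_)
  colnames(nc) <- colnames(freq)
  freq_table(freq, nc, freqs$variants)
}

#' Unweighted breed-mean pooled frequency
#'
#' Sensitivity-check alternative to individual-level pooling: the plain
#' mean of several populations' frequency columns, each breed counting
#' equally regardless of sample size.
#'
#' @param freqs a `freq_table`.
#' @param pops population labels to average.
#' @return named numeric frequency vector.
#' @export
breed_mean_frequency <- function(freqs, pops) {
  miss <- setdiff(pops, colnames(freqs$freq))
  if (length(miss)) stop("unknown population: ", paste(miss, collapse = ", "))
  rowMeans(freqs$freq[, pops, drop = FALSE])
}

#' Write / read a frequency table as TSV
#'
#' Layout: `snp_id` column plus one column per population.
#'
#' @param freqs a `freq_table`.
#' @param path output file.
#' @return `path` (write) or a `freq_table` (read).
#' @export
write_freq_table <- function(freqs, path) {
  df <- data.frame(snp_id = rownames(freqs$freq), freqs$freq,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_freq_table
#' @export
read_freq_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$snp_id
  freq_table(m)
}
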