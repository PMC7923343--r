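pair_key <- function(id_1, id_2) {
  paste(pmin(id_1, id_2), pmax(id_1, id_2), sep = "\r")
}

#' Opposing-homozygote counts for candidate pairs
#'
#' For each pair, counts the SNPs at which one individual carries
#' dosage 0 and the other dosage 2 (both called) — impossible for a
#' true parent-offspring pair absent genotyping error — plus the number
#' of SNPs called in both.
#'
#' @param g a [genotype_matrix()].
#' @param pairs data.frame with columns `id_1`, `id_2`.
#' @param snp_ids SNPs to count over (a panel), default all of `g`.
#' @return `pairs` with integer columns `oph` and `n_comparable`.
#' @export
opposing_homozygote_counts <- function(g, pairs, snp_ids = NULL) {
  ids <- unique(c(pairs$id_1, pairs$id_2))
  i <- match(ids, g$samples$sample_id)
  if (anyNA(i)) stop("unknown sample ids: ",
                     paste(ids[is.na(i)], collapse = ", "))
  d <- g$dosage[i, , drop = FALSE]
  if (!is.null(snp_ids)) {
    j <- match(snp_ids, g$variants$snp_id)
    if (anyNA(j)) stop("unknown snp ids: ",
                       paste(snp_ids[is.na(j)], collapse = ", "))
    d <- d[, j, drop = FALSE]
  }
  A0 <- (!is.na(d)) & d == 0L
  A2 <- (!is.na(d)) & d == 2L
  storage.mode(A0) <- "double"; storage.mode(A2) <- "double"
  OPH <- A0 %*% t(A2)
  OPH <- OPH + t(OPH)
  C <- 1 - is.na(d)
  NC <- C %*% t(C)
  r1 <- match(pairs$id_1, ids)
  r2 <- match(pairs$id_2, ids)
  out <- pairs
  out$oph <- as.integer(OPH[cbind(r1, r2)])
  out$n_comparable <- as.integer(NC[cbind(r1, r2)])
  out
}

#' Enumerate candidate parent-offspring pairs
#'
#' Scenario 1 considers every animal a possible parent of every other:
#' all `N (N - 1) / 2` unordered pairs. Scenario 2 searches only
#' (parent, progeny) pairs: `|parents| x |progeny|` pairs, with the
#' progeny set defaulting to all non-parent samples.
#'
#' @param samples a sample table (data.frame with `sample_id`) or a
#'   character vector of sample ids.
#' @param scenario 1 or 2.
#' @param parent_set sample ids known to be parents (scenario 2).
#' @param progeny_set sample ids considered progeny (scenario 2);
#'   default: all samples not in `parent_set`.
#' @return data.frame with columns `id_1`, `id_2`.
#' @export
candidate_pairs <- function(samples, scenario = 1, parent_set = NULL,
                            progeny_set = NULL) {
  ids <- if (is.data.frame(samples)) samples$sample_id else samples
  if (scenario == 1) {
    n <- length(ids)
    if (n < 2) return(data.frame(id_1 = character(0), id_2 = character(0),
                                 stringsAsFactors = FALSE))
    lens <- (n - 1):1
    first <- rep(seq_len(n - 1), lens)
    second <- sequence(lens, from = seq(2, n))
    data.frame(id_1 = ids[first], id_2 = ids[second],
               stringsAsFactors = FALSE)
  } else if (scenario == 2) {
    if (is.null(parent_set) || !length(parent_set))
      stop("scenario 2 requires a non-empty parent_set")
    if (is.null(progeny_set)) progeny_set <- setdiff(ids, parent_set)
    if (length(intersect(parent_set, progeny_set)))
      stop("parent and progeny sets overlap")
    miss <- setdiff(c(parent_set, progeny_set), ids)
    if (length(miss)) stop("unknown sample ids: ",
                           paste(miss, collapse = ", "))
    data.frame(id_1 = rep(parent_set, each = length(progeny_set)),
               id_2 = rep(progeny_set, times = length(parent_set)),
               stringsAsFactors = FALSE)
  } else stop("scenario must be 1 or 2")
}

#' Reconstruct parent-offspring pairs by the opposing-homozygote rule
#'
#' A pair is assigned whenever its opposing-homozygote count is
#' strictly less than `threshold_fraction` of the number of markers in
#' the assay (the panel size, not the per-pair comparable count).
#'
#' @param counts data.frame from [opposing_homozygote_counts()].
#' @param n_markers number of markers in the assay.
#' @param threshold_fraction allowed opposing-homozygote fraction
#'   (default 0.01).
#' @return the assigned subset of `counts`.
#' @export
reconstruct_pairs <- function(counts, n_markers, threshold_fraction = 0.01) {
  stopifnot(threshold_fraction > 0, threshold_fraction < 1, n_markers >= 1)
  counts[counts$oph < threshold_fraction * n_markers, , drop = FALSE]
}

#' Separation value
#'
#' `sv = min(opH over false pairs) - max(opH over true pairs)`.
#' A positive sv means some threshold cleanly separates every true
#' parent-offspring pair from every unrelated pair.
#'
#' @param counts data.frame from [opposing_homozygote_counts()].
#' @param truth_pairs data.frame of true pairs (`parent_id`,
#'   `offspring_id`, or `id_1`/`id_2`).
#' @return integer sv.
#' @export
separation_value <- function(counts, truth_pairs) {
  tr <- is_true_pair(counts, truth_pairs)
  if (!any(tr)) stop("no true pairs among evaluated pairs")
  if (all(tr)) stop("no false pairs among evaluated pairs")
  min(counts$oph[!tr]) - max(counts$oph[tr])
}

is_true_pair <- function(counts, truth_pairs) {
  cols <- if (all(c("parent_id", "offspring_id") %in% names(truth_pairs)))
    c("parent_id", "offspring_id") else c("id_1", "id_2")
  truth_keys <- pair_key(truth_pairs[[cols[1]]], truth_pairs[[cols[2]]])
  pair_key(counts$id_1, counts$id_2) %in% truth_keys
}

#' Powers of assignment and exclusion
#'
#' `Pa` = correct assignments / total parents;
#' `Pe` = 1 - incorrect assignments / total parents. A correct
#' assignment is an assigned pair present in the truth pedigree; every
#' wrongly assigned pair counts once as incorrect. Both statistics are
#' clamped to `[0,1]`.
#'
#' @param assigned data.frame of assigned pairs (`id_1`, `id_2`).
#' @param truth_pairs truth pedigree (see [separation_value()]).
#' @param total_parents baseline number of true parent-offspring pairs.
#' @return named list with `pa` and `pe`.
#' @export
power_statistics <- function(assigned, truth_pairs, total_parents) {
  stopifnot(total_parents >= 1)
  tr <- is_true_pair(assigned, truth_pairs)
  correct <- sum(tr)
  incorrect <- sum(!tr)
  list(pa = min(1, correct / total_parents),
       pe = min(1, max(0, 1 - incorrect / total_parents)))
}
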