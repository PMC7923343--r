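#' Supervised maximum-likelihood admixture estimation
#'
#' Estimates each individual's ancestry vector `q` over K reference
#' populations with the reference allele frequencies held fixed. The
#' per-individual log-likelihood is
#' `l(q) = sum_j [ g_j log(theta_j) + (2 - g_j) log(1 - theta_j) ]` with
#' `theta_j = sum_k q_k p_kj`, maximized over the simplex by EM-style
#' multiplicative updates (non-decreasing likelihood each iteration).
#' Missing genotypes are skipped; reference frequencies are clamped to
#' `[eps, 1 - eps]` so the likelihood stays finite at fixed alleles.
#'
#' Initialization is uniform (deterministic). If the likelihood cannot
#' improve at all from the uniform start (e.g. identical frequency rows
#' for every reference: the model is unidentifiable), the uniform `q`
#' is returned with `converged = FALSE`.
#'
#' @param g a [genotype_matrix()] of the individuals to estimate.
#' @param refs reference frequencies: a `freq_table` or a SNPs x K
#'   matrix with rownames = snp_ids; SNPs must match `g`'s.
#' @param tol relative log-likelihood change declaring convergence
#'   (default 1e-7).
#' @param max_iter iteration cap (default 2000).
#' @param eps frequency clamp (default 1e-6).
#' @param trace if `TRUE`, keep the per-iteration log-likelihood matrix
#'   (individuals x iterations) in the result.
#' @return an `ancestry_estimate`: list with `Q` (n x K simplex rows),
#'   `loglik`, `n_iter`, `converged`, and `ll_trace` when requested.
#' @export
estimate_admixture_supervised <- function(g, refs, tol = 1e-7,
                                          max_iter = 2000L, eps = 1e-6,
                                          trace = FALSE) {
  stopifnot(tol > 0)
  P <- if (inherits(refs, "freq_table")) refs$freq else as.matrix(refs)
  ids <- g$variants$snp_id
  i <- match(ids, rownames(P))
  if (anyNA(i))
    stop("SNP mismatch: reference frequencies missing for ",
         paste(ids[is.na(i)][seq_len(min(5, sum(is.na(i))))],
               collapse = ", "))
  P <- P[i, , drop = FALSE]
  if (anyNA(P)) stop("reference frequencies contain undefined values")
  P <- pmin(pmax(P, eps), 1 - eps)
  K <- ncol(P)
  n <- nrow(g$dosage)
  m <- ncol(g$dosage)

  G <- g$dosage
  W <- !is.na(G)
  G0 <- ifelse(W, G, 0)                # called dosage, 0 where missing
  G2 <- ifelse(W, 2 - G, 0)            # complement, 0 where missing
  storage.mode(G0) <- "double"; storage.mode(G2) <- "double"
  M_i <- rowSums(W)

  Q <- matrix(1 / K, n, K, dimnames = list(g$samples$sample_id,
                                           colnames(P)))
  loglik_of <- function(Q) {
    Theta <- Q %*% t(P)
    rowSums(G0 * log(Theta) + G2 * log1p(-Theta))
  }
  ll <- loglik_of(Q)
  ll0 <- ll
  n_iter <- rep(0L, n)
  converged <- rep(FALSE, n)
  ll_trace <- if (trace) matrix(ll, ncol = 1) else NULL

  active <- which(M_i > 0)
  for (it in seq_len(max_iter)) {
    if (!length(active)) break
    Qa <- Q[active, , drop = FALSE]
    Theta <- Qa %*% t(P)
    A <- G0[active, , drop = FALSE] / Theta
    B <- G2[active, , drop = FALSE] / (1 - Theta)
    R <- A %*% P + B %*% (1 - P)       # |active| x K
    Qn <- Qa * R / (2 * M_i[active])
    Qn <- Qn / rowSums(Qn)             # guard tiny numeric drift
    Q[active, ] <- Qn
    Tn <- Qn %*% t(P)
    ll_new <- ll
    ll_new[active] <- rowSums(
      G0[active, , drop = FALSE] * log(Tn) +
      G2[active, , drop = FALSE] * log1p(-Tn))
    if (trace) ll_trace <- cbind(ll_trace, ll_new)
    rel <- abs(ll_new[active] - ll[active]) / (abs(ll[active]) + 1e-12)
    done <- rel < tol
    converged[active[done]] <- TRUE
    n_iter[active] <- it
    active <- active[!done]
    ll <- ll_new
  }
  # unidentifiable contract: likelihood never improved from the uniform
  # start (to machine precision) -> report the initialization, not converged
  flat <- is.finite(ll) & (ll - ll0) <= abs(ll0) * 1e-12 & M_i > 0
  if (any(flat)) {
    Q[flat, ] <- 1 / K
    converged[flat] <- FALSE
  }
  if (any(!is.finite(ll)))
    stop("non-finite likelihood after clamping")
  structure(list(Q = Q, loglik = ll, n_iter = n_iter,
                 converged = converged, ll_trace = ll_trace),
            class = "ancestry_estimate")
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat(sprintf(
    "ancestry_estimate: %d individuals x %d references; %d/%d converged\n",
    nrow(x$Q), ncol(x$Q), sum(x$converged), length(x$converged)))
  invisible(x)
}

#' Total dairy proportion
#'
#' Sum of the estimated ancestry components of all European-dairy
#' designated references, per individual.
#'
#' @param est an `ancestry_estimate` (or a Q matrix).
#' @param dairy_designation character vector of reference labels.
#' @return named numeric vector in `[0,1]`.
#' @export
total_dairy_proportion <- function(est, dairy_designation) {
  Q <- if (inherits(est, "ancestry_estimate")) est$Q else as.matrix(est)
  if (length(dairy_designation) == 0) stop("empty dairy designation")
  miss <- setdiff(dairy_designation, colnames(Q))
  if (length(miss)) stop("dairy designation not among references: ",
                         paste(miss, collapse = ", "))
  rowSums(Q[, dairy_designation, drop = FALSE])
}

#' Squared Pearson correlation (accuracy of panel estimates)
#'
#' Computes `r` by the textbook sum formula
#' `sum((x - xbar)(y - ybar)) / sqrt(sum((x - xbar)^2) sum((y - ybar)^2))`
#' and returns `r^2` — the coefficient of determination between panel
#' estimates and a baseline (full-marker or true) proportion.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return scalar in `[0,1]`.
#' @export
accuracy_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx^2); syy <- sum(dy^2)
  if (sxx == 0 || syy == 0)
    stop("zero variance: correlation undefined")
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r^2
}

#' Write ancestry estimates as TSV
#'
#' Columns: sample_id, one column per reference, total_dairy (when a
#' designation is given), loglik, n_iter, converged.
#'
#' @param est an `ancestry_estimate`.
#' @param path output file.
#' @param dairy_designation optional dairy reference labels.
#' @return `path`, invisibly.
#' @export
write_ancestry_estimate <- function(est, path, dairy_designation = NULL) {
  df <- data.frame(sample_id = rownames(est$Q), est$Q,
                   check.names = FALSE)
  if (!is.null(dairy_designation))
    df$total_dairy <- total_dairy_proportion(est, dairy_designation)
  df$loglik <- est$loglik
  df$n_iter <- est$n_iter
  df$converged <- est$converged
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
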