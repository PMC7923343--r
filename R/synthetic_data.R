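# Approximate cattle autosome lengths (bp), BTA1-29; the default genome
# over which variant maps are simulated.
bta_autosomes <- function() {
  mb <- c(158, 137, 121, 121, 120, 118, 113, 113, 106, 104, 107, 91, 84,
          85, 85, 81, 75, 66, 64, 72, 70, 61, 53, 63, 43, 52, 45, 46, 51)
  stats::setNames(as.numeric(mb) * 1e6, paste0("chr", seq_along(mb)))
}

#' Simulation configuration
#'
#' Describes the synthetic world: three divergent ancestral groups
#' (EUT = European taurine dairy, AFT = African taurine, BI = indicine)
#' under the Balding-Nichols model, crossbreds with known admixture, and
#' parent-offspring families with genotyping error.
#'
#' The per-population divergence values `F` are calibrated once so that
#' realized pairwise Hudson differentiation falls inside the target
#' ranges AFT-EUT 0.211-0.332, EUT-BI 0.301-0.427, AFT-BI 0.372-0.492
#' (pairwise differentiation of two Balding-Nichols populations is
#' approximately `(F_i + F_j) / 2`), and frozen as defaults.
#'
#' @param seed integer RNG seed.
#' @param n_snps number of SNPs.
#' @param chromosomes named numeric vector of chromosome lengths in bp
#'   (default: 29 cattle-like autosomes, ~2.5 Gb).
#' @param maf_range range of the uniform law for the shared ancestral
#'   frequency p0.
#' @param divergence named vector of Balding-Nichols F values in (0,1).
#' @param admixture_law list with Beta parameters: `dairy` (shape1,
#'   shape2) for the total exotic dairy fraction and `aft_share` for the
#'   African-taurine share of the indigenous remainder.
#' @param n_reference reference individuals simulated per ancestral group.
#' @param n_crossbred number of admixed individuals.
#' @param n_pairs number of parent-offspring pairs.
#' @param error_rate per-genotype mislabeling probability (default 0.01).
#' @param missing_rate fraction of genotypes set missing.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_snps = 2000L,
                       chromosomes = bta_autosomes(),
                       maf_range = c(0.05, 0.95),
                       divergence = c(EUT = 0.205, AFT = 0.335, BI = 0.525),
                       admixture_law = list(dairy = c(3.5, 2.1),
                                            aft_share = c(2, 3)),
                       n_reference = 40L,
                       n_crossbred = 500L,
                       n_pairs = 25L,
                       error_rate = 0.01,
                       missing_rate = 0) {
  stopifnot(n_snps >= 1,
            all(divergence > 0), all(divergence < 1),
            error_rate >= 0, error_rate < 1,
            missing_rate >= 0, missing_rate < 1)
  if (any(chromosomes <= 0)) stop("chromosome lengths must be positive")
  structure(list(seed = as.integer(seed), n_snps = as.integer(n_snps),
                 chromosomes = chromosomes, maf_range = maf_range,
                 divergence = divergence, admixture_law = admixture_law,
                 n_reference = n_reference, n_crossbred = n_crossbred,
                 n_pairs = n_pairs, error_rate = error_rate,
                 missing_rate = missing_rate),
            class = "sim_config")
}

#' Simulate a variant map
#'
#' SNP counts per chromosome are proportional to chromosome length;
#' positions are uniform, unique and sorted within chromosome.
#'
#' @param config a [sim_config()].
#' @return a variant map data.frame (snp_id, chromosome, position_bp,
#'   allele_a, allele_b).
#' @export
simulate_variant_map <- function(config) {
  set.seed(config$seed)
  len <- config$chromosomes
  if (any(len <= 0)) stop("chromosome lengths must be positive")
  m <- config$n_snps
  if (m > sum(len)) stop("more SNPs requested than distinct positions")
  raw <- len / sum(len) * m
  counts <- floor(raw)
  rem <- m - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  chrom <- rep(names(len), counts)
  pos <- unlist(lapply(seq_along(len), function(i) {
    if (counts[i] == 0) return(integer(0))
    sort(sample.int(len[i], counts[i], replace = FALSE))
  }), use.names = FALSE)
  data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
             chromosome = chrom, position_bp = as.integer(pos),
             allele_a = "A", allele_b = "G",
             stringsAsFactors = FALSE)
}

#' Simulate ancestral allele frequencies (Balding-Nichols)
#'
#' For each population k with divergence `F_k` and shared ancestral
#' frequency p0 ~ Uniform(maf_range), draws
#' `p_k ~ Beta(p0 (1-F_k)/F_k, (1-p0)(1-F_k)/F_k)`.
#'
#' @param config a [sim_config()].
#' @param variants optional variant map (simulated from `config` when
#'   omitted) attached to the result for pruning.
#' @return a [freq_table()] with one column per ancestral population.
#' @export
simulate_ancestral_frequencies <- function(config, variants = NULL) {
  if (is.null(variants)) variants <- simulate_variant_map(config)
  set.seed(config$seed + 1L)
  m <- nrow(variants)
  p0 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  pops <- names(config$divergence)
  freq <- matrix(NA_real_, m, length(pops),
                 dimnames = list(variants$snp_id, pops))
  for (k in pops) {
    F <- config$divergence[[k]]
    p <- stats::rbeta(m, p0 * (1 - F) / F, (1 - p0) * (1 - F) / F)
    freq[, k] <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  }
  freq_table(freq, variants = variants)
}

#' Simulate purebred genotypes from population frequencies
#'
#' Hardy-Weinberg sampling: `dosage_j ~ Binomial(2, p_j)` independently
#' across SNPs and individuals.
#'
#' @param freqs a `freq_table`.
#' @param population population label in `freqs`.
#' @param n number of individuals.
#' @param seed RNG seed.
#' @param prefix sample id prefix.
#' @param role sample role recorded in the sample table.
#' @return a [genotype_matrix()].
#' @export
simulate_genotypes_from_freqs <- function(freqs, population, n, seed = 1L,
                                          prefix = population,
                                          role = "reference") {
  p <- get_pop_freq(freqs, population)
  set.seed(seed)
  m <- length(p)
  dosage <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  ids <- if (n > 0) sprintf("%s_%04d", prefix, seq_len(n)) else character(0)
  samples <- data.frame(sample_id = ids,
                        population = rep(population, n),
                        role = rep(role, n), stringsAsFactors = FALSE)
  genotype_matrix(dosage, freqs$variants, samples)
}

draw_admixture <- function(law, pops, n) {
  d <- stats::rbeta(n, law$dairy[1], law$dairy[2])
  s <- stats::rbeta(n, law$aft_share[1], law$aft_share[2])
  q <- cbind(EUT = d, AFT = (1 - d) * s, BI = (1 - d) * (1 - s))
  if (!all(colnames(q) %in% pops))
    stop("admixture law populations do not match frequency table")
  q[, pops, drop = FALSE]
}

#' Simulate admixed crossbreds with known ancestry
#'
#' Each individual draws a true ancestry vector `q` from the admixture
#' law (total dairy fraction ~ Beta, indigenous remainder split between
#' African taurine and indicine), then genotypes
#' `dosage_j ~ Binomial(2, theta_j)` with `theta_j = sum_k q_k p_kj`.
#'
#' @param freqs a `freq_table` with populations EUT, AFT, BI.
#' @param n number of crossbreds.
#' @param seed RNG seed.
#' @param admixture_law see [sim_config()].
#' @param prefix sample id prefix.
#' @return list with `genotypes` (a `genotype_matrix`, role "crossbred")
#'   and `truth` (matrix `q_true`, rows on the simplex).
#' @export
simulate_crossbreds <- function(freqs, n, seed = 1L,
                                admixture_law = sim_config()$admixture_law,
                                prefix = "xb") {
  pops <- populations(freqs)
  set.seed(seed)
  q <- draw_admixture(admixture_law, pops, n)
  theta <- q %*% t(freqs$freq)                    # n x m
  m <- ncol(theta)
  dosage <- matrix(stats::rbinom(n * m, 2L, theta), n, m)
  ids <- if (n > 0) sprintf("%s_%04d", prefix, seq_len(n)) else character(0)
  rownames(q) <- ids
  samples <- data.frame(sample_id = ids,
                        population = rep("crossbred", n),
                        role = rep("crossbred", n), stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dosage, freqs$variants, samples),
       truth = list(q_true = q, pedigree = NULL))
}

#' Simulate parent-offspring families
#'
#' Each offspring receives one allele sampled from a genotyped parent
#' (drawn from `parent_pool` without replacement) and one allele from an
#' ungenotyped mate drawn from per-SNP population frequencies. Before
#' error injection a true pair can have no opposing homozygotes.
#'
#' @param parent_pool a `genotype_matrix` of candidate parents.
#' @param mate_freq per-SNP allele frequency of the mate population;
#'   defaults to the empirical frequency of `parent_pool`.
#' @param n_pairs number of parent-offspring pairs.
#' @param seed RNG seed.
#' @param prefix offspring id prefix.
#' @return list with `genotypes` (offspring `genotype_matrix`) and
#'   `truth` (data.frame `pedigree` of parent_id, offspring_id).
#' @export
simulate_families <- function(parent_pool, mate_freq = NULL, n_pairs,
                              seed = 1L, prefix = "off") {
  n_pool <- n_samples(parent_pool)
  if (n_pool < 1) stop("parent pool is empty")
  if (n_pairs > n_pool) stop("more pairs requested than pool parents")
  if (is.null(mate_freq)) {
    d <- parent_pool$dosage
    mate_freq <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
  }
  m <- n_snps(parent_pool)
  stopifnot(length(mate_freq) == m)
  set.seed(seed)
  parent_idx <- sample.int(n_pool, n_pairs, replace = FALSE)
  gp <- parent_pool$dosage[parent_idx, , drop = FALSE]
  # transmitted allele: 0 if parent 0, 1 if parent 2, Bernoulli(1/2) if het;
  # a missing parent genotype transmits a population allele
  het_draw <- matrix(stats::rbinom(n_pairs * m, 1L, 0.5), n_pairs, m)
  pop_draw <- matrix(stats::rbinom(n_pairs * m, 1L, rep(mate_freq, each = n_pairs)),
                     n_pairs, m)
  transmitted <- ifelse(is.na(gp), pop_draw,
                        ifelse(gp == 2L, 1L, ifelse(gp == 0L, 0L, het_draw)))
  mate <- matrix(stats::rbinom(n_pairs * m, 1L, rep(mate_freq, each = n_pairs)),
                 n_pairs, m)
  dosage <- transmitted + mate
  ids <- sprintf("%s_%04d", prefix, seq_len(n_pairs))
  samples <- data.frame(sample_id = ids,
                        population = rep("crossbred", n_pairs),
                        role = rep("crossbred", n_pairs),
                        stringsAsFactors = FALSE)
  pedigree <- data.frame(
    parent_id = parent_pool$samples$sample_id[parent_idx],
    offspring_id = ids, stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dosage, parent_pool$variants, samples),
       truth = list(q_true = NULL, pedigree = pedigree))
}

#' Inject genotyping errors
#'
#' Each called genotype is independently replaced, with probability
#' `error_rate`, by one of the other two legal dosage values chosen
#' uniformly. Missing entries are untouched. This is the error model all
#' analytic expectations in the test-suite are derived under.
#'
#' @param g a `genotype_matrix`.
#' @param error_rate probability in `[0,1)`.
#' @param seed RNG seed.
#' @return a `genotype_matrix`.
#' @export
add_genotyping_errors <- function(g, error_rate, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1)
  if (error_rate == 0) return(g)
  set.seed(seed)
  d <- g$dosage
  called <- which(!is.na(d))
  flip <- called[stats::runif(length(called)) < error_rate]
  if (length(flip)) {
    old <- d[flip]
    pick <- stats::rbinom(length(flip), 1L, 0.5)   # which of the two others
    others <- rbind(c(1L, 2L), c(0L, 2L), c(0L, 1L))  # rows: old = 0,1,2
    d[flip] <- others[cbind(old + 1L, pick + 1L)]
  }
  genotype_matrix(d, g$variants, g$samples)
}

#' Set genotypes missing at random
#'
#' @param g a `genotype_matrix`.
#' @param missing_rate probability in `[0,1)`.
#' @param seed RNG seed.
#' @return a `genotype_matrix`.
#' @export
add_missingness <- function(g, missing_rate, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (missing_rate == 0) return(g)
  set.seed(seed)
  d <- g$dosage
  drop <- which(stats::runif(length(d)) < missing_rate)
  d[drop] <- NA_integer_
  genotype_matrix(d, g$variants, g$samples)
}

#' Hudson-style pairwise differentiation of two frequency vectors
#'
#' Ratio-of-averages estimator on population frequencies:
#' `mean((p1-p2)^2) / mean(p1 (1-p2) + p2 (1-p1))`. Used to check that
#' simulated divergence lands in the intended ranges and for run logs.
#'
#' @param p1,p2 numeric frequency vectors.
#' @return scalar differentiation estimate.
#' @export
pairwise_fst <- function(p1, p2) {
  keep <- !(is.na(p1) | is.na(p2))
  p1 <- p1[keep]; p2 <- p2[keep]
  mean((p1 - p2)^2) / mean(p1 * (1 - p2) + p2 * (1 - p1))
}

#' Write a truth record (ancestry and/or pedigree) as TSV
#'
#' @param truth list with `q_true` and/or `pedigree` as produced by the
#'   simulators.
#' @param prefix output file prefix.
#' @return `prefix`, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  if (!is.null(truth$q_true)) {
    df <- data.frame(sample_id = rownames(truth$q_true), truth$q_true,
                     check.names = FALSE)
    utils::write.table(df, paste0(prefix, "_qtrue.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(truth$pedigree)) {
    utils::write.table(truth$pedigree, paste0(prefix, "_pedigree.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
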