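# Fixture builders and independent oracles shared across test files.

toy_variants <- function(n, chromosome = "1", spacing = 1e6, start = 1e5) {
  data.frame(snp_id = sprintf("s%03d", seq_len(n)),
             chromosome = rep(chromosome, length.out = n),
             position_bp = start + spacing * (seq_len(n) - 1),
             allele_a = "A", allele_b = "G",
             stringsAsFactors = FALSE)
}

toy_samples <- function(n, population = "pop1", prefix = "ind") {
  data.frame(sample_id = sprintf("%s%03d", prefix, seq_len(n)),
             population = rep(population, length.out = n),
             role = rep("crossbred", length.out = n),
             stringsAsFactors = FALSE)
}

toy_genotypes <- function(dosage, population = "pop1", ...) {
  dosage <- as.matrix(dosage)
  genotype_matrix(dosage, toy_variants(ncol(dosage), ...),
                  toy_samples(nrow(dosage), population))
}

random_genotypes <- function(n, m, seed = 1, missing_rate = 0,
                             population = "pop1") {
  set.seed(seed)
  d <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (missing_rate > 0)
    d[runif(n * m) < missing_rate] <- NA_integer_
  toy_genotypes(d, population)
}

# random variant map over a few chromosomes, unsorted ids
random_variant_map <- function(m, n_chrom = 3, chrom_len = 5e7, seed = 1) {
  set.seed(seed)
  chrom <- sample(paste0("c", seq_len(n_chrom)), m, replace = TRUE)
  pos <- integer(m)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sample.int(chrom_len, length(idx))
  }
  data.frame(snp_id = sprintf("r%04d", seq_len(m)), chromosome = chrom,
             position_bp = pos, allele_a = "A", allele_b = "G",
             stringsAsFactors = FALSE)
}

# Independent greedy pruning oracle: naive loops, full pairwise distance
# scan against every accepted SNP, stage looked up from first principles.
brute_force_prune <- function(ranked, variants, schedule, max_snps = Inf) {
  acc <- character(0)
  for (id in ranked) {
    if (length(acc) >= max_snps) break
    stage <- 1
    while (length(acc) >= schedule$cum_counts[stage]) stage <- stage + 1
    d_req <- schedule$min_distance_bp[stage]
    vi <- variants[variants$snp_id == id, ]
    ok <- TRUE
    for (a in acc) {
      va <- variants[variants$snp_id == a, ]
      if (va$chromosome == vi$chromosome &&
          abs(va$position_bp - vi$position_bp) < d_req) {
        ok <- FALSE
        break
      }
    }
    if (ok) acc <- c(acc, id)
  }
  acc
}

# Independent opposing-homozygote count: explicit double loop.
brute_force_oph <- function(g, id_1, id_2, snp_ids = NULL) {
  d1 <- g$dosage[match(id_1, g$samples$sample_id), ]
  d2 <- g$dosage[match(id_2, g$samples$sample_id), ]
  if (!is.null(snp_ids)) {
    j <- match(snp_ids, g$variants$snp_id)
    d1 <- d1[j]; d2 <- d2[j]
  }
  oph <- 0L
  ncmp <- 0L
  for (j in seq_along(d1)) {
    if (is.na(d1[j]) || is.na(d2[j])) next
    ncmp <- ncmp + 1L
    if ((d1[j] == 0 && d2[j] == 2) || (d1[j] == 2 && d2[j] == 0))
      oph <- oph + 1L
  }
  c(oph = oph, n_comparable = ncmp)
}

# Independent per-genotype frequency tally.
brute_force_freq <- function(g, ids) {
  m <- ncol(g$dosage)
  f <- numeric(m); nc <- integer(m)
  for (j in seq_len(m)) {
    tot <- 0L; cnt <- 0L
    for (id in ids) {
      v <- g$dosage[match(id, g$samples$sample_id), j]
      if (!is.na(v)) { tot <- tot + v; cnt <- cnt + 1L }
    }
    nc[j] <- cnt
    f[j] <- if (cnt > 0) tot / (2 * cnt) else NA_real_
  }
  list(freq = f, n_called = nc)
}

# tiny ancestral world for estimator tests
toy_freq_table <- function(m = 200, seed = 1,
                           F = c(EUT = 0.2, AFT = 0.3, BI = 0.5)) {
  simulate_ancestral_frequencies(
    sim_config(seed = seed, n_snps = m, divergence = F))
}
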