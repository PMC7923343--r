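#' Simulate a complete experiment dataset
#'
#' One synthetic world: ancestral frequencies, reference individuals
#' per ancestral group, admixed crossbreds with recorded truth, and
#' parent-offspring families (parents drawn among the crossbreds), with
#' genotyping error and missingness applied to the observed matrices.
#'
#' @param config a [sim_config()].
#' @return list with `freqs_true` (population frequency parameters),
#'   `references`, `crossbreds`, `offspring` (genotype matrices),
#'   `truth` (q_true + pedigree), `ref_freqs` (frequencies estimated
#'   from the reference individuals) and `fst` (realized pairwise
#'   differentiation).
#' @export
simulate_dataset <- function(config) {
  variants <- simulate_variant_map(config)
  freqs_true <- simulate_ancestral_frequencies(config, variants)
  pops <- populations(freqs_true)

  refs <- NULL
  for (k in seq_along(pops)) {
    gk <- simulate_genotypes_from_freqs(freqs_true, pops[k],
                                        config$n_reference,
                                        seed = config$seed + 100L + k)
    refs <- if (is.null(refs)) gk else merge_on_common_snps(refs, gk)
  }
  xb <- simulate_crossbreds(freqs_true, config$n_crossbred,
                            seed = config$seed + 200L,
                            admixture_law = config$admixture_law)
  fam <- simulate_families(xb$genotypes, n_pairs = config$n_pairs,
                           seed = config$seed + 300L)

  noisy <- function(g, off) {
    if (config$error_rate > 0)
      g <- add_genotyping_errors(g, config$error_rate,
                                 seed = config$seed + 400L + off)
    if (config$missing_rate > 0)
      g <- add_missingness(g, config$missing_rate,
                           seed = config$seed + 500L + off)
    g
  }
  refs_obs <- noisy(refs, 1L)
  xb_obs <- noisy(xb$genotypes, 2L)
  off_obs <- noisy(fam$genotypes, 3L)

  ref_freqs <- population_allele_frequencies(refs_obs)
  ref_freqs$variants <- variants
  fst <- utils::combn(pops, 2, function(pr)
    pairwise_fst(freqs_true$freq[, pr[1]], freqs_true$freq[, pr[2]]))
  names(fst) <- utils::combn(pops, 2, paste, collapse = "-")

  list(freqs_true = freqs_true, references = refs_obs,
       crossbreds = xb_obs, offspring = off_obs,
       truth = list(q_true = xb$truth$q_true,
                    pedigree = fam$truth$pedigree),
       ref_freqs = ref_freqs, fst = fst)
}

#' Breed-proportion panel evaluation experiment
#'
#' Simulates a dataset, estimates the full-marker baseline total dairy
#' proportion with the supervised estimator, then evaluates every panel
#' criterion at every size: ancestry is re-estimated from the panel's
#' SNPs (reference frequencies recomputed on those SNPs from the same
#' reference individuals) and accuracy is the squared Pearson
#' correlation against the full-marker baseline — and, since simulation
#' truth is available, against the true dairy fraction.
#'
#' @param config a [sim_config()].
#' @param w_grid weighted-pool weights to evaluate.
#' @param f_grid split-fraction values to evaluate (empty to skip).
#' @param sizes panel sizes.
#' @param dairy dairy-designated reference label(s).
#' @return list with `accuracy` (criterion x size table, including
#'   `diff_from_best` per size), `baseline_r2_truth`, and `fst`.
#' @export
run_breed_proportion_experiment <- function(config,
                                            w_grid = seq(0.1, 0.9, 0.1),
                                            f_grid = numeric(0),
                                            sizes = c(100, 200, 300, 400,
                                                      500, 1000, 1500),
                                            dairy = "EUT") {
  dat <- simulate_dataset(config)
  baseline <- estimate_admixture_supervised(dat$crossbreds, dat$ref_freqs)
  base_dairy <- total_dairy_proportion(baseline, dairy)
  true_dairy <- rowSums(dat$truth$q_true[, dairy, drop = FALSE])

  eval_panel <- function(panel, mode, param) {
    out <- list()
    for (n in panel$sizes) {
      snps <- panel_snps(panel, n)
      gsub_ <- subset_genotypes(dat$crossbreds, snps = snps)
      est <- estimate_admixture_supervised(gsub_, dat$ref_freqs)
      d <- total_dairy_proportion(est, dairy)
      out[[length(out) + 1]] <- data.frame(
        mode = mode, param = param, size = n,
        r2_vs_baseline = accuracy_r2(d, base_dairy),
        r2_vs_truth = accuracy_r2(d, true_dairy),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }

  rows <- list()
  for (w in w_grid) {
    panel <- select_panel_weighted(dat$ref_freqs, w, sizes = sizes)
    rows[[length(rows) + 1]] <- eval_panel(panel, "weighted_pool", w)
  }
  for (f in f_grid) {
    panel <- select_panel_split(dat$ref_freqs, f, sizes = sizes)
    rows[[length(rows) + 1]] <- eval_panel(panel, "split_fraction", f)
  }
  accuracy <- do.call(rbind, rows)
  best <- stats::ave(accuracy$r2_vs_baseline, accuracy$size, FUN = max)
  accuracy$diff_from_best <- accuracy$r2_vs_baseline - best

  list(accuracy = accuracy,
       baseline_r2_truth = accuracy_r2(base_dairy, true_dairy),
       fst = dat$fst)
}

#' Parentage panel evaluation experiment
#'
#' Simulates crossbreds plus families, selects MAF panels (pruned and
#' unpruned) on the combined crossbred population, and reports the
#' separation value and the powers of assignment/exclusion per panel,
#' size and search scenario, alongside the full-marker assay.
#'
#' @param config a [sim_config()] (use a MAF-rich `n_snps`, e.g. 5000+).
#' @param sizes panel sizes to evaluate.
#' @param threshold_fraction assignment threshold (default 0.01).
#' @return data.frame with columns panel, pruned, size, scenario, sv,
#'   pa, pe.
#' @export
run_parentage_experiment <- function(config,
                                     sizes = c(100, 200, 300, 400, 500),
                                     threshold_fraction = 0.01) {
  dat <- simulate_dataset(config)
  all_g <- merge_on_common_snps(dat$crossbreds, dat$offspring)
  pedigree <- dat$truth$pedigree
  grouping <- stats::setNames(rep("crossbred", n_samples(all_g)),
                              all_g$samples$sample_id)
  maf_freqs <- population_allele_frequencies(all_g, grouping)
  maf_freqs$variants <- all_g$variants

  pairs1 <- candidate_pairs(all_g$samples, scenario = 1)
  pairs2 <- candidate_pairs(all_g$samples, scenario = 2,
                            parent_set = pedigree$parent_id)
  total_parents <- nrow(pedigree)

  eval_assay <- function(label, pruned, snps, n_markers) {
    out <- list()
    for (sc in 1:2) {
      pairs <- if (sc == 1) pairs1 else pairs2
      cnt <- opposing_homozygote_counts(all_g, pairs, snps)
      assigned <- reconstruct_pairs(cnt, n_markers, threshold_fraction)
      pw <- power_statistics(assigned, pedigree, total_parents)
      out[[sc]] <- data.frame(
        panel = label, pruned = pruned, size = n_markers, scenario = sc,
        sv = separation_value(cnt, pedigree), pa = pw$pa, pe = pw$pe,
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }

  rows <- list()
  rows[[1]] <- eval_assay("full", FALSE, NULL, n_snps(all_g))
  for (pruned in c(TRUE, FALSE)) {
    panel <- select_panel_maf(maf_freqs, "crossbred", sizes = sizes,
                              prune = pruned)
    for (n in panel$sizes)
      rows[[length(rows) + 1]] <-
        eval_assay("maf", pruned, panel_snps(panel, n), n)
  }
  do.call(rbind, rows)
}
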