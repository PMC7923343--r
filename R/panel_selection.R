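#' Stepwise pruning schedule
#'
#' A pruning schedule is a list of stages: while fewer than
#' `cum_counts[s]` SNPs have been accepted, a candidate must be at least
#' `min_distance_bp[s]` away from every already-accepted SNP on the same
#' chromosome. The last stage is unbounded.
#'
#' `breed_schedule()` is the default for breed-proportion panels (first
#' 100 SNPs at 3.5 Mb, next 200 at 3 Mb, additional SNPs at 1.25 Mb);
#' `parentage_schedule()` is the single-stage 1 Mb schedule used for
#' MAF panels.
#'
#' @param cum_counts strictly increasing cumulative acceptance counts,
#'   ending in `Inf`.
#' @param min_distance_bp positive distances in bp, one per stage.
#' @return an object of class `pruning_schedule`.
#' @export
pruning_schedule <- function(cum_counts, min_distance_bp) {
  stopifnot(length(cum_counts) == length(min_distance_bp),
            length(cum_counts) >= 1,
            all(diff(cum_counts) > 0),
            is.infinite(cum_counts[length(cum_counts)]),
            all(min_distance_bp > 0))
  structure(list(cum_counts = cum_counts,
                 min_distance_bp = min_distance_bp),
            class = "pruning_schedule")
}

#' @rdname pruning_schedule
#' @export
breed_schedule <- function() {
  pruning_schedule(c(100, 300, Inf), c(3.5e6, 3.0e6, 1.25e6))
}

#' @rdname pruning_schedule
#' @export
parentage_schedule <- function() pruning_schedule(Inf, 1e6)

# distance stage in force when n_accepted SNPs are already in the panel
stage_distance <- function(schedule, n_accepted) {
  schedule$min_distance_bp[which(n_accepted < schedule$cum_counts)[1]]
}

#' Rank SNPs by a selection score
#'
#' Descending score; ties broken deterministically by (chromosome,
#' position_bp, snp_id). SNPs with `NA` scores are excluded.
#'
#' @param scores named numeric vector (names are snp_ids).
#' @param variants variant map covering the scored SNPs.
#' @return character vector of snp_ids, best first.
#' @export
rank_by_score <- function(scores, variants) {
  scores <- scores[!is.na(scores)]
  ids <- names(scores)
  i <- match(ids, variants$snp_id)
  if (anyNA(i)) stop("scored SNPs missing from variant map: ",
                     paste(ids[is.na(i)], collapse = ", "))
  ord <- order(-scores, variants$chromosome[i], variants$position_bp[i],
               ids, method = "radix")
  ids[ord]
}

#' Greedy stepwise pruning by physical distance
#'
#' Scans the ranked list once; a SNP is accepted iff its distance to
#' every already-accepted SNP on the same chromosome is at least the
#' minimum distance of the stage determined by how many SNPs have been
#' accepted so far (SNPs on different chromosomes never conflict). Rank
#' order is preserved among accepted SNPs.
#'
#' @param ranked character vector of snp_ids, best first.
#' @param variants variant map.
#' @param schedule a [pruning_schedule()].
#' @param max_snps stop once this many SNPs are accepted (default all).
#' @return character vector of accepted snp_ids in rank order.
#' @export
stepwise_prune <- function(ranked, variants, schedule, max_snps = Inf) {
  i <- match(ranked, variants$snp_id)
  if (anyNA(i)) stop("ranked SNPs missing from variant map: ",
                     paste(ranked[is.na(i)], collapse = ", "))
  chrom <- variants$chromosome[i]
  pos <- as.numeric(variants$position_bp[i])
  accepted <- integer(0)
  by_chrom <- split(numeric(0), character(0))   # positions per chromosome
  for (k in seq_along(ranked)) {
    if (length(accepted) >= max_snps) break
    d <- stage_distance(schedule, length(accepted))
    ps <- by_chrom[[chrom[k]]]
    if (is.null(ps) || !length(ps) || min(abs(ps - pos[k])) >= d) {
      accepted <- c(accepted, k)
      by_chrom[[chrom[k]]] <- c(ps, pos[k])
    }
  }
  ranked[accepted]
}

new_snp_panel <- function(criterion, table, sizes, schedule) {
  sizes <- sort(unique(as.integer(sizes)))
  achieved <- nrow(table)
  if (achieved < max(sizes)) {
    warning(sprintf(
      "panel shortfall: %d SNPs requested, %d eligible after pruning",
      max(sizes), achieved))
    sizes <- unique(c(sizes[sizes <= achieved], achieved))
  }
  structure(list(criterion = criterion, table = table,
                 sizes = sizes, schedule = schedule),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel [%s]: %d SNPs, sizes %s\n",
              x$criterion$mode, nrow(x$table),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Extract the first `n` SNPs of a panel
#'
#' Panels are nested: any prefix of the selection order is itself a
#' valid smaller panel.
#'
#' @param panel a `snp_panel`.
#' @param n panel size (defaults to all).
#' @return character vector of snp_ids.
#' @export
panel_snps <- function(panel, n = nrow(panel$table)) {
  if (n > nrow(panel$table))
    stop("panel holds only ", nrow(panel$table), " SNPs")
  panel$table$snp_id[seq_len(n)]
}

panel_table_from_ids <- function(ids, variants, scores, source) {
  i <- match(ids, variants$snp_id)
  data.frame(rank = seq_along(ids), snp_id = ids,
             chromosome = variants$chromosome[i],
             position_bp = variants$position_bp[i],
             score = unname(scores[ids]),
             source = source, stringsAsFactors = FALSE)
}

#' Select a panel from a weighted hypothetical ancestral pool
#'
#' Scores every SNP as `|p_EUT - (w p_AFT + (1-w) p_BI)|`, ranks
#' descending, applies the stepwise pruning schedule, and emits nested
#' panels at the requested sizes.
#'
#' @param freqs a `freq_table` whose variants carry the map.
#' @param w weight on the African taurine frequency, in (0,1).
#' @param sizes panel sizes (default the standard 100-1500 grid).
#' @param schedule a [pruning_schedule()] or `NULL` for no pruning.
#' @param pops named character vector naming the `eut`, `aft`, `bi`
#'   columns of `freqs`.
#' @return a `snp_panel`.
#' @export
select_panel_weighted <- function(freqs, w,
                                  sizes = c(100, 200, 300, 400, 500,
                                            1000, 1500),
                                  schedule = breed_schedule(),
                                  pops = c(eut = "EUT", aft = "AFT",
                                           bi = "BI")) {
  stopifnot(w > 0, w < 1)
  pool <- weighted_hypothetical_frequency(freqs, pops[["aft"]],
                                          pops[["bi"]], w)
  scores <- abs(get_pop_freq(freqs, pops[["eut"]]) - pool)
  ranked <- rank_by_score(scores, freqs$variants)
  kept <- if (is.null(schedule)) ranked[seq_len(min(length(ranked),
                                                    max(sizes)))]
          else stepwise_prune(ranked, freqs$variants, schedule,
                              max_snps = max(sizes))
  new_snp_panel(
    list(mode = "weighted_pool", w = w, pops = pops),
    panel_table_from_ids(kept, freqs$variants, scores, "weighted_pool"),
    sizes, schedule)
}

#' Select a split-fraction panel from two pairwise rankings
#'
#' For each target size n, `ceiling(f * n)` SNPs come from the
#' AFT-vs-EUT absolute-difference ranking and the remainder from the
#' BI-vs-EUT ranking. The panel is built incrementally (so panels are
#' exactly nested across sizes) with every candidate checked against the
#' pruning schedule relative to all SNPs already in the combined panel;
#' a SNP already contributed by the other ranking is skipped and its
#' quota slot filled by the next eligible SNP.
#'
#' @param freqs a `freq_table`.
#' @param f fraction of each panel drawn from the AFT-vs-EUT ranking,
#'   in (0,1).
#' @inheritParams select_panel_weighted
#' @return a `snp_panel`; the `source` column records the contributing
#'   ranking (`"AFTvsEUT"` or `"BIvsEUT"`) of each SNP.
#' @export
select_panel_split <- function(freqs, f,
                               sizes = c(100, 200, 300, 400, 500,
                                         1000, 1500),
                               schedule = breed_schedule(),
                               pops = c(eut = "EUT", aft = "AFT",
                                        bi = "BI")) {
  stopifnot(f > 0, f < 1)
  score_a <- absolute_frequency_difference(freqs, pops[["aft"]],
                                           pops[["eut"]])
  score_b <- absolute_frequency_difference(freqs, pops[["bi"]],
                                           pops[["eut"]])
  rank_a <- rank_by_score(score_a, freqs$variants)
  rank_b <- rank_by_score(score_b, freqs$variants)
  variants <- freqs$variants
  vi_a <- match(rank_a, variants$snp_id)
  vi_b <- match(rank_b, variants$snp_id)

  sizes <- sort(unique(as.integer(sizes)))
  chosen <- character(0)
  source <- character(0)
  by_chrom <- split(numeric(0), character(0))
  ia <- 1L; ib <- 1L
  n_a <- 0L                                 # accepted from ranking A
  eligible <- function(chrom, p) {
    d <- stage_distance(schedule, length(chosen))
    ps <- by_chrom[[chrom]]
    is.null(ps) || !length(ps) || min(abs(ps - p)) >= d
  }
  take_from <- function(which_rank) {
    # advance the pointer past used/ineligible SNPs; returns TRUE if taken
    repeat {
      if (which_rank == "A") {
        if (ia > length(rank_a)) return(FALSE)
        id <- rank_a[ia]; ch <- variants$chromosome[vi_a[ia]]
        p <- as.numeric(variants$position_bp[vi_a[ia]])
        ia <<- ia + 1L
      } else {
        if (ib > length(rank_b)) return(FALSE)
        id <- rank_b[ib]; ch <- variants$chromosome[vi_b[ib]]
        p <- as.numeric(variants$position_bp[vi_b[ib]])
        ib <<- ib + 1L
      }
      if (id %in% chosen) next
      if (is.null(schedule) || eligible(ch, p)) {
        chosen <<- c(chosen, id)
        source <<- c(source, if (which_rank == "A") "AFTvsEUT" else "BIvsEUT")
        by_chrom[[ch]] <<- c(by_chrom[[ch]], p)
        return(TRUE)
      }
    }
  }
  for (n in sizes) {
    quota_a <- as.integer(ceiling(f * n))
    while (n_a < quota_a) {
      if (!take_from("A")) break
      n_a <- n_a + 1L
    }
    while (length(chosen) < n) {
      if (!take_from("B")) {
        if (!take_from("A")) break          # B exhausted: top up from A
        n_a <- n_a + 1L
      }
    }
  }
  scores <- ifelse(source == "AFTvsEUT", score_a[chosen], score_b[chosen])
  names(scores) <- chosen
  tab <- panel_table_from_ids(chosen, variants, scores, source)
  new_snp_panel(list(mode = "split_fraction", f = f, pops = pops),
                tab, sizes, schedule)
}

#' Select a MAF-ranked panel for parentage assignment
#'
#' Ranks SNPs by minor allele frequency in the target (crossbred)
#' population, highest first — high-MAF SNPs maximize the expected
#' number of opposing homozygotes between unrelated individuals — with
#' an optional single-stage 1 Mb pruning pass.
#'
#' @param freqs a `freq_table`.
#' @param target_population population whose MAF drives the ranking.
#' @param sizes panel sizes.
#' @param prune logical; apply `schedule` (default 1 Mb) when `TRUE`.
#' @param schedule schedule used when `prune = TRUE`.
#' @return a `snp_panel`.
#' @export
select_panel_maf <- function(freqs, target_population,
                             sizes = c(100, 200, 300, 400, 500,
                                       1000, 1500),
                             prune = TRUE,
                             schedule = parentage_schedule()) {
  scores <- minor_allele_frequency(freqs, target_population)
  ranked <- rank_by_score(scores, freqs$variants)
  kept <- if (prune) stepwise_prune(ranked, freqs$variants, schedule,
                                    max_snps = max(sizes))
          else ranked[seq_len(min(length(ranked), max(sizes)))]
  new_snp_panel(
    list(mode = "maf", target = target_population, pruned = prune),
    panel_table_from_ids(kept, freqs$variants, scores, "maf"),
    sizes, if (prune) schedule else NULL)
}

#' Independently verify a panel's distance constraints
#'
#' Checker deliberately written as a full pairwise scan, independent of
#' the greedy construction: for the j-th accepted SNP, every earlier
#' same-chromosome SNP must lie at least the stage-j minimum distance
#' away (the stage in force when j-1 SNPs had been accepted).
#'
#' @param snp_ids panel SNPs in acceptance order.
#' @param variants variant map.
#' @param schedule a [pruning_schedule()].
#' @return `TRUE` if valid, otherwise a data.frame of violations
#'   (columns `snp_i`, `snp_j`, `distance_bp`, `required_bp`).
#' @export
check_panel_distances <- function(snp_ids, variants, schedule) {
  i <- match(snp_ids, variants$snp_id)
  chrom <- variants$chromosome[i]
  pos <- as.numeric(variants$position_bp[i])
  viol <- list()
  for (j in seq_along(snp_ids)[-1]) {
    req <- schedule$min_distance_bp[which(j - 1 < schedule$cum_counts)[1]]
    earlier <- seq_len(j - 1)
    same <- earlier[chrom[earlier] == chrom[j]]
    if (!length(same)) next
    dd <- abs(pos[same] - pos[j])
    bad <- which(dd < req)
    for (b in bad)
      viol[[length(viol) + 1]] <- data.frame(
        snp_i = snp_ids[same[b]], snp_j = snp_ids[j],
        distance_bp = dd[b], required_bp = req,
        stringsAsFactors = FALSE)
  }
  if (!length(viol)) TRUE else do.call(rbind, viol)
}

#' Write / read a SNP panel as TSV
#'
#' Columns: rank, snp_id, chromosome, position_bp, score, source.
#'
#' @param panel a `snp_panel`.
#' @param path output file.
#' @return `path` (write) or a data.frame (read).
#' @export
write_panel <- function(panel, path) {
  op <- options(scipen = 15)
  on.exit(options(op), add = TRUE)
  utils::write.table(panel$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
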