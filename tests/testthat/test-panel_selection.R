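test_that("ranking is descending with deterministic positional ties", {
  v <- toy_variants(3)
  expect_equal(rank_by_score(c(s001 = 0.9, s002 = 0.5, s003 = 0.7), v),
               c("s001", "s003", "s002"))
  expect_equal(rank_by_score(c(s003 = 0.4, s001 = 0.4, s002 = 0.4), v),
               c("s001", "s002", "s003"))
  set.seed(31)
  v2 <- random_variant_map(60, seed = 31)
  sc <- stats::setNames(round(runif(60), 2), v2$snp_id)  # many ties
  r1 <- rank_by_score(sc, v2)
  r2 <- rank_by_score(sample(sc), v2)
  expect_identical(r1, r2)
  expect_equal(rank_by_score(c(s001 = 0.2, s002 = NA), v), "s001")
})

test_that("stepwise pruning enforces the stage distances greedily", {
  v <- toy_variants(2, spacing = 1e6)
  expect_equal(stepwise_prune(c("s001", "s002"), v, breed_schedule()),
               "s001")
  v2 <- toy_variants(4, chromosome = c("1", "2", "3", "4"), spacing = 1e4)
  expect_equal(stepwise_prune(v2$snp_id, v2, breed_schedule()), v2$snp_id)
  # 30-SNP toy map against the naive oracle
  v3 <- random_variant_map(30, n_chrom = 2, chrom_len = 2e7, seed = 32)
  sched <- pruning_schedule(c(5, 12, Inf), c(5e6, 3e6, 1e6))
  ranked <- rank_by_score(
    stats::setNames(runif(30), v3$snp_id), v3)
  expect_identical(stepwise_prune(ranked, v3, sched),
                   brute_force_prune(ranked, v3, sched))
})

test_that("weighted-pool selection equals brute-force score + prune", {
  fr <- toy_freq_table(m = 200, seed = 33)
  for (w in c(0.3, 0.5, 0.7)) {
    panel <- select_panel_weighted(fr, w, sizes = c(20, 50),
                                   schedule = breed_schedule())
    # oracle: explicit score, explicit sort, naive prune, prefix
    sc <- abs(fr$freq[, "EUT"] -
                (w * fr$freq[, "AFT"] + (1 - w) * fr$freq[, "BI"]))
    v <- fr$variants
    ord <- order(-sc, v$chromosome[match(names(sc), v$snp_id)],
                 v$position_bp[match(names(sc), v$snp_id)], names(sc),
                 method = "radix")
    oracle <- brute_force_prune(names(sc)[ord], v, breed_schedule(),
                                max_snps = 50)
    expect_identical(panel_snps(panel, min(50, nrow(panel$table))),
                     oracle[seq_len(min(50, nrow(panel$table)))])
  }
  # definitional cases
  fr2 <- freq_table(cbind(EUT = c(1, 0.6), AFT = c(0, 0.5), BI = c(0, 0.5)),
                    variants = toy_variants(2, spacing = 1e8))
  rownames(fr2$freq) <- c("s001", "s002")
  for (w in c(0.2, 0.8))
    expect_equal(panel_snps(select_panel_weighted(fr2, w, sizes = 1))[1],
                 "s001")
})

test_that("split-fraction panels honor quota, dedup and schedule", {
  # wide-spaced universe: no pruning conflicts, pure quota arithmetic
  v <- toy_variants(40, spacing = 1e8)
  set.seed(34)
  pa <- runif(40); pe <- runif(40); pb <- runif(40)
  fr <- freq_table(cbind(EUT = pe, AFT = pa, BI = pb), variants = v)
  rownames(fr$freq) <- v$snp_id
  panel <- suppressWarnings(
    select_panel_split(fr, 0.7, sizes = 10, schedule = breed_schedule()))
  expect_equal(nrow(panel$table), 10L)
  expect_equal(sum(panel$table$source == "AFTvsEUT"), 7L)  # ceil(0.7*10)
  expect_equal(sum(panel$table$source == "BIvsEUT"), 3L)
  expect_false(anyDuplicated(panel$table$snp_id) > 0)
  # f -> 1 behaves as pure AFT-vs-EUT selection
  p95 <- select_panel_split(fr, 0.95, sizes = 10)
  sc_a <- absolute_frequency_difference(fr, "AFT", "EUT")
  pure <- stepwise_prune(rank_by_score(sc_a, v), v, breed_schedule(),
                         max_snps = 10)
  expect_identical(panel_snps(p95, 10), pure)
  # a SNP top of both rankings appears once, attributed to list A,
  # and list B supplies its next eligible SNP
  fr3 <- freq_table(cbind(EUT = c(1, 0.9, 0.1), AFT = c(0, 0.5, 0.6),
                          BI = c(0, 0.2, 0.9)),
                    variants = toy_variants(3, spacing = 1e8))
  rownames(fr3$freq) <- c("s001", "s002", "s003")
  p3 <- select_panel_split(fr3, 0.5, sizes = 2)
  expect_equal(panel_snps(p3, 2), c("s001", "s003"))
  expect_equal(p3$table$source, c("AFTvsEUT", "BIvsEUT"))
})

test_that("MAF panels rank by MAF with optional 1 Mb pruning", {
  v <- toy_variants(3, spacing = 1e8)
  fr <- freq_table(cbind(X = c(0.5, 0.51, 0.9)), variants = v)
  rownames(fr$freq) <- v$snp_id
  p <- suppressWarnings(select_panel_maf(fr, "X", sizes = 3))
  expect_equal(panel_snps(p), c("s001", "s002", "s003"))  # MAF .5,.49,.1
  fr2 <- toy_freq_table(m = 400, seed = 35)
  up <- select_panel_maf(fr2, "EUT", sizes = c(50, 100), prune = FALSE)
  maf <- minor_allele_frequency(fr2, "EUT")
  expect_identical(panel_snps(up, 100),
                   rank_by_score(maf, fr2$variants)[1:100])
  pr <- select_panel_maf(fr2, "EUT", sizes = c(50, 100), prune = TRUE)
  expect_true(isTRUE(check_panel_distances(panel_snps(pr),
                                           fr2$variants,
                                           parentage_schedule())))
})

test_that("panels are exactly nested and schedule-valid in every mode", {
  fr <- toy_freq_table(m = 500, seed = 36)
  sizes <- c(20, 60, 120)
  panels <- list(
    select_panel_weighted(fr, 0.6, sizes = sizes),
    select_panel_split(fr, 0.4, sizes = sizes),
    select_panel_maf(fr, "BI", sizes = sizes))
  for (p in panels) {
    for (i in seq_along(sizes)[-1])
      expect_identical(panel_snps(p, sizes[i])[seq_len(sizes[i - 1])],
                       panel_snps(p, sizes[i - 1]))
    if (!is.null(p$schedule))
      expect_true(isTRUE(check_panel_distances(panel_snps(p),
                                               fr$variants, p$schedule)))
  }
})

test_that("the distance checker reports violations", {
  v <- toy_variants(3, spacing = 5e5)   # 0.5 Mb apart
  res <- check_panel_distances(v$snp_id, v, parentage_schedule())
  expect_true(is.data.frame(res))
  expect_equal(nrow(res), 2L)   # adjacent pairs violate; 1.0 Mb is allowed
  expect_true(all(res$required_bp == 1e6))
})

test_that("shortfall warns and panel IO round-trips", {
  fr <- toy_freq_table(m = 30, seed = 37)
  expect_warning(p <- select_panel_weighted(fr, 0.5, sizes = c(10, 1000)),
                 "shortfall")
  expect_lt(nrow(p$table), 1000)
  dir <- withr::local_tempdir()
  write_panel(p, file.path(dir, "p.tsv"))
  back <- read_panel(file.path(dir, "p.tsv"))
  expect_equal(back$snp_id, p$table$snp_id)
  expect_equal(back$score, p$table$score, tolerance = 1e-12)
})
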