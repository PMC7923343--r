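test_that("opposing homozygotes count exactly and symmetrically", {
  g <- toy_genotypes(rbind(c(0L, 2L, 1L, NA),
                           c(2L, 2L, 0L, 2L)))
  cnt <- opposing_homozygote_counts(
    g, data.frame(id_1 = "ind001", id_2 = "ind002"))
  expect_equal(cnt$oph, 1L)
  expect_equal(cnt$n_comparable, 3L)
  rev <- opposing_homozygote_counts(
    g, data.frame(id_1 = "ind002", id_2 = "ind001"))
  expect_equal(rev$oph, cnt$oph)
  expect_error(opposing_homozygote_counts(
    g, data.frame(id_1 = "ghost", id_2 = "ind001")), "unknown sample")
  expect_error(opposing_homozygote_counts(
    g, data.frame(id_1 = "ind001", id_2 = "ind002"), snp_ids = "zz"),
    "unknown snp")
})

test_that("counts agree with a brute-force double loop", {
  g <- random_genotypes(12, 60, seed = 61, missing_rate = 0.15)
  pairs <- candidate_pairs(g$samples, 1)
  cnt <- opposing_homozygote_counts(g, pairs)
  idx <- sample(nrow(pairs), 20)
  for (k in idx) {
    bf <- brute_force_oph(g, pairs$id_1[k], pairs$id_2[k])
    expect_identical(cnt$oph[k], unname(bf["oph"]))
    expect_identical(cnt$n_comparable[k], unname(bf["n_comparable"]))
  }
  # additive over disjoint panels, monotone under growth
  sA <- g$variants$snp_id[1:30]
  sB <- g$variants$snp_id[31:60]
  cA <- opposing_homozygote_counts(g, pairs, sA)$oph
  cB <- opposing_homozygote_counts(g, pairs, sB)$oph
  expect_identical(cA + cB, cnt$oph)
  expect_true(all(cnt$oph >= cA))
})

test_that("candidate pair enumeration matches both scenarios", {
  ids <- sprintf("a%02d", 1:5)
  p1 <- candidate_pairs(ids, 1)
  expect_equal(nrow(p1), 10L)
  ref <- t(combn(ids, 2))
  expect_identical(paste(p1$id_1, p1$id_2),
                   paste(ref[, 1], ref[, 2]))
  expect_equal(nrow(candidate_pairs(ids[1:2], 1)), 1L)
  p2 <- candidate_pairs(ids, 2, parent_set = ids[1:2])
  expect_equal(nrow(p2), 2L * 3L)
  expect_error(candidate_pairs(ids, 2, parent_set = ids[1:2],
                               progeny_set = ids[2:4]), "overlap")
  expect_error(candidate_pairs(ids, 2), "non-empty")
})

test_that("the 1% threshold is strict on the assay marker count", {
  cnt <- data.frame(id_1 = c("p", "p", "q"), id_2 = c("x", "y", "z"),
                    oph = c(2L, 3L, 0L), n_comparable = 280L)
  asn <- reconstruct_pairs(cnt, n_markers = 300)
  expect_equal(asn$oph, c(2L, 0L))          # 3 is not < 3
  # 38,214 markers: oph = 381 < 382.14 is assigned, 383 is not
  cnt2 <- data.frame(id_1 = "a", id_2 = "b", oph = 381L,
                     n_comparable = 38000L)
  expect_equal(nrow(reconstruct_pairs(cnt2, 38214)), 1L)
  cnt2$oph <- 383L
  expect_equal(nrow(reconstruct_pairs(cnt2, 38214)), 0L)
})

test_that("separation value is a min/max scan over FR and TR", {
  truth <- data.frame(parent_id = c("p1", "p2"),
                      offspring_id = c("o1", "o2"))
  cnt <- data.frame(id_1 = c("p1", "p2", "u1", "u2"),
                    id_2 = c("o1", "o2", "u3", "u4"),
                    oph = c(0L, 1L, 5L, 7L))
  expect_equal(separation_value(cnt, truth), 4L)
  cnt$oph <- c(3L, 3L, 2L, 9L)
  expect_equal(separation_value(cnt, truth), -1L)
  # 50-pair random fixture vs explicit scan
  set.seed(62)
  cnt50 <- data.frame(id_1 = sprintf("i%02d", 1:50),
                      id_2 = sprintf("j%02d", 1:50),
                      oph = sample(0:40, 50, replace = TRUE))
  tr <- cnt50[1:8, c("id_1", "id_2")]
  sv <- separation_value(cnt50, tr)
  expect_equal(sv, min(cnt50$oph[-(1:8)]) - max(cnt50$oph[1:8]))
  expect_error(separation_value(cnt50[1:8, ], tr), "no false")
  expect_error(separation_value(cnt50[9:50, ], tr), "no true")
})

test_that("powers of assignment and exclusion follow their formulas", {
  truth <- data.frame(parent_id = sprintf("p%02d", 1:10),
                      offspring_id = sprintf("o%02d", 1:10))
  correct9 <- data.frame(id_1 = truth$parent_id[1:9],
                         id_2 = truth$offspring_id[1:9])
  wrong2 <- data.frame(id_1 = c("p01", "p02"), id_2 = c("o05", "o09"))
  pw <- power_statistics(rbind(correct9, wrong2), truth, 10)
  expect_equal(pw$pa, 0.9)
  expect_equal(pw$pe, 0.8)
  all_right <- power_statistics(
    data.frame(id_1 = truth$parent_id, id_2 = truth$offspring_id),
    truth, 10)
  expect_equal(all_right, list(pa = 1, pe = 1))
  none <- power_statistics(correct9[0, ], truth, 10)
  expect_equal(none, list(pa = 0, pe = 1))
  # order within a pair does not matter
  flipped <- data.frame(id_1 = truth$offspring_id, id_2 = truth$parent_id)
  expect_equal(power_statistics(flipped, truth, 10)$pa, 1)
})

test_that("zero-error families separate perfectly at full marker count", {
  fr <- toy_freq_table(m = 800, seed = 63)
  pool <- simulate_crossbreds(fr, 40, seed = 64)$genotypes
  fam <- simulate_families(pool, n_pairs = 15, seed = 65)
  all_g <- merge_on_common_snps(pool, fam$genotypes)
  pairs <- candidate_pairs(all_g$samples, 1)
  cnt <- opposing_homozygote_counts(all_g, pairs)
  ped <- fam$truth$pedigree
  tr_oph <- cnt$oph[paste(cnt$id_1, cnt$id_2) %in%
                      paste(ped$parent_id, ped$offspring_id) |
                    paste(cnt$id_2, cnt$id_1) %in%
                      paste(ped$parent_id, ped$offspring_id)]
  expect_true(all(tr_oph == 0L))
  expect_gt(separation_value(cnt, ped), 0)
  asn <- reconstruct_pairs(cnt, n_snps(all_g))
  pw <- power_statistics(asn, ped, nrow(ped))
  expect_equal(pw$pa, 1)
  expect_equal(pw$pe, 1)
})

test_that("unrelated HWE pairs match the analytic opH expectation", {
  # E[opH per SNP] = 2 p^2 (1-p)^2 = 0.125 at p = 0.5
  m <- 1000
  v <- toy_variants(m, spacing = 1e5)
  fr <- freq_table(matrix(0.5, m, 1, dimnames = list(v$snp_id, "P")),
                   variants = v)
  g <- simulate_genotypes_from_freqs(fr, "P", 200, seed = 66)
  pairs <- data.frame(id_1 = g$samples$sample_id[seq(1, 199, 2)],
                      id_2 = g$samples$sample_id[seq(2, 200, 2)])
  cnt <- opposing_homozygote_counts(g, pairs)
  se <- sqrt(m * 0.125 * 0.875 / nrow(pairs))
  expect_lt(abs(mean(cnt$oph) - 0.125 * m), 4 * se)
})

test_that("MAF panels separate pairs better than random panels", {
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, n_snps = 3000, n_crossbred = 80,
                      n_pairs = 15)
    dat <- simulate_dataset(cfg)
    all_g <- merge_on_common_snps(dat$crossbreds, dat$offspring)
    grouping <- stats::setNames(rep("xb", n_samples(all_g)),
                                all_g$samples$sample_id)
    fr <- population_allele_frequencies(all_g, grouping)
    fr$variants <- all_g$variants
    maf_panel <- panel_snps(select_panel_maf(fr, "xb", sizes = 300,
                                             prune = FALSE), 300)
    set.seed(seed + 100)
    rand_panel <- sample(all_g$variants$snp_id, 300)
    pairs <- candidate_pairs(all_g$samples, 1)
    ped <- dat$truth$pedigree
    sv_maf <- separation_value(
      opposing_homozygote_counts(all_g, pairs, maf_panel), ped)
    sv_rand <- separation_value(
      opposing_homozygote_counts(all_g, pairs, rand_panel), ped)
    expect_gte(sv_maf, sv_rand)
  }
})
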