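# build a stage-2-style row from per-study estimates
fake_pair <- function(beta, se, snp1 = "a", snp2 = "b") {
  m <- fixed_effects_meta(beta, se)
  data.frame(snp1 = snp1, snp2 = snp2, enc1 = "dosage", enc2 = "dosage",
             beta = m$beta, se = m$se, p = m$p,
             study_beta = I(list(beta)), study_se = I(list(se)))
}

test_that("replication criterion applies significance and direction rules", {
  thr <- 4.6178e-9
  strong <- fake_pair(rep(0.3, 10), rep(0.03, 10))
  expect_true(check_replication(strong, thr, 8)$pass)
  # 7 of 10 same-sign: fail on the direction count
  mixed <- fake_pair(c(rep(0.45, 7), rep(-0.3, 3)), rep(0.04, 10))
  expect_lt(mixed$p, thr)
  v <- check_replication(mixed, thr, 8)
  expect_false(v$pass)
  expect_equal(v$n_consistent, 7L)
  # meta p above the bar: fail regardless of consistency
  weak <- fake_pair(rep(0.3, 10), rep(0.164, 10))
  expect_gt(weak$p, thr)
  expect_lt(weak$p, 1e-7)
  expect_false(check_replication(weak, thr, 8)$pass)
  # fewer studies than required: fail with reason
  few <- fake_pair(rep(0.4, 3), rep(0.05, 3))
  v2 <- check_replication(few, thr, 8)
  expect_false(v2$pass)
  expect_match(v2$reason, "usable studies")
  # strict reading demands per-study significance
  strict_ok <- fake_pair(rep(0.8, 10), rep(0.1, 10))
  expect_true(check_replication(strict_ok, 1e-6, 8, strict = TRUE)$pass)
  expect_false(check_replication(strong, 1e-25, 8, strict = TRUE)$pass)
})

test_that("pair-LD criterion passes low r2 or different chromosomes", {
  set.seed(41)
  a <- rbinom(500, 2, 0.3)
  b <- rbinom(500, 2, 0.3)          # independent: low r2
  c2 <- ifelse(rbinom(500, 1, 0.05) == 1, 2 - a, a)  # high LD with a
  gm <- genotype_matrix(cbind(a = a, b = b, c = c2),
                        data.frame(id = c("a", "b", "c"),
                                   chrom = c("6", "6", "6"),
                                   pos = c(1e6, 2e6, 3e6)))
  low <- check_pair_ld(gm, "a", "b")
  expect_true(low$pass)
  expect_lt(low$r_squared, 0.2)
  high <- check_pair_ld(gm, "a", "c")
  expect_false(high$pass)
  expect_gt(high$r_squared, 0.2)
  # same variants on different chromosomes: pass regardless of correlation
  gm2 <- genotype_matrix(cbind(a = a, c = c2),
                         data.frame(id = c("a", "c"), chrom = c("1", "2"),
                                    pos = c(1e6, 1e6)))
  expect_true(check_pair_ld(gm2, "a", "c")$pass)
})

test_that("proxy criterion passes vacuously without proxies and detects support", {
  # pool without any high-LD proxy: vacuous pass, flagged
  cfg <- scenario_config("null", seed = 71, n_studies = 2,
                         n_cases = 400, n_controls = 400)
  studies <- simulate_cohorts(cfg)
  merged <- merge_cohorts(studies)
  pair <- data.frame(snp1 = "snpA", snp2 = "snpB", enc1 = "dosage",
                     enc2 = "dosage", beta = 0.3)
  v <- check_proxy_support(studies, merged$genotypes, pair)
  expect_true(v$pass)
  expect_true(v$vacuous)
  # tagging pool: tag1_proxy sits at r2 ~ 0.96 with tag1 and the proxy pair
  # carries the same interaction signal
  cfg2 <- scenario_config("tagging", seed = 72)
  studies2 <- simulate_cohorts(cfg2)
  merged2 <- merge_cohorts(studies2)
  s1 <- do.call(rbind, lapply(studies2, stage1_screen,
                              variant_ids = c("tag1", "tag2")))
  best <- select_best_encoding(meta_screen(s1))
  v2 <- check_proxy_support(studies2, merged2$genotypes, best[1, ])
  expect_false(v2$vacuous)
  expect_true(any(v2$proxies$proxy == "tag1_proxy"))
  expect_true(v2$pass)
})

test_that("conditional LRT is nested, 1 df, and invariant to covariate rescaling", {
  cfg <- scenario_config("interaction", seed = 81, n_studies = 2,
                         n_cases = 500, n_controls = 500)
  merged <- merge_cohorts(simulate_cohorts(cfg))
  res <- conditional_lrt(merged, "snpA", "snpB", "filler1")
  expect_gte(res$lrt, 0)
  expect_equal(res$df, 1L)
  expect_true(res$p > 0 && res$p <= 1)
  # affine rescaling of an attached covariate leaves the LRT unchanged
  merged$mds <- data.frame(sample_id = merged$genotypes$samples,
                           MDS1 = rnorm(length(merged$genotypes$samples)))
  r1 <- conditional_lrt(merged, "snpA", "snpB", "filler1")
  merged$mds$MDS1 <- 100 * merged$mds$MDS1 - 7
  r2 <- conditional_lrt(merged, "snpA", "snpB", "filler1")
  expect_equal(r1$lrt, r2$lrt, tolerance = 1e-8)
})

test_that("conditioning SNP collinear with a target is skipped", {
  cfg <- scenario_config("tagging", seed = 82, n_studies = 2,
                         n_cases = 400, n_controls = 400)
  merged <- merge_cohorts(simulate_cohorts(cfg))
  res <- conditional_lrt(merged, "tag1", "tag2", "tag1")
  expect_false(is.na(res$skip))
  expect_match(res$skip, "collinear")
})

test_that("independent conditioning leaves the null interaction p uniform", {
  # the conditional-LRT p under conditioning on an unrelated SNP should be
  # distributed like the unconditioned interaction p
  p_cond <- p_unc <- numeric(40)
  for (r in seq_len(40)) {
    cfg <- scenario_config("null", seed = 9000 + r, n_studies = 1,
                           n_cases = 400, n_controls = 400)
    merged <- merge_cohorts(simulate_cohorts(cfg))
    p_cond[r] <- conditional_lrt(merged, "snpA", "snpB", "filler1")$p
    y <- merged$phenotypes$status
    a <- dosage_of(merged$genotypes, "snpA")
    b <- dosage_of(merged$genotypes, "snpB")
    red <- glm(y ~ a + b, family = binomial())
    full <- glm(y ~ a * b, family = binomial())
    p_unc[r] <- pchisq(red$deviance - full$deviance, 1, lower.tail = FALSE)
  }
  expect_gt(suppressWarnings(ks.test(p_cond, p_unc)$p.value), 0.01)
  expect_gt(suppressWarnings(ks.test(p_cond, "punif")$p.value), 0.01)
})

test_that("conditioning on the rare variant destroys a tagged interaction", {
  destroyed <- 0
  kept_dependent <- 0
  for (r in 1:8) {
    cfg <- scenario_config("tagging", seed = 500 + r)
    studies <- simulate_cohorts(cfg)
    merged <- merge_cohorts(studies)
    before <- conditional_lrt(merged, "tag1", "tag2", "filler1")  # unrelated
    after <- conditional_lrt(merged, "tag1", "tag2", "rare")
    destroyed <- destroyed + (after$p > 100 * before$p || after$p > 0.01)
    kept_dependent <- kept_dependent + after$dependent
  }
  expect_gte(destroyed, 7)
  expect_gte(kept_dependent, 7)
})

test_that("a genuine interaction survives conditioning on any third variant", {
  survived <- 0
  for (r in 1:8) {
    cfg <- scenario_config("interaction", seed = 600 + r)
    merged <- merge_cohorts(simulate_cohorts(cfg))
    ps <- sapply(c("filler1", "filler2"), function(cs) {
      conditional_lrt(merged, "snpA", "snpB", cs, dependence_p = 0.0125)$p
    })
    survived <- survived + all(ps < 0.0125)
  }
  expect_gte(survived, 7)
})

test_that("window scan finds the planted dependency and honours the window", {
  cfg <- scenario_config("tagging", seed = 91)
  studies <- simulate_cohorts(cfg)
  merged <- merge_cohorts(studies)
  pair <- data.frame(snp1 = "tag1", snp2 = "tag2", enc1 = "dosage",
                     enc2 = "dosage")
  cs <- conditioning_window_scan(merged, pair)
  expect_true("rare" %in% cs$dependent_on)
  expect_equal(cs$bar, 0.05 / nrow(cs$results))
  # the distant SNP lies outside the +/-200 kb windows
  expect_false("distant1" %in% cs$results$cond_snp)
  # excluding the rare variant from the cohort: no dependency found
  keep <- setdiff(merged$genotypes$variants$id, "rare")
  merged_no_rare <- merged
  merged_no_rare$genotypes <- subset_variants(merged$genotypes, keep)
  cs2 <- conditioning_window_scan(merged_no_rare, pair)
  expect_false("rare" %in% cs2$results$cond_snp)
  expect_equal(length(cs2$dependent_on), 0L)
})

test_that("the four criteria combine into an overall verdict", {
  cfg <- scenario_config("interaction", seed = 95)
  studies <- simulate_cohorts(cfg)
  merged <- merge_cohorts(studies)
  scan <- epistasis_scan(studies, stage1_p = 1e-2, count_encodings = TRUE)
  top <- significant_pairs(scan)[1, ]
  rep <- prioritize_pair(top, studies, merged,
                         threshold = scan$config$stage2_threshold,
                         min_consistent = 3)
  expect_true(rep$replication$pass)
  expect_true(rep$ld$pass)
  expect_true(rep$pass)
  expect_output(print(rep), "PASS")
})
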