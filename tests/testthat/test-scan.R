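test_that("stage 1 enumerates all 16 encoding combinations per pair", {
  cohort <- toy_cohort(n = 60, seed = 1, m = 3)
  out <- stage1_screen(cohort)
  expect_equal(nrow(out), 3 * 16)  # 3 pairs x 16 combinations
  per_pair <- table(paste(out$snp1, out$snp2))
  expect_true(all(per_pair == 16))
  combos <- unique(out[, c("enc1", "enc2")])
  expect_equal(nrow(combos), 16)
})

test_that("stage-1 OLS matches the lm() reference to 1e-10", {
  cohort <- toy_cohort(n = 20, seed = 2, m = 2)
  out <- stage1_screen(cohort)
  y <- cohort$phenotypes$status
  for (r in which(is.na(out$skip))) {
    e1 <- encode_genotype(dosage_of(cohort$genotypes, out$snp1[r]), out$enc1[r])
    e2 <- encode_genotype(dosage_of(cohort$genotypes, out$snp2[r]), out$enc2[r])
    ref <- summary(lm(y ~ e1 + e2 + I(e1 * e2)))$coefficients
    expect_equal(out$beta[r], ref[4, 1], tolerance = 1e-10)
    expect_equal(out$se[r], ref[4, 2], tolerance = 1e-10)
    expect_equal(out$p[r], ref[4, 4], tolerance = 1e-10)
  }
})

test_that("degenerate encoded designs are skipped with a reason", {
  # a SNP with no homozygous-minor calls makes the recessive column constant
  d <- cbind(a = c(rep(1, 10), rep(0, 10)), b = rbinom(20, 2, 0.5))
  gm <- genotype_matrix(d, data.frame(id = c("a", "b")))
  ch <- study_cohort(gm, data.frame(sample_id = gm$samples,
                                    status = rep(c(1, 0), 10)))
  out <- stage1_screen(ch)
  rec <- out[out$enc1 == "recessive" & out$snp1 == "a", ]
  expect_true(all(!is.na(rec$skip)))
  expect_true(all(is.na(rec$beta)))
})

test_that("interaction beta is symmetric under swapped SNP order", {
  cohort <- toy_cohort(n = 80, seed = 3, m = 2)
  y <- cohort$phenotypes$status
  a <- dosage_of(cohort$genotypes, "v1")
  b <- dosage_of(cohort$genotypes, "v2")
  f1 <- episcreen:::ols_interaction(y, a, b)
  f2 <- episcreen:::ols_interaction(y, b, a)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
})

test_that("fixed-effects meta-analysis follows the inverse-variance formula", {
  one <- fixed_effects_meta(0.3, 0.1)
  expect_equal(one$beta, 0.3)
  expect_equal(one$se, 0.1)
  k <- 4
  same <- fixed_effects_meta(rep(0.3, k), rep(0.1, k))
  expect_equal(same$beta, 0.3)
  expect_equal(same$se, 0.1 / sqrt(k))
  two <- fixed_effects_meta(c(0.2, 0.4), c(0.1, 0.2))
  expect_equal(two$beta, 0.24)
  expect_equal(two$se, 0.0894427, tolerance = 1e-6)
  expect_equal(two$direction_consistency, 2L)
  none <- fixed_effects_meta(NA_real_, NA_real_)
  expect_equal(none$n_studies, 0L)
  expect_true(is.na(none$beta))
})

test_that("meta-analysis agrees with metafor's fixed-effects model", {
  skip_if_not_installed("metafor")
  set.seed(12)
  beta <- rnorm(6); se <- runif(6, 0.05, 0.3)
  ours <- fixed_effects_meta(beta, se)
  ref <- metafor::rma(yi = beta, sei = se, method = "FE")
  expect_equal(ours$beta, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(ours$se, as.numeric(ref$se), tolerance = 1e-10)
})

test_that("pooled standard error never exceeds the best single study", {
  set.seed(13)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    se <- runif(k, 0.02, 0.5)
    beta <- rnorm(k)
    m <- fixed_effects_meta(beta, se)
    expect_lte(m$se, min(se))
    # adding a study never increases the pooled se
    m2 <- fixed_effects_meta(c(beta, 0), c(se, 0.4))
    expect_lte(m2$se, m$se)
  }
})

test_that("best-encoding selection is deterministic with the stated tie rules", {
  base <- data.frame(snp1 = "a", snp2 = "b",
                     enc1 = rep(genetic_encodings(), each = 4),
                     enc2 = rep(genetic_encodings(), 4),
                     beta = 0.1, se = 0.05, n_studies = 2,
                     direction_consistency = 2)
  base$p <- 0.5
  base$p[base$enc1 == "recessive" & base$enc2 == "dominant"] <- 0.001
  pick <- select_best_encoding(base)
  expect_equal(pick$enc1, "recessive")
  expect_equal(pick$enc2, "dominant")
  # exact tie: (dosage, dosage) wins
  base$p <- 0.01
  tie <- select_best_encoding(base)
  expect_equal(c(tie$enc1, tie$enc2), c("dosage", "dosage"))
  # tie without a dosage-dosage candidate: lexicographic
  sub <- base[base$enc1 != "dosage", ]
  tie2 <- select_best_encoding(sub)
  expect_equal(c(tie2$enc1, tie2$enc2), c("dominant", "dominant"))
  # single valid combination returned unchanged
  one <- base[7, ]
  expect_equal(select_best_encoding(one)[, c("enc1", "enc2")],
               one[, c("enc1", "enc2")], ignore_attr = TRUE)
})

test_that("a planted dosage-dosage interaction selects the dosage-dosage model", {
  hits <- 0
  for (r in 1:20) {
    cfg <- scenario_config("interaction", seed = 400 + r)
    studies <- simulate_cohorts(cfg)
    s1 <- do.call(rbind, lapply(studies, stage1_screen,
                                variant_ids = c("snpA", "snpB")))
    best <- select_best_encoding(meta_screen(s1))
    hits <- hits + (best$enc1 == "dosage" && best$enc2 == "dosage")
  }
  expect_gte(hits, 15)
})

test_that("stage-2 logistic coefficients match a hand-written IRLS to 1e-6", {
  set.seed(14)
  n <- 200
  d <- cbind(a = rbinom(n, 2, 0.35), b = rbinom(n, 2, 0.4))
  gm <- genotype_matrix(d, data.frame(id = c("a", "b")))
  eta <- -0.3 + 0.3 * d[, 1] * d[, 2]
  y <- rbinom(n, 1, plogis(eta))
  ch <- study_cohort(gm, data.frame(sample_id = gm$samples, status = y))
  ch$mds <- data.frame(sample_id = gm$samples, MDS1 = rnorm(n, 0, 0.01),
                       MDS2 = rnorm(n, 0, 0.01))
  fit <- episcreen:::logistic_interaction(ch, "a", "b", "dosage", "dosage")
  e1 <- d[, 1]; e2 <- d[, 2]
  X <- cbind(1, e1, e2, e1 * e2, ch$mds$MDS1, ch$mds$MDS2)
  ref <- irls_logistic(X, y)
  expect_equal(fit$beta, unname(ref$beta[4]), tolerance = 1e-6)
  expect_equal(fit$se, unname(ref$se[4]), tolerance = 1e-6)
})

test_that("the Bonferroni threshold follows the pair-count rule", {
  expect_equal(bonferroni_threshold(4654), 4.6178e-9, tolerance = 1e-4)
  expect_equal(bonferroni_threshold(2), 0.05)
  expect_equal(bonferroni_threshold(10), 0.05 / 45)
  expect_error(bonferroni_threshold(1), "at least 2")
})

test_that("stage-1 null pass counts are consistent with the Poisson bound", {
  # under the global null the expected number of (pair x encoding) tests
  # below t is 16 * n_pairs * t; check an upper bound at a loose t
  set.seed(15)
  n <- 600
  hits <- 0
  reps <- 40
  t_loose <- 1e-3
  for (r in seq_len(reps)) {
    d <- cbind(a = rbinom(n, 2, 0.3), b = rbinom(n, 2, 0.3))
    gm <- genotype_matrix(d, data.frame(id = c("a", "b")))
    ch <- study_cohort(gm, data.frame(sample_id = gm$samples,
                                      status = rbinom(n, 1, 0.5)))
    out <- stage1_screen(ch)
    hits <- hits + sum(out$p < t_loose, na.rm = TRUE)
  }
  lambda <- reps * 16 * 1 * t_loose
  expect_lte(hits, qpois(0.995, lambda) + lambda)
})

test_that("the scan ranks a planted interaction first and stage 2 confirms it", {
  cfg <- scenario_config("interaction", seed = 123)
  studies <- simulate_cohorts(cfg)
  scan <- epistasis_scan(studies, stage1_p = 1e-2, count_encodings = TRUE)
  expect_gt(nrow(scan$stage2), 0)
  top <- scan$stage2[1, ]
  expect_setequal(c(top$snp1, top$snp2), c("snpA", "snpB"))
  expect_true(top$significant)
  # stage-2 and stage-1 directions agree for the powered pair
  s1 <- scan$best[scan$best$snp1 == top$snp1 & scan$best$snp2 == top$snp2, ]
  expect_equal(sign(top$beta), sign(s1$beta))
})
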