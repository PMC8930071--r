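#' Criterion 1: replication across studies
#'
#' A pair passes when its pooled interaction p-value clears the significance
#' threshold and the per-study effect signs agree with the pooled sign in at
#' least `min_consistent` studies. The `strict` reading instead demands
#' per-study significance (p below the threshold) together with sign
#' agreement in at least `min_consistent` studies.
#'
#' @param pair one row of a [stage2_refine()] table (carries `study_beta`,
#'   `study_se`, pooled `beta`, `p`).
#' @param threshold significance threshold (e.g. [bonferroni_threshold()]).
#' @param min_consistent minimum number of same-direction studies
#'   (default 8, of 10).
#' @param strict use the per-study-significance reading.
#' @return list with `pass`, `n_consistent`, `n_studies`, `reason`.
#' @export
check_replication <- function(pair, threshold, min_consistent = 8,
                              strict = FALSE) {
  beta <- pair$study_beta[[1]]
  se <- pair$study_se[[1]]
  ok <- is.finite(beta) & is.finite(se)
  n_total <- sum(ok)
  if (n_total < min_consistent) {
    return(list(pass = FALSE, n_consistent = 0L, n_studies = n_total,
                reason = sprintf("only %d usable studies (< %d required)",
                                 n_total, min_consistent)))
  }
  consistent <- sign(beta[ok]) == sign(pair$beta)
  if (strict) {
    p_study <- 2 * stats::pnorm(abs(beta[ok] / se[ok]), lower.tail = FALSE)
    n_cons <- sum(consistent & p_study < threshold)
    pass <- n_cons >= min_consistent
  } else {
    n_cons <- sum(consistent)
    pass <- (pair$p < threshold) && n_cons >= min_consistent
  }
  reason <- if (pass) NA_character_ else if (!strict && pair$p >= threshold) {
    sprintf("meta p %.3g above threshold %.3g", pair$p, threshold)
  } else {
    sprintf("%d consistent studies (< %d required)", n_cons, min_consistent)
  }
  list(pass = pass, n_consistent = as.integer(n_cons),
       n_studies = as.integer(n_total), reason = reason)
}

#' Criterion 2: low LD between the target SNPs
#'
#' Passes when the two SNPs lie on different chromosomes, or when their
#' r-squared is below `r2_max` (default 0.2).
#'
#' @param gm a [genotype_matrix()] covering both SNPs.
#' @param snp1,snp2 variant ids.
#' @param r2_max same-chromosome r-squared bound.
#' @return list with `pass`, `r_squared`, `same_chromosome`.
#' @export
check_pair_ld <- function(gm, snp1, snp2, r2_max = 0.2) {
  v <- gm$variants
  same <- v$chrom[match(snp1, v$id)] == v$chrom[match(snp2, v$id)]
  r2 <- ld_r2(gm, snp1, snp2)
  pass <- !same || (!is.na(r2) && r2 < r2_max)
  list(pass = pass, r_squared = r2, same_chromosome = same)
}

#' Criterion 3: supporting signal in LD proxies
#'
#' Finds every variant in `gm` with r-squared above `proxy_r2` to either
#' target SNP, substitutes it for the SNP it proxies, re-tests the
#' interaction (stage-1 screen + meta-analysis under the pair's selected
#' encodings), and passes when at least one proxy pair shows a
#' same-direction interaction with p below `proxy_p`. When no proxy exists
#' the criterion passes vacuously with a flag.
#'
#' @param studies list of [study_cohort()] objects.
#' @param gm reference [genotype_matrix()] for LD lookup (e.g. the merged
#'   cohort's genotypes).
#' @param pair one stage-2 row (`snp1`, `snp2`, `enc1`, `enc2`, `beta`).
#' @param proxy_r2 LD bound defining a proxy (default 0.5).
#' @param proxy_p nominal significance bound for the proxy-pair interaction
#'   (default 0.05).
#' @return list with `pass`, `vacuous`, `proxies` (data frame of proxy-pair
#'   tests).
#' @export
check_proxy_support <- function(studies, gm, pair, proxy_r2 = 0.5,
                                proxy_p = 0.05) {
  targets <- c(pair$snp1, pair$snp2)
  others <- setdiff(gm$variants$id, targets)
  prox <- list()
  for (o in others) {
    for (t in 1:2) {
      r2 <- ld_r2(gm, o, targets[t])
      if (!is.na(r2) && r2 > proxy_r2) {
        prox[[length(prox) + 1]] <- data.frame(proxy = o, replaces = t, r2 = r2)
      }
    }
  }
  if (length(prox) == 0) {
    return(list(pass = TRUE, vacuous = TRUE,
                proxies = data.frame(proxy = character(0))))
  }
  prox <- do.call(rbind, prox)
  res <- lapply(seq_len(nrow(prox)), function(i) {
    ids <- targets
    ids[prox$replaces[i]] <- prox$proxy[i]
    per <- lapply(studies, function(s) {
      gm_s <- impute_mean(s$genotypes)
      e1 <- encode_genotype(dosage_of(gm_s, ids[1]), pair$enc1)
      e2 <- encode_genotype(dosage_of(gm_s, ids[2]), pair$enc2)
      ols_interaction(as.numeric(s$phenotypes$status), e1, e2)
    })
    m <- fixed_effects_meta(vapply(per, function(x) x$beta %||% NA_real_, 1),
                            vapply(per, function(x) x$se %||% NA_real_, 1))
    data.frame(proxy = prox$proxy[i], replaces = prox$replaces[i],
               r2 = prox$r2[i], beta = m$beta, p = m$p)
  })
  res <- do.call(rbind, res)
  supported <- is.finite(res$p) & res$p < proxy_p &
    sign(res$beta) == sign(pair$beta)
  list(pass = any(supported), vacuous = FALSE, proxies = res)
}

#' Conditional likelihood-ratio test against a third SNP
#'
#' Tests whether the pairwise interaction term carries information beyond
#' the additive effect of a conditioning SNP: LRT (1 df) between
#' `y ~ snp1 + snp2 + snp3 + covariates` and the same model plus the
#' `snp1 x snp2` interaction, fitted on the merged cohort. The interaction
#' is called *dependent* on the conditioning SNP when the LRT p-value fails
#' the supplied bar. Covariates are the merged-data MDS components (when
#' attached) and the study indicator.
#'
#' @param merged a merged [study_cohort()] (see [merge_cohorts()]).
#' @param snp1,snp2 the target pair's variant ids.
#' @param cond_snp conditioning variant id (coded as minor-allele dosage).
#' @param enc1,enc2 encodings for the target pair (default dosage).
#' @param dependence_p bar below which the interaction is declared
#'   independent of the conditioning SNP (Bonferroni over conditioning SNPs).
#' @param collinear_r2 skip the conditioning SNP when its r-squared with
#'   either target exceeds this (default 0.99).
#' @return object of class `conditional_result`: list with `cond_snp`,
#'   `lrt`, `df`, `p`, `dependent`, `skip`.
#' @export
conditional_lrt <- function(merged, snp1, snp2, cond_snp,
                            enc1 = "dosage", enc2 = "dosage",
                            dependence_p = 0.05, collinear_r2 = 0.99) {
  gm <- impute_mean(merged$genotypes)
  out <- structure(list(cond_snp = cond_snp, lrt = NA_real_, df = 1L,
                        p = NA_real_, dependent = NA, skip = NA_character_),
                   class = "conditional_result")
  for (t in c(snp1, snp2)) {
    r2 <- ld_r2(gm, cond_snp, t)
    if (!is.na(r2) && r2 > collinear_r2) {
      out$skip <- sprintf("collinear with target %s (r2 = %.3f)", t, r2)
      return(out)
    }
  }
  e1 <- encode_genotype(dosage_of(gm, snp1), enc1)
  e2 <- encode_genotype(dosage_of(gm, snp2), enc2)
  s3 <- dosage_of(gm, cond_snp)
  dat <- data.frame(y = merged$phenotypes$status, e1 = e1, e2 = e2,
                    e12 = e1 * e2, s3 = s3)
  covars <- character(0)
  if (!is.null(merged$mds)) {
    mcols <- setdiff(names(merged$mds), "sample_id")
    dat <- cbind(dat, merged$mds[mcols])
    covars <- c(covars, mcols)
  }
  if (!is.null(merged$phenotypes$study) &&
      length(unique(merged$phenotypes$study)) > 1) {
    dat$study <- factor(merged$phenotypes$study)
    covars <- c(covars, "study")
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  rhs <- paste(c("e1", "e2", "s3", covars), collapse = " + ")
  reduced <- stats::glm(stats::as.formula(paste("y ~", rhs)),
                        family = stats::binomial(), data = dat)
  full <- stats::glm(stats::as.formula(paste("y ~", rhs, "+ e12")),
                     family = stats::binomial(), data = dat)
  lrt <- max(0, reduced$deviance - full$deviance)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  out$lrt <- lrt
  out$p <- p
  out$dependent <- p >= dependence_p
  out
}

#' @export
print.conditional_result <- function(x, ...) {
  if (!is.na(x$skip)) {
    cat("conditional_result:", x$cond_snp, "skipped:", x$skip, "\n")
  } else {
    cat(sprintf("conditional_result: %s LRT = %.3f (df 1), p = %.3g -> %s\n",
                x$cond_snp, x$lrt, x$p,
                if (x$dependent) "interaction DEPENDENT" else "independent"))
  }
  invisible(x)
}

#' Criterion 4: conditional scan over a window around the pair
#'
#' Runs [conditional_lrt()] for every eligible SNP within `window` of either
#' target SNP (same chromosome) plus any supplied external SNPs (e.g. known
#' GWAS hits), using a Bonferroni dependence bar of `alpha / n_tested`.
#' Reports all results, the worst-case (largest p) conditioning SNP, and
#' every *dependent* verdict.
#'
#' @param merged merged [study_cohort()].
#' @param pair stage-2 row (`snp1`, `snp2`, `enc1`, `enc2`).
#' @param window half-width of the conditioning window in bp
#'   (default 200 kb).
#' @param extra_snps additional conditioning variant ids.
#' @param alpha family-wise rate for the dependence bar (default 0.05).
#' @return object of class `conditional_scan`: list with `results` (data
#'   frame), `dependent_on` (ids), `worst` (max-p row), `bar`, `vacuous`.
#' @export
conditioning_window_scan <- function(merged, pair, window = 200000L,
                                     extra_snps = character(0), alpha = 0.05) {
  v <- merged$genotypes$variants
  targets <- c(pair$snp1, pair$snp2)
  tv <- v[match(targets, v$id), ]
  in_window <- rep(FALSE, nrow(v))
  for (t in 1:2) {
    in_window <- in_window | (v$chrom == tv$chrom[t] &
                                abs(v$pos - tv$pos[t]) <= window)
  }
  cand <- union(v$id[in_window], intersect(extra_snps, v$id))
  cand <- setdiff(cand, targets)
  if (length(cand) == 0) {
    return(structure(list(results = data.frame(cond_snp = character(0)),
                          dependent_on = character(0), worst = NULL,
                          bar = NA_real_, vacuous = TRUE),
                     class = "conditional_scan"))
  }
  bar <- alpha / length(cand)
  res <- lapply(cand, function(cs) {
    conditional_lrt(merged, pair$snp1, pair$snp2, cs,
                    enc1 = pair$enc1, enc2 = pair$enc2, dependence_p = bar)
  })
  tab <- data.frame(cond_snp = cand,
                    lrt = vapply(res, function(x) x$lrt, 1),
                    p = vapply(res, function(x) x$p, 1),
                    dependent = vapply(res, function(x) isTRUE(x$dependent), TRUE),
                    skip = vapply(res, function(x) x$skip, ""))
  tested <- tab[is.na(tab$skip) | tab$skip == "", , drop = FALSE]
  worst <- if (nrow(tested)) tested[which.max(tested$p), , drop = FALSE] else NULL
  structure(list(results = tab, dependent_on = tab$cond_snp[tab$dependent],
                 worst = worst, bar = bar, vacuous = FALSE),
            class = "conditional_scan")
}

#' @export
print.conditional_scan <- function(x, ...) {
  if (x$vacuous) {
    cat("conditional_scan: no eligible conditioning SNPs (vacuous pass)\n")
    return(invisible(x))
  }
  cat("conditional_scan:", nrow(x$results), "conditioning SNP(s), bar",
      sprintf("%.3g", x$bar), "\n")
  if (length(x$dependent_on)) {
    cat("  interaction DEPENDENT on:", paste(x$dependent_on, collapse = ", "), "\n")
  } else {
    cat("  interaction independent of every conditioning SNP\n")
  }
  invisible(x)
}

#' Apply all four prioritization criteria to a candidate pair
#'
#' @param pair one stage-2 row.
#' @param studies per-study cohorts (criterion 1 and 3).
#' @param merged merged cohort (criteria 2 and 4).
#' @param threshold significance threshold for criterion 1 (the scan's
#'   Bonferroni bar).
#' @param min_consistent criterion-1 direction count (default 8).
#' @param r2_max criterion-2 bound (default 0.2).
#' @param proxy_r2,proxy_p criterion-3 parameters.
#' @param window,extra_snps criterion-4 parameters.
#' @param strict_replication criterion-1 strict reading flag.
#' @return object of class `criteria_report`.
#' @export
prioritize_pair <- function(pair, studies, merged, threshold,
                            min_consistent = 8, r2_max = 0.2,
                            proxy_r2 = 0.5, proxy_p = 0.05,
                            window = 200000L, extra_snps = character(0),
                            strict_replication = FALSE) {
  c1 <- check_replication(pair, threshold, min_consistent, strict_replication)
  c2 <- check_pair_ld(merged$genotypes, pair$snp1, pair$snp2, r2_max)
  c3 <- check_proxy_support(studies, merged$genotypes, pair, proxy_r2, proxy_p)
  c4 <- conditioning_window_scan(merged, pair, window, extra_snps)
  c4_pass <- c4$vacuous || length(c4$dependent_on) == 0
  structure(list(pair = pair[c("snp1", "snp2", "enc1", "enc2")],
                 replication = c1, ld = c2, proxy = c3, conditional = c4,
                 pass = c1$pass && c2$pass && c3$pass && c4_pass),
            class = "criteria_report")
}

#' @export
print.criteria_report <- function(x, ...) {
  cat(sprintf("criteria_report for %s x %s\n", x$pair$snp1, x$pair$snp2))
  cat(sprintf("  1. replication: %s (%d/%d same-direction)\n",
              if (x$replication$pass) "pass" else "FAIL",
              x$replication$n_consistent, x$replication$n_studies))
  cat(sprintf("  2. pair LD: %s (r2 = %.4g)\n",
              if (x$ld$pass) "pass" else "FAIL", x$ld$r_squared))
  cat(sprintf("  3. proxy support: %s%s\n",
              if (x$proxy$pass) "pass" else "FAIL",
              if (x$proxy$vacuous) " (no proxies, vacuous)" else ""))
  c4_pass <- x$conditional$vacuous || length(x$conditional$dependent_on) == 0
  cat(sprintf("  4. conditional independence: %s%s\n",
              if (c4_pass) "pass" else "FAIL",
              if (!c4_pass) paste0(" (dependent on ",
                                   paste(x$conditional$dependent_on,
                                         collapse = ", "), ")") else ""))
  cat("  overall:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
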