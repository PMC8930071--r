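# covariate columns usable from a cohort's phenotype/mds tables
cohort_covariates <- function(cohort, covariates) {
  dat <- list()
  for (cv in covariates) {
    if (!is.null(cohort$phenotypes[[cv]])) {
      dat[[cv]] <- cohort$phenotypes[[cv]]
    } else if (!is.null(cohort$mds) && cv %in% names(cohort$mds)) {
      dat[[cv]] <- cohort$mds[[cv]]
    } else {
      stop("unknown covariate: ", cv)
    }
  }
  if (!is.null(cohort$phenotypes$study) && !"study" %in% covariates &&
      length(unique(cohort$phenotypes$study)) > 1) {
    dat$study <- factor(cohort$phenotypes$study)
  }
  as.data.frame(dat, optional = TRUE)
}

#' Genotypic odds ratios for one SNP
#'
#' Logistic regression of case status on genotype-class indicators
#' (heterozygous and minor-homozygous, hard calls), with the major-allele
#' homozygote as the reference class — no genetic model is assumed. A class
#' with no cases or no controls is flagged unestimable rather than reported.
#'
#' @param cohort a [study_cohort()] (typically merged).
#' @param snp variant id.
#' @param covariates names of covariate columns (phenotype or MDS).
#' @return data frame, one row per genotype class, with `log_or`, `se`, `p`,
#'   `n_cases`, `n_controls`, `estimable`. The reference row has
#'   `log_or = 0` by construction.
#' @export
genotypic_or <- function(cohort, snp, covariates = character(0)) {
  g <- hard_calls(dosage_of(cohort$genotypes, snp))
  y <- cohort$phenotypes$status
  dat <- data.frame(y = y, het = as.numeric(g == 1), hom = as.numeric(g == 2))
  cv <- cohort_covariates(cohort, covariates)
  if (ncol(cv)) dat <- cbind(dat, cv)
  keep <- stats::complete.cases(dat) & !is.na(g)
  dat <- dat[keep, , drop = FALSE]
  gk <- g[keep]
  counts <- t(vapply(0:2, function(cls) {
    c(sum(dat$y == 1 & gk == cls), sum(dat$y == 0 & gk == cls))
  }, numeric(2)))
  estimable <- counts[, 1] > 0 & counts[, 2] > 0
  terms <- c("het", "hom")[estimable[2:3]]
  rhs <- paste(c(terms, names(cv)), collapse = " + ")
  if (rhs == "") rhs <- "1"
  fit <- stats::glm(stats::as.formula(paste("y ~", rhs)),
                    family = stats::binomial(), data = dat)
  cf <- summary(fit)$coefficients
  out <- data.frame(genotype = c("hom_major", "het", "hom_minor"),
                    log_or = c(0, NA, NA), se = c(NA, NA, NA),
                    p = c(NA, NA, NA),
                    n_cases = counts[, 1], n_controls = counts[, 2],
                    estimable = c(TRUE, estimable[2:3]))
  for (i in 2:3) {
    trm <- c("het", "hom")[i - 1]
    if (out$estimable[i] && trm %in% rownames(cf)) {
      out$log_or[i] <- cf[trm, 1]
      out$se[i] <- cf[trm, 2]
      out$p[i] <- cf[trm, 4]
    } else {
      out$estimable[i] <- FALSE
    }
  }
  out
}

#' Forward model selection over a SNP ladder
#'
#' Fits the nested logistic ladder used to dissect a flagged locus: starting
#' from covariates only, then adding the first (rare) SNP, then the two
#' common partner SNPs, their pairwise crossing, all two- and three-way
#' interactions, and — when a fourth SNP is supplied — its main effect and
#' the full four-way crossing. Each row reports residual deviance and df,
#' the likelihood-ratio test against the previous row, and the LRT against
#' a fixed baseline row (default: the first-SNP-only model).
#'
#' @param cohort a [study_cohort()], typically merged.
#' @param snps ordered variant ids (3 or 4; the first is the conditioning /
#'   rare variant). All coded as minor-allele dosage.
#' @param covariates covariate column names.
#' @param baseline_row row index of the fixed comparison model (default 2).
#' @param models optional custom ladder: list of right-hand-side formula
#'   strings over `s1..s4`; must be nested top to bottom.
#' @return object of class `model_ladder`: data frame of the comparison
#'   table with the fitted models in `attr(, "fits")`.
#' @export
forward_model_selection <- function(cohort, snps, covariates = character(0),
                                    baseline_row = 2, models = NULL) {
  stopifnot(length(snps) %in% c(3, 4) || !is.null(models))
  gm <- impute_mean(cohort$genotypes)
  dat <- data.frame(y = cohort$phenotypes$status)
  for (k in seq_along(snps)) dat[[paste0("s", k)]] <- dosage_of(gm, snps[k])
  cv <- cohort_covariates(cohort, covariates)
  if (ncol(cv)) dat <- cbind(dat, cv)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  cvs <- if (ncol(cv)) paste(names(cv), collapse = " + ") else "1"
  if (is.null(models)) {
    models <- c("1", "s1", "s1 + s2 + s3", "s1 + s2 * s3", "s1 * s2 * s3")
    if (length(snps) == 4) {
      models <- c(models, "s1 * s2 * s3 + s4", "s1 * s2 * s3 * s4")
    }
  }
  fits <- vector("list", length(models))
  prev_terms <- NULL
  for (i in seq_along(models)) {
    fml <- stats::as.formula(paste("y ~", cvs, "+", models[[i]]))
    trm <- attr(stats::terms(fml), "term.labels")
    if (!is.null(prev_terms) && !all(prev_terms %in% trm)) {
      stop("model ladder is not nested at row ", i)
    }
    prev_terms <- trm
    fits[[i]] <- stats::glm(fml, family = stats::binomial(), data = dat)
  }
  dev <- vapply(fits, stats::deviance, 1)
  rdf <- vapply(fits, stats::df.residual, 1)
  tab <- data.frame(model = paste("y ~", unlist(models), "+ covariates"),
                    resid_df = rdf, resid_deviance = dev,
                    df = c(NA, -diff(rdf)), deviance = c(NA, -diff(dev)))
  tab$p_vs_previous <- c(NA, stats::pchisq(tab$deviance[-1], tab$df[-1],
                                           lower.tail = FALSE))
  base <- baseline_row
  tab$p_vs_baseline <- NA_real_
  for (i in seq_along(models)) {
    if (i <= base) next
    dd <- dev[base] - dev[i]
    ddf <- rdf[base] - rdf[i]
    tab$p_vs_baseline[i] <- stats::pchisq(max(dd, 0), ddf, lower.tail = FALSE)
  }
  tab$separation <- vapply(fits, function(f) {
    any(abs(stats::coef(f)) > 20, na.rm = TRUE)
  }, TRUE)
  attr(tab, "fits") <- fits
  attr(tab, "baseline_row") <- base
  class(tab) <- c("model_ladder", "data.frame")
  tab
}

#' @export
print.model_ladder <- function(x, digits = 4, ...) {
  cat("Forward model selection (nested LRT ladder)\n")
  show <- as.data.frame(x)[c("model", "resid_df", "resid_deviance", "df",
                             "deviance", "p_vs_previous", "p_vs_baseline")]
  show$resid_deviance <- round(show$resid_deviance, 1)
  show$deviance <- round(show$deviance, 2)
  show$p_vs_previous <- signif(show$p_vs_previous, 3)
  show$p_vs_baseline <- signif(show$p_vs_baseline, 3)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Type-III term tests for a fitted GLM
#'
#' For each term in the model, the p-value of the likelihood-ratio test
#' between the full model and the model dropping that term's columns while
#' retaining all others (marginal, type-III convention — a main effect may
#' be dropped while its interactions remain).
#'
#' @param fit a fitted `glm`.
#' @return data frame with `term`, `df`, `lrt`, `p`.
#' @export
type3_terms <- function(fit) {
  if (any(is.na(stats::coef(fit)))) {
    stop("model contains aliased (duplicate) predictors; type-III tests undefined")
  }
  X <- stats::model.matrix(fit)
  assign <- attr(X, "assign")
  y <- fit$y
  labels <- attr(stats::terms(fit), "term.labels")
  full_dev <- stats::deviance(fit)
  out <- lapply(seq_along(labels), function(t) {
    keep <- assign != t
    Xr <- X[, keep, drop = FALSE]
    rfit <- stats::glm.fit(Xr, y, family = fit$family,
                           offset = fit$offset %||% rep(0, length(y)))
    lrt <- max(0, rfit$deviance - full_dev)
    df <- sum(assign == t)
    data.frame(term = labels[t], df = df, lrt = lrt,
               p = stats::pchisq(lrt, df, lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Rank-based inverse normal transformation
#'
#' Blom scores: `qnorm((rank - 3/8) / (n + 1/4))`, average ranks for ties,
#' applied to the non-missing values (NA preserved in place).
#'
#' @param values numeric vector with at least 2 non-missing values.
#' @return transformed vector (approximately standard normal).
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop("inverse normal transform needs at least 2 values")
  r <- rank(values[ok], ties.method = "average")
  out <- values
  out[ok] <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out
}

#' Association of SNPs (and optional interaction) with a quantitative trait
#'
#' Linear least-squares fit of the (by default inverse-normal-transformed)
#' trait on SNP dosages, optionally their pairwise product, and covariates
#' such as the KIV-repeat count.
#'
#' @param cohort a [study_cohort()].
#' @param trait name of the trait column in the phenotype table.
#' @param snps variant ids used as dosage predictors.
#' @param interaction add the product of the first two SNP dosages.
#' @param covariates covariate column names.
#' @param transform apply [inverse_normal_transform()] to the trait
#'   (default TRUE).
#' @return data frame of `term`, `beta`, `se`, `p` (intercept omitted).
#' @export
trait_association <- function(cohort, trait, snps, interaction = FALSE,
                              covariates = character(0), transform = TRUE) {
  gm <- impute_mean(cohort$genotypes)
  yv <- cohort$phenotypes[[trait]]
  if (is.null(yv)) stop("unknown trait column: ", trait)
  if (transform) yv <- inverse_normal_transform(yv)
  dat <- data.frame(y = yv)
  for (k in seq_along(snps)) dat[[paste0("s", k)]] <- dosage_of(gm, snps[k])
  if (interaction) {
    if (length(snps) < 2) stop("interaction needs two SNPs")
    dat$s1s2 <- dat$s1 * dat$s2
  }
  cv <- cohort_covariates(cohort, covariates)
  if (ncol(cv)) dat <- cbind(dat, cv)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fit <- stats::lm(y ~ ., data = dat)
  cf <- summary(fit)$coefficients
  cf <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  data.frame(term = rownames(cf), beta = cf[, 1], se = cf[, 2], p = cf[, 4],
             row.names = NULL)
}

#' AIC comparison of SNP, interaction and haplotype models
#'
#' Fits the five logistic models contrasted when dissecting a locus:
#' covariates only, haplotype dosages, additive SNPs, SNPs plus all their
#' interactions, and the full model with both haplotypes and interactions.
#' AIC is `deviance + 2 * k` with `k` the number of estimated (non-aliased)
#' regression coefficients including the intercept; EM haplotype
#' frequencies are estimated separately and not penalized. Likelihood-ratio
#' tests are reported against the SNPs model (for the interaction and full
#' models) and against the SNPs+interactions model (for the full model).
#'
#' @param cohort a [study_cohort()].
#' @param snps variant ids (typically 3).
#' @param em a [haplotype_em()] fit over the same SNPs; computed internally
#'   when `NULL`.
#' @param covariates covariate column names.
#' @return object of class `aic_comparison`: data frame with `model`, `aic`,
#'   `k`, `deviance`, `p_vs_snps`, `p_vs_interact`.
#' @export
aic_model_comparison <- function(cohort, snps, em = NULL,
                                 covariates = character(0)) {
  gm <- impute_mean(cohort$genotypes)
  if (is.null(em)) em <- haplotype_em(cohort$genotypes, snps)
  dat <- data.frame(y = cohort$phenotypes$status)
  for (k in seq_along(snps)) dat[[paste0("s", k)]] <- dosage_of(gm, snps[k])
  hd <- em$expected_dosage
  ref <- which.max(em$frequencies)
  hap_cols <- setdiff(seq_len(ncol(hd)), ref)
  hap_cols <- hap_cols[em$frequencies[hap_cols] >= 1e-4]
  hnames <- paste0("hap_", colnames(hd)[hap_cols])
  # EM excludes samples with missing hard calls; align by sample id
  hmat <- matrix(NA_real_, nrow(dat), length(hap_cols),
                 dimnames = list(NULL, hnames))
  idx <- match(rownames(hd), cohort$genotypes$samples)
  hmat[idx, ] <- hd[, hap_cols, drop = FALSE]
  dat <- cbind(dat, hmat)
  cv <- cohort_covariates(cohort, covariates)
  if (ncol(cv)) dat <- cbind(dat, cv)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  cvs <- if (ncol(cv)) paste("+", paste(names(cv), collapse = " + ")) else ""
  svars <- paste0("s", seq_along(snps))
  specs <- list(
    no_genetics = "1",
    haplotypes = paste(hnames, collapse = " + "),
    snps = paste(svars, collapse = " + "),
    snps_interactions = paste(svars, collapse = " * "),
    full = paste(paste(svars, collapse = " * "), "+",
                 paste(hnames, collapse = " + ")))
  fits <- lapply(specs, function(s) {
    stats::glm(stats::as.formula(paste("y ~", s, cvs)),
               family = stats::binomial(), data = dat)
  })
  k <- vapply(fits, function(f) sum(!is.na(stats::coef(f))), 1)
  dev <- vapply(fits, stats::deviance, 1)
  aic <- dev + 2 * k
  lrt_p <- function(red, full) {
    dd <- dev[red] - dev[full]
    ddf <- k[full] - k[red]
    if (ddf <= 0) return(NA_real_)
    stats::pchisq(max(dd, 0), ddf, lower.tail = FALSE)
  }
  tab <- data.frame(model = c("no_genetics", "haplotypes", "snps",
                              "snps_interactions", "full"),
                    aic = aic, k = k, deviance = dev,
                    p_vs_snps = c(NA, NA, NA, lrt_p("snps", "snps_interactions"),
                                  lrt_p("snps", "full")),
                    p_vs_interact = c(NA, NA, NA, NA,
                                      lrt_p("snps_interactions", "full")),
                    row.names = NULL)
  attr(tab, "fits") <- fits
  class(tab) <- c("aic_comparison", "data.frame")
  tab
}

#' @export
print.aic_comparison <- function(x, ...) {
  cat("Model comparison (AIC = deviance + 2k; haplotype frequencies not penalized)\n")
  show <- as.data.frame(x)
  show$aic <- round(show$aic, 1)
  show$deviance <- round(show$deviance, 1)
  show$p_vs_snps <- signif(show$p_vs_snps, 3)
  show$p_vs_interact <- signif(show$p_vs_interact, 3)
  print(show, row.names = FALSE)
  best <- x$model[which.min(x$aic)]
  cat("best AIC:", best, "\n")
  invisible(x)
}
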