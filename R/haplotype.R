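#' EM haplotype-frequency estimation over a few SNPs
#'
#' Multilocus haplotype frequencies from unphased hard-call genotypes under
#' Hardy-Weinberg equilibrium: the classic EM over all diplotypes consistent
#' with each observed multilocus genotype. Initialized deterministically at
#' the product of single-SNP allele frequencies; converged when the largest
#' frequency change falls below `tol`. The log-likelihood is checked to be
#' non-decreasing at every iteration. Samples with any missing call at the
#' `m` SNPs are excluded (`m <= 4`).
#'
#' @param gm a [genotype_matrix()].
#' @param snps variant ids (at most 4).
#' @param tol convergence tolerance on frequencies (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return object of class `haplotype_em`: list with `haplotypes` (2^m x m
#'   allele matrix), `labels` (allele strings from the variants' ref/alt),
#'   `frequencies`, `loglik` (trace), `expected_dosage` (sample x haplotype
#'   posterior-expected copy counts), `n`, `converged`, `iterations`.
#' @export
haplotype_em <- function(gm, snps, tol = 1e-8, max_iter = 1000) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- length(snps)
  if (m < 1 || m > 4) stop("haplotype EM supports 1 to 4 SNPs")
  j <- match(snps, gm$variants$id)
  if (anyNA(j)) stop("unknown variant id(s)")
  G <- apply(gm$dosages[, j, drop = FALSE], 2, hard_calls)
  G <- matrix(G, ncol = m)
  keep <- stats::complete.cases(G)
  G <- G[keep, , drop = FALSE]
  samples <- gm$samples[keep]
  n <- nrow(G)
  if (n == 0) stop("no samples with complete hard calls at the requested SNPs")

  haps <- as.matrix(expand.grid(rep(list(0:1), m)))[, m:1, drop = FALSE]
  dimnames(haps) <- NULL
  H <- nrow(haps)
  # allele-string labels: ref allele for 0, alt (minor) for 1
  va <- gm$variants[j, ]
  labels <- apply(haps, 1, function(h) {
    paste(ifelse(h == 1, va$alt, va$ref), collapse = "")
  })

  # enumerate compatible unordered diplotypes per distinct genotype
  gkey <- apply(G, 1, paste, collapse = "")
  ug <- unique(gkey)
  compat <- lapply(ug, function(k) {
    g <- as.integer(strsplit(k, "")[[1]])
    prs <- list()
    for (a in seq_len(H)) for (b in a:H) {
      if (all(haps[a, ] + haps[b, ] == g)) prs[[length(prs) + 1]] <- c(a, b)
    }
    do.call(rbind, prs)
  })
  names(compat) <- ug
  gcount <- table(gkey)[ug]

  allele_freq <- colMeans(G) / 2
  p <- apply(haps, 1, function(h) {
    prod(ifelse(h == 1, allele_freq, 1 - allele_freq))
  })
  p <- p / sum(p)

  diplo_lik <- function(p) {
    vapply(compat, function(prs) {
      if (is.null(prs)) return(0)
      sum(apply(prs, 1, function(ab) {
        if (ab[1] == ab[2]) p[ab[1]]^2 else 2 * p[ab[1]] * p[ab[2]]
      }))
    }, 1)
  }
  ll_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lik <- diplo_lik(p)
    ll <- sum(gcount * log(lik))
    if (length(ll_trace) && ll < utils::tail(ll_trace, 1) - 1e-9) {
      stop("EM log-likelihood decreased; this indicates a bug")
    }
    ll_trace <- c(ll_trace, ll)
    newc <- numeric(H)
    for (k in seq_along(ug)) {
      prs <- compat[[k]]
      w <- apply(prs, 1, function(ab) {
        if (ab[1] == ab[2]) p[ab[1]]^2 else 2 * p[ab[1]] * p[ab[2]]
      })
      w <- w / sum(w)
      for (r in seq_len(nrow(prs))) {
        newc[prs[r, 1]] <- newc[prs[r, 1]] + gcount[k] * w[r]
        newc[prs[r, 2]] <- newc[prs[r, 2]] + gcount[k] * w[r]
      }
    }
    p_new <- newc / (2 * n)
    if (max(abs(p_new - p)) < tol) { p <- p_new; converged <- TRUE; break }
    p <- p_new
  }
  # posterior-expected haplotype copy counts per sample
  ed <- matrix(0, n, H, dimnames = list(samples, labels))
  for (k in seq_along(ug)) {
    prs <- compat[[k]]
    w <- apply(prs, 1, function(ab) {
      if (ab[1] == ab[2]) p[ab[1]]^2 else 2 * p[ab[1]] * p[ab[2]]
    })
    w <- w / sum(w)
    cnt <- numeric(H)
    for (r in seq_len(nrow(prs))) {
      cnt[prs[r, 1]] <- cnt[prs[r, 1]] + w[r]
      cnt[prs[r, 2]] <- cnt[prs[r, 2]] + w[r]
    }
    ed[gkey == ug[k], ] <- matrix(cnt, sum(gkey == ug[k]), H, byrow = TRUE)
  }
  structure(list(haplotypes = haps, labels = labels,
                 frequencies = stats::setNames(as.numeric(p), labels),
                 loglik = ll_trace, expected_dosage = ed, n = n,
                 converged = converged, iterations = length(ll_trace),
                 snps = snps),
            class = "haplotype_em")
}

#' @export
print.haplotype_em <- function(x, ...) {
  cat("haplotype_em over", paste(x$snps, collapse = ", "),
      sprintf("(n = %d, %d iterations%s)\n", x$n, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  ord <- order(x$frequencies, decreasing = TRUE)
  for (i in ord) {
    if (x$frequencies[i] < 1e-6) next
    cat(sprintf("  %s  %.4f\n", x$labels[i], x$frequencies[i]))
  }
  invisible(x)
}

#' Haplotype odds ratios by GLM on expected dosages
#'
#' Logistic regression of case status on the posterior-expected haplotype
#' copy counts from [haplotype_em()], omitting the most frequent haplotype
#' as the reference (its log-OR is 0 by construction). Haplotypes with
#' estimated frequency below `freq_floor` are dropped from the design and
#' reported unestimable.
#'
#' @param em a [haplotype_em()] fit.
#' @param cohort the [study_cohort()] the EM was run on.
#' @param covariates covariate column names.
#' @param freq_floor minimum haplotype frequency entering the design
#'   (default 1e-4).
#' @return object of class `haplotype_model`: data frame with `haplotype`,
#'   `frequency`, `log_or`, `se`, `p`, `reference`, `estimable`.
#' @export
haplotype_glm <- function(em, cohort, covariates = character(0),
                          freq_floor = 1e-4) {
  stopifnot(inherits(em, "haplotype_em"), inherits(cohort, "study_cohort"))
  ref <- which.max(em$frequencies)
  usable <- em$frequencies >= freq_floor
  design_cols <- setdiff(which(usable), ref)
  ids <- rownames(em$expected_dosage)
  i <- match(ids, cohort$genotypes$samples)
  dat <- data.frame(y = cohort$phenotypes$status[i])
  hn <- character(0)
  if (length(design_cols)) {
    hn <- paste0("hap", design_cols)
    dat[hn] <- em$expected_dosage[, design_cols, drop = FALSE]
  }
  cv <- cohort_covariates(cohort, covariates)
  if (ncol(cv)) dat <- cbind(dat, cv[i, , drop = FALSE])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (ncol(dat) == 1) {  # every non-reference haplotype below the floor
    fit <- stats::glm(y ~ 1, family = stats::binomial(), data = dat)
  } else {
    fit <- stats::glm(y ~ ., family = stats::binomial(), data = dat)
  }
  cf <- summary(fit)$coefficients
  out <- data.frame(haplotype = em$labels, frequency = as.numeric(em$frequencies),
                    log_or = NA_real_, se = NA_real_, p = NA_real_,
                    reference = seq_along(em$labels) == ref,
                    estimable = usable)
  out$log_or[ref] <- 0
  for (k in seq_along(design_cols)) {
    if (hn[k] %in% rownames(cf)) {
      r <- design_cols[k]
      out$log_or[r] <- cf[hn[k], 1]
      out$se[r] <- cf[hn[k], 2]
      out$p[r] <- cf[hn[k], 4]
    } else {
      out$estimable[design_cols[k]] <- FALSE
    }
  }
  attr(out, "fit") <- fit
  class(out) <- c("haplotype_model", "data.frame")
  out
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat("Haplotype odds ratios (reference = most frequent haplotype)\n")
  show <- as.data.frame(x)
  show$or <- exp(show$log_or)
  show <- show[order(-show$frequency),
               c("haplotype", "frequency", "or", "se", "p", "reference")]
  show$frequency <- round(show$frequency, 4)
  show$or <- round(show$or, 3)
  show$se <- round(show$se, 3)
  show$p <- signif(show$p, 3)
  print(show, row.names = FALSE)
  invisible(x)
}
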