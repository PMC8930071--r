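#' Two-locus linkage disequilibrium from unphased genotypes
#'
#' Haplotype frequencies for the four two-locus gametes are estimated by an
#' EM algorithm under Hardy-Weinberg equilibrium (only the double
#' heterozygote is phase-ambiguous); r-squared and D' are computed from the
#' estimated frequencies. Dosages are rounded to hard calls and samples
#' missing at either SNP are excluded.
#'
#' @param snp_a,snp_b numeric dosage vectors over the same samples.
#' @param tol convergence tolerance on haplotype-frequency change.
#' @param max_iter maximum EM iterations.
#' @return object of class `ld_stats`: list with `r_squared`, `d_prime`,
#'   `hap_freq` (named `00,01,10,11`), `n`, `loglik`, `monomorphic`. For a
#'   monomorphic SNP the LD measures are `NA` and `monomorphic` is `TRUE`.
#' @examples
#' a <- c(0, 1, 2, 1, 0, 2)
#' compute_ld(a, a)$r_squared  # 1
#' @export
compute_ld <- function(snp_a, snp_b, tol = 1e-10, max_iter = 1000) {
  if (length(snp_a) != length(snp_b)) stop("SNP vectors must cover the same samples")
  ok <- !is.na(snp_a) & !is.na(snp_b)
  ga <- hard_calls(snp_a[ok])
  gb <- hard_calls(snp_b[ok])
  n <- length(ga)
  out <- structure(list(r_squared = NA_real_, d_prime = NA_real_,
                        hap_freq = stats::setNames(rep(NA_real_, 4),
                                                   c("00", "01", "10", "11")),
                        n = n, loglik = NA_real_, monomorphic = FALSE),
                   class = "ld_stats")
  if (n == 0) { out$monomorphic <- TRUE; return(out) }
  pa <- mean(ga) / 2
  pb <- mean(gb) / 2
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) {
    out$monomorphic <- TRUE
    return(out)
  }
  tab <- table(factor(ga, 0:2), factor(gb, 0:2))
  em <- em_two_locus(tab, tol = tol, max_iter = max_iter)
  p <- em$p  # c(p00, p01, p10, p11); first index = allele at A (1 = minor)
  pA <- p["10"] + p["11"]
  pB <- p["01"] + p["11"]
  D <- p["11"] - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) unname(D^2 / denom) else NA_real_
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (dmax > 0) unname(abs(D) / dmax) else NA_real_
  out$r_squared <- min(r2, 1)
  out$d_prime <- min(dp, 1)
  out$hap_freq <- p
  out$loglik <- em$loglik
  out
}

#' @export
print.ld_stats <- function(x, ...) {
  if (x$monomorphic) {
    cat("ld_stats: undefined (monomorphic SNP), n =", x$n, "\n")
  } else {
    cat(sprintf("ld_stats: r2 = %.4g, D' = %.4g (n = %d)\n",
                x$r_squared, x$d_prime, x$n))
  }
  invisible(x)
}

# EM over the 3x3 genotype table; haplotypes coded 00, 01, 10, 11 where the
# first digit is the minor-allele indicator at locus A. Under HWE only the
# (1,1) double-heterozygote cell mixes two diplotypes.
em_two_locus <- function(tab, tol = 1e-10, max_iter = 1000) {
  n <- sum(tab)
  # fixed haplotype contributions from unambiguous genotypes:
  # genotype (ga, gb) contributes gametes (a1,b1),(a2,b2)
  counts <- c("00" = 0, "01" = 0, "10" = 0, "11" = 0)
  for (ga in 0:2) for (gb in 0:2) {
    nc <- tab[ga + 1, gb + 1]
    if (nc == 0 || (ga == 1 && gb == 1)) next
    a <- c(ga >= 1, ga == 2)  # two gametes' allele at A
    b <- c(gb >= 1, gb == 2)
    if (ga == 1) a <- c(TRUE, FALSE)
    if (gb == 1) b <- c(TRUE, FALSE)
    # when exactly one locus is het the pairing is forced up to exchange
    for (k in 1:2) {
      key <- paste0(as.integer(a[k]), as.integer(b[k]))
      counts[key] <- counts[key] + nc
    }
  }
  ndh <- tab[2, 2]  # double heterozygotes: (11,00) or (10,01)
  pa <- unname(counts["10"] + counts["11"] + ndh) / (2 * n)
  pb <- unname(counts["01"] + counts["11"] + ndh) / (2 * n)
  p <- c("00" = (1 - pa) * (1 - pb), "01" = (1 - pa) * pb,
         "10" = pa * (1 - pb), "11" = pa * pb)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    w_cis <- p["11"] * p["00"]
    w_trans <- p["10"] * p["01"]
    tot <- w_cis + w_trans
    f_cis <- if (tot > 0) unname(w_cis / tot) else 0.5
    new <- counts
    new["11"] <- new["11"] + ndh * f_cis
    new["00"] <- new["00"] + ndh * f_cis
    new["10"] <- new["10"] + ndh * (1 - f_cis)
    new["01"] <- new["01"] + ndh * (1 - f_cis)
    p_new <- new / (2 * n)
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
    ll_old <- ll_old  # loglik tracked after loop
  }
  ll <- em_two_locus_loglik(tab, p)
  list(p = p, loglik = ll, iterations = it)
}

em_two_locus_loglik <- function(tab, p) {
  ll <- 0
  for (ga in 0:2) for (gb in 0:2) {
    nc <- tab[ga + 1, gb + 1]
    if (nc == 0) next
    pr <- genotype_prob_two_locus(ga, gb, p)
    ll <- ll + nc * log(pr)
  }
  ll
}

# P(genotype | haplotype freqs) under HWE
genotype_prob_two_locus <- function(ga, gb, p) {
  haps <- rbind("00" = c(0, 0), "01" = c(0, 1), "10" = c(1, 0), "11" = c(1, 1))
  pr <- 0
  for (i in 1:4) for (j in i:4) {
    if (haps[i, 1] + haps[j, 1] == ga && haps[i, 2] + haps[j, 2] == gb) {
      pr <- pr + (if (i == j) p[i] * p[j] else 2 * p[i] * p[j])
    }
  }
  unname(pr)
}

#' Pairwise r-squared between two variants of a genotype matrix
#' @param gm a [genotype_matrix()].
#' @param id_a,id_b variant ids.
#' @return numeric r-squared (or `NA` if undefined).
#' @export
ld_r2 <- function(gm, id_a, id_b) {
  compute_ld(dosage_of(gm, id_a), dosage_of(gm, id_b))$r_squared
}

#' Greedy LD pruning
#'
#' Walks variants left to right in position order (within each chromosome,
#' or within each supplied region) and keeps a variant unless its r-squared
#' with any already-kept variant of the same group exceeds the threshold.
#' Deterministic given input order. Monomorphic variants have undefined LD
#' and are always kept.
#'
#' @param gm a [genotype_matrix()].
#' @param r2_threshold prune when pairwise r-squared exceeds this (default 0.5).
#' @param regions optional region data frame (`chrom`, `start`, `end`); when
#'   given, pruning is confined to each region and variants outside all
#'   regions are dropped.
#' @return character vector of retained variant ids.
#' @export
ld_prune <- function(gm, r2_threshold = 0.5, regions = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  if (nrow(v) == 0) return(character(0))
  groups <- if (is.null(regions)) {
    split(seq_len(nrow(v)), v$chrom)
  } else {
    lapply(seq_len(nrow(regions)), function(r) {
      which(v$chrom == regions$chrom[r] &
              v$pos >= regions$start[r] & v$pos <= regions$end[r])
    })
  }
  kept <- character(0)
  for (idx in groups) {
    idx <- idx[order(v$pos[idx])]
    kept_here <- integer(0)
    for (j in idx) {
      drop <- FALSE
      for (k in kept_here) {
        r2 <- compute_ld(gm$dosages[, k], gm$dosages[, j])$r_squared
        if (!is.na(r2) && r2 > r2_threshold) { drop <- TRUE; break }
      }
      if (!drop) kept_here <- c(kept_here, j)
    }
    kept <- c(kept, v$id[kept_here])
  }
  unique(kept)
}
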