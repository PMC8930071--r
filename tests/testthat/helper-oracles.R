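# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths.

# logistic regression by hand-written IRLS (reference for glm-backed stages)
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- lm.wfit(X, z, w)
    new <- fit$coefficients
    if (max(abs(new - beta)) < tol) { beta <- new; break }
    beta <- new
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  W <- diag(as.vector(mu * (1 - mu)))
  cov <- solve(t(X) %*% W %*% X)
  list(beta = beta, se = sqrt(diag(cov)),
       deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

# multinomial log-likelihood of a 3x3 genotype table given 2-locus haplotype
# frequencies p = c(p00, p01, p10, p11) under HWE
two_locus_loglik <- function(tab, p) {
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  ll <- 0
  for (ga in 0:2) for (gb in 0:2) {
    nc <- tab[ga + 1, gb + 1]
    if (nc == 0) next
    pr <- 0
    for (i in 1:4) for (j in i:4) {
      if (haps[i, 1] + haps[j, 1] == ga && haps[i, 2] + haps[j, 2] == gb) {
        pr <- pr + if (i == j) p[i]^2 else 2 * p[i] * p[j]
      }
    }
    if (pr <= 0) return(-Inf)
    ll <- ll + nc * log(pr)
  }
  ll
}

# brute-force nested-grid maximization of the two-locus multinomial
# likelihood over (pA, pB, p11); refines three times around the optimum
grid_two_locus <- function(ga, gb) {
  tab <- table(factor(ga, 0:2), factor(gb, 0:2))
  eval_p <- function(pa, pb, p11) {
    p <- c(1 - pa - pb + p11, pb - p11, pa - p11, p11)
    if (any(p < -1e-12)) return(-Inf)
    two_locus_loglik(tab, pmax(p, 0))
  }
  lo <- c(0.01, 0.01, 0); hi <- c(0.99, 0.99, 1)
  best <- c(0.5, 0.5, 0.25)
  width <- c(0.5, 0.5, 0.5)
  for (stage in 1:5) {
    pa_g <- seq(max(1e-4, best[1] - width[1]), min(1 - 1e-4, best[1] + width[1]),
                length.out = 21)
    pb_g <- seq(max(1e-4, best[2] - width[2]), min(1 - 1e-4, best[2] + width[2]),
                length.out = 21)
    bestll <- -Inf
    for (pa in pa_g) for (pb in pb_g) {
      p11_g <- seq(max(0, best[3] - width[3]), min(min(pa, pb), best[3] + width[3]),
                   length.out = 21)
      for (p11 in p11_g) {
        ll <- eval_p(pa, pb, p11)
        if (ll > bestll) { bestll <- ll; cand <- c(pa, pb, p11) }
      }
    }
    best <- cand
    width <- width / 8
  }
  p <- c(1 - best[1] - best[2] + best[3], best[2] - best[3],
         best[1] - best[3], best[3])
  names(p) <- c("00", "01", "10", "11")
  list(p = pmax(p, 0), loglik = bestll)
}

# small fixed cohort builder for regression-oracle tests
toy_cohort <- function(n = 40, seed = 99, m = 3) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, 0.4), n, m)
  gm <- genotype_matrix(d, data.frame(id = paste0("v", seq_len(m)),
                                      chrom = "1", pos = (1:m) * 1000))
  y <- rbinom(n, 1, 0.5)
  study_cohort(gm, data.frame(sample_id = gm$samples, status = y), name = "toy")
}
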