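#' Haplotype pool with independent LD blocks
#'
#' The generator specifies linkage disequilibrium directly through a pool of
#' haplotypes: a list of blocks, each holding a haplotype-by-variant allele
#' matrix (0/1, 1 = minor allele) with frequencies on the simplex. Variants
#' in different blocks are inherited independently; within a block, LD is
#' whatever the haplotype table implies. Diploid individuals are formed by
#' drawing two haplotypes per block under random mating.
#'
#' @param blocks list of blocks; each block is a list with `haps` (matrix of
#'   0/1 alleles, one column per variant), `freq` (haplotype frequencies
#'   summing to 1), `ids`, `chrom`, `pos` (per variant).
#' @return object of class `haplotype_pool`.
#' @export
haplotype_pool <- function(blocks) {
  for (b in blocks) {
    stopifnot(is.matrix(b$haps), length(b$freq) == nrow(b$haps),
              length(b$ids) == ncol(b$haps), length(b$pos) == ncol(b$haps))
    if (abs(sum(b$freq) - 1) > 1e-12) {
      stop("block haplotype frequencies must sum to 1 (tolerance 1e-12)")
    }
    if (any(b$freq < 0)) stop("haplotype frequencies must be non-negative")
    if (!all(b$haps %in% c(0, 1))) stop("haplotype alleles must be 0/1")
  }
  ids <- unlist(lapply(blocks, `[[`, "ids"))
  if (anyDuplicated(ids)) stop("variant ids must be unique across blocks")
  structure(list(blocks = blocks), class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  nv <- sum(vapply(x$blocks, function(b) ncol(b$haps), 1L))
  cat("haplotype_pool:", length(x$blocks), "block(s),", nv, "variants\n")
  mafs <- pool_maf(x)
  cat("  MAF range:", sprintf("%.4f - %.4f", min(mafs), max(mafs)), "\n")
  invisible(x)
}

#' Variant metadata of a pool
#' @param pool a [haplotype_pool()].
#' @return data frame with `id`, `chrom`, `pos`.
#' @export
pool_variants <- function(pool) {
  do.call(rbind, lapply(pool$blocks, function(b) {
    data.frame(id = b$ids, chrom = rep(b$chrom, length(b$ids)), pos = b$pos)
  }))
}

#' Population minor-allele frequencies implied by a pool
#' @param pool a [haplotype_pool()].
#' @return named numeric vector.
#' @export
pool_maf <- function(pool) {
  unlist(lapply(pool$blocks, function(b) {
    stats::setNames(as.numeric(crossprod(b$freq, b$haps)), b$ids)
  }))
}

# single-variant biallelic block (linkage equilibrium with everything else)
le_block <- function(id, maf, chrom, pos) {
  list(haps = matrix(c(0, 1), 2, 1, dimnames = list(NULL, id)),
       freq = c(1 - maf, maf), ids = id, chrom = chrom, pos = pos)
}

# split haplotype rows of a block to append a proxy variant: the proxy copies
# `target`'s allele except on a slice of the allele-1 mass of size `delta`
# (shifts the proxy MAF down by delta and sets r2 accordingly)
add_proxy <- function(block, target, proxy_id, proxy_pos, delta) {
  j <- match(target, block$ids)
  haps <- cbind(block$haps, proxy = block$haps[, j])
  freq <- block$freq
  carriers <- which(haps[, j] == 1)
  need <- delta
  for (i in carriers) {
    if (need <= 0) break
    take <- min(freq[i], need)
    if (take <= 0) next
    if (take < freq[i]) {
      haps <- rbind(haps, haps[i, ])
      haps[nrow(haps), ncol(haps)] <- 0
      freq <- c(freq, take)
      freq[i] <- freq[i] - take
    } else {
      haps[i, ncol(haps)] <- 0
    }
    need <- need - take
  }
  colnames(haps)[ncol(haps)] <- proxy_id
  list(haps = haps, freq = freq, ids = c(block$ids, proxy_id),
       chrom = block$chrom, pos = c(block$pos, proxy_pos))
}

#' Build the rare-variant tagging pool
#'
#' Constructs the haplotype structure behind the tagging confound: a rare
#' variant carried exclusively on the background haplotype defined by the
#' minor alleles of two common tag SNPs, so that the two-SNP genotype
#' product is informative for rare-allele carriage while each single tag SNP
#' is only weakly correlated with it. Defaults emulate an LPA-like locus: a
#' rare variant of MAF 0.015 riding a two-SNP background haplotype of
#' frequency 0.10 (conditional carriage probability 0.15), tag MAFs
#' 0.16 and 0.225, a near-perfect proxy of tag 1, and a few filler SNPs in
#' linkage equilibrium inside and outside the conditioning window.
#'
#' @param maf_rare rare-variant MAF in `(0, 0.05]`.
#' @param bg_freq frequency of the background (minor-minor) tag haplotype;
#'   must be at least `maf_rare` and at most each tag MAF.
#' @param tag_mafs length-2 MAFs of the two tag SNPs.
#' @param proxy_delta haplotype mass on which the tag-1 proxy mismatches
#'   tag 1 (0.0054 gives r-squared about 0.96); `NULL` drops the proxy.
#' @param n_filler number of filler SNPs in linkage equilibrium placed
#'   inside the locus window.
#' @param filler_maf MAF of filler SNPs.
#' @param distant_snp add one LE SNP far outside the +/-200 kb conditioning
#'   window (for window-sensitivity checks).
#' @param chrom,center chromosome label and centre position of the locus.
#' @return a [haplotype_pool()] whose first block holds, in order, `tag1`,
#'   `tag2`, `rare` (and `tag1_proxy` when requested).
#' @export
build_tagging_pool <- function(maf_rare = 0.015, bg_freq = 0.10,
                               tag_mafs = c(0.16, 0.225),
                               proxy_delta = 0.0054,
                               n_filler = 2, filler_maf = 0.25,
                               distant_snp = TRUE,
                               chrom = "6", center = 160960000) {
  if (maf_rare < 0 || maf_rare > 0.05) stop("maf_rare must lie in [0, 0.05]")
  if (bg_freq < maf_rare) {
    stop("infeasible: background haplotype frequency (", bg_freq,
         ") is below maf_rare (", maf_rare, ")")
  }
  if (any(tag_mafs < bg_freq)) {
    stop("infeasible: each tag MAF must be at least bg_freq")
  }
  # combos over (tag1, tag2): 11 is the background pattern
  f11 <- bg_freq
  f10 <- tag_mafs[1] - bg_freq
  f01 <- tag_mafs[2] - bg_freq
  f00 <- 1 - f11 - f10 - f01
  if (f00 < 0) stop("infeasible tag haplotype frequencies")
  haps <- rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))
  freq <- c(f00, f01, f10, f11 - maf_rare, maf_rare)
  keep <- freq > 0
  haps <- haps[keep, , drop = FALSE]
  freq <- freq[keep]
  block <- list(haps = haps, freq = freq,
                ids = c("tag1", "tag2", "rare"),
                chrom = chrom, pos = center + c(-40000L, 35000L, 0L))
  if (!is.null(proxy_delta)) {
    block <- add_proxy(block, "tag1", "tag1_proxy", center - 45000L, proxy_delta)
  }
  blocks <- list(block)
  if (n_filler > 0) {
    for (f in seq_len(n_filler)) {
      blocks[[length(blocks) + 1]] <-
        le_block(paste0("filler", f), filler_maf, chrom,
                 center - 150000L + as.integer(90000 * f))
    }
  }
  if (distant_snp) {
    blocks[[length(blocks) + 1]] <- le_block("distant1", 0.3, chrom, center + 5000000L)
  }
  haplotype_pool(blocks)
}

# pool of independent common SNPs (used by the interaction and null scenarios)
le_pool <- function(mafs, chrom = "6", start = 160800000, spacing = 60000) {
  blocks <- lapply(seq_along(mafs), function(j) {
    le_block(names(mafs)[j] %||% paste0("snp", j), mafs[j], chrom,
             as.integer(start + (j - 1) * spacing))
  })
  haplotype_pool(blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Disease risk model for the generator
#'
#' Case status is drawn as Bernoulli(plogis(eta)) with
#' `eta = intercept + sum additive + sum interaction + sum haplotype` terms:
#' additive terms act on minor-allele dosage, interaction terms on the
#' product of the two encoded genotypes, haplotype terms on the number of
#' carried copies of a given allele pattern.
#'
#' @param intercept baseline log-odds of disease (default `qlogis(0.1)`,
#'   a 10% population prevalence).
#' @param additive named numeric vector of per-allele log-ORs by variant id.
#' @param interactions data frame with `snp1`, `snp2`, `beta`, optional
#'   `enc1`, `enc2` encodings (default dosage) and optional `centered`
#'   (default TRUE): when centered, the product uses encodings centered at
#'   their population means, which leaves every single-SNP marginal
#'   association exactly null — the signature of a pure epistatic pair.
#' @param haplotype optional list with `ids` (variant ids), `pattern`
#'   (0/1 alleles) and `beta` (log-OR per haplotype copy).
#' @return object of class `disease_model`.
#' @export
disease_model <- function(intercept = stats::qlogis(0.1), additive = NULL,
                          interactions = NULL, haplotype = NULL) {
  if (!is.null(interactions)) {
    interactions <- as.data.frame(interactions)
    if (is.null(interactions$enc1)) interactions$enc1 <- "dosage"
    if (is.null(interactions$enc2)) interactions$enc2 <- "dosage"
    if (is.null(interactions$centered)) interactions$centered <- TRUE
  }
  eff <- c(intercept, additive,
           if (!is.null(interactions)) interactions$beta,
           if (!is.null(haplotype)) haplotype$beta)
  if (any(!is.finite(eff))) stop("all disease-model effects must be finite")
  structure(list(intercept = intercept, additive = additive,
                 interactions = interactions, haplotype = haplotype),
            class = "disease_model")
}

# population mean of an encoded genotype under HWE at minor-allele freq p
encoding_mean <- function(p, enc) {
  switch(enc,
         dosage = 2 * p,
         dominant = 1 - (1 - p)^2,
         recessive = p^2,
         heterozygous = 2 * p * (1 - p))
}

# linear predictor given drawn haplotypes (list h1, h2 of allele matrices);
# `mafs` (pool MAFs by id) is needed only for centered interaction terms
linear_predictor <- function(model, geno, h1, h2, ids, mafs = NULL) {
  eta <- rep(model$intercept, nrow(geno))
  if (!is.null(model$additive)) {
    for (id in names(model$additive)) {
      j <- match(id, ids)
      eta <- eta + model$additive[[id]] * geno[, j]
    }
  }
  if (!is.null(model$interactions)) {
    for (r in seq_len(nrow(model$interactions))) {
      j1 <- match(model$interactions$snp1[r], ids)
      j2 <- match(model$interactions$snp2[r], ids)
      e1 <- encode_genotype(geno[, j1], model$interactions$enc1[r])
      e2 <- encode_genotype(geno[, j2], model$interactions$enc2[r])
      if (isTRUE(model$interactions$centered[r])) {
        if (is.null(mafs)) stop("centered interactions need pool MAFs")
        e1 <- e1 - encoding_mean(mafs[[model$interactions$snp1[r]]],
                                 model$interactions$enc1[r])
        e2 <- e2 - encoding_mean(mafs[[model$interactions$snp2[r]]],
                                 model$interactions$enc2[r])
      }
      eta <- eta + model$interactions$beta[r] * e1 * e2
    }
  }
  if (!is.null(model$haplotype)) {
    j <- match(model$haplotype$ids, ids)
    pat <- model$haplotype$pattern
    cnt <- (rowSums(h1[, j, drop = FALSE] == rep(pat, each = nrow(h1))) == length(j)) +
      (rowSums(h2[, j, drop = FALSE] == rep(pat, each = nrow(h2))) == length(j))
    eta <- eta + model$haplotype$beta * cnt
  }
  eta
}

#' Simulation configuration
#'
#' Bundles pool, disease model, study layout and seed. `seed` fully
#' determines the output; each study uses the derived stream
#' `seed + study_index`.
#'
#' @param pool a [haplotype_pool()].
#' @param model a [disease_model()].
#' @param n_studies number of case-control studies.
#' @param n_cases,n_controls per-study counts.
#' @param seed master integer seed.
#' @param trait optional trait-model parameter list (see [simulate_traits()]).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(pool, model, n_studies = 3,
                              n_cases = 1000, n_controls = 1000,
                              seed = 1, trait = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(model, "disease_model"),
            n_studies >= 1, n_cases > 0, n_controls > 0)
  structure(list(pool = pool, model = model, n_studies = n_studies,
                 n_cases = n_cases, n_controls = n_controls,
                 seed = as.integer(seed), trait = trait),
            class = "simulation_config")
}

# draw n diploid individuals from the pool; returns genotype matrix and the
# two underlying haplotype allele matrices
draw_individuals <- function(pool, n) {
  vt <- pool_variants(pool)
  h1 <- matrix(0L, n, nrow(vt))
  h2 <- matrix(0L, n, nrow(vt))
  col0 <- 0
  for (b in pool$blocks) {
    nb <- ncol(b$haps)
    i1 <- sample.int(nrow(b$haps), n, replace = TRUE, prob = b$freq)
    i2 <- sample.int(nrow(b$haps), n, replace = TRUE, prob = b$freq)
    h1[, col0 + seq_len(nb)] <- b$haps[i1, , drop = FALSE]
    h2[, col0 + seq_len(nb)] <- b$haps[i2, , drop = FALSE]
    col0 <- col0 + nb
  }
  list(geno = h1 + h2, h1 = h1, h2 = h2, ids = vt$id, variants = vt)
}

#' Simulate one case-control study
#'
#' Draws diploid genotypes from the haplotype pool, assigns disease status
#' by the logistic disease model, and ascertains the requested numbers of
#' cases and controls by rejection sampling. Deterministic under
#' `(seed, study_index)`.
#'
#' @param config a [simulation_config()].
#' @param study_index 1-based study number.
#' @param max_batches abort after this many rejection-sampling batches with
#'   unmet case or control counts (guards against unattainable models).
#' @return a [study_cohort()] named `study<index>`.
#' @export
simulate_study <- function(config, study_index = 1, max_batches = 200) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + study_index)
  n_cases <- config$n_cases
  n_controls <- config$n_controls
  batch <- 2L * (n_cases + n_controls)
  got_case <- list(); got_ctrl <- list()
  n_case_acc <- 0; n_ctrl_acc <- 0
  for (b in seq_len(max_batches)) {
    ind <- draw_individuals(config$pool, batch)
    eta <- linear_predictor(config$model, ind$geno, ind$h1, ind$h2, ind$ids,
                            mafs = pool_maf(config$pool))
    y <- stats::rbinom(batch, 1, stats::plogis(eta))
    if (n_case_acc < n_cases && any(y == 1)) {
      take <- utils::head(which(y == 1), n_cases - n_case_acc)
      got_case[[length(got_case) + 1]] <-
        list(geno = ind$geno[take, , drop = FALSE],
             h1 = ind$h1[take, , drop = FALSE], h2 = ind$h2[take, , drop = FALSE])
      n_case_acc <- n_case_acc + length(take)
    }
    if (n_ctrl_acc < n_controls && any(y == 0)) {
      take <- utils::head(which(y == 0), n_controls - n_ctrl_acc)
      got_ctrl[[length(got_ctrl) + 1]] <-
        list(geno = ind$geno[take, , drop = FALSE],
             h1 = ind$h1[take, , drop = FALSE], h2 = ind$h2[take, , drop = FALSE])
      n_ctrl_acc <- n_ctrl_acc + length(take)
    }
    if (n_case_acc >= n_cases && n_ctrl_acc >= n_controls) break
  }
  if (n_case_acc < n_cases || n_ctrl_acc < n_controls) {
    stop("case/control ascertainment failed after ", max_batches,
         " batches; the disease model makes the requested counts unattainable")
  }
  geno <- rbind(do.call(rbind, lapply(got_case, `[[`, "geno")),
                do.call(rbind, lapply(got_ctrl, `[[`, "geno")))
  h1 <- rbind(do.call(rbind, lapply(got_case, `[[`, "h1")),
              do.call(rbind, lapply(got_ctrl, `[[`, "h1")))
  h2 <- rbind(do.call(rbind, lapply(got_case, `[[`, "h2")),
              do.call(rbind, lapply(got_ctrl, `[[`, "h2")))
  status <- rep(c(1L, 0L), c(n_cases, n_controls))
  vt <- pool_variants(config$pool)
  vt$ref <- "A"; vt$alt <- "B"
  samples <- sprintf("s%d_%05d", study_index, seq_len(nrow(geno)))
  gm <- genotype_matrix(geno, vt, samples)
  ph <- data.frame(sample_id = samples, status = status)
  if (!is.null(config$trait)) {
    ph <- cbind(ph, simulate_traits(gm, config$trait, haplos = list(h1 = h1, h2 = h2)))
  }
  study_cohort(gm, ph, name = paste0("study", study_index))
}

#' Simulate a multi-study cohort collection
#'
#' @param config a [simulation_config()].
#' @return list of [study_cohort()] objects of length `config$n_studies`.
#' @export
simulate_cohorts <- function(config) {
  lapply(seq_len(config$n_studies), function(k) simulate_study(config, k))
}

#' Default parameters of the skewed-trait model
#'
#' The quantitative trait emulates serum Lp(a): a latent normal scale driven
#' by a trait SNP directly and through a KIV-repeat-like copy-number
#' covariate, exponentiated to produce the strong positive skew of raw
#' Lp(a) measurements. The covariate decreases with the rare-allele dosage
#' (slope -5.74 repeats per allele) and the latent trait decreases with the
#' covariate, so trait and covariate are negatively correlated.
#'
#' @param trait_snp id of the driving variant.
#' @param beta_direct direct genotype effect on the latent (inverse-normal)
#'   scale, per allele.
#' @param kiv_intercept,kiv_slope,kiv_sd covariate model: value =
#'   `kiv_intercept + kiv_slope * dosage + N(0, kiv_sd)`.
#' @param beta_kiv latent-trait slope per covariate unit (negative).
#' @param sd_latent residual SD of the latent trait.
#' @return parameter list for [simulate_traits()].
#' @export
trait_model <- function(trait_snp = "rare", beta_direct = 1.11,
                        kiv_intercept = 27, kiv_slope = -5.74, kiv_sd = 5,
                        beta_kiv = -0.085, sd_latent = 1) {
  list(trait_snp = trait_snp, beta_direct = beta_direct,
       kiv_intercept = kiv_intercept, kiv_slope = kiv_slope, kiv_sd = kiv_sd,
       beta_kiv = beta_kiv, sd_latent = sd_latent)
}

#' Simulate the Lp(a)-like trait and KIV-like covariate
#'
#' @param gm a [genotype_matrix()] holding the trait-driving variant.
#' @param trait parameter list from [trait_model()].
#' @param haplos unused hook for haplotype-driven trait models.
#' @return data frame with `lpa_raw` (skewed), `lpa_latent` and `kiv`.
#' @export
simulate_traits <- function(gm, trait = trait_model(), haplos = NULL) {
  d <- dosage_of(gm, trait$trait_snp)
  n <- length(d)
  kiv <- trait$kiv_intercept + trait$kiv_slope * d + stats::rnorm(n, 0, trait$kiv_sd)
  latent <- trait$beta_direct * d +
    trait$beta_kiv * (kiv - trait$kiv_intercept) +
    stats::rnorm(n, 0, trait$sd_latent)
  data.frame(lpa_raw = exp(latent), lpa_latent = latent, kiv = kiv)
}

#' Canned generative scenarios
#'
#' Four study designs exercised throughout the package, matching the locus
#' archetypes the scan must distinguish:
#' \describe{
#'   \item{interaction}{two common SNPs (MAF 0.3) in linkage equilibrium with
#'     a pure multiplicative dosage-by-dosage interaction (OR 1.4) and zero
#'     marginal effects.}
#'   \item{tagging}{the rare-variant confound from [build_tagging_pool()]:
#'     an additive rare variant (OR 2.0) carried on a two-SNP background
#'     haplotype, no true interaction.}
#'   \item{haplotype}{a three-SNP cis block where one haplotype carries
#'     log-OR log(2) per copy, no product interaction.}
#'   \item{cis_interaction}{the same cis block with a product interaction
#'     (OR 1.8) between its outer SNPs and no haplotype effect — the
#'     contrast case for haplotype-vs-interaction model comparison.}
#'   \item{null}{the interaction pool with all genetic effects zero.}
#' }
#'
#' @param scenario one of `"interaction"`, `"tagging"`, `"haplotype"`,
#'   `"cis_interaction"`, `"null"`.
#' @param seed master seed.
#' @param n_studies,n_cases,n_controls study layout (default 3 studies of
#'   2000 cases / 2000 controls, a desk-scale version of a multi-study
#'   case-control collection).
#' @param trait attach the Lp(a)-like trait model (tagging scenario only by
#'   default).
#' @return a [simulation_config()].
#' @export
scenario_config <- function(scenario = c("interaction", "tagging",
                                         "haplotype", "cis_interaction",
                                         "null"),
                            seed = 1, n_studies = 3,
                            n_cases = 2000, n_controls = 2000,
                            trait = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "interaction") {
    pool <- le_pool(c(snpA = 0.3, snpB = 0.3, filler1 = 0.25, filler2 = 0.25,
                      distant1 = 0.3))
    pool$blocks[[5]]$pos <- 165960000L
    model <- disease_model(interactions = data.frame(
      snp1 = "snpA", snp2 = "snpB", beta = log(1.4)))
  } else if (scenario == "tagging") {
    # concentrated tag: the background haplotype barely exceeds the rare
    # variant's frequency, so the two-SNP product carries about half the
    # rare additive effect (the efficiency seen at real tagged loci) while
    # each single tag SNP stays at r-squared < 0.2 with the rare variant;
    # the carrier count is scaled to the desk-size cohorts
    pool <- build_tagging_pool(maf_rare = 0.03, bg_freq = 0.04)
    model <- disease_model(additive = c(rare = log(2)))
    if (is.null(trait)) trait <- trait_model()
  } else if (scenario %in% c("haplotype", "cis_interaction")) {
    # three-SNP cis block with a decisive phase posterior: the cis/trans
    # odds for (h1, h3) double heterozygotes are ~9, so the expected
    # haplotype dosages are far from the genotype-product basis and
    # haplotype-driven and interaction-driven risk are distinguishable
    haps <- as.matrix(expand.grid(0:1, 0:1, 0:1))
    dimnames(haps) <- NULL
    freq <- c(0.42, 0.077, 0.18, 0.033, 0.077, 0.126, 0.033, 0.054)
    block <- list(haps = haps, freq = freq, ids = c("h1", "h2", "h3"),
                  chrom = "6", pos = c(160920000L, 160960000L, 160995000L))
    pool <- haplotype_pool(list(block,
                                le_block("filler1", 0.25, "6", 160870000L)))
    model <- if (scenario == "haplotype") {
      disease_model(haplotype = list(ids = c("h1", "h2", "h3"),
                                     pattern = c(1, 0, 1), beta = log(2)))
    } else {
      disease_model(interactions = data.frame(snp1 = "h1", snp2 = "h3",
                                              beta = log(1.8)))
    }
  } else {
    pool <- le_pool(c(snpA = 0.3, snpB = 0.3, filler1 = 0.25, filler2 = 0.25))
    model <- disease_model()
  }
  simulation_config(pool, model, n_studies = n_studies, n_cases = n_cases,
                    n_controls = n_controls, seed = seed, trait = trait)
}
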