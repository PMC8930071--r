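#' Construct a genotype matrix
#'
#' The central data container of the package: a sample-by-variant matrix of
#' minor-allele dosages in `[0, 2]` (`NA` = missing) together with per-variant
#' metadata. On construction every variant is re-oriented so that the counted
#' allele is the minor allele (sample MAF <= 0.5); flipped variants have their
#' `ref`/`alt` labels swapped and are recorded in the `flipped` column.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns; values
#'   in `[0, 2]` or `NA`.
#' @param variants data frame with one row per column of `dosages`; must carry
#'   `id`, and optionally `chrom`, `pos`, `ref`, `alt`. Missing columns are
#'   filled with placeholders.
#' @param samples character vector of unique sample ids; defaults to the
#'   rownames of `dosages` or `S1..Sn`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `variants` (including a `maf` column) and `samples`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0, 1, 2, 2, 2, 1), nrow = 3),
#'                       variants = data.frame(id = c("a", "b")))
#' maf(gm)
#' @export
genotype_matrix <- function(dosages, variants = NULL, samples = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  bad <- !is.na(dosages) & (dosages < 0 | dosages > 2)
  if (any(bad)) {
    stop("dosages must lie in [0, 2] or be NA; ", sum(bad), " value(s) outside")
  }
  m <- ncol(dosages)
  if (is.null(variants)) {
    variants <- data.frame(id = paste0("v", seq_len(m)))
  }
  variants <- as.data.frame(variants)
  if (nrow(variants) != m) stop("variants must have one row per dosage column")
  if (is.null(variants$id)) stop("variants must carry an 'id' column")
  variants$id <- as.character(variants$id)
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (is.null(variants$chrom)) variants$chrom <- "1"
  variants$chrom <- as.character(variants$chrom)
  if (is.null(variants$pos)) variants$pos <- seq_len(m)
  if (any(variants$pos < 1)) stop("positions are 1-based and must be >= 1")
  if (is.null(variants$ref)) variants$ref <- "A"
  if (is.null(variants$alt)) variants$alt <- "B"
  if (is.null(samples)) {
    samples <- rownames(dosages)
    if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  }
  samples <- as.character(samples)
  if (length(samples) != nrow(dosages)) stop("samples must match dosage rows")
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  dimnames(dosages) <- list(samples, variants$id)

  # orient to the minor allele
  freq <- colMeans(dosages, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- NA_real_
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    dosages[, flip] <- 2 - dosages[, flip]
    tmp <- variants$ref[flip]
    variants$ref[flip] <- variants$alt[flip]
    variants$alt[flip] <- tmp
    freq[flip] <- 1 - freq[flip]
  }
  variants$flipped <- flip
  variants$maf <- freq
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Minor allele frequencies
#'
#' @param gm a [genotype_matrix()].
#' @return named numeric vector of per-variant MAF (always <= 0.5).
#' @export
maf <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  stats::setNames(gm$variants$maf, gm$variants$id)
}

#' Extract a dosage vector for one variant
#' @param gm a [genotype_matrix()].
#' @param id variant id.
#' @return numeric dosage vector named by sample.
#' @export
dosage_of <- function(gm, id) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- match(id, gm$variants$id)
  if (is.na(j)) stop("unknown variant id: ", id)
  gm$dosages[, j]
}

#' Subset a genotype matrix by variant ids and/or samples
#' @param gm a [genotype_matrix()].
#' @param ids variant ids to keep (default all).
#' @param samples sample ids to keep (default all).
#' @return a new `genotype_matrix` (MAF re-oriented on the subset).
#' @export
subset_variants <- function(gm, ids = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(ids)) ids <- gm$variants$id
  j <- match(ids, gm$variants$id)
  if (anyNA(j)) stop("unknown variant id(s): ", paste(ids[is.na(j)], collapse = ", "))
  i <- seq_along(gm$samples)
  if (!is.null(samples)) {
    i <- match(samples, gm$samples)
    if (anyNA(i)) stop("unknown sample id(s)")
  }
  v <- gm$variants[j, c("id", "chrom", "pos", "ref", "alt"), drop = FALSE]
  genotype_matrix(gm$dosages[i, j, drop = FALSE], v, gm$samples[i])
}

#' Round dosages to hard genotype calls
#'
#' Non-integer dosages are rounded to the nearest integer in `{0, 1, 2}`;
#' ties at .5 round half-up (so 0.5 -> 1, 1.5 -> 2). Missing stays missing.
#'
#' @param d numeric dosage vector in `[0, 2]`.
#' @return integer-valued numeric vector.
#' @export
hard_calls <- function(d) {
  if (any(!is.na(d) & (d < 0 | d > 2))) stop("dosages must lie in [0, 2]")
  pmin(floor(d + 0.5), 2)
}

#' Encode genotypes under a genetic model
#'
#' The four single-SNP encodings used throughout the screen, all with respect
#' to the minor allele: `dosage` (identity), `dominant` (>= 1 minor allele),
#' `recessive` (2 minor alleles) and `heterozygous` (exactly 1). Indicator
#' encodings are computed on hard calls ([hard_calls()]); `dosage` keeps
#' fractional values untouched.
#'
#' @param d numeric dosage vector in `[0, 2]`, oriented to the minor allele.
#' @param model one of `"dosage"`, `"dominant"`, `"recessive"`,
#'   `"heterozygous"`.
#' @return numeric vector, same length as `d`; `NA` propagates.
#' @examples
#' encode_genotype(c(0, 1, 2), "dominant")      # 0 1 1
#' encode_genotype(c(0, 1, 2), "heterozygous")  # 0 1 0
#' encode_genotype(1.37, "recessive")           # 0
#' @export
encode_genotype <- function(d, model = genetic_encodings()) {
  model <- match.arg(model)
  if (any(!is.na(d) & (d < 0 | d > 2))) stop("dosages must lie in [0, 2]")
  if (model == "dosage") return(as.numeric(d))
  g <- hard_calls(d)
  switch(model,
         dominant     = as.numeric(g >= 1),
         recessive    = as.numeric(g == 2),
         heterozygous = as.numeric(g == 1))
}

#' The four genetic encodings
#' @return character vector of the encoding names, in canonical order.
#' @export
genetic_encodings <- function() {
  c("dosage", "dominant", "recessive", "heterozygous")
}

#' Mean-impute missing dosages per variant
#'
#' Regression stages replace missing dosages by the per-variant mean, keeping
#' sample counts constant across pairs. Variants that are entirely missing
#' are imputed to 0.
#'
#' @param gm a [genotype_matrix()].
#' @return a `genotype_matrix` without missing values.
#' @export
impute_mean <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
    gm$dosages <- d
  }
  gm
}
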