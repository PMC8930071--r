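#' Define susceptibility regions around lead SNPs
#'
#' Each region spans `[max(1, pos - window), pos + window]`, 1-based
#' inclusive, on the lead SNP's chromosome. Lead SNPs absent from the
#' genotype matrix are skipped with a warning.
#'
#' @param lead_snps character vector of lead variant ids (looked up in `gm`),
#'   or a data frame with `id`, `chrom`, `pos`.
#' @param gm a [genotype_matrix()] used to resolve ids (ignored when
#'   `lead_snps` is a data frame).
#' @param window half-width in base pairs (default 500 kb).
#' @return data frame with `chrom`, `start`, `end`, `lead_snp`.
#' @export
define_regions <- function(lead_snps, gm = NULL, window = 500000L) {
  if (is.data.frame(lead_snps)) {
    leads <- lead_snps
  } else {
    stopifnot(inherits(gm, "genotype_matrix"))
    j <- match(lead_snps, gm$variants$id)
    if (anyNA(j)) {
      warning("lead SNP(s) absent from genotype matrix, region(s) skipped: ",
              paste(lead_snps[is.na(j)], collapse = ", "))
      j <- j[!is.na(j)]
    }
    leads <- gm$variants[j, c("id", "chrom", "pos")]
  }
  if (nrow(leads) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), lead_snp = character(0)))
  }
  data.frame(chrom = as.character(leads$chrom),
             start = pmax(1, leads$pos - window),
             end = leads$pos + window,
             lead_snp = as.character(leads$id))
}

#' Select the variants falling in a set of regions
#'
#' A variant covered by more than one region appears once (deduplicated
#' union), in genotype-matrix column order.
#'
#' @param gm a [genotype_matrix()].
#' @param regions region data frame as from [define_regions()].
#' @return character vector of variant ids.
#' @export
select_region_snps <- function(gm, regions) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  hit <- rep(FALSE, nrow(v))
  for (r in seq_len(nrow(regions))) {
    hit <- hit | (v$chrom == regions$chrom[r] &
                    v$pos >= regions$start[r] & v$pos <= regions$end[r])
  }
  v$id[hit]
}

#' Ancestry coordinates by classical MDS of the genetic relationship matrix
#'
#' Computes the pairwise allele-sharing distance 1 - IBS, where IBS between
#' two samples is `1 - mean(|d_i - d_j|) / 2` over variants (missing dosages
#' mean-imputed per variant), then extracts the first `k` classical
#' (metric) MDS components. Components are ordered by decreasing eigenvalue
#' and centered; the sign of each axis is fixed by making its
#' largest-magnitude loading positive.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components (default 10); must be < number of samples.
#' @return data frame with `sample_id` and columns `MDS1..MDSk`.
#' @export
compute_mds <- function(gm, k = 10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- length(gm$samples)
  if (k >= n) stop("k must be smaller than the number of samples")
  d <- impute_mean(gm)$dosages
  m <- ncol(d)
  dist_ibs <- stats::dist(d, method = "manhattan") / (2 * m)
  # degenerate inputs (fewer positive eigenvalues than k) are padded below
  fit <- suppressWarnings(stats::cmdscale(dist_ibs, k = k, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate (e.g. all-identical samples): pad zeros
    pts <- cbind(pts, matrix(0, n, k - ncol(pts)))
  }
  pts <- sweep(pts, 2, colMeans(pts))
  for (j in seq_len(k)) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  out <- data.frame(sample_id = gm$samples, pts)
  names(out) <- c("sample_id", paste0("MDS", seq_len(k)))
  rownames(out) <- NULL
  out
}
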