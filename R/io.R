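#' Read a dosage table
#'
#' Plain-text genotype exchange format: a TSV with a `sample_id` column and
#' one column per variant (header = variant id), values in `[0, 2]` or `NA`.
#' Variant metadata (chromosome, position, alleles) can be supplied through
#' `variants`; otherwise placeholder coordinates are used.
#'
#' @param path file path.
#' @param variants optional data frame with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @return a [genotype_matrix()].
#' @export
read_dosage_tsv <- function(path, variants = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("dosage TSV must have a sample_id column")
  ids <- as.character(tab$sample_id)
  d <- as.matrix(tab[setdiff(names(tab), "sample_id")])
  if (!is.null(variants)) {
    variants <- variants[match(colnames(d), variants$id), , drop = FALSE]
  } else {
    variants <- data.frame(id = colnames(d))
  }
  genotype_matrix(d, variants, ids)
}

#' Write a dosage table
#' @param gm a [genotype_matrix()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tab <- data.frame(sample_id = gm$samples, gm$dosages, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Uses the `GT` field for hard calls and, when present and requested, a
#' dosage `FORMAT` field (typically `DS`). Multi-allelic records are rejected:
#' split them upstream. Alleles are counted on the ALT allele and then
#' re-oriented to the minor allele by [genotype_matrix()].
#'
#' @param path VCF file (plain or bgzipped).
#' @param dosage_field optional FORMAT key holding dosages (e.g. `"DS"`);
#'   when `NULL` (default) hard calls from `GT` are used.
#' @return a [genotype_matrix()].
#' @export
read_vcf_genotypes <- function(path, dosage_field = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic sites are not supported; split them before loading")
  }
  ids <- fix$ID
  nameless <- is.na(ids) | ids == "."
  ids[nameless] <- paste0(fix$CHROM[nameless], ":", fix$POS[nameless])
  if (!is.null(dosage_field)) {
    ds <- vcfR::extract.gt(v, element = dosage_field, as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_real_)
      sum(alleles != "0")
    })
  }
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT)
  genotype_matrix(t(ds), variants, colnames(ds))
}

#' Read a phenotype table
#'
#' TSV with `sample_id`, a binary `status` column (case = 1, control = 0) and
#' free additional trait/covariate columns.
#'
#' @param path file path.
#' @return data frame with unique `sample_id`.
#' @export
read_phenotype_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(tab))) {
    stop("phenotype TSV must have sample_id and status columns")
  }
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample_id in phenotype table")
  if (!all(tab$status %in% c(0, 1, NA))) stop("status must be 0/1")
  tab
}

#' Read a region table
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `lead_snp`
#' (1-based inclusive coordinates, unlike BED proper).
#'
#' @param path file path.
#' @return data frame of regions.
#' @export
read_regions_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "lead_snp")
  if (!all(need %in% names(tab))) {
    stop("region TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$start > tab$end)) stop("region start must be <= end")
  tab$chrom <- as.character(tab$chrom)
  tab
}

#' Bundle genotypes, phenotypes and optional MDS coordinates into a study
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes data frame with `sample_id`, `status` and optional trait
#'   and covariate columns; must cover all genotyped samples.
#' @param mds optional data frame of MDS coordinates (from [compute_mds()]).
#' @param name study label.
#' @return object of class `study_cohort`.
#' @export
study_cohort <- function(genotypes, phenotypes, mds = NULL, name = "study") {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  phenotypes <- as.data.frame(phenotypes)
  i <- match(genotypes$samples, phenotypes$sample_id)
  if (anyNA(i)) stop("phenotypes missing for some genotyped samples")
  phenotypes <- phenotypes[i, , drop = FALSE]
  if (!all(phenotypes$status %in% c(0, 1, NA))) stop("status must be 0/1")
  if (!is.null(mds)) {
    mds <- as.data.frame(mds)
    j <- match(genotypes$samples, mds$sample_id)
    if (anyNA(j)) stop("MDS coordinates missing for some samples")
    mds <- mds[j, , drop = FALSE]
  }
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 mds = mds, name = name),
            class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  st <- x$phenotypes$status
  cat(sprintf("study_cohort '%s': %d samples (%d cases / %d controls), %d variants\n",
              x$name, length(x$genotypes$samples),
              sum(st == 1, na.rm = TRUE), sum(st == 0, na.rm = TRUE),
              nrow(x$genotypes$variants)))
  invisible(x)
}

#' Merge several studies into one cohort
#'
#' Concatenates samples (prefixing ids with the study name when needed) over
#' the intersection of variants and adds a `study` factor to the phenotype
#' table, for merged-data analyses such as the conditional LRT.
#'
#' @param studies list of [study_cohort()] objects.
#' @param mds_k if > 0, MDS coordinates are recomputed on the merged genotypes
#'   with this many components (see [compute_mds()]); 0 disables.
#' @return a `study_cohort` whose phenotype table carries a `study` column.
#' @export
merge_cohorts <- function(studies, mds_k = 0) {
  stopifnot(length(studies) >= 1)
  ids <- Reduce(intersect, lapply(studies, function(s) s$genotypes$variants$id))
  if (length(ids) == 0) stop("studies share no variants")
  pieces <- lapply(seq_along(studies), function(k) {
    s <- studies[[k]]
    g <- subset_variants(s$genotypes, ids)
    ph <- s$phenotypes
    ph$study <- if (nzchar(s$name)) s$name else paste0("study", k)
    list(d = g$dosages, ph = ph, v = g$variants)
  })
  # align the counted allele across studies (per-study minor alleles can differ)
  ref_alt <- pieces[[1]]$v$alt
  pieces <- lapply(pieces, function(p) {
    flip <- p$v$alt != ref_alt
    if (any(flip)) p$d[, flip] <- 2 - p$d[, flip]
    p
  })
  d <- do.call(rbind, lapply(pieces, `[[`, "d"))
  ph <- do.call(rbind, lapply(pieces, function(p) {
    p$ph[intersect(names(p$ph), Reduce(intersect, lapply(pieces, function(q) names(q$ph))))]
  }))
  if (anyDuplicated(ph$sample_id)) {
    ph$sample_id <- paste(ph$study, ph$sample_id, sep = ".")
    rownames(d) <- ph$sample_id
  }
  gm <- genotype_matrix(d, pieces[[1]]$v[, c("id", "chrom", "pos", "ref", "alt")],
                        ph$sample_id)
  mds <- if (mds_k > 0) compute_mds(gm, k = mds_k) else NULL
  study_cohort(gm, ph, mds, name = "merged")
}
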