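#' Construct a genotype matrix
#'
#' Biallelic SNP dosages (count of the counted allele, 0/1/2) for a set of
#' lines; `NA` marks a missing call.
#'
#' @param dosages numeric matrix, lines in rows, markers in columns, with
#'   dimnames; values in \{0, 1, 2, NA\}.
#' @return a `geno_matrix` object.
#' @export
geno_matrix <- function(dosages) {
  if (!is.matrix(dosages)) stop2("`dosages` must be a matrix")
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop2("dosage matrix needs line ids as rownames and marker ids as colnames")
  storage.mode(dosages) <- "double"
  bad <- !(dosages %in% c(0, 1, 2) | is.na(dosages))
  if (any(bad))
    stop2("dosages must be 0, 1, 2 or NA; found ",
          paste(unique(dosages[bad]), collapse = ", "))
  structure(list(dosages = dosages), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  d <- x$dosages
  cat(sprintf("<geno_matrix: %d lines x %d markers, %.1f%% missing>\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  invisible(x)
}

#' Line ids of a genotype matrix
#' @param geno a `geno_matrix`.
#' @return character vector.
#' @export
geno_ids <- function(geno) rownames(geno$dosages)

#' Marker ids of a genotype matrix
#' @param geno a `geno_matrix`.
#' @return character vector.
#' @export
marker_ids <- function(geno) colnames(geno$dosages)

#' Per-marker allele frequency of the counted allele
#'
#' Computed on non-missing calls only.
#'
#' @param geno a `geno_matrix`.
#' @return named numeric vector of frequencies.
#' @export
allele_freqs <- function(geno) {
  colMeans(geno$dosages, na.rm = TRUE) / 2
}

#' Read a genotype CSV matrix
#'
#' Layout: first column line id, header row marker ids, cells 0/1/2/NA.
#'
#' @param path CSV file.
#' @return a `geno_matrix`.
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  geno_matrix(m)
}

#' Write a genotype matrix as CSV
#' @param geno a `geno_matrix`.
#' @param path output file.
#' @export
write_genotypes_csv <- function(geno, path) {
  df <- data.frame(line_id = geno_ids(geno), geno$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Dosage is the count of ALT alleles in the GT field; a missing GT becomes
#' `NA`. Multi-allelic records are skipped with a logged warning. Requires
#' the VariantAnnotation package.
#'
#' @param path VCF file (plain or bgzipped).
#' @return a `geno_matrix` (lines = VCF samples, markers = variant ids).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop2("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  multi <- lengths(VariantAnnotation::alt(vcf)) > 1L
  if (any(multi)) {
    kb_log("genotypes", "skipping ", sum(multi), " multi-allelic VCF record(s)")
    vcf <- vcf[!multi]
  }
  gt <- VariantAnnotation::geno(vcf)$GT   # variants x samples
  dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0
  dos[clean %in% c("0/1", "1/0")] <- 1
  dos[clean %in% c("1/1")] <- 2
  geno_matrix(t(dos))
}

#' Quality-control filter for SNP markers
#'
#' Removes markers with minor allele frequency below `maf_min` or with a
#' missing-call fraction above `max_missing`; both statistics are computed
#' on pre-imputation calls. Defaults follow common breeding-program QC
#' (MAF >= 2.5%, missingness <= 20%).
#'
#' @param geno a `geno_matrix` (may contain `NA`).
#' @param maf_min minimum minor allele frequency to retain.
#' @param max_missing maximum fraction of missing calls to retain.
#' @return list with `geno` (filtered `geno_matrix`) and `report` (data frame
#'   `marker_id`, `maf`, `missing_frac`, `removed_reason`; reason `""` for
#'   retained markers).
#' @export
qc_filter <- function(geno, maf_min = 0.025, max_missing = 0.20) {
  d <- geno$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(p)] <- NA_real_  # entirely missing marker
  missf <- colMeans(is.na(d))
  reason <- character(ncol(d))
  reason[is.na(maf) | maf < maf_min] <- "MAF"
  reason[missf > max_missing] <- ifelse(
    nzchar(reason[missf > max_missing]), "MAF;missingness", "missingness")
  keep <- !nzchar(reason)
  if (!any(keep)) stop2("QC removed every marker")
  report <- data.frame(marker_id = colnames(d), maf = maf,
                       missing_frac = missf, removed_reason = reason,
                       stringsAsFactors = FALSE, row.names = NULL)
  list(geno = geno_matrix(d[, keep, drop = FALSE]), report = report)
}

#' Impute missing genotype calls from marginal allele frequencies
#'
#' Each missing cell is replaced by an independent draw from
#' `Binomial(2, p_j)` where `p_j` is the marker's allele frequency among
#' non-missing calls. Deterministic given `seed`; non-missing cells are
#' untouched. Run [qc_filter()] first.
#'
#' @param geno a `geno_matrix`.
#' @param seed integer RNG seed.
#' @return a complete `geno_matrix`.
#' @export
impute_missing <- function(geno, seed) {
  d <- geno$dosages
  if (!anyNA(d)) return(geno)
  p <- colMeans(d, na.rm = TRUE) / 2
  if (anyNA(p))
    stop2("marker(s) entirely missing: ",
          paste(colnames(d)[is.na(p)], collapse = ", "),
          " — run qc_filter() first")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  for (j in which(colSums(is.na(d)) > 0L)) {
    miss <- is.na(d[, j])
    d[miss, j] <- stats::rbinom(sum(miss), 2L, p[j])
  }
  geno_matrix(d)
}

# Save/restore the global RNG state around a seeded computation so that
# seeded helpers do not perturb an enclosing random stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
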