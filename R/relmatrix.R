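#' Construct a labeled relationship matrix
#'
#' A `rel_matrix` is a numeric symmetric matrix with row/column names (the
#' line ids) and a `kind` tag recording its provenance: `"A"` (pedigree
#' numerator relationships), `"G"` (VanRaden genomic), `"Gs"` (genomic
#' rescaled to the pedigree base) or `"K"` (blended).
#'
#' @param values numeric square matrix with identical row and column names.
#' @param kind one of `"A"`, `"G"`, `"Gs"`, `"K"`.
#' @param tol symmetry tolerance.
#' @return a `rel_matrix` object.
#' @export
rel_matrix <- function(values, kind = c("A", "G", "Gs", "K"), tol = 1e-12) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop2("`values` must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop2("relationship matrix must be square")
  ids <- rownames(values)
  if (is.null(ids) || is.null(colnames(values)) ||
      !identical(ids, colnames(values)))
    stop2("row and column names must be present and identical")
  if (anyDuplicated(ids)) stop2("duplicated ids in relationship matrix")
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    stop2(sprintf("matrix is not symmetric (max |M - t(M)| = %.3g)", asym))
  values <- (values + t(values)) / 2  # exact symmetry
  structure(values, class = c("rel_matrix", "matrix", "array"), kind = kind)
}

#' @export
print.rel_matrix <- function(x, ...) {
  cat(sprintf("<rel_matrix kind=%s, %d x %d ids>\n", rel_kind(x), nrow(x),
              ncol(x)))
  cat(sprintf("  mean diag = %.4f, mean all = %.4f\n",
              mean(diag(unclass(x))), mean(unclass(x))))
  invisible(x)
}

#' Kind tag of a relationship matrix
#' @param x a `rel_matrix`.
#' @return character scalar.
#' @export
rel_kind <- function(x) attr(x, "kind")

#' Line ids of a relationship matrix
#' @param x a `rel_matrix`.
#' @return character vector.
#' @export
rel_ids <- function(x) rownames(x)

#' Restrict a relationship matrix to a subset of ids
#'
#' Reorders silently; refuses to drop silently: every requested id must be
#' present.
#'
#' @param x a `rel_matrix`.
#' @param ids character vector of ids to keep, in the requested order.
#' @return a `rel_matrix` of the same kind.
#' @export
rel_subset <- function(x, ids) {
  miss <- setdiff(ids, rel_ids(x))
  if (length(miss))
    stop2("ids absent from relationship matrix: ", paste(miss, collapse = ", "))
  rel_matrix(unclass(x)[ids, ids, drop = FALSE], kind = rel_kind(x))
}

# Check two matrices share exactly the same id set; error lists the
# asymmetric difference. Returns the second matrix reordered to match.
rel_align <- function(x, y, xlab = "first", ylab = "second") {
  a <- rel_ids(x); b <- rel_ids(y)
  only_a <- setdiff(a, b); only_b <- setdiff(b, a)
  if (length(only_a) || length(only_b))
    stop2("id mismatch between matrices: only in ", xlab, ": {",
          paste(only_a, collapse = ","), "}; only in ", ylab, ": {",
          paste(only_b, collapse = ","), "}")
  rel_subset(y, a)
}

#' Write a relationship matrix as square CSV
#'
#' First row and first column carry the ids; values are written at 12
#' significant digits so a read/write round trip is stable at 1e-12.
#'
#' @param x a `rel_matrix`.
#' @param path output file.
#' @export
write_rel_matrix <- function(x, path) {
  m <- unclass(x)
  df <- data.frame(id = rownames(m),
                   signif(m, 12), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a relationship matrix written by [write_rel_matrix()]
#' @param path CSV file.
#' @param kind kind tag to attach.
#' @return a `rel_matrix`.
#' @export
read_rel_matrix <- function(path, kind = c("A", "G", "Gs", "K")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  storage.mode(m) <- "double"
  rel_matrix(m, kind = kind, tol = 1e-9)
}
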