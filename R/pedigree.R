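#' Build a validated, topologically sorted pedigree
#'
#' A pedigree is a data frame with columns `id`, `sire`, `dam` (character;
#' `NA` marks an unknown parent), sorted so that every parent appears before
#' any of its offspring. Selfing records (`sire == dam`) are allowed —
#' inbred-line pedigrees need them.
#'
#' @param id,sire,dam character vectors of equal length; `NA` for unknown
#'   parents.
#' @param strict if `TRUE`, a parent id never declared as an individual is an
#'   error; if `FALSE` (default) such parents are added as founders and a
#'   message is logged. Real breeding pedigrees are usually ragged.
#' @return a `pedigree` object (data frame with attribute `founders`).
#' @examples
#' ped <- pedigree(id = c("F1", "F2", "O"),
#'                 sire = c(NA, NA, "F1"), dam = c(NA, NA, "F2"))
#' @export
pedigree <- function(id, sire, dam, strict = FALSE) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  n <- length(id)
  if (length(sire) != n || length(dam) != n)
    stop2("id, sire, dam must have equal length")
  dup <- id[duplicated(id)]
  if (length(dup))
    stop2("duplicated individual id(s): ", paste(unique(dup), collapse = ", "))

  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(parents)) {
    if (strict)
      stop2("parent id(s) never declared as individuals: ",
            paste(parents, collapse = ", "))
    kb_log("pedigree", "adding ", length(parents),
           " undeclared parent(s) as founders: ",
           paste(utils::head(parents, 10), collapse = ", "),
           if (length(parents) > 10) " ..." else "")
    id <- c(parents, id)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
    n <- length(id)
  }

  # Kahn topological sort; detects cycles and reports one member.
  idx <- stats::setNames(seq_len(n), id)
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in unique(c(si[i], di[i]))) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  queue <- which(indeg == 0L)
  order <- integer(0)
  while (length(queue)) {
    # stable: keep original file order among ready nodes
    queue <- sort(queue)
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    on_cycle <- id[setdiff(seq_len(n), order)]
    stop2("pedigree contains a cycle involving individual '", on_cycle[1], "'")
  }

  out <- data.frame(id = id[order], sire = sire[order], dam = dam[order],
                    stringsAsFactors = FALSE)
  attr(out, "founders") <- out$id[is.na(out$sire) & is.na(out$dam)]
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree: %d individuals, %d founders>\n", nrow(x),
              length(attr(x, "founders"))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Founder ids of a pedigree
#' @param ped a `pedigree`.
#' @return character vector of ids with both parents unknown.
#' @export
founders <- function(ped) attr(ped, "founders")

#' Read a pedigree file
#'
#' Expects 3-column delimited text with a header (`id,sire,dam`); the
#' delimiter is chosen from the file extension (`.csv` comma, otherwise tab).
#' Rows need not be sorted: a topological sort is performed.
#'
#' @param path file path.
#' @param unknown_token token(s) marking a missing parent, besides the empty
#'   string and `NA`. Default `"0"`.
#' @param strict passed to [pedigree()].
#' @return a `pedigree`.
#' @export
read_pedigree <- function(path, unknown_token = "0", strict = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", na.strings = c("NA", ""))
  if (ncol(df) < 3) stop2("pedigree file must have 3 columns: id, sire, dam")
  clean <- function(x) ifelse(is.na(x) | x %in% unknown_token,
                              NA_character_, x)
  pedigree(df[[1]], clean(df[[2]]), clean(df[[3]]), strict = strict)
}

#' Numerator relationship matrix by the tabular method
#'
#' Computes additive relationships over the full pedigree by the tabular
#' recursion: for individual `i` with parents `s`, `d` and any earlier `j`,
#' `a_ij = (a_js + a_jd) / 2` and `a_ii = 1 + a_sd / 2`; unknown parents
#' contribute zero. Dense storage — adequate up to a few thousand
#' individuals.
#'
#' @param ped a `pedigree`.
#' @param subset_ids optional ids to restrict the result to (computed on the
#'   full pedigree first, then restricted).
#' @return a `rel_matrix` of kind `"A"`.
#' @export
numerator_relationship_matrix <- function(ped, subset_ids = NULL) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  si <- ifelse(is.na(ped$sire), 0L, idx[ped$sire])
  di <- ifelse(is.na(ped$dam), 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else rep(0, i - 1L)
      ad_ <- if (d > 0L) A[j, d] else rep(0, i - 1L)
      aij <- (as_ + ad_) / 2
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) A[s, d] / 2 else 0
  }
  out <- rel_matrix(A, kind = "A")
  if (!is.null(subset_ids)) out <- rel_subset(out, subset_ids)
  out
}

#' Inbreeding coefficients from a pedigree
#'
#' `F_i = a_ii - 1` from the tabular relationship recursion. Founders have
#' `F = 0`; selfing raises it (one selfing generation of a non-inbred parent
#' gives `F = 0.5`).
#'
#' @param ped a `pedigree`.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  A <- numerator_relationship_matrix(ped)
  diag(unclass(A)) - 1
}

#' Group lines into full-sib families
#'
#' Lines sharing both (known) parents share a family; the family key is the
#' unordered parent pair `"p1 x p2"`. A line with one or both parents unknown
#' forms its own singleton family — a conservative grouping for
#' cross-validation, since it never inflates within-family relatedness.
#'
#' @param ped a `pedigree`.
#' @param line_ids ids of the lines (cohort) to group; must be in `ped`.
#' @return named list mapping family key to character vector of line ids.
#' @export
full_sib_families <- function(ped, line_ids) {
  miss <- setdiff(line_ids, ped$id)
  if (length(miss))
    stop2("line ids absent from pedigree: ", paste(miss, collapse = ", "))
  rec <- as.data.frame(ped)[match(line_ids, ped$id), ]
  key <- ifelse(
    is.na(rec$sire) | is.na(rec$dam),
    paste0("singleton:", rec$id),
    paste(pmin(rec$sire, rec$dam), pmax(rec$sire, rec$dam), sep = " x "))
  split(line_ids, factor(key, levels = unique(key)))
}
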