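#' Read a wide ISU matrix from delimited text
#'
#' Parses a subjects-by-components table of raw specific-IgE values in ISAC
#' standardized units (ISU). Blank cells are treated as missing, never as
#' zero. Negative values and duplicate subject or component identifiers are
#' rejected.
#'
#' @param path Path to a CSV or TSV file. The first column holds subject IDs
#'   and the header row component IDs (or transposed, see `orientation`).
#' @param orientation `"subjects_by_components"` (default) or
#'   `"components_by_subjects"`.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @return An `isu_matrix`: a numeric matrix (subjects in rows, components in
#'   columns) with class `"isu_matrix"`.
#' @export
read_isu_matrix <- function(path, orientation = c("subjects_by_components",
                                                  "components_by_subjects"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  dup_h <- unique(names(df)[-1L][duplicated(names(df)[-1L])])
  if (length(dup_h)) stop("duplicate column header(s): ",
                          paste(dup_h, collapse = ", "))
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "components_by_subjects") m <- t(m)
  isu_matrix(m)
}

#' Construct and validate an ISU matrix
#'
#' @param m Numeric matrix, subjects in rows, components in columns; `NA`
#'   allowed.
#' @return The validated matrix with class `"isu_matrix"`.
#' @export
isu_matrix <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("C", seq_len(ncol(m)))
  dup_s <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup_s)) stop("duplicate subject ID(s): ", paste(dup_s, collapse = ", "))
  dup_c <- unique(colnames(m)[duplicated(colnames(m))])
  if (length(dup_c)) stop("duplicate component ID(s): ", paste(dup_c, collapse = ", "))
  neg <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative ISU value at subject '%s', component '%s'",
                 rownames(m)[neg[1L, 1L]], colnames(m)[neg[1L, 2L]]))
  }
  structure(m, class = c("isu_matrix", class(unclass(m))))
}

# ISU category bounds. Half-open bins: exactly-on-boundary values fall in the
# upper category, so 0.3 is "low" (consistent with "< 0.3" defining "no").
.isu_breaks <- c(0, 0.3, 1, 15, Inf)

#' Discretize ISU values into four ordinal categories
#'
#' Maps raw ISU onto the manufacturer's semi-quantitative scale:
#' no (< 0.3 ISU) = 0, low (0.3 to < 1) = 1, medium (1 to < 15) = 2,
#' high (>= 15) = 3. Missing values stay missing.
#'
#' @param m An `isu_matrix`.
#' @return Integer matrix of the same shape with values in 0..3, class
#'   `"categorical_matrix"`.
#' @export
discretize_isu <- function(m) {
  stopifnot(inherits(m, "isu_matrix"))
  v <- unclass(m)
  out <- matrix(NA_integer_, nrow(v), ncol(v), dimnames = dimnames(v))
  ok <- !is.na(v)
  out[ok] <- findInterval(v[ok], .isu_breaks[-1L]) # 0..3, right-open bins
  structure(out, class = c("categorical_matrix", class(unclass(out))))
}

#' Binarize an ISU or categorical matrix at the 0.3 ISU positivity threshold
#'
#' @param m An `isu_matrix` (threshold at 0.3 ISU) or `categorical_matrix`
#'   (category >= 1 is positive).
#' @return Integer 0/1 matrix with class `"binary_matrix"`; `NA` preserved.
#' @export
binarize <- function(m) {
  if (inherits(m, "isu_matrix")) {
    out <- ifelse(is.na(unclass(m)), NA_integer_, as.integer(unclass(m) >= 0.3))
  } else if (inherits(m, "categorical_matrix")) {
    out <- ifelse(is.na(unclass(m)), NA_integer_, as.integer(unclass(m) >= 1L))
  } else if (is.matrix(m) && all(m %in% c(0L, 1L, NA))) {
    out <- m
    storage.mode(out) <- "integer"
  } else {
    stop("binarize() expects an isu_matrix or categorical_matrix")
  }
  dimnames(out) <- dimnames(m)
  structure(out, class = c("binary_matrix", "matrix", "array"))
}

as_binary_matrix <- function(m) {
  if (inherits(m, "binary_matrix")) return(m)
  binarize(m)
}

#' Drop components recognized by too few children
#'
#' Retains components with at least `min_positive` positive (missing cells do
#' not count) results across subjects; the study rule keeps components with
#' positive tests in at least 3 children.
#'
#' @param b A `binary_matrix`.
#' @param min_positive Minimum number of positive subjects (default 3).
#' @return List with `matrix` (filtered `binary_matrix`) and `excluded`
#'   (character vector of dropped component IDs).
#' @export
filter_components <- function(b, min_positive = 3L) {
  b <- as_binary_matrix(b)
  npos <- colSums(unclass(b) == 1L, na.rm = TRUE)
  keep <- npos >= min_positive
  if (!any(keep)) stop("no components survive the >=", min_positive, " positives filter")
  list(matrix = structure(unclass(b)[, keep, drop = FALSE],
                          class = class(b)),
       excluded = colnames(b)[!keep])
}

#' Drop subjects with no positive results
#'
#' Retains subjects with at least one positive among the (already filtered)
#' components; subject order is preserved. A row that is entirely missing is
#' excluded.
#'
#' @param b A `binary_matrix`.
#' @return List with `matrix` and `excluded` (dropped subject IDs).
#' @export
filter_subjects <- function(b) {
  b <- as_binary_matrix(b)
  keep <- rowSums(unclass(b) == 1L, na.rm = TRUE) >= 1L
  if (!any(keep)) stop("no subjects with any positive result")
  list(matrix = structure(unclass(b)[keep, , drop = FALSE],
                          class = class(b)),
       excluded = rownames(b)[!keep])
}

#' Read a component catalog
#'
#' @param path CSV/TSV with columns `component`, `source`, `pfam_family` and
#'   optionally `table1_cg`.
#' @param sep Field separator; guessed from the extension when `NULL`.
#' @return A data.frame; component IDs must be unique.
#' @export
read_component_catalog <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("component", "source", "pfam_family") %in% names(df))) {
    stop("catalog needs columns: component, source, pfam_family")
  }
  dup <- unique(df$component[duplicated(df$component)])
  if (length(dup)) stop("duplicate component ID(s) in catalog: ", paste(dup, collapse = ", "))
  df
}

#' Write a binary matrix (or any labelled matrix) as TSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the leading ID column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "subject") {
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
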