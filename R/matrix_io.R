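#' Read a labeled numeric matrix from a delimited text file
#'
#' Parses a CSV/TSV file whose first row holds column labels and whose first
#' column holds row labels (the header cell above the row labels is ignored).
#' Cells matching one of `missing_tokens` become `NA`; every other cell must
#' parse as a number.
#'
#' @param path Path to the file.
#' @param delimiter Single field-separator character. No auto-detection is
#'   attempted; the default is a comma.
#' @param missing_tokens Character vector of cell contents to treat as
#'   missing. Matching is exact after trimming surrounding whitespace.
#' @return A numeric matrix with unique `rownames` and `colnames`, in file
#'   order. Missing cells are `NA`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,a,b", "r1,1,2", "r2,3,NA"), f)
#' m <- read_matrix(f)
#' m
read_matrix <- function(path, delimiter = ",",
                        missing_tokens = c("NA", "NaN", "")) {
  if (!file.exists(path)) {
    stop("matrix file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("empty matrix: file must have a header row and at least one data row",
         call. = FALSE)
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- trimws(fields[[1L]])
  n_cols <- length(header) - 1L
  if (n_cols < 1L) {
    stop("empty matrix: no data columns found", call. = FALSE)
  }
  col_labels <- header[-1L]
  body <- fields[-1L]
  row_labels <- vapply(body, function(f) trimws(f[[1L]]), character(1))

  .check_unique(row_labels, "row")
  .check_unique(col_labels, "column")

  values <- matrix(NA_real_, nrow = length(body), ncol = n_cols,
                   dimnames = list(row_labels, col_labels))
  for (i in seq_along(body)) {
    cells <- trimws(body[[i]])
    # a trailing delimiter drops the final empty field in strsplit; restore it
    cells <- c(cells, rep("", max(0L, n_cols + 1L - length(cells))))
    if (length(cells) != n_cols + 1L) {
      stop("row '", row_labels[i], "' has ", length(cells) - 1L,
           " cells, expected ", n_cols, call. = FALSE)
    }
    for (j in seq_len(n_cols)) {
      tok <- cells[j + 1L]
      if (tok %in% missing_tokens) next
      v <- suppressWarnings(as.numeric(tok))
      if (is.na(v)) {
        stop("cannot parse cell at row '", row_labels[i], "', column '",
             col_labels[j], "': '", tok, "' is not numeric", call. = FALSE)
      }
      values[i, j] <- v
    }
  }
  values
}

#' Write a labeled numeric matrix to a delimited text file
#'
#' Inverse of [read_matrix()]: finite values round-trip bit-exactly (written
#' with full precision via `format(..., digits = 17)`), missing cells are
#' written as `NA`.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param delimiter Field separator character.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, delimiter = ",") {
  m <- validate_matrix(m)
  fmt <- function(v) {
    ifelse(is.na(v), "NA", vapply(v, format, character(1), digits = 17))
  }
  header <- paste(c("", colnames(m)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read categorical annotation tracks aligned to a matrix axis
#'
#' The annotation file's first column holds axis labels and each remaining
#' column is one categorical track (header row gives track names). Tracks are
#' reordered to match `labels`; the file may contain extra labels, but every
#' element of `labels` must be present.
#'
#' @param path Path to the annotation CSV.
#' @param axis `"row"` or `"column"` — which matrix axis the tracks annotate.
#' @param labels Axis labels of the matrix, in matrix order.
#' @param delimiter Field separator character.
#' @return A list of annotation tracks. Each track is a list with fields
#'   `axis`, `name`, `categories` (character, aligned to `labels`) and
#'   `level_order` (distinct categories in order of first appearance).
#' @export
read_annotations <- function(path, axis = c("row", "column"), labels,
                             delimiter = ",") {
  axis <- match.arg(axis)
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  if (ncol(tab) < 2L) {
    stop("annotation file needs a label column plus at least one track",
         call. = FALSE)
  }
  file_labels <- trimws(tab[[1L]])
  absent <- setdiff(labels, file_labels)
  if (length(absent) > 0L) {
    stop("annotation file is missing ", axis, " labels: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  idx <- match(labels, file_labels)
  lapply(seq.int(2L, ncol(tab)), function(j) {
    cats <- trimws(tab[[j]])[idx]
    annotation_track(axis = axis, name = colnames(tab)[j], categories = cats)
  })
}

#' Construct an annotation track
#'
#' @param axis `"row"` or `"column"`.
#' @param name Track name (shown next to its sidebar).
#' @param categories Character vector of category values, one per axis
#'   element, in matrix order.
#' @param level_order Optional ordering of the distinct categories; defaults
#'   to first appearance in `categories`.
#' @return An `interheat_annotation` list.
#' @export
annotation_track <- function(axis, name, categories, level_order = NULL) {
  categories <- as.character(categories)
  if (is.null(level_order)) level_order <- unique(categories)
  if (!all(categories %in% level_order)) {
    stop("categories contain values absent from level_order", call. = FALSE)
  }
  structure(list(axis = axis, name = name, categories = categories,
                 level_order = level_order),
            class = "interheat_annotation")
}

# Validate the package's matrix contract: numeric, >= 1x1, unique dimnames.
# Bare vectors and data frames of numbers are promoted for convenience.
validate_matrix <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("expected a numeric matrix", call. = FALSE)
  }
  if (nrow(m) < 1L || ncol(m) < 1L) {
    stop("empty matrix: need at least one row and one column", call. = FALSE)
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("row", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("col", seq_len(ncol(m)))
  .check_unique(rownames(m), "row")
  .check_unique(colnames(m), "column")
  m
}

.check_unique <- function(labels, what) {
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0L) {
    stop("duplicate ", what, " labels: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  invisible(labels)
}
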