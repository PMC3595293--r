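#' Ordinal RLBH score matrices
#'
#' RLBH signals are scored per (habitat, probe) on an ordinal scale:
#' 0 = no signal, 1 = weak, 2 = normal, 3 = strong. A score matrix is an
#' integer matrix with habitat ids as row names and probe names as column
#' names; every cell must be filled — the assay screens every habitat with
#' every probe.
#'
#' @param x Integer matrix (or coercible) with dimnames.
#' @return Validated matrix of class `score_matrix`.
#' @export
score_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  validate_score_matrix(x)
}

#' @rdname score_matrix
#' @export
validate_score_matrix <- function(x) {
  stopifnot(is.matrix(x))
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("score matrix needs habitat row names and probe column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) stop("duplicate habitat ids", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate probe names", call. = FALSE)
  bad <- which(is.na(x) | !(x %in% 0:3), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop(sprintf(
      "invalid score %s at habitat '%s', probe '%s' (allowed: 0,1,2,3)",
      x[b[1L], b[2L]], rownames(x)[b[1L]], colnames(x)[b[2L]]),
      call. = FALSE)
  }
  class(x) <- c("score_matrix", class(unclass(x)))
  x
}

#' Read an ordinal score table from TSV/CSV
#'
#' First column must be `habitat_id`; remaining columns are probe names with
#' integer cells in 0..3. Row and column order are preserved.
#'
#' @param path File path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A `score_matrix`.
#' @export
read_score_table <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "habitat_id") {
    stop("first column must be 'habitat_id'", call. = FALSE)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)) || any(m != floor(m))) {
    stop("score cells must all be integers in 0..3", call. = FALSE)
  }
  rownames(m) <- as.character(df$habitat_id)
  score_matrix(m)
}

#' @rdname read_score_table
#' @param m Score (or binary) matrix to write.
#' @export
write_score_table <- function(m, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(habitat_id = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse ordinal scores to detection / no detection
#'
#' Detection means any signal at all (score >= 1, i.e. weak, normal or
#' strong); ordination and richness statistics run on this 0/1 view.
#'
#' @param m A `score_matrix` (an already-binary matrix passes through).
#' @return Integer 0/1 matrix of class `binary_matrix`, same dimnames.
#' @export
binarize <- function(m) {
  m <- validate_score_matrix(unclass(m))
  b <- (unclass(m) > 0L) * 1L
  dimnames(b) <- dimnames(m)
  class(b) <- c("binary_matrix", class(unclass(b)))
  b
}

#' Habitat environment tables
#'
#' Per-habitat covariates of the survey: pH (mandatory), conductivity
#' (uS/cm), dissolved oxygen (mg/L), absorbance (a DOC proxy), altitude (m),
#' temperature (degC), and decimal-degree coordinates. Optional covariates
#' may be missing (NA) and are skipped — never imputed — downstream.
#'
#' @param df Data frame with at least `habitat_id` and `ph` columns.
#' @return Validated data frame of class `habitat_table`.
#' @export
habitat_table <- function(df) {
  validate_habitat_table(df)
}

HABITAT_COLUMNS <- c("habitat_id", "ph", "conductivity", "oxygen",
                     "absorbance", "altitude", "temperature",
                     "latitude", "longitude")

#' @rdname habitat_table
#' @export
validate_habitat_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("habitat_id", "ph") %in% names(df))) {
    stop("habitat table needs 'habitat_id' and 'ph' columns", call. = FALSE)
  }
  for (col in setdiff(HABITAT_COLUMNS, names(df))) df[[col]] <- NA_real_
  df <- df[, HABITAT_COLUMNS]
  df$habitat_id <- as.character(df$habitat_id)
  if (anyDuplicated(df$habitat_id)) {
    stop("duplicate habitat ids: ",
         paste(unique(df$habitat_id[duplicated(df$habitat_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$ph))) {
    stop("pH is mandatory; missing for habitat(s): ",
         paste(df$habitat_id[is.na(df$ph)], collapse = ", "), call. = FALSE)
  }
  check_range <- function(col, lo, hi) {
    v <- df[[col]]
    bad <- !is.na(v) & (v < lo | v > hi)
    if (any(bad)) {
      stop(sprintf("%s out of range [%g, %g] for habitat(s): %s", col, lo, hi,
                   paste(df$habitat_id[bad], collapse = ", ")), call. = FALSE)
    }
  }
  check_range("ph", 0, 14)
  check_range("latitude", -90, 90)
  check_range("longitude", -180, 180)
  for (col in c("conductivity", "oxygen", "absorbance")) {
    check_range(col, 0, Inf)
  }
  class(df) <- c("habitat_table", "data.frame")
  df
}

#' Read / write habitat environment tables (TSV)
#'
#' @param path File path.
#' @return `read_habitat_table()` returns a validated `habitat_table`.
#' @export
read_habitat_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  for (col in setdiff(HABITAT_COLUMNS, "habitat_id")) {
    if (col %in% names(df)) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) &
                   trimws(as.character(df[[col]])) != "" &
                   !toupper(trimws(as.character(df[[col]]))) %in% "NA")
      if (length(bad) > 0L) {
        stop(sprintf("unparseable value '%s' in column '%s', row %d",
                     df[[col]][bad[1L]], col, bad[1L]), call. = FALSE)
      }
      df[[col]] <- v
    }
  }
  validate_habitat_table(df)
}

#' @rdname read_habitat_table
#' @param h Habitat table to write.
#' @export
write_habitat_table <- function(h, path) {
  utils::write.table(as.data.frame(h), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align a score/binary matrix with a habitat table
#'
#' Restricts both inputs to their common habitat ids, in the matrix's row
#' order, and reports how many ids were dropped from each side.
#'
#' @param m A `score_matrix` or `binary_matrix`.
#' @param h A `habitat_table`.
#' @return List with elements `scores` (row-subset matrix), `habitats`
#'   (row-subset table in matching order), `dropped_from_matrix`,
#'   `dropped_from_habitats`.
#' @export
align_scores <- function(m, h) {
  h <- validate_habitat_table(as.data.frame(h))
  common <- intersect(rownames(m), h$habitat_id)
  if (length(common) == 0L) {
    stop("no habitat ids in common between scores and habitat table",
         call. = FALSE)
  }
  keep <- rownames(m)[rownames(m) %in% common]   # matrix order wins
  d_m <- nrow(m) - length(keep)
  d_h <- nrow(h) - length(keep)
  if (d_m + d_h > 0L) {
    message(sprintf("align: dropped %d habitat(s) from matrix, %d from table",
                    d_m, d_h))
  }
  hh <- h[match(keep, h$habitat_id), , drop = FALSE]
  rownames(hh) <- NULL
  list(scores = m[keep, , drop = FALSE],
       habitats = hh,
       dropped_from_matrix = d_m,
       dropped_from_habitats = d_h)
}
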