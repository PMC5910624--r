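# TSV I/O for the three interchange formats. All files are tab-separated,
# UTF-8, one header row; leading lines starting with '#' are provenance
# comments written by the CLI and are skipped on read. Missing values are
# written as empty cells and read back from "", "NA" or "NaN"
# (case-insensitive).

.na_markers <- c("", "na", "nan")

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop_mf("file not found: %s", path)
  con <- file(path, "r", encoding = "UTF-8")
  on.exit(close(con))
  skip <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) break
    if (!startsWith(line, "#")) break
    skip <- skip + 1L
  }
  utils::read.delim(path, sep = "\t", header = TRUE, skip = skip,
                    check.names = FALSE, colClasses = "character",
                    quote = "", comment.char = "", na.strings = NULL,
                    fileEncoding = "UTF-8")
}

# parse a character column as numeric; non-numeric, non-missing cells are an
# error reported with row/column coordinates (1-based data rows)
parse_numeric_column <- function(x, colname) {
  x <- trimws(x)
  miss <- tolower(x) %in% .na_markers
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !miss)
  if (length(bad))
    stop_mf("non-numeric value %s at row %d, column '%s'",
            dQuote(x[bad[1L]]), bad[1L], colname)
  out[miss] <- NA_real_
  out
}

#' Read a wide-format feature table
#'
#' @param path TSV path: one header row, a unique feature-ID column, one
#'   numeric column per sample. Columns named `mz`/`m/z` and `rt`
#'   (case-insensitive) are treated as per-feature annotations, not samples;
#'   override via `mz_col`/`rt_col`.
#' @param id_col name of the feature-ID column.
#' @param mz_col,rt_col explicit annotation column names (optional).
#' @return a [feature_table()].
#' @export
read_wide <- function(path, id_col = "rowID", mz_col = NULL, rt_col = NULL) {
  df <- read_tsv_raw(path)
  if (!id_col %in% names(df))
    stop_mf("wide file %s has no ID column '%s'", path, id_col)
  ids <- trimws(df[[id_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_mf("duplicate feature IDs in %s: %s", path, paste(dup, collapse = ", "))

  lown <- tolower(names(df))
  if (is.null(mz_col) && any(lown %in% c("mz", "m/z")))
    mz_col <- names(df)[which(lown %in% c("mz", "m/z"))[1L]]
  if (is.null(rt_col) && any(lown == "rt"))
    rt_col <- names(df)[which(lown == "rt")[1L]]
  ann_cols <- c(mz_col, rt_col)
  sample_cols <- setdiff(names(df), c(id_col, ann_cols))
  if (length(sample_cols) == 0L)
    stop_mf("wide file %s has no sample columns", path)

  values <- vapply(sample_cols,
                   function(cn) parse_numeric_column(df[[cn]], cn),
                   numeric(nrow(df)))
  if (nrow(df) == 1L) values <- matrix(values, nrow = 1L,
                                       dimnames = list(NULL, sample_cols))
  rownames(values) <- ids

  ann <- NULL
  if (length(ann_cols)) {
    ann <- data.frame(row.names = seq_len(nrow(df)))
    if (!is.null(mz_col)) ann$mz <- parse_numeric_column(df[[mz_col]], mz_col)
    if (!is.null(rt_col)) ann$rt <- parse_numeric_column(df[[rt_col]], rt_col)
  }
  feature_table(values, annotations = ann)
}

#' Write a feature table as wide-format TSV
#'
#' @param wide a `feature_table`.
#' @param path output path.
#' @param id_col header name for the feature-ID column.
#' @return `path`, invisibly.
#' @export
write_wide <- function(wide, path, id_col = "rowID") {
  df <- data.frame(id = rownames(wide$values), stringsAsFactors = FALSE)
  names(df) <- id_col
  if (!is.null(wide$annotations))
    df <- cbind(df, wide$annotations, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(wide$values), stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a design (meta-data) file
#'
#' Columns are type-detected: fully numeric columns become numeric, the rest
#' stay character.
#'
#' @param path TSV path with one row per sample.
#' @param id_col name of the sample-ID column.
#' @return a [design_table()].
#' @export
read_design <- function(path, id_col = "sampleID") {
  df <- read_tsv_raw(path)
  if (!id_col %in% names(df))
    stop_mf("design file %s has no ID column '%s'", path, id_col)
  for (cn in names(df)) {
    x <- trimws(df[[cn]])
    miss <- tolower(x) %in% .na_markers
    num <- suppressWarnings(as.numeric(x))
    if (!any(is.na(num) & !miss) && cn != id_col) {
      num[miss] <- NA_real_
      # keep integer-valued columns (run order, batch) integer for sortability
      if (all(is.na(num) | num == round(num)) && all(abs(num) < .Machine$integer.max, na.rm = TRUE))
        num <- as.integer(num)
      df[[cn]] <- num
    } else {
      x[miss] <- NA_character_
      df[[cn]] <- x
    }
  }
  design_table(df, id_col = id_col)
}

#' Write a design table
#' @param design a `design_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) write_tsv(design$data, path)

#' Read a flag file
#'
#' @param path TSV path: ID column plus 0/1 indicator columns.
#' @param id_col name of the ID column; defaults to the first column.
#' @return a [flag_table()].
#' @export
read_flags <- function(path, id_col = NULL) {
  df <- read_tsv_raw(path)
  if (is.null(id_col)) id_col <- names(df)[1L]
  if (!id_col %in% names(df))
    stop_mf("flag file %s has no ID column '%s'", path, id_col)
  ids <- trimws(df[[id_col]])
  flags <- df[setdiff(names(df), id_col)]
  for (cn in names(flags)) flags[[cn]] <- parse_numeric_column(flags[[cn]], cn)
  flag_table(ids, flags, id_col = id_col)
}

#' Write a flag table
#'
#' Serializes indicators as bare `0`/`1` integers (never `0.0`), ID column
#' first.
#'
#' @param flags a `flag_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_flags <- function(flags, path) {
  df <- as.data.frame(flags)
  for (cn in names(df)[-1L]) df[[cn]] <- as.integer(df[[cn]])
  write_tsv(df, path)
}

# shared TSV writer; header optionally prefixed with provenance comments
write_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
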