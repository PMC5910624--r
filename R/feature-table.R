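#' Feature table (wide format)
#'
#' The suite's central container: a feature-by-sample intensity matrix with a
#' unique feature identifier per row and optional per-feature m/z and
#' retention-time annotations. This mirrors the "wide formatted file" used by
#' metabolomics repositories: samples in columns, features in rows.
#'
#' @param values numeric matrix, rows = features, columns = samples. Rownames
#'   are feature IDs, colnames sample IDs; both mandatory and unique. `NA`
#'   encodes a missing intensity.
#' @param annotations optional data.frame of per-feature columns (e.g. `mz` in
#'   Da, `rt` in minutes), one row per feature in row order.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, annotations = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_mf("'values' must be a numeric matrix (features x samples)")
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop_mf("'values' must carry feature IDs as rownames and sample IDs as colnames")
  dup <- unique(fid[duplicated(fid)])
  if (length(dup))
    stop_mf("duplicate feature IDs: %s", paste(dup, collapse = ", "))
  dup <- unique(sid[duplicated(sid)])
  if (length(dup))
    stop_mf("duplicate sample IDs: %s", paste(dup, collapse = ", "))
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != nrow(values))
      stop_mf("annotations must have one row per feature (%d != %d)",
              nrow(annotations), nrow(values))
    rownames(annotations) <- fid
  }
  structure(list(values = values, annotations = annotations),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples", nrow(x$values), ncol(x$values)))
  if (!is.null(x$annotations))
    cat(sprintf(" | annotations: %s", paste(names(x$annotations), collapse = ", ")))
  nmiss <- sum(is.na(x$values))
  cat(sprintf(" | missing cells: %d\n", nmiss))
  invisible(x)
}

#' @rdname feature_table
#' @param x a `feature_table`.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_table
#' @export
n_features <- function(x) nrow(x$values)

#' Sample IDs of a feature table or design table
#' @param x a `feature_table` or `design_table`.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.feature_table <- function(x) colnames(x$values)

#' Design table
#'
#' Per-sample metadata ("design file" / meta-data file): one row per sample,
#' mapping sample IDs to attributes such as treatment group, run order and
#' batch. Downstream tools look attributes up by column name.
#'
#' @param data data.frame, one row per sample; must contain `id_col`.
#' @param id_col name of the sample-identifier column.
#' @return an object of class `design_table`.
#' @export
design_table <- function(data, id_col = "sampleID") {
  data <- as.data.frame(data)
  if (!id_col %in% names(data))
    stop_mf("design is missing its sample ID column '%s'", id_col)
  ids <- as.character(data[[id_col]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_mf("duplicate sample IDs in design: %s", paste(dup, collapse = ", "))
  rownames(data) <- NULL
  structure(list(data = data, id_col = id_col), class = "design_table")
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("<design_table> %d samples | columns: %s\n",
              nrow(x$data), paste(names(x$data), collapse = ", ")))
  invisible(x)
}

#' @export
sample_ids.design_table <- function(x) as.character(x$data[[x$id_col]])

# look a design column up, with a friendly error
design_column <- function(design, col) {
  if (!col %in% names(design$data))
    stop_mf("design has no column '%s' (columns: %s)",
            col, paste(names(design$data), collapse = ", "))
  design$data[[col]]
}

# group labels as character, in design order
design_groups <- function(design, group_col) {
  as.character(design_column(design, group_col))
}

#' Flag table
#'
#' Binary 0/1 indicator columns attached to feature or sample IDs — the
#' interchange currency every QC and statistical tool emits and the filtering
#' utilities consume.
#'
#' @param ids character vector of unique feature or sample IDs.
#' @param flags data.frame (or list) of columns with values in \{0, 1\}
#'   (`NA` allowed where a flag is undefined). May be empty.
#' @param id_col name to use for the ID column on disk.
#' @return an object of class `flag_table` (a data.frame with the ID column
#'   first).
#' @export
flag_table <- function(ids, flags = NULL, id_col = "rowID") {
  ids <- as.character(ids)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_mf("duplicate IDs in flag table: %s", paste(dup, collapse = ", "))
  if (is.null(flags)) flags <- data.frame(row.names = seq_along(ids))
  flags <- as.data.frame(flags, optional = TRUE)
  if (nrow(flags) == 0L && length(ids) > 0L && ncol(flags) == 0L)
    flags <- data.frame(row.names = seq_along(ids))
  if (nrow(flags) != length(ids))
    stop_mf("flag columns must have one value per ID (%d != %d)",
            nrow(flags), length(ids))
  for (cn in names(flags)) {
    v <- flags[[cn]]
    if (!all(v %in% c(0, 1) | is.na(v)))
      stop_mf("flag column '%s' contains values outside {0,1}", cn)
    flags[[cn]] <- as.integer(v)
  }
  out <- cbind(stats::setNames(data.frame(ids, stringsAsFactors = FALSE), id_col),
               flags)
  rownames(out) <- NULL
  class(out) <- c("flag_table", "data.frame")
  out
}

flag_id_col <- function(flags) names(flags)[1L]

flag_ids <- function(flags) as.character(flags[[1L]])

flag_columns <- function(flags) names(flags)[-1L]

#' Align a feature table with a design table
#'
#' Restricts both tables to the intersection of their sample IDs, in
#' design-file order (the suite's canonical sample order). Samples present on
#' one side only are dropped and logged.
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @return list with elements `wide` and `design`, aligned.
#' @export
align_tables <- function(wide, design) {
  sw <- sample_ids(wide)
  sd_ <- sample_ids(design)
  shared <- sd_[sd_ %in% sw]           # design order wins
  if (length(shared) == 0L)
    stop_mf("no shared sample IDs between wide table and design")
  dropped <- c(setdiff(sw, shared), setdiff(sd_, shared))
  if (length(dropped))
    mf_log("align: dropped samples not present on both sides: ",
           paste(dropped, collapse = ", "), level = "WARN")
  wide$values <- wide$values[, shared, drop = FALSE]
  keep <- match(shared, sd_)
  design$data <- design$data[keep, , drop = FALSE]
  rownames(design$data) <- NULL
  list(wide = wide, design = design)
}
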