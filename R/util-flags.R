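# Flag algebra: the glue that lets QC and statistical tools compose.

#' Compare two flag columns
#'
#' Cross-tabulates two binary columns of a flag table into a 2x2 contingency
#' table — with predicted vs true indicators this is the confusion matrix.
#'
#' @param flags a `flag_table`.
#' @param col_a,col_b flag column names.
#' @return 2x2 integer matrix with rows = `col_a` (0/1), columns = `col_b`.
#' @export
compare_flags <- function(flags, col_a, col_b) {
  for (cn in c(col_a, col_b)) {
    if (!cn %in% flag_columns(flags)) stop_mf("no flag column '%s'", cn)
    if (!all(flags[[cn]] %in% c(0L, 1L)))
      stop_mf("flag column '%s' is not binary", cn)
  }
  a <- factor(flags[[col_a]], levels = c(0, 1))
  b <- factor(flags[[col_b]], levels = c(0, 1))
  tab <- table(a, b, dnn = c(col_a, col_b))
  matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
}

#' Merge flag tables
#'
#' Outer join on ID over any number of flag tables. IDs absent from a table
#' get 0 for that table's columns (the feature simply was not flagged there);
#' colliding column names are suffixed by source name.
#'
#' @param tables list of `flag_table`s; names are used as collision suffixes.
#' @return a single merged `flag_table`.
#' @export
merge_flags <- function(tables) {
  if (!length(tables)) stop_mf("no flag tables to merge")
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("src", seq_along(tables))
  all_ids <- unique(unlist(lapply(tables, flag_ids)))
  seen <- character()
  cols <- list()
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    for (cn in flag_columns(tb)) {
      out_cn <- if (cn %in% seen) paste0(cn, "_", nm) else cn
      seen <- c(seen, cn)
      v <- rep(0L, length(all_ids))
      m <- match(flag_ids(tb), all_ids)
      v[m] <- tb[[cn]]
      cols[[out_cn]] <- v
    }
  }
  id_col <- flag_id_col(tables[[1]])
  flag_table(all_ids, as.data.frame(cols, optional = TRUE), id_col = id_col)
}

#' Summarize a flag table
#'
#' @param flags a `flag_table`.
#' @return list with `per_id` (id, n_flagged, proportion, flag_any) and
#'   `per_column` (column, n_flagged, proportion).
#' @export
summarize_flags <- function(flags) {
  cols <- flag_columns(flags)
  m <- as.matrix(as.data.frame(flags)[cols])
  if (!length(cols)) m <- matrix(0L, nrow = nrow(flags), ncol = 0)
  rs <- rowSums(m, na.rm = TRUE)
  nc <- max(1L, ncol(m))
  per_id <- data.frame(id = flag_ids(flags), n_flagged = rs,
                       proportion = rs / nc,
                       flag_any = as.integer(rs > 0), row.names = NULL)
  names(per_id)[1] <- flag_id_col(flags)
  cs <- colSums(m, na.rm = TRUE)
  per_column <- data.frame(column = cols, n_flagged = as.integer(cs),
                           proportion = cs / nrow(flags), row.names = NULL)
  list(per_id = per_id, per_column = per_column)
}

#' Remove flagged features or samples from a wide table
#'
#' @param wide a `feature_table`.
#' @param flags a `flag_table` whose IDs address the chosen axis.
#' @param flag_column binary column selecting what to drop.
#' @param axis `"features"` (rows) or `"samples"` (columns).
#' @return the reduced `feature_table`.
#' @export
drop_flagged <- function(wide, flags, flag_column,
                         axis = c("features", "samples")) {
  axis <- match.arg(axis)
  if (!flag_column %in% flag_columns(flags))
    stop_mf("no flag column '%s'", flag_column)
  if (!all(flags[[flag_column]] %in% c(0L, 1L)))
    stop_mf("flag column '%s' is not binary", flag_column)
  ids <- flag_ids(flags)
  axis_ids <- if (axis == "features") feature_ids(wide) else sample_ids(wide)
  unknown <- setdiff(ids, axis_ids)
  if (length(unknown)) {
    warning(sprintf("%d flag ID(s) not present in the wide table (%s ...)",
                    length(unknown), utils::head(unknown, 3)[1]))
  }
  to_drop <- ids[flags[[flag_column]] == 1L]
  keep <- setdiff(axis_ids, to_drop)
  mf_log("drop_flagged: removing ", length(axis_ids) - length(keep), " ",
         axis, " via '", flag_column, "'")
  v <- if (axis == "features") wide$values[keep, , drop = FALSE]
       else wide$values[, keep, drop = FALSE]
  ann <- wide$annotations
  if (axis == "features" && !is.null(ann))
    ann <- ann[match(keep, feature_ids(wide)), , drop = FALSE]
  feature_table(v, annotations = ann)
}

#' Subset a design table by dropping groups
#'
#' @param design a `design_table`.
#' @param group_col design column holding group labels.
#' @param drop_groups group labels to remove.
#' @return the reduced `design_table`.
#' @export
subset_design <- function(design, group_col = "group", drop_groups) {
  grp <- design_groups(design, group_col)
  unknown <- setdiff(drop_groups, grp)
  if (length(unknown))
    stop_mf("unknown group(s): %s", paste(unknown, collapse = ", "))
  keep <- !grp %in% drop_groups
  if (!any(keep)) stop_mf("dropping %s would empty the design",
                          paste(drop_groups, collapse = ", "))
  design$data <- design$data[keep, , drop = FALSE]
  rownames(design$data) <- NULL
  mf_log("subset_design: ", sum(!keep), " sample(s) removed")
  design
}
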