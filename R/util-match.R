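# m/z - retention time matching between feature sets and against compound
# libraries. Windows are closed intervals: a pair at exactly the tolerance is
# matched, so boundary features never silently vanish.

check_mzrt_columns <- function(df, label, cols = c("id", "mz", "rt")) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop_mf("%s table is missing column(s): %s", label,
            paste(missing_cols, collapse = ", "))
  df
}

#' Match features between two tables by m/z and retention time
#'
#' A pair (a, b) is matched when `|mz_a - mz_b| <= mz_tol` and
#' `|rt_a - rt_b| <= rt_tol` (closed windows). All qualifying pairs are
#' reported — one-to-many matches are retained, not resolved, and tallied per
#' feature.
#'
#' @param features_a,features_b data.frames with columns `id`, `mz` (Da),
#'   `rt` (minutes).
#' @param mz_tol m/z half-window in Da (> 0).
#' @param rt_tol RT half-window in minutes (> 0).
#' @return list with `matched` (id_a, id_b, delta_mz, delta_rt),
#'   `unmatched_a`, `unmatched_b`, and `multiplicity` (per-side tallies of
#'   match counts). Every input feature appears in exactly one of
#'   matched/unmatched per side.
#' @export
mzrt_match <- function(features_a, features_b, mz_tol = 0.005, rt_tol = 0.15) {
  if (mz_tol <= 0 || rt_tol <= 0) stop_mf("tolerances must be > 0")
  a <- check_mzrt_columns(as.data.frame(features_a), "features_a")
  b <- check_mzrt_columns(as.data.frame(features_b), "features_b")

  matched <- data.frame(id_a = character(), id_b = character(),
                        delta_mz = numeric(), delta_rt = numeric())
  if (nrow(a) && nrow(b)) {
    eps <- 1e-9     # keep the closed window closed under float rounding
    hits <- lapply(seq_len(nrow(a)), function(i) {
      dmz <- abs(a$mz[i] - b$mz)
      drt <- abs(a$rt[i] - b$rt)
      j <- which(dmz <= mz_tol + eps & drt <= rt_tol + eps)
      if (!length(j)) return(NULL)
      data.frame(id_a = a$id[i], id_b = b$id[j],
                 delta_mz = a$mz[i] - b$mz[j], delta_rt = a$rt[i] - b$rt[j])
    })
    hits <- hits[!vapply(hits, is.null, logical(1))]
    if (length(hits)) matched <- do.call(rbind, hits)
  }
  mult_a <- table(factor(matched$id_a, levels = a$id))
  mult_b <- table(factor(matched$id_b, levels = b$id))
  mf_log("mzrt_match: ", nrow(matched), " pair(s); ", sum(mult_a == 0),
         " unmatched on side a, ", sum(mult_b == 0), " on side b")
  list(matched = matched,
       unmatched_a = a$id[mult_a == 0],
       unmatched_b = b$id[mult_b == 0],
       multiplicity = list(
         a = data.frame(id = names(mult_a), n_matches = as.integer(mult_a),
                        row.names = NULL),
         b = data.frame(id = names(mult_b), n_matches = as.integer(mult_b),
                        row.names = NULL)))
}

#' Summary figures for an m/z-RT match
#' @param match result of [mzrt_match()].
#' @return list of ggplot objects: `overlap` (matched/unmatched bar summary)
#'   and `deltas` (distribution of m/z and RT differences).
#' @export
mzrt_match_plot <- function(match) {
  counts <- data.frame(
    set = c("a only", "matched a", "matched b", "b only"),
    n = c(length(match$unmatched_a),
          sum(match$multiplicity$a$n_matches > 0),
          sum(match$multiplicity$b$n_matches > 0),
          length(match$unmatched_b)))
  counts$set <- factor(counts$set, levels = counts$set)
  overlap <- ggplot2::ggplot(counts, ggplot2::aes(x = set, y = n)) +
    ggplot2::geom_col(fill = mf_palette(1)) +
    ggplot2::labs(x = NULL, y = "features") + ggplot2::theme_minimal()
  d <- rbind(data.frame(what = "delta m/z", value = match$matched$delta_mz),
             data.frame(what = "delta RT", value = match$matched$delta_rt))
  deltas <- ggplot2::ggplot(d, ggplot2::aes(x = value)) +
    ggplot2::geom_histogram(bins = 30, fill = mf_palette(1)) +
    ggplot2::facet_wrap(~what, scales = "free") +
    ggplot2::theme_minimal()
  list(overlap = overlap, deltas = deltas)
}

#' Annotate features with compound names from a library
#'
#' Attaches to each feature every library compound whose m/z and RT fall
#' within the closed tolerance windows. Features matching more than one
#' compound are flagged ambiguous; unmatched features keep an empty
#' annotation.
#'
#' @param wide a `feature_table` with `mz` and `rt` annotations (or a
#'   data.frame with `id`, `mz`, `rt`).
#' @param library data.frame with columns `name`, `mz`, `rt`.
#' @param mz_tol,rt_tol closed tolerance windows (Da, minutes).
#' @return data.frame: featureID, mz, rt, compound (matched names joined by
#'   `";"`), n_matches, flag_ambiguous.
#' @export
compound_match <- function(wide, library, mz_tol = 0.005, rt_tol = 0.15) {
  if (inherits(wide, "feature_table")) {
    if (is.null(wide$annotations) ||
        !all(c("mz", "rt") %in% names(wide$annotations)))
      stop_mf("feature table has no mz/rt annotations")
    feats <- data.frame(id = feature_ids(wide),
                        mz = wide$annotations$mz, rt = wide$annotations$rt)
  } else {
    feats <- check_mzrt_columns(as.data.frame(wide), "feature")
  }
  library <- check_mzrt_columns(as.data.frame(library), "library",
                                cols = c("name", "mz", "rt"))
  eps <- 1e-9
  ann <- vapply(seq_len(nrow(feats)), function(i) {
    j <- which(abs(feats$mz[i] - library$mz) <= mz_tol + eps &
                 abs(feats$rt[i] - library$rt) <= rt_tol + eps)
    paste(library$name[j], collapse = ";")
  }, character(1))
  n_matches <- ifelse(ann == "", 0L, lengths(strsplit(ann, ";", fixed = TRUE)))
  mf_log("compound_match: ", sum(n_matches > 0), " of ", nrow(feats),
         " features annotated (", sum(n_matches > 1), " ambiguous)")
  data.frame(featureID = feats$id, mz = feats$mz, rt = feats$rt,
             compound = ann, n_matches = as.integer(n_matches),
             flag_ambiguous = as.integer(n_matches > 1), row.names = NULL)
}

#' 2D / 3D scatter plot with the suite palette
#'
#' @param table data.frame of per-sample or per-feature values.
#' @param x_col,y_col numeric columns to plot.
#' @param z_col optional third numeric column; when given a 3D cloud is drawn.
#' @param groups optional vector of group labels (one per row) for coloring.
#' @param palette palette name, see [mf_palette()].
#' @return a ggplot object (2D) or lattice cloud (3D).
#' @export
scatter_plot <- function(table, x_col, y_col, z_col = NULL, groups = NULL,
                         palette = getOption("metaboflag.palette", "secim")) {
  table <- as.data.frame(table)
  for (cn in c(x_col, y_col, z_col)) {
    if (!cn %in% names(table)) stop_mf("no column '%s'", cn)
    if (!is.numeric(table[[cn]])) stop_mf("column '%s' is not numeric", cn)
  }
  grp <- factor(groups %||% rep("all", nrow(table)))
  cols <- group_colors(grp, palette)
  if (!is.null(z_col)) {
    df <- data.frame(x = table[[x_col]], y = table[[y_col]],
                     z = table[[z_col]], group = grp)
    return(lattice::cloud(z ~ x * y, data = df, groups = df$group,
                          xlab = x_col, ylab = y_col, zlab = z_col,
                          par.settings = list(superpose.symbol = list(col = cols)),
                          auto.key = TRUE))
  }
  df <- data.frame(x = table[[x_col]], y = table[[y_col]], group = grp)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, color = group)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = cols) +
    ggplot2::labs(x = x_col, y = y_col) +
    ggplot2::theme_minimal()
}
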