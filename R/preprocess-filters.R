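#' Blank feature filtering (BFF) flags
#'
#' Derives a per-feature limit of detection (LOD) from blank samples and flags
#' features whose group mean intensity is not distinguishable from background:
#' `LOD = mean(blank) + k_sd * sd(blank)` (sd taken as 0 when only one blank
#' value is available), and a group is flagged when its mean is below
#' `multiplier * LOD`. Features missing in all blanks get `LOD = 0` and are
#' never flagged (logged).
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param group_col design column holding group labels.
#' @param blank_group label of the blank group in `group_col`.
#' @param k_sd number of blank standard deviations added to the blank mean.
#' @param multiplier scale factor applied to the LOD before comparison.
#' @return a `flag_table` over features with one `flag_bff_<group>` column per
#'   non-blank group and a combined `flag_bff_all` column (1 when flagged in
#'   every non-blank group). The computed LOD is attached as attribute `lod`.
#' @export
blank_feature_filter <- function(wide, design, group_col = "group",
                                 blank_group, k_sd = 3, multiplier = 1) {
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  if (!blank_group %in% grp)
    stop_mf("blank group '%s' not present in design column '%s'",
            blank_group, group_col)

  blanks <- wide$values[, grp == blank_group, drop = FALSE]
  n_obs <- rowSums(!is.na(blanks))
  bmean <- rowMeans(blanks, na.rm = TRUE)
  bsd <- row_sds(blanks)
  bsd[n_obs <= 1] <- 0
  lod <- bmean + k_sd * bsd
  all_missing <- n_obs == 0
  lod[all_missing] <- 0
  if (any(all_missing))
    mf_log(sum(all_missing), " feature(s) missing in all blanks: LOD set to 0, never flagged")

  groups <- setdiff(unique(grp), blank_group)
  flags <- lapply(groups, function(g) {
    gm <- rowMeans(wide$values[, grp == g, drop = FALSE], na.rm = TRUE)
    as.integer(!all_missing & !is.na(gm) & gm < multiplier * lod)
  })
  names(flags) <- paste0("flag_bff_", groups)
  flags <- as.data.frame(flags, optional = TRUE)
  flags$flag_bff_all <- as.integer(rowSums(flags) == length(groups))
  mf_log("BFF: ", sum(flags$flag_bff_all), " of ", n_features(wide),
         " features flagged in all groups")
  out <- flag_table(feature_ids(wide), flags, id_col = "rowID")
  attr(out, "lod") <- lod
  out
}

#' Threshold-based flags
#'
#' Flags a feature within a group when strictly more than 50% of that group's
#' samples fall below a user-given intensity threshold. Missing values count
#' as below the threshold (missingness in MS data typically means below
#' detection).
#'
#' @param wide a `feature_table`.
#' @param design a `design_table`.
#' @param group_col design column holding group labels.
#' @param cutoff intensity threshold.
#' @return a `flag_table` over features with one `flag_threshold_<group>`
#'   column per group.
#' @export
threshold_flags <- function(wide, design, group_col = "group", cutoff) {
  al <- align_tables(wide, design)
  wide <- al$wide; design <- al$design
  grp <- design_groups(design, group_col)
  groups <- unique(grp)
  flags <- lapply(groups, function(g) {
    sub <- wide$values[, grp == g, drop = FALSE]
    below <- rowSums(is.na(sub) | sub < cutoff)
    as.integer(below / ncol(sub) > 0.5)    # strictly more than half
  })
  names(flags) <- paste0("flag_threshold_", groups)
  out <- flag_table(feature_ids(wide), as.data.frame(flags, optional = TRUE))
  mf_log("threshold flags: ", sum(rowSums(as.data.frame(out)[-1]) > 0),
         " feature(s) flagged in at least one group")
  out
}
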