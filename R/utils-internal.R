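# Internal helpers shared across the suite: user-facing error signalling,
# leveled logging, and the common plot palette.

# Validation failures are signalled with class "mf_error" so the CLI can map
# them to exit code 1 (internal faults map to 2).
stop_mf <- function(fmt, ...) {
  msg <- if (length(list(...)) > 0L) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c("mf_error", "error", "condition")))
}

.mf_levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)

#' Leveled logging for metaboflag tools
#'
#' Every tool logs dropped/flagged counts at INFO. The threshold is read from
#' `options(metaboflag.log_level = )`; messages below it are suppressed.
#'
#' @param ... character pieces pasted into the message.
#' @param level one of "DEBUG", "INFO", "WARN", "ERROR".
#' @return `NULL`, invisibly.
#' @export
mf_log <- function(..., level = "INFO") {
  level <- match.arg(level, names(.mf_levels))
  threshold <- getOption("metaboflag.log_level", "INFO")
  if (!threshold %in% names(.mf_levels)) threshold <- "INFO"
  if (.mf_levels[[level]] >= .mf_levels[[threshold]]) {
    message(sprintf("[metaboflag %s] %s", level, paste0(...)))
  }
  invisible(NULL)
}

#' Suite color palette
#'
#' One palette shared by every plotting tool so that a group keeps the same
#' color across all figures of an analysis.
#'
#' @param n number of colors.
#' @param name palette name; "secim" is the fixed house palette, anything else
#'   is forwarded to [grDevices::hcl.colors()].
#' @return character vector of `n` colors.
#' @export
mf_palette <- function(n, name = getOption("metaboflag.palette", "secim")) {
  base <- c("#1B9E77", "#D95F02", "#7570B3", "#E7298A",
            "#66A61E", "#E6AB02", "#A6761D", "#666666")
  if (identical(name, "secim")) {
    if (n <= length(base)) return(base[seq_len(n)])
    return(grDevices::colorRampPalette(base)(n))
  }
  grDevices::hcl.colors(n, palette = name)
}

#' Stable group-to-color mapping
#'
#' @param groups vector of group labels.
#' @param name palette name, see [mf_palette()].
#' @return named character vector, one color per distinct group (sorted order,
#'   so the mapping is identical across tools for the same group set).
#' @export
group_colors <- function(groups, name = getOption("metaboflag.palette", "secim")) {
  lev <- sort(unique(as.character(groups)))
  stats::setNames(mf_palette(length(lev), name), lev)
}

# sample sd by row that tolerates missing values; n-1 denominator throughout
row_sds <- function(m) {
  n <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  ss <- rowSums((m - mu)^2, na.rm = TRUE)
  out <- sqrt(ss / (n - 1))
  out[n < 2] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
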