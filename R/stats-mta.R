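#' Multiple-testing adjustment (MTA)
#'
#' Adjusts raw p-values by any of Bonferroni (`min(1, m * p)`),
#' Benjamini-Hochberg step-up, and Benjamini-Yekutieli (BH inflated by
#' `sum_{i=1..m} 1/i`, capped at 1). Missing p-values propagate; values
#' outside `[0, 1]` are an error. Output carries one column per requested
#' method next to the raw values.
#'
#' @param p numeric vector of raw p-values.
#' @param methods subset of `"bonferroni"`, `"bh"`, `"by"`.
#' @param ids optional identifier column for the output.
#' @return data.frame with columns `p_raw` and `p_<method>`.
#' @export
adjust_pvalues <- function(p, methods = c("bonferroni", "bh", "by"),
                           ids = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  p <- as.numeric(p)
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad))
    stop_mf("p-values outside [0, 1] at position(s): %s",
            paste(utils::head(which(bad), 10), collapse = ", "))
  out <- data.frame(p_raw = p)
  if (!is.null(ids)) out <- cbind(data.frame(featureID = ids), out)
  map <- c(bonferroni = "bonferroni", bh = "BH", by = "BY")
  for (m in methods)
    out[[paste0("p_", m)]] <- stats::p.adjust(p, method = map[[m]])
  out
}
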