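# In-code fixtures shared across tests. Logging is silenced so test output
# stays readable; individual tests re-enable it when they assert on logs.
options(metaboflag.log_level = "ERROR")

# wide table from a features x samples matrix (values filled by column)
make_wide <- function(values, n_features = NULL, n_samples = NULL,
                      feature_ids = NULL, sample_ids = NULL, annotations = NULL) {
  if (!is.matrix(values))
    values <- matrix(values, nrow = n_features, ncol = n_samples)
  if (is.null(rownames(values)))
    rownames(values) <- feature_ids %||% sprintf("F%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sample_ids %||% sprintf("S%02d", seq_len(ncol(values)))
  feature_table(values, annotations = annotations)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_design <- function(sample_ids, group = NULL, ...) {
  df <- data.frame(sampleID = sample_ids, stringsAsFactors = FALSE)
  if (!is.null(group)) df$group <- group
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  design_table(df, id_col = "sampleID")
}

# two-group wide + design in one call: one row per feature, per-group values
make_two_group <- function(g1, g2, feature_ids = NULL) {
  stopifnot(is.matrix(g1), is.matrix(g2), nrow(g1) == nrow(g2))
  v <- cbind(g1, g2)
  colnames(v) <- c(sprintf("A%02d", seq_len(ncol(g1))),
                   sprintf("B%02d", seq_len(ncol(g2))))
  rownames(v) <- feature_ids %||% sprintf("F%03d", seq_len(nrow(v)))
  list(wide = feature_table(v),
       design = make_design(colnames(v),
                            group = rep(c("A", "B"), c(ncol(g1), ncol(g2)))))
}
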