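#' Specification for synthetic feature-table generation
#'
#' Describes a simulated LC-MS feature-table experiment: Gaussian feature
#' intensities around a common baseline, optional group mean shifts on a
#' leading block of "signal" features, optional linear run-order drift on a
#' trailing block of "drift" features, missing-completely-at-random dropout,
#' and an optional block of blank (background) samples at a low intensity
#' level. Used throughout the test-suite and by validation scripts; the
#' generator is first-class, seeded and bit-reproducible.
#'
#' @param n_features number of features (rows).
#' @param n_samples_per_group samples per biological group.
#' @param groups character vector of group labels.
#' @param n_signal number of leading features carrying a group effect.
#' @param effect_sizes intensity shift added per group step on signal features
#'   (recycled over the signal block). Group `j` is shifted by
#'   `effect_sizes * (j - 1)`.
#' @param noise_sd residual standard deviation of every intensity.
#' @param baseline common mean intensity.
#' @param missing_rate probability a cell is set missing, in `[0, 1]`.
#' @param n_drift number of trailing features with run-order drift.
#' @param run_order_slope intensity change per run-order unit on drift
#'   features (recycled over the drift block).
#' @param n_blanks number of blank samples appended (group label `blank_group`).
#' @param blank_level mean intensity of blank samples.
#' @param blank_group label of the blank group.
#' @param seed RNG seed; identical specs generate identical tables.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_features = 500, n_samples_per_group = 10,
                           groups = c("A", "B"), n_signal = 0, effect_sizes = 0,
                           noise_sd = 1, baseline = 100, missing_rate = 0,
                           n_drift = 0, run_order_slope = 0, n_blanks = 0,
                           blank_level = 5, blank_group = "blank", seed = 1) {
  if (n_features < 1 || n_samples_per_group < 1)
    stop_mf("counts must be >= 1")
  if (missing_rate < 0 || missing_rate > 1)
    stop_mf("missing_rate must be in [0, 1]")
  if (n_signal > n_features || n_drift > n_features)
    stop_mf("signal/drift feature counts cannot exceed n_features")
  if (length(groups) < 1) stop_mf("at least one group required")
  structure(list(n_features = n_features,
                 n_samples_per_group = n_samples_per_group,
                 groups = as.character(groups), n_signal = n_signal,
                 effect_sizes = effect_sizes, noise_sd = noise_sd,
                 baseline = baseline, missing_rate = missing_rate,
                 n_drift = n_drift, run_order_slope = run_order_slope,
                 n_blanks = n_blanks, blank_level = blank_level,
                 blank_group = blank_group, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic feature table and matching design
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `wide` (a `feature_table` with m/z and RT
#'   annotations), `design` (a `design_table` with columns `sampleID`,
#'   `group`, `run_order`), and `truth` (which features carry signal/drift).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    grp <- rep(spec$groups, each = spec$n_samples_per_group)
    sid <- paste0(grp, "_", unlist(lapply(spec$groups, function(g)
      sprintf("%02d", seq_len(spec$n_samples_per_group)))))
    if (spec$n_blanks > 0) {
      grp <- c(grp, rep(spec$blank_group, spec$n_blanks))
      sid <- c(sid, sprintf("%s_%02d", spec$blank_group, seq_len(spec$n_blanks)))
    }
    ns <- length(sid)
    nf <- spec$n_features
    run_order <- sample.int(ns)

    values <- matrix(stats::rnorm(nf * ns, mean = spec$baseline, sd = spec$noise_sd),
                     nrow = nf, ncol = ns,
                     dimnames = list(sprintf("F%04d", seq_len(nf)), sid))

    signal_idx <- seq_len(spec$n_signal)
    if (spec$n_signal > 0) {
      eff <- rep_len(spec$effect_sizes, spec$n_signal)
      gstep <- match(grp, spec$groups) - 1L   # NA for blanks
      for (j in which(!is.na(gstep) & gstep > 0L))
        values[signal_idx, j] <- values[signal_idx, j] + eff * gstep[j]
    }

    drift_idx <- if (spec$n_drift > 0) nf - seq_len(spec$n_drift) + 1L else integer()
    if (spec$n_drift > 0) {
      slope <- rep_len(spec$run_order_slope, spec$n_drift)
      bio <- grp != spec$blank_group
      values[drift_idx, bio] <- values[drift_idx, bio] +
        outer(slope, run_order[bio])
    }

    if (spec$n_blanks > 0) {
      blank <- grp == spec$blank_group
      values[, blank] <- matrix(
        stats::rnorm(nf * sum(blank), mean = spec$blank_level, sd = spec$noise_sd),
        nrow = nf)
    }

    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(nf * ns) < spec$missing_rate, nrow = nf)
      values[mask] <- NA_real_
    }

    ann <- data.frame(mz = round(stats::runif(nf, 50, 1000), 4),
                      rt = round(stats::runif(nf, 0.5, 20), 3))
    wide <- feature_table(values, annotations = ann)
    design <- design_table(data.frame(sampleID = sid, group = grp,
                                      run_order = run_order,
                                      stringsAsFactors = FALSE),
                           id_col = "sampleID")
    list(wide = wide, design = design,
         truth = list(signal_features = rownames(values)[signal_idx],
                      drift_features = rownames(values)[drift_idx]))
  })
}
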