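#' Configuration for discriminant feature selection
#'
#' @param n_iterations number of balanced subsampling iterations (default
#'   100).
#' @param min_group minimum samples required per group (default 10).
#' @param effect_threshold minimum absolute effect to enter scoring: 0.1 on
#'   the PSI difference scale; a sensible gene-mode value is 2 on the log2
#'   fold-change scale.
#' @param discretization `"mdlp"` (supervised, default) or
#'   `"equal_frequency"`.
#' @param seed master seed; per-iteration streams are derived
#'   deterministically from it.
#' @return list of class `selection_config`.
#' @export
selection_config <- function(n_iterations = 100L, min_group = 10L,
                             effect_threshold = 0.1,
                             discretization = c("mdlp", "equal_frequency"),
                             seed = 1L) {
  stopifnot(n_iterations >= 1L, min_group >= 2L)
  structure(
    list(n_iterations = as.integer(n_iterations), min_group = as.integer(min_group),
         effect_threshold = effect_threshold,
         discretization = match.arg(discretization), seed = as.integer(seed)),
    class = "selection_config"
  )
}

# balanced draw: per tumor type present in both groups, draw the per-type
# minimum group size from each group (single-type designs reduce to
# min(|early|, |late|) from each group).
balanced_draw <- function(design) {
  tt <- design$tumor_type_of
  types <- intersect(unique(tt[design$early]), unique(tt[design$late]))
  sub_e <- character(0)
  sub_l <- character(0)
  for (ty in types) {
    e <- design$early[tt[design$early] == ty]
    l <- design$late[tt[design$late] == ty]
    k <- min(length(e), length(l))
    if (k < 1L) next
    sub_e <- c(sub_e, if (length(e) == k) e else sample(e, k))
    sub_l <- c(sub_l, if (length(l) == k) l else sample(l, k))
  }
  list(early = sub_e, late = sub_l)
}

#' Permutation-calibrated discriminant feature selection
#'
#' The core selection procedure: features whose full-cohort effect passes
#' the threshold (|delta PSI| >= 0.1, or the log-fold gate in gene mode) are
#' scored over `n_iterations` balanced subsampling iterations. Each
#' iteration draws the same number of samples from each group (for pooled
#' multi-type designs, the same number per tumor type), discretizes each
#' candidate feature on the drawn subset, computes information gain, gain
#' ratio, and symmetrical uncertainty against the group labels, then
#' permutes the labels of the drawn subset uniformly at random and
#' recomputes the three measures as the permutation null. A feature is
#' discriminant when it passes the effect gate and its mean observed value
#' exceeds its mean permuted value for all three measures. The whole
#' procedure is reproducible from `cfg$seed`.
#'
#' @param features a `psi_matrix` or numeric feature x sample matrix.
#' @param design a `comparison_design` with both groups of size at least
#'   `cfg$min_group`.
#' @param effects an `effect_table` from [effect_sizes()] on the same
#'   design.
#' @param cfg a `selection_config`.
#' @return data.frame of class `discriminant_stats` with per-feature
#'   columns `feature_id`, `delta`, `obs_IG`, `obs_GR`, `obs_SU`,
#'   `null_IG`, `null_GR`, `null_SU`, `n_iterations_used`, `discriminant`.
#'   Features failing the effect gate carry NA measures and are never
#'   discriminant.
#' @export
subsample_selection <- function(features, design, effects, cfg = selection_config()) {
  stopifnot(inherits(design, "comparison_design"), inherits(effects, "effect_table"))
  if (length(design$early) < cfg$min_group || length(design$late) < cfg$min_group) {
    stopf("design '%s' has a group below min_group = %d (%d early, %d late)",
          design$class_name, cfg$min_group, length(design$early), length(design$late))
  }
  m <- feature_values(features)
  gate <- abs(effects$delta) >= cfg$effect_threshold
  cand <- effects$feature_id[gate]
  nc <- length(cand)
  obs_sum <- matrix(0, nrow = 3L, ncol = nc, dimnames = list(c("IG", "GR", "SU"), cand))
  null_sum <- obs_sum

  if (nc > 0L) {
    mc <- m[cand, , drop = FALSE]
    for (it in seq_len(cfg$n_iterations)) {
      with_seed(derive_seed(cfg$seed, it), {
        draw <- balanced_draw(design)
        ids <- c(draw$early, draw$late)
        labels <- c(rep(0L, length(draw$early)), rep(1L, length(draw$late)))
        perm <- sample(labels)
        sub <- mc[, ids, drop = FALSE]
        for (j in seq_len(nc)) {
          v <- sub[j, ]
          obs_sum[, j] <- obs_sum[, j] + score_feature(v, labels, cfg$discretization)
          null_sum[, j] <- null_sum[, j] + score_feature(v, perm, cfg$discretization)
        }
      })
    }
  }

  obs <- obs_sum / cfg$n_iterations
  nul <- null_sum / cfg$n_iterations
  idx <- match(effects$feature_id, cand)
  pick <- function(meas, mat) {
    res <- rep(NA_real_, length(idx))
    ok <- !is.na(idx)
    if (any(ok)) res[ok] <- mat[meas, idx[ok]]
    res
  }
  out <- data.frame(
    feature_id = effects$feature_id,
    delta = effects$delta,
    obs_IG = pick("IG", obs), obs_GR = pick("GR", obs), obs_SU = pick("SU", obs),
    null_IG = pick("IG", nul), null_GR = pick("GR", nul), null_SU = pick("SU", nul),
    n_iterations_used = ifelse(gate, cfg$n_iterations, 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$discriminant <- gate &
    !is.na(out$obs_IG) &
    (out$obs_IG - out$null_IG > 0) &
    (out$obs_GR - out$null_GR > 0) &
    (out$obs_SU - out$null_SU > 0)
  attr(out, "config") <- cfg
  class(out) <- c("discriminant_stats", "data.frame")
  out
}

#' Write discriminant statistics as TSV with a config header
#'
#' @param stats a `discriminant_stats` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_discriminant_stats <- function(stats, path) {
  cfg <- attr(stats, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) {
    writeLines(sprintf(
      "# isosig selection: n_iterations=%d min_group=%d effect_threshold=%g discretization=%s seed=%d",
      cfg$n_iterations, cfg$min_group, cfg$effect_threshold, cfg$discretization, cfg$seed
    ), con)
  }
  utils::write.table(stats, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
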