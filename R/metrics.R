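#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Computed from ranks: the probability that a randomly chosen positive
#' (late) sample scores higher than a randomly chosen negative one, with
#' tied scores contributing 1/2 per pair.
#'
#' @param scores numeric scores (higher = more late-like).
#' @param labels binary labels (1 = late/positive).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("AUC needs both classes")
  r <- rank(scores)  # mean ranks handle ties as half-pairs
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-wise (achievable) interpolation: samples are swept in decreasing
#' score order, tied scores as one block, and each recall increment is
#' weighted by the precision attained at that threshold. This avoids the
#' optimistic bias of trapezoidal interpolation in precision-recall space.
#'
#' @param scores numeric scores (higher = more late-like).
#' @param labels binary labels (1 = late/positive).
#' @return area in [0, 1].
#' @export
prc_area <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- sum(labels == 1L)
  if (pos == 0L) stopf("PRC needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  block <- cumsum(!duplicated(s))
  tp <- cumsum(y)
  fp <- cumsum(1L - y)
  last <- !duplicated(block, fromLast = TRUE)  # end of each tie block
  tp <- tp[last]
  fp <- fp[last]
  recall <- tp / pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Repeated stratified cross-validation of a logistic model tree
#'
#' Stratified `folds`-fold cross-validation repeated `repeats` times. Each
#' held-out fold yields one AUC and one area under the precision-recall
#' curve from the fold's predicted late-class probabilities; the result
#' aggregates all fold-level values. When the minority class has fewer
#' members than `folds`, the fold count is reduced to the minority count
#' (logged) so every fold contains both classes.
#'
#' @param X samples x features numeric matrix.
#' @param y binary labels (1 = late).
#' @param cfg an [lmt_config()]; `cfg$folds` and `cfg$repeats` control the
#'   evaluation, `cfg$seed` makes it reproducible.
#' @return an object of class `cv_result`: list with `auc` and `prc`
#'   vectors (length folds x repeats) and a `summary` matrix of min, mean,
#'   max per metric.
#' @export
cross_validate <- function(X, y, cfg = lmt_config()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!is.null(rownames(X))) {
    # canonical sample order, so the result depends on the data and seed
    # but not on the order samples happen to arrive in
    ord <- order(rownames(X))
    X <- X[ord, , drop = FALSE]
    y <- y[ord]
  }
  minority <- min(table(y))
  if (minority < 2L) stopf("minority class has fewer than 2 members")
  folds <- cfg$folds
  if (minority < folds) {
    isosig_log(sprintf("cross_validate: folds reduced from %d to %d (minority class size)",
                       folds, minority))
    folds <- minority
  }
  auc <- numeric(0)
  prc <- numeric(0)
  for (rep_i in seq_len(cfg$repeats)) {
    assign <- with_seed(derive_seed(cfg$seed, 100L + rep_i), stratified_folds(y, folds))
    for (k in seq_len(folds)) {
      te <- assign == k
      fit_cfg <- cfg
      fit_cfg$seed <- derive_seed(cfg$seed, 1000L * rep_i + k)
      model <- fit_lmt(X[!te, , drop = FALSE], y[!te], fit_cfg)
      pr <- predict_proba(model, X[te, , drop = FALSE])
      auc <- c(auc, auc_score(pr, y[te]))
      prc <- c(prc, prc_area(pr, y[te]))
    }
  }
  structure(
    list(auc = auc, prc = prc,
         summary = rbind(auc = c(min = min(auc), mean = mean(auc), max = max(auc)),
                         prc = c(min = min(prc), mean = mean(prc), max = max(prc)))),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation over %d folds: AUC %.3f [%.3f, %.3f], PRC %.3f [%.3f, %.3f]\n",
              length(x$auc),
              x$summary["auc", "mean"], x$summary["auc", "min"], x$summary["auc", "max"],
              x$summary["prc", "mean"], x$summary["prc", "min"], x$summary["prc", "max"]))
  invisible(x)
}

#' Train a signature: CFS, logistic model tree, and cross-validated accuracy
#'
#' The signature pipeline over an arbitrary feature table: restrict to
#' discriminant features, remove redundancy with [cfs_select()], fit a
#' logistic model tree on the selected subset, and estimate accuracy with
#' repeated stratified cross-validation. The operation is agnostic to
#' feature provenance — isoform PSI, gene TPM, event PSI, or a mixture
#' (rbind the matrices) run identically.
#'
#' @param features a `psi_matrix` or numeric feature x sample matrix.
#' @param design a `comparison_design`.
#' @param selection a `discriminant_stats` table from
#'   [subsample_selection()] (or any data.frame with `feature_id` and
#'   `discriminant` columns).
#' @param cfg an [lmt_config()].
#' @return list of class `signature` with elements `model` (`lmt_model`),
#'   `cv` (`cv_result`), `features` (selected ids), and `design_class`.
#' @export
train_signature <- function(features, design, selection, cfg = lmt_config()) {
  m <- feature_values(features)
  cand <- selection$feature_id[selection$discriminant]
  if (length(cand) == 0L) stopf("no discriminant features")
  samples <- c(design$early, design$late)
  y <- unname(design_labels(design))
  sel <- cfs_select(m[cand, samples, drop = FALSE], y)
  X <- t(m[sel, samples, drop = FALSE])
  model <- fit_lmt(X, y, cfg)
  cv <- cross_validate(X, y, cfg)
  structure(list(model = model, cv = cv, features = as.character(sel),
                 merit = attr(sel, "merit"), design_class = design$class_name),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("signature for class '%s': %d features (CFS merit %.3f), mean CV AUC %.3f\n",
              x$design_class, length(x$features), x$merit,
              x$cv$summary["auc", "mean"]))
  invisible(x)
}
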