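#' Configuration for logistic model trees and cross-validation
#'
#' @param min_split minimum samples in each child for a split to be
#'   admissible (default 15).
#' @param max_depth maximum tree depth considered; the actual depth is
#'   chosen by internal cross-validation between 0 (a single boosted
#'   logistic leaf) and this bound.
#' @param boost_iter maximum LogitBoost iterations; the count actually used
#'   is chosen once by internal 5-fold cross-validation and reused at every
#'   leaf.
#' @param cv_folds folds of the internal model-selection cross-validation.
#' @param folds,repeats folds and repeats of the outer evaluation
#'   cross-validation ([cross_validate()]); ten folds repeated 100 times is
#'   the production setting, smaller repeats keep test runs short.
#' @param seed seed for all classifier randomness.
#' @return list of class `lmt_config`.
#' @export
lmt_config <- function(min_split = 15L, max_depth = 2L, boost_iter = 200L,
                       cv_folds = 5L, folds = 10L, repeats = 10L, seed = 1L) {
  structure(list(min_split = as.integer(min_split), max_depth = as.integer(max_depth),
                 boost_iter = as.integer(boost_iter), cv_folds = as.integer(cv_folds),
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)),
            class = "lmt_config")
}

# Best information-gain binary split over all features and midpoint
# thresholds, requiring min_split samples in each child. Returns NULL when
# no admissible split improves on the parent entropy.
best_split <- function(X, y, min_split) {
  n <- length(y)
  h_parent <- entropy_counts(table(y))
  best <- NULL
  best_gain <- 1e-9
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    ys <- y[ord]
    cum1 <- cumsum(ys == 1L)
    tot1 <- cum1[n]
    cand <- which(xs[-n] < xs[-1L])
    cand <- cand[cand >= min_split & (n - cand) >= min_split]
    if (length(cand) == 0L) next
    nl <- cand
    l1 <- cum1[cand]
    hl <- vapply(seq_along(cand), function(i) entropy_counts(c(l1[i], nl[i] - l1[i])), 0)
    hr <- vapply(seq_along(cand), function(i) {
      entropy_counts(c(tot1 - l1[i], (n - nl[i]) - (tot1 - l1[i])))
    }, 0)
    gain <- h_parent - (nl * hl + (n - nl) * hr) / n
    i <- which.max(gain)
    if (gain[i] > best_gain) {
      best_gain <- gain[i]
      best <- list(feature = colnames(X)[j],
                   threshold = (xs[cand[i]] + xs[cand[i] + 1L]) / 2,
                   gain = gain[i])
    }
  }
  best
}

grow_lmt <- function(X, y, depth_left, n_boost, cfg) {
  pure <- length(unique(y)) < 2L
  if (depth_left <= 0L || pure || nrow(X) < 2L * cfg$min_split) {
    return(list(kind = "leaf",
                model = fit_simple_logistic(X, y, n_iter = n_boost)))
  }
  sp <- best_split(X, y, cfg$min_split)
  if (is.null(sp)) {
    return(list(kind = "leaf",
                model = fit_simple_logistic(X, y, n_iter = n_boost)))
  }
  left <- X[, sp$feature] <= sp$threshold
  list(kind = "split", feature = sp$feature, threshold = sp$threshold,
       left = grow_lmt(X[left, , drop = FALSE], y[left], depth_left - 1L, n_boost, cfg),
       right = grow_lmt(X[!left, , drop = FALSE], y[!left], depth_left - 1L, n_boost, cfg))
}

predict_lmt_node <- function(node, X) {
  if (node$kind == "leaf") return(predict_simple_logistic(node$model, X))
  out <- numeric(nrow(X))
  left <- X[, node$feature] <= node$threshold
  if (any(left)) out[left] <- predict_lmt_node(node$left, X[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_lmt_node(node$right, X[!left, , drop = FALSE])
  out
}

#' Fit a logistic model tree
#'
#' A classification tree grown by information-gain splits whose leaves hold
#' additive logistic models fitted by LogitBoost with one-variable
#' least-squares base learners. Two model-selection choices are made by
#' internal stratified cross-validation on the training data: the LogitBoost
#' iteration count (chosen once at the root and reused at every leaf) and
#' the tree depth, from 0 (a single boosted logistic regression over all
#' features) up to `cfg$max_depth` — depth selection is the pruning step,
#' collapsing subtrees that do not reduce cross-validated error. Missing
#' feature values are imputed with training-data medians; the medians are
#' stored in the model so prediction imputes identically.
#'
#' @param X samples x features numeric matrix (column names required).
#' @param y binary labels (0 = early, 1 = late) aligned with rows of `X`.
#' @param cfg an [lmt_config()].
#' @return an object of class `lmt_model`.
#' @export
fit_lmt <- function(X, y, cfg = lmt_config()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stopf("fit_lmt requires both classes in y")
  if (nrow(X) != length(y)) stopf("X rows and y length differ")

  med <- apply(X, 2L, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  X <- impute_median(X, med)

  n_boost <- cv_boost_iterations(X, y, cfg$boost_iter, cfg$cv_folds,
                                 derive_seed(cfg$seed, 1L))

  depths <- 0:cfg$max_depth
  if (cfg$max_depth > 0L && nrow(X) >= 2L * cfg$min_split) {
    folds <- with_seed(derive_seed(cfg$seed, 2L),
                       stratified_folds(y, min(cfg$cv_folds, min(table(y)))))
    err <- vapply(depths, function(d) {
      e <- 0
      for (k in unique(folds)) {
        te <- folds == k
        if (length(unique(y[!te])) < 2L) return(Inf)
        tree <- grow_lmt(X[!te, , drop = FALSE], y[!te], d, n_boost, cfg)
        pr <- predict_lmt_node(tree, X[te, , drop = FALSE])
        e <- e + sum((pr > 0.5) != (y[te] == 1L))
      }
      e
    }, 0)
    depth <- depths[which.min(err)]  # ties favor the shallower tree
  } else {
    depth <- 0L
  }

  tree <- grow_lmt(X, y, depth, n_boost, cfg)
  structure(list(feature_ids = colnames(X), tree = tree, depth = depth,
                 n_boost = n_boost, medians = med,
                 class_labels = c("early", "late"), config = cfg),
            class = "lmt_model")
}

impute_median <- function(X, med) {
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (any(na)) X[na, j] <- med[j]
  }
  X
}

#' Predict late-class probabilities with a logistic model tree
#'
#' @param model an `lmt_model`.
#' @param X samples x features matrix providing every model feature (extra
#'   columns are ignored; missing values are imputed with the training
#'   medians stored in the model).
#' @return numeric vector of probabilities of the late class, in [0, 1].
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "lmt_model"))
  X <- as.matrix(X)
  miss <- setdiff(model$feature_ids, colnames(X))
  if (length(miss)) {
    stopf("matrix lacks model features: %s", paste(miss, collapse = ", "))
  }
  X <- impute_median(X[, model$feature_ids, drop = FALSE], model$medians)
  predict_lmt_node(model$tree, X)
}

#' @export
predict.lmt_model <- function(object, newdata, ...) predict_proba(object, newdata)

#' @export
print.lmt_model <- function(x, ...) {
  n_leaves <- function(node) {
    if (node$kind == "leaf") 1L else n_leaves(node$left) + n_leaves(node$right)
  }
  cat(sprintf("logistic model tree: %d features, depth %d, %d leaves, %d boosting iterations\n",
              length(x$feature_ids), x$depth, n_leaves(x$tree), x$n_boost))
  invisible(x)
}

#' Serialize a logistic model tree to a self-describing JSON document
#'
#' @param model an `lmt_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  ser_node <- function(node) {
    if (node$kind == "leaf") {
      list(kind = "leaf", beta0 = node$model$beta0,
           beta = as.list(node$model$beta), n_iter = node$model$n_iter)
    } else {
      list(kind = "split", feature = node$feature, threshold = node$threshold,
           left = ser_node(node$left), right = ser_node(node$right))
    }
  }
  doc <- list(
    format = "isosig-lmt", version = 1L,
    feature_ids = model$feature_ids, depth = model$depth,
    n_boost = model$n_boost, medians = as.list(model$medians),
    class_labels = model$class_labels,
    config = unclass(model$config), tree = ser_node(model$tree)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized logistic model tree
#'
#' @param path path to a JSON file written by [write_model()].
#' @return an `lmt_model`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "isosig-lmt")) stopf("%s is not an isosig model file", path)
  de_node <- function(node) {
    if (node$kind == "leaf") {
      list(kind = "leaf",
           model = structure(list(beta0 = node$beta0,
                                  beta = unlist(node$beta),
                                  n_iter = node$n_iter),
                             class = "simple_logistic"))
    } else {
      list(kind = "split", feature = node$feature, threshold = node$threshold,
           left = de_node(node$left), right = de_node(node$right))
    }
  }
  cfg <- do.call(lmt_config, doc$config[names(doc$config) %in% names(formals(lmt_config))])
  structure(list(feature_ids = unlist(doc$feature_ids), tree = de_node(doc$tree),
                 depth = doc$depth, n_boost = doc$n_boost,
                 medians = unlist(doc$medians),
                 class_labels = unlist(doc$class_labels), config = cfg),
            class = "lmt_model")
}
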