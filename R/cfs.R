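# Symmetrical uncertainty between two discrete vectors, using complete
# pairs only.
su_discrete <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(0)
  unname(information_measures(a[ok], b[ok])["SU"])
}

# CFS merit of a subset given the feature-label correlations rcf and the
# feature-feature correlation matrix rff:
#   merit = k * mean(rcf) / sqrt(k + k (k-1) mean(rff))
cfs_merit <- function(subset, rcf, rff) {
  k <- length(subset)
  if (k == 0L) return(0)
  sum_cf <- sum(rcf[subset])
  sum_ff <- if (k > 1L) sum(rff[subset, subset]) - k else 0  # diagonal is 1
  sum_cf / sqrt(k + sum_ff)
}

#' Correlation feature selection (CFS) over discriminant candidates
#'
#' Selects a non-redundant subset of features that keeps discriminating
#' power while penalizing redundancy: the subset maximizing
#' \deqn{merit(F) = k \bar{r}_{cf} / \sqrt{k + k(k-1) \bar{r}_{ff}}}
#' where \eqn{\bar{r}_{cf}} is the mean feature-label correlation and
#' \eqn{\bar{r}_{ff}} the mean pairwise feature-feature correlation, both
#' measured as symmetrical uncertainty on MDLP-discretized values over the
#' full comparison cohort. Instances with at most `exact_limit` candidates
#' are solved by exhaustive subset enumeration (exact); larger instances use
#' best-first search with a stall limit.
#'
#' @param X numeric candidate-feature x sample matrix (discriminant
#'   features only).
#' @param labels binary group labels aligned with the columns of `X`.
#' @param exact_limit maximum number of candidates for exhaustive search.
#' @param stall_limit best-first expansions without improvement before the
#'   search stops.
#' @return character vector of selected feature ids (non-empty), ordered by
#'   decreasing feature-label correlation; the achieved merit is attached as
#'   attribute `merit`.
#' @export
cfs_select <- function(X, labels, exact_limit = 12L, stall_limit = 5L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 1L) stopf("cfs_select needs at least one candidate feature")
  if (ncol(X) != length(labels)) stopf("labels do not match matrix columns")
  ids <- rownames(X) %||% as.character(seq_len(n))

  bins <- lapply(seq_len(n), function(i) {
    v <- X[i, ]
    d <- fit_discretizer(v, labels)
    apply_discretizer(d, v)
  })
  rcf <- vapply(bins, su_discrete, 0, b = labels)
  rff <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        rff[i, j] <- rff[j, i] <- su_discrete(bins[[i]], bins[[j]])
      }
    }
  }

  best_subset <- which.max(rcf)
  best_merit <- cfs_merit(best_subset, rcf, rff)

  if (n <= exact_limit) {
    for (mask in seq_len(2^n - 1L)) {
      subset <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      m <- cfs_merit(subset, rcf, rff)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_subset <- subset
      }
    }
  } else {
    # best-first forward search over subsets keyed by sorted member string
    open <- list(list(subset = integer(0), merit = 0))
    visited <- new.env(hash = TRUE)
    stall <- 0L
    while (length(open) > 0L && stall < stall_limit) {
      scores <- vapply(open, `[[`, 0, "merit")
      pick <- which.max(scores)
      node <- open[[pick]]
      open[[pick]] <- NULL
      improved <- FALSE
      for (f in setdiff(seq_len(n), node$subset)) {
        subset <- sort(c(node$subset, f))
        key <- paste(subset, collapse = ",")
        if (!is.null(visited[[key]])) next
        visited[[key]] <- TRUE
        m <- cfs_merit(subset, rcf, rff)
        open[[length(open) + 1L]] <- list(subset = subset, merit = m)
        if (m > best_merit + 1e-12) {
          best_merit <- m
          best_subset <- subset
          improved <- TRUE
        }
      }
      stall <- if (improved) 0L else stall + 1L
    }
  }

  sel <- ids[best_subset[order(-rcf[best_subset])]]
  attr(sel, "merit") <- best_merit
  sel
}
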