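# Shannon entropy (base 2) from a vector of counts.
entropy_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Information gain, gain ratio, and symmetrical uncertainty
#'
#' Entropy-based dependence measures between a discretized feature A and a
#' binary group label S, all in bits:
#' \deqn{IG(S,A) = H(S) - H(S|A)}
#' \deqn{GR(S,A) = IG(S,A) / H(A)}
#' \deqn{SU(S,A) = 2 IG(S,A) / (H(S) + H(A))}
#' with the conventions GR = 0 when H(A) = 0 and SU = 0 when both entropies
#' are 0, so a constant feature scores 0 on all three. Entropies are
#' empirical plug-in estimates. SU is symmetric in its arguments.
#'
#' @param feature_bins integer/factor vector of discretized feature values.
#' @param labels binary label vector of the same length.
#' @return named numeric vector with elements `IG`, `GR`, `SU`.
#' @export
information_measures <- function(feature_bins, labels) {
  if (length(feature_bins) != length(labels)) {
    stopf("feature and label vectors differ in length (%d vs %d)",
          length(feature_bins), length(labels))
  }
  if (length(labels) < 2L) stopf("need at least 2 samples")
  tab <- table(feature_bins, labels)
  h_s <- entropy_counts(colSums(tab))
  h_a <- entropy_counts(rowSums(tab))
  n <- sum(tab)
  h_cond <- sum(apply(tab, 1L, function(row) sum(row) / n * entropy_counts(row)))
  ig <- max(0, h_s - h_cond)
  gr <- if (h_a > 0) ig / h_a else 0
  su <- if (h_s + h_a > 0) 2 * ig / (h_s + h_a) else 0
  c(IG = ig, GR = gr, SU = su)
}

# Fayyad-Irani MDLP recursive cut search on (values, binary labels).
# Returns the accepted cut points (midpoints between adjacent distinct
# values), possibly empty.
mdlp_cuts <- function(x, y) {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  n <- length(x)
  classes <- sort(unique(y))
  if (n < 4L || length(classes) < 2L || x[1L] == x[n]) return(numeric(0))

  is1 <- as.integer(y == classes[2L])
  cum1 <- cumsum(is1)
  tot1 <- cum1[n]
  # candidate split positions: after index i where the value changes
  cand <- which(x[-n] < x[-1L])
  if (length(cand) == 0L) return(numeric(0))

  nl <- cand
  nr <- n - cand
  l1 <- cum1[cand]
  r1 <- tot1 - l1
  ent2 <- function(a, b) {
    tot <- a + b
    p <- a / tot
    q <- b / tot
    h <- numeric(length(tot))
    pos <- p > 0
    h[pos] <- h[pos] - p[pos] * log2(p[pos])
    pos <- q > 0
    h[pos] <- h[pos] - q[pos] * log2(q[pos])
    h
  }
  ent_l <- ent2(l1, nl - l1)
  ent_r <- ent2(r1, nr - r1)
  e_split <- (nl * ent_l + nr * ent_r) / n
  best <- which.min(e_split)
  i <- cand[best]

  ent_s <- entropy_counts(c(tot1, n - tot1))
  gain <- ent_s - e_split[best]
  k <- 2L
  k1 <- length(unique(y[seq_len(i)]))
  k2 <- length(unique(y[(i + 1L):n]))
  delta <- log2(3^k - 2) - (k * ent_s - k1 * ent_l[best] - k2 * ent_r[best])
  if (gain <= (log2(n - 1) + delta) / n) return(numeric(0))

  cut <- (x[i] + x[i + 1L]) / 2
  left <- seq_len(i)
  right <- (i + 1L):n
  sort(c(mdlp_cuts(x[left], y[left]), cut, mdlp_cuts(x[right], y[right])))
}

#' Fit a per-feature discretizer
#'
#' The default strategy is supervised Fayyad-Irani MDLP: recursive binary
#' cuts accepted by the minimum-description-length criterion. When MDLP
#' accepts no cut the feature falls back to a single median cut (2 bins), so
#' every non-constant feature still contributes a total mapping of the real
#' line onto bins. A constant feature yields a degenerate single-bin
#' discretizer (it will score zero on all information measures). An
#' unsupervised equal-frequency alternative with `k` bins is provided for
#' auditability of the discretization choice.
#'
#' @param values numeric vector (NAs allowed; ignored for fitting).
#' @param labels binary labels aligned with `values` (used by MDLP only).
#' @param method `"mdlp"` or `"equal_frequency"`.
#' @param k number of bins for equal-frequency discretization.
#' @return an object of class `discretizer`: list with strictly increasing
#'   `cuts` and `n_bins`.
#' @export
fit_discretizer <- function(values, labels = NULL, method = c("mdlp", "equal_frequency"),
                            k = 3L) {
  method <- match.arg(method)
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) == 0L || min(x) == max(x)) {
    return(structure(list(cuts = numeric(0), n_bins = 1L, method = method),
                     class = "discretizer"))
  }
  cuts <- if (method == "mdlp") {
    if (is.null(labels)) stopf("MDLP discretization requires labels")
    mdlp_cuts(x, labels[ok])
  } else {
    unique(stats::quantile(x, probs = seq_len(k - 1L) / k, names = FALSE, type = 7L))
  }
  if (length(cuts) == 0L) {
    cut <- stats::median(x)
    if (cut >= max(x)) cut <- mean(range(x))
    cuts <- cut
  }
  cuts <- sort(unique(cuts))
  structure(list(cuts = cuts, n_bins = length(cuts) + 1L, method = method),
            class = "discretizer")
}

#' Map values onto the bins of a fitted discretizer
#'
#' @param d a `discretizer`.
#' @param values numeric vector; NA maps to NA.
#' @return integer bin indices in `1:n_bins`.
#' @export
apply_discretizer <- function(d, values) {
  if (length(d$cuts) == 0L) {
    return(ifelse(is.na(values), NA_integer_, 1L))
  }
  findInterval(values, d$cuts, left.open = TRUE) + 1L
}

# Convenience: discretize then score one feature against labels, using only
# non-missing pairs. Returns c(IG, GR, SU).
score_feature <- function(values, labels, method = "mdlp") {
  ok <- !is.na(values) & !is.na(labels)
  if (sum(ok) < 2L || length(unique(labels[ok])) < 2L) {
    return(c(IG = 0, GR = 0, SU = 0))
  }
  d <- fit_discretizer(values[ok], labels[ok], method = method)
  information_measures(apply_discretizer(d, values[ok]), labels[ok])
}
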