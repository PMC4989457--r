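# Independent oracles used across the suite. These deliberately take
# different computational routes than the package (joint-distribution
# identities, exhaustive enumeration, pair counting) so agreement is
# evidence of correctness rather than shared code.

# Entropy-based measures from the joint probability table, using the
# identity IG = H(S) + H(A) - H(A,S) (the package uses H(S) - H(S|A)).
oracle_info <- function(bins, labels) {
  n <- length(bins)
  ent <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  joint <- table(bins, labels) / n
  hs <- ent(colSums(joint))
  ha <- ent(rowSums(joint))
  has <- ent(as.vector(joint))
  ig <- max(0, hs + ha - has)
  c(IG = ig,
    GR = if (ha > 0) ig / ha else 0,
    SU = if (hs + ha > 0) 2 * ig / (hs + ha) else 0)
}

# CFS merit by direct formula from correlation inputs.
oracle_merit <- function(subset, rcf, rff) {
  k <- length(subset)
  if (k == 0) return(0)
  rbar_cf <- mean(rcf[subset])
  rbar_ff <- if (k > 1) mean(rff[subset, subset][upper.tri(diag(k))]) else 0
  k * rbar_cf / sqrt(k + k * (k - 1) * rbar_ff)
}

# Exhaustive best merit over all non-empty subsets.
oracle_best_merit <- function(rcf, rff) {
  n <- length(rcf)
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    subset <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
    best <- max(best, oracle_merit(subset, rcf, rff))
  }
  best
}

# AUC by counting concordant pairs (ties count one half).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins, summing probabilities not exceeding the observed one
# (with the conventional relative guard for float ties).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c
  nn <- b + d
  kk <- a + b
  lo <- max(0, kk - nn)
  hi <- min(kk, m)
  dens <- dhyper(lo:hi, m, nn, kk)
  sum(dens[dens <= dhyper(a, m, nn, kk) * (1 + 1e-7)])
}

# Two-sided exact Wilcoxon rank-sum p by enumeration of all assignments of
# the pooled ranks to the first group (untied data only).
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  w_all <- apply(combos, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mid <- nx * ny / 2
  p <- if (w_obs > mid) 2 * mean(w_all >= w_obs) else 2 * mean(w_all <= w_obs)
  min(1, p)
}

# Random valid exon tables designed to collide on splice sites: exon
# boundaries are drawn from a coarse grid.
random_annotation <- function(n_tx, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_tx), function(i) {
    n_ex <- sample(1:3, 1)
    bounds <- sort(sample(seq(10, 600, by = 20), 2 * n_ex))
    data.frame(
      transcript_id = sprintf("tx%02d", i),
      gene_id = NA_character_,
      chrom = sample(c("chr1", "chr2"), 1),
      strand = sample(c("+", "-"), 1),
      start = bounds[seq(1, 2 * n_ex, by = 2)],
      end = bounds[seq(2, 2 * n_ex, by = 2)],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Gene partition by brute-force transitive closure of the pairwise relation
# (span overlap AND same chrom/strand AND shared splice site), via boolean
# matrix powers.
oracle_gene_partition <- function(ann) {
  tx <- sort(unique(ann$transcript_id))
  n <- length(tx)
  ss <- lapply(tx, function(t) {
    d <- ann[ann$transcript_id == t, ]
    d <- d[order(d$start), ]
    if (nrow(d) < 2) integer(0) else c(d$end[-nrow(d)], d$start[-1])
  })
  span <- t(vapply(tx, function(t) {
    d <- ann[ann$transcript_id == t, ]
    c(min(d$start), max(d$end))
  }, c(0, 0)))
  meta <- t(vapply(tx, function(t) {
    d <- ann[ann$transcript_id == t, ]
    c(d$chrom[1], d$strand[1])
  }, c("", "")))
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (meta[i, 1] == meta[j, 1] && meta[i, 2] == meta[j, 2] &&
          span[i, 1] <= span[j, 2] && span[j, 1] <= span[i, 2] &&
          length(intersect(ss[[i]], ss[[j]])) > 0) {
        adj[i, j] <- TRUE
      }
    }
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- apply(reach, 1, function(r) paste(which(r), collapse = ","))
  split(tx, comp)
}

# Compare two partitions (lists of member vectors) ignoring names/order.
same_partition <- function(a, b) {
  norm <- function(p) {
    p <- lapply(p, sort)
    p[order(vapply(p, `[[`, "", 1))]
  }
  identical(unname(norm(a)), unname(norm(b)))
}
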