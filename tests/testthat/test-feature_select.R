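test_that("information measures match hand-worked cases and conventions", {
  # perfect predictor with balanced labels: IG = H(S) = 1 bit, GR = SU = 1
  y <- rep(c(0, 1), each = 10)
  expect_equal(unname(information_measures(y + 1, y)), c(1, 1, 1))
  # constant feature: all three zero by the H(A) = 0 convention
  expect_equal(unname(information_measures(rep(1, 20), y)), c(0, 0, 0))
  # counts {bin1: (3 early, 1 late), bin2: (1, 3)} worked by hand:
  # H(S) = 1, H(S|A) = 0.5 * H(3/4) + 0.5 * H(1/4) = 0.811278...
  bins <- c(rep(1, 4), rep(2, 4))
  labs <- c(0, 0, 0, 1, 0, 1, 1, 1)
  h_cond <- -(3 / 4 * log2(3 / 4) + 1 / 4 * log2(1 / 4))
  ig <- 1 - h_cond
  got <- information_measures(bins, labs)
  expect_equal(unname(got["IG"]), ig, tolerance = 1e-12)
  expect_equal(unname(got["GR"]), ig / 1, tolerance = 1e-12)  # H(A) = 1
  expect_equal(unname(got["SU"]), 2 * ig / 2, tolerance = 1e-12)
  # symmetry of SU in its arguments
  expect_equal(information_measures(bins, labs)["SU"],
               information_measures(labs, bins)["SU"])
  expect_error(information_measures(1:3, 1:4), "length")
})

test_that("information measures match the joint-entropy oracle on random instances", {
  set.seed(101)
  for (i in 1:400) {
    n <- sample(4:40, 1)
    bins <- sample(seq_len(sample(1:4, 1)), n, replace = TRUE)
    labs <- sample(0:1, n, replace = TRUE)
    got <- information_measures(bins, labs)
    want <- oracle_info(bins, labs)
    expect_lt(max(abs(got - want)), 1e-12)  # absolute agreement
    # bound invariants
    ent <- function(v) isosig:::entropy_counts(table(v))
    expect_lte(got[["IG"]], min(ent(bins), ent(labs)) + 1e-12)
    expect_true(got[["GR"]] >= 0 && got[["GR"]] <= 1 + 1e-12)
    expect_true(got[["SU"]] >= 0 && got[["SU"]] <= 1 + 1e-12)
  }
})

test_that("MDLP discretizer: separable data gets one clean cut, noise falls back to median", {
  # perfectly separated: one cut between the groups, IG = H(S)
  x <- c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  y <- rep(c(0, 1), each = 10)
  d <- fit_discretizer(x, y)
  expect_equal(d$n_bins, 2)
  expect_true(d$cuts > max(x[y == 0]) && d$cuts < min(x[y == 1]))
  expect_equal(unname(information_measures(apply_discretizer(d, x), y)["IG"]), 1)

  # labels alternating with sorted values: every split has ~zero gain, the
  # MDL criterion rejects, and the fallback is a single median cut
  x2 <- 1:20
  y2 <- rep(c(0, 1), 10)
  d2 <- fit_discretizer(x2, y2)
  expect_equal(d2$cuts, stats::median(x2))
  expect_equal(d2$n_bins, 2)

  # constant vector: degenerate single bin
  d3 <- fit_discretizer(rep(4, 10), rep(c(0, 1), 5))
  expect_equal(d3$n_bins, 1)
  expect_equal(unique(apply_discretizer(d3, rep(4, 5))), 1L)

  # mapping is total over the real line and NA-preserving
  expect_equal(apply_discretizer(d, c(-Inf, Inf)), c(1L, 2L))
  expect_true(is.na(apply_discretizer(d, NA_real_)))
})

test_that("discretizer cut points are strictly increasing on multimodal data", {
  set.seed(7)
  x <- c(rnorm(30, 0, 0.2), rnorm(30, 5, 0.2), rnorm(30, 10, 0.2))
  y <- c(rep(0, 30), rep(1, 30), rep(0, 30))
  d <- fit_discretizer(x, y)
  expect_gte(d$n_bins, 3)
  expect_true(all(diff(d$cuts) > 0))
  d_ef <- fit_discretizer(x, method = "equal_frequency", k = 3)
  expect_equal(d_ef$n_bins, 3)
  expect_true(all(table(apply_discretizer(d_ef, x)) == 30))
})

test_that("subsample selection flags a strong planted feature and gates small effects", {
  co <- simulate_cohort(cohort_spec(
    n_genes = 60L, n_planted_psi = 1L, delta_psi = 0.4, seed = 21L
  ))
  design <- cohort_design(co)
  psi <- compute_psi(co$tx, build_gene_groups(co$annotation))
  eff <- effect_sizes(psi, design)
  st <- subsample_selection(psi, design, eff, selection_config(seed = 5L))
  planted <- co$truth$planted_psi_transcripts
  expect_true(st$discriminant[st$feature_id == planted])
  expect_gt(st$obs_IG[st$feature_id == planted], st$null_IG[st$feature_id == planted])

  # sub-threshold planted effect is never flagged, whatever the measures
  co2 <- simulate_cohort(cohort_spec(
    n_genes = 60L, n_planted_psi = 5L, delta_psi = 0.05, seed = 22L
  ))
  psi2 <- compute_psi(co2$tx, build_gene_groups(co2$annotation))
  d2 <- cohort_design(co2)
  eff2 <- effect_sizes(psi2, d2)
  st2 <- subsample_selection(psi2, d2, eff2, selection_config(seed = 5L))
  expect_false(any(st2$discriminant[st2$feature_id %in% co2$truth$planted_psi_transcripts]))
})

test_that("subsample selection is bit-reproducible from its seed and checks group sizes", {
  co <- simulate_cohort(cohort_spec(n_genes = 40L, n_planted_psi = 3L,
                                    n_early = 15L, n_late = 15L, seed = 31L))
  design <- cohort_design(co)
  psi <- compute_psi(co$tx, build_gene_groups(co$annotation))
  eff <- effect_sizes(psi, design)
  cfg <- selection_config(n_iterations = 20L, seed = 99L)
  s1 <- subsample_selection(psi, design, eff, cfg)
  s2 <- subsample_selection(psi, design, eff, cfg)
  expect_identical(s1, s2)

  small <- isosig:::new_design("M", design$early[1:5], design$late,
                               design$tumor_type_of)
  expect_error(subsample_selection(psi, small, eff, cfg), "min_group")
})

test_that("pooled multi-type designs draw balanced per-type subsamples", {
  co <- simulate_cohort(cohort_spec(n_genes = 50L, n_planted_psi = 5L,
                                    delta_psi = 0.4, n_tumor_types = 2L, seed = 41L))
  design <- cohort_design(co)
  draw <- isosig:::with_seed(1L, isosig:::balanced_draw(design))
  tt <- design$tumor_type_of
  expect_equal(table(tt[draw$early]), table(tt[draw$late]))
  # and selection still recovers the planted features
  psi <- compute_psi(co$tx, build_gene_groups(co$annotation))
  eff <- effect_sizes(psi, design)
  st <- subsample_selection(psi, design, eff, selection_config(seed = 6L))
  expect_true(all(st$discriminant[st$feature_id %in% co$truth$planted_psi_transcripts]))
})

test_that("CFS: single candidate, duplicated features, and the merit formula", {
  set.seed(55)
  y <- rep(c(0L, 1L), each = 20)
  informative <- y + rnorm(40, 0, 0.3)
  X1 <- matrix(informative, nrow = 1, dimnames = list("f1", NULL))
  sel1 <- cfs_select(X1, y)
  expect_equal(as.character(sel1), "f1")

  # an identical copy is redundant: r_ff = 1 lowers merit, one copy kept
  X2 <- rbind(f1 = informative, f2 = informative)
  sel2 <- cfs_select(X2, y)
  expect_length(sel2, 1)
})

test_that("CFS selection achieves the exhaustive-search merit on random small instances", {
  set.seed(77)
  for (i in 1:30) {
    n_feat <- sample(4:8, 1)
    n <- 40
    y <- rep(c(0L, 1L), each = n / 2)
    X <- matrix(rnorm(n_feat * n), nrow = n_feat,
                dimnames = list(paste0("f", seq_len(n_feat)), NULL))
    # a few features carry signal of varying strength
    k_sig <- sample(1:3, 1)
    for (j in seq_len(k_sig)) X[j, ] <- X[j, ] + y * runif(1, 0.5, 2)
    sel <- cfs_select(X, y)
    # oracle: same discretized bins, independent SU + merit + enumeration
    bins <- lapply(seq_len(n_feat), function(r) {
      d <- fit_discretizer(X[r, ], y)
      apply_discretizer(d, X[r, ])
    })
    rcf <- vapply(bins, function(b) oracle_info(b, y)[["SU"]], 0)
    rff <- diag(1, n_feat)
    for (a in seq_len(n_feat - 1)) {
      for (b in (a + 1):n_feat) {
        rff[a, b] <- rff[b, a] <- oracle_info(bins[[a]], bins[[b]])[["SU"]]
      }
    }
    expect_equal(attr(sel, "merit"),
                 oracle_best_merit(rcf, rff), tolerance = 1e-9,
                 info = paste("instance", i))
    expect_equal(oracle_merit(match(sel, rownames(X)), rcf, rff),
                 oracle_best_merit(rcf, rff), tolerance = 1e-9)
  }
})

test_that("best-first CFS search stays sane above the exhaustive-search limit", {
  set.seed(88)
  n <- 60
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(15 * n), nrow = 15,
              dimnames = list(paste0("f", 1:15), NULL))
  X[1, ] <- X[1, ] + y * 2
  X[2, ] <- X[2, ] + y * 1.5
  sel <- cfs_select(X, y, exact_limit = 0L)  # force best-first
  expect_gte(length(sel), 1)
  expect_true("f1" %in% sel)
  expect_gt(attr(sel, "merit"), 0)
})
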