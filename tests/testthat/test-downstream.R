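make_clinical <- function(n, days, event, type = "TT1", stage_m = NA_character_) {
  as_clinical(data.frame(
    sample_id = sprintf("c%03d", seq_len(n)), tumor_type = type,
    stage_M = stage_m %||% "", survival_days = days, event = event,
    stringsAsFactors = FALSE
  ))
}
`%||%` <- function(x, y) if (length(x) == 1 && is.na(x)) y else x

test_that("Fisher enrichment matches hypergeometric enumeration and applies BH", {
  # 100 background genes, query of 10; sets of varying overlap
  bg <- sprintf("g%03d", 1:100)
  query <- bg[1:10]
  sets <- list(
    hit = bg[c(1:8, 11:30)],     # 8/10 of the query, 28 genes total
    flat = bg[seq(2, 100, 2)],   # half the background
    away = bg[60:100]            # no query genes
  )
  res <- fisher_enrichment(query, bg, sets)
  expect_equal(nrow(res), 3)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p[i],
                 oracle_fisher_p(res$a[i], res$b[i], res$c[i], res$d[i]),
                 tolerance = 1e-12)
  }
  expect_equal(res$fdr, p.adjust(res$p, "BH"))
  expect_true(res$significant[res$set_name == "hit"])

  # query = background: p = 1 everywhere, odds ratio guarded
  res2 <- fisher_enrichment(bg, bg, sets["hit"])
  expect_equal(res2$p, 1)
  # disjoint set skipped with a log
  expect_message(
    res3 <- fisher_enrichment(query, bg, list(gone = c("zz1", "zz2"))),
    "disjoint"
  )
  expect_equal(nrow(res3), 0)
  expect_error(fisher_enrichment(c(query, "zz9"), bg, sets), "outside")
})

test_that("Fisher p equals exact enumeration across random small tables", {
  set.seed(31)
  for (i in 1:60) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    cc <- sample(0:40, 1); d <- sample(0:60, 1)
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    p <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
    expect_equal(p, oracle_fisher_p(a, b, cc, d), tolerance = 1e-12)
  }
})

test_that("differential expression flags by fold change and exact Wilcoxon p", {
  clin <- make_clinical(12, days = 100, event = "censored",
                        stage_m = rep(c("M0", "M1"), each = 6))
  design <- build_design(clin, "M", "M0", "M1")
  set.seed(41)
  expr <- rbind(
    up = c(rnorm(6, 2, 0.1), rnorm(6, 8, 0.1)),
    flat = rnorm(12, 5, 0.1),
    const = rep(3, 12)
  )
  colnames(expr) <- clin$sample_id
  res <- differential_expression(expr, design)
  expect_true(res$de_flag[res$gene_id == "up"])
  expect_false(res$de_flag[res$gene_id == "flat"])
  expect_equal(res$p[res$gene_id == "const"], 1)
  expect_equal(res$log2fc[res$gene_id == "up"],
               log2((mean(expr["up", 7:12]) + 0.01) / (mean(expr["up", 1:6]) + 0.01)))
  # Wilcoxon p agrees with exhaustive rank-assignment enumeration
  for (g in c("up", "flat")) {
    expect_equal(res$p[res$gene_id == g],
                 oracle_wilcoxon_p(expr[g, 7:12], expr[g, 1:6]),
                 tolerance = 1e-12)
  }
  clin_small <- make_clinical(4, days = 10, event = "censored",
                              stage_m = c("M0", "M0", "M1", "M1"))
  design_small <- build_design(clin_small, "M", "M0", "M1")
  expect_error(differential_expression(expr[, 1:4], design_small), "3 samples")
})

test_that("identical survival gives HR near 1; Kaplan-Meier equals empirical survival", {
  days <- c(50, 120, 200, 340, 500, 700, 910, 1100)
  clin <- make_clinical(16, days = c(days, days), event = "deceased")
  a <- clin$sample_id[1:8]
  b <- clin$sample_id[9:16]
  sc <- survival_compare(clin, a, b)
  expect_equal(sc$hazard_ratio, 1, tolerance = 1e-6)
  expect_gt(sc$cox_p, 0.99)
  # no censoring: KM is the empirical survival function
  km <- sc$km_curves[[1]]
  emp <- vapply(km$time, function(t) mean(days > t), 0)
  expect_equal(km$survival, emp, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
  expect_error(survival_compare(clin, a[1:3], b), "5 samples")
  clin2 <- make_clinical(16, days = c(days, days), event = "censored")
  expect_error(survival_compare(clin2, a, b), "no events")
})

test_that("Cox recovers a simulated hazard ratio and its magnitude direction", {
  set.seed(51)
  n <- 300
  days <- c(rexp(n / 2, 0.001), rexp(n / 2, 0.003))  # true HR 3 for group b
  clin <- make_clinical(n, days = days, event = "deceased")
  a <- clin$sample_id[1:(n / 2)]
  b <- clin$sample_id[(n / 2 + 1):n]
  sc <- survival_compare(clin, a, b)
  expect_gt(sc$hazard_ratio, 2.2)
  expect_lt(sc$hazard_ratio, 4.0)
  expect_lt(sc$cox_p, 1e-6)
})

test_that("blind test predicts only unlabeled samples of eligible types", {
  spec <- cohort_spec(n_genes = 80L, n_planted_psi = 8L, delta_psi = 0.45,
                      n_early = 60L, n_late = 60L, hazard_ratio = 3,
                      missing_label_fraction = 0.3, n_tumor_types = 2L,
                      seed = 91L)
  co <- simulate_cohort(spec)
  gg <- build_gene_groups(co$annotation)
  psi <- compute_psi(co$tx, gg)
  labeled <- co$clinical$sample_id[co$clinical$stage_M != "MISSING"]
  types <- unique(co$clinical$tumor_type)
  designs <- lapply(types, function(ty) {
    keep <- co$clinical$tumor_type == ty & co$clinical$sample_id %in% labeled
    build_design(structure(co$clinical[keep, ], class = class(co$clinical)),
                 "M", "M0", "M1")
  })
  names(designs) <- types
  models <- lapply(types, function(ty) {
    d <- designs[[ty]]
    eff <- effect_sizes(psi, d)
    st <- subsample_selection(psi, d, eff,
                              selection_config(n_iterations = 30L, seed = 2L))
    cand <- st$feature_id[st$discriminant]
    y <- unname(isosig:::design_labels(d))
    sel <- cfs_select(psi$psi[cand, c(d$early, d$late), drop = FALSE], y)
    fit_lmt(t(psi$psi[sel, c(d$early, d$late), drop = FALSE]), y,
            lmt_config(boost_iter = 30L, seed = 3L))
  })
  names(models) <- types
  feats <- stats::setNames(rep(list(psi), length(types)), types)

  elig <- eligible_tumor_types(co$clinical, designs)
  res <- blind_test(models, feats, co$clinical, "M", eligible_types = elig)
  # leak-freedom: no predicted sample carries the label
  expect_true(all(res$predictions$sample_id %in% co$truth$blanked_samples))
  expect_false(any(res$predictions$sample_id %in% labeled))
  # gate: samples of non-eligible types never predicted
  expect_true(all(res$predictions$tumor_type %in% elig))
  # no unlabeled samples -> empty predictions, flagged not comparable
  co2 <- simulate_cohort(cohort_spec(n_genes = 20L, seed = 92L))
  res2 <- blind_test(models, feats, co2$clinical, "M", eligible_types = types)
  expect_equal(nrow(res2$predictions), 0)
  expect_false(res2$comparable)
})

test_that("gene-set sample scores are rank-based and permutation-equivariant", {
  set.seed(61)
  expr <- matrix(rexp(30 * 12, 0.2), nrow = 30,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
  genes <- rownames(expr)[1:8]
  sc <- geneset_sample_score(expr, genes)
  # oracle: independent rank-mean computation
  oracle <- colMeans(t(apply(expr[genes, ], 1, function(x) scale(rank(x))[, 1])))
  expect_equal(unname(sc), unname(oracle), tolerance = 1e-12)
  # sample where the set is uniformly highest scores maximally
  expr2 <- expr
  expr2[genes, "s05"] <- max(expr) + 1
  sc2 <- geneset_sample_score(expr2, genes)
  expect_equal(names(which.max(sc2)), "s05")
  # permuting samples permutes scores identically
  perm <- sample(ncol(expr))
  expect_equal(unname(geneset_sample_score(expr[, perm], genes)), unname(sc[perm]))
  expect_error(geneset_sample_score(expr, c("g01", "zz")), "at least 5")
})

test_that("PSI-score correlations hit the exact values on constructed vectors", {
  set.seed(71)
  psi <- matrix(runif(5 * 20), nrow = 5,
                dimnames = list(paste0("t", 1:5), paste0("s", 1:20)))
  scores <- setNames(psi["t1", ], colnames(psi))
  r <- correlate_psi_scores(psi, c("t1", "t2"), scores)
  expect_equal(unname(r["t1"]), 1)
  r2 <- correlate_psi_scores(psi, "t1", -2 * scores + 3)
  expect_equal(unname(r2), -1)
  # zero-variance PSI -> NA; too few pairs -> dropped with log
  psi["t3", ] <- 0.5
  expect_true(is.na(correlate_psi_scores(psi, "t3", scores)["t3"]))
  psi["t4", 3:20] <- NA
  expect_message(r4 <- correlate_psi_scores(psi, "t4", scores), "dropped")
  expect_true(is.na(r4[["t4"]]))
})

test_that("null-score correlations are small at n = 200", {
  set.seed(81)
  psi <- matrix(runif(40 * 200), nrow = 40,
                dimnames = list(paste0("t", 1:40), paste0("s", 1:200)))
  scores <- setNames(rnorm(200), colnames(psi))
  r <- correlate_psi_scores(psi, rownames(psi), scores)
  expect_gte(mean(abs(r) < 0.2), 0.95)
})

test_that("robust z-scores follow the MAD formula with guards and location invariance", {
  m <- matrix(c(1, 2, 3), nrow = 1, dimnames = list("g1", c("a", "b", "c")))
  z <- robust_zscores(m)
  expect_equal(unname(z[1, ]), c(-1, 0, 1) / 1.4826, tolerance = 1e-4)
  expect_equal(unname(z[1, 2]), 0)
  # constant gene guarded to zero
  m2 <- rbind(m, g2 = c(5, 5, 5))
  expect_equal(unname(robust_zscores(m2)["g2", ]), c(0, 0, 0))
  # location shift leaves z unchanged
  expect_equal(robust_zscores(m + 10), z)
  expect_error(robust_zscores(m[, 1:2, drop = FALSE]), "3 samples")
})
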