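#' Fisher-exact gene-set enrichment with BH correction
#'
#' One two-sided Fisher exact test per gene set on the 2x2 table of query
#' versus background membership, Benjamini-Hochberg correction across the
#' tested sets, and significance at FDR < 0.05. The intended background is
#' the expressed (gene TPM >= 0.1 in the cohort) multi-transcript genes;
#' the caller supplies it explicitly. Sets disjoint from the background are
#' skipped with a log message.
#'
#' @param query_genes character vector of query genes (genes with selected
#'   isoforms); must be a subset of `background_genes`.
#' @param background_genes character vector, the enrichment universe.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param fdr_threshold significance threshold on the adjusted p value.
#' @return data.frame of class `enrichment_result` with per-set counts
#'   `a` (query in set), `b` (query not in set), `c` (rest of background in
#'   set), `d` (rest), `odds_ratio`, `p`, `fdr`, `significant`.
#' @export
fisher_enrichment <- function(query_genes, background_genes, sets,
                              fdr_threshold = 0.05) {
  query_genes <- unique(query_genes)
  background_genes <- unique(background_genes)
  stray <- setdiff(query_genes, background_genes)
  if (length(stray)) {
    stopf("query genes outside the background: %s",
          paste(utils::head(stray, 5L), collapse = ", "))
  }
  if (length(query_genes) == 0L) {
    isosig_log("fisher_enrichment: empty query, returning no rows")
    return(structure(data.frame(), class = c("enrichment_result", "data.frame")))
  }
  rows <- lapply(names(sets), function(nm) {
    genes <- intersect(sets[[nm]], background_genes)
    if (length(genes) == 0L) {
      isosig_log(sprintf("fisher_enrichment: set '%s' disjoint from background, skipped", nm))
      return(NULL)
    }
    a <- length(intersect(query_genes, genes))
    b <- length(query_genes) - a
    cc <- length(genes) - a
    d <- length(background_genes) - length(query_genes) - cc
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2L, byrow = TRUE))
    or <- if (b == 0L || cc == 0L) {
      if (a == 0L || d == 0L) NA_real_ else Inf
    } else {
      (a * d) / (b * cc)
    }
    data.frame(set_name = nm, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    return(structure(data.frame(), class = c("enrichment_result", "data.frame")))
  }
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_threshold
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Differential gene expression between the two groups of a design
#'
#' Per gene: log2 fold change of group means with a pseudo-count, two-sided
#' Wilcoxon rank-sum p value, Benjamini-Hochberg adjustment across tested
#' genes, and the DE flag at |log2FC| > 0.5 and adjusted p < 0.05. A gene
#' constant across both groups gets p = 1.
#'
#' @param gene_expr numeric gene x sample TPM matrix.
#' @param design a `comparison_design` with at least 3 samples per group.
#' @param epsilon pseudo-count (TPM units).
#' @param lfc_threshold,p_threshold DE flag thresholds.
#' @return data.frame of class `de_result` with `gene_id`, `log2fc`, `p`,
#'   `p_adj`, `de_flag`.
#' @export
differential_expression <- function(gene_expr, design, epsilon = 0.01,
                                    lfc_threshold = 0.5, p_threshold = 0.05) {
  if (length(design$early) < 3L || length(design$late) < 3L) {
    stopf("differential_expression needs at least 3 samples per group")
  }
  e <- gene_expr[, design$early, drop = FALSE]
  l <- gene_expr[, design$late, drop = FALSE]
  log2fc <- log2((rowMeans(l) + epsilon) / (rowMeans(e) + epsilon))
  p <- vapply(seq_len(nrow(gene_expr)), function(i) {
    xe <- e[i, ]
    xl <- l[i, ]
    if (stats::var(c(xe, xl)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(xl, xe)$p.value)
  }, 0)
  out <- data.frame(gene_id = rownames(gene_expr), log2fc = log2fc, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$de_flag <- abs(out$log2fc) > lfc_threshold & out$p_adj < p_threshold
  class(out) <- c("de_result", "data.frame")
  out
}

#' Kaplan-Meier curves and a Cox comparison between two sample groups
#'
#' Kaplan-Meier survival curves per group (right-censoring handled) and a
#' single binary-covariate Cox proportional-hazards fit (Efron tie
#' handling); the hazard ratio is the exponentiated coefficient of
#' membership in `group_b` and the p value comes from the Wald statistic.
#'
#' @param clinical a `clinical_table` with `survival_days` and `event`.
#' @param group_a,group_b disjoint sample-id vectors (at least 5 samples
#'   with survival data each, at least one event overall). In stage designs
#'   `group_a` is the early and `group_b` the late group, so a hazard ratio
#'   above 1 means worse outcome for `group_b`.
#' @return an object of class `survival_comparison`: list with `km_curves`
#'   (per group data.frame of time, survival, at-risk), `hazard_ratio`,
#'   `cox_p`, `fit` (the coxph object), and `n_per_group`.
#' @export
survival_compare <- function(clinical, group_a, group_b) {
  stopifnot(inherits(clinical, "clinical_table"))
  if (length(intersect(group_a, group_b))) stopf("survival groups overlap")
  idx <- match(c(group_a, group_b), clinical$sample_id)
  if (anyNA(idx)) stopf("survival groups contain samples absent from the clinical table")
  d <- clinical[idx, , drop = FALSE]
  keep <- !is.na(d$survival_days) & !is.na(d$event)
  d <- d[keep, , drop = FALSE]
  grp <- factor(ifelse(d$sample_id %in% group_b, "b", "a"), levels = c("a", "b"))
  if (sum(grp == "a") < 5L || sum(grp == "b") < 5L) {
    stopf("survival_compare needs at least 5 samples with survival data per group")
  }
  status <- as.integer(d$event == "deceased")
  if (sum(status) == 0L) stopf("no events")
  surv <- survival::Surv(d$survival_days, status)
  km <- survival::survfit(surv ~ grp)
  cox <- survival::coxph(surv ~ grp, ties = "efron")
  sc <- summary(cox)$coefficients
  strata <- rep(names(km$strata) %||% "grp=a", km$strata %||% length(km$time))
  curves <- split(
    data.frame(time = km$time, survival = km$surv, at_risk = km$n.risk),
    sub("^grp=", "", strata)
  )
  structure(
    list(km_curves = curves,
         hazard_ratio = unname(exp(sc[1L, "coef"])),
         cox_p = unname(sc[1L, "Pr(>|z|)"]),
         coef_se = unname(sc[1L, "se(coef)"]),
         fit = cox,
         n_per_group = c(a = sum(grp == "a"), b = sum(grp == "b")),
         n_events = sum(status)),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("survival comparison: %d vs %d samples (%d events), HR = %.3f, Cox p = %.3g\n",
              x$n_per_group[1L], x$n_per_group[2L], x$n_events,
              x$hazard_ratio, x$cox_p))
  invisible(x)
}

#' Tumor types whose labeled early/late groups differ in survival
#'
#' The eligibility gate of the blind test: only tumor types where the
#' labeled early and late groups already show a significant Cox survival
#' difference are used for predicting unlabeled samples.
#'
#' @param clinical a `clinical_table`.
#' @param designs named list (tumor type -> `comparison_design`) of labeled
#'   designs.
#' @param p_threshold Cox Wald p-value threshold (default 0.05).
#' @return character vector of eligible tumor types.
#' @export
eligible_tumor_types <- function(clinical, designs, p_threshold = 0.05) {
  ok <- vapply(designs, function(d) {
    p <- tryCatch(survival_compare(clinical, d$early, d$late)$cox_p,
                  error = function(e) NA_real_)
    !is.na(p) && p < p_threshold
  }, TRUE)
  names(designs)[ok]
}

#' Blind test: predict unlabeled samples and compare predicted-group survival
#'
#' Samples lacking the stage label for `class_name` (and therefore never
#' used to build the models) are predicted with the signature model of
#' their own tumor type at a 0.5 probability threshold on the late class.
#' Predicted-early and predicted-late samples are pooled across the
#' eligible tumor types and their survival compared with a Cox model. A
#' pool left empty flags the result as not comparable instead of erroring.
#'
#' @param models named list (tumor type -> `lmt_model`).
#' @param features named list (tumor type -> `psi_matrix` or feature x
#'   sample matrix covering that type's samples).
#' @param clinical a `clinical_table`.
#' @param class_name stage class (`"T"`, `"N"`, `"M"`, `"S"`).
#' @param eligible_types tumor types allowed into the test (see
#'   [eligible_tumor_types()]).
#' @param threshold probability threshold for calling the late class.
#' @return list of class `blind_test_result` with `predictions`
#'   (data.frame sample_id, tumor_type, prob_late, predicted), `comparable`
#'   (logical), and `survival` (a `survival_comparison` or NULL).
#' @export
blind_test <- function(models, features, clinical, class_name, eligible_types,
                       threshold = 0.5) {
  stopifnot(inherits(clinical, "clinical_table"))
  col <- paste0("stage_", class_name)
  preds <- list()
  for (ty in intersect(names(models), eligible_types)) {
    m <- feature_values(features[[ty]])
    unl <- clinical$sample_id[clinical$tumor_type == ty &
                                clinical[[col]] == MISSING_LABEL]
    unl <- intersect(unl, colnames(m))
    if (length(unl) == 0L) next
    pr <- predict_proba(models[[ty]], t(m[, unl, drop = FALSE]))
    preds[[ty]] <- data.frame(
      sample_id = unl, tumor_type = ty, prob_late = pr,
      predicted = ifelse(pr > threshold, "late", "early"),
      stringsAsFactors = FALSE
    )
  }
  predictions <- if (length(preds)) do.call(rbind, preds) else
    data.frame(sample_id = character(0), tumor_type = character(0),
               prob_late = numeric(0), predicted = character(0))
  rownames(predictions) <- NULL
  early_pool <- predictions$sample_id[predictions$predicted == "early"]
  late_pool <- predictions$sample_id[predictions$predicted == "late"]
  surv <- NULL
  comparable <- FALSE
  if (length(early_pool) >= 5L && length(late_pool) >= 5L) {
    surv <- tryCatch(survival_compare(clinical, early_pool, late_pool),
                     error = function(e) NULL)
    comparable <- !is.null(surv)
  }
  if (!comparable) {
    isosig_log(sprintf("blind_test (%s): predicted groups not comparable (%d early, %d late)",
                       class_name, length(early_pool), length(late_pool)))
  }
  structure(list(predictions = predictions, comparable = comparable,
                 survival = surv, class_name = class_name),
            class = "blind_test_result")
}

#' Per-sample gene-set score from within-cohort expression ranks
#'
#' For every gene in the set, expression values are ranked across samples
#' and converted to z-scores of the ranks; a sample's score is the mean of
#' these rank z-scores over the set genes. The score is invariant to
#' per-gene monotone transforms of expression, which is all the downstream
#' Pearson correlation screening requires. This is a rank-based summary,
#' not the GSVA kernel estimator.
#'
#' @param gene_expr numeric gene x sample matrix.
#' @param gene_set character vector of gene ids (at least 5 must be present
#'   in the matrix).
#' @return named numeric vector of per-sample scores.
#' @export
geneset_sample_score <- function(gene_expr, gene_set) {
  genes <- intersect(gene_set, rownames(gene_expr))
  if (length(genes) < 5L) {
    stopf("only %d of %d set genes present; need at least 5",
          length(genes), length(unique(gene_set)))
  }
  z <- t(apply(gene_expr[genes, , drop = FALSE], 1L, function(x) {
    r <- rank(x)
    s <- stats::sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  colMeans(z)
}

#' Pearson correlation of model-feature PSIs with per-sample scores
#'
#' Screens the transcripts of a signature against a per-sample score (for
#' example stromal or immune content) using all samples with paired
#' non-missing values. Features with fewer than `min_pairs` pairs are
#' dropped with a log message; a zero-variance PSI yields NA.
#'
#' @param psi a `psi_matrix` (or feature x sample matrix).
#' @param model_features transcript ids to screen.
#' @param scores named per-sample numeric vector.
#' @param min_pairs minimum paired non-missing values per feature.
#' @return named numeric vector of Pearson R (NA where undefined).
#' @export
correlate_psi_scores <- function(psi, model_features, scores, min_pairs = 10L) {
  m <- feature_values(psi)
  miss <- setdiff(model_features, rownames(m))
  if (length(miss)) stopf("features absent from PSI matrix: %s", paste(miss, collapse = ", "))
  common <- intersect(colnames(m), names(scores))
  out <- stats::setNames(rep(NA_real_, length(model_features)), model_features)
  for (f in model_features) {
    v <- m[f, common]
    s <- scores[common]
    ok <- !is.na(v) & !is.na(s)
    if (sum(ok) < min_pairs) {
      isosig_log(sprintf("correlate_psi_scores: %s has %d < %d pairs, dropped", f, sum(ok), min_pairs))
      next
    }
    if (stats::sd(v[ok]) == 0 || stats::sd(s[ok]) == 0) next
    out[f] <- stats::cor(v[ok], s[ok], method = "pearson")
  }
  out
}

#' Robust z-scores per gene across samples
#'
#' Per gene: z = (x - median) / (1.4826 * MAD), with MAD the raw median
#' absolute deviation; a zero-MAD (constant) gene yields all-zero z-scores.
#' Used to put external gene-expression signatures on a common scale.
#'
#' @param gene_expr numeric gene x sample matrix with at least 3 samples.
#' @return matrix of z-scores with the same dimensions.
#' @export
robust_zscores <- function(gene_expr) {
  if (ncol(gene_expr) < 3L) stopf("robust_zscores needs at least 3 samples")
  z <- t(apply(gene_expr, 1L, function(x) {
    med <- stats::median(x)
    s <- stats::mad(x, center = med)  # includes the 1.4826 consistency factor
    if (s == 0) rep(0, length(x)) else (x - med) / s
  }))
  dimnames(z) <- dimnames(gene_expr)
  z
}
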