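#' Specification of a synthetic two-group cohort
#'
#' Describes a cohort with the statistical structure the pipeline assumes:
#' per-gene multi-isoform proportions with Dirichlet noise, planted
#' between-group PSI shifts, group-dependent expression changes,
#' exponential survival with a group hazard ratio, independent exponential
#' censoring, and a fraction of samples with the stage label blanked. The
#' defaults describe the standard study conditions used throughout the test
#' suite: two groups of 50, ~1000 transcript features (340 genes x 3
#' isoforms), 20 planted isoform switches of delta PSI 0.3, PSI noise with
#' concentration 20 (about 0.1 standard deviation at PSI 0.3), and a group
#' hazard ratio of 2 on exponential survival with a median of ~700 days.
#'
#' @param n_early,n_late samples per group.
#' @param n_genes number of genes.
#' @param isoforms_per_gene isoforms per gene (single integer).
#' @param n_planted_psi genes carrying a planted PSI switch (one transcript
#'   per gene).
#' @param delta_psi planted between-group mean PSI difference, in (0, 1).
#' @param n_planted_de genes with a planted expression change (disjoint
#'   from the PSI-planted genes).
#' @param log2fc_de planted log2 fold change of gene expression.
#' @param gene_tpm_meanlog,gene_tpm_sdlog log-normal parameters of per-gene
#'   baseline TPM.
#' @param gene_tpm_within_sd log-scale within-gene sample-to-sample
#'   variation.
#' @param psi_concentration Dirichlet concentration of per-sample isoform
#'   proportions around the gene baseline (larger = less PSI noise).
#' @param baseline_rate exponential event rate of the early group, per day.
#' @param hazard_ratio event-rate multiplier of the late group.
#' @param censoring_rate independent exponential censoring rate (0 = none).
#' @param missing_label_fraction fraction of samples whose stage label is
#'   blanked (kept in the ground truth; these form the blind-test pool).
#' @param n_tumor_types tumor-type tags cycled over the samples.
#' @param seed master seed; the whole cohort is a pure function of the spec.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_early = 50L, n_late = 50L, n_genes = 340L,
                        isoforms_per_gene = 3L, n_planted_psi = 20L,
                        delta_psi = 0.3, n_planted_de = 0L, log2fc_de = 1,
                        gene_tpm_meanlog = 2, gene_tpm_sdlog = 1,
                        gene_tpm_within_sd = 0.5, psi_concentration = 20,
                        baseline_rate = 0.001, hazard_ratio = 2,
                        censoring_rate = 0.0005,
                        missing_label_fraction = 0, n_tumor_types = 1L,
                        seed = 1L) {
  spec <- list(n_early = as.integer(n_early), n_late = as.integer(n_late),
               n_genes = as.integer(n_genes),
               isoforms_per_gene = as.integer(isoforms_per_gene),
               n_planted_psi = as.integer(n_planted_psi), delta_psi = delta_psi,
               n_planted_de = as.integer(n_planted_de), log2fc_de = log2fc_de,
               gene_tpm_meanlog = gene_tpm_meanlog, gene_tpm_sdlog = gene_tpm_sdlog,
               gene_tpm_within_sd = gene_tpm_within_sd,
               psi_concentration = psi_concentration,
               baseline_rate = baseline_rate, hazard_ratio = hazard_ratio,
               censoring_rate = censoring_rate,
               missing_label_fraction = missing_label_fraction,
               n_tumor_types = as.integer(n_tumor_types), seed = as.integer(seed))
  stopifnot(spec$n_planted_psi + spec$n_planted_de <= spec$n_genes,
            spec$delta_psi >= 0, spec$delta_psi < 1,
            spec$missing_label_fraction >= 0, spec$missing_label_fraction <= 1,
            spec$baseline_rate > 0, spec$hazard_ratio > 0,
            spec$isoforms_per_gene >= 1L)
  structure(spec, class = "cohort_spec")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) <= 0) return(alpha / sum(alpha))
  g / sum(g)
}

#' Simulate a cohort with known ground truth
#'
#' Draws a full synthetic cohort from a [cohort_spec()]: a transcript TPM
#' matrix (gene TPM log-normal per gene and sample, isoform proportions
#' Dirichlet around a per-gene baseline, transcript TPM = gene TPM x
#' proportion, so member TPMs sum exactly to the gene TPM), a transcript
#' annotation whose within-gene transcripts share splice sites and whose
#' genes occupy disjoint loci (so [build_gene_groups()] recovers the
#' intended partition), a clinical table with group-coded M stage
#' (`M0` = early, `M1` = late, blanked for a fraction of samples) and
#' exponential survival with the group hazard ratio, and the ground truth.
#' For a planted transcript the late-group baseline proportion is shifted
#' on the logit scale so the realized mean PSI difference matches
#' `delta_psi`; the remaining isoforms are renormalized. An infeasible
#' shift (baseline too extreme for the requested delta) is an error naming
#' the gene.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort` with elements `tx` (matrix),
#'   `annotation` (`tx_annotation`), `clinical` (`clinical_table`), and
#'   `truth` (planted transcript/gene sets, true labels, gene map, true
#'   hazard ratio).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_early + spec$n_late
    samples <- sprintf("S%04d", seq_len(n))
    group <- c(rep("early", spec$n_early), rep("late", spec$n_late))
    tumor_type <- paste0("TT", (seq_len(n) - 1L) %% spec$n_tumor_types + 1L)

    k <- spec$isoforms_per_gene
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    planted_genes <- if (spec$n_planted_psi > 0L) sample(genes, spec$n_planted_psi) else character(0)
    de_genes <- if (spec$n_planted_de > 0L) {
      sample(setdiff(genes, planted_genes), spec$n_planted_de)
    } else character(0)

    tx_ids <- as.vector(t(outer(genes, seq_len(k), function(g, j) paste0(g, ".t", j))))
    gene_of <- stats::setNames(rep(genes, each = k), tx_ids)
    planted_tx <- if (length(planted_genes)) paste0(planted_genes, ".t1") else character(0)

    # per-gene baseline proportions; planted genes keep the shifted
    # transcript's baseline in a range where the logit shift is feasible
    base_early <- matrix(0, nrow = spec$n_genes, ncol = k, dimnames = list(genes, NULL))
    base_late <- base_early
    max_p1 <- 0.95 - spec$delta_psi
    for (gi in seq_len(spec$n_genes)) {
      g <- genes[gi]
      if (g %in% planted_genes) {
        if (max_p1 <= 0.2) {
          stopf("infeasible PSI shift %.2f for gene %s: no baseline in (0.2, %.2f)",
                spec$delta_psi, g, 0.95 - spec$delta_psi)
        }
        p1 <- stats::runif(1L, 0.2, max_p1)
        rest <- if (k > 1L) (1 - p1) * rdirichlet1(rep(2, k - 1L)) else numeric(0)
        b <- c(p1, rest)
        # logit-scale shift of the planted transcript, renormalizing the rest
        shift <- stats::qlogis(p1 + spec$delta_psi) - stats::qlogis(p1)
        p1l <- stats::plogis(stats::qlogis(p1) + shift)
        bl <- c(p1l, if (k > 1L) rest * (1 - p1l) / (1 - p1) else numeric(0))
        base_early[gi, ] <- b
        base_late[gi, ] <- bl
      } else {
        b <- rdirichlet1(rep(2, k))
        base_early[gi, ] <- b
        base_late[gi, ] <- b
      }
    }

    mu_g <- stats::rnorm(spec$n_genes, spec$gene_tpm_meanlog, spec$gene_tpm_sdlog)
    de_shift <- ifelse(genes %in% de_genes, spec$log2fc_de * log(2), 0)
    is_late <- as.numeric(group == "late")

    # gene TPM per gene and sample: log-normal around the gene baseline,
    # shifted by the planted fold change in the late group
    g_tpm <- exp(mu_g + outer(de_shift, is_late) +
                   matrix(stats::rnorm(spec$n_genes * n, 0, spec$gene_tpm_within_sd),
                          nrow = spec$n_genes))

    # per-gene Dirichlet proportions drawn for all samples of a group at
    # once (gamma normalization), columns renormalized to sum to 1
    draw_props <- function(alpha, m) {
      if (k == 1L) return(matrix(1, nrow = 1L, ncol = m))
      p <- matrix(stats::rgamma(k * m, shape = alpha), nrow = k)
      cs <- colSums(p)
      bad <- cs <= 0
      if (any(bad)) p[, bad] <- alpha / sum(alpha)
      sweep(p, 2L, colSums(p), "/")
    }
    tx <- matrix(0, nrow = length(tx_ids), ncol = n, dimnames = list(tx_ids, samples))
    e_idx <- which(group == "early")
    l_idx <- which(group == "late")
    for (gi in seq_len(spec$n_genes)) {
      rows <- ((gi - 1L) * k + 1L):(gi * k)
      prop <- matrix(0, nrow = k, ncol = n)
      prop[, e_idx] <- draw_props(spec$psi_concentration * base_early[gi, ], length(e_idx))
      prop[, l_idx] <- draw_props(spec$psi_concentration * base_late[gi, ], length(l_idx))
      tx[rows, ] <- prop * rep(g_tpm[gi, ], each = k)
    }

    annotation <- simulate_annotation(genes, k)

    rate <- ifelse(group == "late", spec$baseline_rate * spec$hazard_ratio,
                   spec$baseline_rate)
    t_event <- stats::rexp(n, rate)
    t_cens <- if (spec$censoring_rate > 0) stats::rexp(n, spec$censoring_rate) else rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- ifelse(t_event <= t_cens, "deceased", "censored")

    stage_m <- ifelse(group == "late", "M1", "M0")
    n_blank <- round(spec$missing_label_fraction * n)
    blanked <- if (n_blank > 0L) sample(samples, n_blank) else character(0)
    stage_m[samples %in% blanked] <- MISSING_LABEL

    clinical <- as_clinical(data.frame(
      sample_id = samples, tumor_type = tumor_type, stage_M = stage_m,
      survival_days = round(time, 3), event = event, stringsAsFactors = FALSE
    ))

    # every transcript whose generative baseline proportion differs between
    # the groups: the planted transcripts plus their renormalized sibling
    # isoforms (PSI sums to 1 per gene, so a planted shift necessarily
    # moves the siblings in the opposite direction)
    shift_abs <- abs(base_late - base_early)
    shifted_tx <- tx_ids[as.vector(t(shift_abs)) > 1e-9]

    truth <- list(
      planted_psi_transcripts = planted_tx,
      shifted_transcripts = shifted_tx,
      planted_psi_genes = planted_genes,
      planted_de_genes = de_genes,
      true_labels = stats::setNames(group, samples),
      blanked_samples = blanked,
      gene_of = gene_of,
      true_hazard_ratio = spec$hazard_ratio
    )
    structure(list(tx = tx, annotation = annotation, clinical = clinical,
                   truth = truth, spec = spec),
              class = "synthetic_cohort")
  })
}

# Disjoint loci 10 kb apart on one chromosome; within a gene all isoforms
# share the first two exons (hence splice sites) and differ in a third.
simulate_annotation <- function(genes, k) {
  rows <- lapply(seq_along(genes), function(gi) {
    o <- (gi - 1L) * 10000L + 1L
    do.call(rbind, lapply(seq_len(k), function(j) {
      data.frame(
        transcript_id = paste0(genes[gi], ".t", j),
        gene_id = genes[gi],
        chrom = "chr1", strand = "+",
        start = c(o, o + 200L, o + 400L + (j - 1L) * 60L),
        end = c(o + 100L, o + 300L, o + 420L + (j - 1L) * 60L),
        stringsAsFactors = FALSE
      )
    }))
  })
  validate_annotation(do.call(rbind, rows))
}

#' Simulate a null cohort (all planted effects zeroed)
#'
#' Convenience wrapper: same generative process with no PSI shifts, no
#' expression changes, and unit hazard ratio; the ground-truth planted sets
#' are empty.
#'
#' @param spec a [cohort_spec()]; its effect fields are overridden.
#' @return a `synthetic_cohort`.
#' @export
simulate_null_cohort <- function(spec = cohort_spec()) {
  spec$n_planted_psi <- 0L
  spec$n_planted_de <- 0L
  spec$delta_psi <- 0
  spec$hazard_ratio <- 1
  simulate_cohort(spec)
}

#' Early-versus-late design of a synthetic cohort
#'
#' Builds the M0-versus-M1 comparison design from the cohort's clinical
#' table; samples with a blanked label are excluded (they are the
#' blind-test pool).
#'
#' @param cohort a `synthetic_cohort`.
#' @return a `comparison_design`.
#' @export
cohort_design <- function(cohort) {
  build_design(cohort$clinical, "M", "M0", "M1")
}

#' Write a synthetic cohort to disk in the pipeline's input formats
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(cohort$tx, file.path(dir, "transcript_tpm.tsv"),
               id_column = "transcript_id")
  write_gtf(cohort$annotation, file.path(dir, "annotation.gtf"))
  utils::write.table(as.data.frame(cohort$clinical),
                     file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
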