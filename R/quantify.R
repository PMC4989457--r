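#' Group transcripts into genes by shared splice sites
#'
#' A gene is a set of transcripts that overlap in the same genomic locus and
#' strand and share at least one splice-site coordinate, closed
#' transitively: if A shares a site with B and B with C, all three belong to
#' one gene even when A and C share none. Mono-exonic or otherwise
#' unconnected transcripts form singleton genes. Gene identifiers are
#' deterministic: `gene:` followed by the lexicographically smallest member
#' transcript id.
#'
#' @param ann a `tx_annotation` exon table (see [read_gtf()]).
#' @return an object of class `gene_grouping`: list with `gene_of` (named
#'   character vector transcript -> gene) and `members` (named list gene ->
#'   transcript ids).
#' @export
build_gene_groups <- function(ann) {
  ann <- validate_annotation(as.data.frame(ann))
  tx <- sort(unique(ann$transcript_id))
  n <- length(tx)
  sites <- splice_sites(ann)[tx]
  span <- do.call(rbind, lapply(split(ann, ann$transcript_id)[tx], function(d) {
    c(min(d$start), max(d$end))
  }))
  meta <- data.frame(
    tx = tx,
    chrom = vapply(split(ann$chrom, ann$transcript_id)[tx], `[[`, "", 1L),
    strand = vapply(split(ann$strand, ann$transcript_id)[tx], `[[`, "", 1L),
    lo = span[, 1L], hi = span[, 2L], stringsAsFactors = FALSE
  )

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  for (grp in split(seq_len(n), paste(meta$chrom, meta$strand))) {
    grp <- grp[order(meta$lo[grp])]
    for (a in seq_along(grp)) {
      i <- grp[a]
      b <- a + 1L
      while (b <= length(grp) && meta$lo[grp[b]] <= meta$hi[i]) {
        j <- grp[b]
        if (length(sites[[i]]) && length(sites[[j]]) &&
            any(sites[[i]] %in% sites[[j]])) {
          union_(i, j)
        }
        b <- b + 1L
      }
    }
  }

  comp <- vapply(seq_len(n), find, 0L)
  members <- split(tx, comp)
  names(members) <- vapply(members, function(m) paste0("gene:", min(m)), "")
  members <- members[order(names(members))]
  gene_of <- stats::setNames(rep(names(members), lengths(members)), unlist(members))
  structure(list(gene_of = gene_of[tx], members = members), class = "gene_grouping")
}

#' Build a gene grouping from an explicit transcript-to-gene map
#'
#' @param map data.frame with columns `transcript_id` and `gene_id`.
#' @return a `gene_grouping`.
#' @export
grouping_from_map <- function(map) {
  stopifnot(all(c("transcript_id", "gene_id") %in% names(map)))
  if (anyDuplicated(map$transcript_id)) stopf("transcript mapped to several genes")
  gene_of <- stats::setNames(as.character(map$gene_id), map$transcript_id)
  structure(
    list(gene_of = gene_of, members = split(names(gene_of), gene_of)),
    class = "gene_grouping"
  )
}

#' @export
print.gene_grouping <- function(x, ...) {
  cat(sprintf("gene grouping: %d transcripts in %d genes\n",
              length(x$gene_of), length(x$members)))
  invisible(x)
}

#' Gene-level TPM as the sum of member transcript TPMs
#'
#' @param tx numeric transcript x sample TPM matrix.
#' @param grouping a `gene_grouping` covering every transcript in `tx`.
#' @return numeric gene x sample matrix.
#' @export
gene_tpm <- function(tx, grouping) {
  unmapped <- setdiff(rownames(tx), names(grouping$gene_of))
  if (length(unmapped)) {
    stopf("transcripts missing from grouping: %s%s",
          paste(utils::head(unmapped, 5L), collapse = ", "),
          if (length(unmapped) > 5L) ", ..." else "")
  }
  rowsum(tx, group = grouping$gene_of[rownames(tx)])
}

#' Per-transcript relative abundance (PSI)
#'
#' PSI of transcript t in sample s is its TPM divided by the TPM of its gene
#' in that sample. Genes below the expression threshold contribute missing
#' (NA) PSIs for all their transcripts in that sample, so a PSI is never an
#' artifact of an unexpressed gene. Where present, the PSIs of a gene's
#' transcripts sum to 1.
#'
#' @param tx numeric transcript x sample TPM matrix.
#' @param grouping a `gene_grouping`.
#' @param min_gene_tpm minimum gene TPM for the gene to count as expressed
#'   in a sample (default 0.1).
#' @return an object of class `psi_matrix`: list with `psi` (matrix with NA
#'   for missing), `gene_of`, `min_gene_tpm`.
#' @export
compute_psi <- function(tx, grouping, min_gene_tpm = 0.1) {
  g <- gene_tpm(tx, grouping)
  gene_of <- grouping$gene_of[rownames(tx)]
  denom <- g[gene_of, , drop = FALSE]
  psi <- tx / denom
  psi[denom < min_gene_tpm] <- NA_real_
  dimnames(psi) <- dimnames(tx)
  structure(list(psi = psi, gene_of = gene_of, min_gene_tpm = min_gene_tpm),
            class = "psi_matrix")
}

#' @export
print.psi_matrix <- function(x, ...) {
  cat(sprintf("PSI matrix: %d transcripts (%d genes) x %d samples, %.1f%% missing\n",
              nrow(x$psi), length(unique(x$gene_of)), ncol(x$psi),
              100 * mean(is.na(x$psi))))
  invisible(x)
}

# Uniform access to the numeric feature matrix of a psi_matrix or a plain
# abundance matrix.
feature_values <- function(x) {
  if (inherits(x, "psi_matrix")) x$psi else as.matrix(x)
}

#' Per-feature effect sizes between the two groups of a design
#'
#' For PSI features the effect is the difference of per-group means of PSI
#' (missing values excluded); for gene expression it is the log2 fold change
#' of the group means with a pseudo-count. Features observed in less than
#' `min_present` of the samples of either group are dropped (no imputation)
#' and reported in the `dropped` attribute.
#'
#' @param features a `psi_matrix` or numeric feature x sample matrix.
#' @param design a `comparison_design`.
#' @param mode `"psi"` (mean difference, in [-1, 1]) or `"gene"` (log2 fold
#'   change of means).
#' @param epsilon pseudo-count added to both means in gene mode (TPM units).
#' @param min_present minimum fraction of non-missing values required in
#'   each group.
#' @return data.frame of class `effect_table` with columns `feature_id`,
#'   `mean_early`, `mean_late`, `delta`; attributes `mode` and `dropped`.
#' @export
effect_sizes <- function(features, design, mode = c("psi", "gene"),
                         epsilon = 0.01, min_present = 0.8) {
  mode <- match.arg(mode)
  m <- feature_values(features)
  missing_samples <- setdiff(c(design$early, design$late), colnames(m))
  if (length(missing_samples)) {
    stopf("design samples absent from feature matrix: %s",
          paste(utils::head(missing_samples, 5L), collapse = ", "))
  }
  e <- m[, design$early, drop = FALSE]
  l <- m[, design$late, drop = FALSE]
  pres_e <- rowMeans(!is.na(e))
  pres_l <- rowMeans(!is.na(l))
  keep <- pres_e >= min_present & pres_l >= min_present
  dropped <- rownames(m)[!keep]
  if (length(dropped)) {
    isosig_log(sprintf("effect_sizes: dropped %d/%d features below the %.0f%% presence ceiling",
                       length(dropped), nrow(m), 100 * min_present))
  }
  me <- rowMeans(e[keep, , drop = FALSE], na.rm = TRUE)
  ml <- rowMeans(l[keep, , drop = FALSE], na.rm = TRUE)
  delta <- if (mode == "psi") ml - me else log2((ml + epsilon) / (me + epsilon))
  out <- data.frame(feature_id = rownames(m)[keep], mean_early = me,
                    mean_late = ml, delta = delta,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mode") <- mode
  attr(out, "dropped") <- dropped
  class(out) <- c("effect_table", "data.frame")
  out
}

# Rank a named numeric vector, ties broken by name, and return the bottom
# and top floor(n * fraction) names.
rank_extremes <- function(vals, fraction) {
  stopifnot(fraction > 0, fraction <= 0.5 + 1e-12)
  n <- length(vals)
  k <- floor(n * fraction)
  if (k < 1L) stopf("fraction %.3f of %d samples gives empty sets", fraction, n)
  ids <- names(vals)
  bottom <- ids[order(vals, ids)][seq_len(k)]
  top <- ids[order(-vals, ids)][seq_len(k)]
  sv <- sort(vals)
  if (k < n && (sv[k] == sv[k + 1L] || sv[n - k + 1L] == sv[n - k])) {
    isosig_log("rank_extremes: ties across the quantile cut broken by sample id")
  }
  list(low = bottom, high = top)
}

#' Split samples by the expression ranking of a marker gene
#'
#' Samples are ranked by the gene's TPM and the bottom and top
#' `floor(n * fraction)` samples are returned (for example the bottom and
#' top 25% by estrogen-receptor expression); samples between the two cuts
#' are left out. Ties across a cut are broken by sample id.
#'
#' @param gene_expr numeric gene x sample TPM matrix.
#' @param gene_id row to rank by.
#' @param fraction fraction in (0, 0.5] taken at each extreme.
#' @return list with `low` and `high` sample-id vectors.
#' @export
rank_subgroups <- function(gene_expr, gene_id, fraction) {
  if (!gene_id %in% rownames(gene_expr)) stopf("gene %s not in matrix", gene_id)
  vals <- stats::setNames(gene_expr[gene_id, ], colnames(gene_expr))
  rank_extremes(vals, fraction)
}

#' Build a survival-based comparison design
#'
#' Samples are ranked by survival days; the top `floor(n * fraction)` (long
#' survival, the good-prognosis analogue of "early") and the bottom
#' `floor(n * fraction)` (short survival, "late") form the two groups.
#'
#' @param clinical a `clinical_table`.
#' @param samples sample ids to rank (must have survival_days).
#' @param fraction fraction in (0, 0.5] per group.
#' @return a `comparison_design` with `class_name = "survival"`.
#' @export
survival_groups <- function(clinical, samples, fraction) {
  stopifnot(inherits(clinical, "clinical_table"))
  idx <- match(samples, clinical$sample_id)
  if (anyNA(idx)) stopf("samples absent from clinical table")
  days <- clinical$survival_days[idx]
  if (anyNA(days)) stopf("samples without survival_days in survival_groups")
  ext <- rank_extremes(stats::setNames(days, samples), fraction)
  new_design("survival", early = ext$high, late = ext$low,
             stats::setNames(clinical$tumor_type, clinical$sample_id))
}
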