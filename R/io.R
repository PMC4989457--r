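#' Read a transcript annotation from a GTF file
#'
#' Parses exon features of a GTF file into an exon table with one row per
#' exon, carrying `transcript_id`, `chrom`, `strand`, `start`, `end` and
#' (when present) `gene_id`. Coordinates are kept 1-based inclusive, the GTF
#' convention. Exons are sorted by start within each transcript, so the
#' internal splice sites of a transcript are the exon ends and the following
#' exon starts.
#'
#' @param path path to a GTF file.
#' @return a data.frame of class `tx_annotation` with columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[keep], "\t", fixed = TRUE))
  if (any(nfield < 9)) {
    bad <- which(keep)[which(nfield < 9)[1]]
    stopf("malformed GTF line %d in %s: expected 9 tab-separated fields", bad, path)
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stopf("read_gtf requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) stopf("no exon features in %s", path)
  ann <- data.frame(
    transcript_id = as.character(gr$transcript_id),
    gene_id = if (is.null(gr$gene_id)) NA_character_ else as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (anyNA(ann$transcript_id)) {
    stopf("exon feature without transcript_id attribute in %s", path)
  }
  if (any(!ann$strand %in% c("+", "-"))) stopf("invalid strand in %s", path)
  if (any(ann$start > ann$end)) stopf("exon with start > end in %s", path)
  ann <- ann[order(ann$transcript_id, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  req <- c("transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(ann))
  if (length(miss)) stopf("annotation lacks columns: %s", paste(miss, collapse = ", "))
  if (is.null(ann$gene_id)) ann$gene_id <- NA_character_
  by_tx <- split(seq_len(nrow(ann)), ann$transcript_id)
  for (idx in by_tx) {
    s <- ann$start[idx]
    e <- ann$end[idx]
    o <- order(s)
    if (length(idx) > 1L && any(e[o][-length(idx)] >= s[o][-1L])) {
      stopf("overlapping exons in transcript %s", ann$transcript_id[idx[1L]])
    }
    if (length(unique(ann$chrom[idx])) != 1L || length(unique(ann$strand[idx])) != 1L) {
      stopf("transcript %s spans multiple chrom/strand", ann$transcript_id[idx[1L]])
    }
  }
  class(ann) <- c("tx_annotation", "data.frame")
  ann
}

#' Write a transcript annotation as GTF
#'
#' @param ann a `tx_annotation` exon table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  gid <- ifelse(is.na(ann$gene_id), ann$transcript_id, ann$gene_id)
  lines <- sprintf(
    "%s\tisosig\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    ann$chrom, ann$start, ann$end, ann$strand, gid, ann$transcript_id
  )
  writeLines(lines, path)
  invisible(path)
}

#' Internal splice sites of each transcript
#'
#' For a multi-exon transcript the splice sites are the internal exon
#' boundaries: each exon end (donor side on the + strand) and the start of
#' the following exon (acceptor side). Mono-exonic transcripts have none.
#'
#' @param ann a `tx_annotation` exon table.
#' @return named list mapping transcript_id to an integer vector of splice
#'   site coordinates.
#' @export
splice_sites <- function(ann) {
  lapply(split(ann, ann$transcript_id), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    n <- nrow(d)
    if (n < 2L) return(integer(0))
    sort(unique(c(d$end[-n], d$start[-1L])))
  })
}

#' Read a tab-separated abundance matrix
#'
#' Expects a header row of sample identifiers and a first column of feature
#' (transcript or gene) identifiers. Values must be non-negative reals;
#' duplicated feature or sample identifiers are rejected.
#'
#' @param path path to a TSV file.
#' @return numeric matrix, features in rows, samples in columns.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stopf("duplicate feature ids in %s: %s", path, ids[duplicated(ids)][1L])
  }
  if (anyDuplicated(names(tab)[-1L])) stopf("duplicate sample ids in %s", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric values in %s", path)
  rownames(m) <- ids
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf(
      "negative value at feature %s, sample %s in %s",
      rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]], path
    )
  }
  m
}

#' Write an abundance (or PSI) matrix as TSV
#'
#' @param m numeric matrix with feature rownames and sample colnames.
#' @param path output path.
#' @param id_column name for the feature id column (header of column 1).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, id_column = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path path to a GMT file (set name, description, then gene symbols,
#'   tab-separated).
#' @return named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  fields <- fields[lengths(fields) >= 3L]
  sets <- lapply(fields, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stopf("duplicate set names in %s", path)
  if (any(lengths(sets) == 0L)) stopf("empty gene set in %s", path)
  sets
}

#' Read a per-sample clinical table
#'
#' The table is tab-separated with a `sample_id` column and any of:
#' `tumor_type`, `stage_T`, `stage_N`, `stage_M`, `stage_S`,
#' `survival_days`, `event` (\code{deceased}/\code{censored}), and the ISO-8601
#' date columns `collection_date`, `death_date`, `last_contact_date`. Stage
#' labels are normalized with [normalize_stage()]. Survival time is taken
#' from `survival_days` when present; otherwise it is death date minus
#' collection date for deceased patients and last contact minus collection
#' date for the others, in days.
#'
#' @param path path to the TSV file.
#' @return a data.frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stopf("clinical file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  as_clinical(tab)
}

#' Coerce a data.frame to a validated clinical table
#'
#' @param tab data.frame, see [read_clinical()] for recognized columns.
#' @return a data.frame of class `clinical_table`.
#' @export
as_clinical <- function(tab) {
  if (!"sample_id" %in% names(tab)) stopf("clinical table lacks sample_id column")
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id)) {
    stopf("duplicate clinical rows for sample %s",
          tab$sample_id[duplicated(tab$sample_id)][1L])
  }
  if (is.null(tab$tumor_type)) tab$tumor_type <- "unspecified"
  for (cl in c("T", "N", "M", "S")) {
    col <- paste0("stage_", cl)
    raw <- if (is.null(tab[[col]])) rep(NA_character_, nrow(tab)) else as.character(tab[[col]])
    tab[[col]] <- vapply(raw, normalize_stage, "", class = cl, USE.NAMES = FALSE)
  }
  surv <- if (is.null(tab$survival_days)) rep(NA_real_, nrow(tab)) else {
    suppressWarnings(as.numeric(tab$survival_days))
  }
  ev <- if (is.null(tab$event)) rep(NA_character_, nrow(tab)) else as.character(tab$event)
  need <- is.na(surv)
  if (any(need) && !is.null(tab$collection_date)) {
    coll <- as.Date(tab$collection_date)
    death <- if (is.null(tab$death_date)) as.Date(rep(NA, nrow(tab))) else as.Date(tab$death_date)
    last <- if (is.null(tab$last_contact_date)) as.Date(rep(NA, nrow(tab))) else as.Date(tab$last_contact_date)
    dead <- !is.na(death)
    surv[need & dead] <- as.numeric(death[need & dead] - coll[need & dead])
    surv[need & !dead] <- as.numeric(last[need & !dead] - coll[need & !dead])
    ev[is.na(ev)] <- ifelse(dead[is.na(ev)], "deceased", "censored")
  }
  if (any(!is.na(surv) & surv < 0)) stopf("negative survival time in clinical table")
  if (any(!is.na(ev) & !ev %in% c("deceased", "censored"))) {
    stopf("event column must be 'deceased' or 'censored'")
  }
  tab$survival_days <- surv
  tab$event <- ev
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' Normalize a TNM/S stage label
#'
#' Sub-divided stage labels collapse to their common class: `T1a`, `T1b`,
#' `T1c` all become `T1`, `Stage IIIB` becomes `S3`. Empty, `NX`-style or
#' unrecognized labels map to the reserved `MISSING` token. The mapping is
#' idempotent.
#'
#' @param raw_label a raw stage string.
#' @param class one of `"T"`, `"N"`, `"M"`, `"S"`; used to interpret bare
#'   roman-numeral stage labels.
#' @return the normalized label, or `"MISSING"`.
#' @export
normalize_stage <- function(raw_label, class = "T") {
  x <- toupper(trimws(as.character(raw_label %||% "")))
  if (is.na(x) || !nzchar(x) || x == MISSING_LABEL) return(MISSING_LABEL)
  x <- sub("^STAGE\\s*", "S", x)
  roman <- c("0" = "0", "I" = "1", "II" = "2", "III" = "3", "IV" = "4")
  m <- regexec("^([TNMS]?)(0|IV|III|II|I|[0-9])[A-C]?$", x)
  g <- regmatches(x, m)[[1L]]
  if (length(g) == 0L) return(MISSING_LABEL)
  cls <- if (nzchar(g[2L])) g[2L] else toupper(class)
  num <- if (g[3L] %in% names(roman)) roman[[g[3L]]] else g[3L]
  paste0(cls, num)
}

#' Build an early-versus-late comparison design from clinical stage labels
#'
#' Samples whose normalized label for the requested stage class falls into
#' `early_labels` form the early group and likewise for `late_labels`;
#' samples with a missing label are excluded (only patients with a defined
#' stage enter model building — they are the blind-test pool instead).
#'
#' @param clinical a `clinical_table`.
#' @param class_name one of `"T"`, `"N"`, `"M"`, `"S"`.
#' @param early_labels,late_labels disjoint character vectors of normalized
#'   labels, e.g. `c("T1")` versus `c("T3", "T4")`.
#' @return an object of class `comparison_design` with fields `class_name`,
#'   `early`, `late` (sample id vectors) and `tumor_type_of` (named vector).
#' @export
build_design <- function(clinical, class_name, early_labels, late_labels) {
  stopifnot(inherits(clinical, "clinical_table"))
  if (length(intersect(early_labels, late_labels))) {
    stopf("early and late label sets overlap: %s",
          paste(intersect(early_labels, late_labels), collapse = ", "))
  }
  col <- paste0("stage_", class_name)
  if (is.null(clinical[[col]])) stopf("clinical table lacks column %s", col)
  lab <- clinical[[col]]
  early <- clinical$sample_id[lab %in% early_labels]
  late <- clinical$sample_id[lab %in% late_labels]
  new_design(class_name, early, late,
             stats::setNames(clinical$tumor_type, clinical$sample_id))
}

new_design <- function(class_name, early, late, tumor_type_of) {
  if (length(early) == 0L || length(late) == 0L) {
    stopf("empty %s group for class %s",
          if (length(early) == 0L) "early" else "late", class_name)
  }
  if (length(intersect(early, late))) stopf("groups overlap in design %s", class_name)
  structure(
    list(class_name = class_name, early = early, late = late,
         tumor_type_of = tumor_type_of[c(early, late)]),
    class = "comparison_design"
  )
}

#' @export
print.comparison_design <- function(x, ...) {
  cat(sprintf("comparison design '%s': %d early vs %d late samples (%d tumor types)\n",
              x$class_name, length(x$early), length(x$late),
              length(unique(x$tumor_type_of))))
  invisible(x)
}

# binary labels (0 = early, 1 = late) for a sample id vector
design_labels <- function(design, sample_ids = c(design$early, design$late)) {
  stats::setNames(as.integer(sample_ids %in% design$late), sample_ids)
}

#' Default early/late stage groupings per tumor type
#'
#' Loads the configuration file shipped with the package (or a user-supplied
#' file in the same format) giving, per tumor type and stage class, the stage
#' labels pooled into the early and the late group. These groupings are data,
#' not algorithm: they can be overridden by pointing `path` at an edited
#' copy.
#'
#' @param path path to a TSV with columns `cohort`, `class`, `early`, `late`
#'   (labels comma-separated). Defaults to the packaged table.
#' @return data.frame with list-columns `early_labels`, `late_labels`.
#' @export
stage_groupings <- function(path = system.file("extdata", "stage_groups.tsv",
                                               package = "isosig")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$early_labels <- strsplit(tab$early, ",", fixed = TRUE)
  tab$late_labels <- strsplit(tab$late, ",", fixed = TRUE)
  tab
}
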