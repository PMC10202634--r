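#' Analysis thresholds for differential exon usage
#'
#' The filtering rule applied to exon-usage records: the host gene must be
#' expressed (TPM at or above `min_tpm`), the usage change must be at least
#' `min_abs_log2fc` in absolute value, and the BH-adjusted p-value must not
#' exceed `max_padj`. All boundaries are inclusive.
#'
#' @param min_tpm minimum host-gene TPM (default 0.5).
#' @param min_abs_log2fc minimum absolute usage log2 fold change (default 1.0).
#' @param max_padj maximum adjusted p-value (default 0.05).
#' @return An object of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(min_tpm = 0.5, min_abs_log2fc = 1.0,
                                max_padj = 0.05) {
  if (min_tpm < 0) config_error("min_tpm must be >= 0")
  if (min_abs_log2fc < 0) config_error("min_abs_log2fc must be >= 0")
  if (!(max_padj > 0 && max_padj <= 1)) config_error("max_padj must be in (0,1]")
  structure(list(min_tpm = min_tpm, min_abs_log2fc = min_abs_log2fc,
                 max_padj = max_padj),
            class = "analysis_thresholds")
}

#' Transcripts per million
#'
#' `TPM_g = (count_g / length_g) / sum_h(count_h / length_h) * 1e6`, per
#' sample. Columns sum to 1e6.
#'
#' @param gene_counts numeric matrix (genes x samples) or vector.
#' @param gene_lengths positive lengths, one per gene.
#' @return Matrix (or vector) of TPM values with the input dimensions.
#' @export
compute_tpm <- function(gene_counts, gene_lengths) {
  vec <- is.null(dim(gene_counts))
  m <- if (vec) matrix(gene_counts, ncol = 1L,
                       dimnames = list(names(gene_counts), NULL)) else as.matrix(gene_counts)
  if (length(gene_lengths) != nrow(m)) {
    data_error("gene_lengths must have one entry per gene")
  }
  if (any(gene_lengths <= 0)) data_error("gene lengths must be positive")
  rate <- m / gene_lengths
  tot <- colSums(rate)
  if (any(tot == 0)) data_error("TPM undefined: zero total rate in a sample")
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  if (vec) tpm[, 1L] else tpm
}

# total exon length per gene, for TPM
#' Gene lengths (summed exon length) from gene models
#' @param models named list of [gene_model()] objects.
#' @return Named integer vector.
#' @export
gene_lengths <- function(models) {
  vapply(models, function(m) sum(m$exons$end - m$exons$start), integer(1))
}

# sum exon-bin counts to gene level using the gene part of the rowname keys
gene_counts_from_exons <- function(counts) {
  gid <- split_exon_key(rownames(counts))$gene_id
  rowsum(counts, gid, reorder = FALSE)
}

#' Pooled-count differential exon-usage test
#'
#' A transparent stand-in for a full GLM-based differential-exon-usage fit:
#' counts are pooled within each group, usage is the pooled exon count over
#' the pooled gene count, and each exon is tested with a two-sided 2x2 exact
#' test of (exon vs rest-of-gene) x (group). The usage log2 fold change is
#' shrunk with epsilon = 0.5 / pooled gene count (per group) so zero counts
#' give finite values. P-values are BH-adjusted across all tested exons.
#'
#' @param counts integer matrix, rows keyed `gene_id:exon_number`.
#' @param groups character/factor of length `ncol(counts)` with exactly two
#'   levels and at least two samples each; the first level is the reference
#'   ("wt") group.
#' @param models optional named list of [gene_model()] objects; when given,
#'   per-gene TPM (reference-group mean) is attached as `gene_tpm`.
#' @param gene_tpm optional named per-gene TPM vector, used verbatim instead.
#' @return `data.frame` of class `exon_usage` with columns `gene_id`,
#'   `exon_key`, `usage_wt`, `usage_ko`, `usage_log2fc`, `p_value`, `padj`,
#'   `gene_tpm`.
#' @export
exon_usage_test <- function(counts, groups, models = NULL, gene_tpm = NULL) {
  counts <- as.matrix(counts)
  if (length(groups) != ncol(counts)) {
    data_error("groups must have one label per sample column")
  }
  groups <- as.factor(groups)
  lv <- levels(droplevels(groups))
  if (length(lv) != 2L) {
    data_error("exactly two groups are required (got %d)", length(lv))
  }
  if (any(table(groups) < 2L)) {
    data_error("each group needs at least 2 samples")
  }
  keys <- rownames(counts)
  gid <- split_exon_key(keys)$gene_id
  a1 <- rowSums(counts[, groups == lv[1L], drop = FALSE])
  a2 <- rowSums(counts[, groups == lv[2L], drop = FALSE])
  g1 <- rowsum(a1, gid, reorder = FALSE)[, 1L]
  g2 <- rowsum(a2, gid, reorder = FALSE)[, 1L]
  n1 <- g1[gid]; n2 <- g2[gid]
  if (any(n1 <= 0) || any(n2 <= 0)) {
    data_error("every exon's gene must have a positive total in each group")
  }
  u1 <- a1 / n1
  u2 <- a2 / n2
  e1 <- 0.5 / n1
  e2 <- 0.5 / n2
  lfc <- log2((u2 + e2) / (u1 + e1))
  p <- vapply(seq_along(a1), function(i) {
    stats::fisher.test(matrix(c(a1[i], n1[i] - a1[i],
                                a2[i], n2[i] - a2[i]), nrow = 2L))$p.value
  }, numeric(1))
  out <- data.frame(
    gene_id = gid,
    exon_key = keys,
    usage_wt = unname(u1),
    usage_ko = unname(u2),
    usage_log2fc = unname(lfc),
    p_value = pmin(1, p),
    padj = stats::p.adjust(pmin(1, p), method = "BH"),
    stringsAsFactors = FALSE
  )
  if (is.null(gene_tpm) && !is.null(models)) {
    gl <- gene_lengths(models)
    gc1 <- gene_counts_from_exons(counts[, groups == lv[1L], drop = FALSE])
    tpm <- compute_tpm(gc1, gl[rownames(gc1)])
    gene_tpm <- rowMeans(tpm)
  }
  out$gene_tpm <- if (is.null(gene_tpm)) NA_real_ else unname(gene_tpm[gid])
  rownames(out) <- NULL
  class(out) <- c("exon_usage", "data.frame")
  attr(out, "group_levels") <- lv
  out
}

#' Select significantly differentially used exons
#'
#' Keeps records with `gene_tpm >= min_tpm`, `|usage_log2fc| >=
#' min_abs_log2fc` and `padj <= max_padj` (boundaries inclusive).
#'
#' @param records an [exon_usage_test()] table carrying `gene_tpm`.
#' @param thresholds an [analysis_thresholds()].
#' @return The significant subset of `records`.
#' @export
apply_thresholds <- function(records, thresholds = analysis_thresholds()) {
  stopifnot(inherits(thresholds, "analysis_thresholds"))
  if (anyNA(records$gene_tpm)) {
    data_error("records lack gene_tpm; supply models or gene_tpm to exon_usage_test()")
  }
  keep <- records$gene_tpm >= thresholds$min_tpm &
    abs(records$usage_log2fc) >= thresholds$min_abs_log2fc &
    records$padj <= thresholds$max_padj
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify significant exons by the direction of the usage change
#'
#' Exons whose usage drops on regulator loss (`usage_log2fc < 0`) are
#' regulator-activated (the regulator promoted their inclusion); exons whose
#' usage rises are regulator-repressed.
#'
#' @param significant table from [apply_thresholds()].
#' @return `list(activated = , repressed = )`, each a subset of the input.
#' @export
classify_exons <- function(significant) {
  if (nrow(significant) > 0L && any(significant$usage_log2fc == 0)) {
    data_error("zero usage_log2fc in significant set; thresholds should exclude it")
  }
  act <- significant[significant$usage_log2fc < 0, , drop = FALSE]
  rep_ <- significant[significant$usage_log2fc > 0, , drop = FALSE]
  rownames(act) <- NULL; rownames(rep_) <- NULL
  list(activated = act, repressed = rep_)
}

#' Sample regulator-independent background exons
#'
#' Draws a uniform, seeded sample (without replacement) of exons that pass
#' the expression filter but are not significantly differentially used —
#' the "equal number of exons not differentially spliced" background.
#'
#' @param records full [exon_usage_test()] table.
#' @param n sample size; conventionally the number of significant exons.
#' @param seed integer seed.
#' @param thresholds an [analysis_thresholds()].
#' @return The sampled subset of `records`.
#' @export
sample_background <- function(records, n, seed = 1L,
                              thresholds = analysis_thresholds()) {
  sig_keys <- apply_thresholds(records, thresholds)$exon_key
  eligible <- records[records$gene_tpm >= thresholds$min_tpm &
                        !(records$exon_key %in% sig_keys), , drop = FALSE]
  if (n > nrow(eligible)) {
    data_error("requested %d background exons but only %d are eligible",
               n, nrow(eligible))
  }
  withr::with_seed(seed, {
    out <- eligible[sort(sample.int(nrow(eligible), n)), , drop = FALSE]
  })
  rownames(out) <- NULL
  out
}

#' Bundle exon classes with provenance
#'
#' @param activated,repressed,independent exon_usage subsets (disjoint).
#' @param thresholds the [analysis_thresholds()] used.
#' @param seed the background-sampling seed.
#' @return An object of class `exon_class_set` with elements `activated`,
#'   `repressed`, `independent`, `provenance`.
#' @export
exon_class_set <- function(activated, repressed, independent,
                           thresholds = analysis_thresholds(), seed = NA_integer_) {
  keys <- c(activated$exon_key, repressed$exon_key, independent$exon_key)
  if (anyDuplicated(keys)) {
    data_error("exon classes must be disjoint")
  }
  structure(
    list(activated = activated, repressed = repressed,
         independent = independent,
         provenance = list(thresholds = thresholds, seed = seed)),
    class = "exon_class_set"
  )
}

#' @export
print.exon_class_set <- function(x, ...) {
  cat(sprintf("<exon_class_set> activated %d | repressed %d | independent %d\n",
              nrow(x$activated), nrow(x$repressed), nrow(x$independent)))
  invisible(x)
}

#' Write an exon-usage record table
#'
#' Tab-delimited, floats at 6 significant digits.
#' @param records an exon_usage table.
#' @param path output path.
#' @export
write_usage_records <- function(records, path) {
  out <- records
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
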