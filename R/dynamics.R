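#' Overlap between two gene sets
#'
#' @param set_a,set_b character vectors (treated as sets).
#' @return `list(n_intersect, fraction_b_in_a, fraction_a_in_b, jaccard)`;
#'   fractions are 0 when their denominator is empty.
#' @export
overlap_genes <- function(set_a, set_b) {
  a <- unique(set_a); b <- unique(set_b)
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  list(
    n_intersect = i,
    fraction_b_in_a = if (length(b) == 0L) 0 else i / length(b),
    fraction_a_in_b = if (length(a) == 0L) 0 else i / length(a),
    jaccard = if (u == 0L) 0 else i / u
  )
}

#' Fold-change concordance between two differential-splicing analyses
#'
#' Joins two exon-usage tables on `exon_key`, restricts to exons significant
#' in either analysis (`scope = "union"`, default) or in both
#' (`"intersection"`), and reports Pearson and Spearman correlation of the
#' usage log2 fold changes plus the slope of the b-on-a regression — the
#' slope documents magnitude asymmetry between, e.g., adult and embryonic
#' responses.
#'
#' @param records_a,records_b [exon_usage_test()] tables.
#' @param thresholds an [analysis_thresholds()] defining "significant".
#' @param scope `"union"` or `"intersection"`.
#' @return `list(pearson_r, spearman_rho, slope, n)`.
#' @export
lfc_correlation <- function(records_a, records_b,
                            thresholds = analysis_thresholds(),
                            scope = c("union", "intersection")) {
  scope <- match.arg(scope)
  sig_a <- apply_thresholds(records_a, thresholds)$exon_key
  sig_b <- apply_thresholds(records_b, thresholds)$exon_key
  keep <- if (scope == "union") union(sig_a, sig_b) else intersect(sig_a, sig_b)
  shared <- intersect(intersect(records_a$exon_key, records_b$exon_key), keep)
  if (length(shared) < 3L) {
    data_error("need >= 3 shared significant exons (got %d)", length(shared))
  }
  x <- records_a$usage_log2fc[match(shared, records_a$exon_key)]
  y <- records_b$usage_log2fc[match(shared, records_b$exon_key)]
  list(
    pearson_r = stats::cor(x, y, method = "pearson"),
    spearman_rho = stats::cor(x, y, method = "spearman"),
    slope = unname(stats::coef(stats::lm(y ~ x))[2L]),
    n = length(shared)
  )
}

#' Z-score a usage matrix within cohorts
#'
#' Each row is standardized separately within each cohort: subtract the
#' cohort mean and divide by the cohort sample standard deviation (n-1
#' denominator). Zero-variance (row, cohort) cells become all zeros and are
#' flagged.
#'
#' @param mat numeric matrix (features x samples).
#' @param cohorts character/factor of length `ncol(mat)`; every cohort needs
#'   at least 2 samples.
#' @return Matrix of z-scores with attribute `zero_variance`, a logical
#'   matrix (rows x cohorts) marking flagged cells.
#' @export
zscore_by_cohort <- function(mat, cohorts) {
  mat <- as.matrix(mat)
  cohorts <- as.factor(cohorts)
  if (length(cohorts) != ncol(mat)) {
    data_error("cohorts must have one label per column")
  }
  if (any(table(cohorts) < 2L)) {
    data_error("every cohort needs at least 2 samples")
  }
  out <- mat
  zv <- matrix(FALSE, nrow(mat), nlevels(cohorts),
               dimnames = list(rownames(mat), levels(cohorts)))
  for (co in levels(cohorts)) {
    j <- which(cohorts == co)
    mu <- rowMeans(mat[, j, drop = FALSE])
    sd_ <- apply(mat[, j, drop = FALSE], 1L, stats::sd)
    zero <- sd_ == 0
    zv[, co] <- zero
    z <- (mat[, j, drop = FALSE] - mu) / ifelse(zero, 1, sd_)
    z[zero, ] <- 0
    out[, j] <- z
  }
  attr(out, "zero_variance") <- zv
  out
}

#' Detect exons and genes reverting to a reference (embryonic) state
#'
#' An exon reverts when (i) it is significant in the adult analysis, (ii) the
#' knockout moves its usage in the direction of the embryonic wild-type value
#' (`sign(adult_ko - adult_wt) == sign(embryo_wt - adult_wt)`), (iii) the
#' knockout ends up closer to the embryonic value than the adult wild type
#' was (`|adult_ko - embryo_wt| < |adult_wt - embryo_wt|`), and (iv) a
#' developmental difference exists to revert across
#' (`|adult_wt - embryo_wt| >= min_move`). A gene reverts when at least one
#' of its exons does.
#'
#' @param adult_records adult [exon_usage_test()] table (`usage_wt`,
#'   `usage_ko` are the adult WT/KO usages).
#' @param embryo_wt named numeric vector of embryonic wild-type usages keyed
#'   by `exon_key`; every adult-significant exon must be present.
#' @param thresholds an [analysis_thresholds()] defining adult significance.
#' @param min_move minimum absolute usage difference between adult and
#'   embryonic wild type (default 0.1).
#' @return `list(events = SpliceEventComparison data.frame,
#'   reverted_genes = character, n_reverted_genes = integer)`.
#' @export
detect_reversion <- function(adult_records, embryo_wt,
                             thresholds = analysis_thresholds(),
                             min_move = 0.1) {
  sig <- apply_thresholds(adult_records, thresholds)
  missing_keys <- setdiff(sig$exon_key, names(embryo_wt))
  if (length(missing_keys) > 0L) {
    data_error("no embryonic usage for exon(s): %s%s",
               paste(utils::head(missing_keys, 5L), collapse = ", "),
               if (length(missing_keys) > 5L) ", ..." else "")
  }
  emb <- unname(embryo_wt[sig$exon_key])
  move_ko <- sig$usage_ko - sig$usage_wt
  move_dev <- emb - sig$usage_wt
  reverted <- sign(move_ko) == sign(move_dev) &
    abs(sig$usage_ko - emb) < abs(sig$usage_wt - emb) &
    abs(move_dev) >= min_move &
    move_ko != 0
  events <- data.frame(
    exon_key = sig$exon_key,
    gene_id = sig$gene_id,
    adult_wt_usage = sig$usage_wt,
    adult_ko_usage = sig$usage_ko,
    embryo_wt_usage = emb,
    adult_lfc = sig$usage_log2fc,
    reverted = reverted,
    stringsAsFactors = FALSE
  )
  rg <- sort(unique(events$gene_id[events$reverted]))
  list(events = events, reverted_genes = rg, n_reverted_genes = length(rg))
}
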