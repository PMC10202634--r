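# exon-level motif summaries over a region table: for each motif, the number
# of distinct exons with >= 1 hit and the total hit count
motif_exon_summary <- function(regions, motifs) {
  exons <- unique(regions$exon_key)
  res <- lapply(seq_len(nrow(motifs)), function(i) {
    n <- scan_count_many(regions$seq, motifs$pattern[i])
    per_exon <- rowsum(n, regions$exon_key, reorder = FALSE)[, 1L]
    c(exons_hit = sum(per_exon > 0L), total_hits = sum(per_exon))
  })
  data.frame(
    motif_id = motifs$motif_id,
    exons_hit = vapply(res, `[[`, numeric(1), "exons_hit"),
    total_hits = vapply(res, `[[`, numeric(1), "total_hits"),
    n_exons = length(exons),
    stringsAsFactors = FALSE
  )
}

# one-sided (enrichment) exact p for a 2x2 table a,b (fg hit / miss),
# c,d (bg hit / miss)
fisher_greater_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L),
                     alternative = "greater")$p.value
}

#' Rank motif enrichment in foreground versus background regions
#'
#' The unit of analysis is the exon: an exon "has" a motif if any of its four
#' proximal regions contains at least one hit (`unit = "presence"`, default).
#' Each motif is tested with a one-sided 2x2 exact test (enrichment in the
#' foreground), the odds ratio is Haldane-corrected
#' `((a+.5)(d+.5)) / ((b+.5)(c+.5))`, p-values are BH-adjusted across motifs
#' and motifs are ranked by ascending p (ties: descending odds ratio).
#' With `unit = "hits"` total hit counts (vs scanned positions) are compared
#' instead of per-exon presence.
#'
#' @param fg_regions foreground region table ([proximal_regions()]) around
#'   the differentially used exons.
#' @param bg_regions background region table around the matched
#'   not-differentially-used exons; must be extracted with the same
#'   [window_spec()].
#' @param motifs a [motif_table()].
#' @param unit `"presence"` (default) or `"hits"`.
#' @return `data.frame` sorted by rank: `motif_id`, `rbp_name`, `iupac`,
#'   `fg_regions_hit`, `fg_total`, `bg_regions_hit`, `bg_total`,
#'   `odds_ratio`, `p_value`, `padj`, `rank`.
#' @export
enrich_motifs <- function(fg_regions, bg_regions, motifs,
                          unit = c("presence", "hits")) {
  unit <- match.arg(unit)
  if (nrow(fg_regions) == 0L || nrow(bg_regions) == 0L) {
    data_error("foreground and background region sets must be nonempty")
  }
  wf <- attr(fg_regions, "window_spec")
  wb <- attr(bg_regions, "window_spec")
  if (!is.null(wf) && !is.null(wb) && !identical(unclass(wf), unclass(wb))) {
    data_error("foreground and background were extracted with different window specs")
  }
  fg <- motif_exon_summary(fg_regions, motifs)
  bg <- motif_exon_summary(bg_regions, motifs)
  if (unit == "presence") {
    a <- fg$exons_hit; A <- fg$n_exons
    c_ <- bg$exons_hit; C <- bg$n_exons
  } else {
    a <- fg$total_hits; A <- sum(pmax(fg_regions$length, 0))
    c_ <- bg$total_hits; C <- sum(pmax(bg_regions$length, 0))
  }
  b <- A - a; d <- C - c_
  or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  p <- vapply(seq_along(a), function(i) {
    fisher_greater_p(a[i], b[i], c_[i], d[i])
  }, numeric(1))
  out <- data.frame(
    motif_id = motifs$motif_id,
    rbp_name = motifs$rbp_name,
    iupac = motifs$iupac,
    fg_regions_hit = as.integer(a),
    fg_total = as.integer(A),
    bg_regions_hit = as.integer(c_),
    bg_total = as.integer(C),
    odds_ratio = or,
    p_value = p,
    padj = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  ord <- order(out$p_value, -out$odds_ratio)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Positional motif profile per exon class
#'
#' Counts motif hits on the transcript-sense upstream side (upstream intron
#' window plus the exon-start window) and downstream side (exon-end window
#' plus downstream intron window) of every exon in each class, and normalizes
#' by class size: `normalized_count = total hits on that side / number of
#' exons in the class`. A per-offset hit density is also returned for
#' track-style plotting.
#'
#' @param classes an [exon_class_set()]; every class must be nonempty.
#' @param regions region table covering the classed exons
#'   ([proximal_regions()]).
#' @param motif single IUPAC string or one-row [motif_table()].
#' @return Object of class `positional_profile`: `summary` (`class`, `side`,
#'   `n_exons`, `hits`, `normalized_count`), `density` (`class`, `region`,
#'   `offset`, `hits`), `motif`.
#' @export
positional_profile <- function(classes, regions, motif) {
  stopifnot(inherits(classes, "exon_class_set"))
  pat <- as_pattern(motif)
  class_keys <- list(
    activated = classes$activated$exon_key,
    repressed = classes$repressed$exon_key,
    independent = classes$independent$exon_key
  )
  empty <- vapply(class_keys, length, integer(1)) == 0L
  if (any(empty)) {
    data_error("empty exon class(es): %s — profile undefined",
               paste(names(class_keys)[empty], collapse = ", "))
  }
  side_of <- c(upstream_intron = "upstream", exon_start = "upstream",
               exon_end = "downstream", downstream_intron = "downstream")
  summaries <- list(); densities <- list()
  for (cl in names(class_keys)) {
    r <- regions[regions$exon_key %in% class_keys[[cl]], , drop = FALSE]
    miss <- setdiff(class_keys[[cl]], unique(r$exon_key))
    if (length(miss) > 0L) {
      data_error("regions missing for %d exon(s) of class %s", length(miss), cl)
    }
    offs <- scan_offsets_many(r$seq, pat)
    n <- lengths(offs)
    side <- side_of[r$region]
    hits_by_side <- tapply(n, side, sum)
    n_cl <- length(class_keys[[cl]])
    summaries[[cl]] <- data.frame(
      class = cl,
      side = c("upstream", "downstream"),
      n_exons = n_cl,
      hits = as.integer(c(hits_by_side[["upstream"]] %||% 0,
                          hits_by_side[["downstream"]] %||% 0)),
      stringsAsFactors = FALSE
    )
    if (sum(n) > 0L) {
      idx <- rep.int(seq_along(offs), n)
      densities[[cl]] <- stats::aggregate(
        hits ~ class + region + offset,
        data = data.frame(class = cl, region = r$region[idx],
                          offset = unlist(offs, use.names = FALSE), hits = 1L,
                          stringsAsFactors = FALSE),
        FUN = sum
      )
    }
  }
  summary <- do.call(rbind, summaries)
  summary$normalized_count <- summary$hits / summary$n_exons
  rownames(summary) <- NULL
  density <- if (length(densities) > 0L) {
    d <- do.call(rbind, densities); rownames(d) <- NULL; d
  } else {
    data.frame(class = character(0), region = character(0),
               offset = integer(0), hits = integer(0))
  }
  structure(list(summary = summary, density = density, motif = pat),
            class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("<positional_profile> motif %s\n", x$motif))
  print(x$summary)
  invisible(x)
}

#' Infer the regulator's positional mode per exon class
#'
#' For each exon class, the asymmetry index
#' `A = (downstream - upstream) / (downstream + upstream)` of normalized
#' motif counts is compared to the threshold `tau`: `A > tau` is the
#' activator pattern (motifs sit downstream of exons the regulator
#' activates), `A < -tau` the repressor pattern, otherwise the call is
#' ambiguous. A zero denominator yields an ambiguous, flagged call.
#'
#' @param profile a [positional_profile()].
#' @param tau asymmetry threshold in `[0,1)` (default 0.2, conservative
#'   against sampling noise in small classes).
#' @return `data.frame`: `class`, `upstream`, `downstream`, `asymmetry`,
#'   `mode` (`activator-pattern`/`repressor-pattern`/`ambiguous`),
#'   `flagged`.
#' @export
classify_mode <- function(profile, tau = 0.2) {
  stopifnot(inherits(profile, "positional_profile"))
  s <- profile$summary
  up <- s$normalized_count[s$side == "upstream"]
  dn <- s$normalized_count[s$side == "downstream"]
  cls <- s$class[s$side == "upstream"]
  denom <- up + dn
  A <- ifelse(denom == 0, NA_real_, (dn - up) / denom)
  mode <- ifelse(is.na(A), "ambiguous",
                 ifelse(A > tau, "activator-pattern",
                        ifelse(A < -tau, "repressor-pattern", "ambiguous")))
  data.frame(
    class = cls, upstream = up, downstream = dn,
    asymmetry = A, mode = mode, flagged = denom == 0,
    stringsAsFactors = FALSE
  )
}
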