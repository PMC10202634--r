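#' Window specification for proximal regions
#'
#' Defines how much sequence is examined around each exon: a window in each
#' flanking intron and a window just inside each exon edge. Defaults follow
#' the standard positional-map choice of 200 nt of intron and 10 nt of exon.
#'
#' @param intron_window nt of flanking intron per side (default 200).
#' @param exon_window nt inside each exon edge (default 10).
#' @param exon_edges `"both"` (default): a window at each exon edge;
#'   `"start_only"`: only the transcript 5' edge carries an exonic window.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(intron_window = 200L, exon_window = 10L,
                        exon_edges = c("both", "start_only")) {
  exon_edges <- match.arg(exon_edges)
  if (!is_count(intron_window) || !is_count(exon_window)) {
    config_error("intron_window and exon_window must be counts >= 1")
  }
  structure(
    list(intron_window = as.integer(intron_window),
         exon_window = as.integer(exon_window),
         exon_edges = exon_edges),
    class = "window_spec"
  )
}

#' Extract the proximal regions around one exon
#'
#' Returns the four transcript-sense windows around an exon: the
#' `upstream_intron` window (5' of the exon in mRNA direction), the
#' `exon_start` and `exon_end` windows just inside the two exon edges, and the
#' `downstream_intron` window. Windows are truncated, never extended, at the
#' neighbouring exon; when the exon is shorter than twice the exon window the
#' two exonic windows split the exon at its midpoint (transcript-sense 5'
#' half rounds up) so they never overlap. Terminal exons yield an empty,
#' flagged region on the missing-intron side. Each region carries its genomic
#' provenance so sequences can be re-fetched and exported.
#'
#' @param model a [gene_model()].
#' @param exon_number transcript-sense exon number (1 = 5'-most).
#' @param genome a named [Biostrings::DNAStringSet].
#' @param window a [window_spec()].
#' @return `data.frame` with one row per region (`upstream_intron`,
#'   `exon_start`, `exon_end`, `downstream_intron`): columns `exon_key`,
#'   `gene_id`, `region`, `chrom`, `start`, `end`, `strand`, `length`, `seq`,
#'   `truncated`, `terminal`.
#' @export
extract_proximal_regions <- function(model, exon_number, genome,
                                     window = window_spec()) {
  stopifnot(inherits(model, "gene_model"), inherits(window, "window_spec"))
  gi <- genomic_exon_index(model, exon_number)
  k <- n_exons(model)
  ex <- model$exons
  s <- ex$start[gi]; e <- ex$end[gi]
  w <- window$intron_window
  ew <- window$exon_window
  plus <- model$strand == "+"

  up_gi <- if (plus) gi - 1L else gi + 1L     # transcript-upstream neighbour
  dn_gi <- if (plus) gi + 1L else gi - 1L
  has_up <- up_gi >= 1L && up_gi <= k
  has_dn <- dn_gi >= 1L && dn_gi <= k

  # flanking intron windows (genomic coordinates), transcript sense applied
  # at sequence-fetch time
  if (has_up) {
    if (plus) {
      lo <- max(ex$end[up_gi], s - w); up_iv <- c(lo, s)
    } else {
      hi <- min(ex$start[up_gi], e + w); up_iv <- c(e, hi)
    }
  } else up_iv <- if (plus) c(s, s) else c(e, e)
  if (has_dn) {
    if (plus) {
      hi <- min(ex$start[dn_gi], e + w); dn_iv <- c(e, hi)
    } else {
      lo <- max(ex$end[dn_gi], s - w); dn_iv <- c(lo, s)
    }
  } else dn_iv <- if (plus) c(e, e) else c(s, s)

  # exonic edge windows, split at the transcript-sense midpoint if short
  L <- e - s
  if (window$exon_edges == "start_only") {
    ls <- min(ew, L); le <- 0L
  } else if (L >= 2L * ew) {
    ls <- ew; le <- ew
  } else {
    ls <- as.integer(ceiling(L / 2)); le <- L - ls
  }
  if (plus) {
    es_iv <- c(s, s + ls); ee_iv <- c(e - le, e)
  } else {
    es_iv <- c(e - ls, e); ee_iv <- c(s, s + le)
  }

  iv <- rbind(up_iv, es_iv, ee_iv, dn_iv)
  lens <- iv[, 2L] - iv[, 1L]
  seqs <- vapply(seq_len(4L), function(i) {
    fetch_transcript_sense(genome, model$chrom, iv[i, 1L], iv[i, 2L],
                           model$strand)
  }, character(1))
  truncated <- c(has_up && lens[1L] < w,
                 lens[2L] < ew,
                 window$exon_edges == "both" && lens[3L] < ew,
                 has_dn && lens[4L] < w)
  out <- data.frame(
    exon_key = exon_key(model$gene_id, exon_number),
    gene_id = model$gene_id,
    region = REGION_NAMES,
    chrom = model$chrom,
    start = as.integer(iv[, 1L]),
    end = as.integer(iv[, 2L]),
    strand = model$strand,
    length = as.integer(lens),
    seq = seqs,
    truncated = truncated,
    terminal = c(!has_up, FALSE, FALSE, !has_dn),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Extract proximal regions for many exons
#'
#' @param models named list of [gene_model()] objects.
#' @param genome a named [Biostrings::DNAStringSet].
#' @param keys exon keys (`gene:exon_number`, transcript-sense); default all
#'   exons of all models.
#' @param window a [window_spec()].
#' @return Row-bound region table (see [extract_proximal_regions()]) with the
#'   window spec attached as attribute `window_spec`.
#' @export
proximal_regions <- function(models, genome, keys = NULL,
                             window = window_spec()) {
  if (inherits(models, "gene_model")) models <- list(models)
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- vapply(models, `[[`, character(1), "gene_id")
  }
  if (is.null(keys)) keys <- exon_keys(models)
  parts <- split_exon_key(keys)
  miss <- setdiff(unique(parts$gene_id), names(models))
  if (length(miss) > 0L) {
    coord_error("exon keys reference unknown gene(s): %s",
                paste(utils::head(miss, 3L), collapse = ", "))
  }
  out <- do.call(rbind, lapply(seq_along(keys), function(i) {
    extract_proximal_regions(models[[parts$gene_id[i]]], parts$exon_number[i],
                             genome, window)
  }))
  rownames(out) <- NULL
  attr(out, "window_spec") <- window
  out
}

#' Export a region table as BED6
#'
#' 0-based half-open intervals; name column is `gene:exon_number:region`;
#' empty regions are dropped (BED cannot carry zero-length features).
#'
#' @param regions region table from [proximal_regions()].
#' @param path output path.
#' @export
regions_to_bed <- function(regions, path) {
  keep <- regions$length > 0L
  r <- regions[keep, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   r$chrom, r$start, r$end,
                   paste(r$exon_key, r$region, sep = ":"), r$strand)
  writeLines(lines, path)
  invisible(path)
}
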