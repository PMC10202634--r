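#' Construct a gene model
#'
#' A gene model is a gene on one chromosome and strand with an ordered set of
#' non-overlapping exons. Coordinates are internal convention: 0-based,
#' half-open `[start, end)`. Exons are stored in genomic order; transcript-sense
#' exon numbering (1 = 5'-most exon of the mRNA) is derived from the strand.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome (sequence) name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with integer columns `start`, `end`
#'   (0-based half-open).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons) {
  if (!strand %in% c("+", "-")) format_error("strand must be '+' or '-'")
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$end <= exons$start)) {
    format_error("gene %s: exon with end <= start", gene_id)
  }
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    format_error("gene %s: overlapping exons", gene_id)
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand, exons = exons),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s(%s)  %d exons, span [%d,%d)\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              min(x$exons$start), max(x$exons$end)))
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)

# genomic index of the transcript-sense exon_number
genomic_exon_index <- function(model, exon_number) {
  k <- n_exons(model)
  if (!is_count(exon_number) || exon_number > k) {
    coord_error("gene %s has no exon %s", model$gene_id, exon_number)
  }
  if (model$strand == "+") as.integer(exon_number) else k - as.integer(exon_number) + 1L
}

# transcript-sense exon numbers in genomic order
transcript_exon_numbers <- function(model) {
  k <- n_exons(model)
  if (model$strand == "+") seq_len(k) else rev(seq_len(k))
}

#' Exon keys of one or many gene models
#'
#' Keys are `gene_id:exon_number` with transcript-sense exon numbering,
#' listed in transcript order.
#'
#' @param models a `gene_model` or list of them.
#' @return Character vector of exon keys.
#' @export
exon_keys <- function(models) {
  if (inherits(models, "gene_model")) models <- list(models)
  unlist(lapply(models, function(m) {
    exon_key(m$gene_id, seq_len(n_exons(m)))
  }), use.names = FALSE)
}

#' Read a genome FASTA
#'
#' Reads a multi-record FASTA into a `DNAStringSet`, folding sequence to
#' uppercase. Duplicate record names and characters outside `ACGTN` are
#' rejected: the motif scanner's semantics are defined over `ACGTN` only.
#'
#' @param path path to a FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) format_error("bad FASTA: %s", conditionMessage(e)))
  nms <- names(raw)
  if (anyDuplicated(nms)) {
    format_error("duplicate FASTA record name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  chrs <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", chrs)
  if (any(bad)) {
    format_error("FASTA record(s) with characters outside ACGTN: %s",
                 paste(nms[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(chrs)
  names(out) <- nms
  out
}

#' Write a genome FASTA
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' Write gene models as GTF
#'
#' Emits exon features with 1-based inclusive coordinates and attributes
#' `gene_id "X"; exon_number "N";` (transcript-sense numbering), the dialect
#' read back by [read_gtf()].
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @export
write_gtf <- function(models, path) {
  lines <- unlist(lapply(models, function(m) {
    en <- transcript_exon_numbers(m)
    sprintf('%s\tposmap\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; exon_number "%d";',
            m$chrom, m$exons$start + 1L, m$exons$end, m$strand, m$gene_id, en)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' Imports exon features from a GTF file (1-based inclusive coordinates),
#' converts to the internal 0-based half-open convention, and groups and
#' sorts exons per gene. Every exon must carry a `gene_id`; exons of one gene
#' must share chromosome and strand and must not overlap.
#'
#' @param path path to a GTF file.
#' @return Named list of [gene_model()] objects (names = gene ids, input order).
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) format_error("bad GTF: %s", conditionMessage(e)))
  type <- as.character(gr$type)
  gr <- gr[type == "exon"]
  if (length(gr) == 0L) format_error("GTF contains no exon features")
  gid <- gr$gene_id
  if (is.null(gid) || anyNA(gid) || any(gid == "")) {
    format_error("GTF exon feature without gene_id")
  }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L  # to 0-based half-open
  end0 <- GenomicRanges::end(gr)
  ord <- unique(gid)
  models <- lapply(ord, function(g) {
    i <- which(gid == g)
    if (length(unique(chrom[i])) != 1L || length(unique(strand[i])) != 1L) {
      format_error("gene %s: exons on multiple chromosomes or strands", g)
    }
    if (!all(strand[i][1L] %in% c("+", "-"))) {
      format_error("gene %s: missing strand", g)
    }
    gene_model(g, chrom[i][1L], strand[i][1L],
               data.frame(start = start0[i], end = end0[i]))
  })
  names(models) <- ord
  models
}

#' Fetch a genomic interval in transcript sense
#'
#' Returns the sequence of a 0-based half-open interval, reverse-complemented
#' when the strand is `"-"`, so the result always reads 5' to 3' in mRNA
#' direction.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param chrom sequence name.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return A character string of length `end - start`.
#' @export
fetch_transcript_sense <- function(genome, chrom, start, end, strand) {
  if (!chrom %in% names(genome)) coord_error("unknown sequence: %s", chrom)
  L <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (start < 0 || end > L || start > end) {
    coord_error("interval [%d,%d) out of bounds for %s (length %d)",
                start, end, chrom, L)
  }
  if (start == end) return("")
  s <- as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
  if (strand == "-") revcomp_chr(s) else s
}
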