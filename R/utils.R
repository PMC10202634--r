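# IUPAC degenerate nucleotide code -> set of concrete DNA bases.
# U is accepted on input (RNA alphabet) and mapped to T.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

REGION_NAMES <- c("upstream_intron", "exon_start", "exon_end", "downstream_intron")

`%||%` <- function(x, y) if (is.null(x)) y else x

pm_condition <- function(msg, class, call = sys.call(-1)) {
  structure(
    class = c(class, "posmap_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

config_error <- function(fmt, ...) {
  stop(pm_condition(sprintf(fmt, ...), "posmap_config_error"))
}

format_error <- function(fmt, ...) {
  stop(pm_condition(sprintf(fmt, ...), "posmap_format_error"))
}

coord_error <- function(fmt, ...) {
  stop(pm_condition(sprintf(fmt, ...), "posmap_coord_error"))
}

data_error <- function(fmt, ...) {
  stop(pm_condition(sprintf(fmt, ...), "posmap_data_error"))
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# reverse complement of a plain character string (DNA, may contain N)
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# normalize an RNA/DNA IUPAC string to the internal DNA alphabet (U -> T)
normalize_iupac <- function(x, what = "motif") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- setdiff(unique(strsplit(x, "")[[1]]), names(IUPAC_SETS))
  if (length(bad) > 0L) {
    format_error("%s contains non-IUPAC character(s): %s", what,
                 paste(bad, collapse = ", "))
  }
  x
}

# split "gene:exon_number" keys; gene ids must not end in ":<digits>" themselves
split_exon_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.*):([0-9]+)$", keys))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    format_error("malformed exon key(s): %s",
                 paste(utils::head(keys[bad], 3L), collapse = ", "))
  }
  data.frame(
    gene_id = vapply(m, `[`, character(1), 2L),
    exon_number = as.integer(vapply(m, `[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
}

exon_key <- function(gene_id, exon_number) {
  paste0(gene_id, ":", exon_number)
}
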