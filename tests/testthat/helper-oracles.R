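# Independent oracles used to freeze expected values. These deliberately do
# not reuse package internals.

# brute-force position-by-position IUPAC scan (0-based offsets); N in the
# sequence matches no motif position
oracle_scan <- function(s, pat) {
  SETS <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  sc <- strsplit(s, "")[[1]]
  pc <- strsplit(chartr("U", "T", toupper(pat)), "")[[1]]
  L <- length(sc); k <- length(pc)
  if (L < k) return(integer(0))
  hits <- integer(0)
  for (off in 0:(L - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!(sc[off + j] %in% SETS[[pc[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, off)
  }
  hits
}

# reverse complement without Biostrings
oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# exact hypergeometric enumeration for a 2x2 table
#   a b   (row sums m = a+b, n = c+d; first-column total k = a+c)
#   c d
# two-sided: sum of P(X = x) for all x with P(X = x) <= P(a) * (1 + 1e-7)
oracle_fisher2x2 <- function(a, b, c, d,
                             alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  logp <- vapply(lo:hi, function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }, numeric(1))
  ps <- exp(logp)
  xs <- lo:hi
  pobs <- ps[match(a, xs)]
  if (alternative == "greater") {
    sum(ps[xs >= a])
  } else {
    sum(ps[ps <= pobs * (1 + 1e-7)])
  }
}

# random IUPAC motif and random ACGTN sequence for property tests
random_motif <- function(len) {
  paste(sample(c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N"), len, replace = TRUE), collapse = "")
}

random_seq <- function(len, p_n = 0.02) {
  paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# reverse-complement every chromosome and flip all annotations:
# coordinates map [s, e) -> [L - e, L - s), strands toggle
flip_dataset <- function(genome, models) {
  L <- stats::setNames(Biostrings::width(genome), names(genome))
  genome2 <- Biostrings::reverseComplement(genome)
  names(genome2) <- names(genome)
  models2 <- lapply(models, function(m) {
    len <- L[[m$chrom]]
    gene_model(m$gene_id, m$chrom,
               if (m$strand == "+") "-" else "+",
               data.frame(start = len - m$exons$end,
                          end = len - m$exons$start))
  })
  names(models2) <- names(models)
  list(genome = genome2, models = models2)
}

# one gene on a bare genome: exon [1000,1100) with long flanks, 5 exons
toy_gene <- function(strand = "+", intron = 300L, chrom_len = 6000L,
                     base = "A") {
  exons <- data.frame(
    start = c(200L, 1000L, 2000L, 3000L, 4000L),
    end = c(400L, 1100L, 2100L, 3100L, 4100L)
  )
  genome <- Biostrings::DNAStringSet(strrep(base, chrom_len))
  names(genome) <- "chrT"
  list(genome = genome,
       model = gene_model("gT", "chrT", strand, exons))
}

# minimal exon-usage record table for threshold/classification tests
usage_record <- function(exon_key, lfc, padj, tpm, usage_wt = 0.5,
                         usage_ko = 0.5, p = padj) {
  data.frame(
    gene_id = sub(":[0-9]+$", "", exon_key),
    exon_key = exon_key,
    usage_wt = usage_wt,
    usage_ko = usage_ko,
    usage_log2fc = lfc,
    p_value = p,
    padj = padj,
    gene_tpm = tpm,
    stringsAsFactors = FALSE
  )
}

# region table rows for enrichment tests (no genomic provenance needed)
fake_regions <- function(exon_keys, seqs, region = "upstream_intron") {
  data.frame(
    exon_key = exon_keys,
    gene_id = sub(":[0-9]+$", "", exon_keys),
    region = region,
    chrom = "chrF", start = 0L, end = nchar(seqs), strand = "+",
    length = nchar(seqs), seq = seqs,
    truncated = FALSE, terminal = FALSE,
    stringsAsFactors = FALSE
  )
}
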