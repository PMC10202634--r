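#' Build a motif table
#'
#' Constructs the motif container used throughout the package: one row per
#' motif with its identifier, the RNA-binding protein it belongs to, the IUPAC
#' string as supplied (RNA alphabet allowed) and the internal DNA-alphabet
#' pattern (U mapped to T).
#'
#' @param rbp_name character vector of RBP names.
#' @param iupac character vector of degenerate motifs over
#'   `A C G U T R Y S W K M B D H V N`; minimum length 3.
#' @param motif_id optional identifiers; defaults to `rbp_name` made unique.
#' @return A `data.frame` of class `motif_table` with columns `motif_id`,
#'   `rbp_name`, `iupac`, `pattern` (internal DNA alphabet).
#' @export
motif_table <- function(rbp_name, iupac, motif_id = NULL) {
  if (length(rbp_name) != length(iupac)) {
    format_error("rbp_name and iupac must have equal length")
  }
  pattern <- vapply(iupac, normalize_iupac, character(1), USE.NAMES = FALSE)
  if (any(nchar(pattern) < 3L)) {
    format_error("motifs must be at least 3 nt long")
  }
  keep <- !duplicated(paste(rbp_name, pattern, sep = "\r"))
  rbp_name <- rbp_name[keep]
  iupac <- iupac[keep]
  pattern <- pattern[keep]
  if (is.null(motif_id)) {
    motif_id <- make.unique(rbp_name, sep = "_")
  } else {
    motif_id <- motif_id[keep]
  }
  out <- data.frame(
    motif_id = as.character(motif_id),
    rbp_name = as.character(rbp_name),
    iupac = as.character(iupac),
    pattern = pattern,
    stringsAsFactors = FALSE
  )
  class(out) <- c("motif_table", "data.frame")
  out
}

#' Read an ATtRACT-style motif table
#'
#' Parses a tab-delimited RBP motif collection with a header row. The columns
#' `Gene_name` and `Motif` are required; all others are ignored. Duplicate
#' (RBP, motif) pairs collapse to a single entry.
#'
#' @param path path to the tab-delimited file.
#' @return A [motif_table()].
#' @export
parse_attract_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Gene_name", "Motif")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    format_error("motif table lacks required column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  motif_table(rbp_name = tab$Gene_name, iupac = tab$Motif)
}

#' Write a motif table in ATtRACT-style format
#'
#' @param motifs a [motif_table()].
#' @param path output path.
#' @export
write_attract_table <- function(motifs, path) {
  utils::write.table(
    data.frame(Gene_name = motifs$rbp_name, Motif = motifs$iupac),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# Compile an internal (DNA-alphabet) IUPAC pattern to a zero-width lookahead
# regex so overlapping occurrences are all found. N in the *subject* never
# matches because character classes list concrete bases only.
iupac_regex <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  classes <- vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  paste0("(?=", paste(classes, collapse = ""), ")")
}

as_pattern <- function(motif) {
  if (is.character(motif) && length(motif) == 1L) {
    normalize_iupac(motif)
  } else if (inherits(motif, "data.frame") && nrow(motif) == 1L &&
             "pattern" %in% names(motif)) {
    motif$pattern
  } else {
    format_error("motif must be a single IUPAC string or a one-row motif_table")
  }
}

#' Scan a sequence for a degenerate motif
#'
#' Reports every start offset (0-based, transcript sense) at which each motif
#' position's IUPAC class contains the sequence character. Overlapping matches
#' are all reported. `N` in the sequence matches no motif position, including
#' motif `N`: an unknown base is not evidence of a binding site.
#'
#' @param sequence a single uppercase DNA string over `ACGTN` (empty allowed).
#' @param motif a single IUPAC string (RNA alphabet allowed) or a one-row
#'   [motif_table()].
#' @return Integer vector of 0-based start offsets (empty if no hit).
#' @export
scan_region <- function(sequence, motif) {
  pat <- as_pattern(motif)
  m <- gregexpr(iupac_regex(pat), sequence, perl = TRUE)[[1]]
  if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
}

# vectorized hit counts: one gregexpr call over many sequences
scan_count_many <- function(sequences, pattern) {
  if (length(sequences) == 0L) return(integer(0))
  rx <- iupac_regex(pattern)
  hits <- gregexpr(rx, sequences, perl = TRUE)
  vapply(hits, function(m) if (m[1L] == -1L) 0L else length(m), integer(1))
}

# vectorized offsets: list of 0-based offset vectors, one per sequence
scan_offsets_many <- function(sequences, pattern) {
  if (length(sequences) == 0L) return(list())
  rx <- iupac_regex(pattern)
  lapply(gregexpr(rx, sequences, perl = TRUE), function(m) {
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  })
}

#' Tabulate motif hits over a region set
#'
#' Scans every region sequence for every motif and returns one row per
#' (motif, region) pair with at least one hit, with 0-based offsets.
#'
#' @param regions a region table from [proximal_regions()].
#' @param motifs a [motif_table()].
#' @return `data.frame` with columns `motif_id`, `exon_key`, `region`,
#'   `offset` (one row per hit).
#' @export
scan_proximal_regions <- function(regions, motifs) {
  stopifnot(is.data.frame(regions), inherits(motifs, "motif_table"))
  out <- vector("list", nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    offs <- scan_offsets_many(regions$seq, motifs$pattern[i])
    n <- lengths(offs)
    if (sum(n) == 0L) next
    idx <- rep.int(seq_along(offs), n)
    out[[i]] <- data.frame(
      motif_id = motifs$motif_id[i],
      exon_key = regions$exon_key[idx],
      region = regions$region[idx],
      offset = unlist(offs, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(motif_id = character(0), exon_key = character(0),
                      region = character(0), offset = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Generate a decoy motif collection around a planted motif
#'
#' Builds an ATtRACT-style motif collection containing the motif of interest
#' plus random degenerate decoys, for enrichment-ranking experiments on
#' simulated data. Decoys are rejected if they match inside any concrete
#' realization of the planted motif (so a decoy cannot be a disguised copy of
#' the signal).
#'
#' @param n_decoys number of decoy motifs (default 50).
#' @param seed integer seed.
#' @param planted_iupac IUPAC string of the motif of interest (default
#'   `"ACUAAY"`, the QKI binding element).
#' @param planted_name RBP name for the planted motif (default `"QKI"`).
#' @param decoy_len integer range of decoy lengths (default `c(5, 7)`).
#' @return A [motif_table()]; the planted motif is the first row.
#' @export
make_motif_collection <- function(n_decoys = 50L, seed = 1L,
                                  planted_iupac = "ACUAAY",
                                  planted_name = "QKI",
                                  decoy_len = c(5L, 7L)) {
  if (!is_count(n_decoys)) config_error("n_decoys must be a positive count")
  planted_pat <- normalize_iupac(planted_iupac)
  planted_expansions <- expand_iupac(planted_pat)
  letters_pool <- names(IUPAC_SETS)
  # concrete bases dominate; mildly degenerate codes appear; N is rare
  w <- c(A = 1, C = 1, G = 1, T = 1,
         R = 0.15, Y = 0.15, S = 0.15, W = 0.15, K = 0.15, M = 0.15,
         B = 0.05, D = 0.05, H = 0.05, V = 0.05, N = 0.05)[letters_pool]
  withr::with_seed(seed, {
    decoys <- character(0)
    while (length(decoys) < n_decoys) {
      len <- decoy_len[1] + sample.int(decoy_len[2] - decoy_len[1] + 1L, 1L) - 1L
      cand <- paste(sample(letters_pool, len, replace = TRUE, prob = w),
                    collapse = "")
      if (cand == planted_pat) next
      # reject decoys hitting inside the planted motif's realizations
      if (any(scan_count_many(planted_expansions, cand) > 0L)) next
      if (cand %in% decoys) next
      decoys <- c(decoys, cand)
    }
    motif_table(
      rbp_name = c(planted_name, sprintf("DECOY%03d", seq_len(n_decoys))),
      iupac = c(planted_iupac, decoys)
    )
  })
}

# all concrete DNA expansions of an IUPAC pattern (small patterns only)
expand_iupac <- function(pattern) {
  sets <- IUPAC_SETS[strsplit(pattern, "")[[1]]]
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}
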