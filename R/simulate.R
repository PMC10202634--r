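#' Simulation configuration
#'
#' Defines the study conditions for the bundled synthetic-data generator: a
#' multi-gene toy genome with cassette exons, negative-binomial exon-bin
#' counts with group-specific usage shifts on a planted subset of internal
#' exons, and one concrete instance of a degenerate motif written into a
#' flanking intron of every planted exon. The side of planting follows the
#' positional rule for a splicing regulator: exons whose usage drops on
#' regulator loss (direction `down`, regulator-activated) receive the motif
#' in the downstream intron; exons whose usage rises (`up`,
#' regulator-repressed) receive it upstream.
#'
#' @param n_genes number of genes; one gene per chromosome.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene
#'   (minimum 3, so every gene has at least one internal exon).
#' @param exon_len integer range of exon lengths (nt).
#' @param intron_len integer range of intron lengths (nt); the minimum must
#'   be at least `2 * plant_offset + nchar(plant_motif)` so planted instances
#'   fit and cannot collide within a shared intron.
#' @param background_gc GC fraction of the i.i.d. background sequence.
#' @param n_samples_per_group samples per group (reference first).
#' @param mean_gene_expression expected fragments per gene per sample.
#' @param nb_dispersion negative-binomial dispersion of the per-sample gene
#'   total (`variance = mu + dispersion * mu^2`).
#' @param planted_fraction fraction of internal exons given differential
#'   usage plus a planted motif.
#' @param usage_effect absolute log2 usage fold change of planted exons
#'   (group 2 relative to group 1).
#' @param plant_motif IUPAC motif to plant (default `"ACUAAY"`).
#' @param plant_offset nt between the exon boundary and the nearest edge of
#'   the planted instance.
#' @param sample_scale range of per-sample library scale factors.
#' @param seed integer seed; identical configuration implies byte-identical
#'   outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 60L,
                       exons_per_gene = c(5L, 5L),
                       exon_len = c(80L, 160L),
                       intron_len = c(200L, 400L),
                       background_gc = 0.42,
                       n_samples_per_group = 3L,
                       mean_gene_expression = 5000,
                       nb_dispersion = 0.05,
                       planted_fraction = 0.8,
                       usage_effect = 2,
                       plant_motif = "ACUAAY",
                       plant_offset = 50L,
                       sample_scale = c(0.9, 1.1),
                       seed = 1L) {
  cfg <- structure(
    list(n_genes = as.integer(n_genes),
         exons_per_gene = as.integer(exons_per_gene),
         exon_len = as.integer(exon_len),
         intron_len = as.integer(intron_len),
         background_gc = background_gc,
         n_samples_per_group = as.integer(n_samples_per_group),
         mean_gene_expression = mean_gene_expression,
         nb_dispersion = nb_dispersion,
         planted_fraction = planted_fraction,
         usage_effect = usage_effect,
         plant_motif = toupper(plant_motif),
         plant_offset = as.integer(plant_offset),
         sample_scale = as.numeric(sample_scale),
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (!is_count(n_genes)) config_error("n_genes must be a count >= 1")
    if (length(exons_per_gene) != 2L || exons_per_gene[1] < 3L ||
        exons_per_gene[2] < exons_per_gene[1]) {
      config_error("exons_per_gene must be a range with minimum >= 3")
    }
    for (nm in c("exon_len", "intron_len")) {
      r <- cfg[[nm]]
      if (length(r) != 2L || r[1] < 1L || r[2] < r[1]) {
        config_error("%s must be an increasing range of counts", nm)
      }
    }
    if (!is_fraction(background_gc)) config_error("background_gc must be in [0,1]")
    if (!is_count(n_samples_per_group)) {
      config_error("n_samples_per_group must be a count >= 1")
    }
    if (!(mean_gene_expression > 0)) {
      config_error("mean_gene_expression must be positive")
    }
    if (!(nb_dispersion > 0)) config_error("nb_dispersion must be positive")
    if (!is_fraction(planted_fraction)) {
      config_error("planted_fraction must be in [0,1]")
    }
    if (usage_effect < 0) config_error("usage_effect must be >= 0")
    if (!is_count(plant_offset)) config_error("plant_offset must be a count")
    motif_pat <- normalize_iupac(plant_motif, "plant_motif")
    if (intron_len[1] < 2L * plant_offset + nchar(motif_pat)) {
      config_error(
        "intron_len minimum (%d) must be >= 2*plant_offset + motif length (%d)",
        intron_len[1], 2L * plant_offset + nchar(motif_pat))
    }
  })
  cfg
}

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

rint_range <- function(n, range) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

#' Generate a toy genome and annotation
#'
#' Each gene sits on its own chromosome with a 100 nt pad on either side;
#' exon and intron lengths are drawn uniformly from the configured ranges and
#' strands alternate (+,-,+,...). Background sequence is i.i.d. with the
#' configured GC, so chance motif hits occur at the background rate.
#'
#' @param config a [sim_config()].
#' @return `list(genome = DNAStringSet, models = named list of gene_model)`.
#' @export
generate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pad <- 100L
  withr::with_seed(config$seed, {
    models <- vector("list", config$n_genes)
    chrs <- character(config$n_genes)
    for (g in seq_len(config$n_genes)) {
      k <- rint_range(1L, config$exons_per_gene)
      elen <- rint_range(k, config$exon_len)
      ilen <- rint_range(k - 1L, config$intron_len)
      starts <- pad + cumsum(c(0L, elen[-k] + ilen))
      ends <- starts + elen
      chrom <- sprintf("chr%d", g)
      chr_len <- ends[k] + pad
      chrs[g] <- random_dna(chr_len, config$background_gc)
      models[[g]] <- gene_model(
        gene_id = sprintf("g%03d", g),
        chrom = chrom,
        strand = if (g %% 2L == 1L) "+" else "-",
        exons = data.frame(start = starts, end = ends)
      )
    }
    genome <- Biostrings::DNAStringSet(chrs)
    names(genome) <- sprintf("chr%d", seq_len(config$n_genes))
    names(models) <- vapply(models, `[[`, character(1), "gene_id")
    list(genome = genome, models = models)
  })
}

#' Build the planted-truth table
#'
#' Samples `planted_fraction` of the internal exons, assigns usage-shift
#' directions alternating `down`, `up`, ... within each gene (in transcript
#' order), and records the motif side implied by the positional rule:
#' `down` (regulator-activated, skipped on regulator loss) plants downstream;
#' `up` (regulator-repressed) plants upstream.
#'
#' @param models named list of [gene_model()] objects.
#' @param config a [sim_config()].
#' @return `data.frame` with one row per exon bin (transcript order):
#'   `exon_key`, `gene_id`, `exon_number`, `internal`, `is_planted`,
#'   `direction` (`up`/`down`/`none`), `motif_side`
#'   (`upstream`/`downstream`/`none`), `motif_offset`.
#' @export
make_truth_table <- function(models, config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- do.call(rbind, lapply(models, function(m) {
    k <- n_exons(m)
    data.frame(
      exon_key = exon_key(m$gene_id, seq_len(k)),
      gene_id = m$gene_id,
      exon_number = seq_len(k),
      internal = seq_len(k) > 1L & seq_len(k) < k,
      stringsAsFactors = FALSE
    )
  }))
  rownames(rows) <- NULL
  withr::with_seed(config$seed + 1L, {
    eligible <- which(rows$internal)
    n_plant <- round(config$planted_fraction * length(eligible))
    planted <- sort(sample(eligible, n_plant))
    rows$is_planted <- seq_len(nrow(rows)) %in% planted
    rows$direction <- "none"
    rows$motif_side <- "none"
    rows$motif_offset <- NA_integer_
    for (g in unique(rows$gene_id[rows$is_planted])) {
      i <- which(rows$gene_id == g & rows$is_planted)
      i <- i[order(rows$exon_number[i])]
      dirs <- rep_len(c("down", "up"), length(i))
      rows$direction[i] <- dirs
      rows$motif_side[i] <- ifelse(dirs == "down", "downstream", "upstream")
      rows$motif_offset[i] <- config$plant_offset
    }
  })
  rows
}

#' Plant motif instances into the genome
#'
#' For each planted exon, one concrete realization of the configured IUPAC
#' motif (chosen uniformly among its expansions, seeded) is written
#' transcript-sense into the flanking intron on the configured side, with the
#' instance's nearest edge `plant_offset` nt from the exon boundary. On the
#' minus strand the reverse complement is written at the mirrored genomic
#' locus, so re-fetching the region transcript-sense recovers the motif. All
#' other positions are untouched.
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param models named list of [gene_model()] objects.
#' @param truth table from [make_truth_table()].
#' @param config a [sim_config()].
#' @return The modified genome; attribute `placements` records each planted
#'   instance (`exon_key`, `chrom`, `start`, `end`, `strand`, `side`,
#'   `realization`).
#' @export
plant_motifs <- function(genome, models, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  pat <- normalize_iupac(config$plant_motif)
  len <- nchar(pat)
  expansions <- expand_iupac(pat)
  pl <- truth[truth$is_planted, , drop = FALSE]
  placements <- vector("list", nrow(pl))
  withr::with_seed(config$seed + 2L, {
    for (i in seq_len(nrow(pl))) {
      m <- models[[pl$gene_id[i]]]
      gi <- genomic_exon_index(m, pl$exon_number[i])
      s <- m$exons$start[gi]; e <- m$exons$end[gi]
      off <- pl$motif_offset[i]
      side <- pl$motif_side[i]
      plus <- m$strand == "+"
      # genomic right of the exon <=> transcript-downstream on +, upstream on -
      right <- (side == "downstream") == plus
      if (right) {
        iv <- c(e + off, e + off + len)
        gap_ok <- m$exons$start[gi + 1L] - e
      } else {
        iv <- c(s - off - len, s - off)
        gap_ok <- s - m$exons$end[gi - 1L]
      }
      if (off + len > gap_ok) {
        config_error("planted motif does not fit in the %s intron of %s",
                     side, pl$exon_key[i])
      }
      realization <- expansions[sample.int(length(expansions), 1L)]
      written <- if (plus) realization else revcomp_chr(realization)
      chr <- genome[[m$chrom]]
      Biostrings::subseq(chr, iv[1] + 1L, iv[2]) <- Biostrings::DNAString(written)
      genome[[m$chrom]] <- chr
      placements[[i]] <- data.frame(
        exon_key = pl$exon_key[i], chrom = m$chrom,
        start = iv[1], end = iv[2], strand = m$strand,
        side = side, realization = realization, stringsAsFactors = FALSE
      )
    }
  })
  attr(genome, "placements") <- if (nrow(pl) > 0L) {
    do.call(rbind, placements)
  } else {
    data.frame(exon_key = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               side = character(0), realization = character(0))
  }
  genome
}

# per-group usage (multinomial share) vectors for one gene, genomic order
gene_usage_profile <- function(model, truth, config) {
  k <- n_exons(model)
  tg <- truth[truth$gene_id == model$gene_id, , drop = FALSE]
  tg <- tg[match(transcript_exon_numbers(model), tg$exon_number), , drop = FALSE]
  e <- config$usage_effect
  u0 <- min(0.12, 0.3 * 2^(-e / 2))
  hi <- u0 * 2^(e / 2); lo <- u0 * 2^(-e / 2)
  u <- matrix(0, nrow = k, ncol = 2L, dimnames = list(NULL, c("g1", "g2")))
  pl <- tg$is_planted
  u[pl & tg$direction == "down", ] <- rep(c(hi, lo), each = sum(pl & tg$direction == "down"))
  u[pl & tg$direction == "up", ] <- rep(c(lo, hi), each = sum(pl & tg$direction == "up"))
  mass <- colSums(u)
  if (any(mass > 0.9)) {
    config_error("gene %s: planted usage mass exceeds 0.9; lower planted_fraction or usage_effect",
                 model$gene_id)
  }
  n_free <- sum(!pl)
  u[!pl, ] <- rep((1 - mass) / n_free, each = n_free)
  u
}

#' Simulate exon-bin counts
#'
#' Per gene and sample the total fragment count is negative-binomial around
#' `mean_gene_expression` (times a per-sample scale factor); the total is
#' split across exon bins by a multinomial draw whose group-specific shares
#' define exon usage. Planted exons use shares `u0 * 2^(+-usage_effect/2)` in
#' the two groups, so the usage ratio group2/group1 is `2^(-usage_effect)`
#' for direction `down` (and its reciprocal for `up`); unplanted exons split
#' the remaining mass evenly.
#'
#' @param models named list of [gene_model()] objects.
#' @param truth table from [make_truth_table()].
#' @param config a [sim_config()].
#' @return `list(counts = integer matrix (exon bins x samples, rownames
#'   `gene:exon_number`), groups = character vector (`"g1"` reference /
#'   `"g2"`), sample_sheet = data.frame)`.
#' @export
simulate_counts <- function(models, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  nsp <- config$n_samples_per_group
  if (nsp < 1L) config_error("n_samples_per_group must be >= 1")
  samples <- c(sprintf("g1_s%d", seq_len(nsp)), sprintf("g2_s%d", seq_len(nsp)))
  groups <- rep(c("g1", "g2"), each = nsp)
  withr::with_seed(config$seed + 3L, {
    scale <- stats::runif(2L * nsp, config$sample_scale[1], config$sample_scale[2])
    blocks <- lapply(models, function(m) {
      u <- gene_usage_profile(m, truth, config)
      k <- nrow(u)
      cnt <- matrix(0L, nrow = k, ncol = 2L * nsp)
      for (j in seq_len(2L * nsp)) {
        gcol <- if (groups[j] == "g1") 1L else 2L
        tot <- stats::rnbinom(1L, mu = config$mean_gene_expression * scale[j],
                              size = 1 / config$nb_dispersion)
        cnt[, j] <- stats::rmultinom(1L, tot, u[, gcol])[, 1L]
      }
      # rows back into transcript order to match exon keys
      cnt[order(transcript_exon_numbers(m)), , drop = FALSE]
    })
    counts <- do.call(rbind, blocks)
    rownames(counts) <- exon_keys(models)
    colnames(counts) <- samples
    list(counts = counts, groups = groups,
         sample_sheet = data.frame(sample = samples, group = groups,
                                   stringsAsFactors = FALSE))
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [generate_genome_and_annotation()],
#' [make_truth_table()], [plant_motifs()] and [simulate_counts()] under one
#' configuration. Identical configuration gives identical output.
#'
#' @param config a [sim_config()].
#' @return `list(config, genome, models, truth, counts, groups, sample_sheet,
#'   placements)`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ga <- generate_genome_and_annotation(config)
  truth <- make_truth_table(ga$models, config)
  genome <- plant_motifs(ga$genome, ga$models, truth, config)
  placements <- attr(genome, "placements")
  attr(genome, "placements") <- NULL
  cc <- simulate_counts(ga$models, truth, config)
  list(config = config, genome = genome, models = ga$models, truth = truth,
       counts = cc$counts, groups = cc$groups, sample_sheet = cc$sample_sheet,
       placements = placements)
}

#' Write a simulated dataset to disk
#'
#' Emits genome FASTA, annotation GTF, tab-delimited counts (rows keyed
#' `gene_id:exon_number`), truth table, sample sheet and the configuration as
#' YAML.
#'
#' @param dataset result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    counts = file.path(dir, "counts.tsv"),
    truth = file.path(dir, "truth.tsv"),
    sample_sheet = file.path(dir, "samples.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_genome_fasta(dataset$genome, paths[["genome"]])
  write_gtf(dataset$models, paths[["gtf"]])
  write_counts(dataset$counts, paths[["counts"]])
  utils::write.table(dataset$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$sample_sheet, paths[["sample_sheet"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(dataset$config), paths[["config"]])
  invisible(paths)
}

#' Write / read an exon-bin count table
#'
#' Tab-delimited; first column `exon_id` holds `gene_id:exon_number` keys,
#' remaining columns are samples.
#'
#' @param counts integer matrix with exon keys as rownames.
#' @param path file path.
#' @return `write_counts` the path, invisibly; `read_counts` the matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(exon_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "exon_id") {
    format_error("counts table must have 'exon_id' as its first column")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$exon_id
  m
}

#' Simulate a three-condition reversion dataset
#'
#' Builds adult WT/KO exon-usage records plus an embryonic wild-type usage
#' vector in which a known fraction of the adult-significant exons is
#' constructed to revert: the adult knockout usage lands near the embryonic
#' wild-type value. Non-reverting exons get an embryonic usage on the far
#' side of the adult wild-type value, so the sign rule excludes them.
#'
#' @param n_exons number of (all significant) exons.
#' @param revert_fraction fraction constructed as reverted.
#' @param seed integer seed.
#' @param noise s.d. of the usage jitter around the constructed values.
#' @return `list(adult = ExonUsageRecord-style data.frame,
#'   embryo_wt = named usage vector, truth = logical vector)`.
#' @export
simulate_reversion_data <- function(n_exons = 200L, revert_fraction = 0.5,
                                    seed = 1L, noise = 0.02) {
  if (!is_fraction(revert_fraction)) {
    config_error("revert_fraction must be in [0,1]")
  }
  withr::with_seed(seed, {
    key <- sprintf("g%04d:2", seq_len(n_exons))
    wt <- stats::runif(n_exons, 0.45, 0.75)
    delta <- sample(c(-1, 1), n_exons, replace = TRUE) *
      stats::runif(n_exons, 0.25, 0.35)
    ko <- pmin(0.98, pmax(0.02, wt + delta))
    revert <- stats::runif(n_exons) < revert_fraction
    emb <- ifelse(revert,
                  ko + stats::rnorm(n_exons, 0, noise),
                  wt - sign(delta) * stats::runif(n_exons, 0.15, 0.25))
    emb <- pmin(0.99, pmax(0.01, emb))
    adult <- data.frame(
      gene_id = sub(":.*$", "", key),
      exon_key = key,
      usage_wt = wt,
      usage_ko = ko,
      usage_log2fc = log2(ko / wt),
      p_value = 1e-8,
      padj = 1e-6,
      gene_tpm = 50,
      stringsAsFactors = FALSE
    )
    list(adult = adult, embryo_wt = stats::setNames(emb, key), truth = revert)
  })
}
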