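test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 0), class = "posmap_config_error")
  expect_error(sim_config(exons_per_gene = c(2, 2)),
               class = "posmap_config_error")
  expect_error(sim_config(planted_fraction = 1.2),
               class = "posmap_config_error")
  # introns must hold the planted instance on both sides
  expect_error(sim_config(intron_len = c(80, 120), plant_offset = 50),
               class = "posmap_config_error")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("identical seed gives byte-identical genome, annotation and counts", {
  cfg <- sim_config(n_genes = 8, seed = 7)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_genome_fasta(d1$genome, f1)
  write_genome_fasta(d2$genome, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(d1$models, d2$models)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$counts, d2$counts)
})

test_that("gene structure follows the configuration", {
  cfg <- sim_config(n_genes = 10, exons_per_gene = c(3, 3), seed = 2)
  ga <- generate_genome_and_annotation(cfg)
  expect_length(ga$models, 10L)
  for (m in ga$models) {
    expect_equal(nrow(m$exons), 3L)
    # internal exon has a flanking intron on both sides
    expect_true(m$exons$start[2] > m$exons$end[1])
    expect_true(m$exons$start[3] > m$exons$end[2])
    gaps <- m$exons$start[-1] - m$exons$end[-3]
    expect_true(all(gaps >= cfg$intron_len[1] & gaps <= cfg$intron_len[2]))
  }
  # strands alternate
  expect_equal(vapply(ga$models, `[[`, character(1), "strand")[1:4],
               c("+", "-", "+", "-"), ignore_attr = TRUE)
})

test_that("minus-strand transcript-sense exon order reverses genomic order", {
  cfg <- sim_config(n_genes = 2, seed = 4)
  ga <- generate_genome_and_annotation(cfg)
  minus <- ga$models[[2]]
  expect_equal(minus$strand, "-")
  # transcript exon 1 must be the genomically last exon: its downstream
  # intron lies genomically left of it
  r <- extract_proximal_regions(minus, 1L, ga$genome, window_spec())
  dn <- r[r$region == "downstream_intron", ]
  expect_true(dn$end <= max(minus$exons$start))
  up <- r[r$region == "upstream_intron", ]
  expect_true(up$terminal)
})

test_that("truth table mirrors the positional rule and the planted fraction", {
  cfg <- sim_config(n_genes = 20, planted_fraction = 0.5, seed = 9)
  ga <- generate_genome_and_annotation(cfg)
  truth <- make_truth_table(ga$models, cfg)
  expect_equal(sum(truth$is_planted),
               round(0.5 * sum(truth$internal)))
  expect_true(all(truth$internal[truth$is_planted]))
  pl <- truth[truth$is_planted, ]
  expect_true(all(pl$motif_side[pl$direction == "down"] == "downstream"))
  expect_true(all(pl$motif_side[pl$direction == "up"] == "upstream"))
  expect_true(all(truth$motif_side[!truth$is_planted] == "none"))
})

test_that("planting writes the realization at the configured offset", {
  # plus-strand exon [1000,1100), downstream side, offset 50
  exons <- data.frame(start = c(200L, 1000L, 2000L), end = c(400L, 1100L, 2100L))
  genome <- Biostrings::DNAStringSet(c(chrT = strrep("G", 3000)))
  model <- gene_model("gT", "chrT", "+", exons)
  cfg <- sim_config(n_genes = 1, plant_offset = 50, seed = 21)
  truth <- data.frame(exon_key = "gT:2", gene_id = "gT", exon_number = 2L,
                      internal = TRUE, is_planted = TRUE, direction = "down",
                      motif_side = "downstream", motif_offset = 50L,
                      stringsAsFactors = FALSE)
  g2 <- plant_motifs(genome, list(gT = model), truth, cfg)
  pl <- attr(g2, "placements")
  expect_equal(c(pl$start, pl$end), c(1150L, 1156L))
  expect_true(pl$realization %in% c("ACTAAC", "ACTAAT"))
  expect_equal(as.character(Biostrings::subseq(g2[["chrT"]], 1151, 1156)),
               pl$realization)
  # scanning the planted window afterwards finds the motif
  reg <- extract_proximal_regions(model, 2L, g2, window_spec())
  dn <- reg$seq[reg$region == "downstream_intron"]
  expect_gte(length(scan_region(dn, "ACUAAY")), 1L)
  expect_equal(scan_region(dn, "ACUAAY"), 50L)
})

test_that("minus-strand planting reverse-complements at the mirrored locus", {
  exons <- data.frame(start = c(200L, 1000L, 2000L), end = c(400L, 1100L, 2100L))
  genome <- Biostrings::DNAStringSet(c(chrT = strrep("G", 3000)))
  model <- gene_model("gT", "chrT", "-", exons)
  cfg <- sim_config(n_genes = 1, plant_offset = 50, seed = 22)
  truth <- data.frame(exon_key = "gT:2", gene_id = "gT", exon_number = 2L,
                      internal = TRUE, is_planted = TRUE, direction = "down",
                      motif_side = "downstream", motif_offset = 50L,
                      stringsAsFactors = FALSE)
  g2 <- plant_motifs(genome, list(gT = model), truth, cfg)
  pl <- attr(g2, "placements")
  # downstream of a minus-strand exon is the genomically left intron
  expect_equal(c(pl$start, pl$end), c(1000L - 56L, 1000L - 50L))
  raw <- as.character(Biostrings::subseq(g2[["chrT"]], pl$start + 1L, pl$end))
  expect_equal(raw, oracle_revcomp(pl$realization))
  # re-fetching transcript-sense recovers the motif
  expect_equal(fetch_transcript_sense(g2, "chrT", pl$start, pl$end, "-"),
               pl$realization)
})

test_that("planting an oversized offset fails", {
  exons <- data.frame(start = c(200L, 1000L, 2000L), end = c(400L, 1100L, 2100L))
  genome <- Biostrings::DNAStringSet(c(chrT = strrep("G", 3000)))
  model <- gene_model("gT", "chrT", "+", exons)
  cfg <- sim_config(n_genes = 1, plant_offset = 50, seed = 23)
  truth <- data.frame(exon_key = "gT:2", gene_id = "gT", exon_number = 2L,
                      internal = TRUE, is_planted = TRUE, direction = "down",
                      motif_side = "downstream", motif_offset = 2000L,
                      stringsAsFactors = FALSE)
  expect_error(plant_motifs(genome, list(gT = model), truth, cfg),
               class = "posmap_config_error")
})

test_that("count matrix has the contracted shape and integer content", {
  cfg <- sim_config(n_genes = 6, n_samples_per_group = 4, seed = 5)
  ds <- simulate_dataset(cfg)
  expect_equal(dim(ds$counts), c(nrow(ds$truth), 8L))
  expect_identical(rownames(ds$counts), ds$truth$exon_key)
  expect_true(all(ds$counts >= 0))
  expect_true(is.integer(ds$counts))
  expect_equal(ds$groups, rep(c("g1", "g2"), each = 4))
})

test_that("planted usage ratio concentrates at 2^-effect for direction down", {
  cfg <- sim_config(n_genes = 30, mean_gene_expression = 2e4,
                    usage_effect = 2, seed = 31)
  ds <- simulate_dataset(cfg)
  gid <- sub(":[0-9]+$", "", rownames(ds$counts))
  g1 <- rowSums(ds$counts[, ds$groups == "g1", drop = FALSE])
  g2 <- rowSums(ds$counts[, ds$groups == "g2", drop = FALSE])
  tot1 <- tapply(g1, gid, sum)[gid]
  tot2 <- tapply(g2, gid, sum)[gid]
  ratio <- (g2 / tot2) / (g1 / tot1)
  down <- ds$truth$is_planted & ds$truth$direction == "down"
  expect_equal(mean(ratio[down]), 0.25, tolerance = 0.03)
  up <- ds$truth$is_planted & ds$truth$direction == "up"
  expect_equal(mean(ratio[up]), 4, tolerance = 0.12)
})

test_that("planted sides carry the motif, unplanted sides stay at background", {
  ds <- simulate_dataset(sim_config(n_genes = 20, seed = 17))
  reg <- proximal_regions(ds$models, ds$genome,
                          ds$truth$exon_key[ds$truth$is_planted])
  hits <- scan_proximal_regions(reg, motif_table("QKI", "ACUAAY"))
  side_of <- c(upstream_intron = "upstream", exon_start = "upstream",
               exon_end = "downstream", downstream_intron = "downstream")
  per <- table(factor(hits$exon_key, levels = unique(reg$exon_key)),
               factor(side_of[hits$region], levels = c("upstream", "downstream")))
  truth <- ds$truth[match(rownames(per), ds$truth$exon_key), ]
  planted_side <- ifelse(truth$motif_side == "downstream", "downstream",
                         "upstream")
  planted_hits <- per[cbind(seq_len(nrow(per)), match(planted_side,
                                                      colnames(per)))]
  other_hits <- per[cbind(seq_len(nrow(per)), 3L - match(planted_side,
                                                         colnames(per)))]
  expect_true(all(planted_hits >= 1L))
  # unplanted side behaves like background: rare chance hits only
  expect_lt(mean(other_hits), 0.5)
})

test_that("without planting the pipeline stays quiet", {
  n_hits <- vapply(1:10, function(s) {
    ds <- simulate_dataset(sim_config(n_genes = 10, planted_fraction = 0,
                                      seed = 100 + s))
    rec <- exon_usage_test(ds$counts, ds$groups, models = ds$models)
    sum(rec$padj <= 0.05)
  }, numeric(1))
  expect_true(mean(n_hits <= 0.1 * 50) >= 0.95)
})

test_that("dataset files round-trip from disk", {
  ds <- simulate_dataset(sim_config(n_genes = 5, seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  g <- read_genome_fasta(paths[["genome"]])
  expect_identical(as.character(g), as.character(ds$genome))
  models <- read_gtf(paths[["gtf"]])
  expect_equal(lapply(models, `[[`, "exons"),
               lapply(ds$models, `[[`, "exons"))
  cnt <- read_counts(paths[["counts"]])
  expect_identical(cnt, ds$counts)
  cfg <- yaml::read_yaml(paths[["config"]])
  expect_equal(cfg$seed, ds$config$seed)
})
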