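test_that("FASTA round-trips, uppercases, and rejects bad records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", "acgtACGT", ">chrB", "NNACGT"), f)
  g <- read_genome_fasta(f)
  expect_equal(as.character(g[["chrA"]]), "ACGTACGT")
  expect_equal(as.character(g[["chrB"]]), "NNACGT")

  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(g, f2)
  g2 <- read_genome_fasta(f2)
  expect_identical(as.character(g2), as.character(g))
  expect_identical(names(g2), names(g))

  fdup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", "ACGT", ">chrA", "GGCC"), fdup)
  expect_error(read_genome_fasta(fdup), class = "posmap_format_error")

  fbad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrA", "ACRT"), fbad)
  expect_error(read_genome_fasta(fbad), class = "posmap_format_error")
})

test_that("GTF coordinates convert 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tgene_id "gA"; exon_number "1";',
    'chr1\tsrc\texon\t1301\t1400\t.\t+\t.\tgene_id "gA"; exon_number "2";'
  ), f)
  models <- read_gtf(f)
  expect_equal(models[["gA"]]$exons$start, c(1000L, 1300L))
  expect_equal(models[["gA"]]$exons$end, c(1100L, 1400L))
})

test_that("GTF exons are sorted per gene and overlaps are rejected", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1301\t1400\t.\t-\t.\tgene_id "gA";',
    'chr1\tsrc\texon\t1001\t1100\t.\t-\t.\tgene_id "gA";'
  ), f)
  m <- read_gtf(f)[["gA"]]
  expect_equal(m$exons$start, c(1000L, 1300L))

  fo <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tgene_id "gA";',
    'chr1\tsrc\texon\t1050\t1200\t.\t+\t.\tgene_id "gA";'
  ), fo)
  expect_error(read_gtf(fo), class = "posmap_format_error")
})

test_that("GTF writer round-trips through the reader", {
  tg <- toy_gene("-")
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(list(gT = tg$model), f)
  back <- read_gtf(f)[["gT"]]
  expect_equal(back$exons, tg$model$exons)
  expect_equal(back$strand, "-")
  expect_equal(back$gene_id, "gT")
})

test_that("transcript-sense fetch reverse-complements on the minus strand", {
  g <- Biostrings::DNAStringSet(c(chrA = "AACCGGTT"))
  expect_equal(fetch_transcript_sense(g, "chrA", 0, 4, "-"), "GGTT")
  expect_equal(fetch_transcript_sense(g, "chrA", 0, 4, "+"), "AACC")
  withr::with_seed(5, {
    for (i in 1:20) {
      se <- sort(sample(0:8, 2))
      out <- fetch_transcript_sense(g, "chrA", se[1], se[2],
                                    sample(c("+", "-"), 1))
      expect_equal(nchar(out), se[2] - se[1])
    }
  })
  expect_error(fetch_transcript_sense(g, "chrA", 0, 9, "+"),
               class = "posmap_coord_error")
  expect_error(fetch_transcript_sense(g, "chrZ", 0, 2, "+"),
               class = "posmap_coord_error")
})

test_that("proximal windows on the plus strand sit at the documented loci", {
  tg <- toy_gene("+")
  r <- extract_proximal_regions(tg$model, 2L, tg$genome, window_spec())
  expect_equal(r$region, c("upstream_intron", "exon_start", "exon_end",
                           "downstream_intron"))
  expect_equal(r$start, c(800L, 1000L, 1090L, 1100L))
  expect_equal(r$end, c(1000L, 1010L, 1100L, 1300L))
  expect_false(any(r$truncated))
  expect_false(any(r$terminal))
})

test_that("minus-strand windows mirror and reverse-complement", {
  base <- toy_gene("+")
  # give the genome distinguishable sequence
  withr::with_seed(99, {
    chr <- random_seq(6000, p_n = 0)
  })
  genome <- Biostrings::DNAStringSet(c(chrT = chr))
  minus <- gene_model("gT", "chrT", "-", base$model$exons)
  # transcript exon 4 on minus == genomic exon 2 ([1000,1100))
  r <- extract_proximal_regions(minus, 4L, genome, window_spec())
  up <- r[r$region == "upstream_intron", ]
  expect_equal(c(up$start, up$end), c(1100L, 1300L))
  expect_equal(up$seq, oracle_revcomp(substr(chr, 1101, 1300)))
  dn <- r[r$region == "downstream_intron", ]
  expect_equal(c(dn$start, dn$end), c(800L, 1000L))
})

test_that("windows truncate at neighbouring exons and flag terminal sides", {
  exons <- data.frame(start = c(200L, 520L, 900L), end = c(400L, 640L, 1000L))
  g <- Biostrings::DNAStringSet(c(chrT = strrep("A", 1500)))
  m <- gene_model("gT", "chrT", "+", exons)
  r <- extract_proximal_regions(m, 2L, g, window_spec())
  up <- r[r$region == "upstream_intron", ]
  expect_equal(up$length, 120L)   # intron of 120 nt, window clipped
  expect_true(up$truncated)

  r1 <- extract_proximal_regions(m, 1L, g, window_spec())
  u1 <- r1[r1$region == "upstream_intron", ]
  expect_equal(u1$length, 0L)
  expect_true(u1$terminal)
  expect_equal(u1$seq, "")
})

test_that("short exons split their edge windows at the midpoint, no overlap", {
  exons <- data.frame(start = c(100L, 500L, 900L), end = c(200L, 515L, 1000L))
  g <- Biostrings::DNAStringSet(c(chrT = strrep("A", 1500)))
  m <- gene_model("gT", "chrT", "+", exons)
  r <- extract_proximal_regions(m, 2L, g, window_spec(exon_window = 10))
  es <- r[r$region == "exon_start", ]
  ee <- r[r$region == "exon_end", ]
  expect_equal(es$length + ee$length, 15L)
  expect_equal(es$end, ee$start)  # adjacent, never overlapping
  expect_equal(es$length, 8L)     # transcript 5' half rounds up
})

test_that("region sequences match a re-fetch of their genomic provenance", {
  ds <- simulate_dataset(sim_config(n_genes = 6, seed = 3))
  reg <- proximal_regions(ds$models, ds$genome)
  refetched <- vapply(seq_len(nrow(reg)), function(i) {
    fetch_transcript_sense(ds$genome, reg$chrom[i], reg$start[i], reg$end[i],
                           reg$strand[i])
  }, character(1))
  expect_identical(reg$seq, refetched)
  # per-exon budget: at most 2 intron windows + 2 exon windows
  tot <- tapply(reg$length, reg$exon_key, sum)
  expect_true(all(tot <= 2 * 200 + 2 * 10))
})

test_that("flipping genome and annotation leaves region sequences unchanged", {
  ds <- simulate_dataset(sim_config(n_genes = 8, seed = 13))
  reg <- proximal_regions(ds$models, ds$genome)
  fl <- flip_dataset(ds$genome, ds$models)
  reg2 <- proximal_regions(fl$models, fl$genome)
  key <- function(r) paste(r$exon_key, r$region)
  expect_identical(reg2$seq[match(key(reg), key(reg2))], reg$seq)
})

test_that("BED export drops empty regions and respects the strand column", {
  tg <- toy_gene("-")
  reg <- proximal_regions(list(gT = tg$model), tg$genome)
  f <- withr::local_tempfile(fileext = ".bed")
  regions_to_bed(reg, f)
  bed <- utils::read.delim(f, header = FALSE)
  expect_equal(nrow(bed), sum(reg$length > 0))
  expect_true(all(bed$V6 == "-"))
  expect_true(all(bed$V3 > bed$V2))
})
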