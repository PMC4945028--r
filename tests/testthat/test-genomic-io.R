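# I/O and coordinate conventions

test_that("FASTA reading normalises case, validates names and alphabet", {
  p <- write_tmp(c(">chrX", "GAGA"), ".fa")
  g <- read_fasta(p)
  expect_s3_class(g, "Genome")
  expect_equal(unname(chrom_lengths(g)), 4L)
  expect_equal(unname(g$seq["chrX"]), "GAGA")
  expect_equal(unname(g$class_label["chrX"]), "other")

  p <- write_tmp(c(">chrX", "gaga"), ".fa")
  expect_equal(unname(read_fasta(p)$seq["chrX"]), "GAGA")

  p <- write_tmp(c(">a", "ACGT", ">a", "GGGG"), ".fa")
  expect_error(read_fasta(p), "duplicate")

  p <- write_tmp(c(">a", "ACQT"), ".fa")
  expect_error(read_fasta(p), "outside")

  p <- write_tmp(c("ACGT"), ".fa")
  expect_error(read_fasta(p), "header")
})

test_that("FASTA round-trip is byte-stable for canonical input", {
  g <- genome(c(chrX = "GATTACAGATTACA", chr2L = "ACGTACGTNNACGT"),
              class_labels = c(chrX = "X", chr2L = "autosome"))
  p1 <- tempfile(fileext = ".fa")
  write_fasta(g, p1)
  g2 <- read_fasta(p1, classes = c(chrX = "X", chr2L = "autosome"))
  p2 <- tempfile(fileext = ".fa")
  write_fasta(g2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(g2$seq, g$seq)
})

test_that("chromosome class side-car attaches labels and arms", {
  yml <- write_tmp(c("chrX: {class: X, arm: Muller-A}",
                     "chr2L: {class: autosome, arm: Muller-B}",
                     "chrU: other"), ".yaml")
  side <- read_chrom_classes(yml)
  expect_equal(unname(side$class), c("X", "autosome", "other"))
  expect_equal(unname(side$arm["chr2L"]), "Muller-B")
  fa <- write_tmp(c(">chrX", "ACGT", ">chr2L", "ACGT", ">chrU", "ACGT"), ".fa")
  g <- read_fasta(fa, classes = yml)
  expect_equal(unname(g$class_label), c("X", "autosome", "other"))
  bad <- write_tmp("chrX: sex", ".yaml")
  expect_error(read_chrom_classes(bad), "invalid class")
})

test_that("BED parsing keeps 0-based half-open coordinates verbatim", {
  p <- write_tmp("chr2L\t10\t20")
  b <- read_bed(p)
  expect_equal(b$chrom, "chr2L")
  expect_equal(b$start, 10)
  expect_equal(b$end, 20)
  expect_equal(b$strand, ".")
  expect_true(is.na(b$score))

  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_bed(empty)), 0L)

  p <- write_tmp("chrX\t5\t5")
  expect_error(read_bed(p), "start >= end")
  p <- write_tmp("chrX\tfive\t10")
  expect_error(read_bed(p), "non-numeric")
})

test_that("BED round-trips are byte-stable", {
  lines6 <- c("chrX\t0\t100\tpeak1\t5\t+", "chr2L\t50\t80\tpeak2\t1\t-")
  p <- write_tmp(lines6, ".bed")
  out <- tempfile(fileext = ".bed")
  write_bed(read_bed(p), out)
  expect_identical(readLines(out), lines6)
  lines3 <- c("chrX\t0\t100", "chr2L\t50\t80")
  p <- write_tmp(lines3, ".bed")
  write_bed(read_bed(p), out)
  expect_identical(readLines(out), lines3)
})

test_that("0-based half-open and 1-based closed conversions round-trip", {
  set.seed(42)
  for (i in 1:50) {
    s0 <- sample.int(1e6, 1) - 1L
    e0 <- s0 + sample.int(1000, 1)
    s1 <- s0 + 1L; e1 <- e0          # to 1-based closed
    expect_identical(c(s1 - 1L, e1), c(s0, e0))
    expect_equal(e1 - s1 + 1L, e0 - s0)  # widths agree
  }
})

test_that("gene model dialects and TSS/TTS strand conventions", {
  bed <- write_tmp("chr2L\t1000\t2000\tgeneA\t0\t+", ".bed")
  g <- read_gene_models(bed, "bed12")
  expect_equal(tss(g), 1000)
  expect_equal(tts(g), 1999)

  bed <- write_tmp("chr2L\t1000\t2000\tgeneB\t0\t-", ".bed")
  g <- read_gene_models(bed, "bed12")
  expect_equal(tss(g), 1999)
  expect_equal(tts(g), 1000)

  gff <- write_tmp(paste("chr2L", "src", "exon", "1001", "2000", ".", "+",
                         ".", "ID=e1", sep = "\t"), ".gff3")
  expect_equal(nrow(read_gene_models(gff, "gff3")), 0L)

  gff <- write_tmp(paste("chr2L", "src", "gene", "1001", "2000", ".", "+",
                         ".", "ID=geneC", sep = "\t"), ".gff3")
  g <- read_gene_models(gff, "gff3")
  expect_equal(g$start, 1000)   # GFF3 1-based start converted
  expect_equal(g$end, 2000)
  expect_equal(g$id, "geneC")

  nostrand <- write_tmp("chr2L\t10\t20\tg\t0\t.", ".bed")
  expect_error(read_gene_models(nostrand, "bed12"), "strand")
})

test_that("strand flip of a gene swaps TSS and TTS exactly", {
  g <- data.frame(chrom = "c", start = 120, end = 480, strand = "+",
                  id = "g1")
  flipped <- transform(g, strand = "-")
  expect_identical(tss(g), tts(flipped))
  expect_identical(tts(g), tss(flipped))
})

test_that("probe tables compute medians and validate flags", {
  hdr <- paste(c("id", "sequence", "chip_flag", "mre_flag",
                 paste0("intensity_", 1:8)), collapse = "\t")
  seq36 <- strrep("ACGT", 9)
  row <- paste(c("p1", seq36, "+", "-", 1:8), collapse = "\t")
  p <- write_tmp(c(hdr, row), ".tsv")
  probes <- read_probe_table(p)
  expect_equal(probes$median_intensity, 4.5)
  expect_equal(probes$variable_seq, seq36)
  expect_true(is.na(probes$full_seq))

  hdr1 <- paste(c("id", "sequence", "chip_flag", "mre_flag", "intensity_1"),
                collapse = "\t")
  p <- write_tmp(c(hdr1, paste(c("p1", seq36, "+", "+", 7000),
                               collapse = "\t")), ".tsv")
  expect_equal(read_probe_table(p)$median_intensity, 7000)

  p <- write_tmp(c(hdr1, paste(c("p1", seq36, "?", "+", 7000),
                               collapse = "\t")), ".tsv")
  expect_error(read_probe_table(p), "allowed: \\+, -, NA")

  seq60 <- strrep("ACGT", 15)
  p <- write_tmp(c(hdr1, paste(c("p1", seq60, "+", "+", 10),
                               collapse = "\t")), ".tsv")
  probes <- read_probe_table(p)
  expect_equal(nchar(probes$variable_seq), 36L)
  expect_equal(probes$full_seq, seq60)
})

test_that("MEME PWM files parse, validate row sums, and round-trip", {
  meme <- c("MEME version 4", "", "ALPHABET= ACGT", "",
            "Background letter frequencies",
            "A 0.25 C 0.25 G 0.25 T 0.25", "",
            "MOTIF test",
            "letter-probability matrix: alength= 4 w= 2 nsites= 2 E= 0",
            " 0.0 0.0 1.0 0.0", " 1.0 0.0 0.0 0.0")
  p <- write_tmp(meme, ".meme")
  pwms <- read_pwm(p)
  expect_length(pwms, 1L)
  expect_equal(consensus(pwms[[1]]), "GA")

  bad <- meme
  bad[10] <- " 0.0 0.0 0.9 0.0"
  expect_error(read_pwm(write_tmp(bad, ".meme")), "sums to")

  pwm <- build_pwm(c("GATTA", "GATTC", "GCTTA"), pseudocount = 0.5)
  out <- tempfile(fileext = ".meme")
  write_pwm(pwm, out)
  back <- read_pwm(out)[[1]]
  expect_equal(back$freqs, pwm$freqs, tolerance = 1e-6)
})

test_that("shape tables demand completeness and reject bad lookups", {
  tab <- generate_shape_table(seed = 1)
  p <- tempfile(fileext = ".tsv")
  write_shape_table(tab, p)
  back <- read_shape_table(p)
  expect_equal(nrow(back), 1024L)
  expect_equal(unclass(back), unclass(tab), tolerance = 1e-6)

  df <- utils::read.table(p, sep = "\t", header = TRUE)
  p2 <- tempfile(fileext = ".tsv")
  utils::write.table(df[df$pentamer != "AAAAA", ], p2, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_error(read_shape_table(p2), "AAAAA")

  utils::write.table(rbind(df, df[df$pentamer == "GAGAG", ]), p2,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_shape_table(p2), "duplicate")

  expect_error(shape_lookup(tab, "GANGA"), "non-ACGT")
})

test_that("peak windows are centered on floor midpoints and clipped", {
  g <- genome(c(chr1 = paste(rep("ACGT", 250), collapse = "")))
  pk <- intervals("chr1", 100, 120)
  w <- extract_peak_windows(pk, g, half_width = 100)
  expect_equal(nchar(unname(w[1])), 201L)
  expect_equal(names(w), "chr1:10-211")
  expect_equal(unname(w[1]), substr(g$seq[[1]], 11, 211))

  pk_edge <- intervals("chr1", c(4, 100), c(6, 120))
  expect_warning(w2 <- extract_peak_windows(pk_edge, g, 100), "dropped")
  expect_length(w2, 1L)
  expect_equal(attr(w2, "n_dropped"), 1L)

  w0 <- extract_peak_windows(pk, g, half_width = 0)
  expect_equal(nchar(unname(w0[1])), 1L)

  expect_error(extract_peak_windows(intervals("nope", 1, 2), g),
               "unknown chromosome")
})

test_that("bedGraph coverage tracks round-trip", {
  tr <- data.frame(chrom = c("c1", "c1"), start = c(0, 50),
                   end = c(50, 100), value = c(2.5, 1))
  p <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, p)
  back <- read_bedgraph(p)
  expect_equal(back, tr)
})
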