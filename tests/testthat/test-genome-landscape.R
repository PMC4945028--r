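# neighbour distances, randomization, CES proximity, metagene profiles,
# enrichment, KS test

test_that("neighbour distances match hand-computed values", {
  pk <- intervals("c1", c(0, 100, 300), c(1, 101, 301))
  nd <- neighbor_distances(pk, n_max = 2)
  # n=1: nearest distances are 100, 100, 200
  expect_equal(nd$mean_distance[nd$n == 1], mean(c(100, 100, 200)))
  # n=2: per-site means (100+300)/2, (100+200)/2, (200+300)/2
  expect_equal(nd$mean_distance[nd$n == 2], mean(c(200, 150, 250)))
  expect_equal(nd$site_count, c(3L, 3L))

  # a site alone on its chromosome is excluded with counts reported
  pk2 <- rbind(pk, intervals("c2", 5, 6))
  class(pk2) <- class(pk)
  nd2 <- neighbor_distances(pk2, n_max = 1)
  expect_equal(nd2$site_count, 3L)
  expect_equal(nd2$mean_distance, nd$mean_distance[nd$n == 1])

  expect_error(neighbor_distances(pk[1, , drop = FALSE]), "fewer than 2")
})

test_that("neighbour distances are translation- and scale-consistent", {
  set.seed(5)
  mids <- sort(sample.int(1e5, 40))
  pk <- intervals("c1", mids, mids + 1)
  nd <- neighbor_distances(pk, n_max = 3)
  shifted <- intervals("c1", mids + 7919, mids + 7920)
  expect_equal(neighbor_distances(shifted, n_max = 3)$mean_distance,
               nd$mean_distance)
  scaled <- intervals("c1", mids * 10, mids * 10 + 1)
  expect_equal(neighbor_distances(scaled, n_max = 3)$mean_distance,
               10 * nd$mean_distance, tolerance = 1e-3)
  # mean distance non-decreasing in n
  expect_true(all(diff(nd$mean_distance) >= 0))
})

test_that("randomization calibrates uniform peaks near 1, clusters below", {
  g <- genome(c(chrX = strrep("ACGT", 2500000)),
              class_labels = c(chrX = "X"))   # 10 Mb
  set.seed(23)
  mids <- floor(runif(500, 0, 1e7))
  uniform <- intervals("chrX", mids, mids + 1)
  norm_u <- randomize_and_normalize(uniform, g, n_sets = 10, seed = 23)
  expect_true(all(norm_u$normalized > 0.8 & norm_u$normalized < 1.2))

  centers <- floor(runif(25, 0, 1e7))
  cm <- pmax(round(rnorm(500, sample(centers, 500, TRUE), 200)), 1)
  clustered <- intervals("chrX", cm, cm + 1)
  norm_c <- randomize_and_normalize(clustered, g, n_sets = 10, seed = 23)
  expect_lt(norm_c$normalized[norm_c$n == 1], 0.5)

  # n_sets = 1 normalises by that single set
  one <- randomize_and_normalize(uniform, g, n_sets = 1, seed = 4)
  expect_true(all(is.finite(one$normalized)))
  expect_error(randomize_and_normalize(uniform, g, n_sets = 0), "n_sets")
})

test_that("CES proximity labels follow the X median reference", {
  g <- genome(c(chrX = strrep("A", 100000), chr2L = strrep("A", 100000)),
              class_labels = c(chrX = "X", chr2L = "autosome"))
  ces <- intervals("chrX", 5000, 5100)
  pk <- intervals(c("chrX", "chrX", "chr2L"),
                  c(5150, 50000, 5100), c(5151, 50001, 5101))
  lab <- classify_ces_proximity(pk, ces, g, reference = 500)
  expect_equal(lab, c("CES", "X_other", "autosome"))
  expect_error(classify_ces_proximity(pk, ces[0, ], g), "empty CES")
})

test_that("metagene profiles normalise by gene length and flip strands", {
  genes <- data.frame(chrom = "c1", start = 1000, end = 2000,
                      strand = "+", id = "g1")
  hit_mid <- intervals("c1", 1500, 1501)
  prof <- metagene_profile(hit_mid, genes, n_bins = 60)
  expect_equal(sum(prof$count), 1L)
  expect_equal(prof$mid[which(prof$count == 1)], 0.525, tolerance = 0.026)

  # minus-strand gene: the same midpoint still maps to the gene body
  # center (within one bin: the TSS sits at end - 1, so the flipped
  # coordinate differs by 1 bp and the hit lies on a bin edge)
  genes_m <- transform(genes, strand = "-")
  prof_m <- metagene_profile(hit_mid, genes_m, n_bins = 60)
  expect_lte(abs(which(prof_m$count == 1) - which(prof$count == 1)), 1)

  # an upstream hit for a minus-strand gene lies downstream in profile terms
  up <- intervals("c1", 500, 501)
  p_plus <- metagene_profile(up, genes, n_bins = 6)
  p_minus <- metagene_profile(up, genes_m, n_bins = 6)
  expect_equal(which(p_plus$count == 1), 2L)   # x = -0.5
  expect_equal(which(p_minus$count == 1), 5L)  # x = +1.5

  none <- metagene_profile(hit_mid[0, ], genes)
  expect_true(all(none$value == 0))
  expect_error(metagene_profile(hit_mid,
                                transform(genes, end = start)),
               "zero-length")
})

test_that("metagene mass is conserved", {
  set.seed(77)
  genes <- generate_genes(genome(c(c1 = strrep("ACGT", 250000))),
                          n = 40, seed = 7)
  mids <- sort(sample.int(999000, 400))
  feats <- intervals("c1", mids, mids + 1)
  prof <- metagene_profile(feats, genes, n_bins = 60)
  bw <- 3 / 60
  # sum(value) * bw == total in-window incidences / n_genes
  gl <- genes$end - genes$start
  incidences <- sum(vapply(seq_len(nrow(genes)), function(i) {
    lo <- genes$start[i] - gl[i]; hi <- genes$end[i] + gl[i]
    x <- (mids - tss(genes)[i]) / gl[i]
    if (genes$strand[i] == "-") x <- -x
    sum(x >= -1 & x <= 2)
  }, numeric(1)))
  expect_equal(sum(prof$value) * bw, incidences / nrow(genes),
               tolerance = 1e-9)
})

test_that("body to 5' ratios behave under uniform and degenerate input", {
  set.seed(29)
  n_genes <- 100
  starts <- seq(10000, by = 20000, length.out = n_genes)
  genes <- data.frame(chrom = "c1", start = starts, end = starts + 10000,
                      strand = rep(c("+", "-"), n_genes / 2),
                      id = sprintf("g%d", 1:n_genes))
  mids <- sort(sample.int(max(genes$end) + 10000, 50000))
  feats <- intervals("c1", mids, mids + 1)
  r <- body_to_tss_ratio(feats, genes, flank = 250)
  expect_equal(r$ratio, 1, tolerance = 0.1)   # uniform hits: ratio about 1

  # all hits at the TSS: ratio collapses toward 0
  at_tss <- intervals("c1", tss(genes), tss(genes) + 1)
  r0 <- body_to_tss_ratio(at_tss, genes, flank = 250)
  expect_equal(r0$ratio, 0)

  # hits only in bodies: 5' density 0, ratio absent
  body_mid <- intervals("c1", genes$start + 5000, genes$start + 5001)
  rb <- body_to_tss_ratio(body_mid, genes, flank = 250)
  expect_true(is.na(rb$ratio))

  # per-group normalisation to the X value
  grp <- rep(c("X", "autosome"), each = n_genes / 2)
  rn <- body_to_tss_ratio(feats, genes, flank = 250, groups = grp,
                          normalize_to = "X")
  expect_equal(rn$ratio_normalized[rn$group == "X"], 1)
})

test_that("locus enrichment recovers constant and planted ratios", {
  g <- genome(c(c1 = strrep("ACGT", 25000)))
  bins <- seq(0, 99950, by = 50)
  chip <- data.frame(chrom = "c1", start = bins, end = bins + 50,
                     value = 20)
  input <- data.frame(chrom = "c1", start = bins, end = bins + 50,
                      value = 10)
  loci <- intervals("c1", c(0, 50000), c(1000, 51000))
  enr <- locus_enrichment(chip, input, loci)
  # equal library sizes are not assumed: chip mass is 2x input mass
  expect_equal(enr, c(1, 1), tolerance = 0.01)
  chip_eq <- transform(chip, value = c(rep(40, 20), rep(19.5, 1980)))
  enr2 <- locus_enrichment(chip_eq, input, loci[1, , drop = FALSE])
  expect_gt(enr2, 1.9)

  # zero input over a locus stays finite via the pseudocount
  input0 <- transform(input, value = c(rep(0, 20), rep(10, 1980)))
  expect_true(is.finite(locus_enrichment(chip, input0,
                                         loci[1, , drop = FALSE])))
})

test_that("enrichment rises with planted repeat length multipliers", {
  gen <- small_density_genome(x_density = 0, a_density = 0, seed = 31)
  g2 <- generate_genome(list(
    list(name = "chr2", class = "autosome", length = 4e5,
         runs = list(list(unit = "GA", k = 10, count = 30),
                     list(unit = "GA", k = 2, count = 30)))), seed = 31)
  runs <- find_repeat_runs(g2$genome, "GA", min_units = 2)
  long <- runs[runs$n_units == 10, ]
  short <- runs[runs$n_units == 2, ]
  loci <- rbind(intervals(long$chrom, long$start, long$end),
                intervals(short$chrom, short$start, short$end))
  mult <- c(rep(5, nrow(long)), rep(1, nrow(short)))
  cov <- generate_coverage(g2$genome, loci, multiplier = mult, depth = 30,
                           bin = 20, seed = 31)
  enr <- locus_enrichment(cov$chip, cov$input, loci)
  med_long <- median(enr[seq_len(nrow(long))])
  med_short <- median(enr[-seq_len(nrow(long))])
  expect_gt(med_long, med_short)
  expect_gt(med_long / med_short, 2)
})

test_that("KS test matches definition and stays monotone-invariant", {
  expect_equal(ks_two_sample(1:10, 1:10), list(D = 0, p_value = 1))
  a <- runif(100, 0, 1); b <- runif(100, 2, 3)
  ks <- ks_two_sample(a, b)
  expect_equal(ks$D, 1)
  expect_lt(ks$p_value, 1e-10)

  set.seed(12)
  x <- rnorm(60); y <- rnorm(60, 0.5)
  k1 <- ks_two_sample(x, y)
  k2 <- ks_two_sample(exp(x), exp(y))   # strictly monotone transform
  expect_equal(k1$D, k2$D)

  # D agrees with stats::ks.test; p follows the corrected asymptotic
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(k1$D, unname(ref$statistic))
  ne <- 60 * 60 / 120
  t <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * k1$D
  i <- 1:100
  expect_equal(k1$p_value, 2 * sum((-1)^(i - 1) * exp(-2 * i^2 * t^2)),
               tolerance = 1e-10)
  # the correction only sharpens the conservative plain asymptotic p
  expect_lte(k1$p_value, ref$p.value)

  # small samples without ties use the exact distribution
  set.seed(3)
  xs <- rnorm(12); ys <- rnorm(15, 1)
  expect_equal(ks_two_sample(xs, ys)$p_value,
               stats::ks.test(xs, ys, exact = TRUE)$p.value)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
})

test_that("KS type-I error is calibrated at alpha 0.05", {
  set.seed(2026)
  reject <- logical(2000)
  for (i in seq_along(reject)) {
    reject[i] <- ks_two_sample(rnorm(100), rnorm(100))$p_value <= 0.05
  }
  expect_gte(mean(reject), 0.04)
  expect_lte(mean(reject), 0.06)
})
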