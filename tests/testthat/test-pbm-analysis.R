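# probe classification, mixtures, repeat-length intensity, flank scan

test_that("PBM classification uses a strict threshold", {
  expect_equal(classify_pbm(c(6501, 6500, 0)), c("PBM+", "PBM-", "PBM-"))
})

test_that("bimodal threshold lands between planted components", {
  set.seed(7)
  lx <- c(rnorm(1200, 8, 0.5), rnorm(800, 11, 0.5))   # log2 units
  thr <- find_bimodal_threshold(2^lx)
  expect_gt(thr, 2^9)
  expect_lt(thr, 2^10)
  # fewer than 5% of observations are misassigned by the threshold
  truth <- rep(c("lo", "hi"), c(1200, 800))
  called <- ifelse(2^lx > thr, "hi", "lo")
  expect_lt(mean(called != truth), 0.05)

  set.seed(8)
  expect_error(find_bimodal_threshold(2^rnorm(2000, 9, 0.4)),
               "no bimodality")

  # two delta-like clusters: threshold strictly between
  x <- c(rnorm(500, 100, 1), rnorm(500, 10000, 10))
  thr <- find_bimodal_threshold(x)
  expect_gt(thr, 110)
  expect_lt(thr, 9900)
})

test_that("MRE classification honours the unlabeled p-value gap", {
  pwm <- build_pwm(c("GAGATCGAGAT", "GAGATCGAGAT", "GACATCGAGAT",
                     "GAGATCGATAT"), pseudocount = 0.25)
  hit <- paste0("TTTTTT", consensus(pwm), "TTTTTT")
  set.seed(9)
  miss <- paste(sample(c("C", "T"), 30, replace = TRUE), collapse = "")
  labs <- classify_mre(c(hit, miss), pwm)
  expect_equal(labs[1], "MRE+")
  expect_equal(labs[2], "MRE-")
  # the gap between the two cutoffs is reported as ambiguous, not guessed
  p <- best_match_pvalue(pwm, c(hit, miss))
  expect_lt(p[1], 1e-4)
  expect_gt(p[2], 1e-3)
  labs_gap <- classify_mre(c(hit, miss), pwm, p_plus = 1e-12,
                           p_minus = 0.999)
  expect_equal(labs_gap, c("ambiguous", "ambiguous"))
})

test_that("EM mixture recovers planted parameters and defines strong set", {
  set.seed(11)
  n <- 5000
  comp <- sample(c(1, 2), n, replace = TRUE, prob = c(0.6, 0.4))
  x <- rnorm(n, mean = c(8, 11)[comp], sd = 0.5)
  fit <- fit_two_gaussian_mixture(x, seed = 11)
  expect_true(fit$converged)
  expect_equal(fit$means, c(8, 11), tolerance = 0.1 / 8)
  expect_lt(max(abs(fit$means - c(8, 11))), 0.1)
  expect_lt(max(abs(fit$weights - c(0.6, 0.4))), 0.03)
  expect_lt(max(abs(fit$sds - 0.5)), 0.05)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)

  # strong set sits above the posterior-0.5 crossing
  cross <- min(x[fit$posteriors >= 0.5])
  expect_true(all(x[fit$strong] >= cross))
  expect_true(all(fit$posteriors[fit$strong] >= 0.95))

  expect_error(fit_two_gaussian_mixture(rep(5, 100)), "zero-variance")

  # independent cross-check: mclust agrees on the component means
  suppressMessages(library(mclust))
  mc <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(as.numeric(mc$parameters$mean)), fit$means,
               tolerance = 0.05)
})

test_that("mixture split agrees with density-threshold split when well separated", {
  set.seed(12)
  x <- c(rnorm(1500, 8, 0.5), rnorm(1000, 11, 0.5))
  thr <- find_bimodal_threshold(2^x)
  fit <- fit_two_gaussian_mixture(x, seed = 12)
  by_thr <- x > log2(thr)
  by_mix <- fit$posteriors > 0.5
  expect_gt(mean(by_thr == by_mix), 0.95)
})

test_that("quantile split is balanced, ordered, and deterministic", {
  lab <- quantile_split(1:10, k = 5)
  expect_equal(lab[10:9], c("q1", "q1"))
  expect_equal(lab[1:2], c("q5", "q5"))

  lab <- quantile_split(rep(1, 7), k = 3)
  expect_equal(as.vector(table(lab)), c(3, 2, 2))
  expect_equal(lab, c("q1", "q1", "q1", "q2", "q2", "q3", "q3"))

  lab <- quantile_split(c(3, 1, 2), k = 3)
  expect_equal(lab, c("q1", "q3", "q2"))
  expect_error(quantile_split(1:3, k = 4), "at least k")
})

test_that("intensity by repeat length recovers the planted plateau", {
  gen <- generate_probe_set(n_bound = 360, n_unbound = 0,
                            repeat_units = 2:13, base_bound = 6000,
                            effect = 400, plateau = 10, noise_sd = 100,
                            seed = 3)
  res <- intensity_by_repeat_length(gen$probes, bin_cap = 11)
  expect_identical(res$per_probe$n_units, gen$truth$n_units)
  med <- res$summary$median[match(as.character(2:10), res$summary$bin)]
  expect_true(all(diff(med) > 0))              # rises up to the plateau
  top <- res$summary$median[res$summary$bin == ">=11"]
  plateau_med <- res$summary$median[res$summary$bin == "10"]
  expect_lt(abs(top - plateau_med), 3 * 100)   # flat beyond 10 units

  # binning: a 4-unit probe in bin "4", a 13-unit probe pooled into ">=11"
  expect_equal(res$per_probe$bin[gen$truth$n_units == 4][1], "4")
  expect_equal(res$per_probe$bin[gen$truth$n_units == 13][1], ">=11")
})

test_that("flank scan recovers the planted (4,3) window", {
  gen <- generate_probe_set(n_bound = 200, n_unbound = 200, seed = 5)
  core_pwm <- build_pwm(gen$truth$core, pseudocount = 0.01)
  bound <- gen$probes$variable_seq[gen$truth$bound]
  unbound <- gen$probes$variable_seq[!gen$truth$bound]
  fs <- flank_separation_scan(bound, unbound, core_pwm)
  expect_equal(unname(fs$minimal_window), c(4L, 3L))
  expect_equal(fs$total_motif_length, 15L)
  expect_equal(fs$overlap["0", "0"], 100)

  # brute-force set-intersection oracle at a few cells
  frame_of <- function(seqs) substr(seqs, 11 - 10, 14 + 8 + 11)
  for (cell in list(c(0, 0), c(4, 3), c(3, 3), c(4, 2), c(3, 4))) {
    a <- cell[1]; b <- cell[2]
    bk <- unique(substr(bound, 15 - a, 22 + b))
    uk <- substr(unbound, 15 - a, 22 + b)
    expect_equal(fs$overlap[as.character(a), as.character(b)],
                 100 * sum(bk %in% uk) / length(bk))
  }

  # overlap never increases when consensus constraint is added
  expect_true(all(apply(fs$overlap, 1, function(r) all(diff(r) <= 1e-9))))
  expect_true(all(apply(fs$overlap, 2, function(r) all(diff(r) <= 1e-9))))
})

test_that("flank scan degenerate cases", {
  core_pwm <- consensus_pwm("GAGACTGA")
  set.seed(31)
  ctx <- function() paste(sample(c("C", "T"), 14, replace = TRUE),
                          collapse = "")
  seqs <- vapply(1:30, function(i) paste0(ctx(), "GAGACTGA", ctx()),
                 character(1))
  fs <- flank_separation_scan(seqs, seqs, core_pwm, max5 = 3, max3 = 3)
  expect_true(all(fs$overlap == 100))
  expect_null(fs$minimal_window)

  other <- vapply(1:30, function(i) paste0(ctx(), "GGGGCCCC", ctx()),
                  character(1))
  fs2 <- flank_separation_scan(seqs, other, core_pwm, max5 = 3, max3 = 3)
  expect_equal(fs2$overlap["0", "0"], 0)
  expect_equal(unname(fs2$minimal_window), c(0L, 0L))
  expect_equal(fs2$total_motif_length, 8L)

  expect_error(flank_separation_scan(character(0), seqs, core_pwm),
               "non-empty")
})

test_that("occupancy by motif class separates matched from unmatched flanks", {
  # genome where coverage is 3x over planted full-motif sites, 1x elsewhere
  set.seed(9)
  core <- "GAGACTGA"; f5 <- "TGCG"; f3 <- "CTT"
  full <- paste0(f5, core, f3)
  n <- 200
  mk <- function(with_flank) {
    body <- if (with_flank) full else
      paste0(sample_flank(4), core, sample_flank(3))
    paste0(sample_flank(10), body, sample_flank(10))
  }
  sample_flank <- function(k) paste(sample(c("C", "T", "A"), k,
                                           replace = TRUE), collapse = "")
  seqs <- c(vapply(1:n, function(i) mk(TRUE), character(1)),
            vapply(1:n, function(i) mk(FALSE), character(1)))
  gseq <- paste(seqs, collapse = strrep("T", 30))
  g <- genome(c(chr1 = gseq))
  core_hits <- scan_pwm(consensus_pwm(core), g, p_threshold = 1e-4,
                        strands = "forward")
  full_hits <- scan_pwm(consensus_pwm(full), g, p_threshold = 1e-6,
                        strands = "forward")
  expect_gt(nrow(core_hits), 300)
  loci <- intervals(full_hits$seqname, full_hits$offset,
                    full_hits$offset + 15)
  cov <- generate_coverage(g, loci, multiplier = 3, depth = 30, bin = 20,
                           seed = 9)
  res <- occupancy_by_motif_class(core_hits, full_hits, 8, 15,
                                  cov$chip, cov$input, half_width = 50)
  expect_gt(median(res$matched), median(res$unmatched))
  expect_lt(res$ks$p_value, 0.01)

  expect_error(occupancy_by_motif_class(core_hits[0, ], full_hits, 8, 15,
                                        cov$chip, cov$input), "no core")
})
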