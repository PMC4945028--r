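# gcPBM probe analysis: intensity thresholding, bimodal threshold finding,
# motif-based MRE classification, two-Gaussian mixture modelling, repeat
# length vs intensity, and the minimal-motif flank-separation scan.

#' Classify probes as bound/unbound by median intensity
#'
#' A probe is PBM+ iff its median intensity is strictly greater than the
#' threshold (probes at exactly the threshold are PBM-). The default of
#' 6500 fluorescence units is the published valley between the two modes of
#' the gcPBM intensity histogram; [find_bimodal_threshold()] recovers such
#' a value from data.
#'
#' @param probes a `probe_table` data frame (see [read_probe_table()]) or a
#'   numeric vector of median intensities.
#' @param threshold intensity threshold (default 6500).
#' @return character vector of `"PBM+"` / `"PBM-"` labels.
#' @export
classify_pbm <- function(probes, threshold = 6500) {
  x <- if (is.numeric(probes)) probes else probes$median_intensity
  ifelse(x > threshold, "PBM+", "PBM-")
}

#' Find the between-modes intensity threshold of a bimodal distribution
#'
#' Fits a Gaussian kernel density (Silverman's rule-of-thumb bandwidth) to
#' log2 intensities and returns the density minimum between the two highest
#' modes, back-transformed to the original intensity scale. Fails with an
#' explicit "no bimodality" error when fewer than two modes are found.
#'
#' @param intensities numeric vector of raw (positive) intensities, at
#'   least 50 observations.
#' @return the threshold on the original intensity scale.
#' @export
find_bimodal_threshold <- function(intensities) {
  x <- intensities[is.finite(intensities) & intensities > 0]
  if (length(x) < 50L) stop("need at least 50 positive observations")
  lx <- log2(x)
  d <- stats::density(lx, bw = "nrd0")
  y <- d$y
  n <- length(y)
  is_max <- y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf)
  # negligible tail wiggles of the KDE do not count as modes
  modes <- which(is_max & y >= 0.05 * max(y))
  if (length(modes) < 2L) {
    stop("no bimodality: kernel density has fewer than two modes")
  }
  top2 <- modes[order(y[modes], decreasing = TRUE)][1:2]
  lo <- min(top2); hi <- max(top2)
  valley <- seq(lo, hi)[which.min(y[lo:hi])]
  # a genuine valley must dip clearly below the smaller of the two modes
  if (y[valley] > 0.95 * min(y[top2])) {
    stop("no bimodality: no clear valley between the two highest modes")
  }
  2^d$x[valley]
}

#' Classify sequences by similarity to a motif
#'
#' Labels follow the published convention: best scan p-value below 1e-4 is
#' `MRE+`, above 1e-3 is `MRE-`. The gap (1e-4, 1e-3] is deliberately
#' returned as `"ambiguous"` rather than forced into either class.
#'
#' @param seqs character vector of sequences (each at least the PWM width).
#' @param mre_pwm a `pwm` object.
#' @param p_plus p-value below which a sequence is `MRE+`.
#' @param p_minus p-value above which a sequence is `MRE-`.
#' @return character vector of `"MRE+"`, `"MRE-"`, `"ambiguous"`.
#' @export
classify_mre <- function(seqs, mre_pwm, p_plus = 1e-4, p_minus = 1e-3) {
  p <- best_match_pvalue(mre_pwm, seqs)
  out <- rep("ambiguous", length(seqs))
  out[!is.na(p) & p < p_plus] <- "MRE+"
  out[!is.na(p) & p > p_minus] <- "MRE-"
  out[is.na(p)] <- "MRE-"
  out
}

#' Fit a two-component Gaussian mixture to log intensities
#'
#' Plain EM on one-dimensional data, initialised from the empirical median
#' split, run until the absolute log-likelihood change is below `tol` or
#' `max_iter` iterations. Observations whose posterior probability of the
#' higher-mean component is at least `confidence` form the "strongly bound"
#' set.
#'
#' @param log_intensities numeric vector (log2 intensities), >= 50 values
#'   with nonzero variance.
#' @param confidence posterior cutoff for strong-set membership
#'   (default 0.95).
#' @param seed integer seed (reserved for stochastic restarts; the default
#'   fit is deterministic).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param max_iter iteration cap (default 500).
#' @return list of class `mixture_fit`: `means` (ascending), `sds`,
#'   `weights`, `log_likelihood`, `posteriors` (probability of the
#'   higher-mean component per observation), `strong` (logical strong-set
#'   membership), `n_iterations`, `converged`.
#' @export
fit_two_gaussian_mixture <- function(log_intensities, confidence = 0.95,
                                     seed = 1L, tol = 1e-8, max_iter = 500L) {
  x <- log_intensities[is.finite(log_intensities)]
  n <- length(x)
  if (n < 50L) stop("need at least 50 observations")
  if (stats::var(x) == 0) stop("zero-variance input")
  set.seed(seed)
  med <- stats::median(x)
  lower <- x <= med
  mu <- c(mean(x[lower]), mean(x[!lower]))
  sg <- pmax(c(stats::sd(x[lower]), stats::sd(x[!lower])), 1e-3)
  if (anyNA(sg)) sg <- rep(stats::sd(x) / 2, 2)
  w <- c(mean(lower), 1 - mean(lower))
  ll_old <- -Inf
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    r1 <- 1 - r2
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    n1 <- sum(r1); n2 <- sum(r2)
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sg <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                 sum(r2 * (x - mu[2])^2) / n2))
    sg <- pmax(sg, 1e-6)
  }
  if (!converged) {
    warning("EM did not converge within ", it, " iterations")
  }
  # report sorted ascending; posteriors refer to the higher-mean component
  if (mu[1] > mu[2]) {
    mu <- rev(mu); sg <- rev(sg); w <- rev(w); r2 <- 1 - r2
  }
  post <- rep(NA_real_, length(log_intensities))
  post[is.finite(log_intensities)] <- r2
  structure(list(means = mu, sds = sg, weights = w, log_likelihood = ll,
                 posteriors = post,
                 strong = !is.na(post) & post >= confidence,
                 n_iterations = it, converged = converged),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "two-Gaussian mixture: means %.3f / %.3f, sds %.3f / %.3f,\n  weights %.3f / %.3f, logLik %.2f, %d iterations%s, %d strongly bound\n",
    x$means[1], x$means[2], x$sds[1], x$sds[2], x$weights[1], x$weights[2],
    x$log_likelihood, x$n_iterations,
    if (x$converged) "" else " (not converged)", sum(x$strong)))
  invisible(x)
}

#' Split probes into intensity quantiles
#'
#' `q1` is the highest-intensity quantile. Group sizes differ by at most
#' one; ties are assigned to the lower-index (higher-intensity) quantile,
#' and probes with equal intensity are ordered by their input position, so
#' the assignment is deterministic.
#'
#' @param probes a `probe_table` or numeric vector of intensities.
#' @param k number of quantiles (default 5).
#' @return character vector of labels `"q1"` ... `"qk"` in input order.
#' @export
quantile_split <- function(probes, k = 5L) {
  x <- if (is.numeric(probes)) probes else probes$median_intensity
  n <- length(x)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k probes")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ord <- order(-x, seq_len(n))   # stable: ties by input order
  lab <- rep(sprintf("q%d", seq_len(k)), sizes)
  out <- character(n)
  out[ord] <- lab
  out
}

#' Binding intensity by GA-repeat length
#'
#' For each probe, finds the maximal run of `unit` in the 36-nt variable
#' region ([find_repeat_runs()]) and summarises intensity per unit count.
#' Counts at or above `bin_cap` are pooled into a single top bin (very few
#' probes carry more than 11 GA units within 36 bp).
#'
#' @param probes a `probe_table` data frame.
#' @param unit repeat unit (default `"GA"`).
#' @param bin_cap pool counts `>= bin_cap` (default 11).
#' @return list with `per_probe` (data frame: `id`, `n_units`, `bin`,
#'   `median_intensity`) and `summary` (per-bin `n`, `median`, `q1`, `q3`).
#' @export
intensity_by_repeat_length <- function(probes, unit = "GA", bin_cap = 11L) {
  stopifnot(is.data.frame(probes))
  n_units <- vapply(probes$variable_seq, function(s) {
    r <- find_repeat_runs(s, unit)
    if (nrow(r)) max(r$n_units) else 0L
  }, integer(1), USE.NAMES = FALSE)
  bin <- ifelse(n_units >= bin_cap, sprintf(">=%d", bin_cap),
                as.character(n_units))
  per_probe <- data.frame(id = probes$id, n_units = n_units, bin = bin,
                          median_intensity = probes$median_intensity,
                          stringsAsFactors = FALSE)
  lev <- c(as.character(0:(bin_cap - 1L)), sprintf(">=%d", bin_cap))
  groups <- split(per_probe$median_intensity,
                  factor(per_probe$bin, levels = lev))
  summ <- data.frame(
    bin = lev,
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, function(v)
      if (length(v)) stats::median(v) else NA_real_, numeric(1)),
    q1 = vapply(groups, function(v)
      if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
      numeric(1)),
    q3 = vapply(groups, function(v)
      if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
      numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(per_probe = per_probe, summary = summ)
}

#' Minimal-motif flank-separation scan
#'
#' Determines how many consensus bases 5' and 3' of a core motif are needed
#' to separate bound from unbound sequences. Each sequence's core match is
#' located with [align_to_pwm()]; for every window `(a, b)` with
#' `0 <= a <= max5`, `0 <= b <= max3`, the `(a + core + b)`-mer around the
#' match is extracted and
#' `overlap(a, b) = 100 * |bound k-mers shared with unbound| / |bound k-mers|`.
#' By default k-mers are compared as distinct types (order-independent and
#' deterministic); `level = "token"` weights each bound probe instead. The
#' minimal window is the zero-overlap cell minimising `a + b`, ties broken
#' by the smaller 5' extension.
#'
#' @param bound_seqs,unbound_seqs character vectors of probe sequences.
#' @param core_pwm `pwm` for the core motif.
#' @param max5,max3 largest 5'/3' extensions scanned (default 10 each).
#' @param level `"type"` (distinct k-mers) or `"token"` (per bound probe).
#' @return list of class `flank_scan`: `overlap` ((max5+1) x (max3+1)
#'   percent matrix, rows = 5' extension, columns = 3' extension),
#'   `minimal_window` (`c(len5, len3)` or `NULL`), `total_motif_length`
#'   (core width + len5 + len3, or `NULL`), `n_dropped` (per-cell counts of
#'   sequences lacking context, summed over bound and unbound).
#' @export
flank_separation_scan <- function(bound_seqs, unbound_seqs, core_pwm,
                                  max5 = 10L, max3 = 10L,
                                  level = c("type", "token")) {
  level <- match.arg(level)
  if (!length(bound_seqs) || !length(unbound_seqs)) {
    stop("bound and unbound sets must both be non-empty")
  }
  stopifnot(inherits(core_pwm, "pwm"))
  b_ext <- oriented_context(bound_seqs, core_pwm, max5, max3)
  u_ext <- oriented_context(unbound_seqs, core_pwm, max5, max3)
  w <- core_pwm$width
  overlap <- matrix(NA_real_, max5 + 1L, max3 + 1L,
                    dimnames = list(len5 = 0:max5, len3 = 0:max3))
  dropped <- matrix(0L, max5 + 1L, max3 + 1L)
  for (a in 0:max5) {
    for (b in 0:max3) {
      bk <- window_kmers(b_ext, max5, w, a, b)
      uk <- window_kmers(u_ext, max5, w, a, b)
      dropped[a + 1L, b + 1L] <- sum(is.na(bk)) + sum(is.na(uk))
      bk <- bk[!is.na(bk)]; uk <- uk[!is.na(uk)]
      if (!length(bk)) { overlap[a + 1L, b + 1L] <- NA_real_; next }
      if (level == "type") {
        bt <- unique(bk)
        overlap[a + 1L, b + 1L] <- 100 * sum(bt %in% uk) / length(bt)
      } else {
        overlap[a + 1L, b + 1L] <- 100 * sum(bk %in% uk) / length(bk)
      }
    }
  }
  # overlap should not increase when consensus constraint is added
  mono_ok <- all(apply(overlap, 1L, function(r) all(diff(r[!is.na(r)]) <= 1e-9))) &&
    all(apply(overlap, 2L, function(r) all(diff(r[!is.na(r)]) <= 1e-9)))
  if (!mono_ok) {
    warning("overlap matrix is not monotonically non-increasing; ",
            "bound k-mer diversity grows faster than separation")
  }
  zero <- which(!is.na(overlap) & overlap == 0, arr.ind = TRUE)
  minimal <- NULL; total <- NULL
  if (nrow(zero)) {
    a <- zero[, 1] - 1L; b <- zero[, 2] - 1L
    pick <- order(a + b, a)[1]
    minimal <- c(len5 = unname(a[pick]), len3 = unname(b[pick]))
    total <- unname(w + a[pick] + b[pick])
  }
  structure(list(overlap = overlap, minimal_window = minimal,
                 total_motif_length = total, n_dropped = dropped),
            class = "flank_scan")
}

#' @export
print.flank_scan <- function(x, ...) {
  cat("flank separation scan (percent bound k-mers shared with unbound)\n")
  print(round(x$overlap, 1))
  if (is.null(x$minimal_window)) {
    cat("no zero-overlap window found\n")
  } else {
    cat(sprintf("minimal window: %d bp 5', %d bp 3'; total motif %d bp\n",
                x$minimal_window[1], x$minimal_window[2],
                x$total_motif_length))
  }
  invisible(x)
}

# orient each sequence so its best core match reads forward, padded into a
# fixed frame: max5 context bases, the core, max3 context bases; NA bases
# where the sequence runs out
#' @noRd
oriented_context <- function(seqs, core_pwm, max5, max3) {
  al <- align_to_pwm(seqs, core_pwm, strands = "both",
                     flank5 = 0L, flank3 = 0L)
  w <- core_pwm$width
  vapply(seq_along(seqs), function(k) {
    s <- toupper(seqs[k])
    L <- nchar(s)
    off <- al$alignment$offset[k]
    if (al$alignment$strand[k] == "-") {
      s <- revcomp(s)
      off <- L - w - off
    }
    a0 <- off - max5           # 0-based inclusive frame start
    b0 <- off + w + max3       # exclusive frame end
    left_pad <- max(0L, -a0)
    right_pad <- max(0L, b0 - L)
    core <- substr(s, max(a0, 0L) + 1L, min(b0, L))
    paste0(strrep(".", left_pad), core, strrep(".", right_pad))
  }, character(1))
}

# extract the (a + w + b)-mer from frames built by oriented_context;
# NA when padding ('.') intrudes
#' @noRd
window_kmers <- function(frames, max5, w, a, b) {
  from <- max5 - a + 1L
  to <- max5 + w + b
  k <- substr(frames, from, to)
  k[grepl(".", k, fixed = TRUE)] <- NA_character_
  k
}

#' ChIP enrichment of core-motif hits split by flank match
#'
#' Partitions core-motif hits by whether they overlap a full (extended)
#' motif hit, computes per-hit coverage enrichment windows via
#' [locus_enrichment()], and compares the two enrichment distributions with
#' [ks_two_sample()].
#'
#' @param core_hits,full_hits hit data frames from [scan_pwm()] over the
#'   same genome.
#' @param core_width,full_width motif widths of the two scans.
#' @param chip,input coverage tracks (bedGraph data frames).
#' @param half_width enrichment window half-width around each core hit
#'   midpoint (default 100).
#' @return list with `matched` and `unmatched` enrichment vectors and `ks`
#'   (the two-sample KS test between them).
#' @export
occupancy_by_motif_class <- function(core_hits, full_hits, core_width,
                                     full_width, chip, input,
                                     half_width = 100L) {
  if (nrow(core_hits) == 0L) stop("no core motif hits")
  core_start <- core_hits$offset
  core_end <- core_hits$offset + core_width
  matched <- logical(nrow(core_hits))
  for (nm in unique(core_hits$seqname)) {
    ci <- which(core_hits$seqname == nm)
    fi <- which(full_hits$seqname == nm)
    if (!length(fi)) next
    fs <- full_hits$offset[fi]; fe <- fs + full_width
    matched[ci] <- vapply(ci, function(i) {
      any(core_start[i] < fe & core_end[i] > fs)
    }, logical(1))
  }
  mid <- floor((core_start + core_end) / 2)
  loci <- intervals(core_hits$seqname, pmax(mid - half_width, 0),
                    mid + half_width)
  enr <- locus_enrichment(chip, input, loci)
  out <- list(matched = enr[matched], unmatched = enr[!matched])
  if (!length(out$matched) || !length(out$unmatched)) {
    stop("a motif class is empty; cannot compare enrichments")
  }
  out$ks <- ks_two_sample(out$matched, out$unmatched)
  out
}
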