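# Spatial statistics of binding sites: nearest-neighbour distances with
# randomization normalization, CES proximity, metagene profiles, body:5'
# ratios, coverage enrichment, and the two-sample KS test.

#' Mean distance to the n nearest neighbours, per category
#'
#' Distances are measured between peak midpoints on the same chromosome;
#' inter-chromosomal neighbours are undefined. For each site, `dbar(n)` is
#' the mean distance to its n nearest same-category, same-chromosome
#' neighbours; the reported value is the mean of `dbar(n)` over sites.
#' Sites with fewer than n neighbours are excluded from that n (the counts
#' are reported).
#'
#' @param peaks an [intervals()] data frame.
#' @param labels category per peak (e.g. `"CES"`, `"X"`, `"autosome"`);
#'   a single value is recycled.
#' @param n_max largest neighbour index (default 4).
#' @return data frame with columns `category`, `n`, `mean_distance`,
#'   `site_count`.
#' @export
neighbor_distances <- function(peaks, labels = "all", n_max = 4L) {
  labels <- rep_len(as.character(labels), nrow(peaks))
  mid <- midpoints(peaks)
  out <- list()
  for (cat in unique(labels)) {
    sel <- labels == cat
    if (sum(sel) < 2L) stop("category '", cat, "' has fewer than 2 peaks")
    per_site <- site_neighbor_means(mid[sel], peaks$chrom[sel], n_max)
    for (n in seq_len(n_max)) {
      v <- per_site[, n]
      out[[length(out) + 1L]] <- data.frame(
        category = cat, n = n, mean_distance = mean(v, na.rm = TRUE),
        site_count = sum(!is.na(v)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# per-site mean distance to the 1..n_max nearest same-chromosome neighbours
#' @noRd
site_neighbor_means <- function(mid, chrom, n_max) {
  n <- length(mid)
  res <- matrix(NA_real_, n, n_max)
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    m <- sort(mid[idx])
    ord <- idx[order(mid[idx])]
    k <- length(m)
    if (k < 2L) next
    for (i in seq_len(k)) {
      d <- sort(abs(m[-i] - m[i]))
      top <- seq_len(min(n_max, length(d)))
      means <- cumsum(d[top]) / top
      res[ord[i], top] <- means
    }
  }
  res
}

#' Normalise neighbour distances against randomized peak sets
#'
#' Generates `n_sets` randomized peak sets (midpoints placed uniformly at
#' random, preserving the per-chromosome, per-category peak counts),
#' computes the same neighbour statistics, and reports
#' `observed / median(randomized)`. Values below 1 indicate clustering
#' tighter than random placement.
#'
#' @inheritParams neighbor_distances
#' @param g a [genome()] providing chromosome lengths.
#' @param n_sets number of randomized sets (default 10).
#' @param seed integer seed.
#' @return the [neighbor_distances()] data frame with extra columns
#'   `random_median` and `normalized`.
#' @export
randomize_and_normalize <- function(peaks, g, labels = "all", n_max = 4L,
                                    n_sets = 10L, seed = 1L) {
  stopifnot(inherits(g, "Genome"))
  if (n_sets < 1L) stop("n_sets must be >= 1")
  obs <- neighbor_distances(peaks, labels, n_max)
  labels <- rep_len(as.character(labels), nrow(peaks))
  lens <- chrom_lengths(g)
  rand_vals <- array(NA_real_, c(nrow(obs), n_sets))
  set.seed(child_seed(seed, "peak_randomization"))
  for (s in seq_len(n_sets)) {
    rp <- peaks
    for (cn in unique(peaks$chrom)) {
      sel <- peaks$chrom == cn
      m <- floor(stats::runif(sum(sel), 0, lens[[cn]]))
      rp$start[sel] <- m
      rp$end[sel] <- m + 1
    }
    rd <- neighbor_distances(rp, labels, n_max)
    stopifnot(identical(rd$category, obs$category), identical(rd$n, obs$n))
    rand_vals[, s] <- rd$mean_distance
  }
  obs$random_median <- apply(rand_vals, 1L, stats::median)
  obs$normalized <- obs$mean_distance / obs$random_median
  obs
}

#' Label peaks by proximity to chromatin entry sites
#'
#' An X-chromosome peak is labelled `"CES"` when its midpoint lies within
#' the reference distance of any CES midpoint; the reference is the median
#' nearest-neighbour (n = 1) distance among X-chromosome peaks. Remaining X
#' peaks are `"X_other"`; peaks elsewhere are `"autosome"`.
#'
#' @param peaks an [intervals()] data frame.
#' @param ces CES intervals.
#' @param g a [genome()] with class labels.
#' @param reference optional fixed reference distance in bp (computed from
#'   the data when `NULL`).
#' @return character vector of labels per peak.
#' @export
classify_ces_proximity <- function(peaks, ces, g, reference = NULL) {
  stopifnot(inherits(g, "Genome"))
  if (nrow(ces) == 0L) stop("empty CES list")
  x_chroms <- names(g$class_label)[g$class_label == "X"]
  on_x <- peaks$chrom %in% x_chroms
  if (is.null(reference)) {
    if (sum(on_x) < 2L) stop("need X-chromosome peaks to derive the reference")
    mid_x <- midpoints(peaks[on_x, , drop = FALSE])
    nn <- site_neighbor_means(mid_x, peaks$chrom[on_x], 1L)[, 1]
    reference <- stats::median(nn, na.rm = TRUE)
  }
  mid <- midpoints(peaks)
  ces_mid <- midpoints(ces)
  lab <- ifelse(on_x, "X_other", "autosome")
  for (i in which(on_x)) {
    sel <- ces$chrom == peaks$chrom[i]
    if (any(sel) && min(abs(ces_mid[sel] - mid[i])) <= reference) {
      lab[i] <- "CES"
    }
  }
  lab
}

#' Length-normalised metagene profile
#'
#' Maps each feature midpoint falling within one gene length of a gene
#' (from TSS - L to TTS + L, L = that gene's length) to the coordinate
#' `x = signed distance from the TSS along the transcription direction / L`,
#' so x runs from -1 (one gene length upstream) through 0 (TSS) and 1 (TTS)
#' to 2. Minus-strand genes are orientation-flipped. A feature is counted
#' once per overlapping gene window. Per-bin frequency is
#' `count / (n_genes * bin_width)`.
#'
#' @param features [intervals()] data frame or a [scan_pwm()] hit table
#'   (midpoints are used; hits use `offset`).
#' @param genes gene models from [read_gene_models()].
#' @param n_bins number of bins across `[-1, 2]` (default 60).
#' @param feature_width width to assume for hit tables (default 1).
#' @return list of class `metagene_profile`: `bin_edges` (length
#'   `n_bins + 1`), `mid` (bin midpoints), `value` (per-bin frequency),
#'   `count` (raw per-bin counts), `n_genes`.
#' @export
metagene_profile <- function(features, genes, n_bins = 60L,
                             feature_width = 1L) {
  if (nrow(genes) == 0L) stop("no genes")
  if (any(genes$end - genes$start < 1)) stop("zero-length gene")
  mid <- feature_midpoints(features, feature_width)
  chroms <- feature_chroms(features)
  edges <- seq(-1, 2, length.out = n_bins + 1L)
  counts <- integer(n_bins)
  gl <- genes$end - genes$start
  g_tss <- tss(genes)
  for (gi in seq_len(nrow(genes))) {
    sel <- chroms == genes$chrom[gi]
    if (!any(sel)) next
    x <- (mid[sel] - g_tss[gi]) / gl[gi]
    if (genes$strand[gi] == "-") x <- -x
    x <- x[x >= -1 & x <= 2]
    if (!length(x)) next
    b <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              n_bins)
    counts <- counts + tabulate(b, nbins = n_bins)
  }
  bw <- 3 / n_bins
  structure(list(bin_edges = edges, mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 value = counts / (nrow(genes) * bw), count = counts,
                 n_genes = nrow(genes)),
            class = "metagene_profile")
}

#' @noRd
feature_midpoints <- function(features, feature_width = 1L) {
  if (!is.null(features$start) && !is.null(features$end)) {
    return(midpoints(features))
  }
  if (!is.null(features$offset)) {
    return(floor(features$offset + feature_width / 2))
  }
  stop("features must have start/end or offset columns")
}

#' @noRd
feature_chroms <- function(features) {
  if (!is.null(features$chrom)) return(features$chrom)
  if (!is.null(features$seqname)) return(features$seqname)
  stop("features must have a chrom or seqname column")
}

#' Gene body to 5' end feature density ratio
#'
#' The body is `(TSS + flank, TTS]` and the 5' end `[TSS - flank,
#' TSS + flank]`, both along the transcription direction. Densities are
#' pooled across the genes of each group (total hits / total width), and
#' the ratio is body density over 5' density. Groups whose 5' windows
#' contain no hits get an `NA` ratio. Optionally every ratio is divided by
#' the X group's ratio.
#'
#' @param features feature table (see [metagene_profile()]).
#' @param genes gene models.
#' @param flank 5'-window half-width in bp (default 250).
#' @param groups grouping per gene (e.g. chromosome class); a single value
#'   is recycled.
#' @param normalize_to optional group name whose ratio scales the others
#'   (e.g. `"X"`).
#' @return data frame with columns `group`, `body_density`,
#'   `five_prime_density`, `ratio` (and `ratio_normalized` when requested).
#' @export
body_to_tss_ratio <- function(features, genes, flank = 250L, groups = "all",
                              normalize_to = NULL) {
  groups <- rep_len(as.character(groups), nrow(genes))
  if (any(genes$end - genes$start <= flank + 1)) {
    stop("all genes must be longer than flank + 1")
  }
  mid <- feature_midpoints(features)
  chroms <- feature_chroms(features)
  g_tss <- tss(genes); g_tts <- tts(genes)
  out <- lapply(unique(groups), function(gr) {
    body_hits <- 0; body_w <- 0; five_hits <- 0; five_w <- 0
    for (gi in which(groups == gr)) {
      sel <- chroms == genes$chrom[gi]
      m <- mid[sel]
      dirn <- if (genes$strand[gi] == "+") 1 else -1
      rel <- (m - g_tss[gi]) * dirn        # signed distance from TSS
      gene_len <- genes$end[gi] - genes$start[gi]
      body_hits <- body_hits + sum(rel > flank & rel <= gene_len - 1)
      body_w <- body_w + (gene_len - 1 - flank)
      five_hits <- five_hits + sum(rel >= -flank & rel <= flank)
      five_w <- five_w + 2 * flank
    }
    data.frame(group = gr, body_density = body_hits / body_w,
               five_prime_density = five_hits / five_w,
               ratio = if (five_hits == 0) NA_real_ else
                 (body_hits / body_w) / (five_hits / five_w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(normalize_to)) {
    ref <- out$ratio[out$group == normalize_to]
    if (length(ref) != 1L) stop("no group named '", normalize_to, "'")
    out$ratio_normalized <- out$ratio / ref
  }
  out
}

#' Coverage enrichment over loci
#'
#' Per locus, `((chip + pseudocount) / chip library size) /
#' ((input + pseudocount) / input library size)`, where a track's library
#' size is its total mass (sum of value times interval width) and a locus
#' count is the mass overlapping it.
#'
#' @param chip,input coverage tracks (bedGraph data frames, see
#'   [read_bedgraph()]).
#' @param loci an [intervals()] data frame.
#' @param pseudocount added to both counts (default 1), keeping loci with
#'   zero input finite.
#' @return numeric vector of enrichments, one per locus.
#' @export
locus_enrichment <- function(chip, input, loci, pseudocount = 1) {
  chip_lib <- track_mass(chip)
  input_lib <- track_mass(input)
  if (chip_lib <= 0 || input_lib <= 0) stop("coverage track with no mass")
  cc <- locus_counts(chip, loci)
  ic <- locus_counts(input, loci)
  ((cc + pseudocount) / chip_lib) / ((ic + pseudocount) / input_lib)
}

#' @noRd
track_mass <- function(track) sum(track$value * (track$end - track$start))

#' @noRd
locus_counts <- function(track, loci) {
  out <- numeric(nrow(loci))
  for (cn in unique(loci$chrom)) {
    t_sel <- track$chrom == cn
    ts <- track$start[t_sel]; te <- track$end[t_sel]; tv <- track$value[t_sel]
    for (i in which(loci$chrom == cn)) {
      ov <- pmin(te, loci$end[i]) - pmax(ts, loci$start[i])
      pos <- ov > 0
      out[i] <- sum(tv[pos] * ov[pos])
    }
  }
  out
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with the p-value from the asymptotic
#' Kolmogorov distribution evaluated at
#' `(sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D`, `ne = n m / (n + m)` -- the
#' standard effective-n correction, which keeps the test calibrated at
#' moderate sample sizes where the uncorrected asymptotic distribution is
#' noticeably conservative. For small samples (`min(n, m) <= 25`, no ties)
#' the exact p-value is used instead.
#'
#' @param a,b numeric samples, both non-empty.
#' @return list with `D` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (length(unique(c(a, b))) == 1L) return(list(D = 0, p_value = 1))
  n <- length(a); m <- length(b)
  if (min(n, m) <= 25L && !anyDuplicated(c(a, b))) {
    kt <- stats::ks.test(a, b, exact = TRUE)
    return(list(D = unname(kt$statistic),
                p_value = min(max(kt$p.value, 0), 1)))
  }
  D <- unname(suppressWarnings(stats::ks.test(a, b,
                                              exact = FALSE)$statistic))
  ne <- n * m / (n + m)
  t <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  list(D = D, p_value = kolmogorov_sf(t))
}

# survival function of the Kolmogorov distribution
#' @noRd
kolmogorov_sf <- function(t) {
  if (t < 0.05) return(1)
  i <- 1:101
  min(1, max(0, 2 * sum((-1)^(i - 1) * exp(-2 * i^2 * t^2))))
}
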