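# Seeded synthetic-data generators. Every generator is a pure function of
# (config, seed): a single root seed fans out to per-generator child seeds
# via a documented string hash (child_seed), so partial regeneration is
# stable, and each generator returns the planted ground truth alongside its
# output.

#' @noRd
sample_bases <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                  collapse = "")

#' Generate a genome with planted repeat runs and CES
#'
#' Builds chromosomes of uniform random background and plants exact numbers
#' of maximal tandem-repeat runs. The background is sanitised so that it
#' contains no chance run of 2 or more units of any planted unit (or its
#' reverse complement) outside the planted positions, and plantings are
#' spaced so they stay maximal -- [find_repeat_runs()] therefore recovers
#' the planted runs exactly. Only unit counts k >= 2 can be planted (single
#' units are background-dominated by construction). When a chromosome
#' config carries CES, extra runs are concentrated inside the CES windows.
#'
#' Each chromosome config is a list with `name`, `class` (`X`, `autosome`,
#' `other`), optional `arm`, `length` (bp), optional `runs` -- a list of
#' `list(unit =, k =, count =)` plantings -- and optional `ces` --
#' `list(count =, width =, runs = list(...))` with runs planted inside each
#' CES window.
#'
#' @param config list of chromosome configs (see details).
#' @param seed integer root seed.
#' @return list with `genome` (a [genome()]), `ces` ([intervals()], may be
#'   empty) and `truth` (planted run table, CES, config, seed).
#' @export
generate_genome <- function(config, seed) {
  set.seed(child_seed(seed, "genome"))
  seqs <- character(0)
  cls <- character(0)
  arm <- character(0)
  ces_all <- list()
  planted_all <- list()
  for (cc in config) {
    stopifnot(!is.null(cc$name), !is.null(cc$length))
    len <- cc$length
    runs <- cc$runs
    if (is.null(runs)) runs <- list()
    # CES windows and their extra runs
    ces_iv <- NULL
    ces_runs <- list()
    if (!is.null(cc$ces) && cc$ces$count > 0L) {
      w <- cc$ces$width
      starts <- sort(sample.int(len - w, cc$ces$count))
      # keep windows disjoint by nudging collisions apart
      for (i in seq_along(starts)[-1]) {
        if (starts[i] < starts[i - 1] + w) starts[i] <- starts[i - 1] + w
      }
      if (max(starts) + w > len) stop("cannot place disjoint CES windows")
      ces_iv <- intervals(cc$name, starts, starts + w,
                          name = sprintf("%s_CES_%d", cc$name,
                                         seq_along(starts)))
      if (!is.null(cc$ces$runs)) {
        for (r in cc$ces$runs) {
          ces_runs[[length(ces_runs) + 1L]] <-
            list(unit = r$unit, k = r$k, count = r$count * cc$ces$count,
                 windows = ces_iv)
        }
      }
    }
    spec_runs <- c(lapply(runs, function(r) c(r, list(windows = NULL))),
                   ces_runs)
    planted_bp <- sum(vapply(spec_runs, function(r)
      nchar(r$unit) * r$k * r$count, numeric(1)))
    if (planted_bp >= len / 2) {
      stop("infeasible density on ", cc$name, ": planted bases ", planted_bp,
           " exceed half the chromosome length")
    }
    bad_k <- vapply(spec_runs, function(r) r$k < 2L, logical(1))
    if (any(bad_k)) stop("planted runs must have k >= 2")
    built <- build_chromosome(len, spec_runs)
    seqs[cc$name] <- built$seq
    cls[cc$name] <- if (is.null(cc$class)) "other" else cc$class
    arm[cc$name] <- if (is.null(cc$arm)) NA_character_ else cc$arm
    if (nrow(built$planted)) {
      built$planted$chrom <- cc$name
      planted_all[[length(planted_all) + 1L]] <- built$planted
    }
    if (!is.null(ces_iv)) ces_all[[length(ces_all) + 1L]] <- ces_iv
  }
  g <- genome(seqs, class_labels = cls, arm_labels = arm)
  ces <- if (length(ces_all)) do.call(rbind, ces_all) else empty_intervals()
  class(ces) <- c("intervals", "data.frame")
  planted <- if (length(planted_all)) {
    do.call(rbind, planted_all)[, c("chrom", "start", "end", "unit", "k")]
  } else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               unit = character(0), k = integer(0))
  }
  list(genome = g, ces = ces,
       truth = list(seed = seed, config = config, planted_runs = planted,
                    ces = ces))
}

# one chromosome: background + planted runs + cleanup so planted runs are
# the only >= 2-unit runs of any planted unit (or its reverse complement)
#' @noRd
build_chromosome <- function(len, spec_runs) {
  s <- strsplit(sample_bases(len), "")[[1]]
  planted <- data.frame(start = integer(0), end = integer(0),
                        unit = character(0), k = integer(0))
  occupied <- matrix(numeric(0), ncol = 2)   # planted intervals + margins
  for (r in spec_runs) {
    u <- toupper(r$unit)
    span <- nchar(u) * r$k
    placed <- 0L
    tries <- 0L
    while (placed < r$count) {
      tries <- tries + 1L
      if (tries > r$count * 200L) {
        stop("could not place ", r$count, " runs of (", u, ")", r$k,
             "; placed ", placed)
      }
      p0 <- if (is.null(r$windows)) {
        sample.int(len - span - 4L, 1L) + 2L      # 0-based start, margin 2
      } else {
        wi <- sample.int(nrow(r$windows), 1L)
        lo <- r$windows$start[wi] + 2L
        hi <- r$windows$end[wi] - span - 2L
        if (hi <= lo) next
        sample(lo:hi, 1L)
      }
      # keep a >= 4 bp gap to every other planting so runs stay maximal
      if (nrow(occupied) &&
          any(p0 - 4 < occupied[, 2] & p0 + span + 4 > occupied[, 1])) next
      s[(p0 + 1):(p0 + span)] <- strsplit(strrep(u, r$k), "")[[1]]
      occupied <- rbind(occupied, c(p0, p0 + span))
      planted <- rbind(planted,
                       data.frame(start = p0, end = p0 + span, unit = u,
                                  k = r$k))
      placed <- placed + 1L
    }
  }
  seq <- paste(s, collapse = "")
  units <- unique(toupper(vapply(spec_runs, `[[`, character(1), "unit")))
  if (length(units)) {
    seq <- scrub_unplanted_runs(seq, units, planted)
  }
  list(seq = seq, planted = planted)
}

# mutate background bases until the only >= 2-unit runs of the given units
# are exactly the planted intervals
#' @noRd
scrub_unplanted_runs <- function(seq, units, planted) {
  s <- strsplit(seq, "")[[1]]
  inside_plant <- logical(length(s))
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      inside_plant[(planted$start[i] + 1):planted$end[i]] <- TRUE
    }
  }
  key <- paste(planted$start, planted$end)   # plantings are disjoint
  for (pass in 1:60) {
    dirty <- FALSE
    cur <- paste(s, collapse = "")
    for (u in units) {
      runs <- find_repeat_runs(cur, u, min_units = 2L,
                               strand_collapsed = TRUE)
      for (i in seq_len(nrow(runs))) {
        if (paste(runs$start[i], runs$end[i]) %in% key) next
        # mutate a base of this run that lies outside all plantings
        pos <- (runs$start[i] + 1):runs$end[i]
        pos <- pos[!inside_plant[pos]]
        if (!length(pos)) next   # fully inside a planting: leave alone
        p <- pos[sample.int(length(pos), 1L)]
        s[p] <- sample(setdiff(.BASES, s[p]), 1L)
        dirty <- TRUE
      }
      if (dirty) break
    }
    if (!dirty) return(paste(s, collapse = ""))
  }
  stop("could not sanitise background repeat runs")
}

#' Generate a gcPBM-style probe set with known ground truth
#'
#' Two probe populations share an 8-bp core motif. Bound probes carry the
#' consensus flanks (`flank5`, 4 nt, and `flank3`, 3 nt) around the core;
#' unbound probes carry random flanks, rejected whenever they would
#' reproduce both consensus flanks at once. Two "decoy" unbound probes --
#' one matching a bound probe everywhere except the outermost 5' flank
#' base, one except the outermost 3' flank base -- pin the zero-overlap
#' region of [flank_separation_scan()] to windows covering both full
#' flanks, so the minimal window is exactly `(nchar(flank5), nchar(flank3))`
#' by construction. Each probe's variable region is 36 nt, embedded in a
#' 60-nt probe with a fixed 24-nt primer; intensities are
#' `base + effect * min(n_units, plateau) + noise` per replicate, where
#' `n_units` is the probe's maximal GA-run length. When `repeat_units` is
#' given, bound probes instead carry planted GA runs of those lengths
#' (sampled uniformly), which makes the median-intensity vs repeat-length
#' relationship of the generator directly recoverable.
#'
#' @param n_bound,n_unbound probe counts.
#' @param core 8-nt core consensus (default `"GAGAGAGA"`).
#' @param flank5 4-nt 5' consensus flank; `flank3` 3-nt 3' flank.
#' @param repeat_units optional integer vector of GA-run unit counts to
#'   sample for bound probes (e.g. `2:13`); `NULL` keeps the core design.
#' @param base_bound,base_unbound intensity baselines (fluorescence units).
#' @param effect intensity gain per repeat unit up to the plateau.
#' @param plateau unit count where the intensity gain saturates
#'   (default 10).
#' @param noise_sd per-replicate Gaussian noise sd.
#' @param replicates replicate measurements per probe (default 8).
#' @param seed integer root seed.
#' @return list with `probes` (a `probe_table` data frame) and `truth`
#'   (per-probe `bound`, `n_units`, `decoy` flags plus the config).
#' @export
generate_probe_set <- function(n_bound = 200L, n_unbound = 200L,
                               core = "GAGAGAGA", flank5 = "TGCG",
                               flank3 = "CTT", repeat_units = NULL,
                               base_bound = 7000, base_unbound = 3000,
                               effect = 400, plateau = 10L, noise_sd = 300,
                               replicates = 8L, seed = 1L) {
  set.seed(child_seed(seed, "probes"))
  core <- toupper(core); flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  stopifnot(nchar(core) == 8L, nchar(flank5) == 4L, nchar(flank3) == 3L)
  if (effect < 0) stop("effect must be >= 0")
  primer <- "GTCTGTGTTCCGTTGTCCGTGCTG"          # fixed 24-nt primer
  mk_variable <- function(flank5_i = NULL, flank3_i = NULL) {
    # 10 outer + 4 flank + 8 core + 3 flank + 11 outer = 36 nt; flanks are
    # redrawn per attempt when not fixed, because a flank that recreates a
    # shifted copy of the core (e.g. a 5' flank ending in "GA" next to a
    # GA-repeat core) can never yield a unique core match
    for (try in 1:2000) {
      f5 <- if (is.null(flank5_i)) sample_bases(4L) else flank5_i
      f3 <- if (is.null(flank3_i)) sample_bases(3L) else flank3_i
      if (is.null(flank5_i) && f5 == flank5 && f3 == flank3) next
      v <- paste0(sample_bases(10L), f5, core, f3, sample_bases(11L))
      if (single_core_at(v, core, 14L)) return(v)
    }
    stop("could not draw a probe context with a unique core match; ",
         "the flanks recreate the core")
  }
  bound_seq <- character(n_bound)
  bound_units <- integer(n_bound)
  if (is.null(repeat_units)) {
    for (i in seq_len(n_bound)) {
      bound_seq[i] <- mk_variable(flank5, flank3)
      r <- find_repeat_runs(bound_seq[i], "GA")
      bound_units[i] <- if (nrow(r)) max(r$n_units) else 0L
    }
  } else {
    if (any(repeat_units < 2L) || any(2L * repeat_units > 32L)) {
      stop("repeat_units must lie in [2, 16]")
    }
    bound_units <- sample(rep_len(sort(repeat_units), n_bound))
    for (i in seq_len(n_bound)) {
      bound_seq[i] <- plant_run_in_probe(bound_units[i])
    }
  }
  # unbound: random flanks, never both consensus flanks at once
  unbound_seq <- vapply(seq_len(n_unbound), function(i) mk_variable(),
                        character(1))
  decoy <- logical(n_unbound)
  if (is.null(repeat_units) && n_unbound >= 2L && n_bound >= 2L) {
    # decoy 1: bound probe 1 with the outermost 5' flank base changed
    v <- bound_seq[1]
    substr(v, 11L, 11L) <- sample(setdiff(.BASES, substr(flank5, 1, 1)), 1L)
    unbound_seq[1] <- v; decoy[1] <- TRUE
    # decoy 2: bound probe 2 with the outermost 3' flank base changed
    v <- bound_seq[2]
    substr(v, 25L, 25L) <- sample(setdiff(.BASES, substr(flank3, 3, 3)), 1L)
    unbound_seq[2] <- v; decoy[2] <- TRUE
  }
  n <- n_bound + n_unbound
  varseq <- c(bound_seq, unbound_seq)
  bound <- rep(c(TRUE, FALSE), c(n_bound, n_unbound))
  n_units <- c(bound_units, vapply(unbound_seq, function(v) {
    r <- find_repeat_runs(v, "GA")
    if (nrow(r)) max(r$n_units) else 0L
  }, integer(1), USE.NAMES = FALSE))
  mu <- ifelse(bound, base_bound + effect * pmin(n_units, plateau),
               base_unbound)
  imat <- matrix(pmax(stats::rnorm(n * replicates, rep(mu, replicates),
                                   noise_sd), 50),
                 nrow = n)
  colnames(imat) <- sprintf("intensity_%d", seq_len(replicates))
  probes <- data.frame(
    id = sprintf("probe_%04d", seq_len(n)),
    variable_seq = varseq,
    full_seq = paste0(varseq, primer),
    chip_flag = ifelse(bound, "+", "-"),
    mre_flag = ifelse(bound, "+", "-"),
    median_intensity = apply(imat, 1L, stats::median),
    stringsAsFactors = FALSE)
  probes <- cbind(probes, as.data.frame(imat))
  class(probes) <- c("probe_table", "data.frame")
  truth <- list(seed = seed, core = core, flank5 = flank5, flank3 = flank3,
                bound = bound, n_units = n_units,
                decoy = c(logical(n_bound), decoy),
                base_bound = base_bound, base_unbound = base_unbound,
                effect = effect, plateau = plateau, noise_sd = noise_sd)
  list(probes = probes, truth = truth)
}

# TRUE when `core` occurs exactly once in v (forward, 0-based offset
# `at0`) and its reverse complement not at all
#' @noRd
single_core_at <- function(v, core, at0) {
  hits <- gregexpr(core, v, fixed = TRUE)[[1]]
  if (length(hits) != 1L || hits[1] != at0 + 1L) return(FALSE)
  rc <- revcomp(core)
  rc_hits <- gregexpr(rc, v, fixed = TRUE)[[1]]
  rc_hits[1] == -1L
}

# a 36-nt probe whose maximal GA run is exactly n units, centred
#' @noRd
plant_run_in_probe <- function(n_units) {
  span <- 2L * n_units
  left <- (36L - span) %/% 2L
  for (try in 1:200) {
    v <- paste0(sample_bases(left), strrep("GA", n_units),
                sample_bases(36L - left - span))
    runs <- find_repeat_runs(v, "GA")
    ok <- nrow(runs) > 0 && max(runs$n_units) == n_units &&
      sum(runs$n_units == max(runs$n_units)) == 1L &&
      runs$start[which.max(runs$n_units)] == left
    if (ok) return(v)
  }
  stop("could not plant a clean (GA)", n_units, " run in a probe")
}

#' Generate peak sets, uniform or clustered at CES
#'
#' Uniform mode places peak midpoints uniformly per chromosome. Clustered
#' mode additionally draws a fraction of the X-chromosome peaks from
#' Gaussians centered on CES midpoints (sd `cluster_sd`), emulating binding
#' sites concentrated at chromatin entry sites.
#'
#' @param g a [genome()].
#' @param n_per_chrom named vector (or single number) of peak counts per
#'   chromosome.
#' @param mode `"uniform"` or `"clustered_at_CES"`.
#' @param ces CES intervals (required in clustered mode).
#' @param frac_clustered fraction of X peaks drawn around CES (default
#'   0.7).
#' @param cluster_sd Gaussian sd around CES midpoints in bp (default 200).
#' @param width peak width in bp (default 200).
#' @param seed integer root seed.
#' @return list with `peaks` ([intervals()]) and `truth`.
#' @export
generate_peaks <- function(g, n_per_chrom, mode = c("uniform",
                                                    "clustered_at_CES"),
                           ces = NULL, frac_clustered = 0.7,
                           cluster_sd = 200, width = 200L, seed = 1L) {
  stopifnot(inherits(g, "Genome"))
  mode <- match.arg(mode)
  set.seed(child_seed(seed, "peaks"))
  lens <- chrom_lengths(g)
  if (is.null(names(n_per_chrom))) {
    n_per_chrom <- stats::setNames(rep_len(n_per_chrom, length(lens)),
                                   names(lens))
  }
  if (any(n_per_chrom > lens[names(n_per_chrom)] / (width + 1))) {
    stop("peak count exceeds chromosome capacity")
  }
  if (mode == "clustered_at_CES" &&
      (is.null(ces) || nrow(ces) == 0L)) {
    stop("clustered mode requires CES intervals")
  }
  half <- width %/% 2L
  out <- list()
  clustered_flag <- list()
  for (nm in names(n_per_chrom)) {
    n <- n_per_chrom[[nm]]
    if (n == 0L) next
    is_x <- g$class_label[[nm]] == "X"
    ces_here <- if (!is.null(ces)) ces[ces$chrom == nm, , drop = FALSE]
    n_clu <- if (mode == "clustered_at_CES" && is_x &&
                 !is.null(ces_here) && nrow(ces_here)) {
      round(frac_clustered * n)
    } else 0L
    mid <- numeric(0)
    if (n_clu > 0L) {
      centers <- midpoints(ces_here)[sample.int(nrow(ces_here), n_clu,
                                                replace = TRUE)]
      mid <- round(stats::rnorm(n_clu, centers, cluster_sd))
    }
    mid <- c(mid, floor(stats::runif(n - n_clu, 0, lens[[nm]])))
    mid <- pmin(pmax(mid, half), lens[[nm]] - half - 1L)
    out[[nm]] <- intervals(nm, mid - half, mid + half,
                           name = sprintf("%s_peak_%d", nm, seq_len(n)))
    clustered_flag[[nm]] <- rep(c(TRUE, FALSE), c(n_clu, n - n_clu))
  }
  peaks <- do.call(rbind, out)
  class(peaks) <- c("intervals", "data.frame")
  rownames(peaks) <- NULL
  list(peaks = peaks,
       truth = list(seed = seed, mode = mode,
                    clustered = unlist(clustered_flag, use.names = FALSE),
                    frac_clustered = frac_clustered, cluster_sd = cluster_sd))
}

#' Generate non-overlapping gene models
#'
#' Gene lengths are log-normal; placements are rejection-sampled to be
#' non-overlapping; strands are drawn 50/50.
#'
#' @param g a [genome()].
#' @param n total gene count (allocated to chromosomes by length).
#' @param meanlog,sdlog log-normal length parameters (defaults give a
#'   median length of about 2 kb).
#' @param seed integer root seed.
#' @return gene-model data frame (`chrom`, `start`, `end`, `strand`, `id`).
#' @export
generate_genes <- function(g, n, meanlog = log(2000), sdlog = 0.5,
                           seed = 1L) {
  stopifnot(inherits(g, "Genome"), n >= 1L)
  set.seed(child_seed(seed, "genes"))
  lens <- chrom_lengths(g)
  alloc <- round(n * lens / sum(lens))
  alloc[1] <- alloc[1] + (n - sum(alloc))
  out <- list()
  for (nm in names(lens)) {
    placed <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(placed) < alloc[[nm]]) {
      tries <- tries + 1L
      if (tries > alloc[[nm]] * 200L) {
        stop("could not place ", alloc[[nm]], " non-overlapping genes on ",
             nm, "; placed ", nrow(placed))
      }
      len <- max(200, round(stats::rlnorm(1, meanlog, sdlog)))
      if (len >= lens[[nm]]) next
      s0 <- sample.int(lens[[nm]] - len, 1L)
      if (nrow(placed) &&
          any(s0 < placed[, 2] & s0 + len > placed[, 1])) next
      placed <- rbind(placed, c(s0, s0 + len))
    }
    placed <- placed[order(placed[, 1]), , drop = FALSE]
    if (nrow(placed)) {
      out[[nm]] <- data.frame(
        chrom = nm, start = placed[, 1], end = placed[, 2],
        strand = sample(c("+", "-"), nrow(placed), replace = TRUE),
        id = sprintf("%s_gene_%d", nm, seq_len(nrow(placed))),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, out)
  rownames(genes) <- NULL
  genes
}

#' Generate ChIP and input coverage tracks with planted enrichment
#'
#' Coverage is a binned step function; each bin's value is Poisson with
#' mean `depth` for the input track and `depth * multiplier` for the ChIP
#' track over bins overlapping a locus (multiplier 1 elsewhere). This
#' emulates tag-count tracks downstream of alignment, which is all the
#' enrichment analyses consume.
#'
#' @param g a [genome()].
#' @param loci [intervals()] over which enrichment is planted.
#' @param multiplier single value or one per locus.
#' @param depth expected tag count per bin (default 20).
#' @param bin bin width in bp (default 50).
#' @param seed integer root seed.
#' @return list with `chip`, `input` (bedGraph data frames) and `truth`.
#' @export
generate_coverage <- function(g, loci, multiplier = 2, depth = 20,
                              bin = 50L, seed = 1L) {
  stopifnot(inherits(g, "Genome"), depth > 0, bin >= 1L)
  set.seed(child_seed(seed, "coverage"))
  multiplier <- rep_len(multiplier, nrow(loci))
  lens <- chrom_lengths(g)
  chip <- list(); input <- list()
  for (nm in names(lens)) {
    starts <- seq(0L, lens[[nm]] - 1L, by = bin)
    ends <- pmin(starts + bin, lens[[nm]])
    mult <- rep(1, length(starts))
    li <- which(loci$chrom == nm)
    for (i in li) {
      hit <- starts < loci$end[i] & ends > loci$start[i]
      mult[hit] <- pmax(mult[hit], multiplier[i])
    }
    chip[[nm]] <- data.frame(chrom = nm, start = starts, end = ends,
                             value = stats::rpois(length(starts),
                                                  depth * mult))
    input[[nm]] <- data.frame(chrom = nm, start = starts, end = ends,
                              value = stats::rpois(length(starts), depth))
  }
  chip <- do.call(rbind, chip); rownames(chip) <- NULL
  input <- do.call(rbind, input); rownames(input) <- NULL
  list(chip = chip, input = input,
       truth = list(seed = seed, multiplier = multiplier, depth = depth,
                    bin = bin))
}

#' Generate a complete synthetic pentamer shape table
#'
#' Values are drawn uniformly within documented plausible ranges (minor
#' groove width 2.8-6.2 Angstrom, propeller twist -17-0 degrees, roll -8-8
#' degrees, helix twist 30-40 degrees). The table is synthetic: it has the
#' right structure and scale for testing shape-feature plumbing, but no
#' relationship to real DNA structure.
#'
#' @param seed integer root seed.
#' @return a `shape_table` matrix (1024 x 4).
#' @export
generate_shape_table <- function(seed = 1L) {
  set.seed(child_seed(seed, "shape_table"))
  pent <- all_pentamers()
  m <- cbind(MGW = stats::runif(1024, 2.8, 6.2),
             ProT = stats::runif(1024, -17, 0),
             Roll = stats::runif(1024, -8, 8),
             HelT = stats::runif(1024, 30, 40))
  rownames(m) <- pent
  class(m) <- c("shape_table", class(m))
  m
}

#' Write a synthetic shape table to TSV
#'
#' @param table a `shape_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_shape_table <- function(table, path) {
  df <- data.frame(pentamer = rownames(table), as.data.frame(unclass(table)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
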