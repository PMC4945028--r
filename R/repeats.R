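# Detection of maximal tandem dinucleotide (and general short-unit) repeat
# runs, per-megabase densities by chromosome class, and X:A ratios.

#' Find maximal tandem repeat runs of a short unit
#'
#' Finds every maximal run of tandem copies of `unit` (unit lengths 1-6
#' supported; the headline analyses use dinucleotides). Runs are maximal in
#' unit phase: `"AGAGAG"` contains a (GA)2 maximal run plus flanking single
#' letters, and scanning every phase guarantees the longest in-phase run is
#' reported. N bases never match, so runs stop at assembly gaps. When
#' `strand_collapsed` (the default), runs of the reverse-complement unit
#' (TC for GA) are detected on the forward sequence and pooled into the
#' same accounting -- a repeat tract is a strand-symmetric genomic feature;
#' palindromic units (AT, TA, GC, CG) are scanned once to avoid double
#' counting.
#'
#' @param target a [genome()] or a single character sequence.
#' @param unit repeat unit, e.g. `"GA"`.
#' @param min_units report runs of at least this many tandem copies
#'   (default 1).
#' @param strand_collapsed pool runs of `unit` and of its reverse
#'   complement (default `TRUE`).
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open; `end - start == unit length * n_units`), `unit` (the unit
#'   as matched on the forward strand), `n_units`, `strand` (`"+"` for the
#'   given unit, `"-"` for its reverse complement).
#' @export
find_repeat_runs <- function(target, unit, min_units = 1L,
                             strand_collapsed = TRUE) {
  unit <- toupper(unit)
  if (nchar(unit) < 1L || nchar(unit) > 6L) {
    stop("unit length must be between 1 and 6")
  }
  validate_dna(unit, allow_n = FALSE, what = "repeat unit")
  if (nchar(unit) == 2L && substr(unit, 1, 1) == substr(unit, 2, 2)) {
    warning("unit '", unit, "' is a homopolymer dinucleotide; runs will be ",
            "reported in 2-base units")
  }
  seqs <- if (inherits(target, "Genome")) target$seq else {
    stopifnot(is.character(target), length(target) == 1L)
    stats::setNames(toupper(target), "seq")
  }
  units <- c(`+` = unit)
  rcu <- revcomp(unit)
  if (strand_collapsed && rcu != unit) units <- c(units, `-` = rcu)
  res <- list()
  for (nm in names(seqs)) {
    for (st in names(units)) {
      runs <- runs_one(seqs[[nm]], units[[st]])
      if (is.null(runs)) next
      runs$chrom <- nm
      runs$unit <- units[[st]]
      runs$strand <- st
      res[[length(res) + 1L]] <- runs
    }
  }
  if (!length(res)) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      n_units = integer(0), strand = character(0))
    return(out)
  }
  out <- do.call(rbind, res)
  out <- out[out$n_units >= min_units, , drop = FALSE]
  out <- out[order(out$chrom, out$start), c("chrom", "start", "end", "unit",
                                            "n_units", "strand")]
  rownames(out) <- NULL
  out
}

# maximal runs of one unit on one forward sequence; no regular expressions,
# so the regex oracle in the tests stays independent
#' @noRd
runs_one <- function(s, unit) {
  u <- nchar(unit)
  L <- nchar(s)
  if (L < u) return(NULL)
  codes <- encode_seq(s)
  ucode <- encode_seq(unit)
  # match[i] TRUE when a unit copy starts at (1-based) position i
  n_start <- L - u + 1L
  m <- !logical(n_start)
  for (j in seq_len(u)) {
    cj <- codes[j:(j + n_start - 1L)]
    m <- m & !is.na(cj) & cj == ucode[j]
  }
  starts <- which(m)
  if (!length(starts)) return(NULL)
  # chain copies that tile in phase (p, p+u, p+2u, ...); phases are chained
  # separately so self-overlapping units (homopolymers) still yield the
  # longest in-phase run
  res <- lapply(split(starts, (starts - 1L) %% u), function(ph) {
    brk <- c(TRUE, diff(ph) != u)
    first <- ph[brk]
    n_units <- as.integer(tabulate(cumsum(brk)))
    data.frame(start = first - 1L, end = first - 1L + u * n_units,
               n_units = n_units)
  })
  do.call(rbind, res)
}

#' Count repeat runs per length
#'
#' `maximal` mode assigns each run only to its own unit count (a run of 4
#' units increments only `count(4)`); `cumulative` mode lets longer runs
#' contribute to every shorter length (a run of 4 units increments
#' `count(k)` for every `k <= 4`), matching the two published accounting
#' conventions.
#'
#' @param runs data frame from [find_repeat_runs()].
#' @param mode `"maximal"` or `"cumulative"`.
#' @param k_max largest length to tabulate (default: longest observed run).
#' @return data frame with columns `length_k` and `count`.
#' @export
count_by_length <- function(runs, mode = c("maximal", "cumulative"),
                            k_max = NULL) {
  mode <- match.arg(mode)
  if (is.null(k_max)) k_max <- if (nrow(runs)) max(runs$n_units) else 1L
  counts <- integer(k_max)
  if (nrow(runs)) {
    tab <- tabulate(pmin(runs$n_units, k_max), nbins = k_max)
    # runs longer than k_max fold into the top bin in maximal mode
    if (mode == "maximal") {
      counts <- tab
    } else {
      counts <- rev(cumsum(rev(tab)))
    }
  }
  data.frame(length_k = seq_len(k_max), count = counts)
}

#' Per-megabase density table
#'
#' Densities are `count / (length in Mb)` with Mb = 1e6 bases; N bases stay
#' in the denominator.
#'
#' @param counts data frame with at least columns `chrom` and `count`
#'   (extra grouping columns such as `length_k` or `unit` are carried
#'   through).
#' @param lengths named numeric vector of target lengths in bp (e.g.
#'   [chrom_lengths()]).
#' @return the input with a `density_per_mb` column appended.
#' @export
density_per_mb <- function(counts, lengths) {
  if (nrow(counts) == 0L) {
    counts$density_per_mb <- numeric(0)
    return(counts)
  }
  if (any(lengths <= 0)) stop("zero-length target")
  unknown <- setdiff(unique(counts$chrom), names(lengths))
  if (length(unknown)) stop("no length for: ", paste(unknown, collapse = ", "))
  counts$density_per_mb <- counts$count / (lengths[counts$chrom] / 1e6)
  counts
}

#' Tabulate repeat runs per chromosome and length
#'
#' Convenience: [find_repeat_runs()] then [count_by_length()] per
#' chromosome, with densities.
#'
#' @inheritParams find_repeat_runs
#' @param g a [genome()].
#' @param mode counting convention, see [count_by_length()].
#' @param k_max largest run length tabulated (runs beyond it fold into the
#'   top bin); default 25.
#' @return data frame with columns `chrom`, `class_label`, `unit`,
#'   `length_k`, `count`, `density_per_mb`.
#' @export
repeat_density_table <- function(g, unit = "GA", mode = "maximal",
                                 min_units = 1L, strand_collapsed = TRUE,
                                 k_max = 25L) {
  stopifnot(inherits(g, "Genome"))
  runs <- find_repeat_runs(g, unit, min_units = min_units,
                           strand_collapsed = strand_collapsed)
  out <- lapply(names(g$seq), function(nm) {
    cc <- count_by_length(runs[runs$chrom == nm, , drop = FALSE], mode,
                          k_max = k_max)
    data.frame(chrom = nm, class_label = unname(g$class_label[nm]),
               unit = toupper(unit), length_k = cc$length_k,
               count = cc$count, stringsAsFactors = FALSE)
  })
  density_per_mb(do.call(rbind, out), chrom_lengths(g))
}

#' X:A density ratio per repeat length
#'
#' Pooled mode: `(sum of X counts / sum of X lengths) / (sum of autosome
#' counts / sum of autosome lengths)`, per repeat length. Any value above 1
#' indicates a higher density on the X chromosome. Per-arm mode reports one
#' ratio per autosomal chromosome. Ratios with a zero autosomal count are
#' reported as `NA` (absent), never as infinity.
#'
#' @param table output of [repeat_density_table()] (or any table with
#'   `chrom`, `class_label`, `length_k`, `count`).
#' @param lengths named chromosome lengths in bp.
#' @param per_arm compare X against each autosomal arm separately.
#' @return data frame with columns `length_k`, (`arm`,) `ratio`.
#' @export
xa_ratio <- function(table, lengths, per_arm = FALSE) {
  xs <- table$class_label == "X"
  as_ <- table$class_label == "autosome"
  if (!any(xs)) stop("no X-labelled chromosome in the table")
  if (!any(as_)) stop("no autosome-labelled chromosome in the table")
  x_len <- sum(lengths[unique(table$chrom[xs])])
  x_cnt <- tapply(table$count[xs], table$length_k[xs], sum)
  ks <- sort(unique(table$length_k))
  x_density <- as.numeric(x_cnt[as.character(ks)]) / (x_len / 1e6)
  if (!per_arm) {
    a_len <- sum(lengths[unique(table$chrom[as_])])
    a_cnt <- tapply(table$count[as_], table$length_k[as_], sum)
    a_density <- as.numeric(a_cnt[as.character(ks)]) / (a_len / 1e6)
    ratio <- ifelse(is.na(a_density) | a_density == 0, NA_real_,
                    x_density / a_density)
    return(data.frame(length_k = ks, ratio = ratio))
  }
  arms <- unique(table$chrom[as_])
  do.call(rbind, lapply(arms, function(arm) {
    sel <- table$chrom == arm
    a_cnt <- tapply(table$count[sel], table$length_k[sel], sum)
    a_density <- as.numeric(a_cnt[as.character(ks)]) / (lengths[arm] / 1e6)
    data.frame(length_k = ks, arm = arm,
               ratio = ifelse(is.na(a_density) | a_density == 0, NA_real_,
                              x_density / a_density))
  }))
}

#' Motif-hit density per chromosome and its X:A ratio
#'
#' `exact_consensus` mode counts non-overlapping occurrences of the
#' consensus string greedily left-to-right, on both strands (the reverse
#' complement is matched on the forward sequence; a palindromic consensus
#' is counted once). `pwm_pvalue` mode counts [scan_pwm()] hits at
#' `p <= p_threshold`.
#'
#' @param g a [genome()].
#' @param motif a `pwm` or, in `exact_consensus` mode, a consensus string.
#' @param mode `"exact_consensus"` or `"pwm_pvalue"`.
#' @param p_threshold scan threshold for `pwm_pvalue` mode.
#' @return list with `table` (per-chromosome counts and densities) and
#'   `ratio` (pooled X:A density ratio, `NA` when undefined).
#' @export
motif_hit_density <- function(g, motif, mode = c("exact_consensus",
                                                 "pwm_pvalue"),
                              p_threshold = 1e-4) {
  stopifnot(inherits(g, "Genome"))
  mode <- match.arg(mode)
  if (mode == "exact_consensus") {
    cons <- if (inherits(motif, "pwm")) consensus(motif) else toupper(motif)
    validate_dna(cons, allow_n = FALSE, what = "consensus")
    rc <- revcomp(cons)
    counts <- vapply(g$seq, function(s) {
      n <- count_greedy(s, cons)
      if (rc != cons) n <- n + count_greedy(s, rc)
      n
    }, numeric(1))
  } else {
    if (!inherits(motif, "pwm")) stop("pwm_pvalue mode requires a pwm")
    hits <- scan_pwm(motif, g, p_threshold = p_threshold)
    counts <- vapply(names(g$seq),
                     function(nm) sum(hits$seqname == nm), numeric(1))
  }
  tab <- density_per_mb(
    data.frame(chrom = names(g$seq),
               class_label = unname(g$class_label[names(g$seq)]),
               length_k = 1L, count = as.numeric(counts),
               stringsAsFactors = FALSE),
    chrom_lengths(g))
  ratio <- tryCatch(xa_ratio(tab, chrom_lengths(g))$ratio[1],
                    error = function(e) NA_real_)
  list(table = tab[, c("chrom", "class_label", "count", "density_per_mb")],
       ratio = ratio)
}

# greedy non-overlapping left-to-right exact count
#' @noRd
count_greedy <- function(s, pattern) {
  n <- 0L
  from <- 1L
  k <- nchar(pattern)
  repeat {
    i <- regexpr(pattern, substr(s, from, nchar(s)), fixed = TRUE)
    if (i < 0) break
    n <- n + 1L
    from <- from + i - 1L + k
  }
  as.numeric(n)
}

#' Write repeat runs as BED6
#'
#' Name column carries the unit, score the unit count.
#'
#' @param runs data frame from [find_repeat_runs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_runs_bed <- function(runs, path) {
  iv <- intervals(runs$chrom, runs$start, runs$end, name = runs$unit,
                  score = runs$n_units, strand = runs$strand)
  write_bed(iv, path)
}
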