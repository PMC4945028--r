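# Position weight matrices: construction, information content, distances,
# and sequence scanning with exact p-values from a dynamic program over the
# discretised log-odds score distribution (the usual FIMO-style approach).

#' @noRd
new_pwm <- function(freqs, pseudocount, background = rep(0.25, 4),
                    name = NA_character_) {
  stopifnot(is.matrix(freqs), ncol(freqs) == 4L, nrow(freqs) >= 1L)
  if (any(freqs < 0)) stop("PWM frequencies must be non-negative")
  rs <- rowSums(freqs)
  if (any(abs(rs - 1) > 1e-6)) stop("PWM rows must sum to 1 (tolerance 1e-6)")
  if (abs(sum(background) - 1) > 1e-6 || any(background <= 0)) {
    stop("background must be 4 positive values summing to 1")
  }
  colnames(freqs) <- .BASES
  structure(list(width = nrow(freqs), freqs = freqs,
                 pseudocount = pseudocount, background = background,
                 name = name),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s', width %d, pseudocount %g, consensus %s\n",
              ifelse(is.na(x$name), "?", x$name), x$width, x$pseudocount,
              consensus(x)))
  print(round(x$freqs, 4))
  invisible(x)
}

#' Build a PWM from aligned sequences
#'
#' Per-position base frequencies are
#' `(count + pseudocount) / (n + 4 * pseudocount)`.
#'
#' @param aligned_seqs character vector of equal-length A/C/G/T sequences.
#' @param pseudocount non-negative pseudocount added per base (default 0.5).
#' @param background background base frequencies (A, C, G, T), used later
#'   for scanning; default uniform.
#' @param name optional motif name.
#' @return a `pwm` object: list with `width`, `freqs` (width x 4 matrix,
#'   columns A, C, G, T), `pseudocount`, `background`, `name`.
#' @export
build_pwm <- function(aligned_seqs, pseudocount = 0.5,
                      background = rep(0.25, 4), name = NA_character_) {
  if (length(aligned_seqs) == 0L) stop("no sequences to build a PWM from")
  aligned_seqs <- toupper(aligned_seqs)
  lens <- nchar(aligned_seqs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal lengths")
  validate_dna(aligned_seqs, allow_n = FALSE, what = "aligned sequence")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  w <- lens[1]
  n <- length(aligned_seqs)
  codes <- matrix(unlist(lapply(aligned_seqs, encode_seq)), nrow = n,
                  byrow = TRUE)
  counts <- t(apply(codes, 2L, tabulate, nbins = 4L))
  if (w == 1L) counts <- matrix(counts, nrow = 1L)
  freqs <- (counts + pseudocount) / (n + 4 * pseudocount)
  new_pwm(freqs, pseudocount = pseudocount, background = background,
          name = name)
}

#' Per-position information content in bits
#'
#' `IC_i = log2(4) + sum_b f_ib * log2(f_ib)` with `0 * log2(0) = 0`; a
#' degenerate column scores the maximum of 2 bits, a uniform column 0.
#'
#' @param pwm a `pwm` object.
#' @return numeric vector of length `pwm$width`.
#' @export
information_content <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  f <- pwm$freqs
  term <- ifelse(f > 0, f * log2(f), 0)
  2 + rowSums(term)
}

#' Per-position Euclidean distance between two PWMs
#'
#' The distance at position i is the root-mean-square difference of the
#' nucleotide frequencies,
#' `d_i = sqrt( (1/4) * sum_b (f_a,ib - f_b,ib)^2 )`; the summary is the
#' mean over the requested positions (so core and flank regions can be
#' compared separately).
#'
#' @param pwm_a,pwm_b `pwm` objects; any alignment offset must be applied
#'   by the caller before the call.
#' @param positions optional integer vector of positions to compare
#'   (default: all; both PWMs must cover them).
#' @return list with `per_position` (named by position) and `mean`.
#' @export
motif_distance <- function(pwm_a, pwm_b, positions = NULL) {
  stopifnot(inherits(pwm_a, "pwm"), inherits(pwm_b, "pwm"))
  if (is.null(positions)) {
    if (pwm_a$width != pwm_b$width) {
      stop("PWM widths differ (", pwm_a$width, " vs ", pwm_b$width,
           "); pass explicit positions")
    }
    positions <- seq_len(pwm_a$width)
  }
  if (any(positions < 1L) || any(positions > pwm_a$width) ||
      any(positions > pwm_b$width)) {
    stop("positions outside both PWMs")
  }
  d <- sqrt(rowMeans((pwm_a$freqs[positions, , drop = FALSE] -
                        pwm_b$freqs[positions, , drop = FALSE])^2))
  names(d) <- positions
  list(per_position = d, mean = mean(d))
}

#' Consensus sequence of a PWM
#'
#' Per position, the maximum-frequency base; ties broken in A < C < G < T
#' order.
#'
#' @param pwm a `pwm` object.
#' @return a single character string of length `pwm$width`.
#' @export
consensus <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  paste(.BASES[apply(pwm$freqs, 1L, which.max)], collapse = "")
}

#' Reverse complement a PWM
#' @param pwm a `pwm` object.
#' @return a `pwm` scoring the opposite strand.
#' @export
revcomp_pwm <- function(pwm) {
  stopifnot(inherits(pwm, "pwm"))
  f <- pwm$freqs[rev(seq_len(pwm$width)), rev(seq_len(4L)), drop = FALSE]
  new_pwm(unname(f), pwm$pseudocount, pwm$background, pwm$name)
}

# ---- scoring machinery -----------------------------------------------------

# log-odds score matrix in bits; a small score-time pseudocount keeps
# log-odds finite for zero frequencies
#' @noRd
pwm_score_matrix <- function(pwm, score_pseudo = 0.01) {
  f <- pwm$freqs + score_pseudo
  f <- f / rowSums(f)
  log2(sweep(f, 2L, pwm$background, "/"))
}

# integer (discretised) score matrix and exact p-value table.
# granularity is the score grid step in bits: per-position scores are
# rounded to the grid, so DP tail probabilities are exact for the gridded
# score that the scanner itself computes.
#' @noRd
pwm_pvalue_table <- function(pwm, granularity = 1 / 1000,
                             score_pseudo = 0.01) {
  s <- pwm_score_matrix(pwm, score_pseudo)
  s_int <- matrix(as.integer(round(s / granularity)), nrow = nrow(s))
  lo <- sum(apply(s_int, 1L, min))
  hi <- sum(apply(s_int, 1L, max))
  probs <- 1
  offset <- 0L                     # probs[k] is P(score == offset + k - 1)
  bg <- pwm$background
  for (i in seq_len(nrow(s_int))) {
    row <- s_int[i, ]
    rlo <- min(row)
    new_len <- length(probs) + (max(row) - rlo)
    acc <- numeric(new_len)
    for (b in 1:4) {
      sh <- row[b] - rlo
      idx <- seq_along(probs) + sh
      acc[idx] <- acc[idx] + probs * bg[b]
    }
    probs <- acc
    offset <- offset + rlo
  }
  stopifnot(offset == lo, length(probs) == hi - lo + 1L)
  surv <- rev(cumsum(rev(probs)))   # surv[k] = P(score >= lo + k - 1)
  list(s_int = s_int, granularity = granularity, lo = lo, hi = hi,
       surv = surv)
}

# p-value of integer scores against a pwm_pvalue_table
#' @noRd
pvalue_of_int_score <- function(tab, t) {
  p <- rep(NA_real_, length(t))
  ok <- !is.na(t)
  k <- pmax(pmin(t[ok], tab$hi), tab$lo) - tab$lo + 1L
  p[ok] <- tab$surv[k]
  p[ok & t > tab$hi] <- 0
  p[ok] <- pmin(pmax(p[ok], 0), 1)
  p
}

# integer window scores of one encoded sequence at all offsets (NA where a
# window touches a non-ACGT base)
#' @noRd
window_int_scores <- function(codes, s_int) {
  w <- nrow(s_int)
  L <- length(codes)
  if (L < w) return(integer(0))
  n <- L - w + 1L
  sc <- numeric(n)
  for (i in seq_len(w)) {
    sc <- sc + s_int[i, codes[i:(i + n - 1L)]]
  }
  sc
}

#' Scan sequences with a PWM, with exact p-values
#'
#' Scores every offset (and, by default, both strands) with the PWM's
#' log-odds against its background model. P-values are the exact tail
#' probability of the (discretised) score under the background, computed by
#' dynamic programming over the per-position score distribution; all
#' positions with `p <= p_threshold` are reported, including overlapping
#' hits. Windows containing N never match.
#'
#' @param pwm a `pwm` object.
#' @param targets a [genome()] or a (optionally named) character vector of
#'   sequences.
#' @param p_threshold report hits with p-value at or below this (default
#'   1e-4); must lie in (0, 1].
#' @param strands `"both"` or `"forward"`.
#' @param granularity score grid step in bits for the p-value dynamic
#'   program (default 1/1000 bit; the p-value error this induces is bounded
#'   by the probability mass within `width * granularity / 2` bits of the
#'   threshold score).
#' @param score_pseudo frequency added at scoring time to keep log-odds
#'   finite (default 0.01).
#' @return data frame with columns `seqname`, `offset` (0-based start of
#'   the match on the forward strand), `strand`, `score` (bits, on the
#'   score grid), `p_value`.
#' @export
scan_pwm <- function(pwm, targets, p_threshold = 1e-4,
                     strands = c("both", "forward"),
                     granularity = 1 / 1000, score_pseudo = 0.01) {
  stopifnot(inherits(pwm, "pwm"))
  strands <- match.arg(strands)
  if (!is.numeric(p_threshold) || length(p_threshold) != 1L ||
      is.na(p_threshold) || p_threshold <= 0 || p_threshold > 1) {
    stop("p_threshold must lie in (0, 1]")
  }
  seqs <- as_seq_vector(targets)
  tab <- pwm_pvalue_table(pwm, granularity, score_pseudo)
  w <- pwm$width
  res <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    L <- nchar(s)
    if (L < w) next
    variants <- list(`+` = s)
    if (strands == "both") variants$`-` <- revcomp(s)
    for (st in names(variants)) {
      sc <- window_int_scores(encode_seq(variants[[st]]), tab$s_int)
      pv <- pvalue_of_int_score(tab, sc)
      hit <- which(!is.na(pv) & pv <= p_threshold)
      if (!length(hit)) next
      off0 <- hit - 1L
      if (st == "-") off0 <- L - w - off0
      res[[length(res) + 1L]] <- data.frame(
        seqname = nm, offset = off0, strand = st,
        score = sc[hit] * tab$granularity, p_value = pv[hit],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(data.frame(seqname = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$seqname, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best PWM match p-value per sequence
#'
#' Convenience wrapper used for motif-based classification: the smallest
#' p-value over all offsets and both strands of each sequence.
#'
#' @inheritParams scan_pwm
#' @param seqs character vector of sequences.
#' @return numeric vector of best p-values (`NA` where no scorable window
#'   exists).
#' @export
best_match_pvalue <- function(pwm, seqs, granularity = 1 / 1000,
                              score_pseudo = 0.01) {
  stopifnot(inherits(pwm, "pwm"))
  tab <- pwm_pvalue_table(pwm, granularity, score_pseudo)
  vapply(toupper(seqs), function(s) {
    best <- suppressWarnings(max(c(
      window_int_scores(encode_seq(s), tab$s_int),
      window_int_scores(encode_seq(revcomp(s)), tab$s_int)), na.rm = TRUE))
    if (!is.finite(best)) return(NA_real_)
    pvalue_of_int_score(tab, best)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Align sequences to their best PWM match
#'
#' For each sequence, reports the maximum-score offset and strand; ties are
#' broken by the smaller offset, then by the + strand. The aligned block
#' contains the matched `width`-mer (reverse-complemented for - strand
#' matches so every row reads in motif orientation), optionally extended by
#' `flank5`/`flank3` bases of context; sequences lacking the requested
#' context are dropped and counted in attribute `n_dropped`.
#'
#' @inheritParams scan_pwm
#' @param seqs character vector of sequences, each at least `pwm$width`
#'   long.
#' @param strands `"both"` or `"forward"`.
#' @param flank5,flank3 bases of context to include on the 5'/3' side of
#'   the match (in motif orientation).
#' @return list with `alignment` (data frame: `seq_index`, `offset`
#'   0-based, `strand`, `score` in bits) and `aligned` (character vector of
#'   equal-length blocks, `NA` for dropped rows), plus attribute
#'   `n_dropped` on `aligned`.
#' @export
align_to_pwm <- function(seqs, pwm, strands = c("both", "forward"),
                         flank5 = 0L, flank3 = 0L, score_pseudo = 0.01) {
  stopifnot(inherits(pwm, "pwm"))
  strands <- match.arg(strands)
  seqs <- toupper(seqs)
  w <- pwm$width
  if (any(nchar(seqs) < w)) {
    stop("sequence shorter than PWM width ", w)
  }
  s_bits <- pwm_score_matrix(pwm, score_pseudo)
  s_int <- matrix(as.integer(round(s_bits / 1e-4)), nrow = w)
  gran <- 1e-4
  n <- length(seqs)
  off <- integer(n); strand <- character(n); score <- numeric(n)
  aligned <- rep(NA_character_, n)
  n_drop <- 0L
  for (k in seq_len(n)) {
    s <- seqs[k]
    L <- nchar(s)
    fw <- window_int_scores(encode_seq(s), s_int)
    cand <- data.frame(score = fw, offset = seq_along(fw) - 1L, strand = "+")
    if (strands == "both") {
      rv <- window_int_scores(encode_seq(revcomp(s)), s_int)
      cand <- rbind(cand, data.frame(score = rv,
                                     offset = L - w - (seq_along(rv) - 1L),
                                     strand = "-"))
    }
    cand <- cand[!is.na(cand$score), , drop = FALSE]
    if (!nrow(cand)) stop("sequence ", k, " has no scorable window")
    cand <- cand[order(-cand$score, cand$offset,
                       match(cand$strand, c("+", "-"))), , drop = FALSE]
    off[k] <- cand$offset[1]
    strand[k] <- cand$strand[1]
    score[k] <- cand$score[1] * gran
    # extract the (flank5 + w + flank3)-mer in motif orientation
    if (strand[k] == "+") {
      a0 <- off[k] - flank5
      b0 <- off[k] + w + flank3
      if (a0 >= 0 && b0 <= L) aligned[k] <- substr(s, a0 + 1L, b0)
    } else {
      a0 <- off[k] - flank3
      b0 <- off[k] + w + flank5
      if (a0 >= 0 && b0 <= L) aligned[k] <- revcomp(substr(s, a0 + 1L, b0))
    }
    if (is.na(aligned[k])) n_drop <- n_drop + 1L
  }
  attr(aligned, "n_dropped") <- n_drop
  list(alignment = data.frame(seq_index = seq_len(n), offset = off,
                              strand = strand, score = score,
                              stringsAsFactors = FALSE),
       aligned = aligned)
}

#' @noRd
as_seq_vector <- function(targets) {
  if (inherits(targets, "Genome")) return(as.list(targets$seq))
  if (is.character(targets)) {
    nm <- names(targets)
    if (is.null(nm)) nm <- sprintf("seq_%d", seq_along(targets))
    return(stats::setNames(as.list(toupper(targets)), nm))
  }
  stop("targets must be a Genome or a character vector")
}

#' Write motif hits as BED6
#'
#' Scores are `-log10(p)`.
#'
#' @param hits data frame from [scan_pwm()].
#' @param width motif width used for the scan.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, width, path) {
  iv <- intervals(hits$seqname, hits$offset, hits$offset + width,
                  name = sprintf("hit_%d", seq_len(nrow(hits))),
                  score = round(-log10(pmax(hits$p_value, 1e-300)), 3),
                  strand = hits$strand)
  write_bed(iv, path)
}
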