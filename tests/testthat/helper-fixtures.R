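# shared fixtures: tiny files, reference PWMs, and independent oracles

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a small deterministic PWM with consensus "GA"
ga_pwm <- function(pseudocount = 0.01) {
  build_pwm(c("GA", "GA", "GA", "GG"), pseudocount = pseudocount)
}

# degenerate PWM from a consensus string, optional pseudocount
consensus_pwm <- function(cons, pseudocount = 0.01) {
  build_pwm(cons, pseudocount = pseudocount)
}

# brute-force log-odds scoring of one window against a PWM, mirroring the
# scanner's score discretisation but via independent arithmetic
brute_window_score <- function(pwm, kmer, granularity = 1 / 1000,
                               score_pseudo = 0.01) {
  f <- pwm$freqs + score_pseudo
  f <- f / rowSums(f)
  s <- log2(sweep(f, 2, pwm$background, "/"))
  idx <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T"))
  if (anyNA(idx)) return(NA_real_)
  sum(round(s[cbind(seq_along(idx), idx)] / granularity))
}

# exhaustive-enumeration p-values: fraction of all 4^w k-mers whose
# (discretised) score reaches at least each achievable score
brute_pvalues <- function(pwm, granularity = 1 / 1000) {
  w <- pwm$width
  kmers <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), w)), 1,
                 paste, collapse = "")
  scores <- vapply(kmers, brute_window_score, numeric(1), pwm = pwm,
                   granularity = granularity, USE.NAMES = FALSE)
  # weight k-mers by background probability (uniform: equal weights)
  bg <- pwm$background
  probs <- vapply(kmers, function(k) {
    prod(bg[match(strsplit(k, "")[[1]], c("A", "C", "G", "T"))])
  }, numeric(1), USE.NAMES = FALSE)
  uniq <- sort(unique(scores))
  p <- vapply(uniq, function(s) sum(probs[scores >= s]), numeric(1))
  data.frame(score = uniq, p = p)
}

# regex-based maximal-run oracle (independent of the scanner's chaining)
regex_runs <- function(s, unit, strand_collapsed = TRUE) {
  one <- function(u) {
    m <- gregexpr(sprintf("(?:%s)+", u), s, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    lens <- attr(m, "match.length")
    data.frame(start = as.integer(m) - 1L,
               end = as.integer(m) - 1L + (lens %/% nchar(u)) * nchar(u),
               n_units = lens %/% nchar(u))
  }
  out <- one(unit)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(unit)))
  if (strand_collapsed && rc != unit) out <- rbind(out, one(rc))
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_units = integer(0)))
  }
  out[order(out$start), , drop = FALSE]
}

# genome fixture: one X and two autosomes with planted (GA)k runs
small_density_genome <- function(x_density = 30L, a_density = 10L, k = 4L,
                                 len = 1e6, seed = 17L) {
  cfg <- list(
    list(name = "chrX", class = "X", length = len,
         runs = list(list(unit = "GA", k = k, count = x_density))),
    list(name = "chr2L", class = "autosome", length = len,
         runs = list(list(unit = "GA", k = k, count = a_density))),
    list(name = "chr2R", class = "autosome", length = len,
         runs = list(list(unit = "GA", k = k, count = a_density))))
  generate_genome(cfg, seed = seed)
}

emsa_probe_path <- function() {
  system.file("extdata", "emsa_probes.tsv", package = "xdense")
}
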