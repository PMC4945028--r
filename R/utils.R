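# Internal sequence helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

# byte lookup: A/C/G/T -> 1..4, anything else (incl. N) -> NA
.BASE_CODE <- local({
  tab <- rep(NA_integer_, 256L)
  tab[utf8ToInt("A")] <- 1L
  tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L
  tab[utf8ToInt("T")] <- 4L
  tab
})

#' @noRd
encode_seq <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  .BASE_CODE[as.integer(charToRaw(x))]
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the A/C/G/T/N alphabet.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
validate_dna <- function(x, allow_n = TRUE, what = "sequence") {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {%s}: %s",
                 what, paste(strsplit(alphabet, "")[[1]], collapse = ","),
                 substr(x[bad][1], 1, 50)), call. = FALSE)
  }
  invisible(x)
}

#' @noRd
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) && x >= min
}

# deterministic child seed derived from a root seed and a label, < 2^31
#' @noRd
child_seed <- function(seed, label) {
  stopifnot(is_count(seed))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((seed %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483629 + 1)
}
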