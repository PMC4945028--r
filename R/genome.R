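#' Genome container
#'
#' A `Genome` holds named chromosome sequences together with a class label
#' per chromosome (`"X"`, `"autosome"`, or `"other"`) and an optional arm
#' label (e.g. a Muller element identity). Class labels drive every
#' X:autosome density comparison; chromosomes labelled `"other"` are kept in
#' the object but never enter X:A ratios.
#'
#' @param sequences named character vector of chromosome sequences
#'   (A/C/G/T/N, upper case enforced).
#' @param class_labels character vector (recycled or named) with values in
#'   `c("X", "autosome", "other")`. Defaults to `"other"` for every
#'   chromosome.
#' @param arm_labels optional character vector of arm identities (named or
#'   positional), `NA` where unknown.
#' @return an object of class `Genome`: a list with elements `seq`,
#'   `class_label`, `arm_label`, all named by chromosome.
#' @export
genome <- function(sequences, class_labels = NULL, arm_labels = NULL) {
  if (length(sequences) == 0L) stop("genome needs at least one chromosome")
  nm <- names(sequences)
  if (is.null(nm) || any(nm == "") || anyNA(nm)) {
    stop("all chromosome sequences must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name: ", nm[duplicated(nm)][1])
  }
  if (any(nchar(sequences) == 0L)) {
    stop("empty sequence for chromosome: ", nm[nchar(sequences) == 0L][1])
  }
  sequences <- toupper(sequences)
  validate_dna(sequences, allow_n = TRUE, what = "chromosome sequence")

  cls <- resolve_labels(class_labels, nm, default = "other")
  bad <- !cls %in% c("X", "autosome", "other")
  if (any(bad)) {
    stop("class labels must be one of X/autosome/other, got: ",
         paste(unique(cls[bad]), collapse = ", "))
  }
  arm <- resolve_labels(arm_labels, nm, default = NA_character_)
  structure(list(seq = sequences, class_label = cls, arm_label = arm),
            class = "Genome")
}

#' @noRd
resolve_labels <- function(x, nm, default) {
  out <- rep(default, length(nm))
  names(out) <- nm
  if (is.null(x)) return(out)
  if (!is.null(names(x))) {
    unknown <- setdiff(names(x), nm)
    if (length(unknown)) {
      stop("labels refer to unknown chromosomes: ",
           paste(unknown, collapse = ", "))
    }
    out[names(x)] <- unname(x)
  } else {
    if (length(x) == 1L) x <- rep(x, length(nm))
    if (length(x) != length(nm)) stop("label vector length mismatch")
    out[] <- x
  }
  out
}

#' @export
print.Genome <- function(x, ...) {
  cat(sprintf("Genome with %d chromosome(s):\n", length(x$seq)))
  for (nm in names(x$seq)) {
    cat(sprintf("  %s  %d bp  class=%s  arm=%s\n", nm, nchar(x$seq[[nm]]),
                x$class_label[[nm]],
                ifelse(is.na(x$arm_label[[nm]]), "-", x$arm_label[[nm]])))
  }
  invisible(x)
}

#' Chromosome lengths of a Genome
#' @param g a `Genome`.
#' @return named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(g) {
  stopifnot(inherits(g, "Genome"))
  vapply(g$seq, nchar, integer(1))
}

#' Read a genome from FASTA
#'
#' Reads a FASTA file into a [genome()]. Sequences are upper-cased and
#' validated against the A/C/G/T/N alphabet; duplicate record names and
#' empty records are errors. Class and arm labels are attached from a YAML
#' side-car (see [read_chrom_classes()]) or default to `"other"` -- they are
#' never inferred from chromosome names, which differ between species.
#'
#' @param path path to a FASTA file.
#' @param classes optional: either a path to a YAML side-car or a named
#'   character vector of class labels; see [read_chrom_classes()].
#' @param arms optional named character vector of arm labels (ignored when
#'   `classes` is a YAML path that carries arms).
#' @return a `Genome`.
#' @export
read_fasta <- function(path, classes = NULL, arms = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA header at line 1 of ", path, ": ", first)
  }
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("FASTA parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))  # first token of header
  if (is.character(classes) && length(classes) == 1L && file.exists(classes) &&
      is.null(names(classes))) {
    side <- read_chrom_classes(classes)
    cls <- side$class
    if (is.null(arms)) arms <- side$arm
  } else {
    cls <- classes
  }
  genome(seqs, class_labels = cls, arm_labels = arms)
}

#' Write a Genome to FASTA
#'
#' @param g a `Genome`.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "Genome"))
  ss <- Biostrings::BStringSet(g$seq)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a chromosome class side-car file
#'
#' The side-car is a YAML mapping from chromosome name to either a class
#' string or a mapping with keys `class` and optional `arm`:
#'
#' ```yaml
#' chrX: {class: X, arm: Muller-A}
#' chr2L: {class: autosome, arm: Muller-B}
#' chrU: other
#' ```
#'
#' Keeping the labels explicit (rather than inferring them from names)
#' makes the set of chromosomes entering density denominators an explicit,
#' auditable choice.
#'
#' @param path path to the YAML file.
#' @return list with named character vectors `class` and `arm`.
#' @export
read_chrom_classes <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!length(raw)) stop("empty chromosome class file: ", path)
  cls <- vapply(raw, function(x) {
    if (is.list(x)) as.character(x$class) else as.character(x)
  }, character(1))
  arm <- vapply(raw, function(x) {
    if (is.list(x) && !is.null(x$arm)) as.character(x$arm) else NA_character_
  }, character(1))
  names(cls) <- names(arm) <- names(raw)
  bad <- !cls %in% c("X", "autosome", "other")
  if (any(bad)) {
    stop("invalid class label(s) in ", path, ": ",
         paste(unique(cls[bad]), collapse = ", "))
  }
  list(class = cls, arm = arm)
}
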