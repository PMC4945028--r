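#' Interval tables
#'
#' Intervals are plain data frames with columns `chrom`, `start`, `end`
#' (0-based half-open, BED convention), `name`, `score`, `strand`. All
#' interval arithmetic in the package uses this single convention, so BED
#' files round-trip byte-stably.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open; `start < end`.
#' @param name optional names (default `NA`).
#' @param score optional numeric scores (default `NA`).
#' @param strand strand per interval: `"+"`, `"-"` or `"."`.
#' @return data frame of class `c("intervals", "data.frame")`.
#' @export
intervals <- function(chrom, start, end, name = NA_character_,
                      score = NA_real_, strand = ".") {
  n <- length(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start != floor(start)) || any(end != floor(end))) {
    stop("interval coordinates must be integers")
  }
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stop(sprintf("interval with start >= end: %s:%d-%d",
                 chrom[i], start[i], end[i]))
  }
  strand <- rep_len(as.character(strand), n)
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  out <- data.frame(chrom = as.character(chrom), start = start, end = end,
                    name = rep_len(as.character(name), n),
                    score = rep_len(as.numeric(score), n),
                    strand = strand, stringsAsFactors = FALSE)
  class(out) <- c("intervals", "data.frame")
  out
}

#' @noRd
empty_intervals <- function() {
  intervals(character(0), integer(0), integer(0))
}

#' @noRd
midpoints <- function(x) floor((x$start + x$end) / 2)

#' Read a BED file
#'
#' BED3/BED6 (and wider) tab-separated files; coordinates are preserved
#' verbatim as 0-based half-open. Column 4 becomes `name`, column 5
#' `score`, column 6 `strand`.
#'
#' @param path path to the BED file.
#' @return an [intervals()] data frame (possibly empty).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) return(empty_intervals())
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#", colClasses = "character")
  if (ncol(tab) < 3L) stop("BED needs at least 3 columns: ", path)
  start <- suppressWarnings(as.numeric(tab[[2]]))
  end <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(start) || anyNA(end)) stop("non-numeric BED coordinate in ", path)
  intervals(tab[[1]], start, end,
            name = if (ncol(tab) >= 4L) tab[[4]] else NA_character_,
            score = if (ncol(tab) >= 5L)
              suppressWarnings(as.numeric(tab[[5]])) else NA_real_,
            strand = if (ncol(tab) >= 6L) tab[[6]] else ".")
}

#' Write intervals as BED
#'
#' Writes BED3 when no name/score/strand are set, BED6 otherwise.
#'
#' @param x an [intervals()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(is.data.frame(x))
  has_extra <- nrow(x) > 0 &&
    (any(!is.na(x$name)) || any(!is.na(x$score)) || any(x$strand != "."))
  if (has_extra) {
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                      ifelse(is.na(x$name), ".", x$name),
                      ifelse(is.na(x$score), "0", format(x$score,
                                                         scientific = FALSE,
                                                         trim = TRUE)),
                      x$strand)
  } else {
    out <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @noRd
format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read gene models
#'
#' Reads gene models from BED12 (or BED6 with strand) or from the gene
#' features of a GFF3 file. GFF3 1-based closed coordinates are converted
#' to the package's 0-based half-open convention on read. The TSS of a gene
#' is `start` on the + strand and `end - 1` on the - strand; the TTS is
#' symmetric.
#'
#' @param path input path.
#' @param dialect `"bed12"` (any BED with >= 6 columns) or `"gff3"`
#'   (records of type `gene` only; others are skipped).
#' @return data frame with columns `chrom`, `start`, `end`, `strand`, `id`.
#' @export
read_gene_models <- function(path, dialect = c("bed12", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "bed12") {
    bed <- read_bed(path)
    if (nrow(bed) == 0L) return(empty_genes())
    if (any(!bed$strand %in% c("+", "-"))) {
      stop("gene models require an explicit +/- strand: ", path)
    }
    g <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                    strand = bed$strand,
                    id = ifelse(is.na(bed$name),
                                sprintf("gene_%d", seq_len(nrow(bed))),
                                bed$name),
                    stringsAsFactors = FALSE)
  } else {
    if (file.size(path) == 0L) return(empty_genes())
    tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                             comment.char = "#", stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 9L) stop("GFF3 needs 9 columns: ", path)
    keep <- tab[[3]] == "gene"
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) == 0L) return(empty_genes())
    if (any(!tab[[7]] %in% c("+", "-"))) {
      stop("gene records without +/- strand in ", path)
    }
    id <- sub(".*ID=([^;]+).*", "\\1", tab[[9]])
    noid <- !grepl("ID=", tab[[9]])
    id[noid] <- sprintf("gene_%d", which(noid))
    g <- data.frame(chrom = tab[[1]],
                    start = as.numeric(tab[[4]]) - 1,  # 1-based -> 0-based
                    end = as.numeric(tab[[5]]),
                    strand = tab[[7]], id = id, stringsAsFactors = FALSE)
  }
  if (any(g$start >= g$end)) stop("gene with start >= end in ", path)
  if (anyNA(g$start) || anyNA(g$end)) stop("non-numeric gene coordinate")
  g
}

#' @noRd
empty_genes <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             strand = character(0), id = character(0),
             stringsAsFactors = FALSE)
}

#' Transcription start / termination sites
#'
#' @param genes gene-model data frame from [read_gene_models()].
#' @return numeric vector of 0-based positions.
#' @export
tss <- function(genes) ifelse(genes$strand == "+", genes$start, genes$end - 1)

#' @rdname tss
#' @export
tts <- function(genes) ifelse(genes$strand == "+", genes$end - 1, genes$start)

#' Extract fixed-width sequence windows around peak centers
#'
#' For each peak, extracts the `2 * half_width + 1` bp window centered on
#' `floor((start + end) / 2)`. Windows that would run past a chromosome end
#' are dropped; the number dropped is attached as attribute `n_dropped` and
#' reported with a warning.
#'
#' @param peaks an [intervals()] data frame.
#' @param g a [genome()].
#' @param half_width window half-width in bp (default 100, i.e. peak
#'   centers +/- 100 bp).
#' @return character vector of window sequences, named by
#'   `chrom:start-end` (0-based half-open), with attribute `n_dropped`.
#' @export
extract_peak_windows <- function(peaks, g, half_width = 100L) {
  stopifnot(inherits(g, "Genome"), is_count(half_width))
  unknown <- setdiff(unique(peaks$chrom), names(g$seq))
  if (length(unknown)) {
    stop("peak(s) on unknown chromosome: ", paste(unknown, collapse = ", "))
  }
  if (nrow(peaks) == 0L) {
    out <- character(0); attr(out, "n_dropped") <- 0L
    return(out)
  }
  mid <- midpoints(peaks)
  w0 <- mid - half_width            # 0-based inclusive
  w1 <- mid + half_width + 1       # 0-based exclusive
  len <- chrom_lengths(g)[peaks$chrom]
  keep <- w0 >= 0 & w1 <= len
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    warning(sprintf("%d window(s) clipped at chromosome ends were dropped",
                    n_drop))
  }
  out <- substring(g$seq[peaks$chrom[keep]], w0[keep] + 1, w1[keep])
  names(out) <- sprintf("%s:%d-%d", peaks$chrom[keep], w0[keep], w1[keep])
  attr(out, "n_dropped") <- n_drop
  out
}

#' Read / write bedGraph coverage tracks
#'
#' Coverage is represented as a step function: a data frame with columns
#' `chrom`, `start`, `end` (0-based half-open) and `value`.
#'
#' @param path input/output path.
#' @return `read_bedgraph`: the coverage data frame.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0)))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop("bedGraph needs 4 columns: ", path)
  out <- data.frame(chrom = as.character(tab[[1]]),
                    start = as.numeric(tab[[2]]), end = as.numeric(tab[[3]]),
                    value = as.numeric(tab[[4]]))
  if (any(out$start >= out$end)) stop("bedGraph interval with start >= end")
  out
}

#' @rdname read_bedgraph
#' @param track coverage data frame (`chrom`, `start`, `end`, `value`).
#' @return `write_bedgraph`: `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  out <- data.frame(track$chrom, format_coord(track$start),
                    format_coord(track$end),
                    format(track$value, scientific = FALSE, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
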