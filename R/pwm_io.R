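#' Read position weight matrices in MEME minimal text format
#'
#' Parses the minimal MEME motif format ("MEME version" header, `MOTIF`
#' blocks with a `letter-probability matrix` section). Rows whose sum is
#' within 1e-4 of 1 are renormalised; larger deviations are an error.
#'
#' @param path path to a MEME minimal text file.
#' @return list of PWM objects (see [build_pwm()] for the structure).
#' @export
read_pwm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!any(grepl("^MEME version", lines))) {
    stop("not a MEME minimal file (no 'MEME version' line): ", path)
  }
  bg <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    i <- bg_at[1] + 1L
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[c(FALSE, TRUE)]))
    if (length(vals) == 4L && !anyNA(vals)) bg <- vals / sum(vals)
  }
  motif_at <- grep("^MOTIF", lines)
  if (!length(motif_at)) stop("no MOTIF block in ", path)
  out <- vector("list", length(motif_at))
  for (k in seq_along(motif_at)) {
    name <- strsplit(trimws(lines[motif_at[k]]), "\\s+")[[1]][2]
    lpm_at <- grep("^letter-probability matrix",
                   lines[motif_at[k]:length(lines)])[1]
    if (is.na(lpm_at)) stop("MOTIF without letter-probability matrix: ", name)
    lpm_at <- motif_at[k] + lpm_at - 1L
    hdr <- lines[lpm_at]
    w_decl <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr)))
    rows <- list()
    i <- lpm_at + 1L
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || grepl("^(MOTIF|URL)", ln)) break
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (length(vals) != 4L || anyNA(vals)) break
      rows[[length(rows) + 1L]] <- vals
      i <- i + 1L
    }
    freqs <- do.call(rbind, rows)
    if (is.null(freqs) || nrow(freqs) == 0L) {
      stop("empty letter-probability matrix for motif ", name)
    }
    if (!is.na(w_decl) && nrow(freqs) != w_decl) {
      stop(sprintf("motif %s: declared w=%d but %d rows found",
                   name, w_decl, nrow(freqs)))
    }
    rs <- rowSums(freqs)
    if (any(abs(rs - 1) > 1e-4)) {
      stop(sprintf("motif %s: matrix row %d sums to %.6f (tolerance 1e-4)",
                   name, which(abs(rs - 1) > 1e-4)[1],
                   rs[abs(rs - 1) > 1e-4][1]))
    }
    freqs <- freqs / rs
    colnames(freqs) <- .BASES
    out[[k]] <- new_pwm(freqs, pseudocount = 0, background = bg, name = name)
  }
  out
}

#' Write PWMs in MEME minimal text format
#'
#' @param pwms a single PWM or a list of PWMs.
#' @param path output path.
#' @param nsites site count to report per motif (metadata only).
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwms, path, nsites = 20L) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies"), con)
  bg <- pwms[[1]]$background
  writeLines(sprintf("A %.5f C %.5f G %.5f T %.5f",
                     bg[1], bg[2], bg[3], bg[4]), con)
  writeLines("", con)
  for (k in seq_along(pwms)) {
    p <- pwms[[k]]
    nm <- if (is.null(p$name) || is.na(p$name)) sprintf("motif_%d", k) else p$name
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      p$width, nsites), con)
    writeLines(apply(p$freqs, 1L, function(r)
      sprintf(" %.6f %.6f %.6f %.6f", r[1], r[2], r[3], r[4])), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a pentamer DNA-shape lookup table
#'
#' The table is TSV with a header and five columns: `pentamer`, `MGW`
#' (minor groove width, Angstrom), `ProT` (propeller twist, degrees),
#' `Roll` (degrees), `HelT` (helix twist, degrees). All 1024 A/C/G/T
#' pentamers must be present exactly once; looking up an N-containing
#' pentamer later is an explicit failure.
#'
#' @param path path to the TSV file.
#' @return a 1024 x 4 numeric matrix, rows named by pentamer, columns
#'   `MGW`, `ProT`, `Roll`, `HelT`; class `shape_table`.
#' @export
read_shape_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("pentamer", "MGW", "ProT", "Roll", "HelT")
  if (!all(need %in% names(tab))) {
    stop("shape table must have columns: ", paste(need, collapse = ", "))
  }
  pent <- toupper(tab$pentamer)
  dup <- pent[duplicated(pent)]
  if (length(dup)) stop("duplicate pentamer in shape table: ", dup[1])
  all_pent <- all_pentamers()
  absent <- setdiff(all_pent, pent)
  if (length(absent)) {
    stop(sprintf("shape table missing %d pentamer(s), e.g. %s",
                 length(absent), absent[1]))
  }
  m <- as.matrix(tab[c("MGW", "ProT", "Roll", "HelT")])
  rownames(m) <- pent
  m <- m[all_pent, , drop = FALSE]
  class(m) <- c("shape_table", class(m))
  m
}

#' @noRd
all_pentamers <- function() {
  g <- expand.grid(.BASES, .BASES, .BASES, .BASES, .BASES,
                   stringsAsFactors = FALSE)
  # vary last base fastest for a conventional lexicographic order
  sort(apply(g, 1L, paste, collapse = ""))
}

#' Look up shape features for pentamers
#'
#' @param table a `shape_table` from [read_shape_table()].
#' @param pentamers character vector of 5-mers over A/C/G/T.
#' @return numeric matrix, one row per pentamer.
#' @export
shape_lookup <- function(table, pentamers) {
  stopifnot(inherits(table, "shape_table"))
  if (any(nchar(pentamers) != 5L)) stop("shape lookup requires 5-mers")
  bad <- grepl("[^ACGT]", pentamers)
  if (any(bad)) {
    stop("shape lookup of pentamer with non-ACGT base: ", pentamers[bad][1])
  }
  table[pentamers, , drop = FALSE]
}
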