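#' Read a PBM probe table
#'
#' Probe tables are TSV files with a header row and columns `id`,
#' `sequence`, `chip_flag`, `mre_flag`, followed by one or more numeric
#' replicate-intensity columns. Probes carry either the 36-nt variable
#' region alone or the full 60-nt probe (24-nt primer at positions 37-60),
#' in which case the variable region is the first 36 nt.
#'
#' @param path path to the TSV file.
#' @return data frame with columns `id`, `variable_seq`, `full_seq`
#'   (`NA` when only the variable region was supplied), `chip_flag`,
#'   `mre_flag`, `median_intensity`, plus the original intensity columns;
#'   class `c("probe_table", "data.frame")`.
#' @export
read_probe_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  need <- c("id", "sequence", "chip_flag", "mre_flag")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("probe table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  icols <- setdiff(names(tab), need)
  if (length(icols) == 0L) stop("probe table has no intensity columns")
  imat <- as.matrix(tab[icols])
  if (!is.numeric(imat)) stop("non-numeric intensity value in ", path)
  seqs <- toupper(tab$sequence)
  validate_dna(seqs, allow_n = FALSE, what = "probe sequence")
  lens <- nchar(seqs)
  if (!all(lens %in% c(36L, 60L))) {
    stop("probe sequences must be 36 nt (variable region) or 60 nt ",
         "(full probe); got length ", lens[!lens %in% c(36L, 60L)][1])
  }
  for (fl in c("chip_flag", "mre_flag")) {
    ok <- tab[[fl]] %in% c("+", "-", "NA") | is.na(tab[[fl]])
    if (!all(ok)) {
      stop(sprintf("invalid %s value '%s'; allowed: +, -, NA",
                   fl, tab[[fl]][!ok][1]))
    }
  }
  out <- data.frame(
    id = as.character(tab$id),
    variable_seq = ifelse(lens == 60L, substr(seqs, 1L, 36L), seqs),
    full_seq = ifelse(lens == 60L, seqs, NA_character_),
    chip_flag = ifelse(is.na(tab$chip_flag) | tab$chip_flag == "NA",
                       NA_character_, tab$chip_flag),
    mre_flag = ifelse(is.na(tab$mre_flag) | tab$mre_flag == "NA",
                      NA_character_, tab$mre_flag),
    median_intensity = apply(imat, 1L, stats::median),
    stringsAsFactors = FALSE)
  out <- cbind(out, tab[icols])
  class(out) <- c("probe_table", "data.frame")
  out
}

#' Write a probe table as TSV
#'
#' Inverse of [read_probe_table()]; replicate intensity columns are every
#' column named `intensity*`.
#'
#' @param probes a `probe_table` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_table <- function(probes, path) {
  icols <- grep("^intensity", names(probes), value = TRUE)
  out <- data.frame(id = probes$id,
                    sequence = ifelse(is.na(probes$full_seq),
                                      probes$variable_seq, probes$full_seq),
                    chip_flag = ifelse(is.na(probes$chip_flag), "NA",
                                       probes$chip_flag),
                    mre_flag = ifelse(is.na(probes$mre_flag), "NA",
                                      probes$mre_flag),
                    stringsAsFactors = FALSE)
  out <- cbind(out, probes[icols])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
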