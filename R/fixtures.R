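#' Load the transcribed conserved-miRNA worked-example table
#'
#' The package ships, as a plain-text fixture, the published summary table of
#' 142 conserved curry-leaf (*Murraya koenigii*) miRNAs: family label, assigned
#' name, mature sequence, printed length, best-matching reference miRNA,
#' mismatch count (0 or 1), collapsed read count and the original search
#' E-value. The E-value column is opaque metadata and is never recomputed.
#'
#' A handful of printed rows state a length that differs from the character
#' length of the printed sequence; both values are stored verbatim and the
#' discrepancy is flagged in `length_discrepancy` rather than silently
#' corrected.
#'
#' @return data.frame with 142 rows and columns `family` (NA for the
#'   unassigned block), `name`, `sequence`, `length_nt`, `reference_mirna`,
#'   `mismatches`, `read_count`, `e_value`, `length_discrepancy`.
#' @export
#' @examples
#' tab2 <- load_table2_fixture()
#' nrow(tab2)
#' length(unique(stats::na.omit(tab2$family)))
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_conserved_mirnas.tsv",
                      package = "mirprof", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "character",
                                          "integer", "character", "integer",
                                          "integer", "numeric"),
                           stringsAsFactors = FALSE, na.strings = NULL)
  tab$family[tab$family == "NA"] <- NA_character_
  bad <- which(!(tab$mismatches %in% c(0L, 1L)))
  if (length(bad) > 0)
    stop("fixture integrity: mismatches outside {0,1} at row ", bad[1],
         " (", tab$name[bad[1]], ")")
  bad <- which(tab$read_count < 1L)
  if (length(bad) > 0)
    stop("fixture integrity: read_count < 1 at row ", bad[1],
         " (", tab$name[bad[1]], ")")
  if (nrow(tab) != 142L)
    stop("fixture integrity: expected 142 conserved-miRNA records, got ",
         nrow(tab))
  nfam <- length(unique(tab$family[!is.na(tab$family)]))
  if (nfam != 34L)
    stop("fixture integrity: expected 34 distinct family labels, got ", nfam)
  tab$length_discrepancy <- nchar(tab$sequence) != tab$length_nt
  tab
}

#' Load the transcribed novel-miRNA worked-example table
#'
#' Seven novel miRNA candidates with mature sequence (RNA alphabet as
#' printed), length, collapsed read count, genomic strand, and the minimal
#' folding free energy index (MFEI) of the predicted precursor.
#'
#' @return data.frame with 7 rows and columns `name`, `sequence`,
#'   `length_nt`, `read_count`, `strand`, `mfei`.
#' @export
#' @examples
#' tab3 <- load_table3_fixture()
#' mean(tab3$mfei)
load_table3_fixture <- function() {
  path <- system.file("extdata", "table3_novel_mirnas.tsv",
                      package = "mirprof", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "integer",
                                          "integer", "character", "numeric"),
                           stringsAsFactors = FALSE)
  if (nrow(tab) != 7L)
    stop("fixture integrity: expected 7 novel-miRNA records, got ", nrow(tab))
  checks <- list(
    "sequence length != length_nt" = nchar(tab$sequence) != tab$length_nt,
    "mfei < 0.70"                  = tab$mfei < 0.70,
    "read_count < 5"               = tab$read_count < 5L,
    "strand outside {+,-}"         = !(tab$strand %in% c("+", "-")))
  for (what in names(checks)) {
    bad <- which(checks[[what]])
    if (length(bad) > 0)
      stop("fixture integrity: ", what, " at row ", bad[1],
           " (", tab$name[bad[1]], ")")
  }
  tab
}
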