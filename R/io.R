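#' Canonicalize a nucleotide sequence to uppercase DNA space
#'
#' All internal comparisons (homology, mapping, target scanning) are done in
#' uppercase DNA space: U is rewritten to T and lowercase is raised. The
#' original string is kept by callers that need it for display (mature miRNA
#' tables are conventionally printed in RNA alphabet).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector in uppercase over `{A,C,G,T,N}`.
#' @export
#' @examples
#' canonicalize_sequence("uuGacgga")
canonicalize_sequence <- function(x) {
  toupper(chartr("Uu", "Tt", x))
}

#' Convert a canonical DNA-space sequence to RNA alphabet
#' @param x character vector.
#' @return uppercase RNA-alphabet sequences (T rewritten to U).
#' @export
to_rna <- function(x) {
  chartr("Tt", "Uu", toupper(x))
}

#' Reverse complement of DNA-space sequences
#' @param x character vector of canonical DNA sequences.
#' @return reverse complements, same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("fq", "fastq")) "fastq" else "fasta"
}

#' Read small-RNA reads from FASTA or FASTQ
#'
#' Returns one record per entry with the sequence exactly as stored in the
#' file (case and U/T alphabet preserved); canonicalization happens later in
#' the pipeline. FASTQ qualities are kept as Sanger Phred+33 strings.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return data.frame with columns `read_id`, `sequence`, `quality`
#'   (`NA` for FASTA input), in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  if (file.size(path) == 0) {
    warning("empty input file: ", path)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) stop("malformed FASTA in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    qual <- rep(NA_character_, length(set))
  } else {
    parsed <- tryCatch({
      set <- Biostrings::readBStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
      list(set = set, qual = as.character(S4Vectors::mcols(set)$qualities))
    }, error = function(e) stop("malformed FASTQ in ", path, ": ",
                                conditionMessage(e), call. = FALSE))
    set <- parsed$set
    qual <- parsed$qual
  }
  if (length(set) == 0) warning("no records in ", path)
  res <- data.frame(read_id = names(set), sequence = as.character(set),
                    quality = qual, stringsAsFactors = FALSE)
  bad <- which(!nzchar(res$sequence))
  if (length(bad) > 0)
    stop("empty sequence for record ", res$read_id[bad[1]], " in ", path)
  badq <- which(!is.na(res$quality) &
                (nchar(res$quality, type = "bytes") !=
                 nchar(res$sequence, type = "bytes") |
                 grepl("[^!-~]", res$quality, useBytes = TRUE)))
  if (length(badq) > 0)
    stop("malformed quality string for record ", res$read_id[badq[1]])
  rownames(res) <- NULL
  res
}

#' Write reads to FASTA or FASTQ
#'
#' Inverse of [read_sequences()]: writing what was read reproduces ids and
#' sequences byte-identically for canonical single-line inputs.
#'
#' @param reads data.frame with `read_id`, `sequence` and (for FASTQ)
#'   `quality` columns.
#' @param path output file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (format == "fasta") {
    lines <- as.vector(rbind(paste0(">", reads$read_id), reads$sequence))
  } else {
    if (is.null(reads$quality) || anyNA(reads$quality))
      stop("FASTQ output requires quality strings for every read")
    lines <- as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                             "+", reads$quality))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Per-base Phred scores of a Sanger-encoded quality string
#' @param quality character vector of Phred+33 strings.
#' @return list of integer vectors.
#' @export
phred_scores <- function(quality) {
  lapply(quality, function(q) as.integer(charToRaw(q)) - 33L)
}

#' Read a mature-miRNA reference set
#'
#' Accepts FASTA with headers `ref_id|family` (family optional) or TSV with
#' columns `ref_id`, `family`, `sequence`. Sequences are canonicalized to DNA
#' space. Mature reference sequences are required to be 18--26 nt.
#'
#' @param path FASTA or TSV file.
#' @return data.frame with `ref_id`, `family` (`NA` when absent), `sequence`.
#' @export
read_reference <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt", "tab")) {
    ref <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, na.strings = "NA")
    need <- c("ref_id", "family", "sequence")
    if (!all(need %in% names(ref)))
      stop("reference TSV must have columns: ", paste(need, collapse = ", "))
    ref <- ref[, need]
  } else {
    fa <- read_sequences(path, format = "fasta")
    parts <- strsplit(fa$read_id, "|", fixed = TRUE)
    ref <- data.frame(
      ref_id = vapply(parts, `[`, character(1), 1),
      family = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                      character(1)),
      sequence = fa$sequence, stringsAsFactors = FALSE)
  }
  ref$sequence <- canonicalize_sequence(ref$sequence)
  if (anyDuplicated(ref$ref_id))
    stop("duplicated ref_id in reference: ",
         ref$ref_id[duplicated(ref$ref_id)][1])
  len <- nchar(ref$sequence)
  if (any(len < 18 | len > 26))
    stop("reference mature sequence outside 18-26 nt: ",
         ref$ref_id[which(len < 18 | len > 26)[1]])
  ref
}

#' Write collapsed unique tags as FASTA
#'
#' Headers follow the `tag<N>_x<count>` convention used by sRNA collapsing
#' tools, so read multiplicities survive the round trip.
#'
#' @param tags data.frame with `sequence` and `count` columns.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_tags_fasta <- function(tags, path) {
  ids <- sprintf("tag%d_x%d", seq_len(nrow(tags)), tags$count)
  write_sequences(data.frame(read_id = ids, sequence = tags$sequence),
                  path, format = "fasta")
}

#' Read collapsed tags written by [write_tags_fasta()]
#' @param path FASTA with `tag<N>_x<count>` headers.
#' @return data.frame with `sequence`, `count`.
#' @export
read_tags_fasta <- function(path) {
  fa <- read_sequences(path, format = "fasta")
  m <- regmatches(fa$read_id, regexpr("_x[0-9]+$", fa$read_id))
  if (length(m) != nrow(fa))
    stop("tag FASTA headers must end in _x<count>")
  data.frame(sequence = canonicalize_sequence(fa$sequence),
             count = as.integer(sub("_x", "", m)), stringsAsFactors = FALSE)
}
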