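#' Trim a 3' sequencing adapter from reads
#'
#' Removes the read suffix starting at the leftmost position where at least
#' `min_overlap` characters of the adapter prefix match the read exactly (the
#' match must extend to the read end or cover the whole adapter). Qualities
#' are truncated in lockstep. Reads without a match are returned unchanged; a
#' read equal to the adapter trims to an empty sequence, which the later
#' length filter removes.
#'
#' @param reads data.frame from [read_sequences()].
#' @param adapter 3' adapter sequence (canonicalized internally).
#' @param min_overlap minimum adapter-prefix match length (default 8).
#' @return `reads` with trimmed `sequence`/`quality` and a logical
#'   `adapter_found` column.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 8L) {
  stopifnot(nzchar(adapter))
  adapter <- canonicalize_sequence(adapter)
  alen <- nchar(adapter)
  seqs <- canonicalize_sequence(reads$sequence)
  cut_at <- vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < min_overlap) return(NA_integer_)
    for (i in seq_len(n - min_overlap + 1L)) {
      mlen <- min(n - i + 1L, alen)
      if (substr(s, i, i + mlen - 1L) == substr(adapter, 1L, mlen))
        return(i)
    }
    NA_integer_
  }, integer(1), USE.NAMES = FALSE)
  found <- !is.na(cut_at)
  out <- reads
  out$sequence[found] <- substr(seqs[found], 1L, cut_at[found] - 1L)
  out$sequence[!found] <- seqs[!found]
  if (!is.null(out$quality)) {
    keepq <- found & !is.na(out$quality)
    out$quality[keepq] <- substr(out$quality[keepq], 1L, cut_at[keepq] - 1L)
  }
  out$adapter_found <- found
  out
}

#' Mean-quality keep/drop decision per read
#'
#' The low-quality rule is read as: drop a read whose mean Phred score is
#' strictly below `min_mean_q` (default Q30). FASTA input (no qualities)
#' skips the stage with a notice and keeps everything.
#'
#' @param reads data.frame with a `quality` column of Phred+33 strings.
#' @param min_mean_q minimum mean Phred score (default 30).
#' @return logical keep vector, one element per read.
#' @export
quality_keep <- function(reads, min_mean_q = 30) {
  if (is.null(reads$quality) || all(is.na(reads$quality))) {
    message("no quality scores present; quality filter skipped")
    return(rep(TRUE, nrow(reads)))
  }
  vapply(seq_len(nrow(reads)), function(i) {
    q <- reads$quality[i]
    if (is.na(q) || !nzchar(q)) return(TRUE)
    mean(as.integer(charToRaw(q)) - 33L) >= min_mean_q
  }, logical(1))
}

#' Collapse reads to unique tags
#'
#' One tag per distinct canonical sequence, with `count` equal to its
#' multiplicity; the sum of counts equals the number of input reads. Tags are
#' ordered by decreasing count, then lexicographically, so output is
#' deterministic.
#'
#' @param sequences character vector of read sequences (or a reads
#'   data.frame, from which `sequence` is taken).
#' @return data.frame with `sequence` (canonical DNA space) and `count`.
#' @export
collapse_unique <- function(sequences) {
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  sequences <- canonicalize_sequence(sequences)
  if (length(sequences) == 0)
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  tab <- table(sequences)
  out <- data.frame(sequence = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length-filter unique tags
#'
#' Retains tags with `min_len <= length <= max_len` (both bounds inclusive).
#'
#' @param tags data.frame with `sequence`, `count`.
#' @param min_len,max_len inclusive bounds (defaults 16 and 40 nt).
#' @return list with `tags` (retained), `removed_tags` (count of dropped
#'   tags) and `removed_reads` (their summed read counts).
#' @export
length_filter <- function(tags, min_len = 16L, max_len = 40L) {
  len <- nchar(tags$sequence)
  keep <- len >= min_len & len <= max_len
  list(tags = `rownames<-`(tags[keep, , drop = FALSE], NULL),
       removed_tags = sum(!keep),
       removed_reads = sum(tags$count[!keep]))
}

parse_contaminant_class <- function(ids) {
  classes <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  cls <- rep(NA_character_, length(ids))
  for (cl in classes) {
    hit <- grepl(paste0("(^|[|_ ])", cl, "($|[|_ ])"), ids)
    cls[is.na(cls) & hit] <- cl
  }
  if (anyNA(cls))
    stop("contaminant record without a class label (rRNA/tRNA/snRNA/snoRNA): ",
         ids[which(is.na(cls))[1]])
  cls
}

#' Remove tags matching a contaminant ncRNA set
#'
#' A tag is removed when it occurs as a substring of any contaminant record
#' (or of its reverse complement), allowing up to `max_mismatch`
#' substitutions over a same-length window. Small-RNA tags are fragments of
#' the longer ncRNAs, so containment is tag-in-contaminant. When a tag
#' matches several classes, attribution follows the fixed priority order
#' rRNA, snoRNA, snRNA, tRNA so counts are deterministic.
#'
#' @param tags data.frame with `sequence`, `count`.
#' @param contaminants FASTA path or data.frame (`read_id`, `sequence`) whose
#'   headers carry a class label among rRNA/tRNA/snRNA/snoRNA.
#' @param max_mismatch substitutions tolerated in the matching window
#'   (default 0 = exact substring).
#' @return list with `tags` (kept), `removed` (removed tag rows plus a
#'   `class` column) and `removed_by_class` (named read-count totals for
#'   rRNA, snoRNA, snRNA, tRNA).
#' @export
remove_ncrna <- function(tags, contaminants, max_mismatch = 0L) {
  if (is.character(contaminants) && length(contaminants) == 1L)
    contaminants <- read_sequences(contaminants, format = "fasta")
  cls <- parse_contaminant_class(contaminants$read_id)
  cseq <- canonicalize_sequence(contaminants$sequence)
  cseq_rc <- revcomp(cseq)
  order_cls <- c("rRNA", "snoRNA", "snRNA", "tRNA")
  tag_class <- rep(NA_character_, nrow(tags))
  for (cl in order_cls) {
    idx <- which(cls == cl)
    if (length(idx) == 0) next
    todo <- which(is.na(tag_class))
    for (t in todo) {
      tg <- tags$sequence[t]
      hit <- FALSE
      for (j in idx) {
        if (max_mismatch == 0L) {
          hit <- grepl(tg, cseq[j], fixed = TRUE) ||
                 grepl(tg, cseq_rc[j], fixed = TRUE)
        } else {
          hit <- length(scan_matches_cpp(cseq[j], tg, max_mismatch)) > 0 ||
                 length(scan_matches_cpp(cseq_rc[j], tg, max_mismatch)) > 0
        }
        if (hit) break
      }
      if (hit) tag_class[t] <- cl
    }
  }
  removed <- tags[!is.na(tag_class), , drop = FALSE]
  removed$class <- tag_class[!is.na(tag_class)]
  by_class <- vapply(c("rRNA", "snoRNA", "snRNA", "tRNA"), function(cl)
    sum(removed$count[removed$class == cl]), numeric(1))
  list(tags = `rownames<-`(tags[is.na(tag_class), , drop = FALSE], NULL),
       removed = `rownames<-`(removed, NULL),
       removed_by_class = by_class)
}

#' Length distribution of unique tags
#'
#' Tag counts and percentages per length over the retained 16--40 nt range;
#' the modal length is attached as the `argmax` attribute. In typical plant
#' sRNA libraries the 21--24 nt lengths dominate, with 24 nt the most
#' abundant class.
#'
#' @param tags data.frame with `sequence`, `count`.
#' @return data.frame `length`, `n_tags`, `percent` (of unique tags), with
#'   attribute `argmax`.
#' @export
length_distribution <- function(tags) {
  len <- nchar(tags$sequence)
  tab <- table(factor(len, levels = sort(unique(len))))
  out <- data.frame(length = as.integer(names(tab)),
                    n_tags = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- if (nrow(tags) > 0) 100 * out$n_tags / nrow(tags) else numeric(0)
  attr(out, "argmax") <- if (nrow(out) > 0) out$length[which.max(out$n_tags)] else NA_integer_
  out
}

#' Clean a raw sRNA library end to end
#'
#' Quality filter, adapter trim, collapse to unique tags, 16--40 nt length
#' filter, ncRNA contaminant removal, and the length distribution, with a
#' cleaning report whose removal categories partition the input reads
#' exactly (read-count conservation).
#'
#' @param reads data.frame from [read_sequences()] or a FASTQ/FASTA path.
#' @param adapter 3' adapter sequence, or `NULL` to skip trimming.
#' @param contaminants ncRNA contaminant FASTA path or data.frame, or `NULL`.
#' @param min_overlap,min_mean_q,min_len,max_len,max_mismatch stage
#'   parameters (see the individual stage functions).
#' @return list with `tags` (final unique tags), `report` (the cleaning
#'   report), `length_dist`, and `removed_ncrna` (per-tag removals).
#' @export
clean_reads <- function(reads, adapter = NULL, contaminants = NULL,
                        min_overlap = 8L, min_mean_q = 30,
                        min_len = 16L, max_len = 40L, max_mismatch = 0L) {
  if (is.character(reads) && length(reads) == 1L) reads <- read_sequences(reads)
  total <- nrow(reads)
  keep <- quality_keep(reads, min_mean_q)
  removed_low_quality <- sum(!keep)
  reads <- reads[keep, , drop = FALSE]
  if (!is.null(adapter)) reads <- trim_adapter(reads, adapter, min_overlap)
  tags <- collapse_unique(reads$sequence)
  lf <- length_filter(tags, min_len, max_len)
  tags <- lf$tags
  if (!is.null(contaminants)) {
    nc <- remove_ncrna(tags, contaminants, max_mismatch)
  } else {
    nc <- list(tags = tags,
               removed = cbind(tags[0, , drop = FALSE], class = character(0)),
               removed_by_class = c(rRNA = 0, snoRNA = 0, snRNA = 0, tRNA = 0))
  }
  tags <- nc$tags
  report <- list(
    total_reads = total,
    trimmed_reads = total - removed_low_quality,
    removed_low_quality = removed_low_quality,
    removed_short_long = lf$removed_reads,
    removed_by_class = nc$removed_by_class,
    surviving_reads = sum(tags$count),
    unique_tags = nrow(tags))
  stopifnot(report$total_reads ==
            report$surviving_reads + report$removed_low_quality +
            report$removed_short_long + sum(report$removed_by_class))
  list(tags = tags, report = report,
       length_dist = length_distribution(tags), removed_ncrna = nc$removed)
}

#' Write a cleaning report as TSV
#' @param report the `report` element of [clean_reads()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(report, path) {
  flat <- c(total_reads = report$total_reads,
            trimmed_reads = report$trimmed_reads,
            removed_low_quality = report$removed_low_quality,
            removed_short_long = report$removed_short_long,
            setNames(as.numeric(report$removed_by_class),
                     paste0("removed_", names(report$removed_by_class))),
            surviving_reads = report$surviving_reads,
            unique_tags = report$unique_tags)
  utils::write.table(data.frame(metric = names(flat), value = as.numeric(flat)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
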