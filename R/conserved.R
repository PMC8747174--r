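hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Minimum ungapped mismatch count between a tag and a reference mature
#'
#' Homology is substitution-only: the shorter sequence is slid along the
#' longer one and the minimum Hamming distance over all full-containment
#' offsets is returned. Overhanging bases of the longer sequence are free.
#' Offset is the position of the tag start relative to the reference start
#' (negative when the reference lies inside a longer tag); ties are broken
#' by smallest absolute offset, then negative offset first.
#'
#' @param tag,ref nucleotide sequences (canonicalized internally).
#' @return named numeric vector `c(mismatches=, offset=)`.
#' @export
#' @examples
#' count_mismatches("TTTGGATTGAAGGGAGCTCTA", "TTTGGATTGAAGGGAGCTCTA")
count_mismatches <- function(tag, ref) {
  tag <- canonicalize_sequence(tag)
  ref <- canonicalize_sequence(ref)
  if (!nzchar(tag) || !nzchar(ref)) stop("empty sequence")
  if (nchar(tag) <= nchar(ref)) {
    short <- tag; long <- ref; sign <- 1L
  } else {
    short <- ref; long <- tag; sign <- -1L
  }
  ns <- nchar(short); nl <- nchar(long)
  offs <- 0:(nl - ns)
  mms <- vapply(offs, function(p)
    hamming(short, substr(long, p + 1L, p + ns)), numeric(1))
  signed <- sign * offs
  # order candidate offsets: fewest mismatches, smallest |offset|, negative first
  ord <- order(mms, abs(signed), signed)
  best <- ord[1]
  c(mismatches = mms[best], offset = signed[best])
}

#' Classify unique tags as conserved miRNAs by homology
#'
#' Each tag is assigned to the reference mature miRNA with the fewest
#' ungapped mismatches, provided that minimum is within `max_mismatch`
#' (default 1, the conventional conserved-miRNA budget). Ties are broken by
#' lexicographically smallest `ref_id`; a tag whose best score is shared by
#' references from different families is flagged `ambiguous`. Everything
#' else is returned unassigned, as input for novel-miRNA prediction.
#'
#' @param tags data.frame with `sequence`, `count`.
#' @param reference data.frame from [read_reference()].
#' @param max_mismatch mismatch budget (default 1).
#' @param prefix species prefix used for the assigned names (default
#'   `"mko"`).
#' @return list with `assignments` (tag_sequence, ref_id, family,
#'   mismatches, offset, read_count, assigned_name, ambiguous) and
#'   `unassigned` (tag rows left over).
#' @export
classify_conserved <- function(tags, reference, max_mismatch = 1L,
                               prefix = "mko") {
  stopifnot(nrow(reference) > 0)
  ref_seq <- canonicalize_sequence(reference$sequence)
  ord <- order(reference$ref_id)
  n <- nrow(tags)
  rows <- vector("list", n)
  assigned <- logical(n)
  for (i in seq_len(n)) {
    tg <- tags$sequence[i]
    best_mm <- Inf; best_j <- NA_integer_; best_off <- NA_real_
    tied_families <- character(0)
    for (j in ord) { # ref_id-sorted: first best hit is the lexicographic winner
      cm <- count_mismatches(tg, ref_seq[j])
      if (cm[["mismatches"]] < best_mm) {
        best_mm <- cm[["mismatches"]]; best_j <- j; best_off <- cm[["offset"]]
        tied_families <- reference$family[j]
      } else if (cm[["mismatches"]] == best_mm) {
        tied_families <- union(tied_families, reference$family[j])
      }
    }
    if (is.finite(best_mm) && best_mm <= max_mismatch) {
      assigned[i] <- TRUE
      rows[[i]] <- data.frame(
        tag_sequence = tg,
        ref_id = reference$ref_id[best_j],
        family = reference$family[best_j],
        mismatches = as.integer(best_mm),
        offset = as.integer(best_off),
        read_count = tags$count[i],
        assigned_name = sub("^[^-]+-", paste0(prefix, "-"),
                            reference$ref_id[best_j]),
        ambiguous = length(tied_families) > 1L,
        stringsAsFactors = FALSE)
    }
  }
  assignments <- if (any(assigned)) do.call(rbind, rows[assigned]) else
    data.frame(tag_sequence = character(), ref_id = character(),
               family = character(), mismatches = integer(),
               offset = integer(), read_count = integer(),
               assigned_name = character(), ambiguous = logical(),
               stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(assignments = assignments,
       unassigned = `rownames<-`(tags[!assigned, , drop = FALSE], NULL))
}

#' Summarize conserved assignments by miRNA family
#'
#' Groups assignments by family label: `member_count` is the number of
#' distinct family members -- distinct mature sequences, since one name can
#' cover several sequence variants -- and `total_reads` the summed read
#' counts.
#' Assignments without a family label are grouped under `NA` but excluded
#' from the family-count statistic (attribute `n_families`).
#'
#' @param assignments data.frame with `family`, `assigned_name` (or `name`),
#'   `read_count`.
#' @return data.frame `family`, `member_count`, `total_reads`, sorted by
#'   decreasing total reads; attribute `n_families` counts non-NA families.
#' @export
summarize_families <- function(assignments) {
  member_col <- intersect(c("tag_sequence", "sequence", "assigned_name", "name"),
                          names(assignments))[1]
  key <- ifelse(is.na(assignments$family), "<NA>", assignments$family)
  groups <- split(assignments, key)
  out <- do.call(rbind, lapply(names(groups), function(k) {
    g <- groups[[k]]
    data.frame(family = if (k == "<NA>") NA_character_ else k,
               member_count = length(unique(g[[member_col]])),
               total_reads = sum(g$read_count), stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$total_reads, out$family), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_families") <- sum(!is.na(out$family))
  out
}

#' Write conserved assignments as a TSV mirroring the worked-example table
#' @param assignments from [classify_conserved()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  out <- data.frame(family = assignments$family,
                    name = assignments$assigned_name,
                    sequence = assignments$tag_sequence,
                    length_nt = nchar(assignments$tag_sequence),
                    reference_mirna = assignments$ref_id,
                    mismatches = assignments$mismatches,
                    read_count = assignments$read_count,
                    ambiguous = assignments$ambiguous,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
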