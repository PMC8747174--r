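as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    set <- Biostrings::readDNAStringSet(genome)
    genome <- setNames(as.character(set), sub(" .*", "", names(set)))
  }
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a FASTA path or a named character vector of contigs")
  if (anyDuplicated(names(genome)))
    stop("duplicated contig names in genome: ",
         names(genome)[duplicated(names(genome))][1])
  setNames(canonicalize_sequence(genome), names(genome))
}

#' Map unique tags to a reference genome
#'
#' Exhaustive substitution-only alignment of each tag against both strands
#' of every contig (an internal scan; no indels). All hits within the
#' mismatch budget are reported, ordered by (contig, start, strand) so
#' output is deterministic. Coordinates are 0-based, end-exclusive, on the
#' forward strand.
#'
#' @param tags data.frame with `sequence`, `count`.
#' @param genome FASTA path or named character vector of contig sequences.
#' @param max_mismatch substitutions tolerated (default 0; cross-species
#'   mapping may warrant up to 2).
#' @return data.frame `tag_sequence`, `count`, `contig`, `start`, `end`,
#'   `strand`, `mismatches`.
#' @export
map_to_genome <- function(tags, genome, max_mismatch = 0L) {
  genome <- as_genome(genome)
  hits <- list()
  for (i in seq_len(nrow(tags))) {
    tg <- tags$sequence[i]
    tg_rc <- revcomp(tg)
    for (ctg in names(genome)) {
      for (strand in c("+", "-")) {
        probe <- if (strand == "+") tg else tg_rc
        pos <- scan_matches_cpp(genome[[ctg]], probe, as.integer(max_mismatch))
        if (length(pos) == 0) next
        mm <- vapply(pos, function(p)
          hamming(probe, substr(genome[[ctg]], p + 1L, p + nchar(tg))),
          numeric(1))
        hits[[length(hits) + 1L]] <- data.frame(
          tag_sequence = tg, count = tags$count[i], contig = ctg,
          start = pos, end = pos + nchar(tg), strand = strand,
          mismatches = as.integer(mm), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(tag_sequence = character(), count = integer(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$contig, out$start, out$strand, out$tag_sequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Excise candidate precursor windows around a genomic hit
#'
#' For each hit two windows are cut, placing the mature near either end so
#' that a hairpin on either arm can be captured: `[start - flank, end + 20)`
#' and `[start - 20, end + flank)`, clipped to contig bounds. Minus-strand
#' windows are reverse-complemented so the mature always appears in its
#' read orientation; `mature_offset` is 0-based within the returned window.
#' Windows too short to close a loop (`< tag + 2 * min_loop`) are discarded
#' with a message.
#'
#' @param hits data.frame from [map_to_genome()].
#' @param genome as in [map_to_genome()].
#' @param flank long-side flank length in nt (default 150; must be >= 20).
#' @param short_flank short-side flank (default 20).
#' @param min_loop minimal loop length used for the length check (default 3).
#' @return data.frame `window_id`, `tag_sequence`, `count`, `contig`,
#'   `start`, `end`, `strand`, `sequence`, `mature_offset`.
#' @export
excise_precursors <- function(hits, genome, flank = 150L, short_flank = 20L,
                              min_loop = 3L) {
  stopifnot(flank >= 20L)
  genome <- as_genome(genome)
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    clen <- nchar(genome[[h$contig]])
    tlen <- h$end - h$start
    spans <- list(c(max(0L, h$start - flank), min(clen, h$end + short_flank)),
                  c(max(0L, h$start - short_flank), min(clen, h$end + flank)))
    for (w in seq_along(spans)) {
      s <- spans[[w]][1]; e <- spans[[w]][2]
      if (e - s < tlen + 2L * min_loop) {
        message("window too short for a stem-loop; discarded (",
                h$contig, ":", s, "-", e, ")")
        next
      }
      seq <- substr(genome[[h$contig]], s + 1L, e)
      off <- h$start - s
      if (h$strand == "-") {
        seq <- revcomp(seq)
        off <- (e - s) - (off + tlen)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        window_id = sprintf("%s:%d-%d:%s/%d", h$contig, s, e, h$strand, w),
        tag_sequence = h$tag_sequence, count = h$count, contig = h$contig,
        start = s, end = e, strand = h$strand, sequence = seq,
        mature_offset = off, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(window_id = character(), tag_sequence = character(),
                      count = integer(), contig = character(),
                      start = integer(), end = integer(), strand = character(),
                      sequence = character(), mature_offset = integer(),
                      stringsAsFactors = FALSE))
  `rownames<-`(do.call(rbind, rows), NULL)
}

gc_percent <- function(x) {
  chars <- strsplit(canonicalize_sequence(x), "")[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Adjusted MFE and minimal folding free energy index
#'
#' `AMFE = (|MFE| / length) * 100` (energy per 100 nt) and
#' `MFEI = AMFE / GC%`, with GC content on the 0--100 scale. Genuine miRNA
#' precursors typically score MFEI >= 0.70, above tRNAs (~0.64), rRNAs
#' (~0.59) and mRNAs (~0.62-0.66), which is what makes the index a usable
#' discovery gate.
#'
#' @param mfe minimum folding free energy, kcal/mol (<= 0).
#' @param length precursor length in nt (> 0).
#' @param gc_percent GC content in percent, strictly between 0 and 100.
#' @return named numeric vector `c(amfe=, mfei=)`.
#' @export
#' @examples
#' compute_mfei(-50, 100, 50)  # amfe 50, mfei 1
compute_mfei <- function(mfe, length, gc_percent) {
  stopifnot(length > 0)
  if (any(gc_percent <= 0 | gc_percent >= 100))
    stop("MFEI undefined for GC percent outside (0, 100)")
  amfe <- (abs(mfe) / length) * 100
  c(amfe = amfe, mfei = amfe / gc_percent)
}

#' Fold an excised window and collect precursor statistics
#'
#' @param window one row of [excise_precursors()] output (or a list with
#'   `sequence`, `mature_offset`, `tag_sequence`).
#' @param engine,energies,min_loop forwarded to [fold()].
#' @return list: `sequence`, `structure`, `mfe`, `amfe`, `gc_percent`,
#'   `mfei`, `mature_arm` (`"5p"`/`"3p"`/`"loop"`), `mature_offset`,
#'   `mature_length`, plus the window coordinates when present.
#' @export
evaluate_precursor <- function(window, engine = NULL,
                               energies = default_pair_energies(),
                               min_loop = 3L) {
  f <- fold(window$sequence, engine = engine, energies = energies,
            min_loop = min_loop)
  gc <- gc_percent(window$sequence)
  mlen <- nchar(window$tag_sequence)
  stat <- compute_mfei(f$mfe, nchar(window$sequence), gc)
  loops <- hairpin_loop_spans(f$structure)
  mstart <- window$mature_offset + 1L
  mend <- window$mature_offset + mlen
  arm <- "loop"
  if (nrow(loops) >= 1) {
    # arm relative to the loop nearest the mature
    mid <- (loops$start + loops$end) / 2
    near <- which.min(abs(mid - (mstart + mend) / 2))
    if (mend < loops$start[near]) arm <- "5p"
    else if (mstart > loops$end[near]) arm <- "3p"
  }
  c(list(sequence = window$sequence, structure = f$structure, mfe = f$mfe,
         amfe = unname(stat["amfe"]), gc_percent = gc,
         mfei = unname(stat["mfei"]), mature_arm = arm,
         mature_offset = window$mature_offset, mature_length = mlen),
    window[intersect(c("window_id", "contig", "start", "end", "strand",
                       "count", "tag_sequence"), names(window))])
}

#' Stem-loop acceptance criteria for a precursor candidate
#'
#' The stem-loop containing the mature is delimited first: starting from the
#' terminal loop nearest the mature, the nested chain of enclosing pairs is
#' walked outward through bulges and internal loops, stopping at multiloop
#' branch points or the window ends. By construction that stem carries
#' exactly one terminal loop on the mature's path, so the remaining criteria
#' are: (a) the mature does not overlap the terminal loop, (b) at least
#' `min_paired_mature` mature bases pair within that stem (bases folding
#' away into the flanks count as unpaired), (c) the stem carries at least
#' `min_stem_pairs` pairs, and (d) the longest unpaired run inside the
#' mature does not exceed `max_arm_bulge`. The criteria are local to the
#' mature's stem-loop because excised windows are much longer than the
#' hairpin and their flanks fold independently.
#'
#' @param candidate list from [evaluate_precursor()].
#' @param min_paired_mature minimum paired mature bases (default 16).
#' @param max_arm_bulge largest tolerated unpaired run in the mature
#'   (default 4).
#' @param min_stem_pairs minimum total base pairs (default 18).
#' @return list `pass` (logical) and `reasons` (character vector, empty on
#'   pass).
#' @export
hairpin_criteria <- function(candidate, min_paired_mature = 16L,
                             max_arm_bulge = 4L, min_stem_pairs = 18L) {
  partner <- paired_positions(candidate$structure)
  loops <- hairpin_loop_spans(candidate$structure)
  n <- nchar(candidate$structure)
  mstart <- candidate$mature_offset + 1L
  mend <- candidate$mature_offset + candidate$mature_length
  reasons <- character(0)
  if (nrow(loops) == 0)
    return(list(pass = FALSE, reasons = "no terminal loop in the window"))
  # terminal loop nearest the mature, and its stem: the nested chain of
  # enclosing pairs, walked outward through bulges up to a multiloop branch
  mid <- (loops$start + loops$end) / 2
  near <- which.min(abs(mid - (mstart + mend) / 2))
  if (candidate$mature_arm == "loop" ||
      (loops$start[near] <= mend && loops$end[near] >= mstart))
    reasons <- c(reasons, "loop overlap")
  i <- loops$start[near] - 1L
  j <- loops$end[near] + 1L
  npairs <- 1L
  repeat {
    a <- i - 1L
    while (a >= 1L && is.na(partner[a])) a <- a - 1L
    b <- j + 1L
    while (b <= n && is.na(partner[b])) b <- b + 1L
    if (a < 1L || b > n || partner[a] != b) break
    i <- a; j <- b
    npairs <- npairs + 1L
  }
  in_stem <- !is.na(partner[mstart:mend]) &
             seq(mstart, mend) >= i & seq(mstart, mend) <= j
  if (sum(in_stem) < min_paired_mature)
    reasons <- c(reasons,
                 sprintf("only %d mature bases paired in the stem",
                         sum(in_stem)))
  if (npairs < min_stem_pairs)
    reasons <- c(reasons, sprintf("only %d stem pairs", npairs))
  runs <- rle(in_stem)
  bulge <- if (any(!runs$values)) max(runs$lengths[!runs$values]) else 0L
  if (bulge > max_arm_bulge)
    reasons <- c(reasons, sprintf("mature bulge of %d nt", bulge))
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Gate passing precursor candidates into novel miRNA calls
#'
#' Retains candidates with `mfei >= mfei_threshold` (default 0.70) and
#' `read_count >= copy_threshold` (default 5). Multiple genomic loci of the
#' same mature collapse to the maximum-MFEI locus. Names are assigned
#' `"<prefix>-miRN<k>-<arm>"` in descending read-count order.
#'
#' @param candidates data.frame with columns `mature_sequence` (or
#'   `tag_sequence`), `read_count` (or `count`), `strand`, `mfei`,
#'   `mature_arm`, `pass`.
#' @param mfei_threshold MFEI gate, inclusive (default 0.70).
#' @param copy_threshold minimum collapsed read count (default 5).
#' @param prefix species prefix for names (default `"mko"`).
#' @return data.frame `name`, `mature_sequence` (RNA alphabet),
#'   `length_nt`, `read_count`, `strand`, `mfei`.
#' @export
call_novel <- function(candidates, mfei_threshold = 0.70, copy_threshold = 5L,
                       prefix = "mko") {
  if (is.null(candidates$mature_sequence))
    candidates$mature_sequence <- candidates$tag_sequence
  if (is.null(candidates$read_count)) candidates$read_count <- candidates$count
  keep <- candidates$pass & candidates$mfei >= mfei_threshold &
          candidates$read_count >= copy_threshold
  cand <- candidates[keep, , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(name = character(), mature_sequence = character(),
                      length_nt = integer(), read_count = integer(),
                      strand = character(), mfei = numeric(),
                      stringsAsFactors = FALSE))
  # one call per mature: the locus with the best (largest) MFEI
  cand <- cand[order(cand$mature_sequence, -cand$mfei), , drop = FALSE]
  cand <- cand[!duplicated(cand$mature_sequence), , drop = FALSE]
  cand <- cand[order(-cand$read_count, cand$mature_sequence), , drop = FALSE]
  data.frame(name = sprintf("%s-miRN%d-%s", prefix, seq_len(nrow(cand)),
                            cand$mature_arm),
             mature_sequence = to_rna(cand$mature_sequence),
             length_nt = nchar(cand$mature_sequence),
             read_count = cand$read_count, strand = cand$strand,
             mfei = cand$mfei, row.names = NULL, stringsAsFactors = FALSE)
}

#' Discover novel miRNA candidates from unassigned tags
#'
#' The full discovery chain: map tags to the genome, excise candidate
#' precursor windows, fold each window, apply the stem-loop criteria, and
#' gate on MFEI and copy number.
#'
#' @param tags unassigned tags (`sequence`, `count`).
#' @param genome FASTA path or named character vector.
#' @param max_mismatch mapping budget (default 0).
#' @param flank excision flank (default 150).
#' @param mfei_threshold,copy_threshold gates as in [call_novel()].
#' @param engine,energies optional fold-engine overrides.
#' @param prefix species prefix for call names.
#' @param ... forwarded to [hairpin_criteria()].
#' @return list with `calls` (the novel-call table), `candidates` (per
#'   window statistics incl. pass/fail reasons), and `hits` (genome
#'   mapping).
#' @export
discover_novel <- function(tags, genome, max_mismatch = 0L, flank = 150L,
                           mfei_threshold = 0.70, copy_threshold = 5L,
                           engine = NULL, energies = default_pair_energies(),
                           prefix = "mko", ...) {
  hits <- map_to_genome(tags, genome, max_mismatch)
  windows <- excise_precursors(hits, genome, flank = flank)
  cands <- lapply(seq_len(nrow(windows)), function(i) {
    ev <- evaluate_precursor(windows[i, ], engine = engine, energies = energies)
    cr <- hairpin_criteria(ev, ...)
    data.frame(window_id = ev$window_id, tag_sequence = ev$tag_sequence,
               count = ev$count, contig = ev$contig, start = ev$start,
               end = ev$end, strand = ev$strand, mfe = ev$mfe, amfe = ev$amfe,
               gc_percent = ev$gc_percent, mfei = ev$mfei,
               mature_arm = ev$mature_arm, pass = cr$pass,
               reasons = paste(cr$reasons, collapse = "; "),
               sequence = ev$sequence, structure = ev$structure,
               stringsAsFactors = FALSE)
  })
  candidates <- if (length(cands) > 0) do.call(rbind, cands) else
    data.frame(window_id = character(), tag_sequence = character(),
               count = integer(), contig = character(), start = integer(),
               end = integer(), strand = character(), mfe = numeric(),
               amfe = numeric(), gc_percent = numeric(), mfei = numeric(),
               mature_arm = character(), pass = logical(),
               reasons = character(), sequence = character(),
               structure = character(), stringsAsFactors = FALSE)
  calls <- call_novel(candidates, mfei_threshold, copy_threshold, prefix)
  list(calls = calls, candidates = candidates, hits = hits)
}
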