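default_penalties <- function() {
  list(mismatch = 1.0, wobble = 0.5, gap = 2.0, seed_factor = 2.0)
}

as_transcripts <- function(transcripts) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    fa <- read_sequences(transcripts, format = "fasta")
    transcripts <- setNames(fa$sequence, sub(" .*", "", fa$read_id))
  }
  if (is.data.frame(transcripts))
    transcripts <- setNames(transcripts$sequence, transcripts$id)
  if (!is.character(transcripts) || is.null(names(transcripts)))
    stop("transcripts must be a FASTA path, a named character vector, ",
         "or a data.frame with id/sequence")
  setNames(canonicalize_sequence(transcripts), names(transcripts))
}

# Pair class per miRNA position for an ungapped site: miRNA position k
# (5'->3') faces site position L+1-k (antiparallel). "WC" Watson-Crick,
# "GU" wobble, "MM" mismatch. Both inputs canonical DNA space.
alignment_classes <- function(mirna, site) {
  m <- strsplit(mirna, "")[[1]]
  s <- rev(strsplit(site, "")[[1]])
  key <- paste0(m, s)
  cls <- rep("MM", length(m))
  cls[key %in% c("AT", "TA", "GC", "CG")] <- "WC"
  cls[key %in% c("GT", "TG")] <- "GU"
  cls
}

expectation_from_classes <- function(cls, penalties = default_penalties(),
                                     seed = 2:13) {
  pen <- ifelse(cls == "WC", 0,
         ifelse(cls == "GU", penalties$wobble, penalties$mismatch))
  idx <- intersect(seed, seq_along(cls))
  pen[idx] <- pen[idx] * penalties$seed_factor
  sum(pen)
}

#' Plant-mode miRNA target scan
#'
#' Slides the miRNA along every transcript and scores the antiparallel,
#' ungapped duplex at each window with the standard plant penalty scheme:
#' mismatch 1.0, G:U wobble 0.5, with penalties doubled inside the seed
#' (miRNA positions 2--13). The best (lowest-expectation) site per
#' transcript is emitted when its expectation is within the cutoff; ties go
#' to the 5'-most target position. Each emitted hit carries its duplex
#' hybridization energy and a silencing-mode call.
#'
#' @param mirna miRNA sequence (18--26 nt).
#' @param transcripts FASTA path, named character vector, or data.frame
#'   (`id`, `sequence`).
#' @param expectation_cutoff maximum expectation (default 5.0).
#' @param penalties list as [default_penalties()]; `gap` is carried for
#'   completeness but the scan is ungapped.
#' @param seed miRNA positions with doubled penalties (default 2:13).
#' @param mirna_name label used in the output (default `"mirna"`).
#' @param energies pair energies for [duplex_energy()].
#' @return data.frame `mirna_name`, `transcript_id`, `start`, `end`
#'   (1-based inclusive target span), `expectation`, `duplex_energy`,
#'   `mode` (`"cleavage"`/`"translation"`), `alignment` (per-position
#'   WC/GU/MM string).
#' @export
plant_target_scan <- function(mirna, transcripts, expectation_cutoff = 5.0,
                              penalties = default_penalties(), seed = 2:13,
                              mirna_name = "mirna",
                              energies = default_pair_energies()) {
  mirna <- canonicalize_sequence(mirna)
  n <- nchar(mirna)
  stopifnot(n >= 18, n <= 26)
  transcripts <- as_transcripts(transcripts)
  mchars <- strsplit(mirna, "")[[1]]
  hits <- list()
  for (tid in names(transcripts)) {
    tx <- transcripts[[tid]]
    L <- nchar(tx)
    if (L < n) next
    tchars <- strsplit(tx, "")[[1]]
    nwin <- L - n + 1L
    total <- numeric(nwin)
    for (k in seq_len(n)) {
      # miRNA position k faces transcript position s + n - k for window start s
      tc <- tchars[(n - k + 1L):(n - k + nwin)]
      key <- paste0(mchars[k], tc)
      pen <- ifelse(key %in% c("AT", "TA", "GC", "CG"), 0,
             ifelse(key %in% c("GT", "TG"), penalties$wobble,
                    penalties$mismatch))
      if (k %in% seed) pen <- pen * penalties$seed_factor
      total <- total + pen
    }
    best <- which.min(total) # which.min takes the first (5'-most) minimum
    if (total[best] > expectation_cutoff) next
    site <- substr(tx, best, best + n - 1L)
    cls <- alignment_classes(mirna, site)
    hits[[length(hits) + 1L]] <- data.frame(
      mirna_name = mirna_name, transcript_id = tid,
      start = best, end = best + n - 1L,
      expectation = total[best],
      duplex_energy = duplex_energy(mirna, site, energies),
      mode = call_mode(cls),
      alignment = paste(cls, collapse = ""),
      stringsAsFactors = FALSE)
  }
  if (length(hits) == 0)
    return(data.frame(mirna_name = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      expectation = numeric(), duplex_energy = numeric(),
                      mode = character(), alignment = character(),
                      stringsAsFactors = FALSE))
  `rownames<-`(do.call(rbind, hits), NULL)
}

#' Call the silencing mode of a target alignment
#'
#' Near-perfect complementarity across the central positions directs
#' transcript cleavage; a mismatch at miRNA positions 9--11 instead
#' predicts translational repression. Wobble pairs count as paired.
#'
#' @param alignment per-position class vector or string of `WC`/`GU`/`MM`
#'   (as in [plant_target_scan()] output).
#' @param central miRNA positions checked (default 9:11).
#' @return `"cleavage"` or `"translation"`.
#' @export
call_mode <- function(alignment, central = 9:11) {
  if (is.character(alignment) && length(alignment) == 1L &&
      !alignment[1] %in% c("WC", "GU", "MM"))
    alignment <- substring(alignment, seq(1, nchar(alignment) - 1, 2),
                           seq(2, nchar(alignment), 2))
  idx <- intersect(central, seq_along(alignment))
  if (any(alignment[idx] == "MM")) "translation" else "cleavage"
}

#' Cross-kingdom (animal-mode) target scan
#'
#' Strict-seed scan: candidate sites must be perfectly Watson-Crick
#' complementary to the miRNA seed (positions 2--8); wobbles disqualify.
#' Surviving sites are filtered on duplex hybridization energy,
#' keeping those with `|energy| >= energy_cutoff_abs` (i.e. energy at or
#' below -25 kcal/mol by default). The best site per transcript (most
#' negative energy, then 5'-most) is reported. Setting
#' `literal_energy_rule = TRUE` instead keeps sites with
#' `energy >= -energy_cutoff_abs`, the weaker literal reading.
#'
#' @param mirna miRNA sequence.
#' @param transcripts as in [plant_target_scan()].
#' @param energy_cutoff_abs absolute energy threshold in kcal/mol
#'   (default 25).
#' @param seed strict-seed miRNA positions (default 2:8).
#' @param mirna_name output label.
#' @param energies pair energies for [duplex_energy()].
#' @param literal_energy_rule use the literal `energy >= -cutoff` filter.
#' @return data.frame as [plant_target_scan()] (expectation column absent;
#'   `mode` is always `"translation"`-agnostic seed binding, reported as
#'   computed from the site alignment).
#' @export
cross_kingdom_scan <- function(mirna, transcripts, energy_cutoff_abs = 25.0,
                               seed = 2:8, mirna_name = "mirna",
                               energies = default_pair_energies(),
                               literal_energy_rule = FALSE) {
  mirna <- canonicalize_sequence(mirna)
  n <- nchar(mirna)
  transcripts <- as_transcripts(transcripts)
  seed_seq <- substr(mirna, min(seed), max(seed))
  probe <- revcomp(seed_seq) # transcript-strand seed match, WC only
  hits <- list()
  for (tid in names(transcripts)) {
    tx <- transcripts[[tid]]
    pos <- gregexpr(probe, tx, fixed = TRUE)[[1]]
    if (pos[1] == -1) next
    cand <- list()
    for (q in as.integer(pos)) {
      # seed occupies transcript positions q..q+|seed|-1; miRNA position k
      # faces transcript position q + max(seed) - k
      s0 <- q + max(seed) - n
      e0 <- q + max(seed) - 1L
      s <- max(1L, s0)
      e <- min(nchar(tx), e0)
      site <- substr(tx, s, e)
      en <- duplex_energy(mirna, site, energies)
      keep <- if (literal_energy_rule) en >= -energy_cutoff_abs
              else abs(en) >= energy_cutoff_abs
      if (!keep) next
      cand[[length(cand) + 1L]] <- data.frame(
        mirna_name = mirna_name, transcript_id = tid, start = s, end = e,
        duplex_energy = en,
        mode = call_mode(alignment_classes(
          substr(mirna, 1L, e - s + 1L), site)),
        stringsAsFactors = FALSE)
    }
    if (length(cand) == 0) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$duplex_energy, cand$start), , drop = FALSE]
    hits[[length(hits) + 1L]] <- cand[1, , drop = FALSE]
  }
  if (length(hits) == 0)
    return(data.frame(mirna_name = character(), transcript_id = character(),
                      start = integer(), end = integer(),
                      duplex_energy = numeric(), mode = character(),
                      stringsAsFactors = FALSE))
  `rownames<-`(do.call(rbind, hits), NULL)
}

#' Export target hits as an MFE-weighted network edge list
#'
#' One edge per hit, weighted by the duplex energy; interactions weaker
#' than `weak_cutoff` (less negative energy) are flagged so a network
#' viewer can render them as dotted edges.
#'
#' @param hits data.frame with `mirna_name`, `transcript_id`,
#'   `duplex_energy`.
#' @param path optional output TSV.
#' @param weak_cutoff energies above this value are flagged weak
#'   (default -15 kcal/mol).
#' @return data.frame `mirna_name`, `target_id`, `weight`, `weak_flag`.
#' @export
export_network <- function(hits, path = NULL, weak_cutoff = -15) {
  edges <- data.frame(mirna_name = hits$mirna_name,
                      target_id = hits$transcript_id,
                      weight = hits$duplex_energy,
                      weak_flag = hits$duplex_energy > weak_cutoff,
                      stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  edges
}

#' Predict targets for a set of miRNAs with the copy-number gate
#'
#' Applies the discovery convention that only miRNAs with collapsed read
#' counts of at least `copy_threshold` (default 5) enter target prediction,
#' then runs [plant_target_scan()] or [cross_kingdom_scan()] per miRNA.
#'
#' @param mirnas data.frame with `name`, `sequence`, `read_count`.
#' @param transcripts as in [plant_target_scan()].
#' @param mode `"plant"` or `"human"`.
#' @param copy_threshold minimum read count (default 5).
#' @param ... forwarded to the per-miRNA scan.
#' @return combined hits data.frame.
#' @export
predict_targets <- function(mirnas, transcripts, mode = c("plant", "human"),
                            copy_threshold = 5L, ...) {
  mode <- match.arg(mode)
  mirnas <- mirnas[mirnas$read_count >= copy_threshold, , drop = FALSE]
  out <- lapply(seq_len(nrow(mirnas)), function(i) {
    if (mode == "plant")
      plant_target_scan(mirnas$sequence[i], transcripts,
                        mirna_name = mirnas$name[i], ...)
    else
      cross_kingdom_scan(mirnas$sequence[i], transcripts,
                         mirna_name = mirnas$name[i], ...)
  })
  out <- out[vapply(out, nrow, integer(1)) > 0]
  if (length(out) == 0)
    return(data.frame(mirna_name = character(), transcript_id = character(),
                      stringsAsFactors = FALSE))
  `rownames<-`(do.call(rbind, out), NULL)
}
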