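with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else suppressWarnings(rm(".Random.seed", envir = genv))
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, len, probs = rep(0.25, 4)) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = probs),
          collapse = ""), character(1))
}

#' Empirical-style default length distribution for noise reads
#'
#' Probabilities over 16--40 nt shaped like a plant sRNA library: 24 nt the
#' most abundant class (9.52%), then 21 nt (4.94%), 22 nt (4.92%) and 23 nt
#' (4.79%), with the remaining mass spread evenly over the other lengths.
#'
#' @return named numeric vector of probabilities summing to 1.
#' @export
default_length_distribution <- function() {
  lens <- 16:40
  w <- setNames(rep(NA_real_, length(lens)), lens)
  w[c("24", "21", "22", "23")] <- c(9.52, 4.94, 4.92, 4.79)
  w[is.na(w)] <- (100 - sum(w, na.rm = TRUE)) / sum(is.na(w))
  w / sum(w)
}

#' Describe a hairpin precursor to plant in a synthetic genome
#'
#' @param mature mature miRNA sequence, 20--24 nt (DNA or RNA alphabet).
#' @param arm which precursor arm carries the mature (`"5p"` or `"3p"`).
#' @param loop_length terminal loop length in nt (>= 3, default 8).
#' @param stem_mismatches substitutions introduced into the star arm
#'   (must stay below a quarter of the mature length).
#' @param contig,position,strand genomic placement (0-based start).
#' @param copy_number reads of the mature planted in simulated libraries.
#' @param name label used in truth tables.
#' @return a `hairpin_design` list.
#' @export
hairpin_design <- function(mature, arm = c("5p", "3p"), loop_length = 8L,
                           stem_mismatches = 0L, contig = "chr1",
                           position = 0L, strand = "+", copy_number = 10L,
                           name = NULL) {
  arm <- match.arg(arm)
  mature <- canonicalize_sequence(mature)
  if (nchar(mature) < 20L || nchar(mature) > 24L)
    stop("mature must be 20-24 nt")
  if (loop_length < 3L) stop("loop_length must be >= 3")
  if (stem_mismatches >= nchar(mature) / 4)
    stop("stem_mismatches must be below a quarter of the mature length")
  stopifnot(strand %in% c("+", "-"))
  if (is.null(name)) name <- paste0("hp_", substr(mature, 1, 6))
  structure(list(mature = mature, arm = arm, loop_length = loop_length,
                 stem_mismatches = stem_mismatches, contig = contig,
                 position = as.integer(position), strand = strand,
                 copy_number = as.integer(copy_number), name = name),
            class = "hairpin_design")
}

#' Construct the precursor sequence of a hairpin design
#'
#' The precursor is mature + loop + star for a 5p-arm design and
#' star + loop + mature for 3p, where the star is the reverse complement of
#' the mature with `stem_mismatches` seeded substitutions. With zero
#' mismatches the mature arm pairs perfectly by construction.
#'
#' @param design a [hairpin_design()].
#' @param rng_seed integer seed controlling loop sequence and mismatch
#'   placement; the same seed always yields the same precursor.
#' @return precursor sequence (DNA space).
#' @export
make_hairpin_precursor <- function(design, rng_seed = 1L) {
  with_seed(rng_seed, {
    star <- revcomp(design$mature)
    if (design$stem_mismatches > 0L) {
      pos <- sample(nchar(star), design$stem_mismatches)
      chars <- strsplit(star, "")[[1]]
      for (p in pos)
        chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
      star <- paste(chars, collapse = "")
    }
    loop <- random_dna(1, design$loop_length)
    if (design$arm == "5p") paste0(design$mature, loop, star)
    else paste0(star, loop, design$mature)
  })
}

#' Build a synthetic genome with planted hairpin precursors
#'
#' Random background with the stated base composition; each design's
#' precursor is written at its genomic position (reverse-complemented for
#' minus-strand placements). Planted intervals must be disjoint and inside
#' the contig.
#'
#' @param designs list of [hairpin_design()] objects (may be empty).
#' @param contig_length named integer vector of contig lengths (a scalar is
#'   named `chr1`).
#' @param seed integer seed for background and precursor construction.
#' @param base_probs probabilities for A, C, G, T (default uniform).
#' @return list with `genome` (named character vector) and `annotations`
#'   (data.frame: name, contig, start, end, strand, arm, mature, precursor).
#' @export
build_genome <- function(designs = list(), contig_length = 10000L, seed = 1L,
                         base_probs = rep(0.25, 4)) {
  if (is.null(names(contig_length)))
    names(contig_length) <- paste0("chr", seq_along(contig_length))
  genome <- with_seed(seed, setNames(
    vapply(contig_length, function(L)
      random_dna(1, L, base_probs), character(1)),
    names(contig_length)))
  ann <- list()
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    if (!d$contig %in% names(genome))
      stop("design '", d$name, "' names unknown contig ", d$contig)
    prec <- make_hairpin_precursor(d, rng_seed = seed + i)
    plen <- nchar(prec)
    s <- d$position; e <- s + plen
    if (s < 0L || e > nchar(genome[[d$contig]]))
      stop("design '", d$name, "' outside contig bounds")
    ann[[i]] <- data.frame(name = d$name, contig = d$contig, start = s,
                           end = e, strand = d$strand, arm = d$arm,
                           mature = d$mature, precursor = prec,
                           stringsAsFactors = FALSE)
  }
  annotations <- if (length(ann) > 0) do.call(rbind, ann) else
    data.frame(name = character(), contig = character(), start = integer(),
               end = integer(), strand = character(), arm = character(),
               mature = character(), precursor = character(),
               stringsAsFactors = FALSE)
  if (nrow(annotations) > 1) {
    for (ctg in unique(annotations$contig)) {
      a <- annotations[annotations$contig == ctg, , drop = FALSE]
      a <- a[order(a$start), , drop = FALSE]
      if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)]))
        stop("planted precursor intervals overlap on ", ctg)
    }
  }
  for (i in seq_len(nrow(annotations))) {
    a <- annotations[i, ]
    ins <- if (a$strand == "+") a$precursor else revcomp(a$precursor)
    g <- genome[[a$contig]]
    genome[[a$contig]] <- paste0(substr(g, 1, a$start), ins,
                                 substr(g, a$end + 1L, nchar(g)))
  }
  list(genome = genome, annotations = annotations)
}

#' Generate a synthetic ncRNA contaminant set
#'
#' Random sequences labeled by class in the FASTA-style id
#' (`<id>|<class>`), sized like the real molecules: long rRNAs, short
#' tRNAs, and intermediate snRNA/snoRNA.
#'
#' @param seed integer seed.
#' @param n_per_class named counts for rRNA, tRNA, snRNA, snoRNA.
#' @return data.frame `read_id`, `sequence`.
#' @export
make_contaminants <- function(seed = 1L,
                              n_per_class = c(rRNA = 2L, tRNA = 4L,
                                              snRNA = 2L, snoRNA = 2L)) {
  lens <- c(rRNA = 800L, tRNA = 75L, snRNA = 150L, snoRNA = 120L)
  with_seed(seed, {
    rows <- list()
    for (cl in names(n_per_class)) {
      for (k in seq_len(n_per_class[[cl]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s%d|%s", tolower(cl), k, cl),
          sequence = random_dna(1, lens[[cl]]), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Assemble and validate a simulation configuration
#'
#' @param seed integer master seed.
#' @param n_reads library size.
#' @param adapter 3' adapter ligated to every read (default the QIAseq-style
#'   miRNA adapter `AACTGTAGGCACCATCAAT`).
#' @param planted_conserved data.frame `ref_id`, `family`, `sequence`,
#'   `copy_number` (copies are planted exactly).
#' @param planted_hairpins list of [hairpin_design()] objects; their
#'   `copy_number` matures are planted exactly.
#' @param contaminant_fraction,noise_fraction proportions of the library;
#'   noise fills whatever the planted and contaminant reads leave free, and
#'   the declared `noise_fraction` must be consistent with that remainder.
#' @param length_distribution named probabilities over 16--40 nt for
#'   contaminant-fragment and noise read lengths.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_reads = 1000L,
                              adapter = "AACTGTAGGCACCATCAAT",
                              planted_conserved = NULL,
                              planted_hairpins = list(),
                              contaminant_fraction = 0,
                              noise_fraction = NULL,
                              length_distribution = default_length_distribution()) {
  if (is.null(planted_conserved))
    planted_conserved <- data.frame(ref_id = character(), family = character(),
                                    sequence = character(),
                                    copy_number = integer(),
                                    stringsAsFactors = FALSE)
  stopifnot(all(planted_conserved$copy_number >= 1L))
  n_planted <- sum(planted_conserved$copy_number) +
    sum(vapply(planted_hairpins, function(d) d$copy_number, integer(1)))
  n_contam <- round(contaminant_fraction * n_reads)
  n_noise <- n_reads - n_planted - n_contam
  if (n_noise < 0)
    stop("planted copies plus contaminant fraction exceed n_reads")
  if (!is.null(noise_fraction) &&
      abs(noise_fraction - n_noise / n_reads) > 0.5 / max(1, n_reads) + 1e-9)
    stop("declared noise_fraction inconsistent with planted reads (",
         "remainder is ", n_noise, " of ", n_reads, " reads)")
  stopifnot(abs(sum(length_distribution) - 1) < 1e-6)
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 adapter = canonicalize_sequence(adapter),
                 planted_conserved = planted_conserved,
                 planted_hairpins = planted_hairpins,
                 n_contaminant = as.integer(n_contam),
                 n_noise = as.integer(n_noise),
                 length_distribution = length_distribution),
            class = "simulation_config")
}

#' Simulate an adapter-ligated sRNA-seq library with ground truth
#'
#' Every read is one of: a planted conserved mature, a planted hairpin
#' mature, a random fragment of a contaminant ncRNA, or random noise, each
#' with the 3' adapter appended and uniform high quality (Q40). Planting is
#' exact-copy: class counts in the truth table match the configuration
#' exactly, and identical configurations produce byte-identical output.
#'
#' @param cfg a [simulation_config()].
#' @param contaminants contaminant set (data.frame `read_id`, `sequence`);
#'   generated with [make_contaminants()] when needed and absent.
#' @param fastq_path,truth_path optional output paths (FASTQ and TSV).
#' @return list with `reads` (read_id, sequence, quality), `truth`
#'   (read_id, class, source_id, genome_position), `contaminants`, and any
#'   paths written.
#' @export
simulate_library <- function(cfg, contaminants = NULL, fastq_path = NULL,
                             truth_path = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(contaminants) && cfg$n_contaminant > 0)
    contaminants <- make_contaminants(cfg$seed + 1L)
  lens <- as.integer(names(cfg$length_distribution))
  seqs <- character(0); class <- character(0); source <- character(0)
  gpos <- character(0)
  for (i in seq_len(nrow(cfg$planted_conserved))) {
    p <- cfg$planted_conserved[i, ]
    seqs <- c(seqs, rep(canonicalize_sequence(p$sequence), p$copy_number))
    class <- c(class, rep(paste0("conserved:", p$ref_id), p$copy_number))
    source <- c(source, rep(p$ref_id, p$copy_number))
    gpos <- c(gpos, rep(NA_character_, p$copy_number))
  }
  for (d in cfg$planted_hairpins) {
    seqs <- c(seqs, rep(d$mature, d$copy_number))
    class <- c(class, rep(paste0("hairpin:", d$name), d$copy_number))
    source <- c(source, rep(d$name, d$copy_number))
    gpos <- c(gpos, rep(sprintf("%s:%d:%s", d$contig, d$position, d$strand),
                        d$copy_number))
  }
  sim <- with_seed(cfg$seed, {
    cseq <- character(0); csrc <- character(0); ccls <- character(0)
    if (cfg$n_contaminant > 0) {
      pick <- sample(nrow(contaminants), cfg$n_contaminant, replace = TRUE)
      frag_len <- sample(lens, cfg$n_contaminant, replace = TRUE,
                         prob = cfg$length_distribution)
      for (k in seq_len(cfg$n_contaminant)) {
        src <- contaminants[pick[k], ]
        L <- min(frag_len[k], nchar(src$sequence))
        s <- sample(nchar(src$sequence) - L + 1L, 1)
        cseq <- c(cseq, substr(canonicalize_sequence(src$sequence),
                               s, s + L - 1L))
        csrc <- c(csrc, src$read_id)
        ccls <- c(ccls, paste0("contaminant:",
                               parse_contaminant_class(src$read_id)))
      }
    }
    nseq <- character(0)
    if (cfg$n_noise > 0) {
      noise_len <- sample(lens, cfg$n_noise, replace = TRUE,
                          prob = cfg$length_distribution)
      nseq <- vapply(noise_len, function(L) random_dna(1, L), character(1))
    }
    list(cseq = cseq, csrc = csrc, ccls = ccls, nseq = nseq)
  })
  seqs <- c(seqs, sim$cseq, sim$nseq)
  class <- c(class, sim$ccls, rep("noise", cfg$n_noise))
  source <- c(source, sim$csrc, rep(NA_character_, cfg$n_noise))
  gpos <- c(gpos, rep(NA_character_, cfg$n_contaminant + cfg$n_noise))
  stopifnot(length(seqs) == cfg$n_reads)
  full <- paste0(seqs, cfg$adapter)
  reads <- data.frame(read_id = sprintf("read%06d", seq_along(full)),
                      sequence = full,
                      quality = strrep("I", nchar(full)),
                      stringsAsFactors = FALSE)
  truth <- data.frame(read_id = reads$read_id, class = class,
                      source_id = source, genome_position = gpos,
                      stringsAsFactors = FALSE)
  if (!is.null(fastq_path)) write_sequences(reads, fastq_path, "fastq")
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(reads = reads, truth = truth, contaminants = contaminants,
       fastq_path = fastq_path, truth_path = truth_path)
}
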