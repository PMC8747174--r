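# Independent brute-force oracles used to validate the fast implementations.

pair_e <- function(a, b, energies = c(gc = -3, au = -2, gu = -1)) {
  p <- paste0(a, b)
  if (p %in% c("GC", "CG")) return(energies[["gc"]])
  if (p %in% c("AU", "UA")) return(energies[["au"]])
  if (p %in% c("GU", "UG")) return(energies[["gu"]])
  NA_real_
}

# Exhaustive enumeration of every non-crossing structure (as explicit pair
# lists), scoring pair energies plus a closing penalty per hairpin loop.
# Exponential -- use only for short sequences.
oracle_fold_energy <- function(seq, energies = c(gc = -3, au = -2, gu = -1),
                               min_loop = 3L, loop_penalty = 4) {
  s <- strsplit(toupper(chartr("Tt", "Uu", seq)), "")[[1]]
  enum <- function(i, j) {
    if (j - i < min_loop + 1L) return(list(list()))
    out <- enum(i + 1L, j) # i unpaired
    for (k in (i + min_loop + 1L):j) {
      pen <- pair_e(s[i], s[k], energies)
      if (is.na(pen) || pen >= 0) next
      inner <- enum(i + 1L, k - 1L)
      outer <- if (k < j) enum(k + 1L, j) else list(list())
      for (a in inner) for (b in outer)
        out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
    }
    out
  }
  energy <- function(pairs) {
    if (length(pairs) == 0) return(0)
    e <- sum(vapply(pairs, function(p) pair_e(s[p[1]], s[p[2]], energies),
                    numeric(1)))
    hairpins <- sum(vapply(pairs, function(p)
      !any(vapply(pairs, function(q)
        q[1] > p[1] && q[2] < p[2], logical(1))), logical(1)))
    e + loop_penalty * hairpins
  }
  structures <- enum(1L, length(s))
  min(0, vapply(structures, energy, numeric(1)))
}

# Naive substitution-only genome scan, both strands, 0-based starts.
oracle_map <- function(tag, contigs, max_mm = 0L) {
  rc <- mirprof::revcomp(tag)
  hits <- list()
  for (ctg in names(contigs)) {
    g <- strsplit(contigs[[ctg]], "")[[1]]
    for (strand in c("+", "-")) {
      probe <- strsplit(if (strand == "+") tag else rc, "")[[1]]
      k <- length(probe)
      for (s in 0:(length(g) - k)) {
        if (sum(g[(s + 1):(s + k)] != probe) <= max_mm)
          hits[[length(hits) + 1L]] <- data.frame(
            contig = ctg, start = s, strand = strand,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(contig = character(), start = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

# All-offsets, all-references homology scan (naive loops).
oracle_best_mm <- function(tag, refs) {
  best <- Inf
  for (r in refs) {
    if (nchar(tag) <= nchar(r)) { short <- tag; long <- r }
    else { short <- r; long <- tag }
    ns <- nchar(short)
    for (p in 0:(nchar(long) - ns)) {
      a <- strsplit(short, "")[[1]]
      b <- strsplit(substr(long, p + 1, p + ns), "")[[1]]
      best <- min(best, sum(a != b))
    }
  }
  best
}

# Naive plant-mode expectation of one ungapped window (character loop).
oracle_expectation <- function(mirna, site, seed = 2:13,
                               mismatch = 1, wobble = 0.5, factor = 2) {
  m <- strsplit(mirna, "")[[1]]
  s <- rev(strsplit(site, "")[[1]])
  tot <- 0
  for (k in seq_along(m)) {
    p <- paste0(m[k], s[k])
    pen <- if (p %in% c("AT", "TA", "GC", "CG")) 0
           else if (p %in% c("GT", "TG")) wobble else mismatch
    if (k %in% seed) pen <- pen * factor
    tot <- tot + pen
  }
  tot
}

random_tags <- function(n, len = 21L, seed = 1L) {
  set.seed(seed)
  data.frame(sequence = vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1)), count = rep(1L, n), stringsAsFactors = FALSE)
}

small_reference <- function(n = 20L, seed = 2L) {
  set.seed(seed)
  data.frame(
    ref_id = sprintf("ath-miRt%02d", seq_len(n)),
    family = sprintf("MIRT%d", rep(seq_len(max(1, n %/% 2)), length.out = n)),
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE), collapse = ""),
      character(1)),
    stringsAsFactors = FALSE)
}
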