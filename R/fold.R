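default_pair_energies <- function() c(gc = -3, au = -2, gu = -1)

check_rna_alphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop(what, " contains characters outside the RNA alphabet after ",
         "canonicalization: ", x[bad][1])
  invisible(x)
}

#' Predict the minimum-free-energy secondary structure of an RNA
#'
#' The bundled engine is a nearest-neighbor-style energy-minimization
#' dynamic program: per-pair free energies (G:C -3, A:U -2, G:U -1 kcal/mol
#' by default), a minimum hairpin loop of 3 unpaired bases, and a
#' hairpin-loop closing penalty (+4 kcal/mol by default) that makes isolated
#' single pairs unfavorable, as in thermodynamic folders. It is
#' deterministic and exact for its parameterization; with wobble pairing
#' disabled (`gu = 0`) it is also symmetric under reverse complementation
#' (G:U pairs map to unpairable A:C under complementation, so no wobble-aware
#' model has that symmetry). The engine is pluggable: pass a function
#' `engine(sequence)` returning `list(structure=, mfe=)` to substitute an
#' external thermodynamic folder.
#'
#' @param sequence nucleotide sequence (T is rewritten to U; any other
#'   non-RNA character is an error).
#' @param engine optional replacement fold function.
#' @param energies named pair energies `c(gc=, au=, gu=)`; a zero disables
#'   that pair type.
#' @param min_loop minimum hairpin loop length (default 3).
#' @param loop_penalty hairpin-loop closing penalty in kcal/mol (default 4).
#' @return list with `structure` (dot-bracket, same length as the
#'   sequence) and `mfe` (kcal/mol, <= 0).
#' @export
#' @examples
#' fold("GGGGCCCCAAAAGGGGCCCC")$mfe
fold <- function(sequence, engine = NULL,
                 energies = default_pair_energies(), min_loop = 3L,
                 loop_penalty = 4) {
  rna <- to_rna(canonicalize_sequence(sequence))
  check_rna_alphabet(rna)
  if (!is.null(engine)) {
    res <- engine(rna)
  } else {
    res <- fold_cpp(rna, energies[["gc"]], energies[["au"]], energies[["gu"]],
                    as.integer(min_loop), loop_penalty)
  }
  stopifnot(nchar(res$structure) == nchar(rna), res$mfe <= 0)
  res
}

#' Hybridization energy of an intermolecular miRNA:target duplex
#'
#' Optimal non-crossing antiparallel pairing of the two strands under the
#' same pair energies as [fold()], with unpaired bases free. The value is
#' <= 0, deterministic, and symmetric in argument order. A fully
#' non-complementary pair scores 0.
#'
#' @param a,b nucleotide sequences, each at most 40 nt.
#' @param energies named pair energies as in [fold()].
#' @return duplex energy in kcal/mol (<= 0).
#' @export
duplex_energy <- function(a, b, energies = default_pair_energies()) {
  a <- to_rna(canonicalize_sequence(a))
  b <- to_rna(canonicalize_sequence(b))
  if (nchar(a) > 40 || nchar(b) > 40)
    stop("duplex_energy expects short sequences (<= 40 nt)")
  check_rna_alphabet(c(a, b))
  duplex_cpp(a, b, energies[["gc"]], energies[["au"]], energies[["gu"]])
}

#' Base-pair partner table of a dot-bracket structure
#' @param structure dot-bracket string with balanced brackets.
#' @return integer vector: `p[i]` is the partner of position i, `NA` if
#'   unpaired.
#' @export
paired_positions <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  n <- length(chars)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket structure")
  partner
}

# Terminal (hairpin) loops: runs of dots directly enclosed by a pair.
hairpin_loop_spans <- function(structure) {
  m <- gregexpr("\\((\\.*)\\)", structure, perl = TRUE)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m) + 1L,
             end = as.integer(m) + attr(m, "match.length") - 2L)
}

#' Write sequences with structures in Vienna format
#' @param ids,sequences,structures,mfes parallel vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(ids, sequences, structures, mfes, path) {
  lines <- as.vector(rbind(paste0(">", ids), to_rna(sequences),
                           sprintf("%s (%.2f)", structures, mfes)))
  writeLines(lines, path)
  invisible(path)
}
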