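test_that("the bundled fold engine matches exhaustive enumeration at small n", {
  set.seed(4)
  cases <- c("GCGCGCAAAAGCGCGC",
             "GGGGAAAACCCC",
             replicate(6, paste(sample(c("A", "C", "G", "U"), 15, TRUE),
                                collapse = "")))
  for (s in cases) {
    expect_equal(fold(s)$mfe, oracle_fold_energy(s), info = s)
  }
  # the reported structure's own energy equals the reported MFE
  for (s in cases[1:3]) {
    f <- fold(s)
    partner <- paired_positions(f$structure)
    pairs <- which(!is.na(partner) & partner > seq_along(partner))
    e <- sum(vapply(pairs, function(i)
      pair_e(substr(to_rna(s), i, i),
             substr(to_rna(s), partner[i], partner[i])), numeric(1)))
    nloops <- nrow(hairpin_loop_spans(f$structure))
    expect_equal(e + 4 * nloops, f$mfe, info = s)
  }
})

test_that("fold handles canonical hairpins, homopolymers and bad input", {
  hp <- paste0(strrep("GC", 5), "AAAA", strrep("GC", 5))
  f <- fold(hp)
  partner <- paired_positions(f$structure)
  expect_equal(sum(!is.na(partner)), 20) # all stem bases paired
  expect_lt(f$mfe, 0)

  fa <- fold(strrep("A", 50))
  expect_equal(fa$mfe, 0)
  expect_equal(fa$structure, strrep(".", 50))

  expect_error(fold("ACGTX"), "alphabet")
})

test_that("folding is symmetric under reverse complementation", {
  # the symmetric parameterization excludes wobble: under complementation a
  # G:U pair maps to A:C, which cannot pair, so symmetry requires gu = 0
  sym <- c(gc = -3, au = -2, gu = 0)
  set.seed(6)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    expect_equal(abs(fold(s, energies = sym)$mfe),
                 abs(fold(revcomp(s), energies = sym)$mfe), info = s)
  }
})

test_that("genome mapping equals a naive sliding-window scan", {
  g <- build_genome(list(), contig_length = c(chrA = 3000L, chrB = 2000L),
                    seed = 14)$genome
  set.seed(15)
  tags <- random_tags(20, len = 18, seed = 15)
  # plant a few tags so there are guaranteed hits, one reverse-strand
  tags$sequence[1] <- substr(g[["chrA"]], 101, 118)
  tags$sequence[2] <- revcomp(substr(g[["chrB"]], 501, 518))
  tags <- tags[!duplicated(tags$sequence), ]
  hits <- map_to_genome(tags, g, max_mismatch = 1L)
  for (i in seq_len(nrow(tags))) {
    o <- oracle_map(tags$sequence[i], g, max_mm = 1L)
    h <- hits[hits$tag_sequence == tags$sequence[i], ]
    expect_equal(nrow(h), nrow(o))
    if (nrow(o) > 0) {
      expect_setequal(paste(h$contig, h$start, h$strand),
                      paste(o$contig, o$start, o$strand))
    }
  }
  expect_equal(nrow(map_to_genome(
    data.frame(sequence = strrep("ACGT", 5), count = 1L), g)), 0)
  expect_error(map_to_genome(tags, c(chr1 = "ACGT", chr1 = "ACGT")),
               "duplicated")
})

test_that("precursor excision cuts two clipped windows around each hit", {
  g <- list(chr1 = paste(rep("ACGT", 2500), collapse = ""))
  g <- c(chr1 = g$chr1)
  hit <- data.frame(tag_sequence = substr(g[["chr1"]], 5001, 5022),
                    count = 9L, contig = "chr1", start = 5000L, end = 5022L,
                    strand = "+", mismatches = 0L)
  w <- excise_precursors(hit, g, flank = 150L)
  expect_equal(nrow(w), 2)
  expect_true(all(nchar(w$sequence) <= 192))
  expect_equal(w$mature_offset[1], 150)
  expect_equal(w$mature_offset[2], 20)
  expect_equal(substr(w$sequence[1], w$mature_offset[1] + 1,
                      w$mature_offset[1] + 22), hit$tag_sequence)

  near_start <- data.frame(tag_sequence = substr(g[["chr1"]], 11, 32),
                           count = 1L, contig = "chr1", start = 10L,
                           end = 32L, strand = "+", mismatches = 0L)
  wc <- excise_precursors(near_start, g, flank = 150L)
  expect_equal(wc$start[1], 0) # left-clipped
  expect_equal(wc$mature_offset[1], 10)

  # minus-strand windows are reverse-complemented with the offset remapped
  mhit <- data.frame(tag_sequence = revcomp(substr(g[["chr1"]], 5001, 5022)),
                     count = 1L, contig = "chr1", start = 5000L, end = 5022L,
                     strand = "-", mismatches = 0L)
  wm <- excise_precursors(mhit, g, flank = 150L)
  expect_equal(substr(wm$sequence[1], wm$mature_offset[1] + 1,
                      wm$mature_offset[1] + 22), mhit$tag_sequence)
})

test_that("MFEI arithmetic follows the AMFE/GC definition", {
  expect_equal(compute_mfei(-50, 100, 50), c(amfe = 50, mfei = 1))
  expect_equal(compute_mfei(-35, 100, 50)[["mfei"]], 0.70)
  expect_equal(compute_mfei(0, 100, 50)[["mfei"]], 0)
  expect_error(compute_mfei(-50, 100, 0), "GC")
  # MFEI is invariant under U<->T rewriting of the precursor
  s <- "TGCAGGTGAGATGATACCGTCAGCTAAGCTGACGGTATCATCTCACCTGCA"
  w <- function(x) list(sequence = x, mature_offset = 0L,
                        tag_sequence = substr(x, 1, 22))
  expect_equal(evaluate_precursor(w(s))$mfei,
               evaluate_precursor(w(to_rna(s)))$mfei)
})

test_that("hairpin criteria accept designed stems and name failure reasons", {
  d <- hairpin_design("TGCAGGTGAGATGATACCGTCA", arm = "5p")
  prec <- make_hairpin_precursor(d, rng_seed = 2)
  ev <- evaluate_precursor(list(sequence = prec, mature_offset = 0L,
                                tag_sequence = d$mature))
  cr <- hairpin_criteria(ev)
  expect_true(cr$pass)
  expect_length(cr$reasons, 0)
  expect_equal(ev$mature_arm, "5p")

  # mature centered on the terminal loop must fail with a loop reason
  across <- list(sequence = prec, mature_offset = 15L,
                 tag_sequence = substr(prec, 16, 37))
  cr2 <- hairpin_criteria(evaluate_precursor(across))
  expect_false(cr2$pass)
  expect_true(any(grepl("loop", cr2$reasons)))
})

test_that("random genomic windows rarely satisfy the hairpin criteria", {
  g <- build_genome(list(), contig_length = c(chr1 = 20000L), seed = 77)$genome
  set.seed(78)
  starts <- sample(20000 - 192, 40)
  pass <- vapply(starts, function(s) {
    win <- substr(g[["chr1"]], s, s + 191)
    ev <- evaluate_precursor(list(sequence = win, mature_offset = 20L,
                                  tag_sequence = substr(win, 21, 42)))
    hairpin_criteria(ev)$pass
  }, logical(1))
  expect_lt(mean(pass), 0.5)
})

test_that("novel calling gates on MFEI and copy number monotonically", {
  cand <- data.frame(
    window_id = c("w1", "w2", "w3", "w4"),
    tag_sequence = c("TGCAGGTGAGATGATACCGTCA", "ACCGTGTTTCTCTGCCCAATCAG",
                     "TTGTCTCACTGCCTGTTGCACT", "GTGAGCCAAGCAAGTAGTGTCGC"),
    count = c(10L, 4L, 7L, 8L),
    strand = c("+", "+", "-", "+"),
    mfei = c(0.95, 0.95, 0.69, 0.70),
    mature_arm = c("5p", "3p", "3p", "3p"),
    pass = TRUE, stringsAsFactors = FALSE)
  calls <- call_novel(cand)
  expect_equal(nrow(calls), 2) # count-4 and mfei-0.69 rejected; 0.70 kept
  expect_equal(calls$name, c("mko-miRN1-5p", "mko-miRN2-3p"))
  expect_equal(calls$read_count, c(10L, 8L))
  # relaxing either gate never removes a call
  relaxed <- call_novel(cand, mfei_threshold = 0.6, copy_threshold = 4L)
  expect_true(all(calls$mature_sequence %in% relaxed$mature_sequence))
  expect_equal(nrow(relaxed), 4)
  # same mature at two loci collapses to the max-MFEI locus
  dup <- rbind(cand[1, ], cand[1, ])
  dup$window_id <- c("wa", "wb"); dup$mfei <- c(0.8, 1.2)
  expect_equal(call_novel(dup)$mfei, 1.2)
})

test_that("planted hairpins are recovered exactly; low-copy ones are not called", {
  designs <- list(
    hairpin_design("TGCAGGTGAGATGATACCGTCA", arm = "5p", position = 3000,
                   copy_number = 10L, name = "hp1"),
    hairpin_design("ACCGTGTTTCTCTGCCCAATCAG", arm = "3p", position = 9000,
                   strand = "-", copy_number = 7L, name = "hp2",
                   stem_mismatches = 2L),
    hairpin_design("TTGTCTCACTGCCTGTTGCACT", arm = "5p", position = 15000,
                   copy_number = 5L, name = "hp3"))
  g <- build_genome(designs, contig_length = c(chr1 = 20000L), seed = 55)
  tags <- data.frame(
    sequence = vapply(designs, function(d) d$mature, character(1)),
    count = vapply(designs, function(d) d$copy_number, integer(1)))
  res <- discover_novel(tags, g$genome)
  expect_equal(nrow(res$calls), 3) # sensitivity 1.0
  expect_setequal(canonicalize_sequence(res$calls$mature_sequence),
                  tags$sequence)
  m <- merge(data.frame(mature = tags$sequence, planted = tags$count),
             data.frame(mature = canonicalize_sequence(res$calls$mature_sequence),
                        called = res$calls$read_count))
  expect_equal(m$called, m$planted)
  expect_true(all(res$calls$mfei >= 0.70))

  # below the copy gate nothing is called
  low <- tags; low$count <- c(4L, 3L, 2L)
  expect_equal(nrow(discover_novel(low, g$genome)$calls), 0)
})
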