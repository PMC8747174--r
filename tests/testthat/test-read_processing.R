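test_that("adapter trimming removes the leftmost adapter-prefix match", {
  r <- function(s) data.frame(read_id = "r", sequence = s,
                              quality = strrep("I", nchar(s)))
  out <- trim_adapter(r("ACGTACGTAGATCGGA"), "AGATCGGAAGAGC", 8)
  expect_equal(out$sequence, "ACGTACGT")
  expect_equal(out$quality, "IIIIIIII")

  untouched <- trim_adapter(r("ACGTACGTACGTACGT"), "AGATCGGAAGAGC", 8)
  expect_equal(untouched$sequence, "ACGTACGTACGTACGT")
  expect_false(untouched$adapter_found)

  empty <- trim_adapter(r("AGATCGGAAGAGC"), "AGATCGGAAGAGC", 8)
  expect_equal(empty$sequence, "")

  # leftmost match wins when the adapter prefix occurs twice
  twice <- trim_adapter(r("AAAAGATCGGAAGATCGGAA"), "AGATCGGA", 8)
  expect_equal(twice$sequence, "AAA")

  # a partial terminal match shorter than min_overlap is not trimmed
  part <- trim_adapter(r("ACGTACGTACGTAGATC"), "AGATCGGAAGAGC", 8)
  expect_false(part$adapter_found)
})

test_that("mean-quality filtering uses a strict Q30 boundary", {
  mk <- function(q) data.frame(read_id = "r", sequence = strrep("A", length(q)),
                               quality = rawToChar(as.raw(q + 33L)))
  expect_true(quality_keep(mk(rep(40, 20))))
  expect_false(quality_keep(mk(rep(20, 20))))
  # mean 29.95: 19 bases at Q30 and one at Q29 -> dropped
  expect_false(quality_keep(mk(c(rep(30, 19), 29))))
  expect_true(quality_keep(mk(rep(30, 20))))
  # FASTA input (no qualities) keeps everything with a notice
  expect_message(
    keep <- quality_keep(data.frame(read_id = "r", sequence = "ACGT",
                                    quality = NA_character_)),
    "skipped")
  expect_true(keep)
})

test_that("length filtering keeps the inclusive 16-40 nt range", {
  tags <- data.frame(sequence = c(strrep("A", 15), strrep("C", 16),
                                  strrep("G", 40), strrep("T", 41)),
                     count = c(2L, 3L, 4L, 5L))
  lf <- length_filter(tags)
  expect_equal(nchar(lf$tags$sequence), c(16, 40))
  expect_equal(lf$removed_tags, 2)
  expect_equal(lf$removed_reads, 7)
})

test_that("collapsing counts multiplicities and conserves reads", {
  reads <- c(rep("ACGTACGTACGTACGTA", 3), rep("TTTTACGTACGTACGTA", 2))
  tags <- collapse_unique(reads)
  expect_equal(tags$count, c(3L, 2L))
  expect_equal(sum(tags$count), length(reads))

  distinct <- collapse_unique(c("AAAACCCCGGGGTTTTA", "CCCCGGGGTTTTAAAAC"))
  expect_true(all(distinct$count == 1L))
  expect_equal(nrow(collapse_unique(character(0))), 0)
})

test_that("trimming and collapsing commute on error-free reads", {
  planted <- data.frame(ref_id = c("a", "b"), family = NA,
                        sequence = c("TTTGGATTGAAGGGAGCTCTA",
                                     "TGCAGGTGAGATGATACCGTCA"),
                        copy_number = c(30L, 20L))
  cfg <- simulation_config(seed = 5, n_reads = 50,
                           planted_conserved = planted)
  sim <- simulate_library(cfg)
  trim_then_collapse <- collapse_unique(
    trim_adapter(sim$reads, cfg$adapter)$sequence)
  collapsed <- collapse_unique(sim$reads$sequence)
  collapse_then_trim <- trim_adapter(
    data.frame(read_id = seq_len(nrow(collapsed)),
               sequence = collapsed$sequence), cfg$adapter)
  collapse_then_trim <- data.frame(sequence = collapse_then_trim$sequence,
                                   count = collapsed$count)
  ord <- order(-collapse_then_trim$count, collapse_then_trim$sequence)
  expect_equal(trim_then_collapse,
               `rownames<-`(collapse_then_trim[ord, ], NULL))
})

test_that("ncRNA removal matches a brute-force substring scan", {
  contam <- make_contaminants(seed = 9)
  set.seed(10)
  # half random tags, half planted fragments of contaminants
  frag <- vapply(1:10, function(i) {
    src <- contam$sequence[sample(nrow(contam), 1)]
    s <- sample(nchar(src) - 21, 1)
    substr(src, s, s + 20)
  }, character(1))
  tags <- rbind(random_tags(10, seed = 11),
                data.frame(sequence = frag, count = 2L))
  tags <- tags[!duplicated(tags$sequence), ]
  res <- remove_ncrna(tags, contam)
  # oracle: plain grepl containment on both strands
  oracle_removed <- vapply(tags$sequence, function(tg)
    any(grepl(tg, contam$sequence, fixed = TRUE) |
        grepl(tg, revcomp(contam$sequence), fixed = TRUE)),
    logical(1), USE.NAMES = FALSE)
  expect_equal(res$removed$sequence, tags$sequence[oracle_removed])
  expect_equal(sum(res$removed_by_class), sum(tags$count[oracle_removed]))
  expect_equal(nrow(res$tags) + nrow(res$removed), nrow(tags))
})

test_that("contaminant class attribution is deterministic and complete", {
  site <- "ACGTACGTACGTACGTACGTA"
  contam <- data.frame(
    read_id = c("r1|rRNA", "t1|tRNA"),
    sequence = c(paste0(strrep("G", 30), site, strrep("C", 30)),
                 paste0(site, strrep("GGCA", 8))))
  tags <- data.frame(sequence = c(site, "GATTACAGATTACAGATTACA"),
                     count = c(5L, 1L))
  res <- remove_ncrna(tags, contam)
  # matches both classes; rRNA has attribution priority
  expect_equal(res$removed$class, "rRNA")
  expect_equal(res$tags$sequence, "GATTACAGATTACAGATTACA")
  expect_error(
    remove_ncrna(tags, data.frame(read_id = "anon", sequence = "ACGT")),
    "class label")
})

test_that("simulated contaminant reads are fully removed and attributed", {
  cfg <- simulation_config(seed = 21, n_reads = 500,
                           contaminant_fraction = 0.2)
  sim <- simulate_library(cfg)
  res <- clean_reads(sim$reads, adapter = cfg$adapter,
                     contaminants = sim$contaminants)
  expect_equal(sum(res$report$removed_by_class), 100)
})

test_that("read counts are conserved through cleaning on fuzzed libraries", {
  for (seed in c(1, 2, 3)) {
    cfg <- simulation_config(seed = seed, n_reads = 300,
                             contaminant_fraction = 0.15)
    sim <- simulate_library(cfg)
    # degrade some qualities so the quality filter also fires
    set.seed(seed)
    drop <- sample(nrow(sim$reads), 30)
    sim$reads$quality[drop] <- strrep("5", nchar(sim$reads$sequence[drop]))
    rep <- clean_reads(sim$reads, adapter = cfg$adapter,
                       contaminants = sim$contaminants)$report
    expect_equal(rep$total_reads,
                 rep$surviving_reads + rep$removed_low_quality +
                 rep$removed_short_long + sum(rep$removed_by_class))
    expect_lte(rep$unique_tags, rep$trimmed_reads)
  }
})

test_that("length distribution reports per-length shares and the mode", {
  tags <- data.frame(sequence = c(strrep("A", 21), strrep("C", 24),
                                  strrep("G", 24)), count = 1L)
  ld <- length_distribution(tags)
  expect_equal(ld$percent[ld$length == 24], 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(attr(ld, "argmax"), 24)
  expect_equal(sum(ld$percent), 100)

  single <- length_distribution(data.frame(sequence = strrep("A", 19),
                                           count = 7L))
  expect_equal(single$percent, 100)
  expect_equal(attr(single, "argmax"), 19)
})

test_that("a 24-nt-peaked simulation yields an empirical 24-nt mode", {
  cfg <- simulation_config(seed = 31, n_reads = 2000)
  sim <- simulate_library(cfg)
  res <- clean_reads(sim$reads, adapter = cfg$adapter)
  expect_equal(attr(res$length_dist, "argmax"), 24)
})
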