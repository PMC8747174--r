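#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `delta_ct = ct_target - ct_reference` normalizes against
#' the endogenous control (the U6 role); `delta_delta_ct` subtracts the mean
#' delta-Ct of the calibrator miRNA (whose expression is thereby set to 1),
#' and `fold_change = 2^-delta_delta_ct`. Per-miRNA summaries use the mean
#' delta-delta-Ct (i.e. the geometric mean of replicate folds), so the
#' calibrator's summary fold is exactly 1. When a `biological_replicate`
#' column is present, technical replicates are averaged within each
#' biological replicate first.
#'
#' @param ct data.frame with columns `mirna`, `replicate`, `ct_target`,
#'   `ct_reference` and optionally `biological_replicate`. Ct values must
#'   lie in (0, 45).
#' @param calibrator name of the calibrator miRNA (present in `ct`).
#' @return list with `per_replicate` (replicate-level delta-Ct,
#'   delta-delta-Ct, fold and log10 fold) and `summary` (per miRNA:
#'   `delta_ct`, `delta_delta_ct`, `fold_change`, `log10_fold`, `sd` of the
#'   replicate log10 folds, `n_replicates`).
#' @export
#' @examples
#' ct <- data.frame(mirna = rep(c("cal", "x"), each = 2),
#'                  replicate = rep(1:2, 2),
#'                  ct_target = c(25, 25, 23, 23), ct_reference = 18)
#' ddct(ct, calibrator = "cal")$summary
ddct <- function(ct, calibrator) {
  need <- c("mirna", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(ct)))
    stop("ct table must have columns: ", paste(need, collapse = ", "))
  bad <- which(is.na(ct$ct_reference) | is.na(ct$ct_target))
  if (length(bad) > 0)
    stop("missing Ct for record: miRNA ", ct$mirna[bad[1]], ", replicate ",
         ct$replicate[bad[1]])
  rng <- c(ct$ct_target, ct$ct_reference)
  if (any(rng <= 0 | rng >= 45))
    stop("Ct values must lie strictly between 0 and 45 cycles")
  if (!calibrator %in% ct$mirna)
    stop("calibrator '", calibrator, "' absent from the Ct table")
  ct$delta_ct <- ct$ct_target - ct$ct_reference
  if ("biological_replicate" %in% names(ct)) {
    agg <- stats::aggregate(delta_ct ~ mirna + biological_replicate,
                            data = ct, FUN = mean)
    agg$replicate <- agg$biological_replicate
    ct <- agg
  }
  cal_mean <- mean(ct$delta_ct[ct$mirna == calibrator])
  ct$delta_delta_ct <- ct$delta_ct - cal_mean
  ct$fold_change <- 2^(-ct$delta_delta_ct)
  ct$log10_fold <- log10(ct$fold_change)
  per <- ct[order(ct$mirna, ct$replicate),
            c("mirna", "replicate", "delta_ct", "delta_delta_ct",
              "fold_change", "log10_fold")]
  rownames(per) <- NULL
  groups <- split(per, per$mirna)
  summ <- do.call(rbind, lapply(groups, function(g) {
    ddc <- mean(g$delta_delta_ct)
    data.frame(mirna = g$mirna[1], delta_ct = mean(g$delta_ct),
               delta_delta_ct = ddc, fold_change = 2^(-ddc),
               log10_fold = log10(2^(-ddc)),
               sd = stats::sd(g$log10_fold),
               n_replicates = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(per_replicate = per, summary = summ)
}

# Compact letter display by insert-and-absorb over a significance matrix.
# `signif` is a logical matrix (TRUE = significantly different); groups are
# processed in the given order and letters assigned in that order.
compact_letters <- function(signif) {
  g <- rownames(signif)
  sets <- list(g) # letter classes: groups sharing a letter
  for (i in seq_along(g)) for (j in seq_len(i - 1L)) {
    if (!signif[g[i], g[j]]) next
    for (k in seq_along(sets)) {
      if (all(c(g[i], g[j]) %in% sets[[k]])) {
        a <- setdiff(sets[[k]], g[i])
        b <- setdiff(sets[[k]], g[j])
        sets[[k]] <- a
        sets[[length(sets) + 1L]] <- b
      }
    }
    # absorb classes contained in another
    drop <- rep(FALSE, length(sets))
    for (k in seq_along(sets)) for (l in seq_along(sets)) {
      if (k != l && !drop[l] && all(sets[[k]] %in% sets[[l]]) &&
          (length(sets[[k]]) < length(sets[[l]]) || k > l))
        drop[k] <- TRUE
    }
    sets <- sets[!drop]
  }
  # order letter classes by the first (highest-ranked) member they contain
  first <- vapply(sets, function(s) min(match(s, g)), numeric(1))
  sets <- sets[order(first)]
  vapply(g, function(x) {
    paste(letters[which(vapply(sets, function(s) x %in% s, logical(1)))],
          collapse = "")
  }, character(1))
}

#' Compact-letter groups from ANOVA and Tukey's HSD
#'
#' One-way ANOVA of replicate log10 fold changes across miRNAs followed by
#' Tukey's honest significant difference test at level `alpha`; miRNAs
#' sharing a letter are not significantly different. Letters are assigned
#' deterministically in order of descending mean expression. miRNAs with
#' fewer than 2 replicates are excluded with a warning; with a single
#' miRNA the answer is the letter "a".
#'
#' @param records replicate-level data: the `per_replicate` element of
#'   [ddct()] (or any data.frame with `mirna` and `log10_fold`).
#' @param alpha significance level (default 0.05).
#' @return data.frame `mirna`, `mean_log10`, `letters`, ordered by
#'   descending mean.
#' @export
letter_groups <- function(records, alpha = 0.05) {
  if (!is.null(records$per_replicate)) records <- records$per_replicate
  nrep <- table(records$mirna)
  few <- names(nrep)[nrep < 2]
  if (length(few) > 0) {
    warning("excluded (fewer than 2 replicates): ", paste(few, collapse = ", "))
    records <- records[!records$mirna %in% few, , drop = FALSE]
  }
  means <- sort(tapply(records$log10_fold, records$mirna, mean),
                decreasing = TRUE)
  g <- names(means)
  if (length(g) == 0)
    return(data.frame(mirna = character(), mean_log10 = numeric(),
                      letters = character(), stringsAsFactors = FALSE))
  if (length(g) == 1L)
    return(data.frame(mirna = g, mean_log10 = unname(means), letters = "a",
                      stringsAsFactors = FALSE))
  # hyphen-free factor labels so Tukey pair names parse unambiguously
  safe <- setNames(paste0("g", seq_along(g)), g)
  records$grp <- factor(safe[records$mirna], levels = unname(safe))
  fit <- stats::aov(log10_fold ~ grp, data = records)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
  signif <- matrix(FALSE, length(g), length(g), dimnames = list(g, g))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  back <- setNames(names(safe), safe)
  for (r in seq_along(pairs)) {
    a <- back[[pairs[[r]][1]]]; b <- back[[pairs[[r]][2]]]
    sig <- tk[r, "p adj"] < alpha
    signif[a, b] <- sig
    signif[b, a] <- sig
  }
  data.frame(mirna = g, mean_log10 = unname(means),
             letters = unname(compact_letters(signif)),
             stringsAsFactors = FALSE)
}

#' Read a Ct table from TSV
#' @param path TSV with columns `mirna`, `replicate`, `ct_target`,
#'   `ct_reference` (and optionally `biological_replicate`).
#' @return data.frame.
#' @export
read_ct_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
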