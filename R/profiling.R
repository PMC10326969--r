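#' Filter targets by per-sample coverage
#'
#' Retains only targets whose every sample profile (each cell line,
#' replicate and timepoint present in the dataset) has at least `min_reads`
#' mutated reads; a target absent from a sample counts as zero there. A
#' removal log is attached as attribute `"removed"`.
#'
#' @param ds A [screen_dataset()] with per-sample (pre-pooling) profiles.
#' @param min_reads Coverage threshold (default 100).
#' @return Filtered `screen_dataset`.
#' @export
filter_guides <- function(ds, min_reads = 100) {
  tot <- sample_totals(ds)
  samples <- unique(tot[c("cell_line", "replicate", "timepoint")])
  n_samples <- nrow(samples)
  per_target <- rowsum(as.numeric(tot$total >= min_reads), tot$target_id)
  present <- rowsum(rep(1, nrow(tot)), tot$target_id)
  ok <- rownames(per_target)[per_target[, 1L] == n_samples &
                               present[, 1L] == n_samples]
  removed <- setdiff(names(ds$targets), ok)
  if (!length(ok))
    warning("all targets fall below the ", min_reads, "-read threshold")
  counts <- ds$counts[ds$counts$target_id %in% ok, , drop = FALSE]
  out <- if (nrow(counts)) {
    screen_dataset(ds$targets[ok], counts, ds$control_line)
  } else {
    structure(list(targets = ds$targets[ok],
                   counts = counts, control_line = ds$control_line),
              class = "screen_dataset")
  }
  attr(out, "removed") <- removed
  out
}

#' Remove outcomes seen in a single read overall
#'
#' Drops outcomes whose summed count over all samples equals one; totals are
#' recomputed after removal. An outcome with one read in each of two samples
#' (sum two) is kept.
#'
#' @param ds A [screen_dataset()].
#' @return Filtered `screen_dataset`.
#' @export
drop_singletons <- function(ds) {
  k <- paste(ds$counts$target_id, ds$counts$outcome, sep = "\r")
  tot <- rowsum(ds$counts$reads, k)
  singles <- rownames(tot)[tot[, 1L] == 1]
  counts <- ds$counts[!k %in% singles, , drop = FALSE]
  screen_dataset(ds$targets, counts, ds$control_line)
}

#' Pool replicates and/or timepoints
#'
#' Sums read counts over the pooled axes, leaving one profile per
#' (cell line, target) when both axes are pooled. Pooled axes are collapsed
#' to `replicate = 0`, `timepoint = "pooled"`.
#'
#' @param ds A [screen_dataset()].
#' @param over Axes to pool, subset of `c("replicate", "timepoint")`.
#' @return Pooled `screen_dataset`.
#' @export
pool_samples <- function(ds, over = c("replicate", "timepoint")) {
  over <- match.arg(over, several.ok = TRUE)
  counts <- ds$counts
  if ("replicate" %in% over) counts$replicate <- 0L
  if ("timepoint" %in% over) counts$timepoint <- "pooled"
  screen_dataset(ds$targets, counts, ds$control_line)
}

#' Apply the screen's standard filtering pipeline
#'
#' Coverage filter on raw per-sample profiles, then removal of single-read
#' outcomes, then pooling over replicates and timepoints — in that order.
#'
#' @inheritParams filter_guides
#' @return Pooled, filtered `screen_dataset`.
#' @export
standard_pipeline <- function(ds, min_reads = 100) {
  pool_samples(drop_singletons(filter_guides(ds, min_reads)))
}

# frequency table per (cell_line, replicate, timepoint, target):
# counts with an extra freq column (fraction of mutated reads)
outcome_frequencies <- function(ds) {
  k <- paste(ds$counts$cell_line, ds$counts$replicate,
             ds$counts$timepoint, ds$counts$target_id, sep = "\r")
  tot <- rowsum(ds$counts$reads, k)
  counts <- ds$counts
  counts$freq <- counts$reads / tot[match(k, rownames(tot)), 1L]
  counts
}

# annotations for every distinct (target, outcome) pair in the dataset
dataset_annotations <- function(ds, ...) {
  pk <- paste(ds$counts$target_id, ds$counts$outcome, sep = "\r")
  up <- !duplicated(pk)
  tids <- ds$counts$target_id[up]
  outs <- ds$counts$outcome[up]
  parts <- split(seq_along(outs), tids)
  ann <- do.call(rbind, lapply(names(parts), function(tid) {
    idx <- parts[[tid]]
    a <- annotate_outcomes(ds$targets[[tid]], outs[idx], ...)
    a$target_id <- tid
    a
  }))
  rownames(ann) <- NULL
  ann
}

#' Mean outcome-category composition per cell line
#'
#' Per target, category frequencies are computed over mutated reads (they
#' sum to 1); the table entry is the unweighted mean over targets.
#'
#' @param ds A pooled [screen_dataset()].
#' @param ... Passed to [classify_outcome()] (e.g. `mh_threshold`).
#' @return data.frame `cell_line`, `category`, `mean_freq`; per cell line
#'   the `mean_freq` values sum to 1.
#' @export
category_table <- function(ds, ...) {
  fr <- outcome_frequencies(ds)
  ann <- dataset_annotations(ds, ...)
  pk <- paste(fr$target_id, fr$outcome, sep = "\r")
  fr$category <- ann$category[match(pk, paste(ann$target_id, ann$outcome,
                                              sep = "\r"))]
  cats <- outcome_categories()
  res <- expand.grid(category = cats,
                     cell_line = sort(unique(fr$cell_line)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # per (line, target): category freq; then mean over targets
  k <- paste(fr$cell_line, fr$target_id, fr$category, sep = "\r")
  catf <- rowsum(fr$freq, k)
  parts <- strsplit(rownames(catf), "\r", fixed = TRUE)
  df <- data.frame(cell_line = vapply(parts, `[[`, "", 1L),
                   target_id = vapply(parts, `[[`, "", 2L),
                   category = vapply(parts, `[[`, "", 3L),
                   f = catf[, 1L], stringsAsFactors = FALSE)
  n_targets <- rowsum(rep(1, sum(!duplicated(paste(df$cell_line,
                                                   df$target_id)))),
                      df$cell_line[!duplicated(paste(df$cell_line,
                                                     df$target_id))])
  s <- rowsum(df$f, paste(df$cell_line, df$category, sep = "\r"))
  key <- paste(res$cell_line, res$category, sep = "\r")
  res$mean_freq <- ifelse(key %in% rownames(s),
                          s[match(key, rownames(s)), 1L], 0)
  res$mean_freq <- res$mean_freq / n_targets[res$cell_line, 1L]
  res
}

# per (line, target, category) frequency table used by the LFC routines
category_frequencies <- function(ds, ...) {
  fr <- outcome_frequencies(ds)
  ann <- dataset_annotations(ds, ...)
  pk <- paste(fr$target_id, fr$outcome, sep = "\r")
  fr$category <- ann$category[match(pk, paste(ann$target_id, ann$outcome,
                                              sep = "\r"))]
  k <- paste(fr$cell_line, fr$target_id, fr$category, sep = "\r")
  catf <- rowsum(fr$freq, k)
  parts <- strsplit(rownames(catf), "\r", fixed = TRUE)
  data.frame(cell_line = vapply(parts, `[[`, "", 1L),
             target_id = vapply(parts, `[[`, "", 2L),
             category = vapply(parts, `[[`, "", 3L),
             freq = catf[, 1L], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Log2 fold changes of outcome frequencies versus control
#'
#' Per target, `log2((f_ko + eps) / (f_ctrl + eps))` with a frequency
#' pseudocount `eps`; the category-level record is the mean over targets.
#' The outcome-level variant returns per-(target, outcome) values (the
#' clustering input).
#'
#' @param ds A pooled [screen_dataset()] containing the control line.
#' @param unit `"category"` or `"outcome"`.
#' @param pseudocount Frequency pseudocount (default 0.001, i.e. 0.1%).
#' @param ... Passed to [classify_outcome()].
#' @return For `unit = "category"`: data.frame `cell_line`, `category`,
#'   `lfc`, `pseudocount`. For `unit = "outcome"`: data.frame `target_id`,
#'   `outcome`, `cell_line`, `lfc`, `pseudocount`.
#' @export
lfc <- function(ds, unit = c("category", "outcome"), pseudocount = 0.001,
                ...) {
  unit <- match.arg(unit)
  if (!ds$control_line %in% ds$counts$cell_line)
    stop("control line '", ds$control_line, "' missing from dataset")
  eps <- pseudocount
  if (unit == "category") {
    cf <- category_frequencies(ds, ...)
    lines <- setdiff(unique(cf$cell_line), ds$control_line)
    cats <- outcome_categories()
    tids <- unique(cf$target_id)
    # dense (target x category) frequency matrices per line
    fmat <- function(line) {
      sub <- cf[cf$cell_line == line, ]
      m <- matrix(0, length(tids), length(cats),
                  dimnames = list(tids, cats))
      m[cbind(match(sub$target_id, tids), match(sub$category, cats))] <-
        sub$freq
      m
    }
    f0 <- fmat(ds$control_line)
    do.call(rbind, lapply(lines, function(ln) {
      fl <- fmat(ln)
      keep <- rownames(f0)[rowSums(f0) > 0 & rowSums(fl) > 0]
      l2 <- log2((fl[keep, , drop = FALSE] + eps) /
                   (f0[keep, , drop = FALSE] + eps))
      data.frame(cell_line = ln, category = cats,
                 lfc = colMeans(l2), pseudocount = eps,
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  } else {
    fr <- outcome_frequencies(ds)
    lines <- setdiff(unique(fr$cell_line), ds$control_line)
    pk <- paste(fr$target_id, fr$outcome, sep = "\r")
    ctrl <- fr[fr$cell_line == ds$control_line, ]
    ck <- paste(ctrl$target_id, ctrl$outcome, sep = "\r")
    do.call(rbind, lapply(lines, function(ln) {
      sub <- fr[fr$cell_line == ln, ]
      sk <- paste(sub$target_id, sub$outcome, sep = "\r")
      # union of outcomes observed in this line or control, per target
      allk <- union(sk, ck)
      f_ko <- numeric(length(allk))
      f_ko[match(sk, allk)] <- sub$freq
      f_c <- numeric(length(allk))
      f_c[match(ck, allk)] <- ctrl$freq
      parts <- strsplit(allk, "\r", fixed = TRUE)
      data.frame(target_id = vapply(parts, `[[`, "", 1L),
                 outcome = vapply(parts, `[[`, "", 2L),
                 cell_line = ln,
                 lfc = log2((f_ko + eps) / (f_c + eps)),
                 pseudocount = eps, stringsAsFactors = FALSE)
    }))
  }
}

#' Kullback-Leibler divergence between two outcome profiles
#'
#' Profiles are read-count vectors named by outcome; a pseudocount is added
#' to every outcome of the union support before normalizing, which keeps
#' the divergence finite on disjoint raw supports. Reported in bits (log2).
#'
#' @param p,q Named numeric count (or frequency) vectors.
#' @param mode `"directed"` for `D_KL(p || q)`, `"symmetric"` for
#'   `(D_KL(p||q) + D_KL(q||p)) / 2`.
#' @param pseudocount Reads added per outcome (default 0.5; use 0 for exact
#'   closed-form checks).
#' @return Non-negative divergence in bits.
#' @export
profile_divergence <- function(p, q, mode = c("directed", "symmetric"),
                               pseudocount = 0.5) {
  mode <- match.arg(mode)
  keys <- union(names(p), names(q))
  if (is.null(keys)) {  # unnamed equal-length vectors
    stopifnot(length(p) == length(q))
    pv <- p + pseudocount; qv <- q + pseudocount
  } else {
    pv <- qv <- stats::setNames(numeric(length(keys)), keys)
    pv[names(p)] <- p; qv[names(q)] <- q
    pv <- pv + pseudocount; qv <- qv + pseudocount
  }
  pv <- pv / sum(pv); qv <- qv / sum(qv)
  kl <- function(x, y) {
    nz <- x > 0
    sum(x[nz] * log2(x[nz] / y[nz]))
  }
  if (mode == "directed") kl(pv, qv) else (kl(pv, qv) + kl(qv, pv)) / 2
}

#' Null expectation of a flank-matching 1bp insertion
#'
#' Probability that a uniformly random 1bp insertion at the cut matches the
#' PAM-distal flank and not the PAM-proximal one, under independent uniform
#' flanks: computed exactly by enumerating all 64 (distal, proximal, insert)
#' combinations through the flank-match classifier, and by seeded Monte
#' Carlo. By symmetry the proximal-only expectation is identical. The value
#' is 3/16 (about 19%).
#'
#' @param n_mc Monte Carlo draws (default 1e6).
#' @param seed Seed for the draws.
#' @return List with `exact` and `mc` probabilities.
#' @export
flank_match_random_expectation <- function(n_mc = 1e6, seed = 1L) {
  bases <- c("A", "C", "G", "T")
  template <- "GATTACAGGATCCTAGTCATTGG"  # pam_start 20, cut 17
  hit <- matrix(FALSE, 4L, 4L, dimnames = list(bases, bases))
  exact <- 0
  for (d in bases) for (p in bases) {
    s <- template
    substr(s, 17L, 17L) <- d   # 0-based 16 = sequence[c-1]
    substr(s, 18L, 18L) <- p   # 0-based 17 = sequence[c]
    ts <- target_site("null", s, 0L, 20L)
    for (ins in bases) {
      fm <- insertion_flank_match(ts, indel(17L, 17L, ins))
      if (identical(fm, "DISTAL_ONLY")) {
        exact <- exact + 1 / 64
        hit[d, p] <- hit[d, p] || (ins == d)
      }
    }
  }
  set.seed(seed)
  dd <- sample.int(4L, n_mc, replace = TRUE)
  pp <- sample.int(4L, n_mc, replace = TRUE)
  ii <- sample.int(4L, n_mc, replace = TRUE)
  mc <- mean(ii == dd & ii != pp)
  list(exact = exact, mc = mc)
}

#' Per-flank-pair 1bp-insertion report
#'
#' For each (PAM-distal, PAM-proximal) flank pair and cell line: the mean
#' absolute 1bp-insertion frequency over targets with that pair, and —
#' over targets with differing flanks — the PAM-proximal fraction
#' `PROXIMAL_ONLY / (PROXIMAL_ONLY + DISTAL_ONLY)` with a seeded percentile
#' bootstrap CI over targets.
#'
#' @param ds A pooled [screen_dataset()].
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @param conf Confidence level (default 0.95).
#' @return data.frame with one row per (cell_line, distal, proximal):
#'   `n_targets`, `ins1_freq`, `prox_frac`, `prox_lo`, `prox_hi`.
#' @export
insertion_report <- function(ds, n_boot = 1000L, seed = 1L, conf = 0.95) {
  fr <- outcome_frequencies(ds)
  ann <- dataset_annotations(ds)
  pk <- paste(fr$target_id, fr$outcome, sep = "\r")
  ak <- paste(ann$target_id, ann$outcome, sep = "\r")
  fr$ins1 <- ann$ins_len[match(pk, ak)] == 1L &
    ann$del_size[match(pk, ak)] == 0L
  fr$flank_match <- ann$flank_match[match(pk, ak)]
  flank <- t(vapply(ds$targets, function(t)
    c(t$chars[t$cut_index], t$chars[t$cut_index + 1L]), c("", "")))
  fr$distal <- flank[fr$target_id, 1L]
  fr$proximal <- flank[fr$target_id, 2L]
  set.seed(seed)
  alpha <- (1 - conf) / 2
  res <- list()
  for (ln in sort(unique(fr$cell_line))) {
    sub <- fr[fr$cell_line == ln, ]
    for (d in c("A", "C", "G", "T")) for (p in c("A", "C", "G", "T")) {
      tids <- names(ds$targets)[flank[, 1L] == d & flank[, 2L] == p]
      if (!length(tids)) {
        res[[length(res) + 1L]] <- data.frame(
          cell_line = ln, distal = d, proximal = p, n_targets = 0L,
          ins1_freq = NA_real_, prox_frac = NA_real_,
          prox_lo = NA_real_, prox_hi = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      s2 <- sub[sub$target_id %in% tids & sub$ins1, ]
      sum_by <- function(v, ids) {
        out <- stats::setNames(numeric(length(tids)), tids)
        if (length(v)) {
          m <- rowsum(v, ids)
          out[rownames(m)] <- m[, 1L]
        }
        out
      }
      tot1 <- sum_by(s2$freq, s2$target_id)
      px <- sum_by(s2$freq * (s2$flank_match %in% "PROXIMAL_ONLY"),
                   s2$target_id)
      dx <- sum_by(s2$freq * (s2$flank_match %in% "DISTAL_ONLY"),
                   s2$target_id)
      if (d != p && sum(px + dx) > 0) {
        pf <- sum(px) / sum(px + dx)
        bs <- vapply(seq_len(n_boot), function(i) {
          j <- sample.int(length(tids), replace = TRUE)
          den <- sum(px[j] + dx[j])
          if (den > 0) sum(px[j]) / den else NA_real_
        }, 0)
        ci <- stats::quantile(bs, c(alpha, 1 - alpha), na.rm = TRUE)
      } else {
        pf <- NA_real_; ci <- c(NA_real_, NA_real_)
      }
      res[[length(res) + 1L]] <- data.frame(
        cell_line = ln, distal = d, proximal = p,
        n_targets = length(tids), ins1_freq = mean(tot1),
        prox_frac = pf, prox_lo = ci[[1L]], prox_hi = ci[[2L]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}
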