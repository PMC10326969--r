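# Vectorized enumeration and annotation of the candidate outcome space.
# Shared by the synthetic generator (which needs generative weights per
# candidate) and the outcome predictor (which featurizes the same space).

# All deletion windows of size 1..max_del touching the cut, canonicalized
# and annotated, computed with vectorized shift loops (the per-window shift
# counts are tiny, so the while loops run only a handful of passes).
deletion_windows <- function(target, max_del = 30L, strict_span = FALSE) {
  ch <- target$chars
  n <- length(ch)
  cc <- target$cut_index
  L <- rep.int(seq_len(max_del), seq_len(max_del) + 1L)
  a <- unlist(lapply(seq_len(max_del), function(l) (cc - l):cc))
  if (strict_span) {
    keep <- a < cc & (a + L) > cc
    a <- a[keep]; L <- L[keep]
  }
  b <- a + L
  if (min(a) < 0L || max(b) > n)
    stop("target '", target$target_id, "' needs at least ", max_del + 3L,
         "bp of context on each side of the cut")
  # canonical 5' shift
  act <- which(a > 0L & ch[a] == ch[b])
  while (length(act)) {
    a[act] <- a[act] - 1L; b[act] <- b[act] - 1L
    act <- act[a[act] > 0L & ch[a[act]] == ch[b[act]]]
  }
  # microhomology: common prefix length of suffixes at a and b
  k <- integer(length(a))
  act <- which(b < n & ch[a + 1L] == ch[b + 1L])
  while (length(act)) {
    k[act] <- k[act] + 1L
    act <- act[b[act] + k[act] < n &
                 ch[a[act] + k[act] + 1L] == ch[b[act] + k[act] + 1L]]
  }
  df <- data.frame(a = a, b = b, size = L, mh_raw = k,
                   mh = pmin(k, L))
  df[!duplicated(paste(df$a, df$b)), , drop = FALSE]
}

# annotation data.frame for the full candidate space of one target
candidate_annotations <- function(target, max_del = 30L, max_ins = 2L,
                                  ins_window = 3L, strict_span = FALSE,
                                  mh_threshold = 1L, both_as_distal = TRUE) {
  cc <- target$cut_index
  dw <- deletion_windows(target, max_del, strict_span)
  Lft <- pmax(0L, cc - dw$a); Rgt <- pmax(0L, dw$b - cc)
  del <- data.frame(
    outcome = paste0("DEL:", dw$a, "-", dw$b),
    category = ifelse(dw$size == 1L, "D1",
               ifelse(dw$size == 2L, "D2",
               ifelse(dw$size <= 9L,
                      ifelse(dw$mh >= mh_threshold, "D3_9_MH", "D3_9"),
                      ifelse(dw$mh >= mh_threshold, "D10P_MH", "D10P")))),
    del_size = dw$size, ins_len = 0L, mh_len = dw$mh,
    flank_match = NA_character_,
    directionality = pmax(Lft, Rgt) / (Lft + Rgt),
    in_frame = (dw$size %% 3L) == 0L,
    del_start = dw$a, del_end = dw$b,
    stringsAsFactors = FALSE)
  # insertions: all 1..max_ins-mers at positions within ins_window of the cut
  bases <- c("A", "C", "G", "T")
  mers <- bases
  if (max_ins >= 2L)
    mers <- c(mers, as.vector(outer(bases, bases, paste0)))
  pos <- (cc - ins_window):(cc + ins_window)
  grid <- expand.grid(pos = pos, seq = mers, stringsAsFactors = FALSE)
  seen <- new.env(parent = emptyenv())
  ins_rows <- vector("list", nrow(grid))
  m <- 0L
  for (i in seq_len(nrow(grid))) {
    cl <- classify_outcome(target, indel(grid$pos[i], grid$pos[i],
                                         grid$seq[i]),
                           mh_threshold = mh_threshold,
                           both_as_distal = both_as_distal)
    key <- format_indel(cl$indel)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    m <- m + 1L
    ins_rows[[m]] <- data.frame(
      outcome = key, category = cl$category,
      del_size = 0L, ins_len = ins_len(cl$indel), mh_len = 0L,
      flank_match = if (is.na(cl$flank_match)) NA_character_
                    else cl$flank_match,
      directionality = NA_real_, in_frame = cl$in_frame,
      del_start = cl$indel$del_start, del_end = cl$indel$del_end,
      stringsAsFactors = FALSE)
  }
  ins <- do.call(rbind, ins_rows[seq_len(m)])
  ann <- rbind(del, ins)
  rownames(ann) <- NULL
  attr(ann, "n_pre_del") <- sum(seq_len(max_del) + 1L)
  attr(ann, "n_pre_ins") <- length(pos) * length(mers)
  ann
}

#' Enumerate the candidate outcome space of a target
#'
#' Candidates are every deletion of up to `max_del` nucleotides whose window
#' spans or touches the cut site, and every insertion of up to `max_ins`
#' nucleotides within `ins_window` nucleotides of the cut; all are
#' canonicalized and deduplicated.
#'
#' @param target A [target_site()] with at least `max_del + 3` bp of context
#'   on each side of the cut.
#' @param max_del Maximal deletion size (default 30).
#' @param max_ins Maximal insertion length (default 2).
#' @param ins_window Insertion position window around the cut (default 3).
#' @param strict_span Require deletions to strictly span the cut rather than
#'   just touch it (default FALSE).
#' @return Object of class `candidate_set`: list with `target_id`,
#'   `outcomes` (canonical serializations), `annotations` (the data.frame of
#'   [annotate_outcomes()] plus coordinates), and pre-deduplication counts
#'   `n_pre_del`, `n_pre_ins`.
#' @export
enumerate_candidates <- function(target, max_del = 30L, max_ins = 2L,
                                 ins_window = 3L, strict_span = FALSE) {
  cc <- target$cut_index
  n <- nchar(target$sequence)
  margin <- max_del + 3L
  if (cc < margin || n - cc < margin)
    stop("target '", target$target_id, "' needs >= ", margin,
         "bp of sequence context on each side of the cut (has ", cc,
         " / ", n - cc, ")")
  ann <- candidate_annotations(target, max_del, max_ins, ins_window,
                               strict_span)
  structure(list(target_id = target$target_id,
                 outcomes = ann$outcome,
                 annotations = ann,
                 n_pre_del = attr(ann, "n_pre_del"),
                 n_pre_ins = attr(ann, "n_pre_ins")),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> ", x$target_id, ": ", length(x$outcomes),
      " canonical candidates (", x$n_pre_del, " deletion + ",
      x$n_pre_ins, " insertion windows before deduplication)\n", sep = "")
  invisible(x)
}
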