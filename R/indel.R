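#' Indel records
#'
#' An indel is a unified edit record: the half-open interval
#' `[del_start, del_end)` of the construct (0-based) is removed and
#' `insert_seq` is put in its place. Pure deletions have an empty insert,
#' pure insertions have `del_start == del_end`, and compound events have
#' both. The identity edit (empty interval, empty insert) is not a valid
#' outcome.
#'
#' Many distinct coordinate choices can produce the same mutated sequence
#' (microhomology); [canonicalize()] picks the representative with the
#' smallest `del_start` (maximal 5' shift).
#'
#' @param del_start,del_end 0-based half-open deleted interval.
#' @param insert_seq Inserted sequence (possibly "").
#' @return Object of class `indel`.
#' @examples
#' indel(2, 6)              # 4bp deletion
#' indel(17, 17, "T")       # 1bp insertion
#' @export
indel <- function(del_start, del_end, insert_seq = "") {
  a <- as.integer(del_start); b <- as.integer(del_end)
  if (is.na(a) || is.na(b) || a < 0L || a > b)
    stop("invalid indel interval [", del_start, ",", del_end, ")")
  insert_seq <- toupper(insert_seq)
  if (grepl("[^ACGT]", insert_seq))
    stop("insert_seq must be A/C/G/T")
  if (a == b && !nzchar(insert_seq))
    stop("identity edit is not an outcome")
  structure(list(del_start = a, del_end = b, insert_seq = insert_seq),
            class = "indel")
}

#' @export
print.indel <- function(x, ...) {
  cat("<indel> ", format_indel(x), "\n", sep = "")
  invisible(x)
}

is_deletion <- function(x) !nzchar(x$insert_seq)
is_insertion <- function(x) x$del_start == x$del_end
del_size <- function(x) x$del_end - x$del_start
ins_len <- function(x) nchar(x$insert_seq)

#' Serialize / parse indels
#'
#' The serialization used in all outcome tables: `DEL:a-b` for deletions,
#' `INS:pos:SEQ` for insertions and `IND:a-b:SEQ` for compound events
#' (0-based half-open coordinates).
#'
#' @param x An `indel`.
#' @return `format_indel()`: character scalar. `parse_indel()`: an `indel`.
#' @export
format_indel <- function(x) {
  if (is_deletion(x)) {
    paste0("DEL:", x$del_start, "-", x$del_end)
  } else if (is_insertion(x)) {
    paste0("INS:", x$del_start, ":", x$insert_seq)
  } else {
    paste0("IND:", x$del_start, "-", x$del_end, ":", x$insert_seq)
  }
}

#' @rdname format_indel
#' @param s Character scalar like `"DEL:2-6"`.
#' @export
parse_indel <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1L]]
  bad <- function() stop("malformed outcome string: '", s, "'")
  if (length(parts) < 2L) bad()
  kind <- parts[[1L]]
  if (kind == "DEL") {
    if (length(parts) != 2L) bad()
    ab <- strsplit(parts[[2L]], "-", fixed = TRUE)[[1L]]
    if (length(ab) != 2L) bad()
    a <- suppressWarnings(as.integer(ab[[1L]]))
    b <- suppressWarnings(as.integer(ab[[2L]]))
    if (is.na(a) || is.na(b) || a >= b) bad()
    indel(a, b)
  } else if (kind == "INS") {
    if (length(parts) != 3L || !nzchar(parts[[3L]])) bad()
    p <- suppressWarnings(as.integer(parts[[2L]]))
    if (is.na(p)) bad()
    indel(p, p, parts[[3L]])
  } else if (kind == "IND") {
    if (length(parts) != 3L || !nzchar(parts[[3L]])) bad()
    ab <- strsplit(parts[[2L]], "-", fixed = TRUE)[[1L]]
    if (length(ab) != 2L) bad()
    a <- suppressWarnings(as.integer(ab[[1L]]))
    b <- suppressWarnings(as.integer(ab[[2L]]))
    if (is.na(a) || is.na(b) || a >= b) bad()
    indel(a, b, parts[[3L]])
  } else bad()
}

#' Apply an indel to a target sequence
#'
#' @param target A [target_site()] (or plain sequence string).
#' @param x An `indel` within bounds.
#' @return The mutated sequence string.
#' @export
apply_indel <- function(target, x) {
  s <- if (inherits(target, "target_site")) target$sequence else target
  n <- nchar(s)
  if (x$del_end > n)
    stop("indel [", x$del_start, ",", x$del_end,
         ") out of bounds for sequence of length ", n)
  paste0(substr(s, 1L, x$del_start), x$insert_seq,
         substr(s, x$del_end + 1L, n))
}

#' Canonicalize an indel
#'
#' Among all edits with the same deletion and insertion lengths that produce
#' the identical mutated sequence, returns the representative with minimal
#' `del_start` (maximal 5' shift; for insertions the inserted string is
#' rotated accordingly). Idempotent.
#'
#' @inheritParams apply_indel
#' @return Canonical `indel`.
#' @examples
#' ts <- target_site("t", paste0("AATCGATCG", "TAGG"), 0, 10)
#' format_indel(canonicalize(ts, indel(3, 7)))  # "DEL:2-6"
#' @export
canonicalize <- function(target, x) {
  ch <- if (inherits(target, "target_site")) target$chars
        else strsplit(target, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  a <- x$del_start; b <- x$del_end
  if (b > n) stop("indel [", a, ",", b, ") out of bounds (length ", n, ")")
  ins <- x$insert_seq
  if (!nzchar(ins)) {
    # pure deletion: slide the window left while flanks repeat
    while (a > 0L && ch[a] == ch[b]) { a <- a - 1L; b <- b - 1L }
    indel(a, b)
  } else {
    iv <- strsplit(ins, "", fixed = TRUE)[[1L]]
    L <- length(iv)
    # general left shift: valid iff last inserted base equals sequence[b-1];
    # the displaced base is prepended to the insert
    while (a > 0L && iv[L] == ch[b]) {
      iv <- c(ch[a], iv[-L])
      a <- a - 1L; b <- b - 1L
    }
    indel(a, b, paste(iv, collapse = ""))
  }
}

#' Microhomology length of a deletion
#'
#' For a pure deletion `[a,b)`, the microhomology length is the maximal
#' `k >= 0` with `sequence[a:a+k] == sequence[b:b+k]` evaluated on the
#' canonical (left-aligned) form. It equals the number of distinct deletion
#' windows producing the identical mutated sequence, minus one. Note the
#' value can exceed the deletion size inside homopolymer runs (overlapping
#' homology); classification caps it at the deletion size.
#'
#' @inheritParams apply_indel
#' @return Integer microhomology length in bp.
#' @examples
#' ts <- target_site("t", "AATCGATCGTAGG", 0, 10)
#' mh_length(ts, indel(2, 6))  # 3
#' @export
mh_length <- function(target, x) {
  if (!is_deletion(x) || is_insertion(x))
    stop("mh_length requires a pure deletion")
  x <- canonicalize(target, x)
  ch <- if (inherits(target, "target_site")) target$chars
        else strsplit(target, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  a <- x$del_start; b <- x$del_end
  k <- 0L
  while (b + k < n && ch[a + k + 1L] == ch[b + k + 1L]) k <- k + 1L
  k
}

# positions (0-based) at which an insertion's equivalence class sits, plus
# the rotation of the insert at each; returns list(pos0, posmax, rotate_to)
insertion_class_range <- function(ch, x) {
  n <- length(ch)
  p <- x$del_start
  iv <- strsplit(x$insert_seq, "", fixed = TRUE)[[1L]]
  L <- length(iv)
  # left shifts
  p0 <- p; iv0 <- iv
  while (p0 > 0L && iv0[L] == ch[p0]) {
    iv0 <- c(ch[p0], iv0[-L]); p0 <- p0 - 1L
  }
  # right shifts from canonical
  p1 <- p0; iv1 <- iv0
  while (p1 < n && iv1[1L] == ch[p1 + 1L]) {
    iv1 <- c(iv1[-1L], ch[p1 + 1L]); p1 <- p1 + 1L
  }
  list(p0 = p0, iv0 = iv0, pmax = p1)
}

# rotation of insert when placed at position pos within its class
insertion_at <- function(ch, x, pos) {
  cls <- insertion_class_range(ch, x)
  if (pos < cls$p0 || pos > cls$pmax) return(NULL)
  iv <- cls$iv0; p <- cls$p0
  while (p < pos) {
    iv <- c(iv[-1L], ch[p + 1L]); p <- p + 1L
  }
  paste(iv, collapse = "")
}

#' Flank match of a cut-site insertion
#'
#' 1-2bp insertions whose equivalence class includes the cut position are
#' compared to the nucleotides flanking the cut: the PAM-distal flank
#' (`sequence[c-1]`, or `sequence[c-2:c]` for 2bp inserts) and the
#' PAM-proximal flank (`sequence[c]`, or `sequence[c:c+2]`).
#'
#' @inheritParams apply_indel
#' @return One of `"DISTAL_ONLY"`, `"PROXIMAL_ONLY"`, `"BOTH"`, `"NEITHER"`,
#'   or `NA` for insertions that are longer than 2bp or cannot be placed at
#'   the cut.
#' @export
insertion_flank_match <- function(target, x) {
  stopifnot(inherits(target, "target_site"))
  if (!is_insertion(x)) stop("insertion_flank_match requires a pure insertion")
  L <- ins_len(x)
  if (L > 2L) return(NA_character_)
  ch <- target$chars
  cc <- target$cut_index
  ins_at_cut <- insertion_at(ch, x, cc)
  if (is.null(ins_at_cut)) return(NA_character_)
  if (L == 1L) {
    distal <- ch[cc]          # sequence[c-1], 0-based
    proximal <- ch[cc + 1L]   # sequence[c]
  } else {
    distal <- paste0(ch[cc - 1L], ch[cc])
    proximal <- paste0(ch[cc + 1L], ch[cc + 2L])
  }
  md <- ins_at_cut == distal
  mp <- ins_at_cut == proximal
  if (md && mp) "BOTH"
  else if (md) "DISTAL_ONLY"
  else if (mp) "PROXIMAL_ONLY"
  else "NEITHER"
}

#' Is an insertion templated from flanking sequence?
#'
#' True iff the inserted sequence (length >= 2) occurs as an exact substring
#' of the `window` bp of target sequence immediately 5' or immediately 3' of
#' the edit, after removing the deleted interval. 1bp inserts return FALSE.
#'
#' @inheritParams apply_indel
#' @param window Flank window in bp (default 10).
#' @return Logical.
#' @export
templated_insertion <- function(target, x, window = 10L) {
  if (!nzchar(x$insert_seq)) stop("templated_insertion requires an insert")
  if (ins_len(x) < 2L) return(FALSE)
  s <- if (inherits(target, "target_site")) target$sequence else target
  n <- nchar(s)
  a <- x$del_start; b <- x$del_end
  left <- substr(s, max(0L, a - window) + 1L, a)
  right <- substr(s, b + 1L, min(n, b + window))
  grepl(x$insert_seq, left, fixed = TRUE) ||
    grepl(x$insert_seq, right, fixed = TRUE)
}

#' Directionality of a deletion
#'
#' With `L = max(0, c - a)` deleted bases PAM-distal of the cut and
#' `R = max(0, b - c)` PAM-proximal, directionality is `max(L, R) / (L + R)`.
#' Deletions entirely on one side of the cut — including any 1bp deletion
#' adjacent to it — have directionality 1 by definition; a deletion symmetric
#' about the cut has directionality 0.5.
#'
#' @inheritParams apply_indel
#' @return Real in (0, 1].
#' @export
directionality <- function(target, x) {
  if (!is_deletion(x)) stop("directionality requires a pure deletion")
  if (del_size(x) == 0L) stop("zero-length deletion")
  cc <- if (inherits(target, "target_site")) target$cut_index else target
  L <- max(0L, cc - x$del_start)
  R <- max(0L, x$del_end - cc)
  max(L, R) / (L + R)
}

#' Outcome categories
#'
#' The ten outcome categories used throughout: 1bp deletions (`D1`), 2bp
#' deletions (`D2`), medium 3-9bp deletions with/without microhomology
#' (`D3_9_MH`/`D3_9`), long 10bp+ deletions with/without microhomology
#' (`D10P_MH`/`D10P`), 1-2bp cut-site insertions matching the PAM-proximal
#' or PAM-distal flank (`I12_PROX`/`I12_DIST`), and other insertions
#' including insertion-deletions, with/without a match between insert and
#' flanking sequence (`OTHER_I_MH`/`OTHER_I`).
#'
#' @return Character vector of the 10 category labels, in display order.
#' @export
outcome_categories <- function() {
  c("D1", "D2", "D3_9", "D3_9_MH", "D10P", "D10P_MH",
    "I12_DIST", "I12_PROX", "OTHER_I", "OTHER_I_MH")
}

#' Classify a mutational outcome
#'
#' Maps a canonical indel to exactly one of the ten outcome categories and
#' computes its annotations: microhomology length (capped at the deletion
#' size), flank match, directionality (pure deletions only) and frame status.
#'
#' @inheritParams apply_indel
#' @param mh_threshold Minimal microhomology length for the `_MH` split of
#'   medium/long deletions (default 1).
#' @param both_as_distal Count `BOTH`-matching 1-2bp cut insertions with the
#'   PAM-distal category (default TRUE); the flank-match flag is retained
#'   either way.
#' @param templated_window Flank window for [templated_insertion()].
#' @return A list of class `classified_outcome` with fields `indel`,
#'   `category`, `mh_len`, `flank_match`, `directionality`, `in_frame`.
#' @examples
#' ts <- target_site("t", "AATCGATCGTAGG", 0, 10)
#' classify_outcome(ts, indel(2, 6))$category  # "D3_9_MH"
#' @export
classify_outcome <- function(target, x, mh_threshold = 1L,
                             both_as_distal = TRUE, templated_window = 10L) {
  stopifnot(inherits(target, "target_site"))
  x <- canonicalize(target, x)
  size <- del_size(x)
  ilen <- ins_len(x)
  in_frame <- ((ilen - size) %% 3L) == 0L
  mh <- 0L
  fm <- NA_character_
  dir <- NA_real_
  if (ilen == 0L) {                       # pure deletion
    mh <- min(mh_length(target, x), size)
    dir <- directionality(target, x)
    category <-
      if (size == 1L) "D1"
      else if (size == 2L) "D2"
      else if (size <= 9L) { if (mh >= mh_threshold) "D3_9_MH" else "D3_9" }
      else { if (mh >= mh_threshold) "D10P_MH" else "D10P" }
  } else if (size == 0L) {                # pure insertion
    if (ilen <= 2L) fm <- insertion_flank_match(target, x)
    category <-
      if (!is.na(fm) && fm %in% c("DISTAL_ONLY", if (both_as_distal) "BOTH"))
        "I12_DIST"
      else if (!is.na(fm) && fm == "PROXIMAL_ONLY") "I12_PROX"
      else if (templated_insertion(target, x, templated_window)) "OTHER_I_MH"
      else "OTHER_I"
  } else {                                # compound insertion + deletion
    category <- if (templated_insertion(target, x, templated_window))
      "OTHER_I_MH" else "OTHER_I"
  }
  structure(list(indel = x, category = category, mh_len = mh,
                 flank_match = fm, directionality = dir,
                 in_frame = in_frame),
            class = "classified_outcome")
}

#' @export
print.classified_outcome <- function(x, ...) {
  cat("<classified_outcome> ", format_indel(x$indel), " -> ", x$category,
      " (mh=", x$mh_len,
      if (!is.na(x$flank_match)) paste0(", flank=", x$flank_match),
      if (!is.na(x$directionality))
        paste0(", dir=", signif(x$directionality, 3)),
      ", ", if (x$in_frame) "in-frame" else "frameshift", ")\n", sep = "")
  invisible(x)
}

#' Annotate a set of outcomes on one target
#'
#' Vectorized wrapper around [classify_outcome()] for serialized outcomes;
#' used by the profiling and prediction pipelines.
#'
#' @param target A [target_site()].
#' @param outcomes Character vector of serialized indels (see
#'   [format_indel()]).
#' @param ... Passed to [classify_outcome()].
#' @return A data.frame with one row per outcome: `outcome` (the input
#'   serialization), `canonical` (the canonical serialization), `category`,
#'   `del_size`, `ins_len`, `mh_len`, `flank_match`, `directionality`,
#'   `in_frame`.
#' @export
annotate_outcomes <- function(target, outcomes, ...) {
  cls <- lapply(outcomes, function(s)
    classify_outcome(target, parse_indel(s), ...))
  data.frame(
    outcome = outcomes,
    canonical = vapply(cls, function(z) format_indel(z$indel), ""),
    category = vapply(cls, `[[`, "", "category"),
    del_size = vapply(cls, function(z) del_size(z$indel), 0L),
    ins_len = vapply(cls, function(z) ins_len(z$indel), 0L),
    mh_len = vapply(cls, `[[`, 0L, "mh_len"),
    flank_match = vapply(cls, `[[`, "", "flank_match"),
    directionality = vapply(cls, `[[`, 0, "directionality"),
    in_frame = vapply(cls, `[[`, TRUE, "in_frame"),
    stringsAsFactors = FALSE)
}
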