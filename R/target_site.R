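#' Construct a Cas9 target site
#'
#' A target site is a construct sequence together with the coordinates of its
#' protospacer and PAM. All coordinates are 0-based; the blunt Cas9 cut falls
#' between `sequence[cut_index - 1]` and `sequence[cut_index]`, three
#' nucleotides upstream of the PAM (`cut_index = pam_start - 3`). The base
#' immediately 5' of the cut (`sequence[cut_index - 1]`) is the PAM-distal
#' flank; the base immediately 3' (`sequence[cut_index]`) is the PAM-proximal
#' flank.
#'
#' @param target_id Character scalar identifier.
#' @param sequence Uppercase A/C/G/T construct sequence.
#' @param protospacer_start 0-based start of the 20bp protospacer.
#' @param pam_start 0-based start of the NGG PAM.
#' @return An object of class `target_site` with fields `target_id`,
#'   `sequence`, `protospacer_start`, `pam_start` and derived `cut_index`.
#' @examples
#' ts <- target_site("t1", "GATTACAGGATCCTAGTCATTGG", 0, 20)
#' ts$cut_index  # 17
#' @export
target_site <- function(target_id, sequence, protospacer_start, pam_start) {
  stopifnot(is.character(target_id), length(target_id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("sequence must contain only A/C/G/T, got other characters in '",
         target_id, "'")
  n <- nchar(sequence)
  protospacer_start <- as.integer(protospacer_start)
  pam_start <- as.integer(pam_start)
  if (pam_start + 3L > n || pam_start < 0L)
    stop("pam_start out of bounds for target '", target_id, "'")
  if (substr(sequence, pam_start + 2L, pam_start + 3L) != "GG")
    stop("no NGG PAM at pam_start=", pam_start, " for target '", target_id,
         "' (expected GG at offsets +1,+2)")
  cut_index <- pam_start - 3L
  if (cut_index <= 0L || cut_index >= n)
    stop("cut index ", cut_index, " outside sequence for target '",
         target_id, "'")
  if (protospacer_start >= cut_index || protospacer_start < 0L)
    stop("protospacer_start must lie 5' of the cut for target '",
         target_id, "'")
  structure(
    list(target_id = target_id,
         sequence = sequence,
         chars = strsplit(sequence, "", fixed = TRUE)[[1L]],
         protospacer_start = protospacer_start,
         pam_start = pam_start,
         cut_index = cut_index),
    class = "target_site")
}

#' @export
print.target_site <- function(x, ...) {
  c <- x$cut_index
  cat("<target_site> ", x$target_id, "\n", sep = "")
  cat("  ", substr(x$sequence, 1L, c), "|",
      substr(x$sequence, c + 1L, nchar(x$sequence)), "\n", sep = "")
  cat("  length ", nchar(x$sequence), ", protospacer at ",
      x$protospacer_start, ", PAM at ", x$pam_start,
      ", cut between ", c - 1L, " and ", c, " (0-based)\n", sep = "")
  invisible(x)
}

#' Read / write a target library
#'
#' The library is a TSV with columns `target_id`, `sequence`,
#' `protospacer_start`, `pam_start` (0-based coordinates).
#'
#' @param path Path to a tab-separated file.
#' @return `read_target_library()`: a named list of [target_site()] objects.
#' @export
read_target_library <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "integer"),
                          stringsAsFactors = FALSE)
  need <- c("target_id", "sequence", "protospacer_start", "pam_start")
  if (!all(need %in% names(df)))
    stop("target library must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$target_id))
    stop("duplicate target_id in library")
  out <- lapply(seq_len(nrow(df)), function(i)
    target_site(df$target_id[i], df$sequence[i],
                df$protospacer_start[i], df$pam_start[i]))
  names(out) <- df$target_id
  out
}

#' @rdname read_target_library
#' @param targets Named list of `target_site` objects.
#' @export
write_target_library <- function(targets, path) {
  df <- data.frame(
    target_id = vapply(targets, `[[`, "", "target_id"),
    sequence = vapply(targets, `[[`, "", "sequence"),
    protospacer_start = vapply(targets, `[[`, 0L, "protospacer_start"),
    pam_start = vapply(targets, `[[`, 0L, "pam_start"),
    stringsAsFactors = FALSE)
  df <- df[order(df$target_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
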