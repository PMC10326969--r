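#' Screen datasets
#'
#' A screen dataset bundles a target library with a long-format outcome
#' count table. Each count row is keyed by sample (`cell_line`, `replicate`,
#' `timepoint`), `target_id` and serialized `outcome`, with a non-negative
#' `reads` count over mutated reads. Outcome keys are canonical (see
#' [canonicalize()]); duplicate rows are summed on construction.
#'
#' @param targets Named list of [target_site()] objects.
#' @param counts data.frame with columns `cell_line`, `replicate`,
#'   `timepoint`, `target_id`, `outcome`, `reads`.
#' @param control_line Name of the control cell line (must be present).
#' @return Object of class `screen_dataset`.
#' @export
screen_dataset <- function(targets, counts, control_line = "control") {
  need <- c("cell_line", "replicate", "timepoint", "target_id",
            "outcome", "reads")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  counts <- counts[, need]
  counts$replicate <- as.integer(counts$replicate)
  counts$timepoint <- as.character(counts$timepoint)
  counts$reads <- as.numeric(counts$reads)
  if (any(counts$reads < 0)) stop("negative read counts")
  unknown <- setdiff(unique(counts$target_id), names(targets))
  if (length(unknown))
    stop("counts reference unknown target(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  key <- paste(counts$cell_line, counts$replicate, counts$timepoint,
               counts$target_id, counts$outcome, sep = "\r")
  if (anyDuplicated(key)) {
    reads <- rowsum(counts$reads, key, reorder = FALSE)
    counts <- counts[!duplicated(key), ]
    counts$reads <- reads[match(unique(key), rownames(reads)), 1L]
  }
  if (!control_line %in% counts$cell_line)
    stop("control line '", control_line, "' not present in counts")
  rownames(counts) <- NULL
  structure(list(targets = targets, counts = counts,
                 control_line = control_line),
            class = "screen_dataset")
}

#' @export
print.screen_dataset <- function(x, ...) {
  cl <- unique(x$counts$cell_line)
  cat("<screen_dataset> ", length(x$targets), " targets, ",
      length(cl), " cell lines (control: '", x$control_line, "'), ",
      nrow(x$counts), " count rows, ",
      format(sum(x$counts$reads), big.mark = ","), " mutated reads\n",
      sep = "")
  invisible(x)
}

#' Cell lines of a dataset
#' @param ds A `screen_dataset`.
#' @param knockouts_only Drop the control line?
#' @return Character vector.
#' @export
cell_lines <- function(ds, knockouts_only = FALSE) {
  cl <- sort(unique(ds$counts$cell_line))
  if (knockouts_only) setdiff(cl, ds$control_line) else cl
}

# per-sample mutated-read totals: data.frame(cell_line, replicate,
# timepoint, target_id, total)
sample_totals <- function(ds) {
  k <- paste(ds$counts$cell_line, ds$counts$replicate, ds$counts$timepoint,
             ds$counts$target_id, sep = "\r")
  tot <- rowsum(ds$counts$reads, k)
  parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
  data.frame(cell_line = vapply(parts, `[[`, "", 1L),
             replicate = as.integer(vapply(parts, `[[`, "", 2L)),
             timepoint = vapply(parts, `[[`, "", 3L),
             target_id = vapply(parts, `[[`, "", 4L),
             total = tot[, 1L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a screen dataset from disk
#'
#' Reads a target library TSV (see [read_target_library()]) and a long
#' counts TSV with columns `cell_line`, `replicate`, `timepoint`,
#' `target_id`, `outcome`, `reads`. All outcomes are canonicalized on load;
#' rows that become identical after canonicalization are summed.
#'
#' @param library_path,counts_path TSV paths.
#' @param control_line Control cell line name.
#' @return A [screen_dataset()].
#' @export
read_screen <- function(library_path, counts_path,
                        control_line = "control") {
  targets <- read_target_library(library_path)
  counts <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE,
                              colClasses = c(cell_line = "character",
                                             timepoint = "character",
                                             target_id = "character",
                                             outcome = "character"))
  unknown <- setdiff(unique(counts$target_id), names(targets))
  if (length(unknown))
    stop("counts reference unknown target(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  # canonicalize each distinct (target, outcome) pair once
  pk <- paste(counts$target_id, counts$outcome, sep = "\r")
  up <- !duplicated(pk)
  canon <- vapply(which(up), function(i) {
    x <- tryCatch(parse_indel(counts$outcome[i]),
                  error = function(e)
                    stop("row ", i, ": ", conditionMessage(e),
                         call. = FALSE))
    tryCatch(format_indel(canonicalize(targets[[counts$target_id[i]]], x)),
             error = function(e)
               stop("row ", i, " (target ", counts$target_id[i], "): ",
                    conditionMessage(e), call. = FALSE))
  }, "")
  counts$outcome <- canon[match(pk, pk[up])]
  screen_dataset(targets, counts, control_line)
}

#' Write a screen dataset or result table to TSV
#'
#' Datasets are written with deterministic column order and rows sorted by
#' all key columns, so that outputs are diff-able across runs and
#' `write_screen()` followed by [read_screen()] round-trips exactly.
#'
#' @param ds A `screen_dataset`.
#' @param library_path,counts_path Output TSV paths.
#' @export
write_screen <- function(ds, library_path, counts_path) {
  write_target_library(ds$targets, library_path)
  df <- ds$counts
  df <- df[order(df$cell_line, df$replicate, df$timepoint,
                 df$target_id, df$outcome), ]
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_screen
#' @param table Any result data.frame.
#' @param path Output path.
#' @export
write_result_table <- function(table, path) {
  keys <- names(table)[!vapply(table, is.numeric, TRUE)]
  if (length(keys))
    table <- table[do.call(order, table[keys]), , drop = FALSE]
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
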