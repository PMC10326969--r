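#' Tabulate microhomology-deletion frequencies
#'
#' For every pure deletion with microhomology length `s >= 2` observed in
#' one cell line of a pooled dataset, computes the inter-homology distance
#' `d = deletion size - s` (bp of unique sequence lost between the homology
#' copies) and averages the outcome frequency over observations sharing
#' `(s, d)`.
#'
#' @param ds A pooled [screen_dataset()].
#' @param line Cell line to tabulate.
#' @param min_s Minimal MH size (default 2).
#' @return data.frame `s`, `d`, `y` (mean frequency), `n` (observations).
#' @export
mh_tabulate <- function(ds, line, min_s = 2L) {
  fr <- outcome_frequencies(ds)
  fr <- fr[fr$cell_line == line, ]
  if (!nrow(fr)) stop("no profiles for line '", line, "'")
  ann <- dataset_annotations(ds)
  am <- match(paste(fr$target_id, fr$outcome, sep = "\r"),
              paste(ann$target_id, ann$outcome, sep = "\r"))
  fr$mh <- ann$mh_len[am]
  fr$size <- ann$del_size[am]
  fr$pure_del <- ann$ins_len[am] == 0L & fr$size > 0L
  fr <- fr[fr$pure_del & fr$mh >= min_s, ]
  if (!nrow(fr))
    return(data.frame(s = integer(), d = integer(), y = numeric(),
                      n = integer()))
  s <- fr$mh
  d <- fr$size - s
  stopifnot(all(d + s == fr$size), all(d >= 0L))  # geometric identity
  k <- paste(s, d, sep = "\r")
  ys <- rowsum(fr$freq, k)
  ns <- rowsum(rep(1L, length(k)), k)
  parts <- strsplit(rownames(ys), "\r", fixed = TRUE)
  out <- data.frame(s = as.integer(vapply(parts, `[[`, "", 1L)),
                    d = as.integer(vapply(parts, `[[`, "", 2L)),
                    y = ys[, 1L] / ns[, 1L],
                    n = as.integer(ns[, 1L]), row.names = NULL)
  out[order(out$s, out$d), ]
}

#' Fit the exponential microhomology-deletion law
#'
#' Nonlinear least squares of `y = A * exp(B * d)` on the `(d, y)` bins of
#' one microhomology size, initialized from a log-linear regression on the
#' positive bins. `B` is expected negative: deletion frequency decays with
#' the distance between the homologous sequences.
#'
#' @param bins data.frame from [mh_tabulate()] (or any with `d`, `y`,
#'   optionally `n`).
#' @param s Microhomology size to fit (omit if `bins` holds a single size).
#' @param cell_line Optional label stored in the fit.
#' @param min_n Bins with fewer than `min_n` observations are excluded
#'   (default 3; ignored if `bins` has no `n` column).
#' @return Object of class `mh_fit` with `A`, `B`, `rss`, `n_points`,
#'   `converged`; `A`/`B` are `NA` with `converged = FALSE` when the
#'   optimizer fails.
#' @export
mh_fit <- function(bins, s = NULL, cell_line = NA_character_, min_n = 3L) {
  if (!is.null(s)) bins <- bins[bins$s == s, , drop = FALSE]
  else if ("s" %in% names(bins) && length(unique(bins$s)) > 1L)
    stop("bins span several MH sizes; pass s")
  if ("n" %in% names(bins)) bins <- bins[bins$n >= min_n, , drop = FALSE]
  new_fit <- function(A, B, rss, conv)
    structure(list(s = if (is.null(s)) unique(bins$s) else s,
                   cell_line = cell_line, A = A, B = B, rss = rss,
                   n_points = nrow(bins), converged = conv),
              class = "mh_fit")
  if (length(unique(bins$d)) < 3L)
    return(new_fit(NA_real_, NA_real_, NA_real_, FALSE))
  pos <- bins$y > 0
  init <- if (sum(pos) >= 2L) {
    cf <- stats::coef(stats::lm(log(y) ~ d, data = bins[pos, ]))
    list(A = exp(cf[[1L]]), B = cf[[2L]])
  } else list(A = max(bins$y), B = -0.1)
  # an (essentially) exact log-linear fit leaves nls nothing to do and can
  # trip a singular gradient; accept the initializer in that case
  rss0 <- sum((bins$y - init$A * exp(init$B * bins$d))^2)
  if (rss0 <= 1e-24 * max(bins$y)^2 * nrow(bins))
    return(new_fit(init$A, init$B, rss0, TRUE))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(B * d), data = bins, start = init,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(new_fit(NA_real_, NA_real_, NA_real_, FALSE))
  cf <- stats::coef(fit)
  new_fit(cf[["A"]], cf[["B"]], sum(stats::residuals(fit)^2), TRUE)
}

#' @export
print.mh_fit <- function(x, ...) {
  cat("<mh_fit> s=", x$s,
      if (!is.na(x$cell_line)) paste0(" (", x$cell_line, ")"),
      ": y = ", signif(x$A, 4), " * exp(", signif(x$B, 4), " * d), ",
      x$n_points, " bins, rss=", signif(x$rss, 3),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' @export
coef.mh_fit <- function(object, ...) c(A = object$A, B = object$B)

#' @export
predict.mh_fit <- function(object, newdata, ...) {
  d <- if (is.data.frame(newdata)) newdata$d else newdata
  object$A * exp(object$B * d)
}

#' Fit the MH law for every size and cell line, and compare
#'
#' Fits `y = A exp(B d)` for each MH size in `s_range` and each requested
#' line, and reports whether the fitted amplitude increases with MH size
#' (Spearman rank correlation of `A` vs `s`) and whether every decay rate
#' is negative — i.e. longer homologies closer together are more likely.
#'
#' @param ds A pooled [screen_dataset()].
#' @param lines Cell lines (default: all).
#' @param s_range MH sizes to fit (default 2:15).
#' @param min_n Passed to [mh_fit()].
#' @return List of class `mh_comparison`: `fits` (data.frame `cell_line`,
#'   `s`, `A`, `B`, `n_points`, `converged`) and `monotonicity`
#'   (data.frame `cell_line`, `spearman_A_s`, `all_B_negative`).
#' @export
mh_compare <- function(ds, lines = NULL, s_range = 2:15, min_n = 3L) {
  if (is.null(lines)) lines <- cell_lines(ds)
  fits <- do.call(rbind, lapply(lines, function(ln) {
    bins <- mh_tabulate(ds, ln)
    do.call(rbind, lapply(s_range, function(s) {
      f <- mh_fit(bins, s = s, cell_line = ln, min_n = min_n)
      data.frame(cell_line = ln, s = s, A = f$A, B = f$B,
                 n_points = f$n_points, converged = f$converged,
                 stringsAsFactors = FALSE)
    }))
  }))
  mono <- do.call(rbind, lapply(lines, function(ln) {
    sub <- fits[fits$cell_line == ln & fits$converged, ]
    rho <- if (nrow(sub) >= 3L)
      stats::cor(sub$s, sub$A, method = "spearman") else NA_real_
    data.frame(cell_line = ln, spearman_A_s = rho,
               all_B_negative = nrow(sub) > 0L && all(sub$B < 0),
               stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, monotonicity = mono),
            class = "mh_comparison")
}

#' @export
print.mh_comparison <- function(x, ...) {
  cat("<mh_comparison> ", length(unique(x$fits$cell_line)), " lines, ",
      sum(x$fits$converged), "/", nrow(x$fits), " fits converged\n",
      sep = "")
  print(x$monotonicity, row.names = FALSE)
  invisible(x)
}
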