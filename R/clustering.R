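#' Select outcomes for response-profile clustering
#'
#' Keeps (target, outcome) rows observed in the control line (count > 0)
#' and with a nonzero count in at least `min_lines` knockout lines; this
#' removes noise associated with stochastic dropout of rare events.
#'
#' @param ds A pooled, filtered [screen_dataset()].
#' @param min_lines Minimal number of knockout lines (default 10).
#' @return data.frame `target_id`, `outcome`.
#' @export
select_outcomes <- function(ds, min_lines = 10L) {
  cnt <- ds$counts
  pk <- paste(cnt$target_id, cnt$outcome, sep = "\r")
  in_ctrl <- unique(pk[cnt$cell_line == ds$control_line & cnt$reads > 0])
  ko <- cnt[cnt$cell_line != ds$control_line & cnt$reads > 0, ]
  kk <- paste(ko$target_id, ko$outcome, sep = "\r")
  nlines <- rowsum(rep(1, nrow(ko)),
                   paste(kk, ko$cell_line, sep = "\r"))
  # count distinct lines per (target, outcome)
  base <- sub("\r[^\r]*$", "", rownames(nlines))
  per_outcome <- rowsum(rep(1, length(base)), base)
  ok <- intersect(in_ctrl,
                  rownames(per_outcome)[per_outcome[, 1L] >= min_lines])
  parts <- strsplit(sort(ok), "\r", fixed = TRUE)
  data.frame(target_id = vapply(parts, `[[`, "", 1L),
             outcome = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Per-outcome log2 fold-change matrix across knockouts
#'
#' Rows are (target, outcome) instances passing [select_outcomes()];
#' columns are knockout cell lines; values are pseudocounted per-outcome
#' log2 fold changes versus control. Row annotations carry the outcome
#' category, control frequency, deletion size and microhomology length.
#'
#' @param ds A pooled [screen_dataset()].
#' @param rows Optional data.frame (`target_id`, `outcome`) of rows; by
#'   default [select_outcomes()] is applied.
#' @param pseudocount Frequency pseudocount (default 0.001).
#' @param min_lines Passed to [select_outcomes()] when `rows` is NULL.
#' @return Object of class `lfc_matrix`: list with `lfc` (numeric matrix)
#'   and `annotations` (data.frame incl. `target_id`, `outcome`,
#'   `category`, `control_freq`, `del_size`, `mh_len`, `directionality`).
#' @export
lfc_matrix <- function(ds, rows = NULL, pseudocount = 0.001,
                       min_lines = 10L) {
  if (is.null(rows)) rows <- select_outcomes(ds, min_lines)
  fr <- outcome_frequencies(ds)
  lines <- sort(setdiff(unique(fr$cell_line), ds$control_line))
  rk <- paste(rows$target_id, rows$outcome, sep = "\r")
  fmat <- matrix(0, length(rk), length(lines) + 1L,
                 dimnames = list(rk, c(ds$control_line, lines)))
  fk <- paste(fr$target_id, fr$outcome, sep = "\r")
  idx <- cbind(match(fk, rk), match(fr$cell_line, colnames(fmat)))
  keep <- !is.na(idx[, 1L])
  fmat[idx[keep, , drop = FALSE]] <- fr$freq[keep]
  m <- log2((fmat[, lines, drop = FALSE] + pseudocount) /
              (fmat[, ds$control_line] + pseudocount))
  ann <- dataset_annotations(ds)
  am <- match(rk, paste(ann$target_id, ann$outcome, sep = "\r"))
  annotations <- data.frame(
    target_id = rows$target_id, outcome = rows$outcome,
    category = ann$category[am], control_freq = fmat[, ds$control_line],
    del_size = ann$del_size[am], mh_len = ann$mh_len[am],
    directionality = ann$directionality[am],
    in_frame = ann$in_frame[am],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(lfc = m, annotations = annotations,
                 pseudocount = pseudocount),
            class = "lfc_matrix")
}

#' @export
print.lfc_matrix <- function(x, ...) {
  cat("<lfc_matrix> ", nrow(x$lfc), " (target, outcome) rows x ",
      ncol(x$lfc), " knockout lines\n", sep = "")
  invisible(x)
}

#' Embed knockout response profiles in 2D
#'
#' Embeds the rows of an [lfc_matrix()] in two dimensions. `method =
#' "umap"` runs UMAP (via the Python umap-learn package, with
#' `min_dist = 0`, `n_neighbors = 50` defaults and a fixed random state);
#' `method = "pca"` uses the first two principal components — fully
#' deterministic and dependency-free.
#'
#' @param m An `lfc_matrix` (or plain numeric matrix).
#' @param method `"umap"` or `"pca"`.
#' @param n_neighbors,min_dist UMAP parameters.
#' @param seed Random state for UMAP.
#' @return Object of class `embedding`: list with `coords` (n x 2 matrix)
#'   and metadata.
#' @export
embed_outcomes <- function(m, method = c("umap", "pca"),
                           n_neighbors = 50L, min_dist = 0,
                           seed = 1L) {
  method <- match.arg(method)
  x <- if (inherits(m, "lfc_matrix")) m$lfc else as.matrix(m)
  if (method == "umap" && nrow(x) < n_neighbors)
    stop("fewer rows (", nrow(x), ") than n_neighbors (", n_neighbors,
         "); reduce n_neighbors")
  coords <- if (method == "pca") {
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(pr$x))
    cbind(pr$x[, 1L], if (k > 1L) pr$x[, 2L] else 0)
  } else {
    run_umap(x, n_neighbors, min_dist, seed)
  }
  dimnames(coords) <- list(rownames(x), c("dim1", "dim2"))
  structure(list(coords = coords, method = method,
                 n_neighbors = n_neighbors, min_dist = min_dist,
                 seed = seed),
            class = "embedding")
}

# UMAP through the Python umap-learn package (single-threaded, fixed
# random_state for reproducibility)
run_umap <- function(x, n_neighbors, min_dist, seed) {
  python <- Sys.which("python")
  if (!nzchar(python))
    stop("method = 'umap' needs a python interpreter with umap-learn; ",
         "use method = 'pca' otherwise")
  dir <- tempfile("umap")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fin <- file.path(dir, "in.csv")
  fout <- file.path(dir, "out.csv")
  utils::write.table(x, fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- sprintf(paste0(
    "import os; os.environ.setdefault('NUMBA_NUM_THREADS','1')\n",
    "import numpy, umap\n",
    "x = numpy.loadtxt(%s, delimiter=',', ndmin=2)\n",
    "e = umap.UMAP(n_neighbors=%d, min_dist=%s, n_components=2,\n",
    "              random_state=%d, n_jobs=1).fit_transform(x)\n",
    "numpy.savetxt(%s, e, delimiter=',')\n"),
    deparse(fin), as.integer(n_neighbors), format(min_dist),
    as.integer(seed), deparse(fout))
  status <- system2(python, "-", stdout = FALSE, stderr = FALSE,
                    input = script)
  if (status != 0L || !file.exists(fout))
    stop("umap-learn call failed (exit ", status, ")")
  as.matrix(utils::read.table(fout, sep = ","))
}

#' @export
print.embedding <- function(x, ...) {
  cat("<embedding> ", nrow(x$coords), " rows, method=", x$method,
      if (x$method == "umap")
        paste0(" (n_neighbors=", x$n_neighbors, ", min_dist=",
               x$min_dist, ", seed=", x$seed, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Cluster embedded outcomes
#'
#' Groups the 2D embedding into `k` clusters (seeded k-means by default;
#' Ward hierarchical clustering as the deterministic alternative).
#'
#' @param emb An `embedding` (or n x 2 coordinate matrix).
#' @param k Number of clusters (default 7).
#' @param method `"kmeans"` or `"hclust"`.
#' @param seed Seed for k-means initialization.
#' @return Integer vector of cluster labels (1..k).
#' @export
cluster_outcomes <- function(emb, k = 7L, method = c("kmeans", "hclust"),
                             seed = 1L) {
  method <- match.arg(method)
  x <- if (inherits(emb, "embedding")) emb$coords else as.matrix(emb)
  if (k > nrow(x)) stop("k = ", k, " exceeds number of rows ", nrow(x))
  if (method == "kmeans") {
    set.seed(seed)
    stats::kmeans(x, centers = k, nstart = 10L, iter.max = 100L)$cluster
  } else {
    stats::cutree(stats::hclust(stats::dist(x), method = "ward.D2"), k)
  }
}

#' Cluster composition tables
#'
#' From cluster labels and outcome categories, two re-normalizations of the
#' same contingency table: `category_by_cluster` — for each category, the
#' percentage falling in each cluster (each category column sums to 100);
#' `cluster_by_category` — for each cluster, the percentage of each
#' category (each cluster row sums to 100).
#'
#' @param labels Cluster labels.
#' @param categories Outcome category per row.
#' @return List with matrices `category_by_cluster` and
#'   `cluster_by_category` (clusters in rows, categories in columns, in
#'   percent), plus `counts`.
#' @export
cluster_composition <- function(labels, categories) {
  tab <- table(cluster = labels, category = categories)
  counts <- matrix(as.numeric(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  a <- sweep(counts, 2L, colSums(counts), "/") * 100
  b <- sweep(counts, 1L, rowSums(counts), "/") * 100
  list(category_by_cluster = a, cluster_by_category = b, counts = counts)
}

#' Knockout enrichment per cluster
#'
#' Z-scores each knockout's LFC column across all rows, then averages the
#' z-scores within each cluster: negative values mean outcomes of that
#' cluster are depleted by that knockout relative to the library.
#'
#' @param labels Cluster labels.
#' @param m An `lfc_matrix` (or numeric matrix).
#' @return Matrix cluster x knockout of mean z-scores.
#' @export
ko_enrichment <- function(labels, m) {
  x <- if (inherits(m, "lfc_matrix")) m$lfc else as.matrix(m)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance LFC column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "),
            "; their z-scores are set to 0")
    sds[sds == 0] <- Inf
  }
  z <- sweep(sweep(x, 2L, colMeans(x), "-"), 2L, sds, "/")
  agg <- rowsum(z, labels)
  agg / as.vector(table(labels)[rownames(agg)])
}

#' Mean directionality of non-homologous deletions per cluster
#'
#' Restricts to pure deletions with zero microhomology and reports the mean
#' directionality per cluster with a seeded percentile bootstrap CI.
#'
#' @param labels Cluster labels.
#' @param annotations Row annotations (from [lfc_matrix()]), with
#'   `del_size`, `ins_len` implied by `directionality`/`mh_len` columns.
#' @param n_boot Bootstrap resamples.
#' @param seed Bootstrap seed.
#' @param conf Confidence level.
#' @return data.frame `cluster`, `n`, `mean_directionality`, `lo`, `hi`
#'   (NA for clusters with no qualifying outcomes).
#' @export
cluster_directionality <- function(labels, annotations, n_boot = 1000L,
                                   seed = 1L, conf = 0.95) {
  keep <- !is.na(annotations$directionality) & annotations$mh_len == 0L &
    annotations$del_size > 0L
  alpha <- (1 - conf) / 2
  set.seed(seed)
  do.call(rbind, lapply(sort(unique(labels)), function(cl) {
    v <- annotations$directionality[keep & labels == cl]
    if (!length(v))
      return(data.frame(cluster = cl, n = 0L,
                        mean_directionality = NA_real_,
                        lo = NA_real_, hi = NA_real_))
    bs <- vapply(seq_len(n_boot), function(i)
      mean(v[sample.int(length(v), replace = TRUE)]), 0)
    data.frame(cluster = cl, n = length(v),
               mean_directionality = mean(v),
               lo = stats::quantile(bs, alpha)[[1L]],
               hi = stats::quantile(bs, 1 - alpha)[[1L]])
  }))
}
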