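#' Feature schema of the outcome predictor
#'
#' A versioned, documented reconstruction of the binary feature families
#' used by multiclass repair-outcome predictors: outcome type; deletion
#' size (one-hot 1..10, bins 11-15, 16-20, 21-30); left/right deletion
#' boundary offsets from the cut (one-hot, capped at 30); microhomology
#' length (one-hot 0..15, 16+); insertion length and inserted sequence
#' identity; flank-match flags; nucleotide identity at six positions around
#' the cut and two per deletion junction; and declared pairwise products
#' (deletion size x microhomology, insertion length x flank match). All
#' features are binary.
#'
#' @param version Schema version string (only `"v1"` is defined).
#' @return Object of class `feature_schema` with the ordered feature names.
#' @export
feature_schema <- function(version = "v1") {
  if (version != "v1") stop("unknown schema version: ", version)
  bases <- c("A", "C", "G", "T")
  mers <- c(bases, as.vector(outer(bases, bases, paste0)))
  dsize <- c(as.character(1:10), "11_15", "16_20", "21_30")
  mh <- c(as.character(0:15), "16p")
  fm <- c("DISTAL_ONLY", "PROXIMAL_ONLY", "BOTH", "NEITHER")
  ctx_pos <- c("m3", "m2", "m1", "p1", "p2", "p3")
  names <- c(
    "is_del", "is_ins",
    paste0("dsize_", dsize),
    paste0("loff_", 0:30), paste0("roff_", 0:30),
    paste0("mh_", mh),
    paste0("ilen_", 1:2),
    paste0("insseq_", mers),
    paste0("fm_", fm),
    paste0("ctx_", rep(ctx_pos, each = 4L), "_", bases),
    paste0("j", rep(c("l1", "l2", "r1", "r2"), each = 4L), "_", bases),
    paste0("dsize_", rep(dsize, each = length(mh)), ".mh_", mh),
    paste0("ilen_", rep(1:2, each = length(fm)), ".fm_", fm))
  structure(list(version = version, names = names,
                 n_features = length(names)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> version ", x$version, ", ", x$n_features,
      " binary features\n", sep = "")
  invisible(x)
}

dsize_bin <- function(size) {
  ifelse(size <= 10L, as.character(size),
         ifelse(size <= 15L, "11_15",
                ifelse(size <= 20L, "16_20", "21_30")))
}

#' Featurize a candidate set
#'
#' Deterministic sparse binary matrix: rows are the candidates of a target,
#' columns the features of the schema. Pairwise product features equal the
#' logical AND of their parents.
#'
#' @param target A [target_site()].
#' @param cset A [enumerate_candidates()] result (or its annotations
#'   data.frame).
#' @param schema A [feature_schema()].
#' @return A sparse `dgCMatrix` (rows named by outcome).
#' @export
featurize <- function(target, cset, schema = feature_schema()) {
  ann <- if (inherits(cset, "candidate_set")) cset$annotations else cset
  if (!all(c("del_start", "del_end") %in% names(ann)))
    stop("annotations lack coordinates; use enumerate_candidates()")
  nm <- schema$names
  col_of <- stats::setNames(seq_along(nm), nm)
  n <- nrow(ann)
  ch <- target$chars
  len <- length(ch)
  cc <- target$cut_index
  ii <- integer(0); jj <- integer(0)
  put <- function(rows, feat) {
    ok <- !is.na(feat) & feat %in% nm
    ii <<- c(ii, rows[ok]); jj <<- c(jj, col_of[feat[ok]])
  }
  rows <- seq_len(n)
  isdel <- ann$ins_len == 0L & ann$del_size > 0L
  isins <- ann$ins_len > 0L & ann$del_size == 0L
  put(rows[isdel], rep("is_del", sum(isdel)))
  put(rows[isins], rep("is_ins", sum(isins)))
  hasdel <- ann$del_size > 0L
  db <- dsize_bin(ann$del_size[hasdel])
  put(rows[hasdel], paste0("dsize_", db))
  loff <- pmin(pmax(0L, cc - ann$del_start[hasdel]), 30L)
  roff <- pmin(pmax(0L, ann$del_end[hasdel] - cc), 30L)
  put(rows[hasdel], paste0("loff_", loff))
  put(rows[hasdel], paste0("roff_", roff))
  mhb <- ifelse(ann$mh_len[hasdel] <= 15L,
                as.character(ann$mh_len[hasdel]), "16p")
  put(rows[hasdel], paste0("mh_", mhb))
  hasins <- ann$ins_len > 0L
  put(rows[hasins], paste0("ilen_", ann$ins_len[hasins]))
  ins_seq <- vapply(which(hasins), function(i) {
    s <- ann$outcome[i]
    sub("^.*:", "", s)
  }, "")
  put(rows[hasins], paste0("insseq_", ins_seq))
  hasfm <- !is.na(ann$flank_match)
  put(rows[hasfm], paste0("fm_", ann$flank_match[hasfm]))
  # target context around the cut: positions c-3..c+2 (0-based), same for
  # every candidate; matters through its pairwise availability downstream
  ctx_pos <- c("m3", "m2", "m1", "p1", "p2", "p3")
  for (k in seq_along(ctx_pos)) {
    pos0 <- cc - 4L + k    # 0-based: c-3 .. c+2
    if (pos0 >= 0L && pos0 < len)
      put(rows, rep(paste0("ctx_", ctx_pos[k], "_", ch[pos0 + 1L]), n))
  }
  # deletion junction bases: last kept base and first deleted base on each
  # side (S[a-1], S[a]; S[b-1], S[b])
  drows <- rows[hasdel]
  a <- ann$del_start[hasdel]; b <- ann$del_end[hasdel]
  okl <- a > 0L
  put(drows[okl], paste0("jl1_", ch[a[okl]]))
  put(drows, paste0("jl2_", ch[a + 1L]))
  put(drows, paste0("jr1_", ch[b]))
  okr <- b < len
  put(drows[okr], paste0("jr2_", ch[b[okr] + 1L]))
  # pairwise products
  put(rows[hasdel], paste0("dsize_", db, ".mh_", mhb))
  insfm <- hasins & !is.na(ann$flank_match)
  put(rows[insfm], paste0("ilen_", ann$ins_len[insfm], ".fm_",
                          ann$flank_match[insfm]))
  x <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(n, length(nm)),
                            dimnames = list(ann$outcome, nm))
  methods::as(x, "CsparseMatrix")
}

#' Align observed outcomes to a candidate set
#'
#' Counts are aligned to candidate indices; observed outcomes outside the
#' candidate space (e.g. compound insertion-deletions) are dropped and
#' their read fraction reported.
#'
#' @param counts Named numeric vector: canonical outcome -> reads.
#' @param cset A [enumerate_candidates()] result.
#' @return List with `counts` (aligned to `cset$outcomes`) and
#'   `dropped_fraction`.
#' @export
map_observed <- function(counts, cset) {
  out <- stats::setNames(numeric(length(cset$outcomes)), cset$outcomes)
  hit <- names(counts) %in% cset$outcomes
  out[names(counts)[hit]] <- counts[hit]
  total <- sum(counts)
  list(counts = out,
       dropped_fraction = if (total > 0) sum(counts[!hit]) / total else 0)
}

# cross-entropy part of the KL loss (bits) and its gradient, for the
# stacked candidate matrix X, target-wise measured frequencies m (each
# target block sums to 1) and group index list
kl_loss_grad <- function(w, X, m, group_idx, lambda) {
  s <- as.vector(X %*% w)
  p <- numeric(length(s))
  for (g in group_idx) {
    z <- s[g] - max(s[g])
    e <- exp(z)
    p[g] <- e / sum(e)
  }
  loss <- -sum(m * log2(p)) + lambda * sum(w^2)
  grad <- as.vector(Matrix::crossprod(X, (p - m))) / log(2) +
    2 * lambda * w
  list(loss = loss, grad = grad, p = p)
}

#' Fit a per-cell-line outcome-frequency model
#'
#' A softmax (multinomial logistic) profile model: each candidate outcome
#' of a target is scored linearly from its binary features and the
#' predicted profile is the softmax over the target's candidates. The
#' weights minimize the sum over training targets of the KL divergence
#' between the measured profile (0.5 reads added to every candidate, then
#' normalized) and the prediction, plus an L2 penalty `lambda * ||w||^2`,
#' by quasi-Newton (L-BFGS-B) optimization. Targets are split at the
#' target level into train and test sets.
#'
#' @param ds A pooled [screen_dataset()].
#' @param line Cell line whose profiles are modelled.
#' @param schema A [feature_schema()].
#' @param lambda L2 regularization strength (default 1e-3).
#' @param seed Seed for the train/test split.
#' @param test_frac Fraction of targets held out (default 0.1).
#' @param pseudocount Reads added to each candidate (default 0.5).
#' @param maxit Maximal L-BFGS-B iterations.
#' @param feature_cache Optional environment reused across fits to cache
#'   per-target candidate sets and feature matrices.
#' @return Object of class `profile_model`: weights, schema, split,
#'   training diagnostics (`initial_loss`, `final_loss`, `converged`,
#'   `mean_dropped_fraction`).
#' @export
profile_model <- function(ds, line, schema = feature_schema(),
                          lambda = 1e-3, seed = 1L, test_frac = 0.1,
                          pseudocount = 0.5, maxit = 200L,
                          feature_cache = NULL) {
  if (!line %in% ds$counts$cell_line)
    stop("line '", line, "' not in dataset")
  if (is.null(feature_cache)) feature_cache <- new.env(parent = emptyenv())
  tids <- sort(names(ds$targets))
  set.seed(seed)
  n_test <- max(1L, round(test_frac * length(tids)))
  if (n_test >= length(tids)) stop("test_frac leaves no training targets")
  test_ids <- sort(sample(tids, n_test))
  train_ids <- setdiff(tids, test_ids)
  sub <- ds$counts[ds$counts$cell_line == line, ]
  counts_by_target <- split(stats::setNames(sub$reads, sub$outcome),
                            sub$target_id)
  Xs <- vector("list", length(train_ids))
  ms <- vector("list", length(train_ids))
  dropped <- numeric(length(train_ids))
  for (i in seq_along(train_ids)) {
    tid <- train_ids[i]
    tf <- target_features(ds$targets[[tid]], schema, feature_cache)
    obs <- map_observed(counts_by_target[[tid]] %||% numeric(0), tf$cset)
    mm <- obs$counts + pseudocount
    ms[[i]] <- mm / sum(mm)
    Xs[[i]] <- tf$X
    dropped[i] <- obs$dropped_fraction
  }
  X <- do.call(rbind, Xs)
  m <- unlist(ms, use.names = FALSE)
  sizes <- vapply(ms, length, 0L)
  group_idx <- split(seq_len(nrow(X)), rep(seq_along(sizes), sizes))
  w0 <- numeric(schema$n_features)
  trace <- numeric(0)
  last <- NULL  # optim calls fn and gr at the same point; reuse the work
  eval_at <- function(w) {
    if (is.null(last) || !identical(last$w, w))
      last <<- c(list(w = w), kl_loss_grad(w, X, m, group_idx, lambda))
    last
  }
  fn <- function(w) {
    v <- eval_at(w)$loss
    trace <<- c(trace, v)
    v
  }
  gr <- function(w) eval_at(w)$grad
  initial_loss <- fn(w0)
  opt <- stats::optim(w0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  # report the KL-divergence value of the loss: KL = cross-entropy - H(m)
  ent <- sum(m * log2(m))
  structure(list(
    cell_line = line, schema = schema,
    weights = stats::setNames(opt$par, schema$names),
    lambda = lambda, seed = seed, pseudocount = pseudocount,
    split = list(train = train_ids, test = test_ids),
    initial_loss = initial_loss + ent, final_loss = opt$value + ent,
    n_train = length(train_ids),
    converged = opt$convergence %in% c(0L, 1L),
    iterations = opt$counts[["function"]],
    loss_trace = trace + ent,
    mean_dropped_fraction = mean(dropped)),
    class = "profile_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# candidate set + feature matrix for one target, cached
target_features <- function(target, schema, cache) {
  key <- target$target_id
  hit <- cache[[key]]
  if (!is.null(hit) && identical(hit$version, schema$version)) return(hit)
  cset <- enumerate_candidates(target)
  val <- list(cset = cset, X = featurize(target, cset, schema),
              version = schema$version)
  cache[[key]] <- val
  val
}

#' @export
print.profile_model <- function(x, ...) {
  cat("<profile_model> line '", x$cell_line, "': ",
      x$schema$n_features, " features, lambda=", x$lambda, "\n",
      "  trained on ", x$n_train, " targets (", length(x$split$test),
      " held out); mean per-target KL ",
      signif(x$initial_loss / x$n_train, 3), " -> ",
      signif(x$final_loss / x$n_train, 3), " bits",
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' @export
coef.profile_model <- function(object, ...) object$weights

#' @export
summary.profile_model <- function(object, ...) {
  w <- object$weights
  cat("Profile model for cell line '", object$cell_line, "'\n", sep = "")
  cat("  mean training KL: ",
      signif(object$final_loss / object$n_train, 4), " bits (from ",
      signif(object$initial_loss / object$n_train, 4), ")\n", sep = "")
  cat("  mean dropped read fraction: ",
      signif(object$mean_dropped_fraction, 3), "\n", sep = "")
  ord <- order(abs(w), decreasing = TRUE)
  cat("  largest weights:\n")
  print(round(w[ord[seq_len(min(10L, sum(w != 0)))]], 3))
  invisible(object)
}

#' Predict an outcome profile
#'
#' @param object A [profile_model()].
#' @param target A [target_site()] (or precomputed `candidate_set`).
#' @param feature_cache Optional cache environment.
#' @param ... Unused.
#' @return data.frame `outcome`, `prob` over the candidate set (sums to 1).
#' @export
predict.profile_model <- function(object, target,
                                  feature_cache = NULL, ...) {
  if (is.null(feature_cache)) feature_cache <- new.env(parent = emptyenv())
  tf <- target_features(target, object$schema, feature_cache)
  s <- as.vector(tf$X %*% object$weights)
  z <- exp(s - max(s))
  data.frame(outcome = tf$cset$outcomes, prob = z / sum(z),
             stringsAsFactors = FALSE)
}

#' Evaluate a profile model on held-out targets
#'
#' Per-target KL divergence between measured (0.5-read pseudocounted) and
#' predicted profiles over the candidate space, plus Pearson correlations
#' at three levels: individual outcome frequencies pooled over (target,
#' outcome) pairs, per-target outcome-category frequencies, and per-target
#' in-frame fractions (summed frequency of outcomes whose net length
#' change is a multiple of 3).
#'
#' @param model A [profile_model()].
#' @param ds A pooled [screen_dataset()].
#' @param targets Target ids to evaluate (default: the model's test split).
#' @param line Cell line of the measured profiles (default: the model's).
#' @param feature_cache Optional cache environment.
#' @return Object of class `eval_report`: `divergence` (data.frame
#'   `target_id`, `kl`, `dropped_fraction`), `r_outcome`, `r_category`,
#'   `r_inframe`, `mean_kl`.
#' @export
evaluate_model <- function(model, ds, targets = NULL, line = NULL,
                           feature_cache = NULL) {
  if (is.null(targets)) targets <- model$split$test
  if (!length(targets)) stop("empty test set")
  if (is.null(line)) line <- model$cell_line
  if (is.null(feature_cache)) feature_cache <- new.env(parent = emptyenv())
  sub <- ds$counts[ds$counts$cell_line == line &
                     ds$counts$target_id %in% targets, ]
  counts_by_target <- split(stats::setNames(sub$reads, sub$outcome),
                            sub$target_id)
  kls <- numeric(length(targets))
  drops <- numeric(length(targets))
  mo <- list(); po <- list()
  mcat <- list(); pcat <- list()
  mif <- numeric(length(targets)); pif <- numeric(length(targets))
  for (i in seq_along(targets)) {
    tid <- targets[i]
    tf <- target_features(ds$targets[[tid]], model$schema, feature_cache)
    obs <- map_observed(counts_by_target[[tid]] %||% numeric(0), tf$cset)
    mm <- obs$counts + model$pseudocount
    mm <- mm / sum(mm)
    pr <- predict(model, ds$targets[[tid]], feature_cache)$prob
    kls[i] <- sum(mm * log2(mm / pr))
    drops[i] <- obs$dropped_fraction
    f <- if (sum(obs$counts) > 0) obs$counts / sum(obs$counts)
         else obs$counts
    mo[[i]] <- f; po[[i]] <- pr
    cats <- tf$cset$annotations$category
    mcat[[i]] <- rowsum(f, cats)[, 1L]
    pcat[[i]] <- rowsum(pr, cats)[, 1L]
    inf <- tf$cset$annotations$in_frame
    mif[i] <- sum(f[inf]); pif[i] <- sum(pr[inf])
  }
  structure(list(
    divergence = data.frame(target_id = targets, kl = kls,
                            dropped_fraction = drops,
                            stringsAsFactors = FALSE),
    mean_kl = mean(kls),
    r_outcome = stats::cor(unlist(mo), unlist(po)),
    r_category = stats::cor(unlist(mcat), unlist(pcat)),
    r_inframe = if (length(targets) > 2L) stats::cor(mif, pif)
                else NA_real_,
    cell_line = line, n_targets = length(targets)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> line '", x$cell_line, "', ", x$n_targets,
      " targets\n", sep = "")
  cat("  mean KL: ", signif(x$mean_kl, 4), " bits\n", sep = "")
  cat("  Pearson r: outcomes ", signif(x$r_outcome, 3),
      ", categories ", signif(x$r_category, 3),
      ", in-frame ", signif(x$r_inframe, 3), "\n", sep = "")
  invisible(x)
}

#' Replicate-to-replicate divergence baseline
#'
#' KL divergence between the two replicate profiles of each target (pooled
#' over timepoints), computed on the candidate space with the same
#' pseudocount as model evaluation, so the values are directly comparable
#' to [evaluate_model()] divergences.
#'
#' @param ds An unpooled [screen_dataset()] with >= 2 replicates.
#' @param line Cell line.
#' @param targets Targets to evaluate (default: all).
#' @param pseudocount Reads added per candidate (default 0.5).
#' @param mode Divergence mode (see [profile_divergence()]).
#' @param feature_cache Optional cache environment.
#' @return data.frame `target_id`, `kl`.
#' @export
replicate_divergence <- function(ds, line, targets = NULL,
                                 pseudocount = 0.5,
                                 mode = c("directed", "symmetric"),
                                 feature_cache = NULL) {
  mode <- match.arg(mode)
  if (is.null(targets)) targets <- sort(names(ds$targets))
  if (is.null(feature_cache)) feature_cache <- new.env(parent = emptyenv())
  sub <- ds$counts[ds$counts$cell_line == line &
                     ds$counts$target_id %in% targets, ]
  reps <- sort(unique(sub$replicate))
  if (length(reps) < 2L) stop("need >= 2 replicates for line '", line, "'")
  schema <- feature_schema()
  kl <- vapply(targets, function(tid) {
    tf <- target_features(ds$targets[[tid]], schema, feature_cache)
    prof <- function(r) {
      s <- sub[sub$target_id == tid & sub$replicate == reps[r], ]
      v <- rowsum(s$reads, s$outcome)
      map_observed(stats::setNames(v[, 1L], rownames(v)), tf$cset)$counts
    }
    profile_divergence(prof(1L), prof(2L), mode = mode,
                       pseudocount = pseudocount)
  }, 0)
  data.frame(target_id = targets, kl = kl, row.names = NULL,
             stringsAsFactors = FALSE)
}
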