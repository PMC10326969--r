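test_that("candidate space matches the closed-form window counts", {
  wt <- wide_target(61)
  cs <- enumerate_candidates(wt)
  expect_identical(cs$n_pre_del, sum(seq_len(30L) + 1L))  # 495
  expect_identical(cs$n_pre_del, 495L)
  expect_identical(cs$n_pre_ins, 7L * 20L)                # 140
  expect_lte(length(cs$outcomes), 635L)
  expect_false(anyDuplicated(cs$outcomes) > 0)
  # insufficient context is reported with the required margin
  short <- target_site("s", paste0(strrep("A", 10), "CATTGGA", "TGG",
                                   strrep("C", 10)), 0L, 17L)
  expect_error(enumerate_candidates(short), "33")
})

test_that("candidate enumeration equals brute-force mutant enumeration", {
  for (seed in c(71, 72, 73)) {
    wt <- wide_target(seed)
    s <- wt$sequence
    cc <- wt$cut_index
    # oracle: distinct mutated strings from raw deletion/insertion windows
    muts <- character(0)
    for (L in 1:30) for (a in (cc - L):cc)
      muts <- c(muts, apply_edit(s, a, a + L))
    for (p in (cc - 3):(cc + 3))
      for (m in c("A", "C", "G", "T",
                  as.vector(outer(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"), paste0))))
        muts <- c(muts, apply_edit(s, p, p, m))
    cs <- enumerate_candidates(wt)
    got <- vapply(cs$outcomes, function(o)
      apply_indel(wt, parse_indel(o)), "")
    expect_setequal(unique(got), unique(muts))
    expect_identical(length(got), length(unique(muts)))
  }
})

test_that("candidate annotations agree with the per-outcome classifier", {
  wt <- wide_target(81)
  cs <- enumerate_candidates(wt)
  idx <- seq(1, length(cs$outcomes), by = 7)
  ref <- annotate_outcomes(wt, cs$outcomes[idx])
  for (col in c("category", "del_size", "ins_len", "mh_len", "in_frame"))
    expect_identical(cs$annotations[[col]][idx], ref[[col]],
                     info = col)
})

test_that("featurization is deterministic with coherent feature families", {
  wt <- wide_target(91)
  cs <- enumerate_candidates(wt)
  schema <- feature_schema()
  X <- featurize(wt, cs, schema)
  expect_identical(dim(X), c(length(cs$outcomes), schema$n_features))
  expect_true(all(X@x %in% 1))
  expect_identical(X, featurize(wt, cs, schema))
  cc <- wt$cut_index
  key <- paste0("DEL:", cc - 2, "-", cc + 1)
  i <- match(format_indel(canonicalize(wt, indel(cc - 2, cc + 1))),
             rownames(X))
  row <- X[i, ]
  ann_i <- cs$annotations[match(rownames(X)[i], cs$annotations$outcome), ]
  expect_identical(unname(row[paste0("loff_", cc - ann_i$del_start)]), 1)
  expect_identical(unname(row[paste0("roff_", ann_i$del_end - cc)]), 1)
  expect_identical(unname(sum(row[grep("^ilen_|^insseq_", colnames(X))])), 0)
  # every pairwise product column equals the AND of its parents
  pp <- grep("^dsize_.*\\.mh_", colnames(X), value = TRUE)
  parents <- strsplit(pp, ".", fixed = TRUE)
  Xd <- as.matrix(X)
  for (j in sample(seq_along(pp), 25)) {
    expect_identical(Xd[, pp[j]],
                     Xd[, parents[[j]][1]] * Xd[, parents[[j]][2]])
  }
})

test_that("observed outcomes map onto the candidate space with drop logging", {
  wt <- wide_target(95)
  cs <- enumerate_candidates(wt)
  inside <- cs$outcomes[c(1, 5)]
  counts <- stats::setNames(c(70, 20, 10),
                            c(inside, "IND:40-44:TTAA"))
  mo <- map_observed(counts, cs)
  expect_equal(mo$dropped_fraction, 0.1)
  expect_equal(sum(mo$counts), 90)
  mo2 <- map_observed(counts[1:2], cs)
  expect_equal(mo2$dropped_fraction, 0)
})

test_that("analytic KL gradient matches finite differences", {
  set.seed(33)
  X <- Matrix::Matrix(matrix(rbinom(5 * 8, 1, 0.4), 5, 8), sparse = TRUE)
  m <- c(0.5, 0.2, 0.1, 0.1, 0.1)
  gidx <- list(1:5)
  w <- rnorm(8, 0, 0.5)
  lam <- 1e-3
  got <- cas9repair:::kl_loss_grad(w, X, m, gidx, lam)
  num <- vapply(seq_along(w), function(j) {
    h <- 1e-6
    wp <- w; wp[j] <- wp[j] + h
    wm <- w; wm[j] <- wm[j] - h
    (cas9repair:::kl_loss_grad(wp, X, m, gidx, lam)$loss -
       cas9repair:::kl_loss_grad(wm, X, m, gidx, lam)$loss) / (2 * h)
  }, 0)
  expect_lt(max(abs(got$grad - num)) / max(abs(num)), 1e-5)
})

test_that("zero weights predict the uniform profile", {
  wt <- wide_target(97)
  schema <- feature_schema()
  model <- structure(list(cell_line = "control", schema = schema,
                          weights = stats::setNames(numeric(schema$n_features),
                                                    schema$names),
                          pseudocount = 0.5),
                     class = "profile_model")
  pr <- predict(model, wt)
  expect_equal(sum(pr$prob), 1, tolerance = 1e-12)
  expect_true(all(abs(pr$prob - 1 / nrow(pr)) < 1e-12))
})

test_that("a single-target unregularized fit reproduces its profile", {
  p <- sim_params(n_targets = 2L, depth_meanlog = log(5e4),
                  depth_sdlog = 0)
  tg <- generate_targets(p, seed = 41)
  sim <- sample_screen(tg, p, knockout_presets(character(0)), seed = 42)
  ds <- pool_samples(sim$dataset)
  m <- profile_model(ds, "control", lambda = 0, test_frac = 0.5,
                     seed = 1, maxit = 500)
  expect_lt(m$final_loss / m$n_train, 0.01)
  expect_lte(m$final_loss, m$initial_loss)
  expect_lte(min(m$loss_trace), m$initial_loss + 1e-9)
})

test_that("prediction is a proper distribution, invariant to row order", {
  wt <- wide_target(99)
  cs <- enumerate_candidates(wt)
  schema <- feature_schema()
  set.seed(5)
  w <- rnorm(schema$n_features, 0, 0.2)
  X <- featurize(wt, cs, schema)
  s <- as.vector(X %*% w)
  pr <- exp(s - max(s)); pr <- pr / sum(pr)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
  perm <- sample(nrow(X))
  s2 <- as.vector(X[perm, ] %*% w)
  pr2 <- exp(s2 - max(s2)); pr2 <- pr2 / sum(pr2)
  expect_equal(pr2, pr[perm], tolerance = 1e-12)
})

test_that("training improves held-out divergence over the uniform baseline", {
  p <- sim_params(n_targets = 30L, depth_meanlog = log(2000),
                  depth_sdlog = 0.2)
  tg <- generate_targets(p, seed = 51)
  sim <- sample_screen(tg, p, knockout_presets(character(0)), seed = 52)
  ds <- pool_samples(sim$dataset)
  cache <- new.env(parent = emptyenv())
  m <- profile_model(ds, "control", seed = 2, maxit = 120,
                     feature_cache = cache)
  ev <- evaluate_model(m, ds, feature_cache = cache)
  expect_true(all(ev$divergence$kl >= 0))
  uni <- m
  uni$weights[] <- 0
  ev0 <- evaluate_model(uni, ds, targets = m$split$test,
                        feature_cache = cache)
  expect_lt(ev$mean_kl, ev0$mean_kl)
  expect_gt(ev$r_outcome, 0.8)
  # in-frame fraction equals the direct frequency sum
  tid <- m$split$test[1]
  tf <- cas9repair:::target_features(ds$targets[[tid]], m$schema, cache)
  pr <- predict(m, ds$targets[[tid]], cache)
  expect_equal(sum(pr$prob[tf$cset$annotations$in_frame]),
               1 - sum(pr$prob[!tf$cset$annotations$in_frame]),
               tolerance = 1e-9)
})
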