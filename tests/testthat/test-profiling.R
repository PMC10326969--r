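make_toy_ds <- function() {
  ts <- toy_target()
  targets <- list(toy = ts)
  screen_dataset(targets, make_counts(
    list("control", 1, "d7", "toy", "DEL:16-17", 60),
    list("control", 1, "d7", "toy", "INS:17:G", 40),
    list("ko", 1, "d7", "toy", "DEL:16-17", 30),
    list("ko", 1, "d7", "toy", "INS:17:G", 70)))
}

test_that("coverage filter drops targets below threshold in any sample", {
  p <- sim_params(n_targets = 3L, depth_meanlog = log(500),
                  depth_sdlog = 0)
  tg <- generate_targets(p, seed = 2)
  sim <- sample_screen(tg, p, knockout_presets("Nbn"), seed = 3)
  ds <- sim$dataset
  # push one target below 100 reads in a single sample
  pick <- ds$counts$target_id == "T00002" & ds$counts$cell_line == "Nbn" &
    ds$counts$replicate == 1L
  drop <- ds$counts[!pick, ]
  keep1 <- ds$counts[pick, ][1, ]
  keep1$reads <- 99
  ds2 <- screen_dataset(ds$targets, rbind(drop, keep1))
  f <- filter_guides(ds2, 100)
  expect_identical(sort(names(f$targets)), c("T00001", "T00003"))
  expect_identical(attr(f, "removed"), "T00002")
  # min_reads = 0 keeps everything
  expect_identical(sort(names(filter_guides(ds2, 0)$targets)),
                   sort(names(ds2$targets)))
  expect_warning(filter_guides(ds2, 1e9), "threshold")
})

test_that("singleton outcomes are removed by the summed-count rule", {
  ts <- toy_target()
  ds <- screen_dataset(list(toy = ts), make_counts(
    list("control", 1, "d7", "toy", "DEL:16-17", 50),
    list("control", 1, "d7", "toy", "INS:17:G", 1),   # singleton
    list("control", 1, "d7", "toy", "DEL:15-17", 1),  # 1 + 1 across samples
    list("control", 2, "d7", "toy", "DEL:15-17", 1)))
  out <- drop_singletons(ds)
  expect_false("INS:17:G" %in% out$counts$outcome)
  expect_true("DEL:15-17" %in% out$counts$outcome)
  tot <- sample_totals(out)
  expect_identical(sort(tot$total), c(1, 51))
})

test_that("pooling sums reads and is associative", {
  ts <- toy_target()
  ds <- screen_dataset(list(toy = ts), make_counts(
    list("control", 1, "d3", "toy", "DEL:16-17", 10),
    list("control", 2, "d3", "toy", "DEL:16-17", 30),
    list("control", 1, "d7", "toy", "DEL:16-17", 5),
    list("control", 2, "d7", "toy", "INS:17:G", 15)))
  p1 <- pool_samples(ds)
  expect_identical(p1$counts$reads[p1$counts$outcome == "DEL:16-17"], 45)
  p2 <- pool_samples(pool_samples(ds, "replicate"), "timepoint")
  o <- function(d) d$counts[order(d$counts$outcome), c("outcome", "reads")]
  expect_equal(o(p1), o(p2), ignore_attr = TRUE)
  # pooled frequency equals the read-weighted mean of replicate frequencies
  fr_rep <- outcome_frequencies(pool_samples(ds, "timepoint"))
  fr_pool <- outcome_frequencies(p1)
  w <- sample_totals(pool_samples(ds, "timepoint"))
  f_manual <- sum(fr_rep$freq[fr_rep$outcome == "DEL:16-17"] *
                    w$total[match(fr_rep$replicate[fr_rep$outcome ==
                                                     "DEL:16-17"],
                                  w$replicate)]) / sum(w$total)
  expect_equal(fr_pool$freq[fr_pool$outcome == "DEL:16-17"], f_manual)
})

test_that("category composition sums to one per cell line", {
  ds <- pool_samples(make_toy_ds())
  ct <- category_table(ds)
  sums <- tapply(ct$mean_freq, ct$cell_line, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # single dominant outcome
  ds1 <- screen_dataset(list(toy = toy_target()), make_counts(
    list("control", 1, "d7", "toy", "DEL:16-17", 100)))
  ct1 <- category_table(pool_samples(ds1))
  expect_equal(ct1$mean_freq[ct1$category == "D1"], 1)
  expect_equal(sum(ct1$mean_freq), 1)
})

test_that("log2 fold changes are zero at equality and antisymmetric", {
  ts <- toy_target()
  eq <- screen_dataset(list(toy = ts), make_counts(
    list("control", 1, "d7", "toy", "DEL:16-17", 50),
    list("ko", 1, "d7", "toy", "DEL:16-17", 50)))
  l0 <- lfc(pool_samples(eq))
  expect_true(all(abs(l0$lfc) < 1e-12))
  ds <- pool_samples(make_toy_ds())
  l1 <- lfc(ds)
  swapped <- screen_dataset(ds$targets, ds$counts, control_line = "ko")
  # relabel so the old control becomes the knockout
  l2 <- lfc(swapped)
  m1 <- l1$lfc[order(l1$category)]
  m2 <- l2$lfc[order(l2$category)]
  expect_equal(m1, -m2)
  no_ctrl <- ds$counts[ds$counts$cell_line != "control", ]
  expect_error(lfc(screen_dataset(ds$targets, no_ctrl,
                                  control_line = "control")),
               "control")
})

test_that("profile divergence has the closed-form and symmetry properties", {
  p <- c(a = 1, b = 0)
  q <- c(a = 0.5, b = 0.5)
  expect_equal(profile_divergence(p, p, pseudocount = 0), 0)
  expect_equal(profile_divergence(p, q, pseudocount = 0), 1)  # log2(2)
  expect_gt(profile_divergence(p, q, "directed"), 0)
  expect_equal(profile_divergence(p, q, "symmetric"),
               profile_divergence(q, p, "symmetric"))
  # pseudocount keeps disjoint supports finite
  expect_true(is.finite(profile_divergence(c(x = 5), c(y = 5))))
})

test_that("uniformly random insertion expectation is 3/16 both ways", {
  fe <- flank_match_random_expectation(n_mc = 2e5, seed = 3)
  expect_equal(fe$exact, 3 / 16)
  expect_lt(abs(fe$mc - 3 / 16), 0.005)
})

test_that("insertion report recovers planted flank propensities", {
  ts1 <- toy_target("T", "C")
  ts2 <- toy_target("G", "C")
  targets <- list(t1 = ts1, t2 = ts2)
  targets$t1$target_id <- "t1"; targets$t2$target_id <- "t2"
  ds <- screen_dataset(targets, make_counts(
    list("control", 1, "d7", "t1", "INS:17:T", 80),   # distal only
    list("control", 1, "d7", "t1", "DEL:16-17", 20),
    list("control", 1, "d7", "t2", "INS:17:G", 50),
    list("control", 1, "d7", "t2", "DEL:16-17", 50)))
  rep1 <- insertion_report(pool_samples(ds), n_boot = 50, seed = 5)
  tc <- rep1[rep1$distal == "T" & rep1$proximal == "C", ]
  expect_equal(tc$prox_frac, 0)          # all insertions distal
  expect_equal(tc$ins1_freq, 0.8)
  rep2 <- insertion_report(pool_samples(ds), n_boot = 50, seed = 5)
  expect_identical(rep1, rep2)           # bootstrap reproducible
})

test_that("standard pipeline applies filters in the documented order", {
  p <- sim_params(n_targets = 4L, depth_meanlog = log(400), depth_sdlog = 0)
  tg <- generate_targets(p, seed = 6)
  sim <- sample_screen(tg, p, knockout_presets("Nbn"), seed = 7)
  ds <- standard_pipeline(sim$dataset, min_reads = 100)
  expect_identical(unique(ds$counts$timepoint), "pooled")
  expect_identical(unique(ds$counts$replicate), 0L)
  # no singleton outcomes survive
  k <- paste(ds$counts$target_id, ds$counts$outcome)
  tot <- rowsum(ds$counts$reads, k)
  expect_true(all(tot[, 1L] != 1))
})
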