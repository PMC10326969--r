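# a small screen with three planted response archetypes: NHEJ-like
# categories depleted in lines ko1/ko2, MMEJ-like in ko3/ko4, long
# non-homologous deletions in ko5/ko6
archetype_screen <- function(n_targets = 40L, depth = 1e4, seed = 17L) {
  zero <- stats::setNames(numeric(10), outcome_categories())
  eff <- function(cats, v = -4) { z <- zero; z[cats] <- v; z }
  groups <- list(
    A = c("D1", "D2", "I12_DIST", "I12_PROX"),
    B = c("D3_9_MH", "D10P_MH", "D3_9"),
    C = c("D10P", "OTHER_I", "OTHER_I_MH"))
  effects <- list(control = zero,
                  ko1 = eff(groups$A), ko2 = eff(groups$A),
                  ko3 = eff(groups$B), ko4 = eff(groups$B),
                  ko5 = eff(groups$C), ko6 = eff(groups$C))
  p <- sim_params(n_targets = n_targets, depth_meanlog = log(depth),
                  depth_sdlog = 0)
  tg <- generate_targets(p, seed = seed)
  sim <- sample_screen(tg, p, effects, seed = seed + 1L)
  list(sim = sim, groups = groups)
}

group_of <- function(categories, groups) {
  g <- rep(NA_character_, length(categories))
  for (nm in names(groups)) g[categories %in% groups[[nm]]] <- nm
  g
}

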