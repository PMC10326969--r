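#' Parameters of the synthetic screen generator
#'
#' The generator emulates the statistical structure of a Cas9 repair-outcome
#' knockout screen: a library of targets sharing a common sequence context,
#' per-sample mutated-read depths drawn log-normally, and per-target
#' multinomial outcome counts from a generative distribution in which
#'
#' * microhomology-mediated deletions of MH size `s >= 2` at inter-homology
#'   distance `d` have absolute probability `A_s * exp(mh_B * d)` with
#'   `A_s = min(mh_alpha * exp(mh_gamma * s), mh_Amax)` — longer homologies
#'   closer together are more likely;
#' * 1bp insertions at the cut follow a flank-pair propensity table giving
#'   each (PAM-distal, PAM-proximal) nucleotide pair a total 1bp-insertion
#'   weight and a PAM-proximal fraction (defaults: T/A-flanked targets about
#'   three times as insertion-prone as G/C-flanked ones; proximal fractions
#'   spanning about 0.5% to 56% across pairs);
#' * remaining mass is spread over non-MH deletions (weight decaying with
#'   size), off-cut and non-matching insertions, 2bp insertions, and a small
#'   compound insertion-deletion tail outside the predictor's candidate
#'   space.
#'
#' @param n_targets Number of targets (default 2838, the screen's scale).
#' @param context_length Fixed context per side of the construct (>= 27 so
#'   that 30bp deletions spanning the cut stay in bounds).
#' @param depth_meanlog,depth_sdlog Log-normal law of mutated reads per
#'   sample profile.
#' @param replicates,timepoints Replicate count and timepoint labels.
#' @param mh_alpha,mh_gamma,mh_Amax,mh_B Microhomology-deletion law.
#' @param bg_del_weight,bg_del_decay Relative weight scale and per-bp decay
#'   of non-MH (mh < 2) deletions.
#' @param bg_del_long Flat relative weight added to non-MH deletions of
#'   10bp and more (the resection-driven long-deletion tail).
#' @param ins_table Flank propensity table (see [default_flank_table()]).
#' @param ins1_weight Family weight of flank-matching 1bp insertions.
#' @param other_ins_weight,ins2_weight Per-outcome relative weights of
#'   non-matching/off-cut 1bp insertions and of 2bp insertions.
#' @param compound_weight,compound_n Total relative weight and count of the
#'   compound insertion-deletion tail.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_targets = 2838L,
                       context_length = 30L,
                       depth_meanlog = log(1500), depth_sdlog = 0.4,
                       replicates = 2L, timepoints = "d7",
                       mh_alpha = 0.040, mh_gamma = 0.35, mh_Amax = 0.12,
                       mh_B = -0.13,
                       bg_del_weight = 1.8, bg_del_decay = 0.85,
                       bg_del_long = 0.004,
                       ins_table = default_flank_table(),
                       ins1_weight = 15,
                       other_ins_weight = 0.002, ins2_weight = 0.003,
                       compound_weight = 0.5, compound_n = 3L) {
  if (context_length < 27L)
    stop("context_length must be >= 27 so 30bp deletions fit the construct")
  structure(as.list(environment()), class = "sim_params")
}

#' Default flank-pair propensity table for 1bp insertions
#'
#' One row per (PAM-distal, PAM-proximal) flank pair: `total` is the
#' relative 1bp-insertion weight of targets with that pair (T/A-distal
#' targets about 3x more insertion-prone than G/C-distal ones, 0.29 vs
#' 0.097), and `prox_frac` the fraction of flank-matching insertions that
#' match the PAM-proximal base (low when the proximal base is G, high when
#' it is T; the T/G and G/T pairs sit at the extremes, about 0.005 and
#' 0.56).
#'
#' @return data.frame with columns `distal`, `proximal`, `total`,
#'   `prox_frac`.
#' @export
default_flank_table <- function() {
  bases <- c("A", "C", "G", "T")
  tab <- expand.grid(distal = bases, proximal = bases,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$total <- ifelse(tab$distal %in% c("T", "A"), 0.29, 0.097)
  pf <- c(A = 0.25, C = 0.18, G = 0.02, T = 0.50)
  tab$prox_frac <- pf[tab$proximal]
  # distal T pulls insertions towards the distal match
  tab$prox_frac <- tab$prox_frac * ifelse(tab$distal == "T", 0.25, 1)
  tab$prox_frac[tab$distal == "G" & tab$proximal == "T"] <- 0.56
  tab$prox_frac[tab$distal == "T" & tab$proximal == "G"] <- 0.005
  tab
}

#' Generate a synthetic target library
#'
#' Targets are uniform-random 20bp protospacers with a forced NGG PAM,
#' embedded in a fixed context shared by the whole library (drawn once per
#' seed). The construct is `context | protospacer(20) | NGG | context`, so
#' the cut index is `context_length + 17`.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed; the same seed reproduces the same library.
#' @return Named list of [target_site()] objects.
#' @export
generate_targets <- function(params = sim_params(), seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ctx <- params$context_length
  left <- paste(sample(bases, ctx, replace = TRUE), collapse = "")
  right <- paste(sample(bases, ctx, replace = TRUE), collapse = "")
  n <- params$n_targets
  out <- vector("list", n)
  ids <- sprintf("T%05d", seq_len(n))
  for (i in seq_len(n)) {
    proto <- paste(sample(bases, 20L, replace = TRUE), collapse = "")
    pam <- paste0(sample(bases, 1L), "GG")
    out[[i]] <- target_site(ids[i], paste0(left, proto, pam, right),
                            protospacer_start = ctx, pam_start = ctx + 20L)
  }
  names(out) <- ids
  out
}

#' Generative outcome distribution of a target in control cells
#'
#' Builds the per-outcome probability vector over the candidate space (plus
#' a small compound tail). MH deletions (`mh >= 2`) get absolute
#' probabilities `A_s exp(B d)`; all remaining outcome families share the
#' leftover mass with relative weights from `params`.
#'
#' @param target A [target_site()].
#' @param params A [sim_params()] list.
#' @return List with `outcomes`, `prob` (sums to 1), and the `annotations`
#'   data.frame of the support.
#' @export
control_distribution <- function(target, params = sim_params()) {
  ann <- candidate_annotations(target)
  # compound tail: fixed small indels around the cut, outside the candidate
  # space (deterministic given the target)
  cc <- target$cut_index
  tails <- c("GTT", "ACAC", "TGA", "CCGA", "AATG")
  nt <- min(params$compound_n, length(tails))
  if (nt > 0L) {
    comp <- lapply(seq_len(nt), function(j)
      classify_outcome(target, indel(cc - j, cc + j, tails[j])))
    comp_df <- data.frame(
      outcome = vapply(comp, function(z) format_indel(z$indel), ""),
      category = vapply(comp, `[[`, "", "category"),
      del_size = vapply(comp, function(z) del_size(z$indel), 0L),
      ins_len = vapply(comp, function(z) ins_len(z$indel), 0L),
      mh_len = 0L, flank_match = NA_character_,
      directionality = NA_real_,
      in_frame = vapply(comp, `[[`, TRUE, "in_frame"),
      del_start = vapply(comp, function(z) z$indel$del_start, 0L),
      del_end = vapply(comp, function(z) z$indel$del_end, 0L),
      stringsAsFactors = FALSE)
    comp_df <- comp_df[!comp_df$outcome %in% ann$outcome, , drop = FALSE]
    ann <- rbind(ann, comp_df)
  }
  w <- numeric(nrow(ann))
  is_del <- ann$ins_len == 0L & ann$del_size > 0L
  is_mh <- is_del & ann$mh_len >= 2L
  # absolute probabilities for the MH family
  s <- ann$mh_len[is_mh]
  d <- ann$del_size[is_mh] - s
  A <- pmin(params$mh_alpha * exp(params$mh_gamma * s), params$mh_Amax)
  p_mh <- A * exp(params$mh_B * d)
  mh_mass <- sum(p_mh)
  rescaled <- FALSE
  if (mh_mass > 0.9) {
    # repeat-rich targets can overshoot; rescale so other families keep mass
    p_mh <- p_mh * (0.9 / mh_mass)
    mh_mass <- 0.9
    rescaled <- TRUE
  }
  # relative weights for everything else
  bg <- is_del & !is_mh
  w[bg] <- params$bg_del_weight * exp(-params$bg_del_decay *
                                        ann$del_size[bg]) +
    params$bg_del_long * (ann$del_size[bg] >= 10L)
  ch <- target$chars
  distal <- ch[cc]; proximal <- ch[cc + 1L]
  ft <- params$ins_table
  row <- ft[ft$distal == distal & ft$proximal == proximal, ]
  ins1 <- ann$ins_len == 1L & ann$del_size == 0L
  at_cut <- ins1 & !is.na(ann$flank_match)
  w[ins1] <- params$other_ins_weight
  if (distal == proximal) {
    w[at_cut & ann$flank_match == "BOTH"] <- params$ins1_weight * row$total
  } else {
    w[at_cut & ann$flank_match == "DISTAL_ONLY"] <-
      params$ins1_weight * row$total * (1 - row$prox_frac)
    w[at_cut & ann$flank_match == "PROXIMAL_ONLY"] <-
      params$ins1_weight * row$total * row$prox_frac
  }
  ins2 <- ann$ins_len == 2L & ann$del_size == 0L
  w[ins2] <- params$ins2_weight
  comp <- ann$ins_len > 0L & ann$del_size > 0L
  if (any(comp)) w[comp] <- params$compound_weight / sum(comp)
  if (sum(w) <= 0) stop("degenerate distribution: all weights zero")
  p <- numeric(nrow(ann))
  p[is_mh] <- p_mh
  p[!is_mh] <- w[!is_mh] / sum(w[!is_mh]) * (1 - mh_mass)
  list(outcomes = ann$outcome, prob = p, annotations = ann,
       mh_rescaled = rescaled)
}

#' Knockout effect presets
#'
#' Named per-category log2 fold-change specifications for the screen's 18
#' knockout lines, applied multiplicatively to category weights before
#' renormalization. Signs follow the directions the screen reports (NHEJ
#' knockouts deplete small indels and 1-2bp insertions, `Nbn` suppresses
#' medium/large deletions, `Polq` depletes medium MH deletions while
#' increasing large non-MH ones, `Prkdc`/`Polm` specifically deplete
#' PAM-proximal insertions); magnitudes are generator settings, not
#' measurements. The control line maps to all-zero effects.
#'
#' @param lines Optional subset of line names (control always included).
#' @return Named list: cell line -> named numeric vector of log2 effects
#'   over [outcome_categories()].
#' @export
knockout_presets <- function(lines = NULL) {
  z <- stats::setNames(numeric(10L), outcome_categories())
  eff <- function(...) {
    v <- z; upd <- c(...); v[names(upd)] <- upd; v
  }
  presets <- list(
    control = z,
    Nbn = eff(D3_9 = -2, D3_9_MH = -2, D10P = -2, D10P_MH = -2,
              D1 = 1.2, D2 = 0.5, I12_DIST = 1.5, I12_PROX = 1),
    Polq = eff(D3_9_MH = -1.6, D3_9 = -0.5, D10P = 1.6, I12_DIST = 0.5),
    Lig4 = eff(I12_DIST = -5.5, I12_PROX = -2.5, D1 = -1.5, D2 = -0.5,
               D3_9 = 0.3, D3_9_MH = 0.3, D10P = 0.5, D10P_MH = 0.4),
    Xrcc5 = eff(I12_DIST = -3.1, I12_PROX = -4.2, D1 = -1.5,
                D3_9 = 0.3, D10P = 0.8, D10P_MH = 0.6),
    Xlf = eff(I12_DIST = -2, I12_PROX = -1.5, D1 = -1,
              D3_9 = 0.3, D10P = 0.5, D10P_MH = 0.3),
    Prkdc = eff(I12_PROX = -2.3, I12_DIST = -0.3),
    Polm = eff(I12_PROX = -1.5, I12_DIST = -0.3),
    Poll = eff(I12_DIST = -0.8, I12_PROX = -0.8, D1 = -0.3),
    Lig1 = eff(OTHER_I = 0.2),
    Lig3 = z,
    Parp1 = eff(D10P = 0.2),
    Dclre1c = eff(D2 = -0.3),
    Wrn = z, Trex1 = z, Trp53 = z, Trp53bp1 = eff(D10P = 0.3),
    Rad52 = z, Ercc1 = eff(OTHER_I = 0.2))
  if (!is.null(lines))
    presets <- presets[unique(c("control", lines))]
  presets
}

# apply per-category multiplicative effects and renormalize
apply_effects <- function(dist, effect) {
  p <- dist$prob * 2^effect[dist$annotations$category]
  p / sum(p)
}

#' Sample a synthetic knockout screen
#'
#' For every (cell line, replicate, timepoint, target) a mutated-read depth
#' is drawn from the log-normal depth model and outcome counts are drawn
#' multinomially from the effect-adjusted generative distribution.
#' Timepoints are generated i.i.d. (no drift).
#'
#' @param targets Named list from [generate_targets()].
#' @param params A [sim_params()] list.
#' @param effects Named list of per-category log2 effects (e.g.
#'   [knockout_presets()]); must include an all-zero control entry.
#' @param seed Integer seed.
#' @param control_line Name of the control entry in `effects`.
#' @return List of class `screen_sim` with elements `dataset` (a
#'   [screen_dataset()]) and `truth` (ground truth: per-line per-target
#'   probabilities, the effect spec, the MH law parameters, and the realized
#'   per-category log2 fold changes computed on the exact probabilities with
#'   the profiling pseudocount).
#' @export
sample_screen <- function(targets, params = sim_params(),
                          effects = knockout_presets(), seed = 1L,
                          control_line = "control") {
  stopifnot(control_line %in% names(effects))
  if (any(effects[[control_line]] != 0))
    stop("control line must have all-zero effects")
  set.seed(seed)
  lines <- names(effects)
  dists <- lapply(targets, control_distribution, params = params)
  probs <- lapply(lines, function(ln) {
    e <- effects[[ln]]
    lapply(dists, function(dst) {
      p <- apply_effects(dst, e)
      names(p) <- dst$outcomes
      p
    })
  })
  names(probs) <- lines
  n_prof <- length(lines) * length(targets) * params$replicates *
    length(params$timepoints)
  rows <- vector("list", n_prof)
  i <- 0L
  for (ln in lines) {
    for (tid in names(targets)) {
      p <- probs[[ln]][[tid]]
      for (rep in seq_len(params$replicates)) {
        for (tp in params$timepoints) {
          depth <- max(1L, round(stats::rlnorm(1L, params$depth_meanlog,
                                               params$depth_sdlog)))
          cnt <- stats::rmultinom(1L, depth, p)[, 1L]
          nz <- cnt > 0L
          i <- i + 1L
          rows[[i]] <- data.frame(cell_line = ln, replicate = rep,
                                  timepoint = tp, target_id = tid,
                                  outcome = names(p)[nz],
                                  reads = cnt[nz],
                                  stringsAsFactors = FALSE)
        }
      }
    }
  }
  counts <- do.call(rbind, rows)
  ds <- screen_dataset(targets, counts, control_line = control_line)
  truth <- list(
    probs = probs,
    effects = effects,
    mh_params = params[c("mh_alpha", "mh_gamma", "mh_Amax", "mh_B")],
    annotations = lapply(dists, `[[`, "annotations"),
    realized_lfc = realized_category_lfc(probs, dists, control_line),
    pseudocount = 0.001)
  structure(list(dataset = ds, truth = truth), class = "screen_sim")
}

# exact-probability category LFC vs control, with the profiling pseudocount
realized_category_lfc <- function(probs, dists, control_line,
                                  pseudocount = 0.001) {
  cats <- outcome_categories()
  lines <- setdiff(names(probs), control_line)
  catfreq <- function(p, ann) {
    v <- rowsum(p, ann$category)
    f <- stats::setNames(numeric(length(cats)), cats)
    f[rownames(v)] <- v[, 1L]
    f
  }
  ctrl <- lapply(names(dists), function(tid)
    catfreq(probs[[control_line]][[tid]], dists[[tid]]$annotations))
  names(ctrl) <- names(dists)
  do.call(rbind, lapply(lines, function(ln) {
    lfc_t <- vapply(names(dists), function(tid) {
      f_ko <- catfreq(probs[[ln]][[tid]], dists[[tid]]$annotations)
      log2((f_ko + pseudocount) / (ctrl[[tid]] + pseudocount))
    }, numeric(length(cats)))
    data.frame(cell_line = ln, category = cats,
               lfc = rowMeans(lfc_t), row.names = NULL,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("<screen_sim>\n")
  print(x$dataset)
  cat("  ground truth for ", length(x$truth$probs), " cell lines\n",
      sep = "")
  invisible(x)
}
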