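#' Synthetic community-assembly design
#'
#' Describes an experiment-shaped synthetic dataset with known ground truth:
#' two inocula with four replicates each, family-level baseline compositions
#' per carbon source, carbon-source pairs with a class label (SS/AA/SA), and
#' injected interaction effects epsilon per (pair, family). The defaults
#' emulate the enrichment-community design that motivates the package:
#' sugar communities dominated by Enterobacteriaceae, acid communities
#' dominated by respirative families (Pseudomonadaceae, Moraxellaceae,
#' Rhizobiaceae), with replicate-level compositional noise.
#'
#' @param inocula inoculum labels.
#' @param replicates replicates per (inoculum, environment).
#' @param baselines families x carbon-sources matrix of baseline relative
#'   abundances; every column must sum to 1.
#' @param cs_classes named character vector mapping carbon sources to
#'   `"sugar"` or `"acid"`.
#' @param pairs character vector of `CS1+CS2` labels to include.
#' @param focal_cs focal carbon source(s) used to sign dominance in SS/AA
#'   pairs.
#' @param true_epsilon named list: `true_epsilon[[pair]]` is a named numeric
#'   vector of per-family interaction effects, summing to 0 (unlisted pairs
#'   and families default to 0).
#' @param noise_sd replicate-level compositional noise, as the SD of
#'   log-abundance perturbations (0 gives exact baselines); also the relative
#'   SD of the biomass draw.
#' @param biomass_means named vector of mean biomass (OD620-like) per single
#'   carbon source; pair biomass defaults to the mean of the two singles.
#' @return an object of class `synth_design`.
#' @export
synth_design <- function(inocula = c("I1", "I2"), replicates = 4,
                         baselines = default_baselines(),
                         cs_classes = c(glucose = "sugar", fructose = "sugar",
                                        succinate = "acid", fumarate = "acid"),
                         pairs = c("fructose+glucose", "fumarate+succinate",
                                   "glucose+succinate"),
                         focal_cs = c("glucose", "succinate"),
                         true_epsilon = list(), noise_sd = 0.03,
                         biomass_means = c(glucose = 0.5, fructose = 0.5,
                                           succinate = 0.35,
                                           fumarate = 0.35)) {
  stopifnot(replicates >= 1, noise_sd >= 0)
  pairs <- normalize_pair(pairs)
  names(true_epsilon) <- normalize_pair(names(true_epsilon))
  bad <- which(abs(colSums(baselines) - 1) > 1e-9)
  if (length(bad))
    stop("baseline compositions must sum to 1 (carbon source(s): ",
         paste(colnames(baselines)[bad], collapse = ", "), ")",
         call. = FALSE)
  design <- structure(
    list(inocula = inocula, replicates = replicates, baselines = baselines,
         cs_classes = cs_classes, pairs = pairs, focal_cs = focal_cs,
         true_epsilon = true_epsilon, noise_sd = noise_sd,
         biomass_means = biomass_means),
    class = "synth_design")
  ## every pair must yield a feasible mixture composition
  for (p in pairs) mixture_baseline(design, p)
  design
}

#' Default family-level baseline compositions
#'
#' @return families x carbon-sources matrix; sugar columns are dominated by
#'   Enterobacteriaceae, acid columns by the respirative families.
#' @export
default_baselines <- function() {
  fams <- c("Enterobacteriaceae", "Pseudomonadaceae", "Moraxellaceae",
            "Rhizobiaceae")
  sugar <- c(0.94, 0.03, 0.02, 0.01)
  acid <- c(0.07, 0.59, 0.21, 0.13)
  m <- cbind(glucose = sugar, fructose = sugar,
             succinate = acid, fumarate = acid)
  rownames(m) <- fams
  m
}

## Expected (noise-free) mixture composition of a pair: the null prediction
## from the baseline singles with biomass-mean weights, plus epsilon_true.
mixture_baseline <- function(design, pair) {
  cs <- split_pair(pair)
  if (!all(cs %in% colnames(design$baselines)))
    stop("pair '", pair, "' references a carbon source without a baseline",
         call. = FALSE)
  w <- compute_weights(design$biomass_means[[cs[1]]],
                       design$biomass_means[[cs[2]]])
  f12 <- w[1] * design$baselines[, cs[1]] + w[2] * design$baselines[, cs[2]]
  eps <- design$true_epsilon[[pair]]
  if (!is.null(eps)) {
    full <- stats::setNames(numeric(nrow(design$baselines)),
                            rownames(design$baselines))
    full[names(eps)] <- eps
    if (abs(sum(full)) > 1e-9)
      stop("true_epsilon for pair '", pair, "' must sum to 0", call. = FALSE)
    f12 <- f12 + full
  }
  if (any(f12 < -1e-12) || any(f12 > 1 + 1e-12))
    stop("true_epsilon for pair '", pair,
         "' pushes a family outside [0, 1]", call. = FALSE)
  pmin(pmax(f12, 0), 1)
}

## Multiplicative log-normal compositional noise followed by renormalization
## (zeros stay zero; the simplex constraint stays exact).
perturb_composition <- function(f, noise_sd) {
  if (noise_sd == 0) return(f)
  g <- f * exp(stats::rnorm(length(f), 0, noise_sd))
  g / sum(g)
}

#' Generate a synthetic abundance dataset with known truth
#'
#' Single-carbon-source samples are logistic-normal perturbations of the
#' baselines; mixture samples are built as the biomass-weighted sum of the
#' baseline singles plus the injected epsilon, then perturbed with the same
#' noise model. Biomass is drawn log-normally around the design means. The
#' truth table records, per (pair, family), the injected epsilon and the
#' interaction class it implies.
#'
#' @param design a [synth_design()].
#' @param seed optional integer seed.
#' @return list with `abundance` (validated abundance table), `biomass` and
#'   `truth` data.frames.
#' @export
generate_abundance_dataset <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fams <- rownames(design$baselines)
  envs <- c(colnames(design$baselines), design$pairs)
  ab <- list(); bm <- list()
  for (ino in design$inocula) for (env in envs) {
    base <- if (env %in% design$pairs) mixture_baseline(design, env)
            else design$baselines[, env]
    b_mean <- if (env %in% design$pairs) {
      cs <- split_pair(env)
      mean(design$biomass_means[cs])
    } else design$biomass_means[[env]]
    for (r in seq_len(design$replicates)) {
      sid <- paste(ino, gsub("+", ".", env, fixed = TRUE), r, sep = "_")
      f <- perturb_composition(base, design$noise_sd)
      ab[[length(ab) + 1L]] <- data.frame(
        sample_id = sid, inoculum = ino, replicate = r, environment = env,
        taxon = fams, taxon_level = "family", rel_abundance = unname(f))
      bm[[length(bm) + 1L]] <- data.frame(
        sample_id = sid,
        biomass = b_mean * exp(stats::rnorm(1, 0, design$noise_sd)))
    }
  }
  abundance <- do.call(rbind, ab)
  validate_abundance_table(abundance)
  truth <- do.call(rbind, lapply(design$pairs, function(p) {
    cs <- split_pair(p)
    cls <- design$cs_classes[cs]
    pair_class <- if (all(cls == "sugar")) "SS"
                  else if (all(cls == "acid")) "AA" else "SA"
    f1 <- design$baselines[, cs[1]]; f2 <- design$baselines[, cs[2]]
    f12 <- mixture_baseline(design, p)
    eps_full <- stats::setNames(numeric(length(fams)), fams)
    e <- design$true_epsilon[[p]]
    if (!is.null(e)) eps_full[names(e)] <- e
    do.call(rbind, lapply(fams, function(fm) {
      eps <- eps_full[[fm]]
      if (eps == 0) {
        type <- "none"; dom <- NA_character_; delta <- 0
      } else {
        type <- if (f12[[fm]] > max(f1[[fm]], f2[[fm]])) "synergy"
                else if (f12[[fm]] < min(f1[[fm]], f2[[fm]])) "antagonism"
                else "dominance"
        dom <- dominant_nutrient(f1[[fm]], f2[[fm]], eps, cs[1], cs[2])
        delta <- dominance_index(eps, dom, pair_class, design$cs_classes,
                                 intersect(design$focal_cs, cs)[1], type)
        if (length(delta) > 1) delta <- NA_real_
      }
      data.frame(pair = p, family = fm, pair_class = pair_class,
                 epsilon_true = eps, interaction_type = type,
                 dominant_nutrient = dom, delta_expected = delta)
    }))
  }))
  list(abundance = abundance, biomass = do.call(rbind, bm), truth = truth)
}

#' Generate synthetic growth curves
#'
#' Exponential OD trajectories `od(t) = od0 * 2^(r t)` with multiplicative
#' log-normal measurement noise, sampled on a regular grid, so that
#' [average_growth_rate()] recovers the target rate.
#'
#' @param targets data.frame with columns `isolate, family, carbon_source,
#'   r_avg` (the target rates).
#' @param od0 initial OD.
#' @param interval sampling interval in hours (default 10 min).
#' @param t_max end of the time series in hours.
#' @param replicates replicate curves per target.
#' @param noise_sd SD of multiplicative log-OD noise.
#' @param seed optional integer seed.
#' @return data.frame `isolate, family, carbon_source, replicate, time_h, od`.
#' @export
generate_growth_curves <- function(targets, od0 = 0.01, interval = 1 / 6,
                                   t_max = 16.5, replicates = 3,
                                   noise_sd = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, t_max, by = interval)
  out <- lapply(seq_len(nrow(targets)), function(i) {
    do.call(rbind, lapply(seq_len(replicates), function(rep) {
      od <- od0 * 2^(targets$r_avg[i] * times) *
        exp(stats::rnorm(length(times), 0, noise_sd))
      data.frame(isolate = targets$isolate[i], family = targets$family[i],
                 carbon_source = targets$carbon_source[i], replicate = rep,
                 time_h = times, od = od)
    }))
  })
  do.call(rbind, out)
}
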