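#' Configuration for the permutation interaction test
#'
#' @param n_permutations number of random re-formations of the replicate
#'   pairings (default 1000).
#' @param alpha per-permutation significance level of the one-tailed paired
#'   t-test (default 0.05).
#' @param frac_threshold fraction of permutations that must be individually
#'   significant for the interaction to be called (default 0.95).
#' @param pairs_per_inoculum number of observed-vs-predicted pairs formed per
#'   inoculum at the full design (default 4).
#' @param seed optional integer seed for the permutation stream.
#' @return an object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000, alpha = 0.05,
                               frac_threshold = 0.95,
                               pairs_per_inoculum = 4, seed = NULL) {
  stopifnot(alpha > 0, alpha < 1, frac_threshold > 0, frac_threshold < 1,
            n_permutations >= 1, pairs_per_inoculum >= 1)
  structure(list(n_permutations = as.integer(n_permutations), alpha = alpha,
                 frac_threshold = frac_threshold,
                 pairs_per_inoculum = as.integer(pairs_per_inoculum),
                 seed = seed),
            class = "permutation_config")
}

## Replicate-level data for one (pair, taxon): per inoculum, the single-CS
## abundance vectors f1/f2, the observed mixture vector f12, the biomasses of
## the single-CS samples, and the matrix G of all pairing-level null
## predictions (rows = CS1 replicates, cols = CS2 replicates).
gather_replicates <- function(table, biomass, pair, taxon, level = "family",
                              allow_equal_weights = FALSE) {
  if (length(pair) == 1L) pair <- split_pair(pair)
  cs <- sort(pair)
  x <- aggregate_abundance(table, level)
  r1 <- replicate_abundances(x, cs[1], taxon)
  r2 <- replicate_abundances(x, cs[2], taxon)
  r12 <- replicate_abundances(x, pair_label(cs[1], cs[2]), taxon)
  for (nm in c("r1", "r2", "r12"))
    if (is.null(get(nm)))
      stop("missing replicates for '", c(cs, pair_label(cs[1], cs[2]))[
        match(nm, c("r1", "r2", "r12"))], "'", call. = FALSE)
  inocula <- Reduce(intersect, list(unique(r1$inoculum), unique(r2$inoculum),
                                    unique(r12$inoculum)))
  if (!length(inocula))
    stop("no inoculum with replicates of all three treatments", call. = FALSE)
  out <- lapply(inocula, function(ino) {
    s1 <- r1[r1$inoculum == ino, ]
    s2 <- r2[r2$inoculum == ino, ]
    s12 <- r12[r12$inoculum == ino, ]
    b1 <- lookup_biomass(biomass, s1$sample_id, allow_equal_weights)
    b2 <- lookup_biomass(biomass, s2$sample_id, allow_equal_weights)
    W <- outer(b1, b2, function(a, b) a / (a + b))
    G <- W * s1$rel_abundance + (1 - W) *
      matrix(s2$rel_abundance, nrow(W), ncol(W), byrow = TRUE)
    list(inoculum = ino, f1 = s1$rel_abundance, f2 = s2$rel_abundance,
         f12 = s12$rel_abundance, b1 = b1, b2 = b2, G = G)
  })
  names(out) <- inocula
  structure(out, cs = cs, taxon = taxon)
}

#' Form observed-vs-predicted replicate pairs
#'
#' For each inoculum, predictions are built by randomly pairing one replicate
#' of each single carbon source (a random bijection), each prediction using
#' that pairing's biomass weights; each prediction is then matched without
#' replacement to a distinct observed mixture replicate. Both inocula are
#' pooled (8 pairs at the full 4-replicate design; fewer when a treatment has
#' fewer replicates).
#'
#' @inheritParams predict_null_all_pairings
#' @param config a [permutation_config()] (its `seed`, if set, seeds the
#'   random pair formation).
#' @return data.frame with columns `inoculum`, `observed`, `predicted`.
#' @export
form_prediction_pairs <- function(table, biomass, pair, taxon,
                                  level = "family",
                                  config = permutation_config(),
                                  allow_equal_weights = FALSE) {
  repl <- gather_replicates(table, biomass, pair, taxon, level,
                            allow_equal_weights)
  if (!is.null(config$seed)) set.seed(config$seed)
  check_replication(repl)
  do.call(rbind, lapply(repl, function(z) {
    n1 <- length(z$f1); n2 <- length(z$f2); n12 <- length(z$f12)
    k_pred <- min(n1, n2, config$pairs_per_inoculum)
    sig <- sample.int(n1)[seq_len(k_pred)]
    pii <- sample.int(n2)[seq_len(k_pred)]
    k <- min(k_pred, n12)
    rho <- sample.int(n12)[seq_len(k)]
    data.frame(inoculum = z$inoculum,
               observed = z$f12[rho],
               predicted = z$G[cbind(sig[seq_len(k)], pii[seq_len(k)])])
  }))
}

check_replication <- function(repl) {
  for (z in repl) {
    n <- c(length(z$f1), length(z$f2), length(z$f12))
    if (any(n < 2))
      stop("insufficient replication in inoculum '", z$inoculum,
           "' (need >= 2 replicates per treatment, found ",
           paste(n, collapse = "/"), ")", call. = FALSE)
  }
}

## Vectorized permutation t statistics: one paired t per random re-formation
## of the pairs. Returns the vector of t values and the degrees of freedom.
perm_tstats <- function(repl, config) {
  n_perm <- config$n_permutations
  pieces_obs <- list(); pieces_pred <- list()
  for (z in repl) {
    n1 <- length(z$f1); n2 <- length(z$f2); n12 <- length(z$f12)
    k_pred <- min(n1, n2, config$pairs_per_inoculum)
    k <- min(k_pred, n12)
    sig <- replicate(n_perm, sample.int(n1)[seq_len(k)])
    pii <- replicate(n_perm, sample.int(n2)[seq_len(k)])
    rho <- replicate(n_perm, sample.int(n12)[seq_len(k)])
    dim(sig) <- dim(pii) <- dim(rho) <- c(k, n_perm)
    pieces_pred[[z$inoculum]] <- matrix(z$G[cbind(c(sig), c(pii))], k, n_perm)
    pieces_obs[[z$inoculum]] <- matrix(z$f12[c(rho)], k, n_perm)
  }
  D <- do.call(rbind, pieces_obs) - do.call(rbind, pieces_pred)
  n <- nrow(D)
  if (n < 2) stop("fewer than 2 pairs formed", call. = FALSE)
  m <- colMeans(D)
  s2 <- (colSums(D^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  s <- sqrt(s2)
  t <- ifelse(s > 0, m / (s / sqrt(n)), ifelse(m == 0, 0, sign(m) * Inf))
  if (any(s == 0 & m != 0))
    warning("degenerate (zero-variance) differences; verdict by sign rule",
            call. = FALSE)
  list(t = t, df = n - 1, n_pairs = n)
}

#' Permutation test for a nutrient interaction
#'
#' Repeats the random replicate pair formation `n_permutations` times; for
#' each permutation computes the one-tailed paired t statistic of
#' (observed - predicted) in the requested direction and compares it to the
#' t critical value at `alpha`. The interaction is called significant when
#' more than `frac_threshold` of the permutations are individually
#' significant.
#'
#' @inheritParams form_prediction_pairs
#' @param direction `"positive"` (observed above prediction, epsilon > 0) or
#'   `"negative"`.
#' @return list with `significant` (logical), `frac_significant`, `direction`
#'   and `n_pairs`.
#' @export
permutation_interaction_test <- function(table, biomass, pair, taxon,
                                         direction = c("positive", "negative"),
                                         config = permutation_config(),
                                         level = "family",
                                         allow_equal_weights = FALSE) {
  direction <- match.arg(direction)
  repl <- gather_replicates(table, biomass, pair, taxon, level,
                            allow_equal_weights)
  check_replication(repl)
  if (!is.null(config$seed)) set.seed(config$seed)
  ts <- perm_tstats(repl, config)
  crit <- stats::qt(1 - config$alpha, ts$df)
  frac <- if (direction == "positive") mean(ts$t > crit)
          else mean(ts$t < -crit)
  list(significant = frac > config$frac_threshold,
       frac_significant = frac, direction = direction, n_pairs = ts$n_pairs)
}

#' Classify a significant interaction
#'
#' Once an interaction has been detected, synergy occurs when the mixture
#' abundance exceeds the larger of the two single-nutrient abundances and
#' antagonism when it falls below the smaller one (Welch two-sample t-test at
#' `alpha` against the replicates of the extreme single); anything in between
#' is dominance. With no significant interaction the type is `"none"`.
#'
#' @param f1_reps,f2_reps,f12_reps replicate abundance vectors of the taxon in
#'   the two singles and the mixture (inocula pooled).
#' @param significant_pos,significant_neg verdicts of the positive- and
#'   negative-direction permutation tests.
#' @param alpha significance level of the Welch test.
#' @return one of `"none"`, `"dominance"`, `"synergy"`, `"antagonism"`.
#' @export
classify_interaction <- function(f1_reps, f2_reps, f12_reps,
                                 significant_pos, significant_neg,
                                 alpha = 0.05) {
  if (!significant_pos && !significant_neg) return("none")
  m1 <- mean(f1_reps); m2 <- mean(f2_reps); m12 <- mean(f12_reps)
  hi <- if (m1 >= m2) f1_reps else f2_reps
  lo <- if (m1 <= m2) f1_reps else f2_reps
  welch_greater <- function(a, b) {
    if (length(a) < 2 || length(b) < 2 ||
        (stats::sd(a) == 0 && stats::sd(b) == 0)) {
      warning("Welch test unavailable; falling back to point comparison ",
              "(low confidence)", call. = FALSE)
      return(mean(a) > mean(b))
    }
    stats::t.test(a, b, alternative = "greater")$p.value < alpha
  }
  if (significant_pos && m12 > max(m1, m2) && welch_greater(f12_reps, hi))
    return("synergy")
  if (significant_neg && m12 < min(m1, m2) && welch_greater(lo, f12_reps))
    return("antagonism")
  "dominance"
}

#' Identify the dominant nutrient
#'
#' When the interaction is positive (epsilon > 0) the dominant nutrient is the
#' one where the taxon grew to the higher abundance; when it is negative the
#' dominant nutrient is the one where the taxon grew less well.
#'
#' @param f1_mean,f2_mean mean abundances of the taxon in nutrients 1 and 2.
#' @param epsilon_sign sign of the interaction (any nonzero number; only the
#'   sign is used).
#' @param cs1,cs2 labels of the two nutrients.
#' @return the dominant nutrient's label, or `NA` when `f1_mean == f2_mean`
#'   (dominance undefined).
#' @export
dominant_nutrient <- function(f1_mean, f2_mean, epsilon_sign,
                              cs1 = "CS1", cs2 = "CS2") {
  if (f1_mean == f2_mean) return(NA_character_)
  if (epsilon_sign > 0) {
    if (f1_mean > f2_mean) cs1 else cs2
  } else {
    if (f1_mean < f2_mean) cs1 else cs2
  }
}

#' Dominance index
#'
#' Signed magnitude of the interaction. For sugar-acid pairs the index is
#' `-|epsilon|` when the sugar dominates and `+|epsilon|` when the acid
#' dominates; for sugar-sugar and acid-acid pairs the sign is negative when
#' the focal carbon source dominates. With no interaction the index is 0.
#' When the two inocula disagree on the dominant nutrient the sign is
#' undefined and both values are returned.
#'
#' @param epsilon the interaction effect (mean observed minus predicted).
#' @param dominant_nutrient label(s) of the dominant nutrient; a vector with
#'   more than one distinct value (or `NA`) marks an undefined sign.
#' @param pair_class `"SA"` (sugar-acid), `"SS"` or `"AA"`.
#' @param cs_classes named character vector mapping carbon sources to
#'   `"sugar"` or `"acid"` (required for `"SA"` pairs).
#' @param focal_cs the focal carbon source (required for `"SS"`/`"AA"` pairs).
#' @param interaction_type the classified type; `"none"` gives 0.
#' @return the dominance index; length 2 (`c(-|e|, +|e|)`) when the sign is
#'   undefined.
#' @export
dominance_index <- function(epsilon, dominant_nutrient, pair_class,
                            cs_classes = NULL, focal_cs = NULL,
                            interaction_type = "dominance") {
  if (!pair_class %in% c("SA", "SS", "AA"))
    stop("unknown pair class '", pair_class, "'", call. = FALSE)
  if (interaction_type == "none" || epsilon == 0) return(0)
  mag <- abs(epsilon)
  doms <- unique(dominant_nutrient)
  if (length(doms) != 1L || any(is.na(doms))) return(c(-mag, mag))
  if (pair_class == "SA") {
    if (is.null(cs_classes) || is.na(cs_classes[doms]))
      stop("cs_classes must map '", doms, "' to sugar or acid", call. = FALSE)
    if (cs_classes[[doms]] == "sugar") -mag else mag
  } else {
    if (is.null(focal_cs))
      stop("focal_cs is required for ", pair_class, " pairs", call. = FALSE)
    if (doms == focal_cs) -mag else mag
  }
}

#' Test and classify interactions for many pairs and taxa
#'
#' Full driver for the interaction analysis: for every carbon-source pair and
#' taxon it runs the two one-tailed permutation tests, classifies the
#' interaction, identifies the dominant nutrient (per inoculum, to detect
#' disagreements) and computes the dominance index.
#'
#' @inheritParams predict_pairs
#' @param cs_classes named character vector mapping every carbon source to
#'   `"sugar"` or `"acid"`.
#' @param focal_cs focal carbon source(s) used to sign the index of SS/AA
#'   pairs; a pair's focal CS is the member listed here.
#' @param config a [permutation_config()].
#' @param per_inoculum if `TRUE` (the genus/species-level mode), the whole
#'   procedure is run for each inoculum separately with N = 4 pairs.
#' @return data.frame with columns `pair, taxon, level, inoculum,
#'   epsilon_mean, frac_significant, direction, interaction_type,
#'   dominant_nutrient, delta, delta_sign_defined`.
#' @export
test_interactions <- function(table, biomass, cs_classes, pairs = NULL,
                              focal_cs = NULL, level = "family", taxa = NULL,
                              min_mean_abundance = 0.01,
                              config = permutation_config(),
                              per_inoculum = FALSE,
                              allow_equal_weights = FALSE) {
  if (per_inoculum) {
    out <- lapply(sort(unique(table$inoculum)), function(ino) {
      sub <- table[table$inoculum == ino, ]
      res <- test_interactions(sub, biomass, cs_classes, pairs, focal_cs,
                               level, taxa, min_mean_abundance, config,
                               per_inoculum = FALSE, allow_equal_weights)
      res$inoculum <- ino
      res
    })
    return(do.call(rbind, out))
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  x <- aggregate_abundance(table, level)
  if (is.null(pairs))
    pairs <- sort(unique(x$environment[grepl("+", x$environment,
                                             fixed = TRUE)]))
  rows <- list()
  for (p in pairs) {
    cs <- split_pair(p)
    cls <- cs_classes[cs]
    if (any(is.na(cls)))
      stop("cs_classes must cover both members of pair '", p, "'",
           call. = FALSE)
    pair_class <- if (all(cls == "sugar")) "SS"
                  else if (all(cls == "acid")) "AA" else "SA"
    focal <- if (!is.null(focal_cs)) intersect(focal_cs, cs)[1] else NA
    sub <- x[x$environment %in% c(cs, p), ]
    cand <- if (is.null(taxa)) {
      means <- tapply(sub$rel_abundance, sub$taxon, sum) /
        length(unique(sub$sample_id))
      sort(names(means)[means > min_mean_abundance])
    } else taxa
    for (tx in cand) {
      repl <- gather_replicates(table, biomass, cs, tx, level,
                                allow_equal_weights)
      check_replication(repl)
      ts <- perm_tstats(repl, config)
      crit <- stats::qt(1 - config$alpha, ts$df)
      frac_pos <- mean(ts$t > crit)
      frac_neg <- mean(ts$t < -crit)
      sig_pos <- frac_pos > config$frac_threshold
      sig_neg <- frac_neg > config$frac_threshold
      if (sig_pos && sig_neg)
        stop("both directions significant for ", p, " / ", tx,
             ": inconsistent data", call. = FALSE)
      eps <- mean(unlist(lapply(repl, function(z) z$f12 - mean(z$G))))
      f1 <- unlist(lapply(repl, `[[`, "f1"))
      f2 <- unlist(lapply(repl, `[[`, "f2"))
      f12 <- unlist(lapply(repl, `[[`, "f12"))
      type <- classify_interaction(f1, f2, f12, sig_pos, sig_neg,
                                   config$alpha)
      direction <- if (sig_pos) "positive" else if (sig_neg) "negative"
                   else "none"
      if (type == "none") {
        dom <- NA_character_; delta <- 0; sign_def <- TRUE
      } else {
        doms <- vapply(repl, function(z)
          dominant_nutrient(mean(z$f1), mean(z$f2), eps, cs[1], cs[2]),
          character(1))
        doms <- unique(doms[!is.na(doms)])
        delta_v <- dominance_index(eps, if (length(doms)) doms else NA,
                                   pair_class, cs_classes,
                                   if (!is.na(focal)) focal else NULL, type)
        sign_def <- length(delta_v) == 1L
        dom <- if (length(doms) == 1L) doms else NA_character_
        delta <- if (sign_def) delta_v else abs(delta_v[2])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair = p, taxon = tx, level = level, inoculum = "pooled",
        epsilon_mean = eps,
        frac_significant = max(frac_pos, frac_neg),
        direction = direction, interaction_type = type,
        dominant_nutrient = dom, delta = delta,
        delta_sign_defined = sign_def)
    }
  }
  do.call(rbind, rows)
}

#' Prevalence of interaction types
#'
#' Fraction of calls with no interaction, and the breakdown of the interacting
#' calls into dominance, synergy and antagonism (fractions of interacting
#' calls, summing to 1).
#'
#' @param calls data.frame of interaction calls (needs an `interaction_type`
#'   column), e.g. from [test_interactions()].
#' @return list with `frac_none`, `frac_dominance`, `frac_synergy`,
#'   `frac_antagonism` (the last three are `NA` when nothing interacts).
#' @export
interaction_prevalence <- function(calls) {
  if (!nrow(calls)) stop("no interaction calls supplied", call. = FALSE)
  type <- calls$interaction_type
  n <- length(type)
  n_int <- sum(type != "none")
  frac_of_int <- function(t) if (n_int) sum(type == t) / n_int else NA_real_
  list(frac_none = sum(type == "none") / n,
       frac_dominance = frac_of_int("dominance"),
       frac_synergy = frac_of_int("synergy"),
       frac_antagonism = frac_of_int("antagonism"))
}
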