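#' Biomass weights for a pair of single-nutrient communities
#'
#' Computes the weights used by the null additive model from the total
#' population sizes (OD620-like biomass proxies) of the two single-nutrient
#' communities: `w1 = b1 / (b1 + b2)` and `w2 = b2 / (b1 + b2)`.
#'
#' @param biomass_1,biomass_2 non-negative biomass of the communities grown on
#'   nutrient 1 and nutrient 2.
#' @return numeric vector `c(w1, w2)` summing to 1.
#' @export
#' @examples
#' compute_weights(0.4, 0.1)  # c(0.8, 0.2)
compute_weights <- function(biomass_1, biomass_2) {
  if (any(!is.finite(c(biomass_1, biomass_2))) ||
      biomass_1 < 0 || biomass_2 < 0)
    stop("biomass must be finite and non-negative", call. = FALSE)
  tot <- biomass_1 + biomass_2
  if (tot <= 0)
    stop("weights are undefined when both biomasses are zero", call. = FALSE)
  c(w1 = biomass_1 / tot, w2 = biomass_2 / tot)
}

#' Null additive prediction for one taxon in a nutrient mixture
#'
#' Under the null model of independently acting nutrients, the relative
#' abundance of a taxon in a mixture of nutrients 1 and 2 is the
#' biomass-weighted sum of its relative abundances in the single nutrients:
#' `f_null = w1 * f1 + w2 * f2`. The prediction always lies between
#' `min(f1, f2)` and `max(f1, f2)`.
#'
#' @param f1,f2 relative abundances of the taxon in nutrients 1 and 2
#'   (fractions in `[0, 1]`; vectors are recycled element-wise).
#' @param w1,w2 biomass weights, non-negative and summing to 1.
#' @return predicted relative abundance(s) in the mixture.
#' @export
#' @examples
#' predict_null(0.8, 0.2, 0.8, 0.2)  # 0.68
predict_null <- function(f1, f2, w1, w2) {
  if (any(f1 < 0 | f1 > 1) || any(f2 < 0 | f2 > 1))
    stop("relative abundances must lie in [0, 1]", call. = FALSE)
  if (any(w1 < 0) || any(w2 < 0) || any(abs(w1 + w2 - 1) > 1e-9))
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  w1 * f1 + w2 * f2
}

## Aggregate an abundance table to one taxonomic level: rows at that level are
## kept and duplicated (sample, taxon) entries are summed.
aggregate_abundance <- function(table, level = "family") {
  x <- table[table$taxon_level == level, , drop = FALSE]
  if (!nrow(x))
    stop("no rows at taxon_level '", level, "'", call. = FALSE)
  key <- paste(x$sample_id, x$taxon, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- stats::aggregate(
      rel_abundance ~ sample_id + inoculum + replicate + environment + taxon,
      data = x, FUN = sum)
    agg$taxon_level <- level
    x <- agg[, ABUNDANCE_COLS]
  }
  x
}

## Per-replicate abundance vector of one taxon in one environment, indexed by
## (inoculum, replicate). Taxa absent from an existing sample count as 0.
replicate_abundances <- function(table, environment, taxon) {
  env <- table[table$environment == environment, , drop = FALSE]
  if (!nrow(env)) return(NULL)
  samples <- unique(env[, c("sample_id", "inoculum", "replicate")])
  hit <- env[env$taxon == taxon, c("sample_id", "rel_abundance")]
  samples$rel_abundance <- hit$rel_abundance[match(samples$sample_id,
                                                   hit$sample_id)]
  samples$rel_abundance[is.na(samples$rel_abundance)] <- 0
  samples[order(samples$inoculum, samples$replicate), ]
}

lookup_biomass <- function(biomass, sample_id, allow_equal_weights) {
  b <- biomass$biomass[match(sample_id, biomass$sample_id)]
  if (any(is.na(b))) {
    if (!allow_equal_weights)
      stop("missing biomass for sample(s): ",
           paste(sample_id[is.na(b)], collapse = ", "),
           " (set allow_equal_weights = TRUE to fall back to equal weights)",
           call. = FALSE)
    b[is.na(b)] <- 1
  }
  b
}

#' Null-model predictions over all replicate pairings
#'
#' Enumerates, within each inoculum, every pairing of one replicate of the
#' first single-nutrient community with one replicate of the second (4 x 4 =
#' 16 pairings per inoculum at the full design), computes one null prediction
#' per pairing using that pairing's biomass weights, and summarizes them.
#' Pairings never cross inocula. The interaction residual epsilon is filled in
#' from the observed mixture samples when these exist in `table`
#' (per observed mixture replicate, against the mean prediction of its
#' inoculum).
#'
#' @param table abundance table (see [validate_abundance_table()]).
#' @param biomass biomass table with one row per sample.
#' @param pair character vector of the two carbon sources, or a `CS1+CS2`
#'   label.
#' @param taxon taxon to predict.
#' @param level taxonomic level at which to aggregate before predicting.
#' @param allow_equal_weights if `TRUE`, samples with no biomass record fall
#'   back to equal weights instead of failing.
#' @return an object of class `mixture_prediction`: a list with the per-pairing
#'   table (`pairings`), `f_null_values`, `f_null_mean`, mean weights
#'   `w1`/`w2`, `epsilon_values` and `epsilon_mean` (NA when no observed
#'   mixture sample exists).
#' @export
predict_null_all_pairings <- function(table, biomass, pair, taxon,
                                      level = "family",
                                      allow_equal_weights = FALSE) {
  if (length(pair) == 1L) pair <- split_pair(pair)
  cs <- sort(pair)
  x <- aggregate_abundance(table, level)
  reps <- lapply(cs, function(s) replicate_abundances(x, s, taxon))
  for (k in 1:2)
    if (is.null(reps[[k]]))
      stop("no single carbon source replicate found for nutrient '",
           cs[k], "'", call. = FALSE)
  inocula <- intersect(unique(reps[[1]]$inoculum), unique(reps[[2]]$inoculum))
  if (!length(inocula))
    stop("no inoculum with replicates of both '", cs[1], "' and '", cs[2],
         "'", call. = FALSE)
  pairings <- do.call(rbind, lapply(inocula, function(ino) {
    r1 <- reps[[1]][reps[[1]]$inoculum == ino, ]
    r2 <- reps[[2]][reps[[2]]$inoculum == ino, ]
    grid <- expand.grid(i = seq_len(nrow(r1)), j = seq_len(nrow(r2)))
    b1 <- lookup_biomass(biomass, r1$sample_id[grid$i], allow_equal_weights)
    b2 <- lookup_biomass(biomass, r2$sample_id[grid$j], allow_equal_weights)
    w1 <- b1 / (b1 + b2)
    data.frame(inoculum = ino,
               rep1 = r1$replicate[grid$i], rep2 = r2$replicate[grid$j],
               f1 = r1$rel_abundance[grid$i], f2 = r2$rel_abundance[grid$j],
               w1 = w1, w2 = 1 - w1,
               f_null = w1 * r1$rel_abundance[grid$i] +
                 (1 - w1) * r2$rel_abundance[grid$j])
  }))
  obs <- replicate_abundances(x, pair_label(cs[1], cs[2]), taxon)
  eps <- NULL
  if (!is.null(obs)) {
    eps <- unlist(lapply(inocula, function(ino) {
      oi <- obs[obs$inoculum == ino, ]
      if (!nrow(oi)) return(NULL)
      oi$rel_abundance - mean(pairings$f_null[pairings$inoculum == ino])
    }))
  }
  structure(list(
    pair_id = pair_label(cs[1], cs[2]), taxon = taxon, level = level,
    pairings = pairings,
    f_null_values = pairings$f_null, f_null_mean = mean(pairings$f_null),
    w1 = mean(pairings$w1), w2 = mean(pairings$w2),
    epsilon_values = eps,
    epsilon_mean = if (is.null(eps)) NA_real_ else mean(eps)
  ), class = "mixture_prediction")
}

#' @export
print.mixture_prediction <- function(x, ...) {
  cat("Null-model prediction for", x$taxon, "in", x$pair_id,
      "(", x$level, "level )\n")
  cat(sprintf("  f_null = %.4f over %d replicate pairings (w1 = %.3f)\n",
              x$f_null_mean, nrow(x$pairings), x$w1))
  if (!is.na(x$epsilon_mean))
    cat(sprintf("  epsilon = %+.4f over %d observed mixture replicates\n",
                x$epsilon_mean, length(x$epsilon_values)))
  invisible(x)
}

#' Null-model predictions for many pairs and taxa
#'
#' Driver over a set of carbon-source pairs: for every pair and every taxon
#' passing the abundance filter, runs [predict_null_all_pairings()] and
#' collects the tidy prediction table.
#'
#' @param table,biomass abundance and biomass tables.
#' @param pairs character vector of `CS1+CS2` labels; defaults to all pair
#'   environments present in `table`.
#' @param level taxonomic level, default `"family"`.
#' @param taxa taxa to predict; defaults to every taxon at `level` whose mean
#'   abundance in the relevant environments exceeds `min_mean_abundance`.
#' @param min_mean_abundance inclusion filter on the mean abundance of a taxon
#'   over the pair's three environments.
#' @param allow_equal_weights see [predict_null_all_pairings()].
#' @return data.frame with columns
#'   `pair, taxon, w1, w2, f_null_mean, epsilon_mean, n_pairings`.
#' @export
predict_pairs <- function(table, biomass, pairs = NULL, level = "family",
                          taxa = NULL, min_mean_abundance = 0,
                          allow_equal_weights = FALSE) {
  x <- aggregate_abundance(table, level)
  if (is.null(pairs))
    pairs <- sort(unique(x$environment[grepl("+", x$environment,
                                             fixed = TRUE)]))
  out <- lapply(pairs, function(p) {
    cs <- split_pair(p)
    envs <- c(cs, p)
    sub <- x[x$environment %in% envs, ]
    cand <- if (is.null(taxa)) {
      means <- tapply(sub$rel_abundance, sub$taxon, sum) /
        length(unique(sub$sample_id))
      names(means)[means > min_mean_abundance]
    } else taxa
    do.call(rbind, lapply(sort(cand), function(tx) {
      pred <- predict_null_all_pairings(table, biomass, cs, tx, level,
                                        allow_equal_weights)
      data.frame(pair = pred$pair_id, taxon = tx,
                 w1 = pred$w1, w2 = pred$w2,
                 f_null_mean = pred$f_null_mean,
                 epsilon_mean = pred$epsilon_mean,
                 n_pairings = nrow(pred$pairings))
    }))
  })
  do.call(rbind, out)
}

#' Observed-vs-predicted fit metrics
#'
#' Pearson product-moment correlation (via [stats::cor.test()]) and
#' root-mean-square error between observed and null-predicted relative
#' abundances.
#'
#' @param observed,predicted equal-length numeric vectors of fractions.
#' @return list with `pearson_r`, `p_value`, `rmse` and `n`. When either
#'   vector has zero variance the correlation is undefined: `pearson_r` and
#'   `p_value` are `NA` (with a warning) and the RMSE is still returned.
#' @export
fit_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have the same length", call. = FALSE)
  n <- length(observed)
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  rmse <- sqrt(mean((observed - predicted)^2))
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    warning("zero variance: correlation is undefined", call. = FALSE)
    return(list(pearson_r = NA_real_, p_value = NA_real_, rmse = rmse, n = n))
  }
  ct <- stats::cor.test(observed, predicted)
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       rmse = rmse, n = n)
}
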