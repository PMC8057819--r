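#' Parameters of the Microbial Consumer Resource Model
#'
#' The MiCRM couples the abundances `N_i` of `n_species` consumers to the
#' abundances `R_a` of `M` substitutable resources in a well-mixed,
#' chemostat-like habitat with continuous resource supply:
#' \deqn{dN_i/dt = N_i [\sum_a (1-l) R_a c_{ia} - m]}
#' \deqn{dR_a/dt = (R^0_a - R_a)/\tau - \sum_j N_j R_a c_{ja}
#'       + l \sum_{j,b} N_j D_{ab} R_b c_{jb}}
#' Species belong to two equal-sized families (`F_A`, `F_S`), resources to two
#' equal-sized classes (`A`, `S`); each family has, on average, a higher
#' uptake rate on its preferred class, tuned by `q_A` and `q_S`.
#'
#' Per (family, class) block the uptake rates are gamma distributed with mean
#' `mu_c/M * (1 +/- q)` and variance `sigma_c^2/M * (1 +/- q)` (`+` on the
#' preferred class). `sigma_c` is the uptake dispersion scale expressed as a
#' standard deviation.
#'
#' @param n_species number of species, split equally between the families.
#' @param M number of resources, split equally between the classes.
#' @param mu_c mean uptake scale.
#' @param sigma_c uptake dispersion scale (SD; block variance
#'   `sigma_c^2/M * (1 +/- q)`).
#' @param q_A,q_S specialization of each family on its preferred resource
#'   class, in `[0, 1]`.
#' @param l leakage fraction: fraction of consumed resource flux secreted as
#'   metabolic by-products.
#' @param m maintenance (minimal energy requirement).
#' @param tau timescale of external resource supply.
#' @param s sparsity of the metabolic network; the Dirichlet concentration of
#'   each column of the metabolic matrix is `1/(s*M)`.
#' @param R0_total total supplied resource abundance per habitat.
#' @param extinction_threshold abundance below which a species is extinct.
#' @param convergence_threshold bound on `|dlnN_i/dt|` over surviving species
#'   for a run to count as converged.
#' @param initial_abundance initial abundance of every species.
#' @return an object of class `micrm_params`.
#' @export
micrm_params <- function(n_species = 200, M = 20, mu_c = 10, sigma_c = 3,
                         q_A = 0.9, q_S = 0.9, l = 0.5, m = 1, tau = 1,
                         s = 0.3, R0_total = 1000,
                         extinction_threshold = 1e-6,
                         convergence_threshold = 1e-5,
                         initial_abundance = 1) {
  stopifnot(q_A >= 0, q_A <= 1, q_S >= 0, q_S <= 1, l >= 0, l < 1,
            mu_c > 0, sigma_c > 0, tau > 0, s > 0, R0_total > 0,
            n_species %% 2 == 0, M %% 2 == 0)
  structure(as.list(environment()), class = "micrm_params")
}

#' @export
print.micrm_params <- function(x, ...) {
  cat(sprintf(
    "MiCRM parameters: %d species (2 families), %d resources (2 classes)\n",
    x$n_species, x$M))
  cat(sprintf("  mu_c = %g, sigma_c = %g, q_A = %g, q_S = %g\n",
              x$mu_c, x$sigma_c, x$q_A, x$q_S))
  cat(sprintf("  l = %g, m = %g, tau = %g, s = %g, R0_total = %g\n",
              x$l, x$m, x$tau, x$s, x$R0_total))
  invisible(x)
}

#' Sample a family-structured uptake matrix
#'
#' Draws the `n_species x M` uptake matrix from per-block gamma distributions
#' (shape `mean^2/var`, scale `var/mean`). A fully specialized family
#' (`q = 1`) makes the disadvantaged block degenerate at mean 0; those
#' entries are set to 0.
#'
#' @param params a [micrm_params()] object.
#' @return list with the matrix `c`, the species `family` factor
#'   (`"F_A"`/`"F_S"`) and the resource `class` factor (`"A"`/`"S"`).
#' @export
sample_uptake_matrix <- function(params) {
  n <- params$n_species; M <- params$M
  fam <- rep(c("F_A", "F_S"), each = n / 2)
  cls <- rep(c("A", "S"), each = M / 2)
  cmat <- matrix(0, n, M)
  for (fi in c("F_A", "F_S")) for (ca in c("A", "S")) {
    q <- if (ca == "A") params$q_A else params$q_S
    preferred <- (fi == "F_A") == (ca == "A")
    fac <- 1 + if (preferred) q else -q
    mu <- params$mu_c / M * fac
    v <- params$sigma_c^2 / M * fac
    block <- fam == fi
    acol <- cls == ca
    k <- sum(block) * sum(acol)
    cmat[block, acol] <- if (mu <= 0 || v <= 0) 0 else
      stats::rgamma(k, shape = mu^2 / v, scale = v / mu)
  }
  list(c = cmat, family = fam, class = cls)
}

#' Sample a column-stochastic metabolic matrix
#'
#' Each column of the `M x M` matrix `D` is drawn from a symmetric Dirichlet
#' distribution with concentration `1/(s*M)`, so that every column sums to 1
#' and the total secretion flux never exceeds the input flux. `D[a, b]` is
#' the fraction of consumed resource `b` secreted as by-product `a`.
#'
#' @param params a [micrm_params()] object.
#' @return the metabolic matrix `D`.
#' @export
sample_metabolic_matrix <- function(params) {
  M <- params$M
  if (M == 1L) return(matrix(1, 1, 1))
  conc <- 1 / (params$s * M)
  D <- matrix(stats::rgamma(M * M, shape = conc), M, M)
  csum <- colSums(D)
  zero <- csum == 0  # numerically possible at tiny concentrations
  if (any(zero)) { D[, zero] <- 1 / M; csum[zero] <- 1 }
  sweep(D, 2, colSums(D), "/")
}

#' Assemble a MiCRM system
#'
#' Samples one uptake matrix and one metabolic matrix under `params`.
#'
#' @param params a [micrm_params()] object.
#' @param seed optional seed for the sampling.
#' @return an object of class `micrm_system`: list with `c`, `D`, `family`,
#'   `class` and `params`.
#' @export
micrm_system <- function(params = micrm_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  upt <- sample_uptake_matrix(params)
  structure(list(c = upt$c, D = sample_metabolic_matrix(params),
                 family = upt$family, class = upt$class, params = params),
            class = "micrm_system")
}

#' MiCRM time derivatives
#'
#' Evaluates the right-hand side of the consumer and resource equations at a
#' state `(N, R)`.
#'
#' @param N species abundance vector (length `nrow(system$c)`).
#' @param R resource abundance vector (length `M`).
#' @param system a [micrm_system()] (possibly restricted to a species subset).
#' @param R0 supply vector; defaults to zero supply.
#' @return list with `dN` and `dR`.
#' @export
micrm_dynamics <- function(N, R, system, R0 = rep(0, length(R))) {
  if (any(N < 0) || any(R < 0))
    stop("state must be non-negative", call. = FALSE)
  p <- system$params
  growth <- (1 - p$l) * drop(system$c %*% R) - p$m
  consumption <- drop(crossprod(system$c, N))  # per-resource sum_j N_j c_ja
  secretion <- p$l * drop(system$D %*% (consumption * R))
  list(dN = N * growth,
       dR = (R0 - R) / p$tau - consumption * R + secretion)
}

## deSolve interface: derivatives and analytic Jacobian for the stacked state
## x = c(N, R). The analytic Jacobian is what makes stiff integration of the
## 220-dimensional initial community affordable.
micrm_deriv_desolve <- function(t, x, parms) {
  n <- parms$n; M <- parms$M
  N <- x[seq_len(n)]; R <- x[n + seq_len(M)]
  g <- (1 - parms$l) * drop(parms$c %*% R) - parms$m
  cons <- drop(crossprod(parms$c, N))
  dR <- (parms$R0 - R) / parms$tau - cons * R +
    parms$l * drop(parms$D %*% (cons * R))
  list(c(N * g, dR))
}

micrm_jac_desolve <- function(t, x, parms) {
  n <- parms$n; M <- parms$M
  N <- x[seq_len(n)]; R <- x[n + seq_len(M)]
  g <- (1 - parms$l) * drop(parms$c %*% R) - parms$m
  cons <- drop(crossprod(parms$c, N))
  J <- matrix(0, n + M, n + M)
  if (n) {
    J[cbind(seq_len(n), seq_len(n))] <- g
    J[seq_len(n), n + seq_len(M)] <- N * (1 - parms$l) * parms$c
    J[n + seq_len(M), seq_len(n)] <- -R * t(parms$c) +
      parms$l * parms$D %*% (R * t(parms$c))
  }
  J[n + seq_len(M), n + seq_len(M)] <-
    diag(-1 / parms$tau - cons, M) + parms$l * parms$D %*% diag(cons, M)
  J
}

## Newton refinement of the equilibrium on a fixed survivor set; species
## driven non-positive are dropped and the iteration continues.
newton_polish <- function(system, keep, N, R, R0, max_iter = 60) {
  p <- system$params
  M <- p$M
  ext <- p$extinction_threshold
  for (it in seq_len(max_iter)) {
    nn <- length(keep)
    csub <- system$c[keep, , drop = FALSE]
    g <- (1 - p$l) * drop(csub %*% R) - p$m
    cons <- drop(crossprod(csub, N))
    FR <- (R0 - R) / p$tau - cons * R + p$l * drop(system$D %*% (cons * R))
    if (max(abs(c(g, FR))) < 1e-12) break
    J <- matrix(0, nn + M, nn + M)
    if (nn) {
      J[cbind(seq_len(nn), seq_len(nn))] <- g
      J[seq_len(nn), nn + seq_len(M)] <- N * (1 - p$l) * csub
      J[nn + seq_len(M), seq_len(nn)] <- -R * t(csub) +
        p$l * system$D %*% (R * t(csub))
    }
    J[nn + seq_len(M), nn + seq_len(M)] <-
      diag(-1 / p$tau - cons, M) + p$l * system$D %*% diag(cons, M)
    step <- tryCatch(solve(J, c(N * g, FR)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    N <- pmax(N - step[seq_len(nn)], 0)
    R <- pmax(R - step[nn + seq_len(M)], 0)
    dead <- N <= ext
    if (any(dead)) { keep <- keep[!dead]; N <- N[!dead] }
    if (!length(keep)) break
  }
  list(keep = keep, N = N, R = R)
}

#' Solve a MiCRM community to steady state
#'
#' Integrates the dynamics from `N_i = initial_abundance`, `R = R0` with a
#' stiff solver ([deSolve::lsoda()] with the analytic Jacobian) in chunks of
#' increasing horizon, pruning species that fall below the extinction
#' threshold between chunks, then polishes the equilibrium with Newton
#' iterations on the survivor set. Convergence is verified post hoc: the run
#' is flagged converged only when every surviving species satisfies
#' `|dlnN_i/dt| <= convergence_threshold` under [micrm_dynamics()].
#'
#' @param system a [micrm_system()].
#' @param R0 length-`M` supply vector (see [make_environment()]).
#' @param t_chunks increasing integration horizons tried before giving up.
#' @return an object of class `steady_state`: list with the full-length
#'   `N_star` (zeros for extinct species), `R_star`, integer `survivors`,
#'   `rel_abundance` over survivors, `biomass` (total survivor abundance),
#'   per-`family` relative abundances and the `converged` flag.
#' @export
find_steady_state <- function(system, R0,
                              t_chunks = c(2, 5, 10, 20, 50, 100, 200, 400,
                                           800, 1600, 3200)) {
  p <- system$params
  n0 <- nrow(system$c); M <- p$M
  stopifnot(length(R0) == M)
  keep <- seq_len(n0)
  N <- rep(p$initial_abundance, n0)
  R <- R0
  ext <- p$extinction_threshold
  parms <- list(c = system$c, D = system$D, R0 = R0, l = p$l, m = p$m,
                tau = p$tau, n = n0, M = M)
  ok <- TRUE
  for (tc in t_chunks) {
    out <- tryCatch(
      deSolve::lsoda(c(N, R), c(0, tc), micrm_deriv_desolve, parms,
                     jacfunc = micrm_jac_desolve, jactype = "fullusr",
                     rtol = 1e-7, atol = 1e-10),
      error = function(e) NULL)
    if (is.null(out) || nrow(out) < 2) { ok <- FALSE; break }
    x <- unname(out[nrow(out), -1])
    N <- pmax(x[seq_len(parms$n)], 0)
    R <- pmax(x[parms$n + seq_len(M)], 0)
    alive <- N > ext
    keep <- keep[alive]; N <- N[alive]
    parms$c <- system$c[keep, , drop = FALSE]; parms$n <- length(keep)
    if (!length(keep)) break
    g <- (1 - p$l) * drop(parms$c %*% R) - p$m
    if (max(abs(g)) < 1e-3) break
  }
  if (ok && length(keep)) {
    pol <- newton_polish(system, keep, N, R, R0)
    keep <- pol$keep; N <- pol$N; R <- pol$R
  }
  conv <- FALSE
  if (ok) {
    if (length(keep)) {
      sub <- system
      sub$c <- system$c[keep, , drop = FALSE]
      d <- micrm_dynamics(N, R, sub, R0)
      conv <- max(abs(d$dN / N)) <= p$convergence_threshold
    } else conv <- TRUE
  }
  N_star <- numeric(n0); N_star[keep] <- N
  rel <- if (length(keep)) N / sum(N) else numeric(0)
  names(rel) <- keep
  fam_rel <- if (length(keep))
    vapply(c("F_A", "F_S"),
           function(f) sum(rel[system$family[keep] == f]), numeric(1))
  else c(F_A = NA_real_, F_S = NA_real_)
  structure(list(N_star = N_star, R_star = R, survivors = keep,
                 rel_abundance = rel, biomass = sum(N),
                 family_abundance = fam_rel, converged = conv),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf("MiCRM steady state: %d survivors, biomass %.3f, %s\n",
              length(x$survivors), x$biomass,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Build a supply vector for one environment
#'
#' Single-resource environments supply `R0_total` of one resource; mixed
#' environments supply `R0_total/2` of each of two resources, keeping the
#' total constant.
#'
#' @param resources index (length 1 or 2) of the supplied resource(s).
#' @param params a [micrm_params()] object.
#' @return length-`M` supply vector.
#' @export
make_environment <- function(resources, params) {
  stopifnot(length(resources) %in% 1:2, all(resources >= 1),
            all(resources <= params$M))
  R0 <- numeric(params$M)
  R0[resources] <- params$R0_total / length(resources)
  R0
}

#' Run one seven-community replicate
#'
#' Samples one uptake matrix and one metabolic matrix, picks two resources of
#' class A and two of class S (uniformly without replacement), and solves the
#' seven communities of the mixed-nutrient experiment -- the four singles
#' (`single_A1`, `single_A2`, `single_S1`, `single_S2`) and the three
#' mixtures (`mix_AA`, `mix_SS`, `mix_SA` = A1+S1) -- all seeded with the
#' same initial species pool. A replicate is `accepted` only when all seven
#' communities converged.
#'
#' @param params a [micrm_params()] object.
#' @param system optionally, a pre-built [micrm_system()] to reuse.
#' @return an object of class `micrm_replicate`: list with `system`,
#'   `environments` (named list of supplied resource indices), `results`
#'   (named list of [find_steady_state()] outputs) and `accepted`.
#' @export
run_replicate <- function(params = micrm_params(), system = NULL) {
  if (is.null(system)) system <- micrm_system(params)
  idx_A <- which(system$class == "A")
  idx_S <- which(system$class == "S")
  rA <- sample(idx_A, 2)
  rS <- sample(idx_S, 2)
  environments <- list(
    single_A1 = rA[1], single_A2 = rA[2],
    single_S1 = rS[1], single_S2 = rS[2],
    mix_AA = rA, mix_SS = rS, mix_SA = c(rA[1], rS[1]))
  results <- lapply(environments, function(res)
    find_steady_state(system, make_environment(res, params)))
  structure(list(system = system, environments = environments,
                 results = results,
                 accepted = all(vapply(results, `[[`, logical(1),
                                       "converged"))),
            class = "micrm_replicate")
}

#' Run an ensemble of replicate simulations
#'
#' Repeats [run_replicate()] `n_replicates` times, resampling all random
#' parameters each time.
#'
#' @param n_replicates number of replicate simulations.
#' @param params a [micrm_params()] object.
#' @param seed optional integer seed making the ensemble reproducible.
#' @param progress print a dot per replicate.
#' @return list of `micrm_replicate` objects, with attribute `params`.
#' @export
run_ensemble <- function(n_replicates = 100, params = micrm_params(),
                         seed = NULL, progress = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    reps[[r]] <- run_replicate(params)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  attr(reps, "params") <- params
  reps
}

#' Tidy table of an ensemble
#'
#' @param ensemble list of replicates from [run_ensemble()].
#' @return data.frame with one row per (replicate, environment, surviving
#'   species): `replicate, environment, species, family, abundance,
#'   rel_abundance, converged, accepted`.
#' @export
ensemble_to_df <- function(ensemble) {
  out <- lapply(seq_along(ensemble), function(r) {
    rep_r <- ensemble[[r]]
    do.call(rbind, lapply(names(rep_r$results), function(env) {
      st <- rep_r$results[[env]]
      if (!length(st$survivors)) return(NULL)
      data.frame(replicate = r, environment = env,
                 species = st$survivors,
                 family = rep_r$system$family[st$survivors],
                 abundance = st$N_star[st$survivors],
                 rel_abundance = unname(st$rel_abundance),
                 converged = st$converged, accepted = rep_r$accepted)
    }))
  })
  do.call(rbind, out)
}

MIX_DEFS <- list(mix_AA = c("single_A1", "single_A2"),
                 mix_SS = c("single_S1", "single_S2"),
                 mix_SA = c("single_A1", "single_S1"))

## Observed and predicted relative abundance vectors (length n_species) for
## one mixture of one replicate, plus the two single-community family
## profiles needed for dominance calls.
mixture_obs_pred <- function(rep_r, mix) {
  singles <- MIX_DEFS[[mix]]
  st_mix <- rep_r$results[[mix]]
  st1 <- rep_r$results[[singles[1]]]
  st2 <- rep_r$results[[singles[2]]]
  n <- nrow(rep_r$system$c)
  full <- function(st) {
    v <- numeric(n); v[st$survivors] <- st$rel_abundance; v
  }
  w <- compute_weights(st1$biomass, st2$biomass)
  f1 <- full(st1); f2 <- full(st2)
  list(observed = full(st_mix), predicted = w[1] * f1 + w[2] * f2,
       f1 = f1, f2 = f2, w = w)
}

#' Evaluate the null additive model on a simulated ensemble
#'
#' For every accepted replicate and each of its three mixture communities,
#' predicts the mixture composition from the two matching single-resource
#' communities using survivor-biomass weights (the simulation's stand-in for
#' the OD620 proxy), then pools observed-vs-predicted points over all
#' mixtures. Points enter the pool when the species (or family) survives in
#' the mixture or in either single (union of supports; absent taxa count 0).
#' For `mix_SA` communities a family-level interaction record is produced:
#' epsilon, the dominant resource class by the epsilon sign rule, and the
#' dominance index delta (negative when the S class -- the "sugar" --
#' dominates).
#'
#' @param ensemble list from [run_ensemble()].
#' @param level `"species"` or `"family"`.
#' @return list with `pearson_r`, `p_value`, `rmse`, `n`, `n_accepted`, the
#'   pooled `points` data.frame and (per SA mixture and family) the `calls`
#'   data.frame with `epsilon`, `dominant_class` and `delta`.
#' @export
evaluate_null_model <- function(ensemble, level = c("species", "family")) {
  level <- match.arg(level)
  accepted <- Filter(function(z) z$accepted, ensemble)
  if (!length(accepted)) stop("no accepted replicates", call. = FALSE)
  points <- list(); calls <- list()
  for (r in seq_along(accepted)) {
    rep_r <- accepted[[r]]
    fam <- rep_r$system$family
    for (mix in names(MIX_DEFS)) {
      op <- mixture_obs_pred(rep_r, mix)
      if (level == "species") {
        inc <- op$observed > 0 | op$predicted > 0
        points[[length(points) + 1L]] <- data.frame(
          replicate = r, environment = mix, unit = which(inc),
          observed = op$observed[inc], predicted = op$predicted[inc])
      } else {
        obs_f <- tapply(op$observed, fam, sum)
        pred_f <- tapply(op$predicted, fam, sum)
        inc <- obs_f > 0 | pred_f > 0
        points[[length(points) + 1L]] <- data.frame(
          replicate = r, environment = mix, unit = names(obs_f)[inc],
          observed = as.numeric(obs_f[inc]),
          predicted = as.numeric(pred_f[inc]))
      }
      if (mix == "mix_SA") {
        obs_f <- tapply(op$observed, fam, sum)
        pred_f <- tapply(op$predicted, fam, sum)
        f1_f <- tapply(op$f1, fam, sum)   # single_A community
        f2_f <- tapply(op$f2, fam, sum)   # single_S community
        for (f in names(obs_f)) {
          if (obs_f[f] == 0 && pred_f[f] == 0) next
          eps <- obs_f[[f]] - pred_f[[f]]
          if (f1_f[[f]] == f2_f[[f]]) next  # dominant class undefined
          dom_class <- if (eps > 0) {
            if (f1_f[[f]] > f2_f[[f]]) "A" else "S"
          } else {
            if (f1_f[[f]] < f2_f[[f]]) "A" else "S"
          }
          calls[[length(calls) + 1L]] <- data.frame(
            replicate = r, family = f, epsilon = eps,
            dominant_class = dom_class,
            delta = if (dom_class == "S") -abs(eps) else abs(eps))
        }
      }
    }
  }
  pts <- do.call(rbind, points)
  metrics <- fit_metrics(pts$observed, pts$predicted)
  c(metrics,
    list(level = level, n_accepted = length(accepted), points = pts,
         calls = do.call(rbind, calls)))
}

#' Sweep the specialization grid
#'
#' Runs reduced ensembles over a grid of `(q_A, q_S)` values and reports the
#' mean family-level dominance index over the sugar-acid (`mix_SA`) mixtures
#' of each cell. Negative mean delta: the S ("sugar") class dominates.
#'
#' @param q_values numeric vector of specialization values in `[0, 1]` (used
#'   for both axes), or a two-column data.frame of explicit `(q_A, q_S)`
#'   cells.
#' @param replicates_per_cell replicates per grid cell.
#' @param params template [micrm_params()]; `q_A`/`q_S` are overridden.
#' @param seed optional integer seed.
#' @return data.frame with `q_A, q_S, mean_delta, n_calls, n_accepted`.
#' @export
sweep_q_grid <- function(q_values, replicates_per_cell = 10,
                         params = micrm_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- if (is.data.frame(q_values)) q_values else
    expand.grid(q_A = q_values, q_S = q_values)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$q_A <- grid$q_A[i]; p$q_S <- grid$q_S[i]
    ens <- run_ensemble(replicates_per_cell, p)
    ev <- tryCatch(evaluate_null_model(ens, "family"),
                   error = function(e) NULL)
    data.frame(q_A = p$q_A, q_S = p$q_S,
               mean_delta = if (is.null(ev) || is.null(ev$calls))
                 NA_real_ else mean(ev$calls$delta),
               n_calls = if (is.null(ev) || is.null(ev$calls)) 0L
                 else nrow(ev$calls),
               n_accepted = if (is.null(ev)) 0L else ev$n_accepted)
  })
  do.call(rbind, out)
}
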