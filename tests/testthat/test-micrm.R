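small_system <- function(n, M, seed, q_A = 0.3, q_S = 0.3) {
  p <- micrm_params(n_species = n, M = M, q_A = q_A, q_S = q_S)
  micrm_system(p, seed = seed)
}

# subset a system to its first `n` species (for odd-sized oracle cases)
head_species <- function(sys, n) {
  sys$c <- sys$c[seq_len(n), , drop = FALSE]
  sys$family <- sys$family[seq_len(n)]
  sys
}

test_that("uptake blocks have the specialization-scaled gamma moments", {
  p <- micrm_params()
  set.seed(1)
  u <- sample_uptake_matrix(p)
  blk <- function(fam, cls) u$c[u$family == fam, u$class == cls]
  # preferred blocks: mean mu_c/M (1+q) = 0.95; variance sigma_c^2/M (1+q)
  expect_equal(mean(blk("F_S", "S")), 0.5 * 1.9, tolerance = 0.1)
  expect_equal(mean(blk("F_A", "A")), 0.5 * 1.9, tolerance = 0.1)
  expect_equal(var(as.vector(blk("F_S", "S"))), 9 / 20 * 1.9,
               tolerance = 0.2)
  # disfavored blocks: mean mu_c/M (1-q) = 0.05
  expect_equal(mean(blk("F_S", "A")), 0.5 * 0.1, tolerance = 0.3)
  expect_equal(mean(blk("F_A", "S")), 0.5 * 0.1, tolerance = 0.3)
  # gamma support is positive; disfavored blocks have tiny shape and may
  # underflow to numerical zero
  expect_true(all(u$c >= 0))
  expect_true(all(blk("F_S", "S") > 0))
  expect_true(all(blk("F_A", "A") > 0))
  # no specialization: all four block means equal mu_c/M
  set.seed(2)
  u0 <- sample_uptake_matrix(micrm_params(q_A = 0, q_S = 0))
  for (f in c("F_A", "F_S")) for (cl in c("A", "S"))
    expect_equal(mean(u0$c[u0$family == f, u0$class == cl]), 0.5,
                 tolerance = 0.1)
  # full specialization: the disadvantaged block degenerates to zero
  set.seed(3)
  u1 <- sample_uptake_matrix(micrm_params(q_A = 1, q_S = 0.9))
  expect_true(all(u1$c[u1$family == "F_S", u1$class == "A"] == 0))
  expect_true(all(u1$c[u1$family == "F_A", u1$class == "A"] > 0))
})

test_that("metabolic matrix columns are Dirichlet simplex draws", {
  p <- micrm_params()
  set.seed(4)
  D <- sample_metabolic_matrix(p)
  expect_equal(dim(D), c(20, 20))
  expect_true(all(D >= 0))
  expect_equal(colSums(D), rep(1, 20), tolerance = 1e-9)
  p1 <- micrm_params(n_species = 2, M = 2)
  p1$M <- 1L  # single-resource degenerate case
  expect_equal(sample_metabolic_matrix(p1), matrix(1, 1, 1))
})

test_that("dynamics match the consumer-resource equations", {
  p <- micrm_params(n_species = 2, M = 2, q_A = 0, q_S = 0)
  sys <- micrm_system(p, seed = 1)
  R0 <- make_environment(1, p)
  # empty community relaxes to the supply
  d <- micrm_dynamics(c(0, 0), c(100, 50), sys, R0)
  expect_equal(d$dN, c(0, 0))
  expect_equal(d$dR, (R0 - c(100, 50)) / p$tau)
  # single species at (1-l) c R = m is stationary
  p1 <- micrm_params(n_species = 2, M = 2)
  s1 <- micrm_system(p1, seed = 2)
  s1$c[] <- 1
  d1 <- micrm_dynamics(c(1, 0), c(2, 0), s1, rep(0, 2))
  expect_equal(d1$dN, c(0, 0))
  expect_error(micrm_dynamics(c(-1, 0), c(1, 1), s1), "non-negative")
})

test_that("without leakage, resource uptake balances growth plus upkeep", {
  p <- micrm_params(n_species = 6, M = 4, l = 0, q_A = 0.5, q_S = 0.5)
  sys <- micrm_system(p, seed = 9)
  set.seed(10)
  N <- runif(6, 0, 5); R <- runif(4, 0, 50); R0 <- make_environment(1, p)
  d <- micrm_dynamics(N, R, sys, R0)
  uptake <- sum(N * drop(sys$c %*% R))
  expect_equal(sum(d$dN) + p$m * sum(N), uptake, tolerance = 1e-10)
  expect_equal(sum(d$dR), sum((R0 - R) / p$tau) - uptake, tolerance = 1e-8)
})

test_that("single-species equilibrium matches the closed form", {
  # R* = m / ((1-l) c) = 2; with D = [[1]] recycling l of the uptake,
  # (R0 - R*)/tau = (1-l) N* c R*  =>  N* = 998
  p <- micrm_params(n_species = 2, M = 2, R0_total = 1000)
  sys <- micrm_system(p, seed = 1)
  sys$c <- rbind(c(1, 0), c(0, 0))  # one live species on resource 1
  sys$D <- diag(2)
  st <- find_steady_state(sys, c(1000, 0))
  expect_true(st$converged)
  expect_equal(st$survivors, 1L)
  expect_equal(st$N_star[1], 998, tolerance = 1e-6)
  expect_equal(st$R_star[1], 2, tolerance = 1e-6)
  expect_equal(st$biomass, 998, tolerance = 1e-6)
  expect_equal(unname(st$rel_abundance), 1)
})

test_that("a species that cannot pay maintenance goes extinct", {
  p <- micrm_params(n_species = 2, M = 2, R0_total = 1)
  sys <- micrm_system(p, seed = 1)
  sys$c[] <- 1  # (1-l) c R0_total = 0.5 < m
  sys$D <- diag(2)
  st <- find_steady_state(sys, c(1, 0))
  expect_true(st$converged)
  expect_length(st$survivors, 0)
  expect_equal(st$R_star, c(1, 0), tolerance = 1e-6)
})

test_that("accepted equilibria satisfy the convergence criterion", {
  sys <- small_system(20, 4, seed = 5)
  st <- find_steady_state(sys, make_environment(1, sys$params))
  expect_true(st$converged)
  sub <- sys
  sub$c <- sys$c[st$survivors, , drop = FALSE]
  d <- micrm_dynamics(st$N_star[st$survivors], st$R_star, sub,
                      make_environment(1, sys$params))
  expect_lte(max(abs(d$dN / st$N_star[st$survivors])), 1e-5)
  expect_true(all(st$N_star[st$survivors] >
                    sys$params$extinction_threshold))
  expect_equal(sum(st$rel_abundance), 1)
})

test_that("steady states agree with long-horizon integration (oracle)", {
  for (seed in 1:3) {
    n <- c(3, 5, 4)[seed]; M <- c(2, 2, 4)[seed]
    sys <- head_species(small_system(n + n %% 2, M, seed = seed), n)
    R0 <- make_environment(1, sys$params)
    st <- find_steady_state(sys, R0)
    orc <- integrate_oracle(sys, R0)
    expect_true(st$converged)
    scale <- pmax(orc$N, 1e-4)
    expect_lt(max(abs(st$N_star - orc$N) / scale), 1e-4)
    expect_lt(max(abs(st$R_star - orc$R) / pmax(orc$R, 1e-4)), 1e-4)
  }
})

test_that("a replicate solves seven environments from one species pool", {
  p <- micrm_params(n_species = 40, M = 8)
  set.seed(12)
  rep1 <- run_replicate(p)
  expect_length(rep1$results, 7)
  expect_named(rep1$results, c("single_A1", "single_A2", "single_S1",
                               "single_S2", "mix_AA", "mix_SS", "mix_SA"))
  # supply: singles 1000 on one resource, mixes 500 + 500
  for (env in names(rep1$environments)) {
    res <- rep1$environments[[env]]
    R0 <- make_environment(res, p)
    expect_equal(sum(R0), 1000)
    expect_equal(sum(R0 > 0), length(res))
  }
  cls <- rep1$system$class
  expect_true(all(cls[rep1$environments$mix_AA] == "A"))
  expect_true(all(cls[rep1$environments$mix_SS] == "S"))
  expect_equal(sort(cls[rep1$environments$mix_SA]), c("A", "S"))
  expect_equal(rep1$environments$mix_SA,
               c(rep1$environments$single_A1, rep1$environments$single_S1))
})

test_that("fixed seeds reproduce matrices and survivor sets exactly", {
  p <- micrm_params(n_species = 20, M = 4)
  run <- function() {
    set.seed(33)
    run_replicate(p)
  }
  a <- run(); b <- run()
  expect_identical(a$system$c, b$system$c)
  expect_identical(a$system$D, b$system$D)
  expect_identical(lapply(a$results, `[[`, "survivors"),
                   lapply(b$results, `[[`, "survivors"))
})

test_that("null-model evaluation pools mixtures at both levels", {
  p <- micrm_params(n_species = 30, M = 6)
  ens <- run_ensemble(4, p, seed = 14)
  for (lev in c("species", "family")) {
    ev <- evaluate_null_model(ens, lev)
    expect_true(is.finite(ev$pearson_r))
    expect_gte(ev$n, 3)
    expect_equal(ev$n, nrow(ev$points))
    expect_true(all(ev$points$observed >= 0 & ev$points$observed <= 1))
  }
  ev <- evaluate_null_model(ens, "family")
  expect_true(all(ev$calls$delta == ifelse(ev$calls$dominant_class == "S",
                                           -abs(ev$calls$epsilon),
                                           abs(ev$calls$epsilon))))
  df <- ensemble_to_df(ens)
  expect_named(df, c("replicate", "environment", "species", "family",
                     "abundance", "rel_abundance", "converged", "accepted"))
  sums <- tapply(df$rel_abundance, paste(df$replicate, df$environment), sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)), tolerance = 1e-9)
})
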