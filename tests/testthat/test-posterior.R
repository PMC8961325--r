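# Minimal hand-built population: two interventions with known rate samples.
fake_population <- function(glc, wp) {
  structure(list(rates = list(GLC = glc, WP = wp),
                 interventions = c("GLC", "WP"),
                 theta = matrix(0, nrow(glc), 21), window = c(0, 90)),
            class = "pf_population")
}

rate_matrix <- function(values, n = NULL) {
  if (is.null(n)) n <- if (length(values)) length(values[[1]]) else 4
  m <- sapply(postflux:::rate_names(), function(p) {
    if (!is.null(values[[p]])) rep(values[[p]], length.out = n)
    else rep(0.05, n)
  })
  matrix(m, nrow = n, dimnames = list(NULL, postflux:::rate_names()))
}

test_that("the DE-MC sampler reproduces a known Gaussian target", {
  mu <- c(1, -0.5, 2)
  sd_true <- c(0.3, 0.6, 0.2)
  rho <- 0.5  # correlation between dims 1 and 2
  Sigma <- diag(sd_true^2)
  Sigma[1, 2] <- Sigma[2, 1] <- rho * sd_true[1] * sd_true[2]
  Sinv <- solve(Sigma)
  lp <- function(x) -0.5 * as.numeric(t(x - mu) %*% Sinv %*% (x - mu))

  res <- demc_sample(lp, init = mu, lower = rep(-10, 3), upper = rep(10, 3),
                     n = 4000, seed = 11, n_chains = 12, thin = 5)
  expect_equal(nrow(res$samples), 4000)
  expect_equal(unname(colMeans(res$samples)), mu, tolerance = 0.1)
  expect_equal(unname(apply(res$samples, 2, stats::sd)), sd_true,
               tolerance = 0.15)
  expect_equal(stats::cor(res$samples[, 1], res$samples[, 2]), rho,
               tolerance = 0.15)

  # determinism and bounds
  res2 <- demc_sample(lp, init = mu, lower = rep(-10, 3), upper = rep(10, 3),
                      n = 4000, seed = 11, n_chains = 12, thin = 5)
  expect_identical(res$samples, res2$samples)
  expect_true(all(res$samples >= -10 & res$samples <= 10))
})

test_that("posterior populations are reproducible with exact bookkeeping", {
  md <- zero_noise_md()
  prob <- fit_problem(md, c(0, 90))
  fit <- fit_joint(prob, n_restarts = 1, seed = 5,
                   de_control = list(maxiter = 120, polish_maxit = 60))
  pop1 <- sample_posterior(prob, fit, n = 500, seed = 6, thin = 2)
  pop2 <- sample_posterior(prob, fit, n = 500, seed = 6, thin = 2)
  expect_identical(pop1$theta, pop2$theta)
  expect_equal(nrow(pop1$theta), 500)
  info <- postflux:::theta_info(prob)
  expect_true(all(t(pop1$theta) >= info$lower & t(pop1$theta) <= info$upper))
  # every sample respects the ratio constraints by construction
  shared <- setdiff(postflux:::rate_names(), "k_Pro")
  ratio <- pop1$rates$WP[, shared] / pop1$rates$GLC[, shared]
  expect_true(all(ratio >= 0.1 - 1e-12 & ratio <= 10 + 1e-12))
})

test_that("per-parameter AUC equals brute-force pair counting", {
  brute_auc <- function(a, b) {
    # fraction of (a, b) pairs ranked correctly, ties counted half
    s <- 0
    for (x in a) for (y in b) s <- s + (y > x) + 0.5 * (y == x)
    u <- s / (length(a) * length(b))
    max(u, 1 - u)
  }

  # identical populations: no discrimination
  same <- rate_matrix(list())
  expect_true(all(suppressWarnings(
    roc_auc_per_parameter(fake_population(same, same)))$auc == 0.5))

  # completely separated marginals: perfect discrimination
  glc <- rate_matrix(list(k_GLY = c(1, 2, 3, 4) * 1e-3))
  wp <- rate_matrix(list(k_GLY = c(5, 6, 7, 8) * 1e-3))
  res <- suppressWarnings(roc_auc_per_parameter(fake_population(glc, wp)))
  expect_equal(res$auc[res$parameter == "k_GLY"], 1.0)
  expect_true(res$strongly_regulated[res$parameter == "k_GLY"])

  # random small instances against the pair-counting oracle
  set.seed(21)
  for (i in 1:20) {
    a <- stats::rlnorm(7, -2, 0.5)
    b <- stats::rlnorm(5, -2 + stats::runif(1, -1, 1), 0.5)
    res <- suppressWarnings(roc_auc_per_parameter(
      fake_population(rate_matrix(list(k_TCA = rep(a, length.out = 35))),
                      rate_matrix(list(k_TCA = rep(b, length.out = 35))))))
    got <- res$auc[res$parameter == "k_TCA"]
    expect_equal(got, brute_auc(rep(a, length.out = 35),
                                rep(b, length.out = 35)), tolerance = 1e-12)
  }

  # label swap leaves the reported AUC unchanged
  pop_ab <- fake_population(glc, wp)
  pop_ba <- fake_population(wp, glc)
  expect_equal(suppressWarnings(roc_auc_per_parameter(pop_ab))$auc,
               suppressWarnings(roc_auc_per_parameter(pop_ba))$auc)

  # degenerate constant marginal: AUC 0.5 with a warning (other rates vary)
  const <- rate_matrix(list(d_cit = rep(0.05, 4)), n = 4)
  for (p in setdiff(postflux:::rate_names(), "d_cit")) {
    const[, p] <- c(1, 2, 3, 4) * 1e-3
  }
  expect_warning(res <- roc_auc_per_parameter(fake_population(const, const)),
                 "degenerate")
  expect_equal(res$auc[res$parameter == "d_cit"], 0.5)
})

test_that("rate-to-flux conversion follows the worked arithmetic", {
  # k = 0.01/min, median C = 2 uM, s = 1, 2% tracer -> 1 uM/min
  rates <- rate_matrix(list(k_GLY = 0.01))
  fx <- flux_from_rates(rates, list(glc_M6 = 2, pyr_M3 = 1, lac_M3 = 1,
                                    ala_M3 = 1, cit_M2 = 1, protein = 1),
                        s = 1, tracer_fraction = 0.02)
  expect_equal(unname(fx[1, "v_GLY"]), 1.0)

  # zero rate -> zero flux; linear in the rate
  rates0 <- rate_matrix(list(k_GLY = 0))
  fx0 <- flux_from_rates(rates0, list(glc_M6 = 2, pyr_M3 = 1, lac_M3 = 1,
                                      ala_M3 = 1, cit_M2 = 1, protein = 1),
                         s = 1)
  expect_equal(unname(fx0[1, "v_GLY"]), 0)
  fx3 <- flux_from_rates(rate_matrix(list(k_GLY = 0.03)),
                         list(glc_M6 = 2, pyr_M3 = 1, lac_M3 = 1,
                              ala_M3 = 1, cit_M2 = 1, protein = 1), s = 1)
  expect_equal(unname(fx3[1, "v_GLY"]), 3 * unname(fx[1, "v_GLY"]))

  # net and exchange definitions: v_f = 3, v_b = 5 -> net -2, exchange 3
  expect_equal(3 - 5, -2)
  glc <- rate_matrix(list(k_LDHf = 0.003, k_LDHb = 0.005), n = 4)
  pop <- fake_population(glc, glc)
  md <- zero_noise_md()
  fx <- fluxes_from_samples(pop, md, c(0, 90), "early")
  smp <- attr(fx, "samples")$GLC
  expect_equal(smp[, "LDH_net"], smp[, "v_LDHf"] - smp[, "v_LDHb"])
  expect_equal(smp[, "LDH_ex"], pmin(smp[, "v_LDHf"], smp[, "v_LDHb"]))
  expect_true(all(smp[, "LDH_ex"] >= 0))
  # antisymmetry under swapping the forward and backward FLUXES: with equal
  # substrate medians, swapping the two rates swaps the fluxes
  eq_med <- list(glc_M6 = 1, pyr_M3 = 1, lac_M3 = 1, ala_M3 = 1,
                 cit_M2 = 1, protein = 1)
  f1 <- flux_from_rates(rate_matrix(list(k_LDHf = 0.005, k_LDHb = 0.003), n = 2),
                        eq_med, s = 1)
  f2 <- flux_from_rates(rate_matrix(list(k_LDHf = 0.003, k_LDHb = 0.005), n = 2),
                        eq_med, s = 1)
  expect_equal(f2[, "v_LDHf"] - f2[, "v_LDHb"],
               -(f1[, "v_LDHf"] - f1[, "v_LDHb"]))
  expect_equal(pmin(f2[, "v_LDHf"], f2[, "v_LDHb"]),
               pmin(f1[, "v_LDHf"], f1[, "v_LDHb"]))

  # table invariants: lower <= median <= upper
  expect_true(all(fx$ci_lower <= fx$median + 1e-12))
  expect_true(all(fx$median <= fx$ci_upper + 1e-12))
})

test_that("phase selects the scaling factor in flux conversion", {
  md <- zero_noise_md()
  sched <- scaling_schedule(s_pa = 1, s_a = 2)
  pop <- fake_population(rate_matrix(list()), rate_matrix(list()))
  early <- fluxes_from_samples(pop, md, c(0, 90), "early", sched)
  late <- fluxes_from_samples(pop, md, c(90, 360), "late", sched)
  expect_equal(attr(early, "scaling"), 2)
  expect_equal(attr(late, "scaling"), 1)
  # the literal printed form applies the absorptive factor to both windows
  lit <- fluxes_from_samples(pop, md, c(90, 360), "late", sched,
                             literal_scaling = TRUE)
  expect_equal(attr(lit, "scaling"), 2)
})

test_that("credible intervals are equal-tail quantile intervals", {
  expect_equal(unname(credible_interval(rep(3, 10))), c(3, 3))
  set.seed(9)
  u <- stats::runif(20000)
  ci <- credible_interval(u, 0.90)
  expect_equal(unname(ci), c(0.05, 0.95), tolerance = 0.01)
  x <- stats::rnorm(501)
  ci <- credible_interval(x)
  expect_lte(ci[["lower"]], stats::median(x))
  expect_gte(ci[["upper"]], stats::median(x))
  expect_error(credible_interval(1), "two samples")
})
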