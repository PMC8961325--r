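#' Differential-evolution Markov chain Monte Carlo sampler
#'
#' Ensemble MCMC with differential-evolution proposals: each chain moves by
#' `gamma * (x_a - x_b)` between two other randomly chosen chains plus a small
#' Gaussian jitter. The proposal scale adapts toward a target acceptance rate
#' during burn-in and is frozen afterwards; every tenth generation uses
#' `gamma = 1` for mode-to-mode jumps. Uniform (box) prior: proposals outside
#' the bounds are rejected. Deterministic for a fixed seed.
#'
#' @param log_post Log posterior density (up to a constant), called with a
#'   numeric vector.
#' @param init Numeric vector: chain initialization centre.
#' @param lower,upper Box bounds of the uniform prior.
#' @param n Number of retained samples (pooled over chains, post burn-in).
#' @param seed Integer seed.
#' @param n_chains Number of chains; default `max(2 * d, 8)`.
#' @param burn_frac Fraction of generations discarded as burn-in.
#' @param thin Record every `thin`-th generation after burn-in.
#' @param init_jitter Relative scale of the Gaussian jitter applied to `init`
#'   per chain (in units of the box width).
#' @param jitter_sd Absolute proposal jitter.
#' @return List with `samples` (n x d matrix), `log_post` (vector),
#'   `acceptance` (post burn-in rate), `scale` (final adaptation factor).
#' @export
demc_sample <- function(log_post, init, lower, upper, n = 10000, seed = 1,
                        n_chains = NULL, burn_frac = 0.5, thin = 10,
                        init_jitter = 0.02, jitter_sd = 1e-5) {
  d <- length(init)
  stopifnot(length(lower) == d, length(upper) == d, all(upper > lower))
  if (is.null(n_chains)) n_chains <- max(2L * d, 8L)
  if (n_chains < 4L) n_chains <- 4L
  keep_gens <- ceiling(n / n_chains)
  post_gens <- keep_gens * thin
  total_gens <- ceiling(post_gens / (1 - burn_frac))
  burn_gens <- total_gens - post_gens
  gamma0 <- 2.38 / sqrt(2 * d)
  width <- upper - lower

  with_seed(seed, {
    x <- matrix(rep(init, each = n_chains), nrow = n_chains)
    x <- x + matrix(stats::rnorm(n_chains * d, 0, 1), n_chains, d) *
      rep(width * init_jitter, each = n_chains)
    x <- pmin(pmax(x, rep(lower, each = n_chains)),
              rep(upper, each = n_chains))
    lp <- apply(x, 1, log_post)
    if (all(!is.finite(lp))) {
      stop("all chains initialized at zero posterior density", call. = FALSE)
    }
    scale <- 1
    acc_window <- 0L
    prop_window <- 0L
    acc_post <- 0L
    prop_post <- 0L
    keep <- matrix(NA_real_, nrow = keep_gens * n_chains, ncol = d)
    keep_lp <- numeric(keep_gens * n_chains)
    row <- 0L
    for (g in seq_len(total_gens)) {
      gam <- if (g %% 10L == 0L) 1 else scale * gamma0
      for (i in seq_len(n_chains)) {
        ab <- sample(setdiff(seq_len(n_chains), i), 2L)
        prop <- x[i, ] + gam * (x[ab[1], ] - x[ab[2], ]) +
          stats::rnorm(d, 0, jitter_sd)
        lp_prop <- if (any(prop < lower) || any(prop > upper)) -Inf
          else log_post(prop)
        accept <- is.finite(lp_prop) &&
          (lp_prop - lp[i] > log(stats::runif(1)))
        if (accept) {
          x[i, ] <- prop
          lp[i] <- lp_prop
        }
        if (g <= burn_gens) {
          prop_window <- prop_window + 1L
          acc_window <- acc_window + accept
        } else {
          prop_post <- prop_post + 1L
          acc_post <- acc_post + accept
        }
      }
      if (g <= burn_gens && g %% 25L == 0L && prop_window > 0L) {
        rate <- acc_window / prop_window
        if (rate < 0.15) scale <- scale * 0.8
        if (rate > 0.35) scale <- scale * 1.25
        acc_window <- 0L
        prop_window <- 0L
      }
      if (g > burn_gens && (g - burn_gens) %% thin == 0L &&
          row < keep_gens * n_chains) {
        keep[row + seq_len(n_chains), ] <- x
        keep_lp[row + seq_len(n_chains)] <- lp
        row <- row + n_chains
      }
    }
    acceptance <- if (prop_post > 0) acc_post / prop_post else NA_real_
    if (is.finite(acceptance) && (acceptance < 0.05 || acceptance > 0.6)) {
      warning(sprintf("post-adaptation acceptance rate %.3f outside [0.05, 0.6]",
                      acceptance))
    }
    list(samples = keep[seq_len(n), , drop = FALSE],
         log_post = keep_lp[seq_len(n)],
         acceptance = acceptance, scale = scale)
  })
}

#' Sample the parameter posterior of a fitted window
#'
#' Targets `exp(-cost/2)` — the sum of squared scaled residuals treated as a
#' chi-square deviance — under uniform priors on the bounded joint log10
#' parameters, using [demc_sample()] initialized by jittering the optimum of
#' a joint fit.
#'
#' @param problem A `fit_problem`.
#' @param init A `pf_fit` from [fit_joint()] (its cost must be finite).
#' @param n Number of retained samples.
#' @param seed Integer seed.
#' @param ... Further arguments to [demc_sample()].
#' @return A `pf_population`: list with `theta` (n x 21 matrix), per-
#'   intervention rate sample matrices in `rates`, `window`, `seed`,
#'   `acceptance`.
#' @export
sample_posterior <- function(problem, init, n = 10000, seed = 1, ...) {
  stopifnot(inherits(problem, "fit_problem"), inherits(init, "pf_fit"))
  if (!is.finite(init$cost)) stop("`init` has non-finite cost", call. = FALSE)
  info <- theta_info(problem)
  lp <- function(theta) -cost_theta(theta, problem) / 2
  res <- demc_sample(lp, as.numeric(init$theta), info$lower, info$upper,
                     n = n, seed = seed, ...)
  colnames(res$samples) <- info$names
  rates <- population_rates(res$samples, problem)
  structure(list(theta = res$samples, rates = rates,
                 window = problem$window, seed = seed,
                 acceptance = res$acceptance, log_post = res$log_post,
                 interventions = problem$interventions),
            class = "pf_population")
}

# Convert a theta sample matrix to per-intervention rate matrices (natural
# scale, columns = the 11 rate names).
population_rates <- function(theta, problem) {
  free <- setdiff(rate_names(), "k_Pro")
  ref <- 10^theta[, 1:10, drop = FALSE]
  colnames(ref) <- free
  alt <- ref * 10^theta[, 11:20, drop = FALSE]
  colnames(alt) <- free
  ref <- cbind(ref, k_Pro = 0)[, rate_names(), drop = FALSE]
  alt <- cbind(alt, k_Pro = alt[, "k_GLY"] * 10^theta[, 21])[, rate_names(),
                                                             drop = FALSE]
  out <- list(ref, alt)
  names(out) <- problem$interventions
  out
}

#' @export
print.pf_population <- function(x, ...) {
  cat(sprintf("Posterior population: %d samples over [%g, %g] min (acceptance %.2f)\n",
              nrow(x$theta), x$window[1], x$window[2], x$acceptance))
  invisible(x)
}

# Rank-based AUC of scores against binary labels (ties averaged); equals the
# Mann-Whitney U statistic normalized by n1 * n0.
rank_auc <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-parameter ROC-AUC discrimination of the interventions
#'
#' For each rate shared by both interventions, a univariate logistic
#' regression of the intervention label on the pooled posterior samples is
#' fitted and the ROC AUC of its scores computed; since the logistic score is
#' monotone in a single covariate, this equals the rank (Mann-Whitney) AUC of
#' the samples themselves. Reported as `max(AUC, 1 - AUC)`; parameters with
#' AUC >= `threshold` are flagged as strongly regulated. `k_Pro` is excluded
#' (structurally zero in the glucose-only intervention). Degenerate constant
#' marginals yield AUC 0.5 with a warning.
#'
#' @param pop A `pf_population`.
#' @param threshold Flagging threshold (0.75).
#' @return Data frame with columns `parameter`, `auc`, `strongly_regulated`.
#' @export
roc_auc_per_parameter <- function(pop, threshold = 0.75) {
  stopifnot(inherits(pop, "pf_population"))
  shared <- setdiff(rate_names(), "k_Pro")
  a <- pop$rates[[1]]
  b <- pop$rates[[2]]
  labels <- c(rep(0L, nrow(a)), rep(1L, nrow(b)))
  auc <- vapply(shared, function(p) {
    x <- c(a[, p], b[, p])
    if (stats::sd(x) == 0) {
      warning("degenerate constant marginal for ", p, "; AUC set to 0.5")
      return(0.5)
    }
    scores <- tryCatch({
      fit <- suppressWarnings(stats::glm(labels ~ x,
                                         family = stats::binomial()))
      as.numeric(fit$fitted.values)
    }, error = function(e) x)
    if (stats::sd(scores) == 0) scores <- x
    u <- rank_auc(scores, labels)
    max(u, 1 - u)
  }, numeric(1))
  data.frame(parameter = shared, auc = unname(auc),
             strongly_regulated = unname(auc) >= threshold,
             stringsAsFactors = FALSE)
}

#' Equal-tail credible interval
#'
#' @param samples Numeric vector (>= 2 values).
#' @param level Interval mass (default 0.90).
#' @return Named numeric `c(lower, upper)`.
#' @export
credible_interval <- function(samples, level = 0.90) {
  if (length(samples) < 2L) stop("need at least two samples", call. = FALSE)
  assert_number(level, "level", lower = 1e-9, upper = 1 - 1e-9)
  q <- stats::quantile(samples, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lower = q[1], upper = q[2])
}

# Substrate series for each rate parameter (blood-side species in the
# reduced dataset).
flux_substrates <- function() {
  c(k_GLY = "glc_M6", k_LDHf = "pyr_M3", k_LDHb = "lac_M3", k_ALTf = "pyr_M3",
    k_ALTb = "ala_M3", k_TCA = "pyr_M3", k_Pro = "protein", d_pyr = "pyr_M3",
    d_lac = "lac_M3", d_ala = "ala_M3", d_cit = "cit_M2")
}

flux_names <- function() {
  c(k_GLY = "v_GLY", k_LDHf = "v_LDHf", k_LDHb = "v_LDHb", k_ALTf = "v_ALTf",
    k_ALTb = "v_ALTb", k_TCA = "v_TCA", k_Pro = "v_Pro", d_pyr = "v_pyr",
    d_lac = "v_lac", d_ala = "v_ala", d_cit = "v_cit")
}

#' Convert a rate sample matrix to flux samples
#'
#' Implements the rate-to-flux conversion for one intervention:
#' `v = k * median(C_met over the window's data times) * (1 / s) *
#' (1 / tracer_fraction)`, where `C_met` is the blood concentration series of
#' the rate's substrate and `s` the phase's scaling factor.
#'
#' @param rates n x 11 matrix of rate samples (columns = rate names).
#' @param med_conc Named vector of median substrate concentrations (uM) over
#'   the window, named by species.
#' @param s Scaling factor (dimensionless).
#' @param tracer_fraction Labelled fraction (0.02 -> factor 50).
#' @return n x 11 matrix of flux samples (uM/min), columns `v_GLY` ... `v_cit`.
#' @export
flux_from_rates <- function(rates, med_conc, s, tracer_fraction = 0.02) {
  subs <- flux_substrates()
  out <- sapply(names(subs), function(p) {
    rates[, p] * med_conc[[subs[[p]]]] * (1 / s) * (1 / tracer_fraction)
  })
  out <- matrix(out, nrow = nrow(rates),
                dimnames = list(NULL, unname(flux_names()[names(subs)])))
  out
}

#' Fluxes with credible intervals from a posterior population
#'
#' Converts every posterior rate sample to fluxes and summarises each flux by
#' its median and equal-tail 90% credible interval. Net fluxes are
#' `forward - backward` per sample (positive toward lactate/alanine
#' production) and exchange fluxes `min(forward, backward)` per sample.
#' The scaling factor is `s_a` for the early (absorptive) window and `s_pa`
#' for the late (post-absorptive) window; `literal_scaling = TRUE` instead
#' applies `s_a` to both windows, reproducing the conversion formulae exactly
#' as printed.
#'
#' @param pop A `pf_population`.
#' @param model_data A `pf_model_data` supplying the substrate series.
#' @param window Numeric `c(t_start, t_end)`; data times in the closed window
#'   enter the median.
#' @param phase `"early"` or `"late"`.
#' @param schedule A `scaling_schedule`.
#' @param tracer_fraction Labelled fraction.
#' @param level Credible-interval mass.
#' @param literal_scaling Use `s_a` for both phases (formula as printed).
#' @return A `pf_flux_table` data.frame with columns `intervention`, `window`,
#'   `flux`, `median`, `ci_lower`, `ci_upper`, `unit`; per-sample flux
#'   matrices are attached as attribute `"samples"`.
#' @export
fluxes_from_samples <- function(pop, model_data, window, phase,
                                schedule = scaling_schedule(),
                                tracer_fraction = 0.02, level = 0.90,
                                literal_scaling = FALSE) {
  stopifnot(inherits(pop, "pf_population"))
  phase <- match.arg(phase, c("early", "late"))
  s <- if (phase == "early" || literal_scaling) schedule$s_a else schedule$s_pa
  rows <- list()
  sample_store <- list()
  for (iv in pop$interventions) {
    d <- model_data[model_data$intervention == iv, , drop = FALSE]
    med_conc <- sapply(unique(flux_substrates()), function(sp) {
      x <- d[d$species == sp & d$time >= window[1] & d$time <= window[2], ]
      if (!nrow(x)) stop("missing substrate series ", sp, " for ", iv,
                         call. = FALSE)
      stats::median(x$mean)
    })
    fx <- flux_from_rates(pop$rates[[iv]], as.list(med_conc), s, tracer_fraction)
    fx <- cbind(fx,
                LDH_net = fx[, "v_LDHf"] - fx[, "v_LDHb"],
                LDH_ex = pmin(fx[, "v_LDHf"], fx[, "v_LDHb"]),
                ALT_net = fx[, "v_ALTf"] - fx[, "v_ALTb"],
                ALT_ex = pmin(fx[, "v_ALTf"], fx[, "v_ALTb"]))
    sample_store[[iv]] <- fx
    for (f in colnames(fx)) {
      ci <- credible_interval(fx[, f], level)
      rows[[length(rows) + 1L]] <- data.frame(
        intervention = iv, window = phase, flux = f,
        median = stats::median(fx[, f]),
        ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
        unit = "uM/min", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pf_flux_table", "data.frame")
  attr(out, "samples") <- sample_store
  attr(out, "scaling") <- s
  out
}
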