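#' Study design of the crossover tracer experiment
#'
#' Defaults mirror the two-intervention crossover design: a glucose drink
#' (GLC) and a wheat porridge (WP), each carrying 50 g available carbohydrate
#' of which 2% is uniformly 13C-labelled; 11 evaluable subjects, technical
#' triplicates, and 19 plasma sampling times from -60 to 360 min around
#' ingestion at t = 0.
#'
#' @param interventions Character vector of intervention codes.
#' @param n_subjects Number of subjects.
#' @param n_replicates Technical replicates per sample.
#' @param times Sampling times in minutes (sorted; negative = pre-ingestion).
#' @param tracer_fraction Labelled fraction of the carbohydrate load, in (0, 1].
#' @param carbohydrate_g Available carbohydrate per intervention (grams).
#' @return An object of class `study_design`.
#' @export
study_design <- function(interventions = c("GLC", "WP"),
                         n_subjects = 11,
                         n_replicates = 3,
                         times = c(-60, -30, -5, 15, 30, 45, 60, 75, 90, 105,
                                   120, 150, 180, 210, 240, 270, 300, 330, 360),
                         tracer_fraction = 0.02,
                         carbohydrate_g = 50) {
  assert_number(tracer_fraction, "tracer_fraction", lower = 1e-12, upper = 1)
  assert_number(n_replicates, "n_replicates", lower = 1)
  assert_number(n_subjects, "n_subjects", lower = 1)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  structure(list(interventions = interventions,
                 n_subjects = as.integer(n_subjects),
                 n_replicates = as.integer(n_replicates),
                 times = as.numeric(times),
                 tracer_fraction = tracer_fraction,
                 carbohydrate_g = carbohydrate_g),
            class = "study_design")
}

# Metabolite/isotopologue bookkeeping shared between generator and reduction.
modelled_species <- function() {
  data.frame(
    metabolite = c("glucose", "pyruvate", "lactate", "alanine", "citrate"),
    isotopologue = c("M6", "M3", "M3", "M3", "M2"),
    species = c("glc_M6", "pyr_M3", "lac_M3", "ala_M3", "cit_M2"),
    stringsAsFactors = FALSE)
}

protein_species <- function() {
  data.frame(
    metabolite = c("glutamate", "glutamine", "valine", "threonine"),
    isotopologue = c("M5", "M5", "M5", "M4"),
    stringsAsFactors = FALSE)
}

#' Build a unimodal absorption-shaped input curve
#'
#' The exogenous drivers (plasma glucose M6 and the dietary-protein pool)
#' rise from zero at ingestion to a single interior peak and decay back — a
#' scaled gamma-density shape
#' \eqn{c(t) = h (t/t_p)^a \exp(a (1 - t/t_p))} for t > 0 and 0 otherwise,
#' where `h` is the peak height, `t_p` the peak time, and `a` controls the
#' width. Values are returned on the design's sampling grid.
#'
#' @param peak_time Peak location (minutes), strictly inside (0, 360).
#' @param peak_height Peak concentration (uM), >= 0.
#' @param shape Positive width parameter; larger = narrower.
#' @param design A `study_design` providing the evaluation grid.
#' @return An `input_curves`-compatible list with `time` and `value`; use
#'   [input_curves()] to assemble the glucose and protein curves.
#' @export
make_input_curve <- function(peak_time, peak_height, shape = 2.5, design = study_design()) {
  assert_number(peak_time, "peak_time", lower = 1e-9, upper = 360 - 1e-9)
  if (!is.numeric(peak_height) || length(peak_height) != 1L ||
      !is.finite(peak_height) || peak_height < 0) {
    stop("`peak_height` must be a single non-negative number", call. = FALSE)
  }
  assert_number(shape, "shape", lower = 1e-9)
  t <- design$times
  v <- ifelse(t <= 0, 0,
              peak_height * (t / peak_time)^shape * exp(shape * (1 - t / peak_time)))
  list(time = t, value = v)
}

#' Default ground truth for synthetic studies
#'
#' One stated world for recovery experiments: window-switched rate sets per
#' intervention (abrupt change at `switch_time`), absorption-shaped input
#' curves, a scaling schedule, and the noise model. Rate magnitudes are chosen
#' so that converted fluxes land in the physiological range of roughly
#' 1-30 uM/min; the WP arm carries a non-zero protein curve and `k_Pro`, the
#' GLC arm has neither.
#'
#' @param cv Multiplicative measurement coefficient of variation per replicate.
#' @param subject_sd Standard deviation of the subject-level lognormal rate
#'   multipliers.
#' @param baseline_sd Standard deviation (uM) of the pure-noise pre-ingestion
#'   signal.
#' @param switch_time Minute at which the absorptive parameters switch to the
#'   post-absorptive ones.
#' @param identical_rates If `TRUE`, the WP arm uses the GLC rate set in both
#'   windows (plus its protein entry), giving a null world for calibration.
#' @return A list of class `ground_truth`.
#' @export
default_ground_truth <- function(cv = 0.1, subject_sd = 0.1, baseline_sd = 0.02,
                                 switch_time = 90, identical_rates = FALSE) {
  assert_number(switch_time, "switch_time", lower = 1e-9, upper = 360 - 1e-9)
  # The lumped decay rates of lactate (k_LDHb + d_lac) and alanine
  # (k_ALTb + d_ala) are deliberately distinct: if they coincide the two
  # trajectories are exactly proportional and the backward rates become
  # structurally indistinguishable in the pyruvate balance.
  glc_early <- rate_params(k_GLY = 0.010, k_LDHf = 0.30, k_LDHb = 0.06,
                           k_ALTf = 0.10, k_ALTb = 0.04, k_TCA = 0.05,
                           k_Pro = 0, d_pyr = 0.05, d_lac = 0.04,
                           d_ala = 0.10, d_cit = 0.05)
  glc_late <- rate_params(k_GLY = 0.002, k_LDHf = 0.15, k_LDHb = 0.10,
                          k_ALTf = 0.05, k_ALTb = 0.05, k_TCA = 0.02,
                          k_Pro = 0, d_pyr = 0.10, d_lac = 0.10,
                          d_ala = 0.05, d_cit = 0.05)
  if (identical_rates) {
    wp_early <- glc_early
    wp_late <- glc_late
    wp_early[["k_Pro"]] <- 0.010
    wp_late[["k_Pro"]] <- 0.002
    wp_early <- as_rate_params(unclass(wp_early))
    wp_late <- as_rate_params(unclass(wp_late))
  } else {
    wp_early <- rate_params(k_GLY = 0.007, k_LDHf = 0.45, k_LDHb = 0.08,
                            k_ALTf = 0.15, k_ALTb = 0.10, k_TCA = 0.08,
                            k_Pro = 0.010, d_pyr = 0.08, d_lac = 0.06,
                            d_ala = 0.06, d_cit = 0.07)
    wp_late <- rate_params(k_GLY = 0.004, k_LDHf = 0.20, k_LDHb = 0.15,
                           k_ALTf = 0.06, k_ALTb = 0.06, k_TCA = 0.03,
                           k_Pro = 0.008, d_pyr = 0.15, d_lac = 0.15,
                           d_ala = 0.06, d_cit = 0.06)
  }
  structure(list(
    rates = list(
      GLC = list(early = glc_early, late = glc_late),
      WP = list(early = wp_early, late = wp_late)),
    input_shapes = list(
      GLC = list(glc = list(peak_time = 45, peak_height = 80, shape = 2.5),
                 pro = NULL),
      WP = list(glc = list(peak_time = 60, peak_height = 70, shape = 2.5),
                pro = list(peak_time = 90, peak_height = 10, shape = 3))),
    schedule = scaling_schedule(s_pa = 1, s_a = 1),
    noise = list(cv = cv, subject_sd = subject_sd, baseline_sd = baseline_sd),
    switch_time = switch_time,
    # total-pool ceilings (uM) used by the tracer-fraction consistency check
    pool_ceilings = c(glucose = 8000, pyruvate = 200, lactate = 3000,
                      alanine = 600, citrate = 250, glutamate = 300,
                      glutamine = 800, valine = 400, threonine = 300),
    # split of the protein pool over its marker amino-acid isotopologues
    aa_weights = c(glutamate = 0.55, glutamine = 0.25, valine = 0.12,
                   threonine = 0.08)
  ), class = "ground_truth")
}

truth_inputs <- function(truth, intervention, design) {
  sh <- truth$input_shapes[[intervention]]
  g <- make_input_curve(sh$glc$peak_time, sh$glc$peak_height, sh$glc$shape, design)
  if (is.null(sh$pro)) {
    p <- list(time = design$times, value = rep(0, length(design$times)))
  } else {
    p <- make_input_curve(sh$pro$peak_time, sh$pro$peak_height, sh$pro$shape, design)
  }
  # The model interpolates the drivers from post-ingestion measurements with a
  # zero anchor at t = 0 (the convention the reduced dataset uses as well), so
  # the generator must simulate with the same knot grid.
  keep <- design$times > 0
  input_curves(c(0, design$times[keep]),
               c(0, g$value[keep]),
               c(0, p$value[keep]))
}

# Noiseless blood-side curves for one subject (rate multipliers applied),
# with the abrupt parameter switch at truth$switch_time.
noiseless_curves <- function(truth, intervention, design, multipliers = NULL) {
  inputs <- truth_inputs(truth, intervention, design)
  early <- truth$rates[[intervention]]$early
  late <- truth$rates[[intervention]]$late
  if (!is.null(multipliers)) {
    early <- as_rate_params(unclass(early) * multipliers)
    late <- as_rate_params(unclass(late) * multipliers)
  }
  sw <- truth$switch_time
  post_times <- design$times[design$times >= 0]
  t_early <- sort(unique(c(0, post_times[post_times <= sw], sw)))
  traj1 <- simulate_pools(early, inputs, t_early)
  t_late <- sort(unique(c(sw, post_times[post_times >= sw])))
  init_late <- traj1$states[nrow(traj1$states), ]
  traj2 <- simulate_pools(late, inputs, t_late, initial = pmax(init_late, 0))
  keep1 <- traj1$times %in% post_times
  keep2 <- traj2$times %in% post_times & traj2$times > max(traj1$times[keep1])
  traj <- structure(list(
    times = c(traj1$times[keep1], traj2$times[keep2]),
    states = rbind(traj1$states[keep1, , drop = FALSE],
                   traj2$states[keep2, , drop = FALSE]),
    scale = "intracellular"), class = "pf_trajectory")
  blood <- to_blood(traj, truth$schedule)
  u <- eval_inputs(inputs, blood$times)
  list(times = blood$times, states = blood$states, glc = u$glc, pro = u$pro)
}

#' Simulate a full synthetic study
#'
#' Generates a tidy replicate-level dataset with the study's structure:
#' per subject, lognormal rate multipliers perturb the ground-truth rates;
#' the window-switched model is simulated, scaled to blood, and evaluated at
#' the sampling times; technical replicates receive multiplicative Gaussian
#' noise truncated at zero. Amino-acid isotopologues (glutamate M5,
#' glutamine M5, valine M5, threonine M4) are emitted in fixed proportions of
#' the protein curve so that the protein-pool reconstruction is exercised.
#' Pre-ingestion samples are pure noise around zero, truncated at zero.
#'
#' @param truth A `ground_truth` object.
#' @param design A `study_design` object.
#' @param seed Integer seed; the same seed yields an identical dataset.
#' @return A tidy `data.frame` with columns `subject`, `intervention`,
#'   `replicate`, `time_min`, `metabolite`, `isotopologue`,
#'   `concentration_uM`, carrying the ground truth as attribute
#'   `"ground_truth"`.
#' @export
simulate_study <- function(truth = default_ground_truth(),
                           design = study_design(), seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "study_design"))
  ms <- modelled_species()
  ps <- protein_species()
  aa_w <- truth$aa_weights / sum(truth$aa_weights)
  # Eq.-3 style reconstruction: protein = sum(aa) * 100 / 40.1, so the four
  # isotopologues must sum to protein * 0.401 to round-trip exactly.
  aa_total_factor <- sum(c(31.9, 5.4, 2.8)) / 100
  with_seed(seed, {
    rows <- vector("list", 0L)
    for (iv in design$interventions) {
      for (subj in seq_len(design$n_subjects)) {
        mult <- exp(stats::rnorm(11, 0, truth$noise$subject_sd))
        names(mult) <- rate_names()
        nc <- noiseless_curves(truth, iv, design, mult)
        for (sp_i in seq_len(nrow(ms))) {
          sp <- ms$species[sp_i]
          truth_vals <- switch(sp,
            glc_M6 = nc$glc,
            pyr_M3 = nc$states[, "pyr"],
            lac_M3 = nc$states[, "lac"],
            ala_M3 = nc$states[, "ala"],
            cit_M2 = nc$states[, "cit"])
          rows[[length(rows) + 1L]] <- emit_replicates(
            design, truth, iv, subj, ms$metabolite[sp_i], ms$isotopologue[sp_i],
            nc$times, truth_vals)
        }
        for (aa_i in seq_len(nrow(ps))) {
          aa_vals <- nc$pro * aa_total_factor * aa_w[[ps$metabolite[aa_i]]]
          rows[[length(rows) + 1L]] <- emit_replicates(
            design, truth, iv, subj, ps$metabolite[aa_i], ps$isotopologue[aa_i],
            nc$times, aa_vals)
        }
      }
    }
    out <- do.call(rbind, rows)
  })
  rownames(out) <- NULL
  attr(out, "ground_truth") <- truth
  attr(out, "design") <- design
  out
}

# Emit noisy replicate rows for one subject x species, including the pure-noise
# pre-ingestion samples.
emit_replicates <- function(design, truth, intervention, subject, metabolite,
                            isotopologue, post_times, post_vals) {
  pre_times <- design$times[design$times < 0]
  all_times <- c(pre_times, post_times)
  all_truth <- c(rep(0, length(pre_times)), post_vals)
  n_t <- length(all_times)
  reps <- vector("list", design$n_replicates)
  for (r in seq_len(design$n_replicates)) {
    z <- stats::rnorm(n_t)
    noisy <- ifelse(all_times < 0,
                    pmax(0, truth$noise$baseline_sd * z),
                    pmax(0, all_truth * (1 + truth$noise$cv * z)))
    reps[[r]] <- data.frame(
      subject = sprintf("S%02d", subject),
      intervention = intervention,
      replicate = r,
      time_min = all_times,
      metabolite = metabolite,
      isotopologue = isotopologue,
      concentration_uM = noisy,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, reps)
}

#' Inject multiplicative outliers into a dataset
#'
#' Multiplies a random subset of post-ingestion, non-zero measurements by
#' `magnitude` and returns both the corrupted dataset and an exact injection
#' log, for exercising the interquartile-range outlier filter.
#'
#' @param data A tidy isotopologue dataset (as from [simulate_study()]).
#' @param fraction Fraction of eligible records to corrupt, in `[0, 0.2]`.
#' @param magnitude Multiplier (> 1).
#' @param seed Integer seed.
#' @return A list with `data` (corrupted copy) and `log` (data.frame of the
#'   modified rows: row index, original and corrupted value).
#' @export
inject_outliers <- function(data, fraction, magnitude = 10, seed = 1) {
  assert_number(fraction, "fraction", lower = 0, upper = 0.2)
  assert_number(magnitude, "magnitude", lower = 1 + 1e-12)
  eligible <- which(data$time_min > 0 & data$concentration_uM > 0)
  n_inject <- floor(fraction * length(eligible))
  if (n_inject == 0L) {
    return(list(data = data,
                log = data.frame(row = integer(), original = numeric(),
                                 corrupted = numeric())))
  }
  with_seed(seed, {
    idx <- sort(sample(eligible, n_inject))
  })
  original <- data$concentration_uM[idx]
  data$concentration_uM[idx] <- original * magnitude
  list(data = data,
       log = data.frame(row = idx, original = original,
                        corrupted = original * magnitude))
}
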