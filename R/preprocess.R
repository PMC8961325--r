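#' Isotopologue concentration from enrichment and total concentration
#'
#' The labelled-species concentration is the product of the metabolite's
#' absolute plasma concentration and its 13C enrichment fraction.
#'
#' @param enrichment Enrichment fraction(s) in `[0, 1]`.
#' @param total Total metabolite concentration(s), uM, >= 0.
#' @return Isotopologue concentration(s), uM.
#' @export
#' @examples
#' isotopologue_concentration(0.02, 2000) # 40 uM
isotopologue_concentration <- function(enrichment, total) {
  if (any(!is.finite(enrichment)) || any(enrichment < 0) || any(enrichment > 1)) {
    stop("`enrichment` must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(total)) || any(total < 0)) {
    stop("`total` must be non-negative", call. = FALSE)
  }
  enrichment * total
}

#' Dietary-protein pool from marker amino-acid isotopologues
#'
#' The protein-derived pool is reconstructed from the fully labelled
#' amino-acid isotopologues glutamate M5, glutamine M5, valine M5 and
#' threonine M4, scaled by the mol% abundance of these amino acids in wheat
#' gluten: `(glu + gln + val + thr) * 100 / (31.9 + 5.4 + 2.8)`. The printed
#' composition has three terms for four isotopologues; it is applied exactly
#' as printed and the denominator is configurable.
#'
#' @param glu_M5,gln_M5,val_M5,thr_M4 Isotopologue concentrations (uM), >= 0.
#' @param composition Mol% terms of the denominator.
#' @return Protein-pool concentration (uM).
#' @export
#' @examples
#' protein_pool(0.2, 0.1, 0.06, 0.041) # sums to 0.401 -> 1 uM
protein_pool <- function(glu_M5, gln_M5, val_M5, thr_M4,
                         composition = c(31.9, 5.4, 2.8)) {
  vals <- cbind(glu_M5, gln_M5, val_M5, thr_M4)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("amino-acid isotopologue concentrations must be non-negative",
         call. = FALSE)
  }
  if (any(composition <= 0)) stop("`composition` must be positive", call. = FALSE)
  (glu_M5 + gln_M5 + val_M5 + thr_M4) * 100 / sum(composition)
}

#' Contribution of food-derived label to the plasma pool
#'
#' Percentage of a metabolite's plasma pool that derives from the ingested
#' food: the isotopologue concentration at its maximum divided by the total
#' plasma concentration, scaled by the inverse tracer fraction (x50 for 2%
#' labelling) and by 100 to obtain percent.
#'
#' @param c_iso Isotopologue concentration (uM), >= 0.
#' @param c_met Total metabolite plasma concentration (uM), > 0.
#' @param tracer_fraction Labelled fraction of the ingested food.
#' @return Contribution in percent.
#' @export
#' @examples
#' contribution_percent(4.2, 6000) # 3.5 %
contribution_percent <- function(c_iso, c_met, tracer_fraction = 0.02) {
  if (any(!is.finite(c_iso)) || any(c_iso < 0)) {
    stop("`c_iso` must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(c_met)) || any(c_met <= 0)) {
    stop("`c_met` must be strictly positive", call. = FALSE)
  }
  assert_number(tracer_fraction, "tracer_fraction", lower = 1e-12, upper = 1)
  c_iso / c_met * (1 / tracer_fraction) * 100
}

#' Remove outliers by the 1.5 x IQR rule
#'
#' Within each group (by default all replicate-level values sharing
#' intervention, time, metabolite and isotopologue), values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are removed. Quartiles use the linear
#' interpolation convention (R type 7). Groups smaller than `min_group`
#' pass through unfiltered and are logged.
#'
#' @param data Tidy isotopologue dataset.
#' @param group_cols Columns defining a filter group.
#' @param k Fence multiplier (1.5).
#' @param min_group Minimum group size for filtering.
#' @param quantile_type Quantile convention passed to [stats::quantile()].
#' @return A list with `data` (filtered) and `log` (one row per removed value
#'   or skipped group, with fences).
#' @export
remove_outliers_iqr <- function(data,
                                group_cols = c("intervention", "time_min",
                                               "metabolite", "isotopologue"),
                                k = 1.5, min_group = 4, quantile_type = 7) {
  stopifnot(all(group_cols %in% names(data)),
            "concentration_uM" %in% names(data))
  key <- interaction(data[group_cols], drop = TRUE)
  keep <- rep(TRUE, nrow(data))
  logs <- vector("list", 0L)
  for (g in levels(key)) {
    idx <- which(key == g)
    v <- data$concentration_uM[idx]
    if (length(idx) < min_group) {
      logs[[length(logs) + 1L]] <- data.frame(
        group = g, action = "group_too_small", row = NA_integer_,
        value = NA_real_, lower_fence = NA_real_, upper_fence = NA_real_)
      next
    }
    q <- stats::quantile(v, c(0.25, 0.75), type = quantile_type, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr
    hi <- q[2] + k * iqr
    bad <- which(v < lo | v > hi)
    if (length(bad)) {
      keep[idx[bad]] <- FALSE
      logs[[length(logs) + 1L]] <- data.frame(
        group = g, action = "removed", row = idx[bad], value = v[bad],
        lower_fence = lo, upper_fence = hi)
    }
  }
  log_df <- if (length(logs)) do.call(rbind, logs) else
    data.frame(group = character(), action = character(), row = integer(),
               value = numeric(), lower_fence = numeric(),
               upper_fence = numeric())
  rownames(log_df) <- NULL
  list(data = data[keep, , drop = FALSE], log = log_df)
}

#' Reduce replicate-level data to the modelling dataset
#'
#' Per subject, time and species the median over technical replicates is
#' taken; the protein pool is reconstructed from the four marker amino-acid
#' isotopologues; pre-ingestion values are averaged into a subject baseline
#' that is subtracted (results clipped at zero) and collapse to a t = 0 row;
#' then the across-subject mean and standard deviation are formed, with the
#' standard deviation floored at `max(sigma_floor_abs, sigma_floor_frac *
#' peak mean)` per intervention and species.
#'
#' @param data Tidy isotopologue dataset (outlier-filtered).
#' @param protein_composition Mol% denominator for [protein_pool()].
#' @param subject_average `"mean"` (default) or `"median"` across subjects.
#' @param sigma_floor_abs Absolute floor for the standard deviation (uM).
#' @param sigma_floor_frac Fractional floor relative to the species' peak mean.
#' @return A `pf_model_data` data.frame with columns `intervention`, `time`,
#'   `species` (`glc_M6`, `pyr_M3`, `lac_M3`, `ala_M3`, `cit_M2`, `protein`),
#'   `mean` and `sd`.
#' @export
reduce_to_model_dataset <- function(data,
                                    protein_composition = c(31.9, 5.4, 2.8),
                                    subject_average = c("mean", "median"),
                                    sigma_floor_abs = 1e-6,
                                    sigma_floor_frac = 0.01) {
  subject_average <- match.arg(subject_average)
  ms <- modelled_species()
  ps <- protein_species()
  need <- rbind(ms[c("metabolite", "isotopologue")],
                ps[c("metabolite", "isotopologue")])
  have <- unique(paste(data$metabolite, data$isotopologue))
  missing <- !(paste(need$metabolite, need$isotopologue) %in% have)
  if (any(missing)) {
    stop("species missing from the dataset: ",
         paste(paste(need$metabolite[missing], need$isotopologue[missing]),
               collapse = ", "), call. = FALSE)
  }

  # replicate medians per subject/intervention/time/metabolite/isotopologue
  med <- stats::aggregate(
    concentration_uM ~ subject + intervention + time_min + metabolite + isotopologue,
    data = data, FUN = stats::median)

  # map to model species; protein from the four amino-acid markers
  med$species <- NA_character_
  for (i in seq_len(nrow(ms))) {
    sel <- med$metabolite == ms$metabolite[i] & med$isotopologue == ms$isotopologue[i]
    med$species[sel] <- ms$species[i]
  }
  aa_sel <- paste(med$metabolite, med$isotopologue) %in%
    paste(ps$metabolite, ps$isotopologue)
  aa <- med[aa_sel, , drop = FALSE]
  aa_sum <- stats::aggregate(concentration_uM ~ subject + intervention + time_min,
                             data = aa, FUN = sum)
  aa_sum$species <- "protein"
  aa_sum$concentration_uM <- aa_sum$concentration_uM * 100 / sum(protein_composition)

  long <- rbind(
    med[!is.na(med$species),
        c("subject", "intervention", "time_min", "species", "concentration_uM")],
    aa_sum[c("subject", "intervention", "time_min", "species", "concentration_uM")])

  # subject baseline from pre-ingestion samples, subtracted and clipped
  base <- stats::aggregate(concentration_uM ~ subject + intervention + species,
                           data = long[long$time_min < 0, , drop = FALSE],
                           FUN = mean)
  names(base)[names(base) == "concentration_uM"] <- "baseline"
  post <- long[long$time_min >= 0, , drop = FALSE]
  post <- merge(post, base, all.x = TRUE,
                by = c("subject", "intervention", "species"))
  post$baseline[is.na(post$baseline)] <- 0
  post$concentration_uM <- pmax(0, post$concentration_uM - post$baseline)
  # the baseline itself collapses to a zero-valued t = 0 anchor
  anchor <- unique(post[c("subject", "intervention", "species")])
  anchor$time_min <- 0
  anchor$concentration_uM <- 0
  anchor$baseline <- 0
  post <- rbind(post[names(anchor)], anchor)
  post <- post[!duplicated(post[c("subject", "intervention", "species", "time_min")]), ]

  avg_fun <- if (subject_average == "mean") mean else stats::median
  agg_mean <- stats::aggregate(concentration_uM ~ intervention + time_min + species,
                               data = post, FUN = avg_fun)
  agg_sd <- stats::aggregate(concentration_uM ~ intervention + time_min + species,
                             data = post,
                             FUN = function(v) if (length(v) > 1) stats::sd(v) else 0)
  out <- agg_mean
  names(out)[names(out) == "concentration_uM"] <- "mean"
  out$sd <- agg_sd$concentration_uM[match(
    paste(out$intervention, out$time_min, out$species),
    paste(agg_sd$intervention, agg_sd$time_min, agg_sd$species))]

  # sigma floor per intervention x species
  for (iv in unique(out$intervention)) {
    for (sp in unique(out$species)) {
      sel <- out$intervention == iv & out$species == sp
      floor_val <- max(sigma_floor_abs, sigma_floor_frac * max(out$mean[sel]))
      out$sd[sel] <- pmax(out$sd[sel], floor_val)
    }
  }
  names(out)[names(out) == "time_min"] <- "time"
  out <- out[order(out$intervention, out$species, out$time), ]
  rownames(out) <- NULL
  class(out) <- c("pf_model_data", "data.frame")
  attr(out, "conventions") <- list(subject_average = subject_average,
                                   sigma_floor_abs = sigma_floor_abs,
                                   sigma_floor_frac = sigma_floor_frac,
                                   protein_composition = protein_composition)
  out
}
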