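test_that("isotopologue concentration is enrichment times total", {
  expect_equal(isotopologue_concentration(0, 100), 0)
  expect_equal(isotopologue_concentration(1, 100), 100)
  expect_equal(isotopologue_concentration(0.02, 2000), 40)
  expect_error(isotopologue_concentration(1.2, 10), "\\[0, 1\\]")
  expect_error(isotopologue_concentration(0.5, -1), "non-negative")
})

test_that("protein pool reconstruction follows the mol% composition", {
  expect_equal(protein_pool(0, 0, 0, 0), 0)
  # inputs summing to 0.401 uM scale to exactly 1 uM with the 40.1 denominator
  expect_equal(protein_pool(0.2, 0.1, 0.06, 0.041), 1.0)
  expect_equal(protein_pool(0.4, 0.2, 0.12, 0.082), 2.0)  # linearity
  expect_error(protein_pool(-1, 0, 0, 0), "non-negative")
})

test_that("contribution percentages match the worked arithmetic", {
  expect_equal(contribution_percent(0, 100), 0)
  expect_equal(contribution_percent(0.02 * 6000, 6000), 100)
  expect_equal(contribution_percent(4.2, 6000), 3.5)
  # scale invariance
  expect_equal(contribution_percent(4.2 * 7, 6000 * 7),
               contribution_percent(4.2, 6000))
  expect_error(contribution_percent(1, 0), "positive")
})

make_group_df <- function(values) {
  data.frame(intervention = "GLC", time_min = 60, metabolite = "lactate",
             isotopologue = "M3", subject = seq_along(values), replicate = 1,
             concentration_uM = values)
}

test_that("the 1.5 IQR filter agrees with the hand-computed fences", {
  # degenerate group: identical values, nothing removed
  res <- remove_outliers_iqr(make_group_df(rep(2, 6)))
  expect_equal(nrow(res$data), 6)
  expect_equal(nrow(res$log), 0)

  # {1,2,3,4,100}: Q1=2, Q3=4, fences [-1, 7], 100 removed
  res <- remove_outliers_iqr(make_group_df(c(1, 2, 3, 4, 100)))
  expect_equal(res$data$concentration_uM, c(1, 2, 3, 4))
  expect_equal(res$log$value, 100)
  expect_equal(res$log$lower_fence, -1)
  expect_equal(res$log$upper_fence, 7)

  # small groups pass through but are logged
  res <- remove_outliers_iqr(make_group_df(c(1, 2, 1000)))
  expect_equal(nrow(res$data), 3)
  expect_equal(res$log$action, "group_too_small")
})

test_that("the filter matches a brute-force quantile oracle on random groups", {
  set.seed(77)
  for (i in 1:300) {
    n <- sample(4:12, 1)
    v <- round(stats::rlnorm(n, 0, 1), sample(c(1, 2, 6), 1))
    res <- remove_outliers_iqr(make_group_df(v))
    q1 <- oracle_quantile7(v, 0.25)
    q3 <- oracle_quantile7(v, 0.75)
    keep_oracle <- v >= q1 - 1.5 * (q3 - q1) & v <= q3 + 1.5 * (q3 - q1)
    expect_equal(res$data$concentration_uM, v[keep_oracle])
  }
})

test_that("the filter is idempotent where single-pass filtering converges", {
  # Idempotence is a property of the data, not just the code: removing
  # extremes shrinks the quartile range, so on noisy data a second pass can
  # remove a little more (~1% of records at the default noise model; see
  # the methods vignette). On noise-free and spike-injected noise-free data
  # the filter is exactly idempotent.
  for (d in list(zero_noise_data(),
                 inject_outliers(zero_noise_data(), 0.05, 10, seed = 4)$data)) {
    once <- remove_outliers_iqr(d)
    twice <- remove_outliers_iqr(once$data)
    expect_equal(nrow(twice$log[twice$log$action == "removed", ]), 0)
    expect_identical(once$data, twice$data)
  }
  # on the default noisy world the second pass touches ~1% of records
  once <- remove_outliers_iqr(noisy_data())
  twice <- remove_outliers_iqr(once$data)
  second_pass <- sum(twice$log$action == "removed")
  expect_lt(second_pass / nrow(once$data), 0.02)
})

test_that("reduction takes replicate medians, subject means, and baselines", {
  # replicate median robustness: {1, 2, 30} -> 2
  base <- expand.grid(subject = c("S1", "S2"), replicate = 1:3,
                      time_min = c(-5, 30), stringsAsFactors = FALSE)
  rows <- list()
  for (met in split(postflux:::modelled_species(),
                    seq_len(nrow(postflux:::modelled_species())))) {
    b <- base
    b$metabolite <- met$metabolite
    b$isotopologue <- met$isotopologue
    b$concentration_uM <- ifelse(b$time_min < 0, 0,
                                 c(1, 2, 30)[b$replicate])
    rows[[met$species]] <- b
  }
  for (aa in split(postflux:::protein_species(),
                   seq_len(nrow(postflux:::protein_species())))) {
    b <- base
    b$metabolite <- aa$metabolite
    b$isotopologue <- aa$isotopologue
    b$concentration_uM <- 0
    rows[[aa$metabolite]] <- b
  }
  d <- do.call(rbind, rows)
  d$intervention <- "GLC"
  d2 <- d
  d2$intervention <- "WP"
  md <- reduce_to_model_dataset(rbind(d, d2))
  pyr30 <- md[md$species == "pyr_M3" & md$time == 30 & md$intervention == "GLC", ]
  expect_equal(pyr30$mean, 2)
  # identical subjects: sd hits the floor
  expect_equal(pyr30$sd, max(1e-6, 0.01 * 2))
  # baseline collapses to a zero t = 0 anchor
  expect_equal(md$mean[md$time == 0], rep(0, sum(md$time == 0)))

  # a missing species is a named error
  expect_error(reduce_to_model_dataset(d[d$metabolite != "citrate", ]),
               "citrate")
})

test_that("zero-noise data reduce exactly to the noiseless model curve", {
  md <- zero_noise_md()
  truth <- zero_noise_truth()
  design <- study_design()
  for (iv in c("GLC", "WP")) {
    nc <- postflux:::noiseless_curves(truth, iv, design)
    for (sp in c("pyr_M3", "lac_M3", "ala_M3", "cit_M2")) {
      col <- c(pyr_M3 = "pyr", lac_M3 = "lac", ala_M3 = "ala",
               cit_M2 = "cit")[[sp]]
      got <- md[md$intervention == iv & md$species == sp & md$time > 0, ]
      expect_equal(got$mean[order(got$time)],
                   unname(nc$states[match(sort(got$time), nc$times), col]),
                   tolerance = 1e-12)
    }
    # the protein pool reconstruction inverts the generator's split
    pro <- md[md$intervention == iv & md$species == "protein" & md$time > 0, ]
    expect_equal(pro$mean[order(pro$time)],
                 nc$pro[match(sort(pro$time), nc$times)], tolerance = 1e-12)
  }
})

test_that("reduction is invariant to row order", {
  d <- noisy_data()
  md1 <- reduce_to_model_dataset(d)
  set.seed(1)
  md2 <- reduce_to_model_dataset(d[sample(nrow(d)), ])
  expect_equal(md1, md2, ignore_attr = TRUE)
})
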