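# metrics straight from generator ground truth: exercises the inference
# layer without paying for rasterisation
truth_metrics <- function(design, seed = 1, effects = treatment_effects()) {
  sim <- simulate_experiment(design, effects, seed = seed,
                             render_images = FALSE)
  sim$truth |>
    dplyr::left_join(design$treatments, by = c(treatment = "label")) |>
    dplyr::transmute(
      aquarium_id = .data$aquarium_id, treatment = .data$treatment,
      n_rd = .data$n_rd, n_rp = .data$n_rp, replicate = .data$replicate,
      day = design$analysis_day,
      l_max_mm = .data$true_l_max_mm, l_med_mm = .data$true_l_med_mm,
      l_mean_mm = .data$true_l_mean_mm, sbr_mm = .data$true_sbr_mm)
}

test_that("the bioturbation battery has the full table layout", {
  d <- make_design()
  sim <- simulate_experiment(d, seed = 31, render_images = FALSE)
  metrics <- truth_metrics(d, seed = 31)
  tests <- run_bioturbation_tests(metrics, n_permutations = 99, seed = 7)
  # 3 depth metrics x (1 main + 5 contrasts) + SBR main only = 19
  expect_equal(nrow(tests), 19)
  expect_equal(sum(tests$test == "ratios"), 4)
  sbr_rows <- tests[tests$response == "sbr_mm", ]
  expect_equal(nrow(sbr_rows), 1)   # no control contrasts for SBR
  counts <- table(tests$response)
  expect_equal(as.integer(counts[c("l_max_mm", "l_med_mm", "l_mean_mm")]),
               c(6L, 6L, 6L))
  # every cell appears exactly once
  expect_false(anyDuplicated(tests[c("response", "test")]) > 0)
})

test_that("the nutrient battery covers 3 nutrients x (1 + 5) tests", {
  d <- make_design()
  sim <- simulate_experiment(d, seed = 5, render_images = FALSE)
  tests <- run_nutrient_tests(sim$nutrients, analysis_day = 21,
                              n_permutations = 99, seed = 11)
  expect_equal(nrow(tests), 18)
  expect_equal(sum(tests$test == "ratios"), 3)
  expect_equal(sum(tests$statistic_type == "t"), 15)
})

test_that("a ratios matrix containing the control is rejected", {
  d <- make_design()
  metrics <- truth_metrics(d, seed = 2)
  expect_error(run_ratios_main_test(metrics, "l_max_mm", seed = 1),
               "exclude the control")
})

test_that("degenerate variance surfaces as a per-test error", {
  d <- make_design()
  metrics <- truth_metrics(d, seed = 3) |>
    dplyr::mutate(l_max_mm = 5)  # no variance anywhere
  expect_error(run_bioturbation_tests(metrics, n_permutations = 99,
                                      seed = 1),
               "l_max_mm")
})

test_that("missing columns and days are caught", {
  d <- make_design()
  metrics <- truth_metrics(d, seed = 4)
  expect_error(run_bioturbation_tests(metrics[-7], n_permutations = 99,
                                      seed = 1), "lacks column")
  sim <- simulate_experiment(d, seed = 4, render_images = FALSE)
  nut <- dplyr::filter(sim$nutrients,
                       !(.data$aquarium_id == "A01" & .data$day == 21))
  expect_error(run_nutrient_tests(nut, 21, n_permutations = 99, seed = 1),
               "missing for some aquaria")
})

test_that("the nutrient PCA ordinates per-treatment day means", {
  d <- make_design()
  sim <- simulate_experiment(d, seed = 9, render_images = FALSE)
  fit <- run_nutrient_pca(sim$nutrients)
  expect_equal(nrow(fit$scores), 6 * 7)  # 6 groups x 7 sampling days
  expect_equal(nrow(fit$loadings), 3)
  expect_true(all(diff(fit$variance_fraction) <= 1e-12))
  # degenerate request
  one_day <- dplyr::filter(sim$nutrients, .data$day == 0)
  expect_error(run_nutrient_pca(one_day), "2 treatments and 2 days")
})

test_that("a full analysis is reproducible under a fixed seed", {
  d <- small_design()
  sim <- simulate_experiment(d, small_effects(), seed = 13,
                             render_images = FALSE)
  metrics <- truth_metrics(d, seed = 13, effects = small_effects())
  r1 <- analyze_experiment(metrics, sim$nutrients,
                           n_permutations = 199, seed = 3)
  r2 <- analyze_experiment(metrics, sim$nutrients,
                           n_permutations = 199, seed = 3)
  expect_identical(r1$bioturbation_tests, r2$bioturbation_tests)
  expect_identical(r1$nutrient_tests, r2$nutrient_tests)
  expect_true(all(c("seed", "config_hash", "package_version") %in%
                    names(r1$provenance)))
  expect_identical(r1$provenance$config_hash, r2$provenance$config_hash)
  # significance flags mirror the 0.05 rule
  expect_equal(r1$bioturbation_tests$significant,
               r1$bioturbation_tests$p_perm < 0.05)
})
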