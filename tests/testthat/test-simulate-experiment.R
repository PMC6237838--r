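test_that("a simulated experiment has the full design cardinality", {
  d <- small_design(n_replicates = 2)  # 3 groups x 2 replicates
  sim <- simulate_experiment(d, small_effects(), small_render(),
                             seed = 21)
  expect_equal(length(sim$images), 6)
  expect_equal(nrow(sim$truth), 6)
  expect_equal(nrow(sim$nutrients), 6 * 3)
  expect_setequal(names(sim$images), d$aquaria$aquarium_id)
})

test_that("control ground truth is a pure surface carpet", {
  d <- small_design()
  sim <- simulate_experiment(d, small_effects(), small_render(), seed = 4)
  ctrl <- sim$truth[sim$truth$treatment == "control", ]
  expect_true(all(ctrl$true_l_max_mm == 0))
  expect_true(all(ctrl$true_l_med_mm == 0))
  expect_true(all(ctrl$true_l_mean_mm == 0))
  expect_true(all(is.na(ctrl$true_sbr_mm)))
})

test_that("truth metrics respect ordering and truncation bounds", {
  d <- make_design(n_replicates = 2)
  # truth only (no rasterisation): depths are frame-independent
  sim <- simulate_experiment(d, treatment_effects(n_particles = 300),
                             seed = 8, render_images = FALSE)
  tr <- sim$truth
  expect_true(all(tr$true_l_med_mm <= tr$true_l_max_mm))
  expect_true(all(tr$true_l_mean_mm <= tr$true_l_max_mm))
  expect_true(all(tr$true_l_max_mm >= 0))
  tab <- dplyr::left_join(tr, d$treatments, by = c(treatment = "label"))
  rd <- tab[tab$n_rd > 0, ]
  rp_only <- tab[tab$n_rd == 0 & tab$n_rp > 0, ]
  expect_true(all(rd$true_l_max_mm <= 120))
  expect_true(all(rp_only$true_l_max_mm <= 80))
})

test_that("simulations are seed-deterministic, differing only in noise", {
  d <- small_design()
  a <- simulate_experiment(d, small_effects(), small_render(), seed = 5)
  b <- simulate_experiment(d, small_effects(), small_render(), seed = 5)
  expect_identical(a$images[["A01"]]$pixels, b$images[["A01"]]$pixels)
  expect_identical(a$nutrients, b$nutrients)
  expect_identical(a$truth, b$truth)

  c <- simulate_experiment(d, small_effects(), small_render(), seed = 6)
  expect_false(identical(a$particles, c$particles))
  expect_identical(a$truth$aquarium_id, c$truth$aquarium_id)  # same design
})

test_that("on-disk bundles follow the declared file layout", {
  d <- small_design()
  out <- withr::local_tempdir()
  sim <- simulate_experiment(d, small_effects(), small_render(), seed = 2,
                             keep_images = FALSE, out_dir = out)
  pngs <- list.files(out, pattern = "\\.png$")
  expect_equal(sort(pngs),
               sort(sprintf("%s_d21.png", d$aquaria$aquarium_id)))
  nut <- utils::read.csv(file.path(out, "nutrients.csv"))
  expect_named(nut, c("aquarium_id", "treatment", "replicate", "day",
                      "nh4_n_mg_l", "nox_n_mg_l", "po4_p_mg_l"))
  gt <- utils::read.csv(file.path(out, "ground_truth.csv"))
  expect_named(gt, c("aquarium_id", "true_l_max_mm", "true_l_med_mm",
                     "true_l_mean_mm", "true_sbr_mm"))
  expect_equal(nrow(gt), 6)
})
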