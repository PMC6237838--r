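test_that("a flat synthetic interface is recovered exactly, every column", {
  fx <- flat_fixture(c(3, 6, 9), noise_sd = 4, base_row_px = 50L)
  mask <- segment_luminophores(fx$img)
  tr <- detect_interface(fx$img, mask, mode = "treatment")
  # carpet-free fixture: all columns at the true elevation
  expect_true(all(tr$elevation_row == 50L))
})

test_that("the control convention tracks the sediment below the carpet", {
  # dense carpet at depth 0 plus sediment beneath a flat interface
  fx <- flat_fixture(rep(0, 60), columns = seq(5, 115, length.out = 60),
                     noise_sd = 0, base_row_px = 50L)
  mask <- segment_luminophores(fx$img)
  ctrl <- detect_interface(fx$img, mask, mode = "control")
  # sediment top, not the carpet top (which sits above row 50)
  expect_true(all(ctrl$elevation_row == 50L))
  fp_rows <- which(mask, arr.ind = TRUE)[, 1] - 1
  expect_lt(min(fp_rows), 50)  # the carpet really is above the interface
})

test_that("interface recovery stays within the window on rough fixtures", {
  rp <- small_render(noise_sd = 4)
  tr_true <- generate_interface_trace(120, sbr_target_mm = 4,
                                      resolution_mm_per_px = 0.1,
                                      smoothness = 60, base_row_px = 60,
                                      seed = 13)
  img <- render_profile_image(tr_true,
                              tibble::tibble(column = numeric(0),
                                             depth_mm = numeric(0)),
                              rp, seed = 13)
  mask <- segment_luminophores(img)
  det <- detect_interface(img, mask, mode = "treatment", window = 9)
  expect_true(all(abs(det$elevation_row - tr_true) <= 9))
})

test_that("an all-water image has no detectable interface", {
  rp <- small_render(noise_sd = 0)
  water <- array(rep(rp$water_rgb / 255,
                     each = rp$image_height_px * rp$image_width_px),
                 dim = c(rp$image_height_px, rp$image_width_px, 3))
  img <- profile_image(water, 0.1)
  mask <- segment_luminophores(img)
  expect_error(detect_interface(img, mask, "treatment"), "no sediment")
})

test_that("a floating luminophore disc does not fake an interface", {
  rp <- small_render(noise_sd = 0)
  interface <- rep(80L, 120)
  attr(interface, "resolution_mm_per_px") <- 0.1
  img <- render_profile_image(interface,
                              tibble::tibble(column = 60, depth_mm = 1),
                              rp, seed = 1)
  # graft just the 5-row disc 40 rows up into the water column
  px <- img$pixels
  disc <- px[89:93, 59:63, ]
  px[49:53, 59:63, ] <- disc
  for (k in 1:3) px[89:93, 59:63, k] <- rp$sediment_rgb[k] / 255
  img2 <- profile_image(px, 0.1)
  mask2 <- segment_luminophores(img2)
  det <- detect_interface(img2, mask2, mode = "treatment")
  expect_true(all(det$elevation_row == 80L))
})

test_that("shifting the scene down shifts elevations, not the profile", {
  mk <- function(base) {
    fx <- flat_fixture(c(2, 5, 8), noise_sd = 0, base_row_px = base)
    mask <- segment_luminophores(fx$img)
    tr <- detect_interface(fx$img, mask, "treatment")
    list(tr = tr, prof = flatten_and_profile(mask, tr))
  }
  a <- mk(50L)
  b <- mk(65L)
  expect_equal(b$tr$elevation_row, a$tr$elevation_row + 15L)
  expect_equal(as.data.frame(b$prof), as.data.frame(a$prof))
})
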