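profile_of <- function(depth_mm, n_pixels) {
  prof <- tibble::tibble(depth_mm = depth_mm,
                         n_pixels = as.integer(n_pixels))
  class(prof) <- c("depth_profile", class(prof))
  prof
}

trace_of <- function(elev, res = 0.07, mode = "treatment") {
  tr <- tibble::tibble(column = seq_along(elev) - 1L,
                       elevation_row = as.integer(elev))
  attr(tr, "mode") <- mode
  attr(tr, "resolution_mm_per_px") <- res
  class(tr) <- c("interface_trace", class(tr))
  tr
}

test_that("the three depth statistics agree with hand arithmetic", {
  expect_equal(l_max(profile_of(0.70, 1)), 0.70)
  expect_equal(l_max(profile_of(0, 100)), 0)

  expect_equal(l_med(profile_of(c(1, 2, 3), c(1, 1, 1))), 2.0)
  expect_equal(l_med(profile_of(c(1, 2, 3, 4), c(1, 1, 1, 1))), 2.5)

  expect_equal(l_mean(profile_of(c(1, 2, 3), c(1, 1, 1))), 2.0)
  expect_equal(l_mean(profile_of(0, 50)), 0)
})

test_that("weighted statistics match a brute-force expanded oracle", {
  for (seed in 1:10) {
    prof <- withr::with_seed(seed, profile_of(
      depth_mm = sort(sample(0:50, 8)) * 0.07,
      n_pixels = sample(1:20, 8, replace = TRUE)))
    expanded <- rep(prof$depth_mm, prof$n_pixels)
    expect_equal(l_mean(prof), mean(expanded))
    expect_equal(l_med(prof), stats::median(expanded))
    expect_equal(l_max(prof), max(expanded))
    # ordering invariant
    expect_lte(l_med(prof), l_max(prof))
    expect_lte(l_mean(prof), l_max(prof))
  }
})

test_that("SBR is the interface span times the resolution", {
  expect_equal(sbr(trace_of(c(10, 14, 12))), 0.28)  # (14 - 10) x 0.07
  expect_equal(sbr(trace_of(rep(7, 5))), 0)
  expect_error(sbr(trace_of(5)), "2 columns")
  expect_error(sbr(trace_of(c(10, 14), mode = "control")), "control")
})

test_that("all four statistics scale linearly with the resolution", {
  px_depths <- c(0, 3, 10, 25)
  px_counts <- c(5, 2, 7, 1)
  elev <- c(10, 18, 14)
  for (res in c(0.07, 0.14)) {
    prof <- profile_of(px_depths * res, px_counts)
    tr <- trace_of(elev, res = res)
    m <- compute_metrics(prof, tr)
    base <- compute_metrics(profile_of(px_depths, px_counts),
                            trace_of(elev, res = 1))
    expect_equal(m$l_max_mm, base$l_max_mm * res)
    expect_equal(m$l_med_mm, base$l_med_mm * res)
    expect_equal(m$l_mean_mm, base$l_mean_mm * res)
    expect_equal(m$sbr_mm, base$sbr_mm * res)
  }
})

test_that("control bundles have zero depths and no SBR entry", {
  m <- compute_metrics(profile_of(0, 200), trace_of(rep(30, 6)),
                       is_control = TRUE)
  expect_equal(m$l_max_mm, 0)
  expect_equal(m$l_med_mm, 0)
  expect_equal(m$l_mean_mm, 0)
  expect_true(is.na(m$sbr_mm))
})

test_that("empty profiles are rejected", {
  empty <- profile_of(numeric(0), integer(0))
  expect_error(l_max(empty), "empty")
  expect_error(l_med(empty), "empty")
  expect_error(l_mean(empty), "empty")
})
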