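#' Generate a rough sediment-water interface trace
#'
#' Produces a smooth random elevation series (one interface row index per
#' image column) whose vertical span equals a requested surface boundary
#' roughness (SBR). Smoothed Gaussian noise is rescaled so that
#' `(max - min) * resolution` matches `sbr_target_mm` to the nearest pixel;
#' with a zero target the trace is flat.
#'
#' @param width_px Number of image columns (>= 2).
#' @param sbr_target_mm Target SBR in mm (>= 0).
#' @param resolution_mm_per_px Physical pixel size (mm).
#' @param smoothness Moving-average window (px) applied to the raw noise;
#'   larger values give longer-wavelength topography.
#' @param base_row_px Row index around which the interface undulates.
#' @param seed Integer seed.
#'
#' @return Integer vector of interface row indices (0-based, top of frame =
#'   row 0), length `width_px`, with attribute `resolution_mm_per_px`.
#' @export
generate_interface_trace <- function(width_px,
                                     sbr_target_mm,
                                     resolution_mm_per_px = 0.07,
                                     smoothness = 150,
                                     base_row_px = 120,
                                     seed = 1) {
  if (width_px < 2) stop("`width_px` must be >= 2", call. = FALSE)
  if (sbr_target_mm < 0) stop("`sbr_target_mm` must be >= 0", call. = FALSE)
  if (resolution_mm_per_px <= 0) {
    stop("`resolution_mm_per_px` must be positive", call. = FALSE)
  }

  span_px <- round(sbr_target_mm / resolution_mm_per_px)
  if (span_px == 0) {
    rows <- rep.int(as.integer(base_row_px), width_px)
  } else {
    rows <- withr::with_seed(seed, {
      k <- max(3L, as.integer(smoothness))
      # smoothed Brownian motion: long-wavelength relief with negligible
      # column-to-column jitter once rescaled to the target span
      raw <- cumsum(stats::rnorm(width_px + k))
      sm <- as.numeric(stats::filter(raw, rep(1 / k, k), sides = 2))
      sm <- sm[!is.na(sm)][seq_len(width_px)]
      if (max(sm) == min(sm)) sm <- sm + seq_len(width_px) * 1e-9
      # min maps to 0 and max to span_px exactly, and both survive rounding
      scaled <- (sm - min(sm)) / (max(sm) - min(sm)) * span_px
      as.integer(base_row_px - span_px %/% 2 + round(scaled))
    })
  }
  if (any(rows < 0)) {
    stop("interface rises above the frame; increase `base_row_px`",
         call. = FALSE)
  }
  attr(rows, "resolution_mm_per_px") <- resolution_mm_per_px
  rows
}
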