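#' Maximum mixed depth
#'
#' Greatest burial depth with at least one luminophore pixel: the maximum
#' extent of particle mixing over the long term.
#'
#' @param profile A `depth_profile` from [flatten_and_profile()].
#' @return Depth in mm.
#' @export
l_max <- function(profile) {
  check_profile(profile)
  max(profile$depth_mm)
}

#' Median mixed depth
#'
#' Median of the pixel-weighted depth distribution: the typical short-term
#' depth of mixing. An even total pixel count takes the midpoint of the two
#' middle order statistics.
#'
#' @inheritParams l_max
#' @return Depth in mm.
#' @export
l_med <- function(profile) {
  check_profile(profile)
  weighted_median(profile$depth_mm, profile$n_pixels)
}

#' Mean mixed depth
#'
#' Pixel-count-weighted arithmetic mean depth: a time-dependent indication
#' of mixing.
#'
#' @inheritParams l_max
#' @return Depth in mm.
#' @export
l_mean <- function(profile) {
  check_profile(profile)
  sum(profile$depth_mm * profile$n_pixels) / sum(profile$n_pixels)
}

check_profile <- function(profile) {
  if (!inherits(profile, "depth_profile") && !is.data.frame(profile)) {
    stop("`profile` must be a depth profile", call. = FALSE)
  }
  if (nrow(profile) == 0) {
    stop("empty depth profile: no luminophore pixels", call. = FALSE)
  }
  invisible(profile)
}

# midpoint-interpolated median of depths replicated by integer counts,
# computed from cumulative counts (no expansion)
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- as.numeric(w[o])
  total <- sum(w)
  cw <- cumsum(w)
  if (total %% 2 == 1) {
    k <- (total + 1) / 2
    x[which(cw >= k)[1]]
  } else {
    k1 <- total / 2
    k2 <- k1 + 1
    (x[which(cw >= k1)[1]] + x[which(cw >= k2)[1]]) / 2
  }
}

#' Surface boundary roughness
#'
#' Maximum vertical deviation of the sediment-water interface:
#' `(max - min elevation) * resolution`, in mm. Defined only for stocked
#' aquaria - in controls the luminophore carpet is never reworked and no
#' sediment-water interface relief exists, so control-mode traces are
#' rejected.
#'
#' @param interface An `interface_trace` from [detect_interface()] (or from
#'   the generator, with a `resolution_mm_per_px` attribute).
#' @return SBR in mm.
#' @export
sbr <- function(interface) {
  mode <- attr(interface, "mode")
  if (identical(mode, "control")) {
    stop("SBR is undefined for control-mode interface traces",
         call. = FALSE)
  }
  elev <- if (is.data.frame(interface)) interface$elevation_row
          else as.numeric(interface)
  if (length(elev) < 2) {
    stop("SBR needs at least 2 columns", call. = FALSE)
  }
  res <- attr(interface, "resolution_mm_per_px")
  if (is.null(res)) stop("interface carries no resolution", call. = FALSE)
  (max(elev) - min(elev)) * res
}

#' Bundle the per-aquarium mixing statistics
#'
#' Computes the maximum, median and mean mixed depth from the depth profile
#' and, for stocked aquaria only, the surface boundary roughness from the
#' interface trace.
#'
#' @param profile A `depth_profile`.
#' @param interface The matching `interface_trace`.
#' @param is_control Is this an unstocked control aquarium? (Its SBR is
#'   reported as `NA`.)
#' @return A one-row tibble: `l_max_mm`, `l_med_mm`, `l_mean_mm`, `sbr_mm`.
#' @export
compute_metrics <- function(profile, interface, is_control = FALSE) {
  tibble::tibble(
    l_max_mm = l_max(profile),
    l_med_mm = l_med(profile),
    l_mean_mm = l_mean(profile),
    sbr_mm = if (is_control) NA_real_ else sbr(interface)
  )
}
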