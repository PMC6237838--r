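#' Colour rule for luminophore segmentation
#'
#' Pink-dominance thresholds on the 0-255 scale: a pixel is a luminophore
#' when its red channel exceeds `r_min` and dominates green and blue by the
#' given margins. Defaults separate the renderer's pink (255, 105, 180)
#' from sediment and water by more than five noise SDs at the default noise
#' level.
#'
#' @param r_min Minimum red value.
#' @param rg_margin Minimum red minus green.
#' @param rb_margin Minimum red minus blue.
#' @return A list of class `colour_rule`.
#' @export
colour_rule <- function(r_min = 150, rg_margin = 50, rb_margin = 40) {
  structure(list(r_min = r_min, rg_margin = rg_margin,
                 rb_margin = rb_margin), class = "colour_rule")
}

as_pixels <- function(image) {
  if (inherits(image, "profile_image")) return(image$pixels)
  image
}

#' Segment luminophore particles from a profile image
#'
#' Applies the pink-dominance [colour_rule()] pixelwise.
#'
#' @param image A [profile_image()] or an RGB array (`rows x cols x 3`,
#'   values in `[0, 1]`).
#' @param rule A [colour_rule()].
#' @return Logical matrix (`TRUE` = luminophore) with attribute `n_pixels`.
#' @export
segment_luminophores <- function(image, rule = colour_rule()) {
  px <- as_pixels(image)
  if (length(dim(px)) != 3 || dim(px)[3] != 3) {
    stop("segmentation requires an RGB image (rows x cols x 3)",
         call. = FALSE)
  }
  r <- px[, , 1] * 255
  g <- px[, , 2] * 255
  b <- px[, , 3] * 255
  mask <- r >= rule$r_min & (r - g) >= rule$rg_margin &
    (r - b) >= rule$rb_margin
  attr(mask, "n_pixels") <- sum(mask)
  mask
}

# water-dominance rule used by interface detection
is_water <- function(px, b_over_r_margin = 30) {
  (px[, , 3] - px[, , 1]) * 255 >= b_over_r_margin
}

#' Detect the sediment interface of a profile image
#'
#' Finds, per column, the topmost row from which a sliding vertical window
#' is mostly occupied. In `treatment` mode occupancy means any non-water
#' pixel (sediment or luminophore): the trace is the sediment-water
#' interface. In `control` mode luminophore pixels are excluded, so the
#' trace follows the boundary between the undisturbed luminophore carpet
#' and the sediment beneath it - the convention for unstocked aquaria,
#' whose carpet is never reworked. The candidate row itself must be
#' occupied, which anchors a clean flat interface exactly and lets the
#' window reject isolated particles floating in the water column.
#'
#' @param image A [profile_image()] or RGB array.
#' @param mask Luminophore mask from [segment_luminophores()] (same shape).
#' @param mode `"treatment"` or `"control"`.
#' @param window Sliding window length in rows.
#' @param occupancy Minimum occupied fraction of the window.
#' @param despeckle_px Width (odd, in columns) of a running-median filter
#'   applied to the raw trace. Particles lying on a sloping interface dent
#'   the raw trace by up to their own diameter in a few adjacent columns;
#'   the median filter removes these particle-scale bumps while leaving
#'   monotone topography untouched. Set to 1 to disable.
#' @return An `interface_trace`: tibble with columns `column` (0-based) and
#'   `elevation_row` (0-based row index), with attributes `mode` and
#'   `resolution_mm_per_px`.
#' @export
detect_interface <- function(image, mask, mode = c("treatment", "control"),
                             window = 9, occupancy = 0.6,
                             despeckle_px = 5) {
  mode <- match.arg(mode)
  px <- as_pixels(image)
  if (!identical(dim(px)[1:2], dim(mask))) {
    stop("`mask` must align with the image", call. = FALSE)
  }
  h <- dim(px)[1]
  w <- dim(px)[2]
  if (window > h) stop("`window` exceeds image height", call. = FALSE)

  occupied <- !is_water(px)
  if (mode == "control") occupied <- occupied & !mask
  need <- ceiling(window * occupancy)

  # windowed occupancy via columnwise cumulative sums
  cs <- apply(occupied, 2, cumsum)
  win <- cs[window:h, , drop = FALSE] -
    rbind(0, cs)[1:(h - window + 1), , drop = FALSE]
  ok <- win >= need & occupied[1:(h - window + 1), , drop = FALSE]

  elev <- rep(NA_integer_, w)
  hit <- apply(ok, 2, function(v) {
    i <- which(v)
    if (length(i)) i[1] else NA_integer_
  })
  elev <- as.integer(hit - 1L)  # back to 0-based rows
  if (anyNA(elev)) {
    bad <- which(is.na(elev)) - 1L
    stop(sprintf("no sediment interface found in %d column(s) (e.g. %s)",
                 length(bad),
                 paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  }
  if (despeckle_px > 1 && w > despeckle_px) {
    k <- despeckle_px + (despeckle_px + 1) %% 2   # force odd
    elev <- as.integer(stats::runmed(elev, k, endrule = "median"))
  }
  res <- if (inherits(image, "profile_image")) image$resolution_mm_per_px
         else attr(image, "resolution_mm_per_px")
  trace <- tibble::tibble(column = 0:(w - 1), elevation_row = elev)
  attr(trace, "mode") <- mode
  attr(trace, "resolution_mm_per_px") <- res
  class(trace) <- c("interface_trace", class(trace))
  trace
}

#' Flatten the interface and build a depth profile
#'
#' Each luminophore pixel contributes a burial depth of
#' `max(0, row - elevation of its column) * resolution`: the interface is
#' flattened to depth zero, and pixels above it (surface carpet, floating
#' grains) are clipped to depth 0 rather than discarded, so the carpet
#' contributes a defined depth-0 mass. Counts are aggregated by depth.
#'
#' @param mask Logical luminophore mask.
#' @param interface An `interface_trace` from [detect_interface()].
#' @param resolution_mm_per_px Pixel size (mm); defaults to the trace's.
#' @return A `depth_profile`: tibble with columns `depth_mm` and `n_pixels`,
#'   attribute `total_pixels`.
#' @export
flatten_and_profile <- function(mask, interface,
                                resolution_mm_per_px = NULL) {
  res <- resolution_mm_per_px %||% attr(interface, "resolution_mm_per_px")
  if (is.null(res) || is.na(res)) {
    stop("resolution is required (set it on the trace or pass it)",
         call. = FALSE)
  }
  if (ncol(mask) != nrow(interface)) {
    stop("`mask` and `interface` disagree on image width", call. = FALSE)
  }
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) == 0) {
    prof <- tibble::tibble(depth_mm = numeric(), n_pixels = integer())
  } else {
    elev <- interface$elevation_row[pix[, 2]]      # columns are 1-based here
    depth_px <- pmax(0L, (pix[, 1] - 1L) - elev)
    counts <- table(depth_px)
    prof <- tibble::tibble(
      depth_mm = as.numeric(names(counts)) * res,
      n_pixels = as.integer(counts)
    ) |> dplyr::arrange(.data$depth_mm)
  }
  attr(prof, "total_pixels") <- sum(prof$n_pixels)
  attr(prof, "resolution_mm_per_px") <- res
  class(prof) <- c("depth_profile", class(prof))
  prof
}

#' Quantify one profile image
#'
#' The full per-image pipeline: segment luminophores, detect the interface
#' under the requested convention, flatten it and aggregate the depth
#' profile. Logs a per-image line with pixel counts.
#'
#' @param image A [profile_image()].
#' @param mode Interface convention: `"treatment"` (sediment-water) or
#'   `"control"` (sediment-luminophore carpet).
#' @param rule A [colour_rule()].
#' @param window,occupancy,despeckle_px Interface-detection settings, see
#'   [detect_interface()].
#' @param quiet Suppress the log line?
#' @return A list with elements `profile` (a `depth_profile`), `interface`
#'   (an `interface_trace`) and `mask`.
#' @export
quantify_image <- function(image, mode = c("treatment", "control"),
                           rule = colour_rule(), window = 9,
                           occupancy = 0.6, despeckle_px = 5,
                           quiet = TRUE) {
  mode <- match.arg(mode)
  mask <- segment_luminophores(image, rule)
  interface <- detect_interface(image, mask, mode = mode,
                                window = window, occupancy = occupancy,
                                despeckle_px = despeckle_px)
  profile <- flatten_and_profile(mask, interface)
  if (!quiet) {
    message(sprintf("[quantify] %s d%s: %d luminophore px, %d depth bins (%s mode)",
                    image$aquarium_id, image$day, sum(mask),
                    nrow(profile), mode))
  }
  list(profile = profile, interface = interface, mask = mask)
}

#' Load the analysis-day images of an experiment
#'
#' Expects one `<aquarium_id>_d<day>.png` per aquarium of the design, and
#' nothing else image-like that the design does not mention.
#'
#' @param dir Directory of PNG files.
#' @param design A [make_design()].
#' @param resolution_mm_per_px Pixel size (mm) to stamp on each image.
#' @param day Analysis day; defaults to the design's.
#' @return Named list of [profile_image()]s (one per aquarium).
#' @export
load_images <- function(dir, design, resolution_mm_per_px = 0.07,
                        day = design$analysis_day) {
  stopifnot(inherits(design, "microcosm_design"))
  expected <- sprintf("%s_d%d.png", design$aquaria$aquarium_id, day)
  present <- list.files(dir, pattern = "\\.png$", ignore.case = TRUE)
  missing <- setdiff(expected, present)
  if (length(missing)) {
    stop("missing image(s) for aquarium(s): ",
         paste(sub("_d\\d+\\.png$", "", missing), collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(present, expected)
  if (length(extra)) {
    stop("unexpected file(s) in image directory: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  imgs <- purrr::map2(
    expected, design$aquaria$aquarium_id,
    function(f, id) read_profile_png(file.path(dir, f),
                                     resolution_mm_per_px,
                                     aquarium_id = id, day = day))
  rlang::set_names(imgs, design$aquaria$aquarium_id)
}

#' Quantify every image of a simulated or loaded experiment
#'
#' Runs [quantify_image()] on each aquarium with the interface convention
#' dictated by its treatment (control aquaria use the carpet convention)
#' and bundles the per-aquarium mixing statistics.
#'
#' @param images Named list of [profile_image()]s (names = aquarium ids),
#'   or a `microcosm_simulation` holding them.
#' @param design A [make_design()]; taken from the simulation if omitted.
#' @param ... Passed to [quantify_image()].
#' @return A tibble of per-aquarium metrics (see [compute_metrics()]).
#' @export
quantify_experiment <- function(images, design = NULL, ...) {
  if (inherits(images, "microcosm_simulation")) {
    design <- images$design
    images <- images$images
  }
  stopifnot(inherits(design, "microcosm_design"), !is.null(images))
  tab <- design_table(design)
  rows <- purrr::map(seq_len(nrow(tab)), function(i) {
    trt <- tab[i, ]
    img <- images[[trt$aquarium_id]]
    if (is.null(img)) stop("no image for aquarium ", trt$aquarium_id,
                           call. = FALSE)
    mode <- if (trt$is_control) "control" else "treatment"
    q <- quantify_image(img, mode = mode, ...)
    compute_metrics(q$profile, q$interface,
                    is_control = trt$is_control) |>
      dplyr::mutate(aquarium_id = trt$aquarium_id,
                    treatment = trt$treatment,
                    n_rd = trt$n_rd, n_rp = trt$n_rp,
                    replicate = trt$replicate, day = img$day, .before = 1)
  })
  dplyr::bind_rows(rows)
}
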