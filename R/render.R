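#' Rendering parameters for synthetic profile images
#'
#' Geometry, palette and noise settings used to rasterise one aquarium face.
#' Defaults follow f-SPI practice: 0.07 mm per pixel, a 150 mm sediment
#' column, near-black sediment, bluish water and pink luminophores; the
#' frame width is a 21 mm analysis window (300 columns) which keeps
#' rendering and segmentation fast without changing any depth statistic.
#'
#' @param image_width_px,image_height_px Frame size in pixels.
#' @param resolution_mm_per_px Physical pixel size (mm).
#' @param sediment_column_mm Height of the sediment column (mm); particles
#'   deeper than this cannot be rendered.
#' @param particle_radius_px Rendered luminophore disc radius (px).
#' @param luminophore_rgb,sediment_rgb,water_rgb Colour triples on 0-255.
#' @param noise_sd Additive Gaussian pixel noise SD on the 0-255 scale.
#' @param base_row_px Default interface elevation (row index).
#' @return A list of class `render_params`.
#' @export
render_params <- function(image_width_px = 300,
                          image_height_px = 2300,
                          resolution_mm_per_px = 0.07,
                          sediment_column_mm = 150,
                          particle_radius_px = 2,
                          luminophore_rgb = c(255, 105, 180),
                          sediment_rgb = c(25, 22, 20),
                          water_rgb = c(55, 85, 140),
                          noise_sd = 4,
                          base_row_px = 250) {
  if (resolution_mm_per_px <= 0) {
    stop("`resolution_mm_per_px` must be positive", call. = FALSE)
  }
  if (sediment_column_mm > image_height_px * resolution_mm_per_px) {
    stop("sediment column does not fit in the frame", call. = FALSE)
  }
  structure(
    list(image_width_px = as.integer(image_width_px),
         image_height_px = as.integer(image_height_px),
         resolution_mm_per_px = resolution_mm_per_px,
         sediment_column_mm = sediment_column_mm,
         particle_radius_px = as.integer(particle_radius_px),
         luminophore_rgb = luminophore_rgb,
         sediment_rgb = sediment_rgb,
         water_rgb = water_rgb,
         noise_sd = noise_sd,
         base_row_px = as.integer(base_row_px)),
    class = "render_params"
  )
}

#' Construct a profile image object
#'
#' @param pixels Numeric array `rows x cols x 3` with values in `[0, 1]`.
#' @param resolution_mm_per_px Physical pixel size (mm).
#' @param aquarium_id,day Identification metadata.
#' @return An object of class `profile_image`.
#' @export
profile_image <- function(pixels, resolution_mm_per_px,
                          aquarium_id = NA_character_, day = NA_integer_) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("`pixels` must be a rows x cols x 3 RGB array", call. = FALSE)
  }
  if (dim(pixels)[1] < 2 || dim(pixels)[2] < 2) {
    stop("image must have at least 2 rows and 2 columns", call. = FALSE)
  }
  if (resolution_mm_per_px <= 0) {
    stop("`resolution_mm_per_px` must be positive", call. = FALSE)
  }
  structure(
    list(pixels = pixels, resolution_mm_per_px = resolution_mm_per_px,
         aquarium_id = aquarium_id, day = as.integer(day)),
    class = "profile_image"
  )
}

#' @export
print.profile_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<profile_image> %s d%s: %d x %d px @ %.3f mm/px\n",
              x$aquarium_id, x$day, d[1], d[2], x$resolution_mm_per_px))
  invisible(x)
}

disc_offsets <- function(radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
}

#' Render a synthetic sediment profile image
#'
#' Rasterises one aquarium face: water colour above the interface, sediment
#' colour below, and one pink luminophore disc per particle. A particle with
#' depth `d > 0` is centred `d / resolution` rows below its column's
#' interface; a particle with depth 0 (surface-carpet mass) is drawn with
#' its disc resting on the interface, entirely above it, so that its deepest
#' pixel sits at burial depth 0 - this keeps quantified control carpets at
#' exactly zero mixed depth. Optional additive Gaussian noise is applied and
#' the frame is quantised to 8 bits, so writing and re-reading a PNG is
#' lossless.
#'
#' @param interface Integer vector of interface row indices per column
#'   (from [generate_interface_trace()]), length = image width.
#' @param particles Data frame with columns `column` (0-based image column)
#'   and `depth_mm` (>= 0). May have zero rows.
#' @param params A [render_params()].
#' @param seed Integer seed for the pixel noise.
#' @param aquarium_id,day Metadata carried on the image.
#'
#' @return A [profile_image()] with attribute `footprint`: the logical
#'   matrix of pixels covered by luminophore discs (the segmentation ground
#'   truth).
#' @export
render_profile_image <- function(interface, particles, params,
                                 seed = 1, aquarium_id = NA_character_,
                                 day = NA_integer_) {
  stopifnot(inherits(params, "render_params"))
  h <- params$image_height_px
  w <- params$image_width_px
  res <- params$resolution_mm_per_px
  if (length(interface) != w) {
    stop("`interface` length must equal image width", call. = FALSE)
  }
  particles <- tibble::as_tibble(particles)
  if (nrow(particles) > 0) {
    if (any(particles$depth_mm < 0)) {
      stop("particle depths must be >= 0", call. = FALSE)
    }
    if (any(particles$depth_mm > params$sediment_column_mm)) {
      stop("particle deeper than the rendered sediment column",
           call. = FALSE)
    }
    if (any(particles$column < 0 | particles$column >= w)) {
      stop("particle column outside the frame", call. = FALSE)
    }
  }

  # base layers (row-major matrices per channel)
  rows0 <- matrix(0:(h - 1), nrow = h, ncol = w)          # 0-based row index
  elev <- matrix(interface, nrow = h, ncol = w, byrow = TRUE)
  below <- rows0 >= elev
  channels <- lapply(1:3, function(k) {
    m <- matrix(params$water_rgb[k], nrow = h, ncol = w)
    m[below] <- params$sediment_rgb[k]
    m
  })

  footprint <- matrix(FALSE, nrow = h, ncol = w)
  if (nrow(particles) > 0) {
    r <- params$particle_radius_px
    off <- disc_offsets(r)
    col0 <- as.integer(particles$column)             # 0-based
    elev_p <- interface[col0 + 1L]
    depth_px <- round(particles$depth_mm / res)
    # buried discs are embedded flush with the surface (top never above the
    # interface), so surface relief equals the interface trace by
    # construction; the surface carpet (depth 0) rests on top of it
    centre_row <- ifelse(particles$depth_mm > 0,
                         elev_p + pmax(depth_px, r), elev_p - r - 1L)
    if (any(centre_row + r >= h) || any(centre_row - r < 0)) {
      stop("particle disc falls outside the frame", call. = FALSE)
    }
    pr <- rep(centre_row, each = nrow(off)) + off$dr   # 0-based rows
    pc <- rep(col0, each = nrow(off)) + off$dc
    keep <- pc >= 0 & pc < w
    idx <- cbind(pr[keep] + 1L, pc[keep] + 1L)
    footprint[idx] <- TRUE
    for (k in 1:3) channels[[k]][idx] <- params$luminophore_rgb[k]
  }

  pixels <- array(0, dim = c(h, w, 3))
  if (params$noise_sd > 0) {
    noise <- withr::with_seed(seed,
      array(stats::rnorm(h * w * 3, sd = params$noise_sd), dim = c(h, w, 3)))
  } else {
    noise <- 0
  }
  for (k in 1:3) pixels[, , k] <- channels[[k]]
  pixels <- pixels + noise
  pixels <- round(pmin(pmax(pixels, 0), 255)) / 255    # 8-bit quantisation

  img <- profile_image(pixels, res, aquarium_id = aquarium_id, day = day)
  attr(img, "footprint") <- footprint
  img
}

#' Write a profile image to an 8-bit RGB PNG
#'
#' @param image A [profile_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_png <- function(image, path) {
  stopifnot(inherits(image, "profile_image"))
  png::writePNG(image$pixels, target = path)
  invisible(path)
}

#' Read an 8-bit RGB PNG as a profile image
#'
#' @param path PNG file path.
#' @param resolution_mm_per_px Physical pixel size (mm).
#' @param aquarium_id,day Metadata to attach.
#' @return A [profile_image()].
#' @export
read_profile_png <- function(path, resolution_mm_per_px = 0.07,
                             aquarium_id = NA_character_,
                             day = NA_integer_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3]  # drop alpha
  if (length(dim(px)) != 3) {
    stop("`", path, "` is not an RGB PNG", call. = FALSE)
  }
  profile_image(px, resolution_mm_per_px, aquarium_id = aquarium_id,
                day = day)
}
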