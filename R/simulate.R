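#' Treatment-dependent generator calibration
#'
#' How the stocking ratio shapes the synthetic data. Each stocked aquarium
#' draws a mixing scale around `base_scale_mm + scale_per_rp_mm * n_rp`
#' (deeper average reworking with more Manila clams) with between-aquarium
#' SD `scale_sd_mm`, and an interface roughness target around
#' `sbr_base_mm + sbr_per_rp_mm * n_rp` with SD `sbr_sd_mm`. Burial is
#' truncated at 120 mm when the native clam is present and 80 mm when only
#' the invasive clam is (their species burial limits). Controls keep every
#' particle in the surface carpet (`surface_fraction = 1`) and an almost
#' flat interface.
#'
#' The default slopes are deliberately gentle: they are sized so that the
#' among-ratio signal stays at the weak, non-significant level the
#' experiment exhibits (expected one-way pseudo-F of roughly 1-2 with five
#' replicates), while the control contrast remains overwhelming. The
#' between-aquarium SDs match the observed replicate spread (about 1.5-4 mm
#' depending on the statistic).
#'
#' @param base_scale_mm,scale_per_rp_mm,scale_sd_mm Mixing-scale calibration
#'   (mm).
#' @param surface_fraction Carpet mass fraction in stocked aquaria.
#' @param n_particles Particles rendered per image face.
#' @param trunc_rd_mm,trunc_rp_mm Burial truncation depths (mm) with and
#'   without the native clam.
#' @param sbr_base_mm,sbr_per_rp_mm,sbr_sd_mm,sbr_max_mm SBR-target
#'   calibration (mm).
#' @param control_sbr_mm Interface roughness of unstocked controls (mm).
#' @param smoothness Interface smoothing window (px).
#' @return A list of class `treatment_effects`.
#' @export
treatment_effects <- function(base_scale_mm = 8.5,
                              scale_per_rp_mm = 0.18,
                              scale_sd_mm = 2.2,
                              surface_fraction = 0.1,
                              n_particles = 600,
                              trunc_rd_mm = 120,
                              trunc_rp_mm = 80,
                              sbr_base_mm = 7,
                              sbr_per_rp_mm = 0.25,
                              sbr_sd_mm = 4,
                              sbr_max_mm = 20,
                              control_sbr_mm = 1,
                              smoothness = 150) {
  structure(as.list(environment()), class = "treatment_effects")
}

# realised per-aquarium generator parameters; called inside the master-seed
# RNG scope so draws are reproducible
draw_aquarium_params <- function(trt, effects) {
  if (trt$is_control) {
    list(
      model = depth_model(surface_fraction = 1, mixing_scale_mm = 0,
                          truncation_depth_mm = effects$trunc_rd_mm,
                          n_particles = effects$n_particles),
      sbr_target_mm = effects$control_sbr_mm
    )
  } else {
    scale_mean <- effects$base_scale_mm + effects$scale_per_rp_mm * trt$n_rp
    scale_i <- max(0.5, stats::rnorm(1, scale_mean, effects$scale_sd_mm))
    sbr_mean <- effects$sbr_base_mm + effects$sbr_per_rp_mm * trt$n_rp
    sbr_i <- min(effects$sbr_max_mm,
                 max(1, stats::rnorm(1, sbr_mean, effects$sbr_sd_mm)))
    trunc <- if (trt$n_rd > 0) effects$trunc_rd_mm else effects$trunc_rp_mm
    list(
      model = depth_model(surface_fraction = effects$surface_fraction,
                          mixing_scale_mm = scale_i,
                          truncation_depth_mm = trunc,
                          n_particles = effects$n_particles),
      sbr_target_mm = sbr_i
    )
  }
}

#' Simulate a complete microcosm experiment
#'
#' Generates, for every aquarium of a design: a rough interface trace, a
#' particle population from the treatment's burial-depth model, the rendered
#' analysis-day profile image, the nutrient time series, and a ground-truth
#' record holding the mixing statistics computed directly from the sampled
#' depths (the recovery oracle for the image pipeline). All randomness is
#' governed by `seed`; identical seeds reproduce byte-identical images and
#' tables.
#'
#' @param design A [make_design()].
#' @param effects A [treatment_effects()] calibration.
#' @param render A [render_params()].
#' @param nutrients A [nutrient_model()].
#' @param seed Master integer seed.
#' @param quantify Also run the image-quantification pipeline on each image
#'   as it is produced (adds a `metrics` tibble to the result)?
#' @param keep_images Keep the rendered [profile_image()]s in the returned
#'   object? Set `FALSE` with `quantify = TRUE` to bound memory on large
#'   frames.
#' @param render_images Rasterise images at all? `FALSE` gives a fast
#'   truth-and-nutrients-only simulation (no images, no metrics).
#' @param out_dir Optional directory; when given, writes one
#'   `<aquarium_id>_d<day>.png` per aquarium plus `nutrients.csv`,
#'   `ground_truth.csv` and `design.csv`.
#'
#' @return A list of class `microcosm_simulation` with elements `design`,
#'   `images` (named list or `NULL`), `particles` (named list of sampled
#'   depth vectors), `truth`, `nutrients`, and `metrics` (when
#'   `quantify = TRUE`).
#' @export
simulate_experiment <- function(design,
                                effects = treatment_effects(),
                                render = render_params(),
                                nutrients = nutrient_model(),
                                seed = 1,
                                quantify = FALSE,
                                keep_images = TRUE,
                                render_images = TRUE,
                                out_dir = NULL) {
  if (!render_images) {
    quantify <- FALSE
    keep_images <- FALSE
  }
  stopifnot(inherits(design, "microcosm_design"),
            inherits(effects, "treatment_effects"),
            inherits(render, "render_params"))
  tab <- design_table(design)
  n_aq <- nrow(tab)
  day <- design$analysis_day

  seeds_and_params <- withr::with_seed(seed, {
    sub_seeds <- matrix(sample.int(.Machine$integer.max, n_aq * 4),
                        nrow = n_aq)
    params <- purrr::map(seq_len(n_aq),
                         function(i) draw_aquarium_params(tab[i, ], effects))
    list(seeds = sub_seeds, params = params)
  })
  sub_seeds <- seeds_and_params$seeds

  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  images <- if (keep_images) vector("list", n_aq) else NULL
  particles <- vector("list", n_aq)
  truth <- vector("list", n_aq)
  metrics <- if (quantify) vector("list", n_aq) else NULL
  nutrient_rows <- vector("list", n_aq)
  r_mm <- render$particle_radius_px * render$resolution_mm_per_px

  for (i in seq_len(n_aq)) {
    trt <- tab[i, ]
    ap <- seeds_and_params$params[[i]]

    depths <- sample_particle_depths(ap$model, seed = sub_seeds[i, 1])
    interface <- generate_interface_trace(
      width_px = render$image_width_px,
      sbr_target_mm = ap$sbr_target_mm,
      resolution_mm_per_px = render$resolution_mm_per_px,
      smoothness = effects$smoothness,
      base_row_px = render$base_row_px,
      seed = sub_seeds[i, 2]
    )
    r <- render$particle_radius_px
    cols <- withr::with_seed(
      sub_seeds[i, 3],
      sample(r:(render$image_width_px - 1 - r), length(depths),
             replace = TRUE)
    )
    img <- if (render_images) {
      render_profile_image(
        interface, tibble::tibble(column = cols, depth_mm = depths),
        render, seed = sub_seeds[i, 3], aquarium_id = trt$aquarium_id,
        day = day
      )
    }

    true_sbr <- (max(interface) - min(interface)) *
      render$resolution_mm_per_px
    truth[[i]] <- tibble::tibble(
      aquarium_id = trt$aquarium_id,
      treatment = trt$treatment,
      replicate = trt$replicate,
      mixing_scale_mm = ap$model$mixing_scale_mm,
      true_l_max_mm = max(depths),
      true_l_med_mm = stats::median(depths),
      true_l_mean_mm = mean(depths),
      true_sbr_mm = if (trt$is_control) NA_real_ else true_sbr
    )
    particles[[i]] <- depths

    nutrient_rows[[i]] <- simulate_nutrient_series(
      trt, nutrients, design$sampling_days, seed = sub_seeds[i, 4]) |>
      dplyr::mutate(aquarium_id = trt$aquarium_id,
                    treatment = trt$treatment,
                    replicate = trt$replicate, .before = 1)

    if (quantify) {
      mode <- if (trt$is_control) "control" else "treatment"
      q <- quantify_image(img, mode = mode)
      metrics[[i]] <- compute_metrics(q$profile, q$interface,
                                      is_control = trt$is_control) |>
        dplyr::mutate(aquarium_id = trt$aquarium_id,
                      treatment = trt$treatment,
                      n_rd = trt$n_rd, n_rp = trt$n_rp,
                      replicate = trt$replicate, day = day,
                      .before = 1)
    }
    if (!is.null(out_dir) && render_images) {
      write_profile_png(img, file.path(out_dir,
                                       sprintf("%s_d%d.png",
                                               trt$aquarium_id, day)))
    }
    if (keep_images) images[[i]] <- img
  }

  truth <- dplyr::bind_rows(truth)
  nutrients_tbl <- dplyr::bind_rows(nutrient_rows)
  if (keep_images) names(images) <- tab$aquarium_id
  names(particles) <- tab$aquarium_id

  if (!is.null(out_dir)) {
    utils::write.csv(nutrients_tbl, file.path(out_dir, "nutrients.csv"),
                     row.names = FALSE)
    utils::write.csv(
      dplyr::select(truth, "aquarium_id", dplyr::starts_with("true_")),
      file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
    utils::write.csv(design_table(design),
                     file.path(out_dir, "design.csv"), row.names = FALSE)
  }

  structure(
    list(design = design, images = images, particles = particles,
         truth = truth, nutrients = nutrients_tbl,
         metrics = if (quantify) dplyr::bind_rows(metrics) else NULL,
         particle_radius_mm = r_mm, seed = seed),
    class = "microcosm_simulation"
  )
}

#' @export
print.microcosm_simulation <- function(x, ...) {
  cat(sprintf("<microcosm_simulation> %d aquaria, seed %d\n",
              nrow(x$truth), x$seed))
  invisible(x)
}
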