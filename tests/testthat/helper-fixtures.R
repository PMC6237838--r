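# Shared miniature fixtures: a 12 x 40 mm frame at 0.1 mm/px keeps renders
# ~50x smaller than the default geometry while exercising the same code.

small_render <- function(...) {
  args <- utils::modifyList(
    list(image_width_px = 120L, image_height_px = 400L,
         resolution_mm_per_px = 0.1, sediment_column_mm = 25,
         particle_radius_px = 2L, base_row_px = 60L, noise_sd = 4),
    list(...))
  do.call(render_params, args)
}

small_effects <- function(...) {
  args <- utils::modifyList(
    list(base_scale_mm = 3, scale_per_rp_mm = 0.2, scale_sd_mm = 1,
         surface_fraction = 0.1, n_particles = 150L,
         trunc_rd_mm = 20, trunc_rp_mm = 15,
         sbr_base_mm = 3, sbr_per_rp_mm = 0.2, sbr_sd_mm = 1,
         sbr_max_mm = 6, control_sbr_mm = 0.5, smoothness = 60),
    list(...))
  do.call(treatment_effects, args)
}

small_design <- function(n_replicates = 2) {
  make_design(ratios = tibble::tibble(n_rd = c(2L, 0L), n_rp = c(0L, 2L)),
              n_replicates = n_replicates,
              sampling_days = c(0L, 5L, 21L), analysis_day = 21L)
}

# a rendered fixture with a flat interface and known particle placement
flat_fixture <- function(depths_mm, columns = NULL, noise_sd = 0,
                         base_row_px = 60L, seed = 7) {
  rp <- small_render(noise_sd = noise_sd, base_row_px = base_row_px)
  interface <- generate_interface_trace(
    rp$image_width_px, sbr_target_mm = 0,
    resolution_mm_per_px = rp$resolution_mm_per_px,
    base_row_px = base_row_px, seed = seed)
  if (is.null(columns)) {
    columns <- seq(10, rp$image_width_px - 10,
                   length.out = max(1, length(depths_mm)))
  }
  particles <- tibble::tibble(column = round(columns), depth_mm = depths_mm)
  img <- render_profile_image(interface, particles, rp, seed = seed,
                              aquarium_id = "FIX", day = 21L)
  list(img = img, interface = interface, particles = particles, render = rp)
}

noiseless_model <- function() {
  nutrient_model(nh4 = list(noise_sd = 0), nox = list(noise_sd = 0),
                 po4 = list(noise_sd = 0))
}
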