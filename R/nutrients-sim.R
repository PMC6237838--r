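#' Nutrient trend model for synthetic microcosms
#'
#' Default endpoints of the per-aquarium nutrient trends, anchored to the
#' concentrations a 21-day clam microcosm typically shows: ammonium
#' (NH4-N) and phosphate (PO4-P) build up in stocked aquaria because the
#' water is never renewed and clams excrete and biodeposit, while oxidised
#' nitrogen (NOx-N) accumulates only in unstocked controls where the
#' undisturbed surface favours nitrification. Concentrations evolve
#' linearly between the day-0 and day-21 endpoints, with additive Gaussian
#' noise truncated at zero.
#'
#' Control endpoints: NH4-N 1.0 to 3.56, NOx-N 0.17 to 1.42, PO4-P 0.10 to
#' 0.32 mg/L. Treatment endpoints: NH4-N rises to 9.24-11.18 mg/L
#' (increasing with the number of native clams), NOx-N stays low
#' (endpoint 0.40 mg/L), PO4-P rises to 0.42-0.72 mg/L with ratio-specific
#' day-0 values of 0.12-0.19 mg/L.
#'
#' @param nh4,nox,po4 Lists overriding individual per-nutrient parameters;
#'   see the function body for names. All concentrations in mg/L.
#' @return A list of class `nutrient_model`.
#' @export
nutrient_model <- function(nh4 = list(), nox = list(), po4 = list()) {
  nh4 <- utils::modifyList(list(
    initial = 1.0, final_control = 3.56,
    final_mono_rd = 11.18, final_mono_rp = 9.24, noise_sd = 1.8), nh4)
  nox <- utils::modifyList(list(
    initial = 0.17, final_control = 1.42,
    final_treatment = 0.40, noise_sd = 0.12), nox)
  po4 <- utils::modifyList(list(
    initial_control = 0.10, final_control = 0.32,
    n_rd_grid = c(0, 2, 4, 6, 8),
    initial_by_n_rd = c(0.12, 0.12, 0.13, 0.19, 0.16),
    final_by_n_rd = c(0.49, 0.42, 0.49, 0.55, 0.72),
    noise_sd = 0.25), po4)
  vals <- c(unlist(nh4), unlist(nox),
            unlist(po4[setdiff(names(po4), "n_rd_grid")]))
  if (any(vals < 0)) {
    stop("nutrient model parameters must be non-negative", call. = FALSE)
  }
  structure(list(nh4 = nh4, nox = nox, po4 = po4), class = "nutrient_model")
}

# day-0 / final-day endpoints for one treatment, as a 3-row tibble
nutrient_endpoints <- function(model, n_rd, n_rp, is_control) {
  stopifnot(inherits(model, "nutrient_model"))
  if (is_control) {
    tibble::tibble(
      nutrient = c("nh4_n_mg_l", "nox_n_mg_l", "po4_p_mg_l"),
      initial = c(model$nh4$initial, model$nox$initial,
                  model$po4$initial_control),
      final = c(model$nh4$final_control, model$nox$final_control,
                model$po4$final_control),
      noise_sd = c(model$nh4$noise_sd, model$nox$noise_sd,
                   model$po4$noise_sd)
    )
  } else {
    frac_rd <- n_rd / max(1, n_rd + n_rp)
    nh4_final <- model$nh4$final_mono_rp +
      (model$nh4$final_mono_rd - model$nh4$final_mono_rp) * frac_rd
    po4_initial <- stats::approx(model$po4$n_rd_grid,
                                 model$po4$initial_by_n_rd,
                                 xout = n_rd, rule = 2)$y
    po4_final <- stats::approx(model$po4$n_rd_grid,
                               model$po4$final_by_n_rd,
                               xout = n_rd, rule = 2)$y
    tibble::tibble(
      nutrient = c("nh4_n_mg_l", "nox_n_mg_l", "po4_p_mg_l"),
      initial = c(model$nh4$initial, model$nox$initial, po4_initial),
      final = c(nh4_final, model$nox$final_treatment, po4_final),
      noise_sd = c(model$nh4$noise_sd, model$nox$noise_sd,
                   model$po4$noise_sd)
    )
  }
}

#' Simulate one aquarium's nutrient time series
#'
#' Concentrations follow the linear trend between the treatment's day-0 and
#' final-day endpoints defined by a [nutrient_model()], plus Gaussian noise
#' clipped at zero. With `noise_sd = 0` the series is exactly linear.
#'
#' @param treatment A list or one-row data frame with `n_rd`, `n_rp` and
#'   `is_control` (e.g. one row of `design$treatments`).
#' @param model A [nutrient_model()].
#' @param sampling_days Integer days, starting at 0, strictly increasing.
#' @param seed Integer seed.
#' @return A tibble with columns `day`, `nh4_n_mg_l`, `nox_n_mg_l`,
#'   `po4_p_mg_l`.
#' @examples
#' ctrl <- list(n_rd = 0, n_rp = 0, is_control = TRUE)
#' s <- simulate_nutrient_series(ctrl, nutrient_model(nh4 = list(noise_sd = 0),
#'   nox = list(noise_sd = 0), po4 = list(noise_sd = 0)), c(0, 21), seed = 1)
#' s$po4_p_mg_l # 0.10 at day 0, 0.32 at day 21
#' @export
simulate_nutrient_series <- function(treatment, model = nutrient_model(),
                                     sampling_days = c(0, 2, 5, 8, 12, 16, 21),
                                     seed = 1) {
  if (length(sampling_days) == 0 || sampling_days[1] != 0 ||
      any(diff(sampling_days) <= 0)) {
    stop("`sampling_days` must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  ep <- nutrient_endpoints(model, treatment$n_rd, treatment$n_rp,
                           treatment$is_control)
  final_day <- max(sampling_days)
  frac <- if (final_day == 0) rep(0, length(sampling_days)) else
    sampling_days / final_day

  withr::with_seed(seed, {
    cols <- purrr::map(seq_len(nrow(ep)), function(i) {
      trend <- ep$initial[i] + (ep$final[i] - ep$initial[i]) * frac
      noise <- if (ep$noise_sd[i] > 0) {
        stats::rnorm(length(trend), sd = ep$noise_sd[i])
      } else 0
      pmax(0, trend + noise)
    })
    names(cols) <- ep$nutrient
    tibble::tibble(day = as.integer(sampling_days), !!!cols)
  })
}
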