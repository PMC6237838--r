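#' Default clam stocking ratios
#'
#' The five native:invasive stocking ratios used throughout the package,
#' from the monospecific native treatment (8 Rd + 0 Rp) to the monospecific
#' invasive treatment (0 Rd + 8 Rp). Rd is the native grooved carpet-shell
#' clam *Ruditapes decussatus*; Rp the invasive Manila clam
#' *R. philippinarum*.
#'
#' @return A tibble with columns `n_rd` and `n_rp`.
#' @export
default_ratios <- function() {
  tibble::tibble(
    n_rd = c(8L, 6L, 4L, 2L, 0L),
    n_rp = c(0L, 2L, 4L, 6L, 8L)
  )
}

treatment_label <- function(n_rd, n_rp) sprintf("%dRd+%dRp", n_rd, n_rp)

#' Build a microcosm experiment design
#'
#' Lays out a one-factor microcosm experiment: a set of clam stocking-ratio
#' treatments, an optional unstocked control group, a fixed number of
#' replicate aquaria per group, the water-sampling days and the image
#' analysis day. Defaults reproduce the standard design: five ratios plus a
#' control, five replicates each (30 aquaria), nutrient sampling at days
#' 0, 2, 5, 8, 12, 16 and 21, images analysed at day 21.
#'
#' @param ratios Data frame with columns `n_rd`, `n_rp` (clams per aquarium),
#'   one row per treatment. Must be non-empty with unique labels.
#' @param n_replicates Replicate aquaria per group (>= 1).
#' @param sampling_days Strictly increasing integer days starting at 0.
#' @param analysis_day Day whose images are quantified; must be one of
#'   `sampling_days` (or the final day).
#' @param include_control Add an unstocked (0 Rd + 0 Rp) control group?
#'
#' @return An object of class `microcosm_design`: a list with `treatments`
#'   (tibble: `label`, `n_rd`, `n_rp`, `is_control`), `aquaria` (tibble:
#'   `aquarium_id`, `treatment`, `replicate`), `n_replicates`,
#'   `sampling_days`, `analysis_day`.
#' @examples
#' d <- make_design()
#' nrow(d$aquaria) # 30
#' @export
make_design <- function(ratios = default_ratios(),
                        n_replicates = 5,
                        sampling_days = c(0, 2, 5, 8, 12, 16, 21),
                        analysis_day = 21,
                        include_control = TRUE) {
  ratios <- tibble::as_tibble(ratios)
  if (nrow(ratios) == 0) {
    stop("`ratios` must contain at least one treatment", call. = FALSE)
  }
  if (!all(c("n_rd", "n_rp") %in% names(ratios))) {
    stop("`ratios` needs columns `n_rd` and `n_rp`", call. = FALSE)
  }
  if (any(ratios$n_rd < 0 | ratios$n_rp < 0)) {
    stop("clam counts must be non-negative", call. = FALSE)
  }
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  if (length(sampling_days) == 0 || sampling_days[1] != 0 ||
      any(diff(sampling_days) <= 0)) {
    stop("`sampling_days` must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  if (!analysis_day %in% sampling_days) {
    stop("`analysis_day` must be one of `sampling_days`", call. = FALSE)
  }

  treatments <- ratios |>
    dplyr::mutate(
      label = treatment_label(.data$n_rd, .data$n_rp),
      is_control = FALSE
    )
  if (include_control) {
    treatments <- dplyr::bind_rows(
      treatments,
      tibble::tibble(n_rd = 0L, n_rp = 0L, label = "control",
                     is_control = TRUE)
    )
  }
  if (anyDuplicated(treatments$label)) {
    stop("duplicate treatment labels in design", call. = FALSE)
  }
  treatments <- dplyr::select(treatments, "label", "n_rd", "n_rp",
                              "is_control")

  aquaria <- tidyr::expand_grid(
    treatment = treatments$label,
    replicate = seq_len(n_replicates)
  ) |>
    dplyr::mutate(
      aquarium_id = sprintf("A%02d", dplyr::row_number()),
      .before = 1
    )

  structure(
    list(
      treatments = treatments,
      aquaria = aquaria,
      n_replicates = as.integer(n_replicates),
      sampling_days = as.integer(sampling_days),
      analysis_day = as.integer(analysis_day)
    ),
    class = "microcosm_design"
  )
}

#' @export
print.microcosm_design <- function(x, ...) {
  cat("<microcosm_design>\n")
  cat(sprintf("  %d groups x %d replicates = %d aquaria\n",
              nrow(x$treatments), x$n_replicates, nrow(x$aquaria)))
  cat("  groups:", paste(x$treatments$label, collapse = ", "), "\n")
  cat("  sampling days:", paste(x$sampling_days, collapse = ", "),
      "| analysis day:", x$analysis_day, "\n")
  invisible(x)
}

# aquaria joined with their treatment description
design_table <- function(design) {
  dplyr::left_join(design$aquaria, design$treatments,
                   by = c(treatment = "label"))
}
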