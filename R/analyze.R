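NUTRIENT_COLS <- c("nh4_n_mg_l", "nox_n_mg_l", "po4_p_mg_l")
METRIC_COLS <- c("l_max_mm", "l_med_mm", "l_mean_mm", "sbr_mm")

#' Load and validate a nutrient table
#'
#' Reads the per-aquarium nutrient CSV (schema
#' `aquarium_id,treatment,replicate,day,nh4_n_mg_l,nox_n_mg_l,po4_p_mg_l`)
#' and checks it against the design: every aquarium must be known, every
#' sampling day present for every aquarium, and all concentrations
#' non-negative.
#'
#' @param path CSV file path, or a data frame already in the schema.
#' @param design A [make_design()].
#' @return A validated tibble.
#' @export
load_nutrients <- function(path, design) {
  stopifnot(inherits(design, "microcosm_design"))
  tbl <- if (is.data.frame(path)) tibble::as_tibble(path) else
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("aquarium_id", "treatment", "replicate", "day", NUTRIENT_COLS)
  miss <- setdiff(needed, names(tbl))
  if (length(miss)) {
    stop("nutrient table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(tbl$aquarium_id, design$aquaria$aquarium_id)
  if (length(unknown)) {
    stop("unknown aquarium id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(as.matrix(tbl[NUTRIENT_COLS]) < 0, na.rm = TRUE) ||
      anyNA(tbl[NUTRIENT_COLS])) {
    stop("nutrient concentrations must be present and non-negative",
         call. = FALSE)
  }
  have <- dplyr::count(tbl, .data$aquarium_id)
  expected_days <- design$sampling_days
  for (id in design$aquaria$aquarium_id) {
    days <- sort(tbl$day[tbl$aquarium_id == id])
    missing_days <- setdiff(expected_days, days)
    if (length(missing_days)) {
      stop(sprintf("aquarium %s is missing day(s) %s", id,
                   paste(missing_days, collapse = ", ")), call. = FALSE)
    }
  }
  tbl
}

assert_no_control <- function(data, control_label) {
  if (any(data$treatment == control_label)) {
    stop("ratios matrix must exclude the control group", call. = FALSE)
  }
  invisible(data)
}

#' Among-ratios main test for one response
#'
#' One-way PERMANOVA over the stocking-ratio groups only; the control group
#' must already be excluded (its inclusion is a precondition violation, not
#' a silent filter).
#'
#' @param data Data frame of bivalve-aquarium rows.
#' @param response Response column name.
#' @param control_label Label that identifies control rows (rejected).
#' @inheritParams permanova_oneway
#' @return A `permanova_fit`.
#' @export
run_ratios_main_test <- function(data, response, control_label = "control",
                                 n_permutations = 9999, seed) {
  assert_no_control(data, control_label)
  permanova_test(data, response, "treatment",
                 n_permutations = n_permutations, seed = seed)
}

# one main test + one contrast per ratio, as tidy rows
test_battery <- function(data, response, control_label, contrasts,
                         n_permutations, seed, sbr_style = FALSE) {
  with_context <- function(expr, what) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("%s [%s]: %s", what, response, conditionMessage(e)),
           call. = FALSE)
    })
  }
  ratio_data <- dplyr::filter(data, .data$treatment != control_label)
  main <- with_context(
    run_ratios_main_test(ratio_data, response, control_label,
                         n_permutations = n_permutations, seed = seed),
    "ratios main test")
  rows <- list(tibble::tibble(
    response = response, test = "ratios", statistic_type = "pseudo_f",
    statistic = main$pseudo_f, df1 = main$df_among, df2 = main$df_within,
    p_perm = main$p_perm, n_permutations = main$n_permutations,
    method = main$method
  ))
  if (!sbr_style) {
    for (k in seq_along(contrasts)) {
      lab <- contrasts[k]
      ct <- with_context(
        permanova_test(
          dplyr::filter(data, .data$treatment %in% c(control_label, lab)),
          response, "treatment", pair = c(control_label, lab),
          n_permutations = n_permutations, seed = seed + k),
        paste("contrast control vs", lab))
      rows <- c(rows, list(tibble::tibble(
        response = response, test = paste("control vs", lab),
        statistic_type = "t", statistic = ct$t_statistic,
        df1 = 1L, df2 = ct$df_within, p_perm = ct$p_perm,
        n_permutations = ct$n_permutations, method = ct$method
      )))
    }
  }
  dplyr::bind_rows(rows)
}

#' Bioturbation test battery
#'
#' The full inferential layout for the mixing statistics at the analysis
#' day: for each of the maximum, median and mean mixed depth, one
#' among-ratios main test (control excluded) plus one control-vs-ratio
#' contrast per stocking ratio; for SBR the main test only, since SBR is
#' undefined for controls.
#'
#' @param metrics Per-aquarium metrics table (see [quantify_experiment()]).
#' @param control_label Treatment label of the control group.
#' @inheritParams permanova_oneway
#' @return A tidy tibble, one row per test, with a `significant` flag at
#'   p < 0.05.
#' @export
run_bioturbation_tests <- function(metrics, control_label = "control",
                                   n_permutations = 9999, seed) {
  miss <- setdiff(c("treatment", METRIC_COLS), names(metrics))
  if (length(miss)) {
    stop("metrics table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ratios <- setdiff(unique(metrics$treatment), control_label)
  out <- list()
  for (i in seq_along(c("l_max_mm", "l_med_mm", "l_mean_mm"))) {
    resp <- c("l_max_mm", "l_med_mm", "l_mean_mm")[i]
    out[[resp]] <- test_battery(metrics, resp, control_label, ratios,
                                n_permutations,
                                seed = seed + 100 * (i - 1))
  }
  sbr_data <- dplyr::filter(metrics, .data$treatment != control_label)
  out$sbr <- test_battery(sbr_data, "sbr_mm", control_label, ratios,
                          n_permutations, seed = seed + 300,
                          sbr_style = TRUE)
  dplyr::bind_rows(out) |>
    dplyr::mutate(significant = .data$p_perm < 0.05)
}

#' Nutrient test battery at the analysis day
#'
#' For each nutrient (NH4-N, NOx-N, PO4-P) at the analysis day: one
#' among-ratios main test plus one control-vs-ratio contrast per stocking
#' ratio, on log(X + 1)-transformed concentrations.
#'
#' @param nutrients Validated nutrient table (see [load_nutrients()]).
#' @param analysis_day Day to test (must be present for every aquarium).
#' @inheritParams run_bioturbation_tests
#' @return A tidy tibble, one row per test.
#' @export
run_nutrient_tests <- function(nutrients, analysis_day = 21,
                               control_label = "control",
                               n_permutations = 9999, seed) {
  day_tbl <- dplyr::filter(nutrients, .data$day == analysis_day)
  all_ids <- unique(nutrients$aquarium_id)
  if (!setequal(day_tbl$aquarium_id, all_ids) || nrow(day_tbl) == 0) {
    stop("analysis day ", analysis_day,
         " missing for some aquaria", call. = FALSE)
  }
  ratios <- setdiff(unique(day_tbl$treatment), control_label)
  out <- list()
  for (i in seq_along(NUTRIENT_COLS)) {
    resp <- NUTRIENT_COLS[i]
    out[[resp]] <- test_battery(day_tbl, resp, control_label, ratios,
                                n_permutations,
                                seed = seed + 100 * (i - 1))
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(significant = .data$p_perm < 0.05)
}

#' Nutrient principal component ordination
#'
#' Ordination of the water-nutrient trajectories: input points are the
#' per-treatment per-day mean concentration vectors (NH4-N, NOx-N, PO4-P),
#' normalised PCA by default. With the standard design this is 6 groups x
#' 7 days = 42 points in 3 variables.
#'
#' @param nutrients Validated nutrient table.
#' @param normalize Correlation-form PCA? (Default `TRUE`.)
#' @param by `"treatment_day_mean"` (default) averages replicates;
#'   `"aquarium_day"` ordinates every aquarium-day sample.
#' @return A [pca_ordination()] whose scores carry `treatment` and `day`.
#' @export
run_nutrient_pca <- function(nutrients, normalize = TRUE,
                             by = c("treatment_day_mean", "aquarium_day")) {
  by <- match.arg(by)
  if (by == "treatment_day_mean") {
    pts <- nutrients |>
      dplyr::group_by(.data$treatment, .data$day) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(NUTRIENT_COLS), mean),
                       .groups = "drop")
  } else {
    pts <- dplyr::select(nutrients, "treatment", "day",
                         dplyr::all_of(NUTRIENT_COLS))
  }
  if (dplyr::n_distinct(pts$treatment) < 2 ||
      dplyr::n_distinct(pts$day) < 2) {
    stop("PCA needs at least 2 treatments and 2 days", call. = FALSE)
  }
  m <- as.matrix(pts[NUTRIENT_COLS])
  rownames(m) <- paste0(pts$treatment, "_d", pts$day)
  fit <- pca_ordination(m, normalize = normalize)
  fit$scores <- dplyr::mutate(fit$scores, treatment = pts$treatment,
                              day = pts$day, .before = 1)
  fit
}

#' Run the complete experiment analysis
#'
#' Assembles the full report: the bioturbation test battery on the metrics
#' table, the nutrient test battery at the analysis day, and the nutrient
#' PCA, with provenance (seed, permutation count, configuration hash).
#'
#' @param metrics Per-aquarium metrics table.
#' @param nutrients Validated nutrient table.
#' @param analysis_day Day for the nutrient tests.
#' @param control_label Treatment label of the control group.
#' @inheritParams permanova_oneway
#' @return An object of class `bioturb_report`.
#' @export
analyze_experiment <- function(metrics, nutrients, analysis_day = 21,
                               control_label = "control",
                               n_permutations = 9999, seed = 1) {
  biot <- run_bioturbation_tests(metrics, control_label,
                                 n_permutations, seed = seed)
  nut <- run_nutrient_tests(nutrients, analysis_day, control_label,
                            n_permutations, seed = seed + 1000)
  pca <- run_nutrient_pca(nutrients)
  provenance <- list(
    seed = seed, n_permutations = n_permutations,
    analysis_day = analysis_day, control_label = control_label,
    config_hash = rlang::hash(list(metrics, nutrients, analysis_day,
                                   n_permutations, seed)),
    package_version = as.character(utils::packageVersion("bioturbr")),
    timestamp = NA_character_  # kept NA so reruns are byte-identical
  )
  structure(
    list(metrics = tibble::as_tibble(metrics),
         nutrients = tibble::as_tibble(nutrients),
         bioturbation_tests = biot, nutrient_tests = nut,
         pca = pca, provenance = provenance),
    class = "bioturb_report"
  )
}

#' @export
print.bioturb_report <- function(x, ...) {
  cat("<bioturb_report>\n")
  cat(sprintf("  %d bioturbation tests, %d nutrient tests, PCA on %d points\n",
              nrow(x$bioturbation_tests), nrow(x$nutrient_tests),
              nrow(x$pca$scores)))
  sig <- dplyr::bind_rows(x$bioturbation_tests, x$nutrient_tests)
  cat(sprintf("  significant at p < 0.05: %d of %d\n",
              sum(sig$significant), nrow(sig)))
  invisible(x)
}

#' Write the analysis report to disk
#'
#' Emits `metrics.csv`, `tests.csv` (bioturbation and nutrient batteries,
#' with a `family` column), `pca_scores.csv`, `pca_loadings.csv` and
#' `report.json` (tests, variance fractions and provenance). Reruns with
#' the same inputs and seed produce byte-identical files.
#'
#' @param report A `bioturb_report`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "bioturb_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  tests <- dplyr::bind_rows(
    dplyr::mutate(report$bioturbation_tests, family = "bioturbation",
                  .before = 1),
    dplyr::mutate(report$nutrient_tests, family = "nutrients", .before = 1)
  )
  paths <- c(
    metrics = file.path(out_dir, "metrics.csv"),
    tests = file.path(out_dir, "tests.csv"),
    pca_scores = file.path(out_dir, "pca_scores.csv"),
    pca_loadings = file.path(out_dir, "pca_loadings.csv"),
    report = file.path(out_dir, "report.json")
  )
  utils::write.csv(report$metrics, paths["metrics"], row.names = FALSE)
  utils::write.csv(tests, paths["tests"], row.names = FALSE)
  has_pca <- !is.null(report$pca)
  if (has_pca) {
    utils::write.csv(report$pca$scores, paths["pca_scores"],
                     row.names = FALSE)
    utils::write.csv(report$pca$loadings, paths["pca_loadings"],
                     row.names = FALSE)
  }
  json <- list(
    provenance = report$provenance,
    tests = tests,
    pca = if (has_pca) {
      list(present = TRUE,
           variance_fraction = report$pca$variance_fraction)
    } else {
      list(present = FALSE)
    }
  )
  jsonlite::write_json(json, paths["report"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
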