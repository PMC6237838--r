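#' Principal component ordination
#'
#' Eigen-decomposition of the covariance (or, when `normalize = TRUE`, the
#' correlation) matrix of centred data, via [stats::prcomp()]. The
#' normalised form is the default because the nutrient variables share
#' units but span very different scales.
#'
#' @param x Numeric matrix or data frame (samples x variables, >= 2 of
#'   each). Row names, if present, label the scores.
#' @param normalize Scale each variable to unit variance? A constant
#'   column is an error under normalisation.
#' @return An object of class `pca_ordination`: list with `scores`
#'   (tibble, one row per sample), `loadings` (tibble, one row per
#'   variable), `variance_fraction` (numeric, non-increasing, sums to 1)
#'   and the underlying `prcomp` fit.
#' @export
pca_ordination <- function(x, normalize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("PCA needs at least 2 samples and 2 variables", call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (normalize && any(sds == 0)) {
    stop("constant column(s) cannot be normalised: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = normalize)
  var_frac <- fit$sdev^2 / sum(fit$sdev^2)
  axes <- paste0("PC", seq_along(var_frac))

  scores <- tibble::as_tibble(fit$x, .name_repair = "minimal")
  names(scores) <- axes
  scores <- dplyr::mutate(
    scores,
    sample = rownames(x) %||% as.character(seq_len(nrow(x))),
    .before = 1)

  loadings <- tibble::as_tibble(fit$rotation, .name_repair = "minimal")
  names(loadings) <- axes
  loadings <- dplyr::mutate(
    loadings,
    variable = colnames(x) %||% paste0("V", seq_len(ncol(x))),
    .before = 1)

  structure(
    list(scores = scores, loadings = loadings,
         variance_fraction = var_frac, normalize = normalize,
         prcomp = fit),
    class = "pca_ordination"
  )
}

#' @export
print.pca_ordination <- function(x, ...) {
  cat("<pca_ordination>\n")
  cat(sprintf("  %d samples, %d axes (%s)\n", nrow(x$scores),
              length(x$variance_fraction),
              if (x$normalize) "correlation" else "covariance"))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' @method tidy pca_ordination
#' @export
tidy.pca_ordination <- function(x,
                                matrix = c("scores", "loadings",
                                           "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    scores = x$scores,
    loadings = x$loadings,
    eigenvalues = tibble::tibble(
      axis = paste0("PC", seq_along(x$variance_fraction)),
      variance_fraction = x$variance_fraction,
      cumulative = cumsum(x$variance_fraction)
    ))
}

#' @method glance pca_ordination
#' @export
glance.pca_ordination <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_axes = length(x$variance_fraction),
    axis1_variance_fraction = x$variance_fraction[1],
    normalized = x$normalize
  )
}
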