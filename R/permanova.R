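#' Log(X + 1) transform
#'
#' Elementwise natural log of `X + 1`, the variance-stabilising transform
#' applied before building Euclidean resemblance matrices. Negative entries
#' are rejected.
#'
#' @param x Numeric vector, matrix or data frame of non-negative values.
#' @return The transformed object, same shape and type as the input.
#' @export
log1p_transform <- function(x) {
  vals <- if (is.data.frame(x)) unlist(x) else x
  if (!is.numeric(vals)) stop("`x` must be numeric", call. = FALSE)
  if (any(vals < 0, na.rm = TRUE)) {
    stop("log(X + 1) requires non-negative entries", call. = FALSE)
  }
  if (is.data.frame(x)) {
    dplyr::mutate(x, dplyr::across(dplyr::everything(), log1p))
  } else {
    log1p(x)
  }
}

#' Euclidean distance matrix
#'
#' Pairwise Euclidean distances between sample rows, returned as a full
#' symmetric matrix (zero diagonal).
#'
#' @param x Numeric matrix or data frame, samples in rows.
#' @return An `N x N` symmetric numeric matrix.
#' @export
euclidean_distances <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  as.matrix(stats::dist(x, method = "euclidean"))
}

as_d2 <- function(d) {
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  if (nrow(m) != ncol(m)) stop("`d` must be a square distance matrix",
                               call. = FALSE)
  m^2
}

# sums of squares of a one-way partition of a squared-distance matrix
ss_partition <- function(d2, idx_list) {
  n <- nrow(d2)
  ss_total <- sum(d2) / (2 * n)
  ss_within <- sum(vapply(idx_list, function(ix)
    sum(d2[ix, ix]) / (2 * length(ix)), numeric(1)))
  c(total = ss_total, within = ss_within, among = ss_total - ss_within)
}

pseudo_f_stat <- function(ss, a, n) {
  f <- (ss["among"] / (a - 1)) / (ss["within"] / (n - a))
  if (ss["within"] == 0) f <- if (ss["among"] > 0) Inf else NaN
  unname(f)
}

# all distinct assignments of n items to labelled groups of given sizes,
# as a list of index-list partitions (enumeration oracle for small designs)
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(remaining, sizes_left) {
    if (length(sizes_left) == 1) return(list(list(remaining)))
    k <- sizes_left[1]
    picks <- utils::combn(remaining, k, simplify = FALSE)
    out <- list()
    for (p in picks) {
      rest <- rec(setdiff(remaining, p), sizes_left[-1])
      out <- c(out, lapply(rest, function(r) c(list(p), r)))
    }
    out
  }
  rec(seq_len(n), sizes)
}

#' Count label permutations of a grouping
#'
#' For group sizes `n_1, ..., n_a` (N samples in total) there are `N!`
#' orderings of the sample labels and `N! / prod(n_g!)` distinct
#' assignments of samples to the labelled groups; the test statistic only
#' depends on the assignment, so exhaustive enumeration works over the
#' latter.
#'
#' @param sizes Integer vector of group sizes (>= 1 each, >= 2 groups).
#' @return A one-row tibble with `n_label_permutations` and
#'   `n_distinct_assignments`.
#' @export
exact_permutation_count <- function(sizes) {
  if (length(sizes) == 0) stop("`sizes` must be non-empty", call. = FALSE)
  if (length(sizes) < 2) {
    stop("a single group cannot be permutation-tested", call. = FALSE)
  }
  if (any(sizes < 1)) stop("group sizes must be >= 1", call. = FALSE)
  n <- sum(sizes)
  tibble::tibble(
    n_label_permutations = factorial(n),
    n_distinct_assignments = round(exp(lfactorial(n) -
                                         sum(lfactorial(sizes))))
  )
}

#' One-way PERMANOVA
#'
#' Partitions the squared inter-sample distances of a one-factor design
#' into among- and within-group sums of squares and tests the pseudo-F
#' statistic against a group-label permutation null. For a Euclidean
#' distance matrix on univariate data the pseudo-F equals the classical
#' one-way ANOVA F.
#'
#' The p-value uses random label permutations with the
#' `(1 + #(F_perm >= F_obs)) / (1 + n_permutations)` estimator; when the
#' number of distinct label assignments is at most `n_permutations` the
#' test switches to exhaustive enumeration and reports the exact
#' `#(F_perm >= F_obs) / #assignments` (the observed assignment counted
#' once, no +1 correction). Ties count as exceeding.
#'
#' @param d Distance matrix (square symmetric matrix or `dist`).
#' @param groups Group label per sample (factor or vector), >= 2 groups.
#' @param n_permutations Number of random permutations (default 9999).
#' @param seed Integer seed for the permutation draw (required: permutation
#'   p-values must be reproducible).
#' @return An object of class `permanova_fit` with fields `pseudo_f`,
#'   `ss_total`, `ss_among`, `ss_within`, `df_among`, `df_within`,
#'   `p_perm`, `n_permutations`, `method` (`"exhaustive"` or
#'   `"monte-carlo"`), `seed`.
#' @examples
#' d <- euclidean_distances(matrix(c(0, 1, 2, 3)))
#' fit <- permanova_oneway(d, c("a", "a", "b", "b"), seed = 1)
#' fit$pseudo_f # 8
#' fit$p_perm   # 1/3 (exhaustive over the 6 assignments)
#' @export
permanova_oneway <- function(d, groups, n_permutations = 9999, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  d2 <- as_d2(d)
  n <- nrow(d2)
  groups <- as.factor(groups)
  if (length(groups) != n) {
    stop("`groups` length must match the distance matrix", call. = FALSE)
  }
  a <- nlevels(droplevels(groups))
  groups <- droplevels(groups)
  if (a < 2) stop("need at least 2 groups", call. = FALSE)
  if (n - a < 1) stop("no residual degrees of freedom", call. = FALSE)

  idx <- split(seq_len(n), groups)
  sizes <- lengths(idx)
  ss <- ss_partition(d2, idx)
  if (ss["total"] <= 0) {
    stop("all pairwise distances are zero: pseudo-F undefined",
         call. = FALSE)
  }
  f_obs <- pseudo_f_stat(ss, a, n)

  n_distinct <- exact_permutation_count(sizes)$n_distinct_assignments
  if (n_distinct <= n_permutations) {
    assignments <- enumerate_assignments(unname(sizes))
    f_perm <- vapply(assignments, function(part)
      pseudo_f_stat(ss_partition(d2, part), a, n), numeric(1))
    p <- sum(f_perm >= f_obs) / length(f_perm)
    method <- "exhaustive"
    n_used <- length(f_perm)
  } else {
    f_perm <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        pi <- sample.int(n)
        pseudo_f_stat(ss_partition(d2, lapply(idx, function(ix) pi[ix])),
                      a, n)
      }, numeric(1))
    })
    p <- (1 + sum(f_perm >= f_obs)) / (1 + n_permutations)
    method <- "monte-carlo"
    n_used <- n_permutations
  }

  structure(
    list(pseudo_f = f_obs,
         ss_total = unname(ss["total"]),
         ss_among = unname(ss["among"]),
         ss_within = unname(ss["within"]),
         df_among = a - 1L, df_within = n - a,
         p_perm = p, n_permutations = n_used, method = method,
         seed = seed, n = n, group_sizes = sizes),
    class = "permanova_fit"
  )
}

#' Pairwise PERMANOVA contrast
#'
#' Restricts the distance matrix to two groups, runs the two-group test and
#' reports the permutation t statistic (the non-negative square root of the
#' two-group pseudo-F) with its permutation p-value.
#'
#' @inheritParams permanova_oneway
#' @param pair Character vector of the two group labels to contrast.
#' @return An object of class `permanova_pairwise` with fields `pair`,
#'   `t_statistic`, `p_perm`, `n_permutations`, `method`, `df_within`.
#' @export
permanova_pairwise <- function(d, groups, pair, n_permutations = 9999,
                               seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (length(pair) != 2) stop("`pair` must name two groups", call. = FALSE)
  groups <- as.character(groups)
  keep <- groups %in% pair
  sizes <- table(groups[keep])
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  m <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  fit <- permanova_oneway(m[keep, keep, drop = FALSE], groups[keep],
                          n_permutations = n_permutations, seed = seed)
  structure(
    list(pair = pair, t_statistic = sqrt(fit$pseudo_f),
         p_perm = fit$p_perm, n_permutations = fit$n_permutations,
         method = fit$method, df_within = fit$df_within, seed = seed,
         fit = fit),
    class = "permanova_pairwise"
  )
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat("One-way PERMANOVA\n")
  cat(sprintf("  pseudo-F = %.4f on %d and %d df\n",
              x$pseudo_f, x$df_among, x$df_within))
  cat(sprintf("  SS among = %.4f, within = %.4f, total = %.4f\n",
              x$ss_among, x$ss_within, x$ss_total))
  cat(sprintf("  p = %.4f (%s, %d permutations, seed %d)\n",
              x$p_perm, x$method, x$n_permutations, x$seed))
  invisible(x)
}

#' @export
print.permanova_pairwise <- function(x, ...) {
  cat(sprintf("Pairwise PERMANOVA %s vs %s: t = %.4f, p = %.4f (%s)\n",
              x$pair[1], x$pair[2], x$t_statistic, x$p_perm, x$method))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy permanova_fit
#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble::tibble(
    term = c("among groups", "within groups", "total"),
    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
    sum_of_squares = c(x$ss_among, x$ss_within, x$ss_total),
    pseudo_f = c(x$pseudo_f, NA, NA),
    p_perm = c(x$p_perm, NA, NA)
  )
}

#' @method glance permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble::tibble(
    pseudo_f = x$pseudo_f, df_among = x$df_among,
    df_within = x$df_within, p_perm = x$p_perm,
    n_permutations = x$n_permutations, method = x$method, seed = x$seed
  )
}

#' @method tidy permanova_pairwise
#' @export
tidy.permanova_pairwise <- function(x, ...) {
  tibble::tibble(
    contrast = paste(x$pair, collapse = " vs "),
    t_statistic = x$t_statistic, df_within = x$df_within,
    p_perm = x$p_perm, n_permutations = x$n_permutations,
    method = x$method
  )
}

#' Univariate permutation test on a tidy table
#'
#' Convenience wrapper used throughout the analysis pipeline: takes a data
#' frame, applies the log(X + 1) transform to one response column, builds
#' the Euclidean distance matrix and runs either the one-way main test over
#' all groups or a single pairwise contrast.
#'
#' @param data A data frame.
#' @param response Name of the numeric response column.
#' @param group Name of the grouping column.
#' @param pair Optional character vector of two group labels; when given a
#'   pairwise contrast is run instead of the main test.
#' @param n_permutations,seed Passed to the underlying test.
#' @param transform Apply log(X + 1) first? (Default `TRUE`.)
#' @return A `permanova_fit` or `permanova_pairwise` object.
#' @export
permanova_test <- function(data, response, group, pair = NULL,
                           n_permutations = 9999, seed,
                           transform = TRUE) {
  if (!response %in% names(data)) {
    stop("response column `", response, "` not found", call. = FALSE)
  }
  x <- data[[response]]
  if (transform) x <- log1p_transform(x)
  d <- euclidean_distances(matrix(x, ncol = 1))
  g <- data[[group]]
  if (is.null(pair)) {
    permanova_oneway(d, g, n_permutations = n_permutations, seed = seed)
  } else {
    permanova_pairwise(d, g, pair, n_permutations = n_permutations,
                       seed = seed)
  }
}
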