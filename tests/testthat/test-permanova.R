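test_that("the two-group worked example partitions exactly", {
  # {0,1} vs {2,3}: SS_T = 5, SS_W = 1, SS_A = 4 -> F = (4/1)/(1/2) = 8
  d <- euclidean_distances(matrix(c(0, 1, 2, 3)))
  fit <- permanova_oneway(d, c("a", "a", "b", "b"), seed = 1)
  expect_equal(fit$ss_total, 5)
  expect_equal(fit$ss_within, 1)
  expect_equal(fit$ss_among, 4)
  expect_equal(fit$pseudo_f, 8)
  # exhaustive over the 6 labelled assignments; 2 reach F >= 8
  expect_equal(fit$method, "exhaustive")
  expect_equal(fit$p_perm, 1 / 3)
  # and the pairwise t is the square root of that F
  pw <- permanova_pairwise(d, c("a", "a", "b", "b"), c("a", "b"), seed = 1)
  expect_equal(pw$t_statistic, sqrt(8))
  expect_equal(pw$p_perm, 1 / 3)
})

test_that("pseudo-F equals classical one-way ANOVA F on univariate data", {
  max_rel_err <- 0
  for (seed in 1:25) {
    dat <- withr::with_seed(seed, {
      a <- sample(2:5, 1)
      sizes <- sample(2:6, a, replace = TRUE)
      tibble::tibble(
        g = rep(letters[seq_len(a)], sizes),
        y = stats::rnorm(sum(sizes), mean = rep(stats::runif(a, 0, 3),
                                                sizes)))
    })
    fit <- permanova_oneway(euclidean_distances(matrix(dat$y)), dat$g,
                            n_permutations = 49, seed = seed)
    f_aov <- summary(stats::aov(y ~ g, dat))[[1]]$`F value`[1]
    max_rel_err <- max(max_rel_err, abs(fit$pseudo_f - f_aov) / f_aov)
  }
  expect_lt(max_rel_err, 1e-10)
})

test_that("pseudo-F matches an independent multivariate implementation", {
  skip_if_not_installed("vegan")
  dat <- withr::with_seed(99, matrix(stats::rnorm(45), nrow = 15))
  g <- rep(c("a", "b", "c"), each = 5)
  fit <- permanova_oneway(euclidean_distances(dat), g,
                          n_permutations = 199, seed = 2)
  ref <- vegan::adonis2(dat ~ g, method = "euclidean", permutations = 99)
  expect_equal(fit$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(fit$ss_among, ref$SumOfSqs[1], tolerance = 1e-10)
})

test_that("Monte-Carlo p converges to the exhaustive p", {
  # sizes (6, 6): 924 assignments; both routes on the same data
  dat <- withr::with_seed(5, matrix(stats::rnorm(12, rep(c(0, 1.2),
                                                         each = 6))))
  g <- rep(c("a", "b"), each = 6)
  d <- euclidean_distances(dat)
  exact <- permanova_oneway(d, g, n_permutations = 1000, seed = 1)
  expect_equal(exact$method, "exhaustive")
  expect_equal(exact$n_permutations, 924)
  mc <- permanova_oneway(d, g, n_permutations = 600, seed = 3)
  expect_equal(mc$method, "monte-carlo")
  expect_lt(abs(mc$p_perm - exact$p_perm), 0.05)
})

test_that("the statistic is invariant to translation and relabelling", {
  dat <- withr::with_seed(11, matrix(stats::rnorm(30), nrow = 10))
  g <- rep(c("a", "b"), each = 5)
  f0 <- permanova_oneway(euclidean_distances(dat), g, 99, seed = 1)
  shifted <- sweep(dat, 2, c(10, -3, 100), "+")
  f1 <- permanova_oneway(euclidean_distances(shifted), g, 99, seed = 1)
  expect_equal(f1$pseudo_f, f0$pseudo_f)
  expect_equal(f1$p_perm, f0$p_perm)
  relabelled <- ifelse(g == "a", "zz", "aa")
  f2 <- permanova_oneway(euclidean_distances(dat), relabelled, 99, seed = 1)
  expect_equal(f2$pseudo_f, f0$pseudo_f)
})

test_that("sums of squares are additive on random inputs", {
  for (seed in 1:10) {
    dat <- withr::with_seed(seed, matrix(stats::rnorm(36), nrow = 12))
    g <- rep(c("a", "b", "c"), each = 4)
    fit <- permanova_oneway(euclidean_distances(dat), g, 49, seed = seed)
    expect_equal(fit$ss_among + fit$ss_within, fit$ss_total,
                 tolerance = 1e-9)
  }
})

test_that("degenerate inputs are caught", {
  same <- matrix(rep(1, 6))
  expect_error(permanova_oneway(euclidean_distances(same),
                                rep(c("a", "b"), 3), seed = 1),
               "distances are zero")
  d <- euclidean_distances(matrix(1:4))
  expect_error(permanova_oneway(d, rep("a", 4), seed = 1), "2 groups")
  expect_error(permanova_oneway(d, c("a", "b", "c", "d"), seed = 1),
               "residual degrees")
  expect_error(permanova_oneway(d, c("a", "a", "b", "b")), "seed")
  # identical groups: F = 0, t = 0 (not an error)
  d2 <- euclidean_distances(matrix(c(0, 1, 0, 1)))
  pw <- permanova_pairwise(d2, c("a", "a", "b", "b"), c("a", "b"),
                           seed = 1)
  expect_equal(pw$t_statistic, 0)
  expect_error(permanova_pairwise(d, c("a", "a", "a", "b"), c("a", "b"),
                                  seed = 1),
               "at least 2 samples")
})

test_that("label-permutation counts follow the multinomial formula", {
  pc <- exact_permutation_count(c(2, 2))
  expect_equal(pc$n_label_permutations, 24)
  expect_equal(pc$n_distinct_assignments, 6)
  expect_equal(exact_permutation_count(c(1, 1))$n_distinct_assignments, 2)
  expect_equal(exact_permutation_count(c(5, 5))$n_distinct_assignments,
               choose(10, 5))
  expect_error(exact_permutation_count(c(3)), "single group")
  expect_error(exact_permutation_count(integer(0)), "non-empty")
})

test_that("log(X + 1) transform is exact and guards its domain", {
  expect_equal(log1p_transform(0), 0)
  expect_equal(log1p_transform(exp(1) - 1), 1)
  expect_error(log1p_transform(-0.1), "non-negative")
  df <- tibble::tibble(a = c(0, 1), b = c(2, 3))
  expect_equal(log1p_transform(df)$b, log1p(c(2, 3)))
})

test_that("euclidean distances match a brute-force double loop", {
  x <- withr::with_seed(7, matrix(stats::rnorm(15), nrow = 5))
  d <- euclidean_distances(x)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)))
  }
  expect_equal(euclidean_distances(matrix(c(0, 3)))[1, 2], 3)
  expect_equal(d[2, 2], 0)
  expect_error(euclidean_distances(matrix(1, 1, 3)), "2 samples")
})
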