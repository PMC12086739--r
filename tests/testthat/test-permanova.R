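test_that("euclidean distance matrix matches the pairwise loop oracle", {
  expect_true(all(euclidean_distances(matrix(1, 4, 2)) == 0))
  expect_equal(euclidean_distances(c(0, 3))[1, 2], 3)

  set.seed(14)
  x <- matrix(rnorm(18), 6, 3)
  d <- euclidean_distances(x)
  for (i in 1:6) for (j in 1:6) {
    expect_equal(d[i, j], sqrt(sum((x[i, ] - x[j, ])^2)), tolerance = 1e-12)
  }
  expect_equal(d, t(d))
  expect_error(euclidean_distances(c(1, NA)), "finite")
})

test_that("sums of squares decompose and match the brute-force oracle", {
  set.seed(8)
  for (rep in 1:5) {
    x <- matrix(rnorm(24), 12, 2)
    g <- sample(rep(c("a", "b", "c"), 4))
    d <- euclidean_distances(x)
    res <- permanova_oneway(d, g, n_permutations = 99, seed = rep)
    expect_equal(res$ss_among + res$ss_within, res$ss_total,
                 tolerance = 1e-9)
    expect_equal(res$f_stat, brute_force_f(d, g), tolerance = 1e-12)
    expect_gt(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("F is invariant to relabeling, translation, and scaling", {
  set.seed(19)
  x <- matrix(rnorm(20), 10, 2)
  g <- rep(c("a", "b"), each = 5)
  f0 <- permanova_oneway(euclidean_distances(x), g, 9, seed = 1)$f_stat
  g2 <- ifelse(g == "a", "z", "y")
  expect_equal(permanova_oneway(euclidean_distances(x), g2, 9,
                                seed = 1)$f_stat, f0)
  shifted <- sweep(x, 2, c(100, -5), `+`)
  expect_equal(permanova_oneway(euclidean_distances(shifted), g, 9,
                                seed = 1)$f_stat, f0, tolerance = 1e-9)
  expect_equal(permanova_oneway(euclidean_distances(3.5 * x), g, 9,
                                seed = 1)$f_stat, f0, tolerance = 1e-9)
})

test_that("degenerate and pathological inputs take their defined values", {
  x <- matrix(1, 6, 2)
  res <- permanova_oneway(euclidean_distances(x), rep(c("a", "b"), 3))
  expect_equal(res$p_value, 1)
  expect_true(is.nan(res$f_stat))

  # perfectly separated groups: F = +Inf, p from enumeration
  y <- c(0, 0, 0, 1, 1, 1)
  g <- rep(c("a", "b"), each = 3)
  res2 <- permanova_oneway(euclidean_distances(y), g, exact = TRUE)
  expect_true(is.infinite(res2$f_stat))

  expect_error(permanova_oneway(euclidean_distances(y), rep("a", 6)),
               "two groups")
})

test_that("exact enumeration equals an independent combinatorial oracle", {
  # separated two-groups-of-three case: only the observed split and its
  # mirror reach F = +Inf among the choose(6,3) = 20 label orderings
  y <- c(0, 0, 0, 1, 1, 1)
  g <- rep(c("a", "b"), each = 3)
  d <- euclidean_distances(y)
  res <- permanova_oneway(d, g, exact = TRUE)

  combos <- utils::combn(6, 3)
  f_obs <- brute_force_f(d, g)
  hits <- 0; total <- 0
  for (k in seq_len(ncol(combos))) {
    lab <- rep("b", 6); lab[combos[, k]] <- "a"
    f <- brute_force_f(d, lab)
    if (f >= f_obs) hits <- hits + 1
    total <- total + 1
  }
  expect_equal(res$p_value, hits / total)
  expect_equal(res$p_value, 2 / 20)
  expect_equal(res$n_permutations, 20)

  # a continuous random instance, same oracle
  set.seed(33)
  y2 <- rnorm(7)
  g2 <- c("a", "a", "a", "b", "b", "b", "b")
  d2 <- euclidean_distances(y2)
  res2 <- permanova_oneway(d2, g2, exact = TRUE)
  combos2 <- utils::combn(7, 3)
  f_obs2 <- brute_force_f(d2, g2)
  hits2 <- sum(apply(combos2, 2, function(idx) {
    lab <- rep("b", 7); lab[idx] <- "a"
    brute_force_f(d2, lab) >= f_obs2
  }))
  expect_equal(res2$p_value, hits2 / ncol(combos2))
})

test_that("permutation p agrees with exact enumeration within binomial error", {
  set.seed(101)
  y <- c(rnorm(4, 0), rnorm(4, 1.2))
  g <- rep(c("a", "b"), each = 4)
  d <- euclidean_distances(y)
  p_exact <- permanova_oneway(d, g, exact = TRUE)$p_value
  m <- 9999
  p_perm <- permanova_oneway(d, g, n_permutations = m, seed = 5)$p_value
  se <- sqrt(p_exact * (1 - p_exact) / m)
  expect_lt(abs(p_perm - p_exact), 3 * se + 2 / m)
})

test_that("pseudo-F matches an independent reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(55)
  x <- matrix(rnorm(60), 20, 3)
  g <- sample(rep(c("a", "b", "c"), c(7, 7, 6)))
  res <- permanova_oneway(euclidean_distances(x), g, n_permutations = 999,
                          seed = 2)
  ref <- vegan::adonis2(dist(x) ~ g, permutations = 999)
  expect_equal(res$f_stat, ref$F[1], tolerance = 1e-9)
  expect_equal(res$ss_among, ref$SumOfSqs[1], tolerance = 1e-9)
  expect_equal(res$ss_total, ref$SumOfSqs[rownames(ref) == "Total"],
               tolerance = 1e-9)
  expect_lt(abs(res$p_value - ref$`Pr(>F)`[1]), 0.05)
})

test_that("group comparison wrapper handles transforms and missing metrics", {
  set.seed(61)
  df <- data.frame(supply_class = rep(c("private_tw", "public_tw"), each = 6),
                   sum_tq = c(rlnorm(6, 0, 1), rlnorm(6, 2, 1)))
  raw <- compare_supply_groups(df, "sum_tq", n_permutations = 99, seed = 3)
  logd <- compare_supply_groups(df, "sum_tq", n_permutations = 99, seed = 3,
                                transform = "log10")
  expect_s3_class(raw, "permanova_result")
  expect_false(identical(raw$f_stat, logd$f_stat))
  expect_error(compare_supply_groups(df, "nope", 9), "not found")
})
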