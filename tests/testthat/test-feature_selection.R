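test_that("singleton merit equals the feature-class correlation in both modes", {
  toy <- toy_classes()
  for (mode in c("pearson", "su")) {
    rcf <- mrspattern:::feature_class_correlation(toy$x, toy$labels, mode)
    for (j in c(1L, 3L, 6L))
      expect_equal(cfs_merit(j, toy$x, toy$labels, mode), rcf[j])
  }
})

test_that("a perfectly redundant pair gains nothing over the singleton", {
  toy <- toy_classes()
  x <- cbind(toy$x, toy$x[, 1])      # exact duplicate of column 1
  dup <- ncol(x)
  for (mode in c("pearson", "su")) {
    m1 <- cfs_merit(1L, x, toy$labels, mode)
    m2 <- cfs_merit(c(1L, dup), x, toy$labels, mode)
    expect_equal(m2, m1, tolerance = 1e-12)
  }
})

test_that("duplicating a singleton feature gives exactly no merit gain", {
  toy <- toy_classes(seed = 21)
  x <- cbind(toy$x, toy$x[, 2])
  dup <- ncol(x)   # exact copy of informative column 2
  for (mode in c("pearson", "su")) {
    expect_equal(cfs_merit(c(2L, dup), x, toy$labels, mode),
                 cfs_merit(2L, x, toy$labels, mode), tolerance = 1e-12)
  }
})

test_that("merit matches the direct-formula oracle over all 3-subsets of 8 features", {
  withr::with_seed(31, {
    x <- matrix(rnorm(30 * 8), 30)
    x[, 1] <- x[, 1] + rep(c(0, 1.5, 3), each = 10)
    x[, 2] <- x[, 2] + rep(c(0, 2, 0), each = 10)
    labels <- rep(c("a", "b", "c"), each = 10)
  })
  subsets <- utils::combn(8, 3)
  for (mode in c("pearson", "su")) {
    for (q in seq_len(ncol(subsets))) {
      s <- subsets[, q]
      expect_equal(cfs_merit(s, x, labels, mode),
                   oracle_cfs_merit(s, x, labels, mode),
                   tolerance = 1e-10,
                   info = sprintf("%s subset %s", mode, paste(s, collapse = ",")))
    }
  }
})

test_that("the greedy forward path equals brute-force stepwise enumeration", {
  withr::with_seed(32, {
    x <- matrix(rnorm(40 * 10), 40)
    x[, 3] <- x[, 3] + rep(c(0, 2, 4), c(14, 13, 13))
    x[, 7] <- x[, 7] + rep(c(0, 3, 0), c(14, 13, 13))
    labels <- rep(c("a", "b", "c"), c(14, 13, 13))
  })
  for (mode in c("pearson", "su")) {
    got <- sffs_select(x, max_features = 4, labels = labels,
                       correlation = mode)$features$index
    expect_identical(got, as.integer(oracle_greedy_path(x, labels, 4, mode)))
  }
})

test_that("a perfectly separating feature is selected first", {
  withr::with_seed(33, {
    x <- matrix(rnorm(45 * 12), 45)
    labels <- rep(c("a", "b", "c"), each = 15)
    x[, 5] <- rep(c(0, 10, 20), each = 15) + rnorm(45, 0, 0.1)
  })
  sel <- sffs_select(x, max_features = 3, labels = labels)
  expect_identical(sel$features$index[1], 5L)
  expect_identical(sel$trace$k, 1:3)
  expect_true(all(diff(sel$trace$k) == 1))
})

test_that("merit ties break towards the lower datapoint index", {
  withr::with_seed(34, {
    base <- rnorm(30)
    labels <- rep(c("a", "b", "c"), each = 10)
    sig <- rep(c(0, 2, 4), each = 10) + rnorm(30, 0, 0.2)
    x <- cbind(sig, base, sig, base)   # columns 1 and 3 identical
  })
  for (mode in c("pearson", "su"))
    expect_identical(sffs_select(x, 1, labels = labels,
                                 correlation = mode)$features$index, 1L)
})

test_that("merit is invariant to per-feature affine rescaling", {
  toy <- toy_classes(seed = 35)
  scales <- seq(0.2, 3, length.out = ncol(toy$x))
  shifted <- sweep(sweep(toy$x, 2, scales, "*"), 2, rnorm(ncol(toy$x)), "+")
  for (mode in c("pearson", "su")) {
    expect_equal(cfs_merit(c(1, 2, 4), shifted, toy$labels, mode),
                 cfs_merit(c(1, 2, 4), toy$x, toy$labels, mode),
                 tolerance = 1e-10)
  }
})

test_that("repeated runs of the selection are identical", {
  toy <- toy_classes(seed = 36)
  a <- sffs_select(toy$x, 4, labels = toy$labels)
  b <- sffs_select(toy$x, 4, labels = toy$labels)
  expect_identical(a$features, b$features)
  expect_identical(a$trace, b$trace)
})

test_that("floating mode returns a valid ordered feature set", {
  toy <- toy_classes(seed = 37)
  sel <- sffs_select(toy$x, 4, labels = toy$labels, floating = TRUE)
  expect_identical(sel$features$selection_order, seq_len(nrow(sel$features)))
  expect_false(anyDuplicated(sel$features$index) > 0)
})

test_that("recommended cap follows the 1/3-of-smallest-class rule", {
  expect_identical(recommended_feature_cap(c(32, 13, 9)), 3L)
  expect_identical(recommended_feature_cap(c(32, 54, 22)), 7L)
  expect_identical(recommended_feature_cap(c(10, 3, 12)), 2L)  # clamped
  co <- tiny_cohort()
  expect_identical(recommended_feature_cap(co),
                   max(2L, as.integer(min(table(co$meta$label)) %/% 3)))
})

test_that("constant features carry zero correlation and are never preferred", {
  toy <- toy_classes(seed = 38)
  x <- cbind(toy$x, 5)
  const <- ncol(x)
  for (mode in c("pearson", "su")) {
    expect_equal(cfs_merit(const, x, toy$labels, mode), 0)
    expect_false(const %in% sffs_select(x, 3, labels = toy$labels,
                                        correlation = mode)$features$index)
  }
  expect_error(cfs_merit(integer(0), x, toy$labels), "empty")
})
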