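test_that("BER follows the weighted per-class error formula", {
  cm <- confusion_matrix(diag(c(10, 5, 8)), c("a", "b", "c"))
  expect_equal(ber(cm), 0)
  cm2 <- confusion_matrix(rbind(c(15, 1, 0),
                                c(0, 7, 0),
                                c(1, 0, 4)), c("a", "b", "c"))
  expect_equal(ber(cm2), (1 / 16 + 0 / 7 + 1 / 5) / 3 * 100)
  expect_equal(ber(cm2), 8.75)
  # uniformly wrong classifier
  cm3 <- confusion_matrix(rbind(c(0, 3, 0), c(0, 0, 4), c(5, 0, 0)),
                          c("a", "b", "c"))
  expect_equal(ber(cm3), 100)
  expect_error(ber(confusion_matrix(rbind(c(1, 0), c(0, 0)), c("a", "b"))),
               "empty class")
})

test_that("BER equals the direct per-class mean on random confusion matrices", {
  withr::with_seed(51, {
    for (i in 1:1000) {
      m <- matrix(rpois(9, 4), 3)
      diag(m) <- diag(m) + 1      # non-empty rows
      cm <- confusion_matrix(m, c("a", "b", "c"))
      direct <- mean(sapply(1:3, function(r) (sum(m[r, ]) - m[r, r]) / sum(m[r, ])))
      expect_equal(ber(cm), direct * 100)
    }
  })
})

test_that("dichotomized counts partition the confusion total", {
  withr::with_seed(52, {
    for (i in 1:50) {
      m <- matrix(rpois(9, 5), 3)
      diag(m) <- diag(m) + 1
      cm <- confusion_matrix(m, c("a", "b", "c"))
      for (cl in c("a", "b", "c")) {
        d <- dichotomize(cm, cl)
        expect_identical(d$tp + d$fn + d$fp + d$tn, as.integer(sum(m)))
      }
    }
  })
})

test_that("a perfect confusion gives all dichotomized metrics 100%", {
  cm <- confusion_matrix(diag(c(4, 6, 3)), c("a", "b", "c"))
  for (cl in c("a", "b", "c")) {
    d <- dichotomize(cm, cl)
    expect_equal(unlist(d[c("sensitivity", "specificity", "ppv", "npv")]),
                 c(sensitivity = 100, specificity = 100, ppv = 100, npv = 100))
  }
})

test_that("zero denominators yield NA rather than 0", {
  cm <- confusion_matrix(rbind(c(0, 4, 0), c(0, 6, 0), c(0, 3, 0)),
                         c("a", "b", "c"))
  d <- dichotomize(cm, "a")      # nothing predicted as a -> ppv undefined
  expect_true(is.na(d$ppv))
  expect_equal(d$sensitivity, 0)
})

test_that("AUC matches brute-force pair counting", {
  withr::with_seed(53, {
    scores <- rnorm(200)
    labels <- rnorm(200) + scores > 0.3
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
    # with ties
    ts <- sample(1:8, 100, replace = TRUE)
    tl <- runif(100) < 0.4
    expect_equal(roc_auc(ts, tl)$auc, oracle_auc(ts, tl))
  })
})

test_that("AUC endpoints behave canonically", {
  sep <- roc_auc(c(1, 2, 3, 10, 11, 12), c(F, F, F, T, T, T))
  expect_equal(sep$auc, 1)
  expect_equal(sep$se, 0)
  same <- roc_auc(rep(c(1, 2, 3), 2), rep(c(TRUE, FALSE), each = 3))
  expect_equal(same$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both label values")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(54, {
    scores <- rnorm(80)
    labels <- rbinom(80, 1, plogis(scores))
    if (length(unique(labels)) == 2) {
      ref <- suppressMessages(pROC::auc(labels, scores,
                                        direction = "<", quiet = TRUE))
      expect_equal(roc_auc(scores, labels == 1)$auc, as.numeric(ref),
                   tolerance = 1e-10)
    }
  })
})

test_that("bootstrap CCC is exact for separable data and seed-reproducible", {
  co <- normalize_cohort(tiny_cohort(n_animals = 12L, seed = 55))
  # implant a perfectly separating datapoint per class
  lab <- co$meta$label
  co$intensities[, 3] <- c(0, 50, 100)[match(lab, co$class_labels)]
  fs <- feature_set(c(3L, 10L), co$ppm)
  b1 <- bootstrap_ccc(co, fs, n_boot = 60, seed = 9)
  expect_equal(b1$mean, 100)
  expect_equal(b1$sd, 0)
  co2 <- normalize_cohort(tiny_cohort(n_animals = 12L, seed = 56))
  fs2 <- feature_set(c(3L, 10L, 20L), co2$ppm)
  r1 <- bootstrap_ccc(co2, fs2, n_boot = 80, seed = 4)
  r2 <- bootstrap_ccc(co2, fs2, n_boot = 80, seed = 4)
  expect_identical(r1$replicates, r2$replicates)
  expect_error(bootstrap_ccc(co2, fs2, n_boot = 10), "seed")
})

test_that("bootstrap CCC means are stable across seeds on the default cohort", {
  cfg <- default_config("infarct_evolution")
  tr <- subset_cohort(normalize_cohort(simulate_cohort(cfg, seed = 42)),
                      split = "train")
  fs <- sffs_select(tr, max_features = 3)$features
  a <- bootstrap_ccc(tr, fs, n_boot = 1000, seed = 1)
  b <- bootstrap_ccc(tr, fs, n_boot = 1000, seed = 2)
  expect_lt(abs(a$mean - b$mean), 0.5)
})

test_that("chronological split assigns whole animals in id order", {
  axis <- default_ppm_axis(24)
  recs <- list()
  for (a in 1:3) for (s in 1:2)
    recs[[length(recs) + 1L]] <- spectrum_record(
      abs(rnorm(24)) + 1, axis, spectrum_id = sprintf("S%d%d", a, s),
      animal_id = sprintf("R%02d", a), label = "non_infarcted")
  co <- mrs_cohort(recs)
  sp <- chronological_split(co, 2 / 3)
  expect_identical(sp$meta$split,
                   rep(c("train", "train", "test"), each = 2))
  one <- subset_cohort(co, 1:2)
  expect_error(chronological_split(one), "single animal")
})

test_that("splits never share spectra and respect whole animals", {
  for (seed in c(61, 62)) {
    cfg <- default_config("infarct_evolution",
                          class_sizes = c(12L, 6L, 6L))
    co <- simulate_cohort(cfg, seed = seed)
    tr_ids <- co$meta$spectrum_id[co$meta$split == "train"]
    te_ids <- co$meta$spectrum_id[co$meta$split == "test"]
    expect_length(intersect(tr_ids, te_ids), 0L)
    by_animal <- split(co$meta$split, co$meta$animal_id)
    expect_true(all(vapply(by_animal, function(s) length(unique(s)) == 1L,
                           logical(1))))
    frac <- length(tr_ids) / n_spectra(co)
    expect_gt(frac, 0.55)
    expect_lt(frac, 0.8)
  }
})

test_that("the sweep covers the requested range and applies the selection rule", {
  cfg <- default_config("infarct_evolution", class_sizes = c(24L, 10L, 8L))
  co <- normalize_cohort(simulate_cohort(cfg, seed = 63))
  tr <- subset_cohort(co, split = "train")
  te <- subset_cohort(co, split = "test")
  sw <- suppressWarnings(feature_sweep(tr, te, k_min = 2, k_max = 6, n_boot = 0))
  expect_identical(sw$k, 2:6)
  expect_identical(nrow(sw), 5L)
  sk <- attr(sw, "selected_k")
  expect_true(sk %in% sw$k)
  expect_lte(sw$test_ber[sw$k == sk], sw$test_ber[sw$k == 2])
})

test_that("the model-size rule picks the first local BER minimum", {
  pick <- mrspattern:::select_model_size
  expect_identical(pick(2:7, c(12, 9, 8.8, 10, 7, 11)), 4L)  # paper-like valley
  expect_identical(pick(2:6, c(10, 8, 6, 5, 4)), 6L)          # monotone decrease
  expect_identical(pick(2:6, c(5, 6, 7, 8, 9)), 2L)           # monotone increase
  expect_identical(pick(2:7, c(12, 9, 8.8, 10, 7, 11), rule = "global_min"), 6L)
})

test_that("disjointness of train and test is enforced in the sweep", {
  co <- normalize_cohort(tiny_cohort(n_animals = 9L, seed = 64))
  expect_error(feature_sweep(co, co, k_min = 2, k_max = 3, n_boot = 0),
               "share spectra")
})

test_that("one-vs-rest latent scores produce coherent metrics tables", {
  cfg <- default_config("infarct_evolution", class_sizes = c(16L, 8L, 8L))
  co <- normalize_cohort(simulate_cohort(cfg, seed = 65))
  tr <- subset_cohort(co, split = "train")
  fs <- sffs_select(tr, max_features = 3)$features
  fit <- fit_fisher_lda(tr, fs)
  mt <- class_metrics(fit, tr)
  expect_identical(mt$target_class, tr$class_labels)
  expect_true(all(mt$auc >= 0 & mt$auc <= 1))
  expect_true(all(mt$auc_se >= 0, na.rm = TRUE))
  expect_identical(unique(mt$tp + mt$fn + mt$fp + mt$tn), n_spectra(tr))
})
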