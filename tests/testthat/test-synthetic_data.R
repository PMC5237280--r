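test_that("both scenarios build three-class configs with study-sized cohorts", {
  ie <- default_config("infarct_evolution")
  br <- default_config("brain_regions")
  expect_identical(ie$class_labels, c("non_infarcted", "acute", "subacute"))
  expect_identical(br$class_labels, c("non_infarcted", "svz", "infarcted"))
  expect_identical(unname(ie$class_sizes), c(48L, 20L, 14L))
  expect_identical(unname(br$class_sizes), c(48L, 82L, 34L))
  expect_setequal(round(diagnostic_ppm(ie), 2), c(1.33, 3.05, 0.85))
  expect_setequal(round(diagnostic_ppm(br), 2), c(3.04, 3.05, 3.62))
})

test_that("noiseless class templates reproduce the published reference medians", {
  targets <- list(
    infarct_evolution = list(
      "1.33" = c(2.78, 7.39, 19.88),
      "3.05" = c(3.83, 1.96, 2.01),
      "0.85" = c(3.32, 3.02, 12.30)),
    brain_regions = list(
      "3.62" = c(2.73, 3.45, 1.61),
      "3.04" = c(6.92, 6.91, 2.84)))
  for (scen in names(targets)) {
    cfg <- default_config(scen)
    S <- vapply(seq_len(nrow(cfg$peaks)), function(i)
      mrspattern:::peak_shape(cfg$ppm, cfg$peaks$ppm[i], cfg$peaks$fwhm[i],
                              cfg$peaks$lineshape[i]),
      numeric(length(cfg$ppm)))
    for (pp in names(targets[[scen]])) {
      idx <- ppm_to_index(cfg$ppm, as.numeric(pp))
      got <- vapply(seq_along(cfg$class_labels), function(ci)
        sum(S[idx, ] * cfg$amp[ci, ]), numeric(1))
      expect_equal(got, targets[[scen]][[pp]], tolerance = 0.02,
                   info = paste(scen, pp))
    }
    # reference-class template norm is 100 (self-normalization consistency)
    expect_equal(sqrt(sum((S %*% cfg$amp[1, ])^2)), 100, tolerance = 1e-3)
  }
})

test_that("a single noiseless Lorentzian peaks at its nominal datapoint", {
  axis <- default_ppm_axis()
  y <- mrspattern:::peak_shape(axis, 3.03, 0.05, "lorentzian")
  expect_identical(which.max(y), ppm_to_index(axis, 3.03))
  expect_gt(max(y), 0.99)  # apex falls within half a datapoint of the centre
  g <- mrspattern:::peak_shape(axis, 1.33, 0.06, "gaussian")
  expect_identical(which.max(g), ppm_to_index(axis, 1.33))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- default_config("infarct_evolution", class_sizes = c(10L, 4L, 4L))
  a <- simulate_cohort(cfg, seed = 81)
  b <- simulate_cohort(cfg, seed = 81)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$meta, b$meta)
  c <- simulate_cohort(cfg, seed = 82)
  expect_false(isTRUE(all.equal(a$intensities, c$intensities)))
  expect_identical(dim(a$intensities), dim(c$intensities))
})

test_that("cohort structure matches the study design", {
  cfg <- default_config("infarct_evolution")
  co <- simulate_cohort(cfg, seed = 83)
  expect_identical(n_spectra(co), 82L)
  expect_identical(as.integer(table(factor(co$meta$label, cfg$class_labels))),
                   c(48L, 20L, 14L))
  # every record has a contralateral reference of the reference tissue
  expect_setequal(names(co$contralateral), co$meta$spectrum_id)
  ref_regions <- co$meta$region[match(unname(co$contralateral),
                                      co$meta$spectrum_id)]
  expect_true(all(ref_regions == "non_infarcted"))
  # references belong to the same animal
  own <- co$meta$animal_id[match(names(co$contralateral), co$meta$spectrum_id)]
  ref <- co$meta$animal_id[match(unname(co$contralateral), co$meta$spectrum_id)]
  expect_identical(own, ref)
  expect_true(all(co$meta$split %in% c("train", "test")))
})

test_that("the brain-regions design distributes lesion spectra over reference animals", {
  cfg <- default_config("brain_regions")
  co <- simulate_cohort(cfg, seed = 84)
  expect_identical(n_spectra(co), 164L)
  expect_identical(as.integer(table(factor(co$meta$label, cfg$class_labels))),
                   c(48L, 82L, 34L))
  expect_setequal(names(co$contralateral), co$meta$spectrum_id)
})

test_that("the two-piece lognormal reproduces median and both quartiles", {
  s <- mrspattern:::lognormal_sigmas(19.88, 10.38, 22.11)
  withr::with_seed(85, {
    draws <- mrspattern:::rtwopiece_lognorm(2e5, 19.88, s["lo"], s["hi"])
  })
  q <- unname(stats::quantile(draws, c(.25, .5, .75)))
  expect_equal(q, c(10.38, 19.88, 22.11), tolerance = 0.02)
})

test_that("empirical normalized medians converge to the calibrated targets", {
  cfg <- default_config("infarct_evolution")
  n_rep <- 400L
  idx <- vapply(c(1.33, 3.05, 0.85), function(p) ppm_to_index(cfg$ppm, p),
                integer(1))
  targets <- rbind(c(2.78, 3.83, 3.32),
                   c(7.39, 1.96, 3.02),
                   c(19.88, 2.01, 12.30))
  withr::with_seed(86, {
    for (ci in seq_along(cfg$class_labels)) {
      cl <- cfg$class_labels[ci]
      heights <- matrix(NA_real_, n_rep, length(idx))
      for (r in seq_len(n_rep)) {
        ref <- simulate_spectrum("non_infarcted", cfg, spectrum_id = "ref")
        les <- simulate_spectrum(cl, cfg, spectrum_id = "les")
        heights[r, ] <- les$intensities[idx] /
          sqrt(sum(ref$intensities^2)) * 100
      }
      med <- apply(heights, 2, stats::median)
      expect_equal(med, unname(targets[ci, ]), tolerance = 0.15,
                   info = cl)
    }
  })
})

test_that("classification approaches perfection as noise vanishes", {
  cfg <- default_config("infarct_evolution", noise_sd = 0.005,
                        shift_jitter_sd = 0, baseline_amplitude = 0,
                        class_sizes = c(18L, 8L, 8L))
  co <- normalize_cohort(simulate_cohort(cfg, seed = 87))
  tr <- subset_cohort(co, split = "train")
  fs <- sffs_select(tr, max_features = 3)$features
  fit <- fit_fisher_lda(tr, fs)
  expect_gte(ccc(confusion(fit, tr)), 95)
})

test_that("interleaving mixes groups evenly along the id order", {
  out <- mrspattern:::interleave_classes(rep("a", 6), rep("b", 3))
  expect_identical(sum(out == "a"), 6L)
  first_half <- out[1:4]
  expect_gte(sum(first_half == "a"), 2L)
  expect_gte(sum(first_half == "b"), 1L)
})
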