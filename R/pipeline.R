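# End-to-end orchestration of the two classifier workflows.

#' Run a classifier workflow end-to-end
#'
#' Executes the full analysis on a cohort: chemical-shift referencing (when
#' requested), UL2CA normalization via the contralateral map, sequential
#' forward feature selection on the training split, the feature-count sweep
#' with bootstrap CCC and test-set BER, the final Fisher LDA fit at the
#' selected model size, per-class diagnostic metrics on training and test
#' sets, and univariate summaries of the selected features.
#'
#' @param cohort an `mrs_cohort` with train/test splits assigned (e.g. from
#'   [simulate_cohort()] or [read_cohort()] + [chronological_split()]).
#' @param k_range feature-count range for the sweep.
#' @param n_boot bootstrap replicates for the training CCC.
#' @param seed RNG seed for all stochastic stages.
#' @param reference logical; apply [reference_to_tcr()] per spectrum first.
#' @param rule model-size selection rule, see [feature_sweep()].
#' @param out_dir optional directory; when given, all tables are written as
#'   tab-delimited text and the three diagnostic figures as PNG files.
#' @return an object of class `"mrs_run"`: a list with the normalized
#'   `train`/`test` cohorts, `sweep`, `selected_k`, `features` (truncated to
#'   the selected size), `model`, `confusion_train`, `confusion_test`,
#'   `metrics_train`, `metrics_test`, `ber_train`, `ber_test`, `ccc_boot`,
#'   `latent` (per-spectrum latent coordinates and predictions) and
#'   `feature_stats`.
#' @export
run_classifier <- function(cohort, k_range = c(2L, 20L), n_boot = 1000L,
                           seed = 1L, reference = FALSE,
                           rule = "first_local_min", out_dir = NULL) {
  stopifnot(inherits(cohort, "mrs_cohort"))
  if (!all(c("train", "test") %in% cohort$meta$split))
    stop("cohort needs assigned train and test splits", call. = FALSE)

  if (reference) {
    for (i in seq_len(n_spectra(cohort))) {
      rec <- get_record(cohort, cohort$meta$spectrum_id[i])
      cohort$intensities[i, ] <- reference_to_tcr(rec)$intensities
    }
  }
  norm <- normalize_cohort(cohort)
  train <- subset_cohort(norm, split = "train")
  test <- subset_cohort(norm, split = "test")

  k_max <- min(k_range[2L], ncol(train$intensities))
  sweep <- feature_sweep(train, test, k_min = k_range[1L], k_max = k_max,
                         n_boot = n_boot, seed = seed, rule = rule)
  selected_k <- attr(sweep, "selected_k")
  fs_full <- attr(sweep, "features")
  features <- feature_set(fs_full$index[seq_len(selected_k)], norm$ppm)

  model <- fit_fisher_lda(train, features)
  cm_train <- confusion(model, train)
  cm_test <- confusion(model, test)
  ccc_boot <- if (n_boot > 0L)
    bootstrap_ccc(train, features, n_boot = n_boot, seed = seed + selected_k)
  else list(mean = NA_real_, sd = NA_real_)

  latent <- rbind(
    cbind(classify(model, train), split = "train",
          true = train$meta$label, spectrum_id = train$meta$spectrum_id),
    cbind(classify(model, test), split = "test",
          true = test$meta$label, spectrum_id = test$meta$spectrum_id))
  rownames(latent) <- NULL

  feature_stats <- lapply(features$index, function(i)
    summarize_feature(train, i))
  names(feature_stats) <- sprintf("%.3f", features$ppm)

  run <- structure(list(
    train = train, test = test, sweep = sweep, selected_k = selected_k,
    features = features, model = model,
    confusion_train = cm_train, confusion_test = cm_test,
    metrics_train = class_metrics(model, train),
    metrics_test = class_metrics(model, test),
    ber_train = ber(cm_train), ber_test = ber(cm_test),
    ccc_boot = ccc_boot, latent = latent, feature_stats = feature_stats,
    seed = seed, n_boot = n_boot, k_range = c(k_range[1L], k_max)),
    class = "mrs_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.mrs_run <- function(x, ...) {
  cat(sprintf("<mrs_run> %d train / %d test spectra, classes: %s\n",
              n_spectra(x$train), n_spectra(x$test),
              paste(x$model$class_names, collapse = ", ")))
  cat(sprintf("  selected_k = %d (features at %s ppm)\n", x$selected_k,
              paste(sprintf("%.2f", x$features$ppm), collapse = ", ")))
  cat(sprintf("  test BER = %.1f%%, bootstrap training CCC = %.1f +/- %.1f%%\n",
              x$ber_test, x$ccc_boot$mean, x$ccc_boot$sd))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(obj, name)
    utils::write.table(obj, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  w(as.data.frame(run$sweep), "sweep.tsv")
  w(as.data.frame(run$features), "features.tsv")
  w(run$metrics_train, "metrics_train.tsv")
  w(run$metrics_test, "metrics_test.tsv")
  w(run$latent, "latent.tsv")
  cm_df <- function(cm) data.frame(true = rownames(cm), as.data.frame.matrix(cm))
  w(cm_df(run$confusion_train), "confusion_train.tsv")
  w(cm_df(run$confusion_test), "confusion_test.tsv")
  stats_df <- do.call(rbind, lapply(names(run$feature_stats), function(nm) {
    s <- run$feature_stats[[nm]]
    cbind(ppm = nm, s$per_class, kw_h = s$kw$h, kw_p = s$kw$p)
  }))
  w(stats_df, "feature_stats.tsv")
  summary_df <- data.frame(
    selected_k = run$selected_k, ber_train = run$ber_train,
    ber_test = run$ber_test, ccc_boot_mean = run$ccc_boot$mean,
    ccc_boot_sd = run$ccc_boot$sd, seed = run$seed, n_boot = run$n_boot)
  w(summary_df, "summary.tsv")
  for (nm in c("sweep", "latent", "class_means")) {
    grDevices::png(file.path(out_dir, paste0(nm, ".png")),
                   width = 900, height = 600)
    switch(nm,
           sweep = plot_sweep(run$sweep),
           latent = plot_latent(run),
           class_means = plot_class_means(run$train))
    grDevices::dev.off()
  }
  manifest <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("mrspattern"))),
    sprintf("seed\t%d", run$seed),
    sprintf("n_boot\t%d", run$n_boot),
    sprintf("k_range\t%d-%d", run$k_range[1L], run$k_range[2L]),
    sprintf("selected_k\t%d", run$selected_k))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(NULL)
}

#' Simulate a cohort and write it to disk
#'
#' @param config a `"sim_config"`.
#' @param out_dir output directory; receives `spectra.tsv`, `metadata.tsv`
#'   and `ground_truth.tsv` (diagnostic chemical shifts).
#' @param seed RNG seed; defaults to the config's.
#' @return the simulated `mrs_cohort`, invisibly.
#' @export
run_simulation <- function(config, out_dir, seed = config$seed) {
  cohort <- simulate_cohort(config, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(out_dir, "spectra.tsv"),
               file.path(out_dir, "metadata.tsv"))
  utils::write.table(attr(cohort, "ground_truth"),
                     file.path(out_dir, "ground_truth.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(cohort)
}

#' Diagnostic plots
#'
#' `plot_sweep()` draws the test-set BER and bootstrap training CCC against
#' the number of features; `plot_latent()` the 2D Fisher latent space with
#' class centroids; `plot_class_means()` the per-class mean spectrum with a
#' shaded +/- SD band.
#'
#' @param sweep a `"sweep_result"`.
#' @name mrs_plots
#' @export
plot_sweep <- function(sweep) {
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(sweep$k, sweep$test_ber, type = "b", pch = 19,
                 xlab = "number of features", ylab = "test BER (%)",
                 main = "model-size sweep")
  sk <- attr(sweep, "selected_k")
  graphics::abline(v = sk, col = "red", lty = 2)
  if (!all(is.na(sweep$ccc_mean))) {
    graphics::par(new = TRUE)
    graphics::plot(sweep$k, sweep$ccc_mean, type = "b", pch = 1, col = "blue",
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "blue")
    graphics::mtext("bootstrap training CCC (%)", side = 4, line = 2.5,
                    col = "blue")
  }
  invisible(NULL)
}

#' @rdname mrs_plots
#' @param run an `"mrs_run"`.
#' @export
plot_latent <- function(run) {
  z <- run$latent
  cls <- run$model$class_names
  col <- stats::setNames(seq_along(cls) + 1L, cls)
  graphics::plot(z$ld1, z$ld2, col = col[z$true],
                 pch = ifelse(z$split == "train", 19, 1),
                 xlab = "LD1", ylab = "LD2", main = "Fisher LDA latent space")
  graphics::points(run$model$centroids, pch = 8, cex = 2,
                   col = col[rownames(run$model$centroids)])
  graphics::legend("topright", legend = c(cls, "train", "test"),
                   col = c(col, 1, 1), pch = c(rep(15, length(cls)), 19, 1))
  invisible(NULL)
}

#' @rdname mrs_plots
#' @param cohort a normalized `mrs_cohort`.
#' @export
plot_class_means <- function(cohort) {
  cls <- cohort$class_labels
  op <- graphics::par(mfrow = c(length(cls), 1), mar = c(3, 4, 2, 1))
  on.exit(graphics::par(op))
  for (cl in cls) {
    m <- cohort$intensities[cohort$meta$label == cl, , drop = FALSE]
    mu <- colMeans(m)
    sd <- apply(m, 2L, stats::sd)
    graphics::plot(cohort$ppm, mu, type = "n", xlim = rev(range(cohort$ppm)),
                   ylim = range(mu - sd, mu + sd),
                   xlab = "ppm", ylab = "UL2CA", main = cl)
    graphics::polygon(c(cohort$ppm, rev(cohort$ppm)),
                      c(mu - sd, rev(mu + sd)),
                      col = "grey85", border = NA)
    graphics::lines(cohort$ppm, mu)
  }
  invisible(NULL)
}
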