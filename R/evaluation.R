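# Classifier evaluation: BER, bootstrap CCC, one-vs-rest metrics, sweeps.

#' Balanced error rate of a confusion matrix
#'
#' The mean over classes of the per-class misclassification proportion, in
#' percent: each class contributes its misclassified fraction with equal
#' weight, so small classes count as much as large ones.
#'
#' @param cm a [confusion_matrix()].
#' @return BER in percent (0 for a perfect classifier, 100 for a uniformly
#'   wrong one).
#' @export
ber <- function(cm) {
  cm <- as.matrix(cm)
  totals <- rowSums(cm)
  if (any(totals == 0))
    stop("confusion matrix has an empty class row; BER undefined", call. = FALSE)
  mean((totals - diag(cm)) / totals) * 100
}

#' Correctly classified cases (CCC) of a confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @return percentage of cases on the diagonal.
#' @export
ccc <- function(cm) {
  cm <- as.matrix(cm)
  sum(diag(cm)) / sum(cm) * 100
}

#' Bootstrap estimate of training-set CCC
#'
#' Resamples the training cases with replacement `n_boot` times; each
#' replicate refits the Fisher LDA on the fixed feature set and is scored by
#' its CCC on the full original training set. Replicates that lose a class
#' entirely are redrawn (the count of redraws is attached as attribute
#' `"redraws"`).
#'
#' @param train normalized training `mrs_cohort`.
#' @param features a [feature_set()].
#' @param n_boot number of bootstrap replicates (>= 1).
#' @param seed RNG seed (mandatory; results are bit-reproducible given it).
#' @return a list with `mean` and `sd` of the replicate CCC values (percent)
#'   and the `replicates` vector itself.
#' @export
bootstrap_ccc <- function(train, features, n_boot = 1000L, seed) {
  stopifnot(inherits(train, "mrs_cohort"), inherits(features, "feature_set"),
            n_boot >= 1L)
  if (missing(seed)) stop("bootstrap_ccc requires an explicit seed", call. = FALSE)
  x <- train$intensities[, features$index, drop = FALSE]
  labels <- train$meta$label
  class_names <- train$class_labels
  n <- nrow(x)
  with_seed(seed, {
    vals <- numeric(n_boot)
    redraws <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        lb <- labels[idx]
        if (all(class_names %in% lb) &&
            all(table(factor(lb, levels = class_names)) >= 2L)) break
        redraws <- redraws + 1L
      }
      fit <- fit_fisher_lda(x[idx, , drop = FALSE], labels = lb,
                            class_names = class_names)
      pred <- classify(fit, x)$class
      vals[b] <- mean(pred == labels) * 100
    }
    structure(list(mean = mean(vals), sd = stats::sd(vals), replicates = vals),
              redraws = redraws)
  })
}

#' One-vs-rest metrics from a confusion matrix
#'
#' Dichotomizes a multi-class confusion matrix to target class versus the
#' other classes combined and computes sensitivity, specificity, positive and
#' negative predictive value (percent). A metric with a zero denominator is
#' reported as `NA` (undefined), not as 0.
#'
#' @param cm a [confusion_matrix()].
#' @param target the target class name (or row index).
#' @return a one-row data frame with the counts `tp`, `fn`, `fp`, `tn` and
#'   the four metrics in percent.
#' @export
dichotomize <- function(cm, target) {
  cm <- as.matrix(cm)
  if (is.character(target)) target <- match(target, rownames(cm))
  if (is.na(target) || target < 1 || target > nrow(cm))
    stop("unknown target class", call. = FALSE)
  tp <- cm[target, target]
  fn <- sum(cm[target, ]) - tp
  fp <- sum(cm[, target]) - tp
  tn <- sum(cm) - tp - fn - fp
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  data.frame(target_class = rownames(cm)[target],
             tp = tp, fn = fn, fp = fp, tn = tn,
             sensitivity = pct(tp, tp + fn),
             specificity = pct(tn, tn + fp),
             ppv = pct(tp, tp + fp),
             npv = pct(tn, tn + fn),
             stringsAsFactors = FALSE)
}

#' ROC area under the curve with Hanley-McNeil standard error
#'
#' AUC by the rank (Mann-Whitney) formulation, with midranks for ties, and
#' its standard error by the Hanley-McNeil formula.
#'
#' @param scores continuous per-case score (higher = more target-like).
#' @param labels logical (or two-level) vector; `TRUE`/second level = target.
#' @return a list with `auc` and `se`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- labels == levels(labels)[2L]
  if (!is.logical(labels)) labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both label values must be present", call. = FALSE)
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  list(auc = auc, se = se)
}

#' One-vs-rest continuous score in the LDA latent space
#'
#' The score behind the per-class ROC curves: distance to the nearest
#' non-target centroid minus distance to the target centroid, so larger
#' values are more target-like.
#'
#' @param model fitted `"fisher_lda"`.
#' @param data normalized `mrs_cohort` or feature matrix.
#' @param target target class name.
#' @return numeric score per spectrum.
#' @export
ovr_scores <- function(model, data, target) {
  stopifnot(target %in% model$class_names)
  z <- if (inherits(data, "mrs_cohort"))
    data$intensities[, model$features$index, drop = FALSE] %*% model$projection
  else as.matrix(data) %*% model$projection
  dmat <- sapply(seq_len(nrow(model$centroids)), function(i)
    sqrt(rowSums(sweep(z, 2L, model$centroids[i, ])^2)))
  if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1L)
  ti <- match(target, model$class_names)
  apply(dmat[, -ti, drop = FALSE], 1L, min) - dmat[, ti]
}

#' Per-class diagnostic metrics table for a fitted model
#'
#' Convenience wrapper producing, for every class, the dichotomized counts
#' and metrics plus the one-vs-rest ROC AUC with its standard error.
#'
#' @param model fitted `"fisher_lda"`.
#' @param cohort normalized `mrs_cohort` to evaluate on.
#' @return data frame, one row per class.
#' @export
class_metrics <- function(model, cohort) {
  cm <- confusion(model, cohort)
  rows <- lapply(model$class_names, function(cl) {
    d <- dichotomize(cm, cl)
    a <- roc_auc(ovr_scores(model, cohort, cl), cohort$meta$label == cl)
    d$auc <- a$auc
    d$auc_se <- a$se
    d
  })
  do.call(rbind, rows)
}

#' Chronological train/test split by animal identifier
#'
#' Emulates prospective accrual: whole animals are assigned to the training
#' set in increasing order of the numeric part of their identifier until the
#' training quota (about two thirds of the spectra) is reached; all remaining
#' animals form the independent test set. No animal straddles the split.
#'
#' @param cohort an `mrs_cohort` whose animal ids contain a sortable number.
#' @param train_fraction fraction of spectra targeted for training.
#' @return the cohort with the `split` column assigned.
#' @export
chronological_split <- function(cohort, train_fraction = 2 / 3) {
  stopifnot(inherits(cohort, "mrs_cohort"), train_fraction > 0, train_fraction < 1)
  ids <- cohort$meta$animal_id
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", ids)))
  if (anyNA(num))
    stop("animal ids must contain a numeric part for chronological splitting",
         call. = FALSE)
  animals <- unique(ids[order(num)])
  if (length(animals) < 2L)
    stop("cannot split a cohort with a single animal", call. = FALSE)
  quota <- round(train_fraction * nrow(cohort$meta))
  split <- rep("test", nrow(cohort$meta))
  assigned <- 0L
  for (a in animals) {
    if (assigned >= quota) break
    sel <- ids == a
    split[sel] <- "train"
    assigned <- assigned + sum(sel)
  }
  out <- cohort
  out$meta$split <- split
  out
}

#' Feature-count sweep with the model-size selection rule
#'
#' Runs the forward selection once up to `k_max` features on the training
#' set, then for every subset size `k` fits the Fisher LDA on the first `k`
#' selected datapoints, records the bootstrap CCC on the training set and the
#' BER on the independent test set, and selects the model size by the first
#' local minimum of the test BER (the operative rule; a global-minimum mode
#' is available). The first local minimum guards against overtraining: once
#' the test BER starts rising, larger models are not considered even if a
#' later k dips slightly lower.
#'
#' @param train,test normalized `mrs_cohort`s with disjoint spectra.
#' @param k_min,k_max range of feature counts to examine.
#' @param n_boot bootstrap replicates for the training CCC; 0 skips the
#'   bootstrap (CCC columns become `NA`).
#' @param seed RNG seed for the bootstrap.
#' @param rule `"first_local_min"` (default) or `"global_min"`.
#' @param features optional precomputed selection result from
#'   [sffs_select()]; computed if missing.
#' @return a data frame of class `"sweep_result"` with columns `k`,
#'   `ccc_mean`, `ccc_sd`, `test_ber`, and attributes `selected_k` and
#'   `features` (the full [feature_set()] to `k_max`).
#' @export
feature_sweep <- function(train, test, k_min = 2L, k_max = 20L,
                          n_boot = 1000L, seed = 1L,
                          rule = c("first_local_min", "global_min"),
                          features = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(train, "mrs_cohort"), inherits(test, "mrs_cohort"),
            k_min >= 1L, k_max >= k_min)
  if (length(intersect(train$meta$spectrum_id, test$meta$spectrum_id)))
    stop("training and test sets share spectra", call. = FALSE)
  cap <- recommended_feature_cap(train)
  if (k_max > cap)
    warning(sprintf(paste0("k_max = %d exceeds the recommended cap of %d ",
                           "(1/3 of the smallest class)"), k_max, cap),
            call. = FALSE)
  sel <- features %||% sffs_select(train, max_features = k_max)
  fs <- sel$features
  if (nrow(fs) < k_max) k_max <- nrow(fs)
  ks <- seq.int(k_min, k_max)
  rows <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    fk <- feature_set(fs$index[seq_len(k)], train$ppm)
    fit <- fit_fisher_lda(train, fk)
    tb <- ber(confusion(fit, test))
    if (n_boot > 0L) {
      bc <- bootstrap_ccc(train, fk, n_boot = n_boot, seed = seed + k)
      data.frame(k = k, ccc_mean = bc$mean, ccc_sd = bc$sd, test_ber = tb)
    } else {
      data.frame(k = k, ccc_mean = NA_real_, ccc_sd = NA_real_, test_ber = tb)
    }
  })
  res <- do.call(rbind, rows)
  class(res) <- c("sweep_result", "data.frame")
  attr(res, "selected_k") <- select_model_size(res$k, res$test_ber, rule)
  attr(res, "features") <- fs
  res
}

# first local minimum of the test BER over k (or global minimum)
select_model_size <- function(k, test_ber, rule = "first_local_min") {
  stopifnot(length(k) == length(test_ber), length(k) >= 1L)
  if (rule == "global_min") return(k[which.min(test_ber)])
  n <- length(k)
  for (i in seq_len(n)) {
    arrived_down <- i == 1L || test_ber[i] <= test_ber[i - 1L]
    leaves_up <- i == n || test_ber[i] < test_ber[i + 1L]
    if (arrived_down && leaves_up) return(k[i])
  }
  k[which.min(test_ber)]
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> k = %d..%d, selected_k = %d\n",
              min(x$k), max(x$k), attr(x, "selected_k")))
  print(as.data.frame(x))
  invisible(x)
}
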