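# Multi-class Fisher linear discriminant analysis on selected datapoints.

#' Fit a multi-class Fisher LDA on selected spectral features
#'
#' Solves the generalized eigenproblem of the between-class versus the pooled
#' within-class scatter matrix on the selected feature columns and keeps the
#' two leading eigenvectors (classes - 1 = 2 latent dimensions for a
#' three-class problem). Classification is by the nearest class centroid in
#' this latent space. When the within-class scatter is ill-conditioned
#' (condition number above `cond_tol`, e.g. more features than cases per
#' class) a small ridge `eps * trace(S_w)/p` is added to its diagonal and
#' recorded in the model.
#'
#' @param x a normalized training `mrs_cohort`, or a numeric matrix of cases
#'   by feature columns.
#' @param features a [feature_set()] giving the datapoint columns to use
#'   (cohort interface; for a matrix, all columns are used unless given).
#' @param labels class labels per row (matrix interface).
#' @param class_names ordered class names; defaults to the cohort's
#'   `class_labels` or the labels' order of appearance. Their order fixes the
#'   tie-break in classification.
#' @param eps ridge factor applied when regularization is needed.
#' @param cond_tol condition-number threshold that triggers the ridge.
#' @param ... passed between methods.
#' @return an object of class `"fisher_lda"`: selected `features`,
#'   `class_names`, per-class `class_means`, `within_scatter`,
#'   `between_scatter`, `projection` (features x 2), per-class latent
#'   `centroids`, eigenvalues `evals` and the `ridge` actually used.
#' @export
fit_fisher_lda <- function(x, ...) UseMethod("fit_fisher_lda")

#' @rdname fit_fisher_lda
#' @export
fit_fisher_lda.mrs_cohort <- function(x, features, class_names = x$class_labels, ...) {
  if (!all(x$meta$normalized))
    stop("fit_fisher_lda expects a normalized cohort", call. = FALSE)
  stopifnot(inherits(features, "feature_set"))
  m <- fit_fisher_lda(x$intensities[, features$index, drop = FALSE],
                      labels = x$meta$label, class_names = class_names, ...)
  m$features <- features
  m
}

#' @rdname fit_fisher_lda
#' @export
fit_fisher_lda.default <- function(x, labels, class_names = NULL,
                                   eps = 1e-6, cond_tol = 1e10, ...) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  class_names <- class_names %||% unique(labels)
  stopifnot(all(labels %in% class_names))
  sizes <- table(factor(labels, levels = class_names))
  if (any(sizes < 2L))
    stop("every class needs at least 2 cases to fit the scatter matrices",
         call. = FALSE)
  p <- ncol(x)
  n <- nrow(x)
  grand <- colMeans(x)
  Sw <- matrix(0, p, p)
  Sb <- matrix(0, p, p)
  means <- matrix(NA_real_, length(class_names), p,
                  dimnames = list(class_names, colnames(x)))
  for (cl in class_names) {
    xc <- x[labels == cl, , drop = FALSE]
    mc <- colMeans(xc)
    means[cl, ] <- mc
    cent <- sweep(xc, 2L, mc)
    Sw <- Sw + crossprod(cent)
    d <- mc - grand
    Sb <- Sb + nrow(xc) * tcrossprod(d)
  }
  ridge <- 0
  Swr <- Sw
  if (p == 1L) {
    if (Sw[1, 1] <= 0) { ridge <- eps; Swr <- Sw + eps }
  } else if (!is.finite(kappa(Sw)) || kappa(Sw) > cond_tol) {
    ridge <- eps * sum(diag(Sw)) / p
    if (ridge <= 0) ridge <- eps
    Swr <- Sw + diag(ridge, p)
  }
  eig <- eigen(solve(Swr, Sb))
  ord <- order(Re(eig$values), decreasing = TRUE)
  ndim <- min(length(class_names) - 1L, p)
  W <- Re(eig$vectors[, ord[seq_len(ndim)], drop = FALSE])
  # deterministic sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  centroids <- means %*% W
  structure(list(features = NULL, class_names = class_names,
                 class_sizes = as.integer(sizes), class_means = means,
                 within_scatter = Sw, between_scatter = Sb,
                 projection = W, centroids = centroids,
                 evals = Re(eig$values[ord[seq_len(ndim)]]), ridge = ridge),
            class = "fisher_lda")
}

#' @export
print.fisher_lda <- function(x, ...) {
  cat(sprintf("<fisher_lda> %d classes (%s), %d features, %d latent dims\n",
              length(x$class_names), paste(x$class_names, collapse = ", "),
              nrow(x$projection), ncol(x$projection)))
  if (x$ridge > 0) cat(sprintf("  ridge regularization: %.3g\n", x$ridge))
  invisible(x)
}

#' Classify spectra with a fitted Fisher LDA
#'
#' Projects the selected feature heights into the 2D latent space and assigns
#' the class of the nearest centroid (Euclidean distance). On an exact
#' distance tie the first class in the model's `class_names` order wins.
#'
#' @param model a fitted `"fisher_lda"`.
#' @param newdata a normalized [spectrum_record()], a normalized `mrs_cohort`,
#'   or a numeric matrix already restricted to the model's feature columns.
#' @return a data frame with columns `class` and the latent coordinates
#'   `ld1`, `ld2`, one row per spectrum (rownames = spectrum ids when
#'   available).
#' @export
classify <- function(model, newdata) {
  stopifnot(inherits(model, "fisher_lda"))
  if (inherits(newdata, "spectrum_record")) {
    if (!newdata$normalized)
      stop("classify expects UL2CA-normalized input", call. = FALSE)
    if (is.null(model$features))
      stop("model carries no feature set; supply a feature matrix", call. = FALSE)
    m <- matrix(newdata$intensities[model$features$index], 1L)
    rownames(m) <- newdata$spectrum_id
  } else if (inherits(newdata, "mrs_cohort")) {
    if (!all(newdata$meta$normalized))
      stop("classify expects UL2CA-normalized input", call. = FALSE)
    if (is.null(model$features))
      stop("model carries no feature set; supply a feature matrix", call. = FALSE)
    m <- newdata$intensities[, model$features$index, drop = FALSE]
  } else {
    m <- as.matrix(newdata)
    if (ncol(m) != nrow(model$projection))
      stop("feature count does not match the model", call. = FALSE)
  }
  z <- m %*% model$projection
  d2 <- outer(rowSums(z^2), rep(1, nrow(model$centroids))) -
    2 * z %*% t(model$centroids) +
    outer(rep(1, nrow(z)), rowSums(model$centroids^2))
  pred <- model$class_names[max.col(-d2, ties.method = "first")]
  out <- data.frame(class = pred,
                    ld1 = z[, 1L],
                    ld2 = if (ncol(z) >= 2L) z[, 2L] else NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- rownames(m)
  out
}

#' Confusion matrix of a fitted model on a cohort
#'
#' @param model a fitted `"fisher_lda"`.
#' @param cohort a normalized `mrs_cohort` (or matrix plus `labels`).
#' @param labels true labels (matrix interface).
#' @return a [confusion_matrix()]: rows = true class, columns = predicted.
#' @export
confusion <- function(model, cohort, labels = NULL) {
  if (inherits(cohort, "mrs_cohort")) {
    labels <- cohort$meta$label
  } else if (is.null(labels)) {
    stop("labels required when classifying a bare matrix", call. = FALSE)
  }
  pred <- classify(model, cohort)$class
  confusion_matrix(table(factor(labels, levels = model$class_names),
                         factor(pred, levels = model$class_names)),
                   model$class_names)
}

#' Construct a 3x3 (or CxC) confusion matrix
#'
#' @param counts square matrix of non-negative counts, rows = true class,
#'   columns = predicted class.
#' @param class_names class names in order.
#' @return an integer matrix of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(counts, class_names = rownames(counts)) {
  counts <- as.matrix(unclass(counts))
  if (nrow(counts) != ncol(counts)) stop("confusion matrix must be square", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(class_names)) class_names <- paste0("class", seq_len(nrow(counts)))
  dimnames(counts) <- list(true = class_names, predicted = class_names)
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

#' Serialize a fitted Fisher LDA to plain text
#'
#' Writes the model (features, scatter matrices, projection, centroids) as an
#' R expression via [dput()], re-readable with [read_fisher_model()], so a
#' trained classifier can be reused on new spectra without binary files.
#'
#' @param model a `"fisher_lda"`.
#' @param path output file.
#' @export
write_fisher_model <- function(model, path) {
  stopifnot(inherits(model, "fisher_lda"))
  payload <- unclass(model)
  payload$features <- if (!is.null(model$features)) as.data.frame(model$features)
  dput(payload, file = path,
       control = c("keepNA", "keepInteger", "niceNames", "showAttributes",
                   "hexNumeric"))
  invisible(NULL)
}

#' @rdname write_fisher_model
#' @return `read_fisher_model()` returns the restored `"fisher_lda"`.
#' @export
read_fisher_model <- function(path) {
  payload <- dget(path)
  if (!is.null(payload$features))
    payload$features <- structure(payload$features,
                                  class = c("feature_set", "data.frame"))
  structure(payload, class = "fisher_lda")
}
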