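# Correlation-based feature subset selection over spectral datapoints.

#' Construct a feature set
#'
#' An ordered set of selected spectral datapoints. `selection_order` runs
#' consecutively from 1 in the order the forward search admitted the
#' datapoints.
#'
#' @param indices 1-based datapoint indices in selection order.
#' @param ppm_axis chemical-shift axis the indices refer to; `NULL` when the
#'   features come from a bare matrix without an axis.
#' @param metabolite optional character vector of tentative resonance
#'   assignments.
#' @return a data frame of class `"feature_set"` with columns
#'   `selection_order`, `index`, `ppm`, `metabolite`.
#' @export
feature_set <- function(indices, ppm_axis = NULL, metabolite = NA_character_) {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("feature indices must be unique", call. = FALSE)
  if (any(indices < 1L))
    stop("feature indices must be positive", call. = FALSE)
  if (!is.null(ppm_axis) && any(indices > length(ppm_axis)))
    stop("feature index outside the ppm axis", call. = FALSE)
  structure(data.frame(selection_order = seq_along(indices),
                       index = indices,
                       ppm = if (is.null(ppm_axis)) NA_real_ else ppm_axis[indices],
                       metabolite = rep_len(as.character(metabolite), length(indices)),
                       stringsAsFactors = FALSE),
            class = c("feature_set", "data.frame"))
}

## ---- correlation measures ---------------------------------------------
#
# Two interchangeable feature-class / feature-feature correlation measures
# drive the CFS merit:
#   "su"      - Hall's original: symmetric uncertainty between features
#               discretized by the Fayyad-Irani MDL criterion on the class
#               labels. Uninformative datapoints collapse to a single bin
#               and drop out (correlation 0).
#   "pearson" - mean over the class levels of the absolute point-biserial
#               correlation (one-vs-rest encoding); feature-feature
#               correlation is absolute Pearson.

# entropy in bits of a count vector
count_entropy <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# rowwise entropy of a count matrix
row_entropy <- function(m) {
  tot <- rowSums(m)
  p <- m / ifelse(tot > 0, tot, 1)
  plp <- ifelse(p > 0, p * log2(p), 0)
  -rowSums(plp)
}

# Fayyad-Irani MDL-based supervised discretization of one numeric feature.
# Returns integer bin codes (1 = single bin when no cut is accepted).
mdl_discretize <- function(x, y) {
  y <- as.integer(factor(y))
  ord <- order(x)
  xv <- x[ord]
  yv <- y[ord]
  k_all <- max(y)
  cuts <- numeric(0)
  rec <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L) return(invisible())
    xx <- xv[lo:hi]
    yy <- yv[lo:hi]
    cand <- which(diff(xx) > 0)
    if (!length(cand)) return(invisible())
    tab <- vapply(seq_len(k_all), function(cl) cumsum(yy == cl), numeric(n))
    if (is.null(dim(tab))) tab <- matrix(tab, nrow = n)
    tot <- tab[n, ]
    Hs <- count_entropy(tot)
    left <- tab[cand, , drop = FALSE]
    right <- -sweep(left, 2L, tot)
    H1 <- row_entropy(left)
    H2 <- row_entropy(right)
    E <- (cand * H1 + (n - cand) * H2) / n
    j <- which.min(E)
    gain <- Hs - E[j]
    k0 <- sum(tot > 0)
    k1 <- sum(left[j, ] > 0)
    k2 <- sum(right[j, ] > 0)
    delta <- log2(3^k0 - 2) - (k0 * Hs - k1 * H1[j] - k2 * H2[j])
    if (gain <= (log2(n - 1) + delta) / n) return(invisible())
    i <- cand[j]
    cuts <<- c(cuts, (xv[lo + i - 1L] + xv[lo + i]) / 2)
    rec(lo, lo + i - 1L)
    rec(lo + i, hi)
    invisible()
  }
  rec(1L, length(xv))
  if (!length(cuts)) rep(1L, length(x))
  else findInterval(x, sort(cuts)) + 1L
}

# symmetric uncertainty between two integer-coded variables
symmetric_uncertainty <- function(a, b) {
  ka <- max(a)
  kb <- max(b)
  joint <- tabulate((b - 1L) * ka + a, nbins = ka * kb)
  ha <- count_entropy(tabulate(a, nbins = ka))
  hb <- count_entropy(tabulate(b, nbins = kb))
  if (ha + hb == 0) return(0)
  hab <- count_entropy(joint)
  2 * (ha + hb - hab) / (ha + hb)
}

# Pearson correlations of every column of x with y, with zero-variance
# columns (or constant y) mapped to correlation 0 instead of NA.
safe_cor <- function(x, y) {
  x <- as.matrix(x)
  n <- nrow(x)
  xc <- sweep(x, 2L, colMeans(x))
  yc <- y - mean(y)
  sx <- sqrt(colSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- rep(0, ncol(x))
  ok <- sx > 0 & sy > 0
  if (any(ok)) r[ok] <- drop(crossprod(xc[, ok, drop = FALSE], yc)) / (sx[ok] * sy)
  r
}

# class-supervised discretization of every column
discretize_matrix <- function(data, labels) {
  apply(data, 2L, mdl_discretize, y = labels)
}

# per-feature class correlation under either measure; `disc` may carry a
# precomputed discretized matrix for the "su" mode
feature_class_correlation <- function(data, labels, correlation = "su",
                                      disc = NULL) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) < 2L) stop("need at least 2 classes", call. = FALSE)
  if (correlation == "pearson") {
    rs <- vapply(lev, function(l) abs(safe_cor(data, as.numeric(labels == l))),
                 numeric(ncol(data)))
    if (is.null(dim(rs))) rs <- matrix(rs, nrow = ncol(data))
    return(rowMeans(rs))
  }
  disc <- disc %||% discretize_matrix(data, labels)
  ycode <- as.integer(factor(labels))
  vapply(seq_len(ncol(disc)), function(j)
    symmetric_uncertainty(disc[, j], ycode), numeric(1))
}

#' Merit of a feature subset under the CFS criterion
#'
#' Computes Hall's correlation-based feature-subset merit
#' \deqn{M_S = \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\,\bar r_{ff}}}}{
#'       M = k*rcf / sqrt(k + k(k-1)*rff)}
#' where \eqn{k} is the subset size, \eqn{\bar r_{cf}} the mean feature-class
#' correlation over the subset and \eqn{\bar r_{ff}} the mean pairwise
#' feature-feature correlation. Two correlation measures are available:
#' * `"su"` (default) - Hall's original formulation: symmetric uncertainty
#'   between variables discretized by the Fayyad-Irani MDL criterion on the
#'   class labels. Datapoints carrying no class information collapse to a
#'   single bin and get correlation 0 with everything.
#' * `"pearson"` - feature-class correlation is the mean over the class
#'   levels of the absolute point-biserial correlation of the one-vs-rest
#'   indicator; feature-feature correlation is absolute Pearson.
#'
#' A constant (zero-variance) feature contributes correlation 0 under either
#' measure.
#'
#' @param subset integer vector of datapoint (column) indices, non-empty.
#' @param data numeric matrix, cases in rows, datapoints in columns.
#' @param labels class label per row; at least two classes present.
#' @param correlation correlation measure, `"su"` or `"pearson"`.
#' @return the merit (scalar).
#' @export
cfs_merit <- function(subset, data, labels, correlation = c("su", "pearson")) {
  correlation <- match.arg(correlation)
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("empty feature subset", call. = FALSE)
  data <- as.matrix(data)
  k <- length(subset)
  sub <- data[, subset, drop = FALSE]
  disc <- if (correlation == "su") discretize_matrix(sub, labels)
  rcf <- mean(feature_class_correlation(sub, labels, correlation, disc = disc))
  if (k == 1L) return(rcf)
  rff_sum <- 0
  for (i in seq_len(k - 1L)) {
    if (correlation == "pearson") {
      rff_sum <- rff_sum +
        sum(abs(safe_cor(sub[, (i + 1L):k, drop = FALSE], sub[, i])))
    } else {
      rff_sum <- rff_sum + sum(vapply((i + 1L):k, function(j)
        symmetric_uncertainty(disc[, i], disc[, j]), numeric(1)))
    }
  }
  rff <- rff_sum / (k * (k - 1L) / 2)
  k * rcf / sqrt(k + k * (k - 1L) * rff)
}

#' Sequential forward feature selection with the CFS merit
#'
#' Greedy forward search over individual spectral datapoints: at each step the
#' datapoint whose addition maximizes the CFS merit of the augmented subset is
#' admitted. Ties in merit are broken towards the lower datapoint index
#' (higher ppm on the descending axis), making the trace deterministic. An
#' optional floating mode re-examines previously admitted datapoints after
#' each addition and drops one when that improves the merit of the smaller
#' subset (conditional exclusion).
#'
#' @param x a normalized training `mrs_cohort`, or a numeric matrix of cases
#'   by datapoints.
#' @param max_features number of datapoints to select (>= 1).
#' @param labels class labels per row (matrix interface only).
#' @param floating logical; enable conditional exclusion (off by default).
#' @param ... passed between methods.
#' @return a list with `features` (a [feature_set()]) and `trace` (a
#'   data frame of class `"merit_trace"` with columns `k`, `chosen_index`,
#'   `merit`).
#' @export
sffs_select <- function(x, max_features, ...) UseMethod("sffs_select")

#' @rdname sffs_select
#' @export
sffs_select.mrs_cohort <- function(x, max_features, floating = FALSE,
                                   correlation = c("su", "pearson"), ...) {
  if (!all(x$meta$normalized))
    stop("feature selection expects a normalized cohort", call. = FALSE)
  sffs_select(x$intensities, max_features, labels = x$meta$label,
              floating = floating, correlation = match.arg(correlation),
              ppm_axis = x$ppm)
}

#' @rdname sffs_select
#' @param ppm_axis optional axis used to annotate the returned feature set.
#' @export
sffs_select.default <- function(x, max_features, labels, floating = FALSE,
                                correlation = c("su", "pearson"),
                                ppm_axis = NULL, ...) {
  correlation <- match.arg(correlation)
  x <- as.matrix(x)
  p <- ncol(x)
  max_features <- as.integer(max_features)
  stopifnot(max_features >= 1L, max_features <= p)
  disc <- if (correlation == "su") discretize_matrix(x, labels)
  rcf_all <- feature_class_correlation(x, labels, correlation, disc = disc)
  cor_with <- function(j) {
    if (correlation == "pearson") {
      v <- abs(safe_cor(x, x[, j]))
    } else {
      v <- vapply(seq_len(p), function(i)
        symmetric_uncertainty(disc[, i], disc[, j]), numeric(1))
    }
    v[j] <- 0
    v
  }

  selected <- integer(0)
  trace <- data.frame(k = integer(), chosen_index = integer(), merit = numeric())
  # running sums for incremental merit evaluation
  sum_rcf <- 0                       # sum of r_cf over selected
  sum_rff <- 0                       # sum of |r_ff| over selected pairs
  rff_cand <- rep(0, p)              # sum of |cor(candidate, selected)|
  best_merit_at <- numeric(0)        # best merit seen for each subset size

  while (length(selected) < max_features) {
    k <- length(selected) + 1L
    cand <- setdiff(seq_len(p), selected)
    new_rcf <- (sum_rcf + rcf_all[cand]) / k
    denom <- sqrt(k + 2 * (sum_rff + rff_cand[cand]))
    merit <- k * new_rcf / denom
    best <- cand[which.max(merit)]       # first max = lowest index tie-break
    best_merit <- merit[match(best, cand)]
    if (!is.finite(best_merit) || best_merit <= 0) {
      warning("fewer informative datapoints than requested; returning ",
              length(selected), " features", call. = FALSE)
      break
    }
    selected <- c(selected, best)
    sum_rcf <- sum_rcf + rcf_all[best]
    sum_rff <- sum_rff + rff_cand[best]
    rff_cand <- rff_cand + cor_with(best)
    best_merit_at[k] <- best_merit
    trace <- rbind(trace, data.frame(k = k, chosen_index = best, merit = best_merit))

    if (floating && length(selected) > 2L) {
      repeat {
        k_now <- length(selected)
        drop_merit <- vapply(seq_len(k_now - 1L), function(j)
          cfs_merit(selected[-j], x, labels, correlation), numeric(1))
        j_best <- which.max(drop_merit)
        if (drop_merit[j_best] > best_merit_at[k_now - 1L] + 1e-12) {
          removed <- selected[j_best]
          selected <- selected[-j_best]
          sum_rcf <- sum_rcf - rcf_all[removed]
          rem_cor <- cor_with(removed)
          rff_cand <- rff_cand - rem_cor
          sum_rff <- sum_rff - sum(rem_cor[selected])
          best_merit_at[k_now - 1L] <- drop_merit[j_best]
        } else break
        if (length(selected) <= 2L) break
      }
    }
  }
  class(trace) <- c("merit_trace", "data.frame")
  list(features = feature_set(selected, ppm_axis),
       trace = trace)
}

#' Recommended cap on the number of selected features
#'
#' Rule of thumb for the classifier size: about one third of the number of
#' cases in the smallest class of the training set, never below 2.
#'
#' @param x an `mrs_cohort` (its records' labels are used), a vector of class
#'   labels, or a numeric vector of class sizes.
#' @return integer cap, `max(2, floor(min class size / 3))`.
#' @export
recommended_feature_cap <- function(x) {
  sizes <- if (inherits(x, "mrs_cohort")) table(x$meta$label)
           else if (is.numeric(x)) x
           else table(x)
  if (length(sizes) == 0L || any(sizes <= 0)) stop("empty class", call. = FALSE)
  max(2L, as.integer(floor(min(sizes) / 3)))
}
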