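# Univariate follow-up statistics on selected spectral features.

#' Distribution checks per class
#'
#' Kolmogorov-Smirnov normality test with Lilliefors correction (moments
#' estimated from the data) per class, and Levene's test of variance
#' homogeneity across classes. Classes with fewer than 4 values are skipped
#' with a warning (the Lilliefors statistic is undefined below that).
#'
#' @param values named list of numeric vectors, one per class.
#' @return a list with `ks` (data frame of per-class statistic and p-value)
#'   and `levene` (statistic, df and p-value across classes).
#' @export
normality_check <- function(values) {
  stopifnot(is.list(values), length(values) >= 2L)
  nm <- names(values) %||% paste0("class", seq_along(values))
  ks <- do.call(rbind, lapply(seq_along(values), function(i) {
    v <- values[[i]]
    if (length(v) < 4L || stats::sd(v) == 0) {
      warning("class '", nm[i], "' skipped in normality check (needs >= 4 ",
              "distinct values)", call. = FALSE)
      return(data.frame(class = nm[i], n = length(v),
                        ks_d = NA_real_, ks_p = NA_real_))
    }
    t <- nortest::lillie.test(v)
    data.frame(class = nm[i], n = length(v),
               ks_d = unname(t$statistic), ks_p = t$p.value)
  }))
  g <- factor(rep(nm, lengths(values)), levels = nm)
  lev <- car::leveneTest(unlist(values, use.names = FALSE), g, center = stats::median)
  list(ks = ks,
       levene = list(statistic = lev[1, "F value"],
                     df = unname(unlist(lev["Df"])),
                     p = lev[1, "Pr(>F)"]))
}

#' Kruskal-Wallis rank test across classes
#'
#' Rank-based H statistic with tie correction and chi-square p-value
#' (df = groups - 1). When every observation is identical the statistic is 0
#' with p = 1 by convention.
#'
#' @param values named list of numeric vectors, one per class (>= 2 non-empty
#'   groups).
#' @return a list with `h`, `df` and `p`.
#' @export
kruskal_wallis <- function(values) {
  stopifnot(is.list(values))
  values <- values[lengths(values) > 0L]
  if (length(values) < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  all_v <- unlist(values, use.names = FALSE)
  if (length(unique(all_v)) == 1L)
    return(list(h = 0, df = length(values) - 1L, p = 1))
  kt <- stats::kruskal.test(values)
  list(h = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's rank-based pairwise post-hoc comparisons
#'
#' Follow-up to the Kruskal-Wallis test: pairwise z statistics on mean ranks
#' with the tie correction, two-sided normal p-values, Bonferroni-adjusted
#' over the number of pairs.
#'
#' @param values named list of numeric vectors, one per class.
#' @param p_adjust adjustment method (any [stats::p.adjust()] method;
#'   default `"bonferroni"`).
#' @return data frame with one row per class pair: `z`, `p` (raw) and
#'   `p_adj`.
#' @export
posthoc_pairwise <- function(values, p_adjust = "bonferroni") {
  stopifnot(is.list(values))
  values <- values[lengths(values) > 0L]
  if (length(values) < 2L) stop("need at least 2 non-empty groups", call. = FALSE)
  nm <- names(values) %||% paste0("class", seq_along(values))
  all_v <- unlist(values, use.names = FALSE)
  n <- length(all_v)
  r <- rank(all_v)
  grp <- rep(seq_along(values), lengths(values))
  mean_rank <- tapply(r, grp, mean)
  sizes <- lengths(values)
  ties <- table(all_v)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(seq_along(values), 2L)
  rows <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    sigma <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[i] + 1 / sizes[j]))
    z <- if (sigma > 0) (mean_rank[i] - mean_rank[j]) / sigma else 0
    data.frame(class_a = nm[i], class_b = nm[j], z = unname(z),
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = p_adjust)
  rownames(out) <- NULL
  out
}

#' Median/IQR summary and tests for one selected feature
#'
#' Per-class median and 25th-75th percentile range of the UL2CA-normalized
#' peak height at one datapoint, plus the Kruskal-Wallis test and Dunn
#' post-hoc comparisons across the classes. The percentile convention is
#' linear interpolation between order statistics (R type 7) by default;
#' type 6 (the SPSS default) is available because interquartile ranges of
#' small classes depend visibly on the convention.
#'
#' @param cohort a normalized `mrs_cohort`.
#' @param feature a datapoint index, or a chemical shift in ppm when
#'   `by = "ppm"`.
#' @param by how to interpret `feature`.
#' @param split restrict to this split (`"train"` by default when assigned;
#'   `NULL` uses all records).
#' @param quantile_type percentile convention (7 or 6).
#' @return an object of class `"feature_summary"`: a list with the per-class
#'   summary data frame (`class`, `n`, `median`, `q25`, `q75`), `kw` (the
#'   Kruskal-Wallis result) and `posthoc`.
#' @export
summarize_feature <- function(cohort, feature, by = c("index", "ppm"),
                              split = NULL, quantile_type = 7) {
  by <- match.arg(by)
  stopifnot(inherits(cohort, "mrs_cohort"))
  if (!is.null(split)) cohort <- subset_cohort(cohort, split = split)
  idx <- if (by == "ppm") ppm_to_index(cohort$ppm, feature) else as.integer(feature)
  v <- cohort$intensities[, idx]
  values <- split(v, factor(cohort$meta$label, levels = cohort$class_labels))
  empty <- lengths(values) == 0L
  per_class <- do.call(rbind, lapply(names(values), function(cl) {
    x <- values[[cl]]
    if (length(x) == 0L)
      return(data.frame(class = cl, n = 0L, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_))
    q <- stats::quantile(x, c(.25, .5, .75), type = quantile_type, names = FALSE)
    data.frame(class = cl, n = length(x), median = q[2L], q25 = q[1L], q75 = q[3L])
  }))
  structure(list(index = idx, ppm = cohort$ppm[idx], per_class = per_class,
                 kw = kruskal_wallis(values[!empty]),
                 posthoc = posthoc_pairwise(values[!empty])),
            class = "feature_summary")
}

#' @export
print.feature_summary <- function(x, ...) {
  cat(sprintf("<feature_summary> datapoint %d (%.3f ppm), Kruskal-Wallis H = %.3g, p = %.3g\n",
              x$index, x$ppm, x$kw$h, x$kw$p))
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
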