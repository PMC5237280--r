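# Shared fixtures and independent oracles for the test suite.

# small random cohort built record by record (short axis for speed)
tiny_cohort <- function(n_animals = 6L, n_points = 96L, seed = 7L,
                        labels = c("non_infarcted", "acute", "subacute")) {
  withr::with_seed(seed, {
    axis <- default_ppm_axis(n_points)
    records <- list()
    contra <- character()
    si <- 0L
    for (a in seq_len(n_animals)) {
      lab <- labels[(a - 1L) %% length(labels) + 1L]
      ref_id <- sprintf("S%03d", si <- si + 1L)
      les_id <- sprintf("S%03d", si <- si + 1L)
      base <- abs(rnorm(n_points, 10, 2)) + 1
      records[[length(records) + 1L]] <- spectrum_record(
        base, axis, spectrum_id = ref_id, animal_id = sprintf("R%02d", a),
        region = "non_infarcted", label = "non_infarcted", hemisphere = "left")
      records[[length(records) + 1L]] <- spectrum_record(
        base + rnorm(n_points), axis, spectrum_id = les_id,
        animal_id = sprintf("R%02d", a), region = "infarcted",
        phase = "acute", label = lab, hemisphere = "right")
      contra[ref_id] <- ref_id
      contra[les_id] <- ref_id
    }
    mrs_cohort(records, class_labels = unique(c("non_infarcted", labels)),
               contralateral_map = contra)
  })
}

# class-labelled gaussian toy matrix
toy_classes <- function(n_per = 12L, p = 6L, shift = 3, seed = 1L) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * p), n_per),
               matrix(rnorm(n_per * p, shift), n_per),
               matrix(rnorm(n_per * p, 2 * shift), n_per))
    # only the first two columns carry the class signal
    x[, 3:p] <- rnorm(3 * n_per * (p - 2))
    list(x = x, labels = rep(c("a", "b", "c"), each = n_per))
  })
}

# ---- independent oracles -------------------------------------------------

# direct, loop-based evaluation of the CFS merit (no shared code with the
# package implementation beyond the correlation primitives' definitions)
oracle_cfs_merit <- function(subset, x, labels, correlation = "pearson") {
  k <- length(subset)
  if (correlation == "pearson") {
    lev <- unique(labels)
    rcf_one <- function(j) {
      rs <- sapply(lev, function(l) {
        v <- x[, j]
        if (stats::sd(v) == 0) return(0)
        abs(stats::cor(v, as.numeric(labels == l)))
      })
      mean(rs)
    }
    rff_one <- function(i, j) {
      if (stats::sd(x[, i]) == 0 || stats::sd(x[, j]) == 0) return(0)
      abs(stats::cor(x[, i], x[, j]))
    }
  } else {
    disc <- apply(x, 2L, mrspattern:::mdl_discretize, y = labels)
    ycode <- as.integer(factor(labels))
    rcf_one <- function(j) mrspattern:::symmetric_uncertainty(disc[, j], ycode)
    rff_one <- function(i, j) mrspattern:::symmetric_uncertainty(disc[, i], disc[, j])
  }
  rcf <- mean(sapply(subset, rcf_one))
  if (k == 1L) return(rcf)
  rff <- 0
  pairs <- utils::combn(subset, 2L)
  for (q in seq_len(ncol(pairs)))
    rff <- rff + rff_one(pairs[1, q], pairs[2, q])
  rff <- rff / ncol(pairs)
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# stepwise brute-force forward search using the oracle merit
oracle_greedy_path <- function(x, labels, k_max, correlation = "pearson") {
  sel <- integer(0)
  for (k in seq_len(k_max)) {
    cand <- setdiff(seq_len(ncol(x)), sel)
    merits <- sapply(cand, function(j)
      oracle_cfs_merit(c(sel, j), x, labels, correlation))
    sel <- c(sel, cand[which.max(merits)])
  }
  sel
}

# AUC by explicit concordant/discordant pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# permutation p-value for the Kruskal-Wallis statistic
oracle_kw_perm <- function(values, B = 10000L, seed = 99L) {
  obs <- kruskal_wallis(values)$h
  all_v <- unlist(values, use.names = FALSE)
  sizes <- lengths(values)
  withr::with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(B)) {
      perm <- sample(all_v)
      grp <- split(perm, rep(seq_along(sizes), sizes))
      if (kruskal_wallis(grp)$h >= obs - 1e-12) cnt <- cnt + 1L
    }
    cnt / B
  })
}

# confusion matrices reconstructed from the published training-set
# one-vs-rest count tables of the two classifiers
published_confusions <- function() {
  ie <- confusion_matrix(rbind(c(32, 0, 0),
                               c(0, 13, 0),
                               c(0, 2, 7)),
                         c("non_infarcted", "acute", "subacute"))
  br <- confusion_matrix(rbind(c(27, 4, 1),
                               c(12, 41, 1),
                               c(0, 0, 22)),
                         c("non_infarcted", "svz", "infarcted"))
  list(infarct_evolution = ie, brain_regions = br)
}
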