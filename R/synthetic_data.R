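# Synthetic three-class MRS cohort generator.
#
# Spectra are sums of Lorentzian/Gaussian resonances on the 0-4.5 ppm axis
# plus a smooth random baseline and (slightly smoothed) Gaussian noise,
# mimicking the net effect of line broadening on processed real-part spectra.
# Peak amplitudes are lognormal; their class-conditional medians are
# calibrated so that the class medians of the UL2CA-normalized peak heights
# at the diagnostic datapoints reproduce the published reference values of
# each study scenario.

peak_shape <- function(axis, center, fwhm, lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  if (lineshape == "lorentzian") {
    g <- fwhm / 2
    g^2 / ((axis - center)^2 + g^2)
  } else {
    exp(-4 * log(2) * (axis - center)^2 / fwhm^2)
  }
}

# Two-piece lognormal: lower and upper log-sd chosen so that median, 25th
# and 75th percentile are reproduced exactly (published IQRs are often
# asymmetric around the median in log space, which a single sigma cannot
# match).
lognormal_sigmas <- function(med, q25, q75) {
  z <- stats::qnorm(0.75)
  c(lo = log(med / q25) / z, hi = log(q75 / med) / z)
}

# draw from the two-piece lognormal with median `med`
rtwopiece_lognorm <- function(n, med, sig_lo, sig_hi) {
  z <- stats::rnorm(n)
  med * exp(ifelse(z < 0, sig_lo * z, sig_hi * z))
}

#' Default simulation configuration for a study scenario
#'
#' Builds the peak list and class-conditional amplitude distributions of one
#' of the two study designs:
#' * `infarct_evolution` - classes non-infarcted parenchyma / acute infarct /
#'   subacute infarct (48/20/14 spectra); diagnostic datapoints at 1.33 ppm
#'   (lactate + mobile-lipid methylene, modelled as two co-located
#'   components), 3.05 ppm (total creatine, peak centred at 3.03 ppm) and
#'   0.85 ppm (mobile-lipid methyl).
#' * `brain_regions` - classes non-infarcted parenchyma / SVZ / infarcted
#'   parenchyma (48/82/34 spectra); diagnostic datapoints at 3.05 and
#'   3.04 ppm (two datapoints of the same total-creatine resonance) and
#'   3.62 ppm (myoinositol).
#'
#' Amplitude medians are calibrated numerically (fixed-point over the peak
#' overlap) so the noiseless class templates reproduce the scenario's
#' published per-class medians at the diagnostic datapoints, in UL2CA units.
#' Amplitude spreads use a two-piece lognormal whose lower and upper log-sd
#' are fitted separately to the published 25th and 75th percentiles, so
#' median and both quartiles are reproduced exactly even when the published
#' interquartile range is asymmetric around the median.
#' Background resonances (NAA, glutamate/glutamine, choline, the 3.93 ppm
#' creatine line, ...) are class-invariant and jointly rescaled so the
#' noiseless non-infarcted template has Euclidean norm 100, consistent with
#' self-normalization of the reference tissue.
#'
#' @param scenario `"infarct_evolution"` or `"brain_regions"`.
#' @param n_points datapoints on the 0-4.5 ppm axis.
#' @param noise_sd standard deviation of the additive noise, UL2CA units.
#' @param noise_smooth moving-average width (datapoints) applied to the noise,
#'   emulating line-broadening of the processed spectra.
#' @param shift_jitter_sd per-spectrum global chemical-shift jitter (ppm).
#' @param baseline_amplitude standard deviation of the smooth random baseline.
#' @param class_sizes named or ordered integer vector of three class sizes.
#' @param seed default RNG seed carried by the config.
#' @return an object of class `"sim_config"`.
#' @export
default_config <- function(scenario = c("infarct_evolution", "brain_regions"),
                           n_points = 1383L, noise_sd = 0.2, noise_smooth = 3L,
                           shift_jitter_sd = 0.004, baseline_amplitude = 0.4,
                           class_sizes = NULL, seed = 42L) {
  scenario <- match.arg(scenario)
  axis <- default_ppm_axis(n_points)

  peaks <- data.frame(
    name      = c("ml_ch3", "lac", "ml_ch2", "naa", "glx", "tcr", "cho", "myo", "tcr_ch2"),
    ppm       = c(0.85, 1.33, 1.33, 2.02, 2.35, 3.03, 3.21, 3.62, 3.93),
    lineshape = c("gaussian", "lorentzian", "gaussian", "lorentzian", "gaussian",
                  "lorentzian", "lorentzian", "lorentzian", "lorentzian"),
    fwhm      = c(0.06, 0.03, 0.09, 0.035, 0.14, 0.076, 0.035, 0.05, 0.05),
    stringsAsFactors = FALSE)

  if (scenario == "infarct_evolution") {
    class_labels <- c("non_infarcted", "acute", "subacute")
    class_sizes <- class_sizes %||% c(non_infarcted = 48L, acute = 20L, subacute = 14L)
    groups <- list(
      list(peaks = c("lac", "ml_ch2"), at = 1.33,
           frac = rbind(c(.5, .5), c(.7, .3), c(.3, .7)),
           med = cbind(c(2.78, 7.39, 19.88)),
           q25 = cbind(c(2.38, 6.67, 10.38)),
           q75 = cbind(c(3.21, 8.90, 22.11))),
      list(peaks = "tcr", at = 3.05,
           med = cbind(c(3.83, 1.96, 2.01)),
           q25 = cbind(c(3.42, 1.63, 1.62)),
           q75 = cbind(c(4.18, 2.36, 2.31))),
      list(peaks = "ml_ch3", at = 0.85,
           med = cbind(c(3.32, 3.02, 12.30)),
           q25 = cbind(c(3.09, 2.33, 8.39)),
           q75 = cbind(c(3.95, 4.27, 15.52))))
    background <- c(naa = 12, glx = 5, cho = 4.5, myo = 2.7, tcr_ch2 = 2.8)
  } else {
    class_labels <- c("non_infarcted", "svz", "infarcted")
    class_sizes <- class_sizes %||% c(non_infarcted = 48L, svz = 82L, infarcted = 34L)
    groups <- list(
      list(peaks = "tcr", at = c(3.04, 3.05),
           med = rbind(c(6.92, 5.80), c(6.91, 5.74), c(2.84, 2.43)),
           q25 = rbind(c(6.47, 5.31), c(6.38, 5.26), c(1.95, 2.01)),
           q75 = rbind(c(7.37, 6.04), c(7.70, 6.44), c(3.80, 3.32))),
      list(peaks = "myo", at = 3.62,
           med = cbind(c(2.73, 3.45, 1.61)),
           q25 = cbind(c(2.31, 3.15, 1.41)),
           q75 = cbind(c(2.93, 3.91, 2.01))))
    background <- c(naa = 12, glx = 5, cho = 4.5, tcr_ch2 = 2.8,
                    lac = 2, ml_ch2 = 2, ml_ch3 = 3.3)
  }
  names(class_sizes) <- class_labels

  cfg <- structure(list(
    scenario = scenario, class_labels = class_labels,
    class_sizes = class_sizes, peaks = peaks, groups = groups,
    background = background, n_points = n_points, ppm = axis,
    noise_sd = noise_sd, noise_smooth = as.integer(noise_smooth),
    shift_jitter_sd = shift_jitter_sd,
    baseline_amplitude = baseline_amplitude, seed = seed),
    class = "sim_config")
  calibrate_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config '%s'> classes %s (n = %s), %d datapoints\n",
              x$scenario, paste(x$class_labels, collapse = "/"),
              paste(x$class_sizes, collapse = "/"), x$n_points))
  cat(sprintf("  noise sd %.3g, jitter sd %.3g ppm, baseline %.3g\n",
              x$noise_sd, x$shift_jitter_sd, x$baseline_amplitude))
  invisible(x)
}

#' Diagnostic chemical shifts of a scenario
#'
#' @param config a `"sim_config"`.
#' @return numeric vector of the datapoint chemical shifts (ppm) whose class
#'   medians the generator is calibrated to.
#' @export
diagnostic_ppm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  unlist(lapply(config$groups, `[[`, "at"), use.names = FALSE)
}

# Fill config$amp (classes x peaks apex-amplitude medians) and config$sig
# (lognormal log-sd) so noiseless class templates hit the group targets at
# the diagnostic datapoints and the reference-class template has norm 100.
calibrate_config <- function(cfg) {
  axis <- cfg$ppm
  pk <- cfg$peaks
  C <- length(cfg$class_labels)
  S <- vapply(seq_len(nrow(pk)), function(i)
    peak_shape(axis, pk$ppm[i], pk$fwhm[i], pk$lineshape[i]),
    numeric(length(axis)))
  colnames(S) <- pk$name

  amp_for_alpha <- function(alpha, class_i) {
    amps <- stats::setNames(rep(0, nrow(pk)), pk$name)
    amps[names(cfg$background)] <- alpha * cfg$background
    for (it in 1:40) {
      for (g in cfg$groups) {
        ti <- vapply(g$at, function(p) ppm_to_index(axis, p), integer(1))
        fr <- if (!is.null(g$frac)) g$frac[class_i, ] else rep(1, length(g$peaks))
        others <- setdiff(pk$name, g$peaks)
        resid <- g$med[class_i, ] -
          drop(S[ti, others, drop = FALSE] %*% amps[others])
        gshape <- drop(S[ti, g$peaks, drop = FALSE] %*% fr)
        A <- max(0, sum(resid * gshape) / sum(gshape^2))
        amps[g$peaks] <- A * fr
      }
    }
    amps
  }
  template_norm <- function(alpha) {
    amps <- amp_for_alpha(alpha, 1L)
    sqrt(sum((S %*% amps)^2))
  }
  alpha <- stats::uniroot(function(a) template_norm(a) - 100,
                          lower = 1e-3, upper = 100)$root
  amp <- t(vapply(seq_len(C), function(ci) amp_for_alpha(alpha, ci),
                  numeric(nrow(pk))))
  rownames(amp) <- cfg$class_labels

  dn <- list(cfg$class_labels, pk$name)
  sig_lo <- matrix(0.08, C, nrow(pk), dimnames = dn)
  sig_hi <- matrix(0.08, C, nrow(pk), dimnames = dn)
  for (g in cfg$groups)
    for (ci in seq_len(C)) {
      s <- vapply(seq_along(g$at), function(t)
        lognormal_sigmas(g$med[ci, t], g$q25[ci, t], g$q75[ci, t]), numeric(2))
      sig_lo[ci, g$peaks] <- mean(s["lo", ])
      sig_hi[ci, g$peaks] <- mean(s["hi", ])
    }
  cfg$background_scale <- alpha
  cfg$amp <- amp
  cfg$sig_lo <- sig_lo
  cfg$sig_hi <- sig_hi
  cfg
}

#' Simulate one spectrum
#'
#' Draws per-peak apex amplitudes from the class's two-piece lognormal
#' distributions,
#' evaluates the lineshapes on the (optionally jittered) axis, and adds a
#' smooth random baseline and noise. The result is an unnormalized record:
#' the whole spectrum is multiplied by the acquisition `gain`, which cancels
#' under UL2CA normalization when spectrum and reference share it.
#'
#' @param class class label (one of `config$class_labels`).
#' @param config a `"sim_config"`.
#' @param gain multiplicative acquisition gain (shared per animal).
#' @param global_shift global chemical-shift offset in ppm (default drawn
#'   from the config's jitter distribution).
#' @param spectrum_id,animal_id,region,phase,hemisphere,split metadata
#'   passed to [spectrum_record()].
#' @return an unnormalized [spectrum_record()].
#' @export
simulate_spectrum <- function(class, config, gain = 1,
                              global_shift = stats::rnorm(1, 0, config$shift_jitter_sd),
                              spectrum_id = "S001", animal_id = "R01",
                              region = "non_infarcted", phase = "healthy",
                              hemisphere = "n/a", split = "unassigned") {
  stopifnot(inherits(config, "sim_config"), class %in% config$class_labels)
  axis <- config$ppm
  pk <- config$peaks
  z <- stats::rnorm(nrow(pk))
  # co-located peaks of one diagnostic group share the draw so that the
  # distribution of their summed height matches the calibrated quantiles
  for (g in config$groups)
    if (length(g$peaks) > 1L) {
      gi <- match(g$peaks, pk$name)
      z[gi] <- z[gi[1L]]
    }
  sig <- ifelse(z < 0, config$sig_lo[class, ], config$sig_hi[class, ])
  amps <- config$amp[class, ] * exp(sig * z)
  y <- numeric(length(axis))
  for (i in seq_len(nrow(pk)))
    y <- y + amps[i] * peak_shape(axis, pk$ppm[i] + global_shift,
                                  pk$fwhm[i], pk$lineshape[i])
  y <- y + smooth_baseline(length(axis), config$baseline_amplitude) +
    smoothed_noise(length(axis), config$noise_sd, config$noise_smooth)
  spectrum_record(gain * y, axis, spectrum_id = spectrum_id,
                  animal_id = animal_id, region = region, phase = phase,
                  hemisphere = hemisphere, split = split, label = class,
                  normalized = FALSE)
}

# smooth random baseline: spline through a few random knots, sd-scaled
smooth_baseline <- function(n, amplitude, knots = 8L) {
  if (amplitude <= 0) return(numeric(n))
  kx <- seq(1, n, length.out = knots)
  ky <- stats::rnorm(knots)
  b <- stats::spline(kx, ky, xout = seq_len(n))$y
  s <- stats::sd(b)
  if (s == 0) return(numeric(n))
  b / s * amplitude
}

# iid Gaussian noise passed through a short moving average, then rescaled
smoothed_noise <- function(n, sd, width = 3L) {
  if (sd <= 0) return(numeric(n))
  e <- stats::rnorm(n + width - 1L)
  if (width > 1L) {
    e <- stats::filter(e, rep(1 / width, width), sides = 1)
    e <- as.numeric(e[width:(n + width - 1L)])
    e <- e / sqrt(1 / width)     # restore unit variance
  } else e <- e[seq_len(n)]
  e * sd
}

#' Simulate a full study cohort
#'
#' Emulates the study design: each "stroke" animal contributes its lesion-side
#' spectra (classes 2 and 3) plus one non-infarcted spectrum from the
#' contralateral hemisphere, which serves both as a member of the reference
#' class and as that animal's normalization reference; remaining reference
#' class spectra come from "healthy" animals contributing a homologous pair
#' (each hemisphere normalized to the other). Animal identifiers interleave
#' the groups so the chronological split preserves approximate class balance.
#' The chronological 2/3-1/3 split is applied before returning.
#'
#' @param config a `"sim_config"`.
#' @param seed RNG seed; defaults to the config's seed.
#' @param train_fraction passed to [chronological_split()].
#' @return an unnormalized `mrs_cohort` with contralateral map and splits
#'   assigned; the diagnostic ground truth (peak table) is attached as
#'   attribute `"ground_truth"`.
#' @export
simulate_cohort <- function(config, seed = config$seed, train_fraction = 2 / 3) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- config$class_sizes
  cls <- config$class_labels
  n1 <- sizes[1L]
  n23 <- sum(sizes[-1L])
  if (n1 < 1L) stop("the reference class must be non-empty", call. = FALSE)
  if (n23 < 1L) stop("need spectra outside the reference class", call. = FALSE)

  # lesion-side spectra in interleaved class order (balanced across ID order)
  lesion <- interleave_classes(rep(cls[2L], sizes[2L]), rep(cls[3L], sizes[3L]))
  n_stroke <- min(n23, n1)
  per_animal <- split(lesion, rep_len(seq_len(n_stroke), n23))
  n_healthy_spectra <- n1 - n_stroke
  n_healthy <- ceiling(n_healthy_spectra / 2)

  # animal roster interleaving stroke and healthy animals
  roster <- interleave_classes(rep("stroke", n_stroke), rep("healthy", n_healthy))

  with_seed(seed, {
    records <- list()
    contra <- character()
    si <- 0L
    stroke_i <- 0L
    healthy_left <- n_healthy_spectra
    next_id <- function() { si <<- si + 1L; sprintf("S%03d", si) }
    for (ai in seq_along(roster)) {
      animal <- sprintf("R%02d", ai)
      gain <- exp(stats::rnorm(1, 0, 0.3))
      if (roster[ai] == "stroke") {
        stroke_i <- stroke_i + 1L
        ref_id <- next_id()
        ref <- simulate_spectrum(cls[1L], config, gain = gain,
                                 spectrum_id = ref_id, animal_id = animal,
                                 region = "non_infarcted",
                                 phase = lesion_phase(config, per_animal[[stroke_i]][1L]),
                                 hemisphere = "left")
        records[[length(records) + 1L]] <- ref
        contra[ref_id] <- ref_id
        for (lab in per_animal[[stroke_i]]) {
          id <- next_id()
          records[[length(records) + 1L]] <-
            simulate_spectrum(lab, config, gain = gain, spectrum_id = id,
                              animal_id = animal,
                              region = lesion_region(config, lab),
                              phase = lesion_phase(config, lab),
                              hemisphere = "right")
          contra[id] <- ref_id
        }
      } else {
        k <- min(2L, healthy_left)
        healthy_left <- healthy_left - k
        ids <- replicate(k, next_id())
        for (j in seq_len(k))
          records[[length(records) + 1L]] <-
            simulate_spectrum(cls[1L], config, gain = gain,
                              spectrum_id = ids[j], animal_id = animal,
                              region = "non_infarcted", phase = "healthy",
                              hemisphere = c("left", "right")[j])
        contra[ids[1L]] <- ids[min(2L, k)]
        if (k == 2L) contra[ids[2L]] <- ids[1L]
      }
    }
    cohort <- mrs_cohort(records, class_labels = cls, contralateral_map = contra)
    cohort <- chronological_split(cohort, train_fraction)
    attr(cohort, "ground_truth") <- ground_truth_table(config)
    cohort
  })
}

# deterministic even interleave of two label vectors
interleave_classes <- function(a, b) {
  pos <- c(if (length(a)) (seq_along(a) - 0.5) / length(a),
           if (length(b)) (seq_along(b) - 0.5) / length(b))
  c(a, b)[order(pos)]
}

lesion_region <- function(config, label) {
  if (config$scenario == "brain_regions") label else "infarcted"
}

lesion_phase <- function(config, label) {
  if (config$scenario == "infarct_evolution") label else "subacute"
}

# diagnostic ground truth for recovery experiments
ground_truth_table <- function(config) {
  rows <- lapply(config$groups, function(g)
    data.frame(ppm = g$at,
               peaks = paste(g$peaks, collapse = "+"),
               stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
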