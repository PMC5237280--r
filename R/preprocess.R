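# UL2CA normalization and chemical-shift referencing.

#' Unit-length normalization to the contralateral area (UL2CA)
#'
#' Divides every datapoint of a spectrum by the Euclidean norm, over the whole
#' 0-4.5 ppm window, of the same animal's contralateral (non-infarcted)
#' spectrum, and multiplies by 100. A spectrum normalized against itself has
#' Euclidean norm exactly 100 afterwards, and the transform is invariant to
#' any joint rescaling of spectrum and reference, so the arbitrary acquisition
#' gain cancels.
#'
#' @param spectrum a [spectrum_record()], not yet normalized.
#' @param contralateral the reference [spectrum_record()] on the same axis;
#'   defaults to the spectrum itself (self-normalization for records that are
#'   the designated reference).
#' @return a list with components `spectrum` (the normalized record) and
#'   `report` (a one-row data frame with `spectrum_id`, `reference_id` and the
#'   `norm_constant` used).
#' @export
ul2ca_normalize <- function(spectrum, contralateral = spectrum) {
  stopifnot(inherits(spectrum, "spectrum_record"),
            inherits(contralateral, "spectrum_record"))
  if (spectrum$normalized || contralateral$normalized)
    stop("ul2ca_normalize expects unnormalized spectra", call. = FALSE)
  if (!isTRUE(all.equal(spectrum$ppm_axis, contralateral$ppm_axis)))
    stop("spectrum and contralateral reference must share the ppm axis",
         call. = FALSE)
  nc <- sqrt(sum(contralateral$intensities^2))
  if (!is.finite(nc) || nc <= 0)
    stop("degenerate contralateral reference: zero Euclidean norm", call. = FALSE)
  out <- spectrum
  out$intensities <- spectrum$intensities / nc * 100
  out$normalized <- TRUE
  report <- data.frame(spectrum_id = spectrum$spectrum_id,
                       reference_id = contralateral$spectrum_id,
                       norm_constant = nc, stringsAsFactors = FALSE)
  list(spectrum = out, report = report)
}

#' Normalize a whole cohort via its contralateral map
#'
#' Applies [ul2ca_normalize()] to every record, using the cohort's
#' contralateral map to find each record's reference spectrum. Records without
#' a map entry are normalized to themselves only if they are non-infarcted
#' (the designated reference tissue); otherwise an error is raised.
#'
#' @param cohort an unnormalized `mrs_cohort`.
#' @return the cohort with UL2CA-scaled intensities; the per-record
#'   normalization report is attached as attribute `"norm_report"`.
#' @export
normalize_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "mrs_cohort"))
  if (any(cohort$meta$normalized))
    stop("cohort already contains normalized records", call. = FALSE)
  ids <- cohort$meta$spectrum_id
  ref_ids <- unname(cohort$contralateral[ids])
  no_ref <- is.na(ref_ids)
  if (any(no_ref & cohort$meta$region != "non_infarcted"))
    stop("records without a contralateral reference: ",
         paste(ids[no_ref & cohort$meta$region != "non_infarcted"], collapse = ", "),
         call. = FALSE)
  ref_ids[no_ref] <- ids[no_ref]
  ri <- match(ref_ids, ids)
  norms <- sqrt(rowSums(cohort$intensities[ri, , drop = FALSE]^2))
  if (any(!is.finite(norms) | norms <= 0))
    stop("degenerate contralateral reference: zero Euclidean norm", call. = FALSE)
  out <- cohort
  out$intensities <- cohort$intensities / norms * 100
  out$meta$normalized <- TRUE
  attr(out, "norm_report") <- data.frame(
    spectrum_id = ids, reference_id = ref_ids, norm_constant = norms,
    stringsAsFactors = FALSE)
  out
}

#' Reference a spectrum to the total-creatine peak at 3.03 ppm
#'
#' Finds the local intensity maximum inside a search window around 3.03 ppm
#' and shifts the spectrum by a whole number of datapoints (no interpolation,
#' so intensity values are preserved exactly) so that this maximum falls on
#' the datapoint nearest 3.03 ppm. Points shifted in from outside the window
#' repeat the edge value. If no local maximum exists in the window (e.g. a
#' flat spectrum) the record is returned unshifted with a warning.
#'
#' @param spectrum an unnormalized [spectrum_record()].
#' @param target reference chemical shift in ppm (total creatine, 3.03).
#' @param window half-width of the search window in ppm.
#' @return the referenced record; the applied shift is attached as attributes
#'   `"shift_points"` (datapoints, positive towards lower index) and
#'   `"shift_ppm"`.
#' @export
reference_to_tcr <- function(spectrum, target = 3.03, window = 0.15) {
  stopifnot(inherits(spectrum, "spectrum_record"))
  axis <- spectrum$ppm_axis
  y <- spectrum$intensities
  in_win <- which(abs(axis - target) <= window)
  if (length(in_win) < 3L)
    stop("search window contains fewer than 3 datapoints", call. = FALSE)
  yw <- y[in_win]
  pk <- in_win[which.max(yw)]
  # demand a genuine local maximum: strictly above the window floor and not
  # below either neighbour
  is_peak <- diff(range(yw)) > 0 &&
    pk > 1L && pk < length(y) && y[pk] >= y[pk - 1L] && y[pk] >= y[pk + 1L]
  if (!is_peak) {
    warning("no local maximum near ", target,
            " ppm; spectrum returned unshifted", call. = FALSE)
    attr(spectrum, "shift_points") <- 0L
    attr(spectrum, "shift_ppm") <- 0
    return(spectrum)
  }
  anchor <- ppm_to_index(axis, target)
  k <- anchor - pk   # move peak by k datapoints
  out <- spectrum
  out$intensities <- shift_pad(y, k)
  attr(out, "shift_points") <- k
  attr(out, "shift_ppm") <- axis[anchor] - axis[pk]
  out
}

# integer shift with edge padding; positive k moves content to higher indices
shift_pad <- function(y, k) {
  n <- length(y)
  if (k == 0L) return(y)
  if (k > 0L) c(rep(y[1L], k), y[seq_len(n - k)])
  else c(y[(-k + 1L):n], rep(y[n], -k))
}
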