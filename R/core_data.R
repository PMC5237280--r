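# Core containers for single-voxel MRS spectra and cohorts.

MRS_REGIONS     <- c("non_infarcted", "svz", "infarcted")
MRS_PHASES      <- c("healthy", "acute", "subacute")
MRS_HEMISPHERES <- c("left", "right", "n/a")
MRS_SPLITS      <- c("train", "test", "unassigned")

#' Default chemical-shift axis
#'
#' The stored spectral window runs from 4.5 down to 0 ppm, digitized with 1383
#' datapoints and kept in NMR display order (descending ppm, index 1 = 4.5 ppm;
#' all indices in this package are 1-based).
#'
#' @param n number of datapoints.
#' @param ppm_max,ppm_min window limits in ppm.
#' @return numeric vector of length `n`, strictly decreasing.
#' @export
default_ppm_axis <- function(n = 1383L, ppm_max = 4.5, ppm_min = 0) {
  stopifnot(n >= 2, ppm_max > ppm_min)
  seq(ppm_max, ppm_min, length.out = n)
}

#' Construct a single-spectrum record
#'
#' Holds one processed real-part spectrum together with its cohort metadata.
#' Intensities are in arbitrary units before normalization and in UL2CA units
#' (percent of the contralateral Euclidean norm) afterwards.
#'
#' @param intensities numeric vector of real-part intensities.
#' @param ppm_axis chemical-shift axis, same length, strictly monotone,
#'   within \[0, 4.5\] ppm.
#' @param spectrum_id,animal_id identifiers (animal ids should contain a
#'   numeric part if chronological splitting is to be used).
#' @param region one of `"non_infarcted"`, `"svz"`, `"infarcted"`.
#' @param phase one of `"healthy"`, `"acute"`, `"subacute"`.
#' @param hemisphere one of `"left"`, `"right"`, `"n/a"`.
#' @param label class label used for classification; defaults to `region`.
#' @param split one of `"train"`, `"test"`, `"unassigned"`.
#' @param normalized logical; `TRUE` once UL2CA normalization was applied.
#' @return an object of class `"spectrum_record"`.
#' @export
spectrum_record <- function(intensities, ppm_axis = default_ppm_axis(length(intensities)),
                            spectrum_id, animal_id,
                            region = "non_infarcted", phase = "healthy",
                            hemisphere = "n/a", label = region,
                            split = "unassigned", normalized = FALSE) {
  rec <- structure(list(
    spectrum_id = as.character(spectrum_id),
    animal_id   = as.character(animal_id),
    region      = match.arg(region, MRS_REGIONS),
    phase       = match.arg(phase, MRS_PHASES),
    hemisphere  = match.arg(hemisphere, MRS_HEMISPHERES),
    label       = as.character(label),
    split       = match.arg(split, MRS_SPLITS),
    ppm_axis    = as.numeric(ppm_axis),
    intensities = as.numeric(intensities),
    normalized  = isTRUE(normalized)
  ), class = "spectrum_record")
  validate_spectrum_record(rec)
}

validate_spectrum_record <- function(rec) {
  if (length(rec$ppm_axis) != length(rec$intensities))
    stop("ppm axis and intensity vector differ in length", call. = FALSE)
  d <- diff(rec$ppm_axis)
  if (!(all(d > 0) || all(d < 0)))
    stop("ppm axis must be strictly monotone", call. = FALSE)
  if (min(rec$ppm_axis) < -1e-9 || max(rec$ppm_axis) > 4.5 + 1e-9)
    stop("ppm axis must lie within [0, 4.5] ppm", call. = FALSE)
  if (anyNA(rec$intensities))
    stop("intensities contain NA", call. = FALSE)
  rec
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record %s> animal %s, %s/%s, label '%s', split %s\n",
              x$spectrum_id, x$animal_id, x$region, x$phase, x$label, x$split))
  cat(sprintf("  %d datapoints, %.3g-%.3g ppm, %s\n",
              length(x$intensities), min(x$ppm_axis), max(x$ppm_axis),
              if (x$normalized) "UL2CA-normalized" else "unnormalized"))
  invisible(x)
}

#' Construct an MRS cohort
#'
#' A cohort bundles spectra sharing one chemical-shift axis with the class
#' structure of the study: an ordered set of three class labels and a map from
#' each spectrum to the same animal's contralateral (non-infarcted) reference
#' spectrum used for UL2CA normalization.
#'
#' @param records list of [spectrum_record()] objects on a common axis.
#' @param class_labels ordered character vector of class names; defaults to
#'   the labels in order of first appearance.
#' @param contralateral_map named character vector mapping `spectrum_id` to
#'   the reference `spectrum_id` (a record may reference itself).
#' @return an object of class `"mrs_cohort"` with components `intensities`
#'   (spectra-by-datapoints matrix), `ppm`, `meta` (per-spectrum data frame),
#'   `class_labels` and `contralateral`.
#' @export
mrs_cohort <- function(records, class_labels = NULL, contralateral_map = character()) {
  stopifnot(is.list(records))
  if (length(records) == 0L) {
    x <- structure(list(
      intensities = matrix(numeric(0), 0L, length(default_ppm_axis())),
      ppm = default_ppm_axis(), meta = empty_cohort_meta(),
      class_labels = class_labels %||% character(),
      contralateral = character()), class = "mrs_cohort")
    return(x)
  }
  for (r in records) stopifnot(inherits(r, "spectrum_record"))
  ppm <- records[[1L]]$ppm_axis
  for (r in records)
    if (!isTRUE(all.equal(r$ppm_axis, ppm)))
      stop("all records in a cohort must share the ppm axis", call. = FALSE)
  ints <- do.call(rbind, lapply(records, `[[`, "intensities"))
  meta <- do.call(rbind, lapply(records, function(r)
    data.frame(spectrum_id = r$spectrum_id, animal_id = r$animal_id,
               region = r$region, phase = r$phase, hemisphere = r$hemisphere,
               label = r$label, split = r$split, normalized = r$normalized,
               stringsAsFactors = FALSE)))
  rownames(ints) <- meta$spectrum_id
  rownames(meta) <- NULL
  x <- structure(list(
    intensities = ints, ppm = ppm, meta = meta,
    class_labels = class_labels %||% unique(meta$label),
    contralateral = contralateral_map), class = "mrs_cohort")
  validate_cohort(x)
}

empty_cohort_meta <- function() {
  data.frame(spectrum_id = character(), animal_id = character(),
             region = character(), phase = character(), hemisphere = character(),
             label = character(), split = character(), normalized = logical(),
             stringsAsFactors = FALSE)
}

new_mrs_cohort <- function(intensities, ppm, meta, class_labels, contralateral = character()) {
  rownames(intensities) <- meta$spectrum_id
  rownames(meta) <- NULL
  x <- structure(list(intensities = intensities, ppm = ppm, meta = meta,
                      class_labels = class_labels, contralateral = contralateral),
                 class = "mrs_cohort")
  validate_cohort(x)
}

validate_cohort <- function(x) {
  stopifnot(inherits(x, "mrs_cohort"))
  if (nrow(x$intensities) != nrow(x$meta))
    stop("intensity matrix and metadata disagree in spectrum count", call. = FALSE)
  if (ncol(x$intensities) != length(x$ppm))
    stop("intensity matrix and ppm axis disagree in datapoint count", call. = FALSE)
  if (anyDuplicated(x$meta$spectrum_id))
    stop("duplicate spectrum_id in cohort", call. = FALSE)
  bad <- setdiff(unique(x$meta$label), x$class_labels)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(x$contralateral)) {
    missing_ref <- setdiff(unname(x$contralateral), x$meta$spectrum_id)
    if (length(missing_ref))
      stop("contralateral map points at unknown spectrum_id: ",
           paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  x
}

#' @export
print.mrs_cohort <- function(x, ...) {
  cat(sprintf("<mrs_cohort> %d spectra x %d datapoints (%.3g-%.3g ppm)\n",
              nrow(x$intensities), ncol(x$intensities),
              min(x$ppm), max(x$ppm)))
  if (nrow(x$meta)) {
    tab <- table(factor(x$meta$label, levels = x$class_labels),
                 factor(x$meta$split, levels = MRS_SPLITS))
    print(tab)
  }
  invisible(x)
}

#' Number of spectra in a cohort
#' @param x an `mrs_cohort`.
#' @export
n_spectra <- function(x) nrow(x$intensities)

#' Extract one spectrum from a cohort
#'
#' @param cohort an `mrs_cohort`.
#' @param spectrum_id identifier of the record to extract.
#' @return a [spectrum_record()].
#' @export
get_record <- function(cohort, spectrum_id) {
  i <- match(spectrum_id, cohort$meta$spectrum_id)
  if (is.na(i)) stop("unknown spectrum_id: ", spectrum_id, call. = FALSE)
  m <- cohort$meta[i, ]
  spectrum_record(cohort$intensities[i, ], cohort$ppm,
                  spectrum_id = m$spectrum_id, animal_id = m$animal_id,
                  region = m$region, phase = m$phase, hemisphere = m$hemisphere,
                  label = m$label, split = m$split, normalized = m$normalized)
}

#' Subset a cohort
#'
#' @param cohort an `mrs_cohort`.
#' @param i row indices, logical mask, or spectrum ids.
#' @param split alternatively, keep only records of this split
#'   (`"train"` or `"test"`).
#' @return the reduced `mrs_cohort` (class labels and contralateral map are
#'   carried over; map entries pointing outside the subset are dropped).
#' @export
subset_cohort <- function(cohort, i = NULL, split = NULL) {
  stopifnot(inherits(cohort, "mrs_cohort"))
  if (!is.null(split)) {
    split <- match.arg(split, MRS_SPLITS)
    i <- which(cohort$meta$split == split)
  } else if (is.character(i)) {
    i <- match(i, cohort$meta$spectrum_id)
  } else if (is.logical(i)) {
    i <- which(i)
  }
  meta <- cohort$meta[i, , drop = FALSE]
  keep <- cohort$contralateral[names(cohort$contralateral) %in% meta$spectrum_id]
  keep <- keep[keep %in% meta$spectrum_id]
  new_mrs_cohort(cohort$intensities[i, , drop = FALSE], cohort$ppm, meta,
                 cohort$class_labels, keep)
}

#' Map a chemical shift to its nearest datapoint index
#'
#' @param axis ppm axis (monotone).
#' @param target chemical shift in ppm; must lie within the axis range.
#' @return 1-based index of the axis value nearest `target`; on an exact
#'   midpoint tie the datapoint at the lower ppm wins.
#' @export
ppm_to_index <- function(axis, target) {
  stopifnot(is.numeric(axis), length(axis) >= 1, is.numeric(target), length(target) == 1)
  if (target < min(axis) - 1e-12 || target > max(axis) + 1e-12)
    stop(sprintf("target %.4g ppm outside axis range [%.4g, %.4g]",
                 target, min(axis), max(axis)), call. = FALSE)
  d <- abs(axis - target)
  cand <- which(d <= min(d) + 1e-12)
  cand[which.min(axis[cand])]
}

#' Read a cohort from delimited text files
#'
#' The on-disk layout mirrors processed-spectrum ASCII exports: one spectrum
#' per row in the intensity table (first column `spectrum_id`), metadata in a
#' separate delimited file keyed by `spectrum_id`. The delimiter (tab, comma
#' or semicolon) is sniffed from the first line of each file. If the table
#' header carries numeric ppm values they define the axis; otherwise an
#' evenly spaced axis over \[0, 4.5\] ppm is synthesized from the row length.
#'
#' @param table_path path of the intensity table.
#' @param metadata_path path of the metadata table; columns `spectrum_id`,
#'   `animal_id`, `region`, `phase`, `hemisphere`, `label`, `split`,
#'   `normalized`, `contralateral_id` (missing metadata columns fall back to
#'   defaults; a missing contralateral reference is flagged with a warning).
#' @param class_labels optional declared class order; labels found outside it
#'   raise a validation error.
#' @return an [mrs_cohort()].
#' @export
read_cohort <- function(table_path, metadata_path, class_labels = NULL) {
  sep_t <- sniff_delim(table_path)
  nf <- utils::count.fields(table_path, sep = sep_t, quote = "\"")
  if (length(unique(nf)) > 1L)
    stop("format error: rows of ", table_path, " have differing datapoint counts",
         call. = FALSE)
  tab <- utils::read.table(table_path, header = TRUE, sep = sep_t,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(tab) >= 2L) stop("format error: intensity table needs id + data columns",
                             call. = FALSE)
  ids <- as.character(tab[[1L]])
  ints <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(ints) <- "double"
  if (anyNA(ints))
    stop("format error: non-numeric intensity values in ", table_path, call. = FALSE)
  hdr <- suppressWarnings(as.numeric(colnames(tab)[-1L]))
  ppm <- if (!anyNA(hdr)) hdr else default_ppm_axis(ncol(ints))

  sep_m <- sniff_delim(metadata_path)
  meta_in <- utils::read.table(metadata_path, header = TRUE, sep = sep_m,
                               stringsAsFactors = FALSE)
  if (!"spectrum_id" %in% names(meta_in))
    stop("metadata must contain a spectrum_id column", call. = FALSE)
  m <- match(ids, meta_in$spectrum_id)
  if (anyNA(m))
    stop("metadata missing for spectra: ",
         paste(ids[is.na(m)], collapse = ", "), call. = FALSE)
  meta_in <- meta_in[m, , drop = FALSE]
  col <- function(nm, default) {
    if (nm %in% names(meta_in)) as.character(meta_in[[nm]]) else
      rep(default, length(ids))
  }
  meta <- data.frame(
    spectrum_id = ids,
    animal_id   = col("animal_id", NA_character_),
    region      = col("region", "non_infarcted"),
    phase       = col("phase", "healthy"),
    hemisphere  = col("hemisphere", "n/a"),
    label       = col("label", NA_character_),
    split       = col("split", "unassigned"),
    normalized  = as.logical(col("normalized", "FALSE")),
    stringsAsFactors = FALSE)
  if (anyNA(meta$label)) meta$label <- meta$region
  if (!is.null(class_labels)) {
    bad <- setdiff(unique(meta$label), class_labels)
    if (length(bad))
      stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  contra <- character()
  if ("contralateral_id" %in% names(meta_in)) {
    cid <- as.character(meta_in$contralateral_id)
    ok <- !is.na(cid) & nzchar(cid)
    contra <- stats::setNames(cid[ok], ids[ok])
  }
  need <- setdiff(ids[!meta$normalized], names(contra))
  if (length(contra) && length(need))
    warning("records without a contralateral reference: ",
            paste(need, collapse = ", "), call. = FALSE)
  new_mrs_cohort(ints, ppm, meta, class_labels %||% unique(meta$label), contra)
}

#' Write a cohort to delimited text files
#'
#' Inverse of [read_cohort()]: intensities (with the ppm axis as numeric
#' column header) and metadata go to two delimited files, losslessly up to
#' float round-trip.
#'
#' @param cohort an `mrs_cohort`.
#' @param table_path,metadata_path output paths.
#' @param sep field delimiter (default tab).
#' @export
write_cohort <- function(cohort, table_path, metadata_path, sep = "\t") {
  stopifnot(inherits(cohort, "mrs_cohort"))
  hdr <- c("spectrum_id", sprintf("%.10f", cohort$ppm))
  con <- file(table_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(hdr, collapse = sep), con)
  if (n_spectra(cohort) > 0L) {
    body <- vapply(seq_len(n_spectra(cohort)), function(i)
      paste(c(cohort$meta$spectrum_id[i],
              sprintf("%.12g", cohort$intensities[i, ])), collapse = sep),
      character(1))
    writeLines(body, con)
  }
  meta <- cohort$meta
  meta$contralateral_id <- unname(cohort$contralateral[meta$spectrum_id])
  utils::write.table(meta, metadata_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}

sniff_delim <- function(path) {
  l1 <- readLines(path, n = 1L, warn = FALSE)
  if (length(l1) == 0L) return("\t")
  counts <- c("\t" = lengths(regmatches(l1, gregexpr("\t", l1, fixed = TRUE))),
              ","  = lengths(regmatches(l1, gregexpr(",",  l1, fixed = TRUE))),
              ";"  = lengths(regmatches(l1, gregexpr(";",  l1, fixed = TRUE))))
  if (all(counts == 0L)) return("\t")
  names(counts)[which.max(counts)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# restore RNG state after a seeded computation
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
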