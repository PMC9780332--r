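# Per-cell condensate calling: candidate foci are pixels at least
# `threshold` times brighter than the cytoplasm reference taken at the
# midpoint of the cell's medial axis; a cell has condensates iff at least
# one 8-connected focus of `min_focus_px` pixels survives. Strain-level
# statistics: fraction of condensate-containing cells, the 0.11 cutoff, and
# the 1.05-2.00 threshold sweep.

cell_rows_cols <- function(cell) {
  nr <- cell$image_dim[1]
  idx <- cell$mask_idx
  cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
}

#' Cytoplasm reference intensity at the cell midpoint
#'
#' Median (or mean) intensity over the intersection of the cell mask with a
#' disk centred at the midpoint of the medial axis. The midpoint sits far
#' from polar condensates, so the reference reads the dilute cytoplasm.
#'
#' @param cell A `cell_region`.
#' @param img The [micrograph()] (or matrix) the cell was segmented from.
#' @param disk_radius_px Disk radius in px (default 3).
#' @param stat `"median"` (robust default) or `"mean"`.
#' @return Reference intensity (scalar).
#' @export
midpoint_reference <- function(cell, img, disk_radius_px = 3,
                               stat = c("median", "mean")) {
  stat <- match.arg(stat)
  px <- as_pixels(img)
  ax <- cell$medial_axis
  if (is.null(ax) || nrow(ax) < 3)
    ct_stop("medial axis has fewer than 3 points", "degenerate_cell")
  mid <- ax[ceiling(nrow(ax) / 2), ] + 1  # to 1-based
  rc <- cell_rows_cols(cell)
  d <- sqrt((rc[, 1] - mid[1])^2 + (rc[, 2] - mid[2])^2)
  sel <- d <= disk_radius_px
  if (!any(sel)) ct_stop("midpoint disk does not intersect the cell mask",
                         "degenerate_cell")
  vals <- px[cell$mask_idx[sel]]
  if (stat == "median") median(vals) else mean(vals)
}

#' Detect condensates in one cell
#'
#' Pixels inside the cell whose intensity is at least `threshold` times the
#' midpoint cytoplasm reference form candidate foci (8-connected); foci
#' smaller than `min_focus_px` pixels are discarded. The enrichment ratio
#' is the mean intensity over surviving focus pixels divided by the mean
#' over the remaining interior -- an in-cell estimate of the
#' condensed/dilute partition ratio.
#'
#' @inheritParams midpoint_reference
#' @param threshold Intensity ratio (> 1); default 1.20, i.e. condensate
#'   pixels at least 20% brighter than the cytoplasm.
#' @param min_focus_px Minimum focus size in pixels (default 4), which
#'   suppresses single-pixel noise.
#' @return A `condensate_call` with fields `label`, `reference_intensity`,
#'   `foci` (list of pixel indices and mean intensities), `has_condensate`,
#'   `enrichment_ratio` (NA when no focus survives) and `threshold_used`.
#' @export
detect_condensates <- function(cell, img, threshold = 1.20,
                               min_focus_px = 4L, disk_radius_px = 3,
                               stat = "median") {
  if (threshold <= 1.0)
    ct_stop("threshold must exceed 1.0", "invalid_argument")
  px <- as_pixels(img)
  ref <- midpoint_reference(cell, img, disk_radius_px, stat)
  rc <- cell_rows_cols(cell)
  vals <- px[cell$mask_idx]
  hot <- vals >= threshold * ref
  foci <- list()
  if (any(hot)) {
    r0 <- min(rc[, 1]); c0 <- min(rc[, 2])
    sub <- matrix(FALSE, max(rc[, 1]) - r0 + 1, max(rc[, 2]) - c0 + 1)
    sub[cbind(rc[hot, 1] - r0 + 1, rc[hot, 2] - c0 + 1)] <- TRUE
    lab <- .label8_cpp(sub)
    labs <- lab[cbind(rc[hot, 1] - r0 + 1, rc[hot, 2] - c0 + 1)]
    hot_idx <- cell$mask_idx[hot]
    for (l in seq_len(max(lab))) {
      fi <- hot_idx[labs == l]
      if (length(fi) >= min_focus_px) {
        foci[[length(foci) + 1]] <- list(pixels = fi,
                                         mean_intensity = mean(px[fi]))
      }
    }
  }
  has <- length(foci) > 0
  enrich <- NA_real_
  if (has) {
    fpix <- unlist(lapply(foci, `[[`, "pixels"))
    rest <- setdiff(cell$mask_idx, fpix)
    if (length(rest)) enrich <- mean(px[fpix]) / mean(px[rest])
  }
  structure(list(label = cell$label, reference_intensity = ref,
                 foci = foci, has_condensate = has,
                 enrichment_ratio = enrich, threshold_used = threshold),
            class = "condensate_call")
}

#' @export
print.condensate_call <- function(x, ...) {
  cat(sprintf(
    "<condensate_call> cell %d: %s (%d foci, ref %.1f, enrichment %s, tau %.2f)\n",
    x$label, if (x$has_condensate) "condensate" else "no condensate",
    length(x$foci), x$reference_intensity,
    if (is.na(x$enrichment_ratio)) "NA" else sprintf("%.2f", x$enrichment_ratio),
    x$threshold_used))
  invisible(x)
}

#' Call condensates for every segmented cell
#'
#' @param cells List of `cell_region`s.
#' @inheritParams detect_condensates
#' @return List of `condensate_call`s.
#' @export
call_cells <- function(cells, img, threshold = 1.20, min_focus_px = 4L,
                       disk_radius_px = 3, stat = "median") {
  lapply(cells, detect_condensates, img = img, threshold = threshold,
         min_focus_px = min_focus_px, disk_radius_px = disk_radius_px,
         stat = stat)
}

#' Fraction of condensate-containing cells
#'
#' The per-stack statistic used to score a strain.
#'
#' @param calls Non-empty list of `condensate_call`s (or a logical vector of
#'   per-cell presence flags).
#' @return A `fraction_result` with `n_cells`, `n_with_condensates`,
#'   `fraction` and `threshold_used`.
#' @export
fraction_with_condensates <- function(calls) {
  if (!length(calls)) ct_stop("no calls", "empty_input")
  if (is.logical(calls)) {
    flags <- calls
    thr <- NA_real_
  } else {
    flags <- vapply(calls, `[[`, TRUE, "has_condensate")
    thr <- calls[[1]]$threshold_used
  }
  structure(list(n_cells = length(flags),
                 n_with_condensates = sum(flags),
                 fraction = mean(flags),
                 threshold_used = thr),
            class = "fraction_result")
}

#' @export
print.fraction_result <- function(x, ...) {
  cat(sprintf("<fraction_result> %d/%d cells with condensates (%.3f)\n",
              x$n_with_condensates, x$n_cells, x$fraction))
  invisible(x)
}

#' Classify a strain as condensate-forming
#'
#' A strain is condensate-forming when the fraction of condensate-containing
#' cells reaches the cutoff (default 0.11, above the false-positive rate of
#' the automated detection).
#'
#' @param fraction A `fraction_result` or a bare fraction in `[0, 1]`.
#' @param cutoff Cutoff on the cell fraction (default 0.11); the boundary is
#'   inclusive (fraction >= cutoff).
#' @return `TRUE` iff the strain is called condensate-forming.
#' @export
#' @examples
#' classify_strain(0.10)  # FALSE
#' classify_strain(0.11)  # TRUE
classify_strain <- function(fraction, cutoff = 0.11) {
  f <- if (inherits(fraction, "fraction_result")) fraction$fraction
       else fraction
  if (is.na(f) || f < 0 || f > 1)
    ct_stop("fraction must be in [0,1]", "invalid_argument")
  f >= cutoff
}

#' Fraction of condensate-containing cells across a threshold sweep
#'
#' Re-evaluates condensate calls at each intensity-ratio threshold; because
#' super-threshold pixel sets are nested, the fraction is non-increasing in
#' the threshold, and the decay of the curve probes the partitioning of
#' protein between the condensed and dilute phases.
#'
#' @param cells List of `cell_region`s.
#' @param img The micrograph.
#' @param thresholds Ascending thresholds, all > 1 (default 1.05 to 2.00 in
#'   0.05 steps).
#' @inheritParams detect_condensates
#' @return data.frame with columns threshold, n_cells, n_with, fraction.
#' @export
threshold_sweep <- function(cells, img, thresholds = seq(1.05, 2.00, by = 0.05),
                            min_focus_px = 4L, disk_radius_px = 3,
                            stat = "median") {
  if (any(thresholds <= 1.0))
    ct_stop("all thresholds must exceed 1.0", "invalid_argument")
  if (is.unsorted(thresholds, strictly = TRUE))
    ct_stop("thresholds must be sorted in ascending order",
            "invalid_argument")
  if (!length(cells)) ct_stop("no cells", "empty_input")
  rows <- lapply(thresholds, function(tau) {
    fr <- fraction_with_condensates(
      call_cells(cells, img, threshold = tau, min_focus_px = min_focus_px,
                 disk_radius_px = disk_radius_px, stat = stat))
    data.frame(threshold = tau, n_cells = fr$n_cells,
               n_with = fr$n_with_condensates, fraction = fr$fraction)
  })
  do.call(rbind, rows)
}

#' Per-cell call table
#'
#' @param calls List of `condensate_call`s.
#' @return data.frame, one row per cell.
#' @export
calls_to_table <- function(calls) {
  data.frame(
    label = vapply(calls, `[[`, 0L, "label"),
    reference_intensity = vapply(calls, `[[`, 0, "reference_intensity"),
    n_foci = vapply(calls, function(x) length(x$foci), 0L),
    has_condensate = vapply(calls, `[[`, TRUE, "has_condensate"),
    enrichment_ratio = vapply(calls, `[[`, 0, "enrichment_ratio"),
    threshold_used = vapply(calls, `[[`, 0, "threshold_used")
  )
}
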