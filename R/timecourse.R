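# Time-course aggregation: per-variant, per-replicate fractions of
# condensate-containing cells over hours post-induction, replicate
# mean +/- SD, persistence classification (none / transient / persistent)
# and the fluorescence/OD expression proxy.

#' Aggregate per-replicate fractions into a strain time course
#'
#' @param df data.frame with columns `replicate`, `timepoint` (hours
#'   post-induction) and `fraction`; optional `variant` (single value) and
#'   `n_cells`. Every replicate must cover the same set of timepoints.
#' @return A `strain_timecourse`: the replicate-by-timepoint fraction
#'   matrix and a summary data.frame (timepoint, mean, sd, n_replicates).
#'   SD is the sample SD (n - 1); it is 0 when there is a single replicate.
#' @export
#' @examples
#' df <- data.frame(replicate = rep(1:3, each = 2),
#'                  timepoint = rep(c(6, 24), 3),
#'                  fraction = c(0.9, 0.95, 1.0, 0.85, 0.8, 0.9))
#' aggregate_timecourse(df)
aggregate_timecourse <- function(df) {
  need <- c("replicate", "timepoint", "fraction")
  if (!all(need %in% names(df)))
    ct_stop("need columns replicate, timepoint, fraction", "invalid_argument")
  reps <- sort(unique(df$replicate))
  tps <- sort(unique(df$timepoint))
  sets <- lapply(reps, function(r) sort(df$timepoint[df$replicate == r]))
  ok <- vapply(sets, function(s) identical(as.numeric(s), as.numeric(tps)),
               TRUE)
  if (!all(ok)) {
    ct_stop(paste0("replicates with mismatched timepoints: ",
                   paste(reps[!ok], collapse = ", ")), "alignment_error")
  }
  m <- matrix(NA_real_, length(reps), length(tps),
              dimnames = list(replicate = as.character(reps),
                              timepoint = as.character(tps)))
  for (i in seq_along(reps)) {
    sub <- df[df$replicate == reps[i], ]
    m[i, as.character(sub$timepoint)] <- sub$fraction
  }
  summary <- data.frame(
    timepoint = tps,
    mean = apply(m, 2, mean),
    sd = if (length(reps) > 1) apply(m, 2, sd) else rep(0, length(tps)),
    n_replicates = length(reps)
  )
  rownames(summary) <- NULL
  structure(list(
    variant = if ("variant" %in% names(df)) unique(df$variant)[1] else NA,
    timepoints = tps, fractions = m, summary = summary
  ), class = "strain_timecourse")
}

#' @export
print.strain_timecourse <- function(x, ...) {
  cat(sprintf("<strain_timecourse> %s: %d replicates x %d timepoints\n",
              x$variant, nrow(x$fractions), length(x$timepoints)))
  print(x$summary)
  invisible(x)
}

#' Classify condensate persistence over a time course
#'
#' Uses the replicate-mean fraction: `persistent` when the final timepoint
#' is at or above the cutoff; `transient` when some earlier timepoint
#' reaches the cutoff but the final one does not (condensates formed, then
#' disassembled); `none` otherwise. The final timepoint is the largest time
#' present.
#'
#' @param tc A `strain_timecourse` (or a data.frame with columns
#'   `timepoint`, `mean`).
#' @param cutoff Cell-fraction cutoff (default 0.11).
#' @return One of `"none"`, `"transient"`, `"persistent"`.
#' @export
#' @examples
#' df <- data.frame(replicate = 1, timepoint = c(2, 4, 6.5, 24),
#'                  fraction = c(0, 0.3, 0.8, 0.02))
#' persistence_class(aggregate_timecourse(df))  # "transient"
persistence_class <- function(tc, cutoff = 0.11) {
  s <- if (inherits(tc, "strain_timecourse")) tc$summary else tc
  if (!all(c("timepoint", "mean") %in% names(s)))
    ct_stop("need columns timepoint and mean", "invalid_argument")
  if (nrow(s) < 2)
    ct_stop("need at least 2 timepoints including a final one",
            "insufficient_data")
  s <- s[order(s$timepoint), ]
  final <- s$mean[nrow(s)]
  earlier <- s$mean[-nrow(s)]
  if (final >= cutoff) "persistent"
  else if (any(earlier >= cutoff)) "transient"
  else "none"
}

#' Fluorescence/OD expression proxy
#'
#' The ratio of bulk fluorescence to cell density is a proxy for the
#' intracellular protein concentration. Optional blanks are subtracted from
#' both channels first; points where the blanked OD is not positive are
#' masked (NA) with a warning.
#'
#' @param curve data.frame with columns `time`, `od`, `fluorescence`
#'   (e.g. from [generate_growth_table()]).
#' @param blank_od,blank_fluorescence Scalar or per-row blanks (default 0).
#' @return The input with blank-corrected columns and a `proxy` column.
#' @export
expression_proxy <- function(curve, blank_od = 0, blank_fluorescence = 0) {
  need <- c("time", "od", "fluorescence")
  if (!all(need %in% names(curve)))
    ct_stop("need columns time, od, fluorescence", "invalid_argument")
  if (is.unsorted(curve$time, strictly = TRUE))
    ct_stop("times must be strictly increasing", "invalid_argument")
  od <- curve$od - blank_od
  fl <- curve$fluorescence - blank_fluorescence
  bad <- od <= 0
  if (any(bad)) {
    ct_warn(sprintf("masked %d point(s) with non-positive blanked OD",
                    sum(bad)), "masked_points")
  }
  proxy <- ifelse(bad, NA_real_, fl / od)
  out <- curve
  out$od <- od
  out$fluorescence <- fl
  out$proxy <- proxy
  out
}
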