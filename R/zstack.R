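# Axial-offset quantification for two-channel confocal z-stacks: per-ROI
# z-profiles, peak-slice detection and summary statistics.
#
# Stacks are arrays of dim c(n_slices, height, width); slice indices are
# 0-based internally (reports also carry 1-based Fiji-style indices).

#' Rectangular region of interest
#'
#' @param x,y Top-left pixel, 0-based.
#' @param width,height Extent in pixels (>= 1).
#' @param label Identifier.
#' @return An object of class `roi`.
#' @export
roi <- function(x, y, width, height, label = "roi") {
  .check_number(x, "x", nonnegative = TRUE)
  .check_number(y, "y", nonnegative = TRUE)
  .check_number(width, "width", positive = TRUE)
  .check_number(height, "height", positive = TRUE)
  structure(list(x = as.integer(x), y = as.integer(y),
                 width = as.integer(width), height = as.integer(height),
                 label = as.character(label)),
            class = "roi")
}

.check_stack <- function(stack, name = "stack") {
  if (!is.array(stack) || length(dim(stack)) != 3) {
    stop(sprintf("'%s' must be a 3D array (slices, height, width)", name),
         call. = FALSE)
  }
  invisible(stack)
}

.check_roi_bounds <- function(r, stack) {
  d <- dim(stack)
  if (r$x + r$width > d[3] || r$y + r$height > d[2]) {
    stop(sprintf("ROI '%s' extends outside the %d x %d image", r$label,
                 d[3], d[2]), call. = FALSE)
  }
  invisible(r)
}

#' Per-slice mean-intensity profile of an ROI
#'
#' Element k is the arithmetic mean of the pixel values of slice k restricted
#' to the ROI rectangle — the same quantity Fiji's "Plot Z-axis Profile"
#' reports for an active ROI.
#'
#' @param stack Single-channel stack, array of dim
#'   `c(n_slices, height, width)`.
#' @param roi An [roi()] lying inside the image bounds.
#' @return An object of class `z_profile`: `roi_label` and `mean_intensity`
#'   (one value per slice).
#' @export
z_profile <- function(stack, roi) {
  .check_stack(stack)
  stopifnot(inherits(roi, "roi"))
  .check_roi_bounds(roi, stack)
  rows <- roi$y + seq_len(roi$height) # 0-based y -> 1-based rows
  cols <- roi$x + seq_len(roi$width)
  sub <- stack[, rows, cols, drop = FALSE]
  prof <- apply(sub, 1, mean)
  structure(list(roi_label = roi$label, mean_intensity = as.numeric(prof)),
            class = "z_profile")
}

#' Peak slice of a z-profile
#'
#' The 0-based index of the slice with the maximum mean intensity; ties are
#' broken toward the smallest index. A completely flat profile returns 0
#' with attribute `flat = TRUE` and a warning.
#'
#' @param profile A [z_profile()] (or bare numeric vector).
#' @return Integer slice index (0-based), with attribute `flat`.
#' @export
peak_slice <- function(profile) {
  v <- if (inherits(profile, "z_profile")) profile$mean_intensity else profile
  .check_number(v, "profile", len = NULL)
  if (!length(v)) stop("empty profile", call. = FALSE)
  flat <- length(unique(v)) == 1L
  if (flat) {
    warning("flat z-profile: peak slice is undefined, returning 0",
            call. = FALSE)
  }
  structure(which.max(v) - 1L, flat = flat)
}

#' Axial offsets between two channels over a set of ROIs
#'
#' For each ROI (applied identically to both channels) the peak slice is
#' found per channel and the signed axial offset
#' `delta_z = peak_slice(ch2) - peak_slice(ch1)` is computed (channel 2 is
#' conventionally the deeper/protein channel). Summary statistics (mean,
#' sample sd, median, min, max) are reported for the signed offsets and,
#' because the sign convention is not always meaningful, for their absolute
#' values as well.
#'
#' @param stack_ch1,stack_ch2 Single-channel stacks of identical dimension.
#' @param rois List of [roi()] objects.
#' @return An object of class `axial_offset_report`: `per_roi` (data frame
#'   with 0- and 1-based peak slices and signed `delta_z`), `summary` and
#'   `summary_abs` (named numeric vectors), `n_rois`.
#' @export
axial_offsets <- function(stack_ch1, stack_ch2, rois) {
  .check_stack(stack_ch1, "stack_ch1")
  .check_stack(stack_ch2, "stack_ch2")
  if (!identical(dim(stack_ch1), dim(stack_ch2))) {
    stop("channel stacks must have identical dimensions", call. = FALSE)
  }
  if (inherits(rois, "roi")) rois <- list(rois)
  if (!length(rois)) stop("'rois' must be nonempty", call. = FALSE)
  stopifnot(all(vapply(rois, inherits, logical(1), "roi")))

  rows <- lapply(rois, function(r) {
    p1 <- as.integer(peak_slice(z_profile(stack_ch1, r)))
    p2 <- as.integer(peak_slice(z_profile(stack_ch2, r)))
    data.frame(roi_label = r$label,
               peak_slice_ch1 = p1, peak_slice_ch2 = p2,
               peak_slice_ch1_fiji = p1 + 1L, peak_slice_ch2_fiji = p2 + 1L,
               delta_z = p2 - p1)
  })
  per_roi <- do.call(rbind, rows)
  dz <- per_roi$delta_z
  summarize <- function(x) c(
    mean = mean(x),
    sd = if (length(x) > 1) stats::sd(x) else 0,
    median = stats::median(x), min = min(x), max = max(x)
  )
  structure(
    list(per_roi = per_roi, summary = summarize(dz),
         summary_abs = summarize(abs(dz)), n_rois = nrow(per_roi)),
    class = "axial_offset_report"
  )
}

#' @export
print.axial_offset_report <- function(x, ...) {
  cat(sprintf("Axial-offset report over %d ROIs\n", x$n_rois))
  print(x$per_roi, row.names = FALSE)
  s <- x$summary
  cat(sprintf(
    "signed delta_z: mean %.2f +/- %.2f slices (median %g; range %g to %g)\n",
    s["mean"], s["sd"], s["median"], s["min"], s["max"]))
  s <- x$summary_abs
  cat(sprintf(
    "|delta_z|:      mean %.2f +/- %.2f slices (median %g; range %g to %g)\n",
    s["mean"], s["sd"], s["median"], s["min"], s["max"]))
  invisible(x)
}
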