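#' Signal-to-noise report over a rectangular ROI
#'
#' Lifetime precision is summarised as SNR = mean lifetime / sd lifetime
#' over a fixed-size region of interest (conventionally 400 pixels), so
#' that the same cell can be compared between calcium states.
#'
#' @param lifetime_img Numeric matrix of per-pixel lifetimes (ns).
#' @param roi List or vector with `row`, `col` (top-left, 1-based),
#'   `height`, `width`.
#' @param expected_pixels Required ROI pixel count (default 400); set to
#'   `NULL` to accept any size.
#' @return A list with `mean_ns`, `sd_ns`, `snr` (`Inf` for a constant
#'   ROI), `n_pixels`.
#' @export
snr_report <- function(lifetime_img, roi, expected_pixels = 400L) {
  stopifnot(is.matrix(lifetime_img))
  roi <- as.list(roi)
  stopifnot(all(c("row", "col", "height", "width") %in% names(roi)))
  r2 <- roi$row + roi$height - 1L
  c2 <- roi$col + roi$width - 1L
  if (roi$row < 1L || roi$col < 1L || r2 > nrow(lifetime_img) ||
      c2 > ncol(lifetime_img)) {
    stop("ROI extends outside the image", call. = FALSE)
  }
  px <- lifetime_img[roi$row:r2, roi$col:c2]
  if (!is.null(expected_pixels) && length(px) != expected_pixels) {
    stop(sprintf("ROI has %d pixels; expected %d", length(px),
                 expected_pixels), call. = FALSE)
  }
  m <- mean(px)
  s <- stats::sd(px)
  list(mean_ns = m, sd_ns = s, snr = if (s == 0) Inf else m / s,
       n_pixels = length(px))
}

#' Normalise per-cell green/red intensity ratios to controls
#'
#' The raw GFP/RFP ratio of each cell is mapped linearly so that a cell
#' matching the no-GFP control reads 0 and one matching the EGFP control
#' reads 1, removing transfection-efficiency and illumination factors:
#' `normalized = (raw - no_gfp) / (egfp - no_gfp)`.
#'
#' @param green,red Per-cell mean intensities (same length).
#' @param egfp_control_ratio Raw ratio of the EGFP + RFP control.
#' @param no_gfp_control_ratio Raw ratio of the RFP-only control.
#' @return A data.frame with `raw`, `normalized`, and `excluded` (cells
#'   with non-positive red signal, `NA` ratios).
#' @export
ratio_normalize <- function(green, red, egfp_control_ratio,
                            no_gfp_control_ratio) {
  stopifnot(length(green) == length(red))
  if (egfp_control_ratio == no_gfp_control_ratio) {
    stop("control ratios must be distinct", call. = FALSE)
  }
  excluded <- !(red > 0)
  raw <- ifelse(excluded, NA_real_, green / red)
  data.frame(
    raw = raw,
    normalized = (raw - no_gfp_control_ratio) /
      (egfp_control_ratio - no_gfp_control_ratio),
    excluded = excluded
  )
}

#' Summarise a lifetime change between two conditions
#'
#' The lifetime change of a sensor is the mean lifetime in the calcium-bound
#' condition minus the mean in the calcium-free condition. Values are kept
#' at full precision; `format()` on the result rounds to two decimals for
#' presentation, matching the convention for reporting lifetimes in ns.
#'
#' @param pre Per-cell lifetimes (ns) in the first (calcium-free) condition.
#' @param post Per-cell lifetimes (ns) in the second (calcium-bound)
#'   condition.
#' @return An object of class `lifetime_change` with `mean_pre`, `sd_pre`,
#'   `mean_post`, `sd_post`, `change`.
#' @export
lifetime_change_summary <- function(pre, post) {
  if (length(pre) < 1L || length(post) < 1L) {
    stop("need at least one cell per condition", call. = FALSE)
  }
  structure(
    list(
      mean_pre = mean(pre), sd_pre = stats::sd(pre),
      mean_post = mean(post), sd_post = stats::sd(post),
      change = mean(post) - mean(pre)
    ),
    class = "lifetime_change"
  )
}

#' @export
format.lifetime_change <- function(x, ...) {
  sprintf("pre %.2f ns, post %.2f ns, change %+.2f ns",
          x$mean_pre, x$mean_post, x$change)
}

#' @export
print.lifetime_change <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
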