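# Grid fitting and colony quantification from plate images: a functional
# stand-in for grid-based colony quantifiers such as the common R tools
# used on 1536-format arrays.

# Local maxima of a profile above a prominence threshold.
find_peaks <- function(p, prominence = 0.2) {
  thr <- stats::median(p) + prominence * (max(p) - stats::median(p))
  n <- length(p)
  idx <- which(p > thr)
  idx <- idx[idx > 1 & idx < n]
  idx[p[idx] >= p[idx - 1] & p[idx] >= p[idx + 1] &
        (p[idx] > p[idx - 1] | p[idx] > p[idx + 1])]
}

# Collapse plateau runs of adjacent peak indices to their centre.
collapse_runs <- function(idx) {
  if (!length(idx)) return(numeric(0))
  grp <- cumsum(c(1, diff(idx) > 1))
  as.numeric(tapply(idx, grp, function(v) mean(range(v))))
}

# Coerce detected peak positions to an arithmetic grid of n centres.
regularize_axis <- function(peaks, n) {
  if (length(peaks) == n) {
    pitch <- stats::median(diff(peaks))
    return(list(centres = peaks, pitch = pitch,
                residual = max(abs(peaks - (peaks[1] + (seq_len(n) - 1) * pitch)))))
  }
  d <- diff(peaks)
  pitch0 <- stats::median(d[d < 1.5 * stats::median(d)])
  k <- round((peaks - peaks[1]) / pitch0)
  fit <- stats::lm.fit(cbind(1, k), peaks)
  a <- fit$coefficients[1]; pitch <- fit$coefficients[2]
  list(centres = a + (seq_len(n) - 1) * pitch, pitch = pitch,
       residual = max(abs(fit$residuals)))
}

#' Locate a colony grid in a plate image
#'
#' Finds the centres of a declared rows x cols colony array from smoothed
#' row and column intensity projection profiles. Detected peaks are
#' coerced to an evenly pitched grid when pins are missing; fewer than
#' half the expected peaks on either axis is treated as "grid not found".
#'
#' @param image numeric matrix in \[0, 1\] (`[row, col]` indexed), or a
#'   [render_plate_image()] result.
#' @param rows,cols declared array format.
#' @param min_peak_prominence peak threshold as a fraction of the profile
#'   range above its median.
#' @return An object of class `grid_geometry`: `row_centres`,
#'   `col_centres` (px), `pitch` (named length-2), `halfwidth` (px,
#'   non-overlapping window half-width) and per-axis `residuals`.
#' @export
fit_grid <- function(image, rows, cols, min_peak_prominence = 0.2) {
  if (inherits(image, "plate_render")) image <- image$image
  stopifnot(is.matrix(image))
  axes <- list(row = rowMeans(image), col = colMeans(image))
  n_exp <- c(row = rows, col = cols)
  out <- lapply(names(axes), function(ax) {
    prof <- axes[[ax]]
    width <- max(3, floor(length(prof) / n_exp[[ax]] / 2))
    prof <- smooth_ma(prof, width)
    pk <- collapse_runs(find_peaks(prof, min_peak_prominence))
    if (length(pk) < n_exp[[ax]] / 2)
      stop(sprintf("grid not found: %d of %d %s peaks detected",
                   length(pk), n_exp[[ax]], ax), call. = FALSE)
    regularize_axis(pk, n_exp[[ax]])
  })
  names(out) <- names(axes)
  pitch <- c(row = out$row$pitch, col = out$col$pitch)
  structure(
    list(row_centres = out$row$centres, col_centres = out$col$centres,
         pitch = pitch, halfwidth = floor(min(pitch) / 2),
         residuals = c(row = out$row$residual, col = out$col$residual)),
    class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d, pitch %.2f x %.2f px, window halfwidth %d px\n",
              length(x$row_centres), length(x$col_centres),
              x$pitch[["row"]], x$pitch[["col"]], x$halfwidth))
  invisible(x)
}

#' Quantify colony sizes on a fitted grid
#'
#' For each grid window, foreground pixels are those above a locally
#' estimated threshold (background median + `threshold_k` times the MAD,
#' estimated from the window's border frame); the colony size is the
#' pixel count (or background-subtracted intensity sum) of the largest
#' connected foreground blob, ties broken by distance to the window
#' centre. Windows with no foreground blob of at least `min_size` pixels
#' get size 0 and an `"empty"` flag. The threshold is relative, so sizes
#' are invariant to rescaling the image intensity.
#'
#' @param image numeric matrix or [render_plate_image()] result.
#' @param grid a [fit_grid()] geometry.
#' @param measure `"area"` (foreground pixel count, default) or
#'   `"intensity"` (background-subtracted intensity sum).
#' @param threshold_k MAD multiplier for the local threshold (default 3).
#' @param min_size smallest blob accepted as a colony, px (default 4).
#' @param plate_id,replicate,isolate,array_role metadata passed to the
#'   returned [plate_grid()].
#' @return A [plate_grid()] of quantified sizes with QC flags.
#' @export
quantify_colonies <- function(image, grid, measure = c("area", "intensity"),
                              threshold_k = 3, min_size = 4L,
                              plate_id = "plate1", replicate = 1L,
                              isolate = 1L, array_role = "query") {
  if (inherits(image, "plate_render")) image <- image$image
  measure <- match.arg(measure)
  stopifnot(inherits(grid, "grid_geometry"))
  hw <- grid$halfwidth
  rows <- length(grid$row_centres); cols <- length(grid$col_centres)
  sizes <- matrix(0, rows, cols)
  flags <- matrix("", rows, cols)
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    yc <- grid$row_centres[i]; xc <- grid$col_centres[j]
    ys <- round(yc - hw):round(yc + hw)
    xs <- round(xc - hw):round(xc + hw)
    if (min(ys) < 1 || min(xs) < 1 || max(ys) > nrow(image) || max(xs) > ncol(image))
      stop(sprintf("window (%d,%d) outside image bounds", i - 1L, j - 1L),
           call. = FALSE)
    win <- image[ys, xs]
    frame <- c(win[c(1, 2, nrow(win) - 1, nrow(win)), ],
               win[, c(1, 2, ncol(win) - 1, ncol(win))])
    bg <- stats::median(frame)
    thr <- bg + threshold_k * stats::mad(frame)
    fg <- win > thr
    if (!any(fg)) { flags[i, j] <- "empty"; next }
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(fg))))
    areas <- tabulate(lab)
    big <- which(areas == max(areas))
    if (length(big) > 1L) {
      # tie: blob whose centroid is closest to the window centre
      cen <- (dim(win) + 1) / 2
      d <- vapply(big, function(b) {
        px <- which(t(lab) == b, arr.ind = TRUE)
        sum((colMeans(px) - cen)^2)
      }, 0)
      big <- big[which.min(d)]
    }
    if (areas[big] < min_size) { flags[i, j] <- "empty"; next }
    blob <- t(lab) == big
    sizes[i, j] <- if (measure == "area") sum(blob) else sum(win[blob] - bg)
  }
  plate_grid(sizes, plate_id = plate_id, replicate = replicate,
             isolate = isolate, array_role = array_role, flags = flags)
}
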