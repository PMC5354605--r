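#' Render a colony plate as a grayscale image
#'
#' Draws each colony as a filled disc whose area (in pixels) equals the
#' colony size, centred on its grid node, over a uniform background, with
#' optional Gaussian blur and additive noise. The returned geometry is the
#' ground truth for [fit_grid()] / [quantify_colonies()] round-trips.
#'
#' @param plate a [plate_grid()].
#' @param pitch grid pitch in pixels (node-to-node distance). Must exceed
#'   twice the largest colony radius so neighbouring colonies cannot touch.
#' @param margin border around the outermost nodes, px (default `pitch`).
#' @param background background intensity in \[0, 1\].
#' @param amplitude colony intensity above background.
#' @param blur_sigma Gaussian blur sigma in px (0 = none).
#' @param noise_sd additive Gaussian noise SD (0 = none).
#'
#' @return A list of class `plate_render`: `image` (numeric matrix in
#'   \[0, 1\], `[row, col]` indexed), `row_centres`, `col_centres` (px),
#'   `pitch`, and the input `plate`.
#' @examples
#' pl <- plate_grid(matrix(c(80, 120, 60, 100), 2, 2))
#' r <- render_plate_image(pl, pitch = 30)
#' dim(r$image)
#' @export
render_plate_image <- function(plate, pitch = 20, margin = pitch,
                               background = 0.1, amplitude = 0.8,
                               blur_sigma = 0, noise_sd = 0) {
  stopifnot(inherits(plate, "plate_grid"))
  sizes <- plate$sizes
  radii <- sqrt(sizes / pi)
  if (2 * max(radii) >= pitch)
    stop(sprintf("colonies would overlap: max radius %.1f px needs pitch > %.1f",
                 max(radii), 2 * max(radii)), call. = FALSE)
  rows <- nrow(sizes); cols <- ncol(sizes)
  row_centres <- margin + (seq_len(rows) - 1) * pitch
  col_centres <- margin + (seq_len(cols) - 1) * pitch
  h <- as.integer(ceiling(max(row_centres) + margin))
  w <- as.integer(ceiling(max(col_centres) + margin))
  img <- matrix(background, h, w)
  half <- ceiling(pitch / 2)
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    r <- radii[i, j]
    if (r <= 0) next
    yc <- row_centres[i]; xc <- col_centres[j]
    ys <- max(1L, floor(yc - half)):min(h, ceiling(yc + half))
    xs <- max(1L, floor(xc - half)):min(w, ceiling(xc + half))
    d2 <- outer((ys - yc)^2, (xs - xc)^2, "+")
    img[ys, xs][d2 <= r^2] <- background + amplitude
  }
  if (blur_sigma > 0)
    img <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(img)),
                                               sigma = blur_sigma)))
  if (noise_sd > 0)
    img <- img + matrix(rnorm(length(img), 0, noise_sd), h, w)
  img[img < 0] <- 0; img[img > 1] <- 1
  structure(list(image = img, row_centres = row_centres,
                 col_centres = col_centres, pitch = pitch, plate = plate),
            class = "plate_render")
}

#' @export
print.plate_render <- function(x, ...) {
  cat(sprintf("<plate_render> %d x %d px, %d x %d grid, pitch %.1f px\n",
              nrow(x$image), ncol(x$image),
              length(x$row_centres), length(x$col_centres), x$pitch))
  invisible(x)
}
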