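#' Configure a synthetic fluorescence cell field
#'
#' Defines a field of non-overlapping elliptical cells imitating a
#' three-channel acquisition: a cell-wall stain (bright cell outlines,
#' total population), a dead-cell stain (filled signal in a fraction of
#' cells) and a vacuole stain (one ring of known diameter per live cell).
#'
#' @param n_cells number of cells to place.
#' @param axis_ratio_mean,axis_ratio_sd major:minor axis ratio of the
#'   cell ellipses (>= 1; sd 0 gives identical shapes).
#' @param minor_radius_px minor semi-axis in pixels.
#' @param dead_fraction proportion of cells carrying dead-stain signal,
#'   in \[0, 1\].
#' @param vacuole_diameter_mean,vacuole_diameter_sd vacuole ring diameter
#'   in micrometres (the ring's outer edge).
#' @param pixel_size micrometres per pixel (> 0; default 0.05).
#' @param image_size image height and width in pixels.
#' @param wall_thickness cell-outline thickness, px.
#' @param background background intensity; `noise_sd` adds Gaussian noise.
#' @param noise_sd additive noise SD (0 = none).
#' @param max_tries placement attempts before giving up with an error.
#' @param seed integer RNG seed.
#' @return A `cell_field_config` list.
#' @export
cell_field_config <- function(n_cells = 40L, axis_ratio_mean = 2.5,
                              axis_ratio_sd = 0.2, minor_radius_px = 12,
                              dead_fraction = 0,
                              vacuole_diameter_mean = 0.4,
                              vacuole_diameter_sd = 0.05,
                              pixel_size = 0.05,
                              image_size = c(512L, 512L),
                              wall_thickness = 2, background = 0.05,
                              noise_sd = 0, max_tries = 200L, seed = 1L) {
  stopifnot_scalar(pixel_size, "pixel_size", 0, strict = TRUE)
  stopifnot_scalar(dead_fraction, "dead_fraction", 0)
  if (dead_fraction > 1) stop("`dead_fraction` must be in [0, 1]", call. = FALSE)
  stopifnot_scalar(axis_ratio_mean, "axis_ratio_mean", 1)
  stopifnot_scalar(vacuole_diameter_mean, "vacuole_diameter_mean", 0)
  structure(
    list(n_cells = as.integer(n_cells), axis_ratio_mean = axis_ratio_mean,
         axis_ratio_sd = axis_ratio_sd, minor_radius_px = minor_radius_px,
         dead_fraction = dead_fraction,
         vacuole_diameter_mean = vacuole_diameter_mean,
         vacuole_diameter_sd = vacuole_diameter_sd,
         pixel_size = pixel_size, image_size = as.integer(image_size),
         wall_thickness = wall_thickness, background = background,
         noise_sd = noise_sd, max_tries = as.integer(max_tries),
         seed = as.integer(seed)),
    class = "cell_field_config")
}

# Pixel coordinates (row, col) inside an ellipse at (cy, cx), semi-axes
# (a, b), orientation theta; returns index matrix plus the quadratic form.
ellipse_pixels <- function(cy, cx, a, b, theta, h, w) {
  ext <- ceiling(a) + 1L
  ys <- max(1L, floor(cy - ext)):min(h, ceiling(cy + ext))
  xs <- max(1L, floor(cx - ext)):min(w, ceiling(cx + ext))
  dy <- rep(ys - cy, times = length(xs))
  dx <- rep(xs - cx, each = length(ys))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  q <- u^2 + v^2
  keep <- q <= 1
  list(idx = cbind(rep(ys, times = length(xs))[keep],
                   rep(xs, each = length(ys))[keep]),
       q = q[keep])
}

#' Simulate a three-channel fluorescence cell field
#'
#' Places `n_cells` non-overlapping rasterized ellipses by rejection
#' sampling and renders the wall, dead-stain and vacuole channels plus
#' ground-truth masks.
#'
#' @param config a [cell_field_config()].
#' @return Object of class `cell_field`: list with
#'   \describe{
#'     \item{wall, dead, vacuole}{numeric channel matrices in \[0, 1\].}
#'     \item{labels}{integer matrix of truth masks (0 = background,
#'       k = cell k).}
#'     \item{truth}{data frame `cell`, `cy`, `cx`, `axis_ratio`, `a_px`,
#'       `b_px`, `theta`, `dead`, `vacuole_diameter_um` (`NA` for dead
#'       cells).}
#'     \item{config}{the config used.}
#'   }
#' @examples
#' f <- simulate_cell_field(cell_field_config(n_cells = 10, seed = 3))
#' table(f$truth$dead)
#' @export
simulate_cell_field <- function(config) {
  if (!inherits(config, "cell_field_config"))
    stop("`config` must be a cell_field_config")
  cf <- config
  h <- cf$image_size[1]; w <- cf$image_size[2]
  with_seed(cf$seed, {
    wall <- matrix(cf$background, h, w)
    dead_ch <- matrix(cf$background, h, w)
    vac <- matrix(cf$background, h, w)
    labels <- matrix(0L, h, w)
    occupied <- matrix(FALSE, h, w)

    n_dead <- round(cf$dead_fraction * cf$n_cells)
    is_dead <- rep(FALSE, cf$n_cells)
    if (n_dead > 0) is_dead[sample.int(cf$n_cells, n_dead)] <- TRUE

    truth <- vector("list", cf$n_cells)
    tries <- 0L; gap <- 3
    for (k in seq_len(cf$n_cells)) {
      repeat {
        tries <- tries + 1L
        if (tries > cf$max_tries * cf$n_cells)
          stop("could not place all cells without overlap; reduce n_cells or enlarge image",
               call. = FALSE)
        ratio <- max(1, rnorm(1, cf$axis_ratio_mean, cf$axis_ratio_sd))
        b <- cf$minor_radius_px; a <- ratio * b
        theta <- runif(1, 0, pi)
        if (2 * (a + 2) >= min(h, w))
          stop("image too small for the requested cell size", call. = FALSE)
        cy <- runif(1, a + 2, h - a - 2)
        cx <- runif(1, a + 2, w - a - 2)
        px <- ellipse_pixels(cy, cx, a + gap, b + gap, theta, h, w)
        if (any(occupied[px$idx])) next
        occupied[px$idx] <- TRUE
        body <- ellipse_pixels(cy, cx, a, b, theta, h, w)
        inner <- ellipse_pixels(cy, cx, a - cf$wall_thickness,
                                b - cf$wall_thickness, theta, h, w)
        labels[body$idx] <- k
        ring <- body$idx[!(paste(body$idx[, 1], body$idx[, 2]) %in%
                             paste(inner$idx[, 1], inner$idx[, 2])), , drop = FALSE]
        wall[ring] <- cf$background + 0.85
        vd <- NA_real_
        if (is_dead[k]) {
          dead_ch[body$idx] <- cf$background + 0.8
        } else if (cf$vacuole_diameter_mean > 0) {
          vd <- max(0, rnorm(1, cf$vacuole_diameter_mean, cf$vacuole_diameter_sd))
          rv <- vd / cf$pixel_size / 2
          if (rv >= 1.5) {
            vo <- ellipse_pixels(cy, cx, rv, rv, 0, h, w)
            vi <- ellipse_pixels(cy, cx, max(0.5, rv - 2), max(0.5, rv - 2),
                                 0, h, w)
            vring <- vo$idx[!(paste(vo$idx[, 1], vo$idx[, 2]) %in%
                                paste(vi$idx[, 1], vi$idx[, 2])), , drop = FALSE]
            vac[vring] <- cf$background + 0.8
          }
        }
        truth[[k]] <- data.frame(cell = k, cy = cy, cx = cx, axis_ratio = ratio,
                                 a_px = a, b_px = b, theta = theta,
                                 dead = is_dead[k], vacuole_diameter_um = vd)
        break
      }
    }
    if (cf$noise_sd > 0) {
      for (ch in c("wall", "dead_ch", "vac")) {
        m <- get(ch)
        m <- m + matrix(rnorm(h * w, 0, cf$noise_sd), h, w)
        m[m < 0] <- 0; m[m > 1] <- 1
        assign(ch, m)
      }
    }
    structure(list(wall = wall, dead = dead_ch, vacuole = vac,
                   labels = labels, truth = do.call(rbind, truth),
                   config = cf),
              class = "cell_field")
  })
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("<cell_field> %d cells in %d x %d px (%.3f um/px); %d dead\n",
              nrow(x$truth), nrow(x$wall), ncol(x$wall),
              x$config$pixel_size, sum(x$truth$dead)))
  invisible(x)
}
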