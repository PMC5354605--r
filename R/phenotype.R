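# Microscopy phenotype quantification: segmentation of wall-stained
# cells, elongation scoring, live/dead viability, vacuole diameters.

#' Segment cells from a wall-stain image
#'
#' Global Otsu threshold on the wall channel, hole filling to convert the
#' bright cell outlines into solid regions, connected-component
#' labelling, then size filtering. Cells touching the image border are
#' excluded. Masks are returned in raster order (top-to-bottom, then
#' left-to-right of the centroid).
#'
#' @param image single-channel numeric matrix in \[0, 1\]
#'   (`[row, col]` indexed), e.g. the `wall` channel of
#'   [simulate_cell_field()].
#' @param min_area,max_area accepted region area range, px^2.
#' @return List of `cell_mask` objects, each with `id`, `mask` (cropped
#'   binary matrix), `bbox` (`ymin, ymax, xmin, xmax`), `area` (px^2),
#'   `perimeter` (px, sub-pixel contour estimate) and `centroid`
#'   (`(row, col)` px). Empty list (with a warning) when nothing passes
#'   the filters.
#' @export
segment_cells <- function(image, min_area = 100, max_area = Inf) {
  stopifnot(is.matrix(image))
  # Otsu on a subsample: the threshold is a histogram statistic, so
  # orientation and subsampling (above 1e6 px) do not change it materially
  v <- as.vector(image)
  if (length(v) > 1e6) v <- v[round(seq(1, length(v), length.out = 1e6))]
  thr <- EBImage::otsu(EBImage::Image(matrix(v, ncol = 1L)))
  mask <- image > thr
  # fillHull/bwlabel act on connectivity only; no transposition needed
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1)))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(filled)))
  n <- max(lab)
  if (n == 0) { warning("no cells found"); return(list()) }
  fg <- which(lab > 0)
  px_by_lab <- split(fg, lab[fg])
  out <- list()
  for (k in seq_len(n)) {
    lin <- px_by_lab[[as.character(k)]]
    if (is.null(lin)) next
    px <- cbind((lin - 1L) %% nrow(image) + 1L, (lin - 1L) %/% nrow(image) + 1L)
    area <- nrow(px)
    if (area < min_area || area > max_area) next
    if (min(px) == 1L || max(px[, 1]) == nrow(image) || max(px[, 2]) == ncol(image))
      next  # touching the border
    bbox <- c(ymin = min(px[, 1]), ymax = max(px[, 1]),
              xmin = min(px[, 2]), xmax = max(px[, 2]))
    sub <- matrix(FALSE, bbox["ymax"] - bbox["ymin"] + 1L,
                  bbox["xmax"] - bbox["xmin"] + 1L)
    sub[cbind(px[, 1] - bbox["ymin"] + 1L, px[, 2] - bbox["xmin"] + 1L)] <- TRUE
    g <- mask_geometry(sub)
    out[[length(out) + 1L]] <- structure(
      list(id = k, mask = sub, bbox = bbox, area = area,
           perimeter = if (is.null(g)) NA_real_ else g$perimeter,
           centroid = colMeans(px)),
      class = "cell_mask")
  }
  if (!length(out)) { warning("no cells in the accepted area range"); return(list()) }
  ord <- order(vapply(out, function(m) m$centroid[1], 0),
               vapply(out, function(m) m$centroid[2], 0))
  out <- out[ord]
  for (i in seq_along(out)) out[[i]]$id <- i
  out
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> id %d, area %d px^2, perimeter %.1f px, centroid (%.1f, %.1f)\n",
              x$id, x$area, x$perimeter, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Summarize elongation across experiments
#'
#' Averages elongation scores within each dataset (independent
#' experiment) over its first `n_per_dataset` cells, then summarizes the
#' condition as the mean and SEM across dataset means — the independent
#' experiment, not the cell, is the replication unit.
#'
#' @param scores list of numeric score vectors, one per dataset, in
#'   acquisition order; a single vector is treated as one dataset.
#' @param n_per_dataset cells scored per dataset (default 30). Datasets
#'   with fewer cells are rejected with a warning.
#' @return List of class `elongation_summary`: `dataset_means`, `mean`,
#'   `sem` (`NA` for a single dataset), `n_datasets`, `n_per_dataset`.
#' @examples
#' summarize_elongation(list(rep(0.2, 30), rep(0.3, 30)))
#' @export
summarize_elongation <- function(scores, n_per_dataset = 30L) {
  if (is.numeric(scores)) scores <- list(scores)
  keep <- lengths(scores) >= n_per_dataset
  if (!all(keep))
    warning(sum(!keep), " dataset(s) rejected: fewer than ", n_per_dataset,
            " cells")
  scores <- scores[keep]
  if (!length(scores)) stop("no dataset with enough cells", call. = FALSE)
  dm <- vapply(scores, function(s) mean(s[seq_len(n_per_dataset)]), 0)
  structure(list(dataset_means = dm, mean = mean(dm),
                 sem = if (length(dm) >= 2) sem(dm) else NA_real_,
                 n_datasets = length(dm), n_per_dataset = n_per_dataset),
            class = "elongation_summary")
}

#' @export
print.elongation_summary <- function(x, ...) {
  cat(sprintf("elongation %.3f +/- %.3f (mean +/- SEM of %d datasets, %d cells each)\n",
              x$mean, x$sem, x$n_datasets, x$n_per_dataset))
  invisible(x)
}

#' Score live/dead viability
#'
#' Viability is `100 * (1 - n_dead / n_total)`: the total population
#' comes from the wall-stain channel and dead cells from the dead-stain
#' channel. Given images, cells are segmented from the wall channel and a
#' cell counts as dead when more than half of its pixels carry dead-stain
#' signal above background; the first `n_scored` cells in raster order
#' are scored, so the count is deterministic and intensity-scale
#' invariant.
#'
#' @param total wall-channel image matrix, or the total cell count.
#' @param dead dead-channel image matrix, or the dead cell count.
#' @param n_scored cells scored per dataset when images are given
#'   (default 500; fewer if the field has fewer cells).
#' @param timepoint optional timepoint label (h) carried in the record.
#' @param min_area,max_area segmentation filters (image input only).
#' @return List of class `viability_record`: `timepoint`, `n_total`,
#'   `n_dead`, `viability` (%).
#' @examples
#' score_viability(500, 10)  # 98%
#' @export
score_viability <- function(total, dead, n_scored = 500L, timepoint = NA_real_,
                            min_area = 100, max_area = Inf) {
  if (is.matrix(total)) {
    stopifnot(is.matrix(dead))
    cells <- segment_cells(total, min_area = min_area, max_area = max_area)
    if (!length(cells)) stop("no cells to score (n_total = 0)", call. = FALSE)
    cells <- cells[seq_len(min(n_scored, length(cells)))]
    bg <- stats::median(dead)
    cut <- bg + 0.5 * (max(dead) - bg)
    n_dead <- sum(vapply(cells, function(m) {
      sub <- dead[m$bbox["ymin"]:m$bbox["ymax"], m$bbox["xmin"]:m$bbox["xmax"]]
      mean(sub[m$mask] > cut) > 0.5
    }, TRUE))
    n_total <- length(cells)
  } else {
    n_total <- total; n_dead <- dead
  }
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  if (n_dead < 0 || n_dead > n_total)
    stop("need 0 <= n_dead <= n_total", call. = FALSE)
  structure(list(timepoint = timepoint, n_total = as.integer(n_total),
                 n_dead = as.integer(n_dead),
                 viability = 100 * (1 - n_dead / n_total)),
            class = "viability_record")
}

#' @export
print.viability_record <- function(x, ...) {
  cat(sprintf("viability %.1f%% (%d/%d cells dead%s)\n", x$viability,
              x$n_dead, x$n_total,
              if (is.na(x$timepoint)) "" else sprintf(", %g h", x$timepoint)))
  invisible(x)
}

#' Measure vacuole diameters from a ring-stained channel
#'
#' Detects ring-shaped vacuole signals by thresholding the channel at
#' background median + 3 MAD, fills the ring interiors and labels them;
#' each vacuole's diameter is the equivalent-circle diameter of its
#' filled region, converted to micrometres.
#'
#' @param image vacuole-channel matrix in \[0, 1\].
#' @param pixel_size micrometres per pixel.
#' @param min_area smallest filled region accepted, px^2 (default 6).
#' @return Data frame `vacuole`, `area_px2`, `diameter_um`.
#' @export
measure_vacuoles <- function(image, pixel_size, min_area = 6) {
  stopifnot(is.matrix(image))
  stopifnot_scalar(pixel_size, "pixel_size", 0, strict = TRUE)
  thr <- stats::median(image) + 3 * stats::mad(image)
  mask <- image > thr
  if (!any(mask)) stop("no vacuole signal detected", call. = FALSE)
  filled <- EBImage::imageData(EBImage::fillHull(
    EBImage::bwlabel(EBImage::Image(mask * 1))))
  areas <- tabulate(filled)
  keep <- which(areas >= min_area)
  if (!length(keep)) stop("no vacuole signal detected", call. = FALSE)
  data.frame(vacuole = seq_along(keep), area_px2 = areas[keep],
             diameter_um = 2 * sqrt(areas[keep] / pi) * pixel_size)
}

#' Summarize vacuole diameters across experiments
#'
#' Per-dataset mean over the first `n_per_dataset` vacuoles, then mean
#' and SEM across dataset means (the experiment is the replication
#' unit).
#'
#' @param diameters list of numeric diameter vectors (um), one per
#'   dataset; a single vector is treated as one dataset.
#' @param n_per_dataset vacuoles per dataset (default 300; datasets with
#'   fewer are rejected with a warning).
#' @return List `dataset_means`, `mean`, `sem`, `n_datasets`.
#' @export
summarize_vacuoles <- function(diameters, n_per_dataset = 300L) {
  if (is.numeric(diameters)) diameters <- list(diameters)
  keep <- lengths(diameters) >= n_per_dataset
  if (!all(keep))
    warning(sum(!keep), " dataset(s) rejected: fewer than ", n_per_dataset,
            " vacuoles")
  diameters <- diameters[keep]
  if (!length(diameters)) stop("no dataset with enough vacuoles", call. = FALSE)
  dm <- vapply(diameters, function(d) mean(d[seq_len(n_per_dataset)]), 0)
  list(dataset_means = dm, mean = mean(dm),
       sem = if (length(dm) >= 2) sem(dm) else NA_real_,
       n_datasets = length(dm))
}
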