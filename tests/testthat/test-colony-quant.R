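# Plate rendering, grid detection and window-based colony quantification.

make_render <- function(seed = 11, blur = 0, noise = 0, pitch = 36) {
  s <- simulate_screen(toy_screen_config(rows = 8L, cols = 12L, n_genes = 96L,
                                         n_isolates = 1L, n_replicates = 1L,
                                         base_size_cv = 0.3, seed = seed))
  render_plate_image(s$plates$r1_i1_query_p1, pitch = pitch,
                     blur_sigma = blur, noise_sd = noise)
}

test_that("rendered discs have the requested area and renders are bounded", {
  p <- plate_grid(matrix(pi * 100, 1, 1))
  r <- render_plate_image(p, pitch = 40)
  fg <- sum(r$image > 0.5)
  expect_lt(abs(fg - pi * 100) / (pi * 100), 0.05)
  # all-zero plate renders as pure background
  r0 <- render_plate_image(plate_grid(matrix(0, 3, 3)), pitch = 20)
  expect_equal(unique(as.vector(r0$image)), 0.1)
  # overlap guard
  expect_error(render_plate_image(plate_grid(matrix(4000, 2, 2)), pitch = 20),
               "overlap")
})

test_that("fit_grid recovers rendered centres within 2 px", {
  r <- make_render(blur = 1, noise = 0.02)
  g <- fit_grid(r, 8, 12)
  expect_lt(max(abs(g$row_centres - r$row_centres)), 2)
  expect_lt(max(abs(g$col_centres - r$col_centres)), 2)
  expect_equal(g$pitch[["row"]], 36, tolerance = 0.03)
})

test_that("fit_grid errors on a blank image and reflects under 180-degree rotation", {
  expect_error(fit_grid(matrix(0.1, 200, 300), 8, 12), "grid not found")
  r <- make_render()
  g <- fit_grid(r, 8, 12)
  rot <- r$image[nrow(r$image):1, ncol(r$image):1]
  g2 <- fit_grid(rot, 8, 12)
  expect_equal(g2$row_centres, rev(nrow(r$image) + 1 - g$row_centres),
               tolerance = 0.5)
  expect_equal(g2$col_centres, rev(ncol(r$image) + 1 - g$col_centres),
               tolerance = 0.5)
})

test_that("quantified sizes track truth on noise-free renders", {
  r <- make_render()
  g <- fit_grid(r, 8, 12)
  q <- quantify_colonies(r, g)
  truth <- r$plate$sizes
  expect_gt(cor(as.vector(truth), as.vector(q$sizes)), 0.99)
  # sizes are pixel counts of rasterized discs: proportional, near-unity slope
  expect_equal(unname(coef(lm(as.vector(q$sizes) ~ 0 + as.vector(truth)))), 1,
               tolerance = 0.1)
})

test_that("all-background windows are flagged empty and bounds are enforced", {
  r <- render_plate_image(plate_grid(matrix(0, 4, 6)), pitch = 30)
  g <- structure(list(row_centres = r$row_centres, col_centres = r$col_centres,
                      pitch = c(row = 30, col = 30), halfwidth = 14,
                      residuals = c(row = 0, col = 0)),
                 class = "grid_geometry")
  q <- quantify_colonies(r, g)
  expect_true(all(q$sizes == 0))
  expect_true(all(q$flags == "empty"))
  g$row_centres[1] <- 2  # window sticks out of the image
  expect_error(quantify_colonies(r, g), "outside image bounds")
})

test_that("quantification is invariant to intensity scaling and monotone in radius", {
  r <- make_render()
  g <- fit_grid(r, 8, 12)
  q1 <- quantify_colonies(r$image, g)
  q2 <- quantify_colonies(r$image * 0.35, g)
  expect_identical(q1$sizes, q2$sizes)
  # with blur, edge pixels sit near the threshold and float rounding can
  # move single pixels; sizes still agree to well under 2%
  rb <- make_render(blur = 1)
  gb <- fit_grid(rb, 8, 12)
  qb1 <- quantify_colonies(rb$image, gb)
  qb2 <- quantify_colonies(rb$image * 0.35, gb)
  expect_lt(max(abs(qb1$sizes - qb2$sizes) / qb1$sizes), 0.02)
  # growing disc radius never shrinks the quantified size
  sizes <- vapply(c(4, 6, 8, 10, 12), function(rad) {
    p <- plate_grid(matrix(pi * rad^2, 1, 1))
    rr <- render_plate_image(p, pitch = 40)
    gg <- structure(list(row_centres = rr$row_centres,
                         col_centres = rr$col_centres,
                         pitch = c(row = 40, col = 40), halfwidth = 19,
                         residuals = c(row = 0, col = 0)),
                    class = "grid_geometry")
    quantify_colonies(rr, gg)$sizes[1, 1]
  }, 0)
  expect_true(all(diff(sizes) > 0))
})

test_that("intensity-sum measure is offered and scales with colony brightness", {
  p <- plate_grid(matrix(pi * 64, 1, 1))
  r <- render_plate_image(p, pitch = 40)
  g <- structure(list(row_centres = r$row_centres, col_centres = r$col_centres,
                      pitch = c(row = 40, col = 40), halfwidth = 19,
                      residuals = c(row = 0, col = 0)),
                 class = "grid_geometry")
  qa <- quantify_colonies(r, g, measure = "area")$sizes[1, 1]
  qi <- quantify_colonies(r, g, measure = "intensity")$sizes[1, 1]
  # amplitude 0.8 over background: intensity sum ~ 0.8 * area
  expect_equal(qi / qa, 0.8, tolerance = 0.05)
})
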