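# Shared fixtures, built in code at test time.

# Binary disc of radius r centred in an n x n matrix.
mk_disc <- function(r, n = ceiling(2 * r) + 14) {
  c0 <- (n + 1) / 2
  xy <- expand.grid(seq_len(n), seq_len(n))
  matrix(sqrt((xy[, 1] - c0)^2 + (xy[, 2] - c0)^2) <= r, n, n) * 1
}

# Binary axis-aligned ellipse with semi-axes (a, b), padded by `pad`.
mk_ellipse <- function(a, b, pad = 8) {
  h <- ceiling(2 * b) + 2 * pad; w <- ceiling(2 * a) + 2 * pad
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  xy <- expand.grid(seq_len(h), seq_len(w))
  matrix(((xy[, 2] - cx) / a)^2 + ((xy[, 1] - cy) / b)^2 <= 1, h, w) * 1
}

# Exact ellipse perimeter by numerical quadrature of the arc length.
ellipse_perimeter <- function(a, b)
  integrate(function(t) sqrt(a^2 * sin(t)^2 + b^2 * cos(t)^2), 0, 2 * pi,
            rel.tol = 1e-10)$value

# Continuum elongation of an (a, b) ellipse.
ellipse_elongation <- function(a, b)
  1 - 4 * pi * (pi * a * b) / ellipse_perimeter(a, b)^2

# A 2x2 toy plate with the given sizes (column-major fill).
toy_plate <- function(sizes = c(100, 200, 300, 400), ...)
  plate_grid(matrix(sizes, 2, 2), ...)

# Small screen config used across scoring tests.
toy_screen_config <- function(...) {
  args <- utils::modifyList(
    list(n_genes = 16L, rows = 4L, cols = 4L, n_isolates = 2L,
         n_replicates = 2L, base_size_cv = 0.1, noise_cv = 0,
         plate_scale_sd = 0.1, edge_effect = 1,
         interaction_fractions = c(negative = 0, positive = 0),
         seed = 99L),
    list(...))
  do.call(screen_config, args)
}
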