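# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Lognormal draws with mean 1 and coefficient of variation `cv` (cv = 0
# returns exactly 1): multiplicative noise that keeps sizes positive.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

stopifnot_scalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("`", name, "` must be a single number", call. = FALSE)
  if (strict && x <= min) stop("`", name, "` must be > ", min, call. = FALSE)
  if (!strict && x < min) stop("`", name, "` must be >= ", min, call. = FALSE)
  invisible(x)
}

# Moving-average smoothing with edge replication (odd window).
smooth_ma <- function(x, width) {
  width <- max(3L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  h <- (width - 1L) %/% 2L
  xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[(h + 1L):(h + length(x))]
}

# Matrix <-> image I/O. Internally images are plain numeric matrices in
# [0, 1], indexed [row, col] with row 1 at the top; EBImage stores (x, y),
# so transpose at the boundary.
write_gray_image <- function(img, path, bits = 16L) {
  EBImage::writeImage(EBImage::Image(t(img)), path, type = "tiff",
                      bits.per.sample = as.integer(bits))
  invisible(path)
}

read_gray_image <- function(path) {
  im <- EBImage::readImage(path)
  if (EBImage::colorMode(im) != EBImage::Grayscale) im <- EBImage::channel(im, "gray")
  d <- EBImage::imageData(im)
  if (length(dim(d)) > 2L) d <- d[, , 1]
  t(d)
}
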