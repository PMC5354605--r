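#' Configure a synthetic SGA screen
#'
#' Defines the generative model for a synthetic genetic array screen: a
#' deletion library arrayed in 1536 format (32 x 48 by default) is crossed
#' to a query mutant and to a neutral control query; colony size is
#'
#' \deqn{s_{g} = b_g \cdot f_{plate} \cdot f_{pos} \cdot \varepsilon_g
#'   \cdot \eta}{s = base * plate_factor * positional_factor * epsilon * noise}
#'
#' where \eqn{b_g} is a per-gene baseline, \eqn{f_{plate}} a per-plate
#' multiplicative scale, \eqn{f_{pos}} an edge boost on the outermost
#' rows/columns, \eqn{\varepsilon_g} the planted interaction effect
#' (query plates only; 1 on control plates and for non-interacting genes)
#' and \eqn{\eta} lognormal noise with mean 1. Genes fill consecutive
#' plates row-major; the layout is identical across isolates, replicates
#' and roles, as in a fixed-library screen.
#'
#' @param n_genes number of library genes.
#' @param rows,cols plate format (default 32 x 48 = 1536).
#' @param n_isolates independent query strain isolates per replicate
#'   (default 4).
#' @param n_replicates independent biological replicates (default 2).
#' @param n_plates plates per isolate/role, or `NULL` (default) to use as
#'   many as the library needs. An explicit value too small for `n_genes`
#'   is an error.
#' @param base_size mean baseline colony size (px^2-equivalent units).
#' @param base_size_cv coefficient of variation of the per-gene baseline.
#' @param plate_scale_sd relative SD of the per-plate multiplicative factor.
#' @param edge_effect multiplicative growth boost on the outermost
#'   `edge_width` rows and columns (1 = none).
#' @param edge_width number of edge rows/cols affected (default 2).
#' @param noise_cv coefficient of variation of per-colony lognormal noise.
#' @param interaction_fractions length-2 numeric `c(negative=, positive=)`:
#'   fractions of genes planted with each effect sign; must sum to <= 1.
#' @param effect_magnitudes length-2 numeric `c(negative=, positive=)`:
#'   planted multiplicative effects (e.g. 0.5 and 1.5).
#' @param dropout_prob per-position probability of a failed pinning
#'   (size 0; default 0).
#' @param seed integer RNG seed; the whole screen is deterministic given
#'   the config.
#'
#' @return A `screen_config` list.
#' @export
screen_config <- function(n_genes = 1536L, rows = 32L, cols = 48L,
                          n_isolates = 4L, n_replicates = 2L,
                          n_plates = NULL,
                          base_size = 200, base_size_cv = 0.2,
                          plate_scale_sd = 0.1,
                          edge_effect = 1.1, edge_width = 2L,
                          noise_cv = 0.1,
                          interaction_fractions = c(negative = 0.02, positive = 0.02),
                          effect_magnitudes = c(negative = 0.5, positive = 1.5),
                          dropout_prob = 0, seed = 1L) {
  stopifnot_scalar(n_genes, "n_genes", 1, strict = FALSE)
  stopifnot_scalar(base_size, "base_size", 0, strict = TRUE)
  for (nm in c("base_size_cv", "plate_scale_sd", "noise_cv", "dropout_prob"))
    stopifnot_scalar(get(nm), nm, 0)
  stopifnot_scalar(edge_effect, "edge_effect", 0, strict = TRUE)
  if (length(interaction_fractions) != 2L ||
      any(interaction_fractions < 0) || any(interaction_fractions > 1) ||
      sum(interaction_fractions) > 1)
    stop("`interaction_fractions` must be two fractions in [0,1] summing to <= 1",
         call. = FALSE)
  if (length(effect_magnitudes) != 2L || any(effect_magnitudes <= 0))
    stop("`effect_magnitudes` must be two positive multipliers", call. = FALSE)
  per_plate <- as.integer(rows) * as.integer(cols)
  need <- as.integer(ceiling(n_genes / per_plate))
  if (is.null(n_plates)) n_plates <- need
  if (n_plates * per_plate < n_genes)
    stop(sprintf("grid too small for n_genes: %d plates of %d x %d hold %d positions, need %d",
                 n_plates, rows, cols, n_plates * per_plate, n_genes), call. = FALSE)
  structure(
    list(n_genes = as.integer(n_genes), rows = as.integer(rows),
         cols = as.integer(cols), n_isolates = as.integer(n_isolates),
         n_replicates = as.integer(n_replicates), n_plates = as.integer(n_plates),
         base_size = base_size, base_size_cv = base_size_cv,
         plate_scale_sd = plate_scale_sd, edge_effect = edge_effect,
         edge_width = as.integer(edge_width), noise_cv = noise_cv,
         interaction_fractions = interaction_fractions,
         effect_magnitudes = effect_magnitudes,
         dropout_prob = dropout_prob, seed = as.integer(seed)),
    class = "screen_config")
}

# Edge multiplier matrix for one plate.
positional_factors <- function(rows, cols, edge_effect, edge_width) {
  f <- matrix(1, rows, cols)
  if (edge_width > 0 && edge_effect != 1) {
    e <- seq_len(min(edge_width, rows))
    f[c(e, rows + 1 - e), ] <- edge_effect
    e <- seq_len(min(edge_width, cols))
    f[, c(e, cols + 1 - e)] <- edge_effect
  }
  f
}

#' Simulate a full SGA screen with known ground truth
#'
#' Generates query and control plates for every replicate x isolate
#' combination under the model described in [screen_config()], together
#' with the truth table of planted interaction effects.
#'
#' @param config a [screen_config()].
#' @return An object of class `sga_sim`: a list with elements
#'   \describe{
#'     \item{plates}{named list of [plate_grid()] objects
#'       (`r<rep>_i<isolate>_<role>_p<plate>`).}
#'     \item{truth}{data frame `gene`, `epsilon`, `category`
#'       (negative/none/positive).}
#'     \item{config}{the config used.}
#'   }
#' @examples
#' sim <- simulate_screen(screen_config(n_genes = 96, rows = 8, cols = 12,
#'                                      noise_cv = 0, seed = 7))
#' sim$plates[[1]]
#' table(sim$truth$category)
#' @export
simulate_screen <- function(config) {
  if (!inherits(config, "screen_config")) stop("`config` must be a screen_config")
  cf <- config
  with_seed(cf$seed, {
    genes <- sprintf("gene%04d", seq_len(cf$n_genes))
    base <- cf$base_size * rlnorm_cv(cf$n_genes, cf$base_size_cv)

    n_neg <- round(cf$interaction_fractions[[1]] * cf$n_genes)
    n_pos <- round(cf$interaction_fractions[[2]] * cf$n_genes)
    hit_idx <- sample.int(cf$n_genes, n_neg + n_pos)
    eps <- rep(1, cf$n_genes)
    eps[hit_idx[seq_len(n_neg)]] <- cf$effect_magnitudes[[1]]
    eps[hit_idx[seq_len(n_pos) + n_neg]] <- cf$effect_magnitudes[[2]]
    category <- ifelse(eps < 1, "negative", ifelse(eps > 1, "positive", "none"))
    truth <- data.frame(gene = genes, epsilon = eps, category = category,
                        stringsAsFactors = FALSE)

    per_plate <- cf$rows * cf$cols
    pos_f <- positional_factors(cf$rows, cf$cols, cf$edge_effect, cf$edge_width)
    plates <- list()
    for (r in seq_len(cf$n_replicates)) for (i in seq_len(cf$n_isolates))
      for (role in c("query", "control")) for (p in seq_len(cf$n_plates)) {
        idx <- ((p - 1L) * per_plate + 1L):min(p * per_plate, cf$n_genes)
        gmat <- matrix(NA_character_, cf$rows, cf$cols)
        smat <- matrix(0, cf$rows, cf$cols)
        # row-major fill: transpose trick since R matrices are column-major
        slot <- seq_along(idx)
        rr <- (slot - 1L) %/% cf$cols + 1L
        cc <- (slot - 1L) %% cf$cols + 1L
        gmat[cbind(rr, cc)] <- genes[idx]
        plate_factor <- rlnorm_cv(1L, cf$plate_scale_sd)
        e <- if (role == "query") eps[idx] else rep(1, length(idx))
        noise <- rlnorm_cv(length(idx), cf$noise_cv)
        smat[cbind(rr, cc)] <- base[idx] * plate_factor * pos_f[cbind(rr, cc)] *
          e * noise
        flags <- matrix("", cf$rows, cf$cols)
        flags[is.na(gmat)] <- "empty"
        if (cf$dropout_prob > 0) {
          drop <- runif(length(idx)) < cf$dropout_prob
          smat[cbind(rr, cc)][drop] <- 0
        }
        id <- sprintf("r%d_i%d_%s_p%d", r, i, role, p)
        plates[[id]] <- plate_grid(smat, gmat, plate_id = id, replicate = r,
                                   isolate = i, array_role = role, flags = flags)
      }
    structure(list(plates = plates, truth = truth, config = cf),
              class = "sga_sim")
  })
}

#' @export
print.sga_sim <- function(x, ...) {
  cat(sprintf("<sga_sim> %d genes, %d replicate(s) x %d isolate(s) x 2 roles x %d plate(s) (%d plates total)\n",
              x$config$n_genes, x$config$n_replicates, x$config$n_isolates,
              x$config$n_plates, length(x$plates)))
  print(table(planted = x$truth$category))
  invisible(x)
}

#' Compare interaction calls with a simulation truth table
#'
#' Precision and recall of the classified interactions against the planted
#' effects of [simulate_screen()], per interaction sign.
#'
#' @param calls a data frame with columns `gene` and `call` (e.g. the
#'   `robust` element of an [sga_score()] fit), or an `sga_screen` object.
#' @param truth the `truth` data frame of an `sga_sim`.
#' @return Data frame with one row per sign (`negative`, `positive`):
#'   true/false positive and false negative counts, `precision`, `recall`.
#' @export
evaluate_recovery <- function(calls, truth) {
  if (inherits(calls, "sga_screen")) calls <- calls$robust
  out <- lapply(c("negative", "positive"), function(sign) {
    called <- calls$gene[calls$call == sign]
    planted <- truth$gene[truth$category == sign]
    tp <- length(intersect(called, planted))
    data.frame(sign = sign, n_called = length(called), n_planted = length(planted),
               tp = tp, fp = length(called) - tp, fn = length(planted) - tp,
               precision = if (length(called)) tp / length(called) else NA_real_,
               recall = if (length(planted)) tp / length(planted) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
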