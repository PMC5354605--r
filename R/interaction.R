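# Interaction scoring: plate-median normalization, query/control ratios,
# isolate averaging, threshold classification, replicate intersection.

#' Normalize a plate to its median colony size
#'
#' Divides every retained colony size by the median of retained sizes on
#' the same plate, accounting for differential growth between plates.
#' Retained positions are those with an empty QC flag and size > 0;
#' flagged or zero positions propagate as `NA`. The even-count median is
#' the midpoint of the two central order statistics (`stats::median`).
#'
#' @param plate a [plate_grid()].
#' @return An object of class `normalized_plate`: the plate with a
#'   `values` matrix of dimensionless normalized sizes (`NA` where not
#'   retained) and the `median_size` used.
#' @examples
#' p <- plate_grid(matrix(c(100, 200, 300, 400), 2, 2))
#' normalize_plate(p)$values  # median 250 -> 0.4 0.8 1.2 1.6
#' @export
normalize_plate <- function(plate) {
  stopifnot(inherits(plate, "plate_grid"))
  retained <- plate$flags == "" & plate$sizes > 0 & !is.na(plate$sizes)
  if (!any(retained))
    stop("no retained positions on plate ", plate$plate_id, call. = FALSE)
  med <- stats::median(plate$sizes[retained])
  values <- plate$sizes / med
  values[!retained] <- NA_real_
  structure(c(plate, list(values = values, median_size = med)),
            class = c("normalized_plate", "plate_grid"))
}

#' Query/control colony-size ratios
#'
#' Divides normalized query values by normalized control values at
#' matching gene positions. A ratio is undefined (`NA`) when either side
#' is missing or the normalized control value falls below `control_floor`
#' (a dead control pin would otherwise blow the ratio up).
#'
#' @param query,control [normalize_plate()] results with identical gene
#'   layouts.
#' @param control_floor smallest usable normalized control value
#'   (default 0.05).
#' @return Named numeric vector of per-gene ratios (empty positions
#'   dropped), with a `"reasons"` attribute naming the genes whose ratio
#'   is undefined and why (`missing_query`, `missing_control`,
#'   `control_below_floor`).
#' @export
compute_ratios <- function(query, control, control_floor = 0.05) {
  stopifnot(inherits(query, "normalized_plate"),
            inherits(control, "normalized_plate"))
  if (!identical(query$genes, control$genes))
    stop("layout mismatch between query and control plates", call. = FALSE)
  occupied <- !is.na(query$genes)
  g <- query$genes[occupied]
  q <- query$values[occupied]
  c_ <- control$values[occupied]
  ratio <- q / c_
  reason <- rep(NA_character_, length(g))
  reason[is.na(q)] <- "missing_query"
  reason[is.na(c_)] <- "missing_control"
  low <- !is.na(c_) & c_ < control_floor
  reason[low] <- "control_below_floor"
  ratio[!is.na(reason)] <- NA_real_
  names(ratio) <- g
  structure(ratio, reasons = setNames(reason[!is.na(reason)], g[!is.na(reason)]))
}

#' Mean ratio across query isolates
#'
#' Averages the per-isolate query/control ratios for each gene, the
#' screen's summary statistic. Genes with fewer than `min_isolates`
#' defined ratios are dropped with a reason.
#'
#' @param ratios a genes x isolates numeric matrix (rownames = genes), or
#'   a list of named per-isolate ratio vectors as returned by
#'   [compute_ratios()].
#' @param min_isolates minimum defined ratios for a gene to be scored
#'   (default 2).
#' @return Data frame `gene`, `mean_ratio`, `n_used`, `dropped`, `reason`
#'   (`"no_ratio"` when nothing was defined, `"too_few_isolates"`
#'   otherwise).
#' @examples
#' m <- rbind(geneA = c(0.70, 0.75, 0.80, 0.75),
#'            geneB = c(0.70, NA, 0.80, NA))
#' mean_over_isolates(m)
#' @export
mean_over_isolates <- function(ratios, min_isolates = 2L) {
  if (is.list(ratios) && !is.data.frame(ratios)) {
    genes <- sort(unique(unlist(lapply(ratios, names))))
    ratios <- vapply(ratios, function(v) v[genes], numeric(length(genes)))
    rownames(ratios) <- genes
  }
  stopifnot(is.matrix(ratios))
  n_used <- rowSums(!is.na(ratios))
  mean_ratio <- rowMeans(ratios, na.rm = TRUE)
  mean_ratio[n_used == 0L] <- NA_real_
  dropped <- n_used < min_isolates
  reason <- rep(NA_character_, nrow(ratios))
  reason[dropped] <- ifelse(n_used[dropped] == 0L, "no_ratio", "too_few_isolates")
  data.frame(gene = rownames(ratios), mean_ratio = mean_ratio,
             n_used = n_used, dropped = dropped, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify genetic interactions by ratio thresholds
#'
#' A mean colony-size ratio below `low` is a negative interaction, above
#' `high` a positive interaction, otherwise none. Inequalities are
#' strict, so boundary values classify as none.
#'
#' @param scores numeric vector of mean ratios (optionally named), or a
#'   [mean_over_isolates()] data frame (dropped genes classify as `NA`).
#' @param low,high thresholds with `0 < low < high`
#'   (defaults 0.8 and 1.2).
#' @return Factor of calls (`negative`, `none`, `positive`), or the input
#'   data frame with a `call` column appended.
#' @examples
#' classify_interactions(c(0.79, 0.80, 1.00, 1.20, 1.21))
#' @export
classify_interactions <- function(scores, low = 0.8, high = 1.2) {
  if (!(is.numeric(low) && is.numeric(high) && 0 < low && low < high))
    stop("invalid thresholds: need 0 < low < high", call. = FALSE)
  lev <- c("negative", "none", "positive")
  if (is.data.frame(scores)) {
    x <- scores$mean_ratio
    x[scores$dropped] <- NA_real_
    scores$call <- factor(ifelse(x < low, "negative",
                                 ifelse(x > high, "positive", "none")), lev)
    return(scores)
  }
  factor(ifelse(scores < low, "negative",
                ifelse(scores > high, "positive", "none")), lev)
}

#' Intersect interaction calls across biological replicates
#'
#' A gene is retained only when every replicate makes the same non-none
#' call for it; genes called with opposite signs in different replicates
#' are recorded as discordant.
#'
#' @param calls list of >= 2 per-replicate call sets, each a data frame
#'   with columns `gene` and `call` (e.g. [classify_interactions()]
#'   output on a [mean_over_isolates()] frame).
#' @return Object of class `robust_interactions`: data frame `gene`,
#'   `call` of the concordant non-none interactions, with attribute
#'   `discordant` (genes called with conflicting signs).
#' @export
intersect_replicates <- function(calls) {
  if (!is.list(calls) || length(calls) < 2L)
    stop("need >= 2 replicates to intersect", call. = FALSE)
  hits <- lapply(calls, function(d) {
    d <- d[!is.na(d$call) & d$call != "none", c("gene", "call")]
    d$call <- as.character(d$call)
    d
  })
  genes <- Reduce(intersect, lapply(hits, `[[`, "gene"))
  per_rep <- vapply(hits, function(d) setNames(d$call, d$gene)[genes],
                    character(length(genes)))
  if (length(genes) == 1L) per_rep <- matrix(per_rep, nrow = 1L,
                                             dimnames = list(genes, NULL))
  concordant <- apply(per_rep, 1L, function(v) all(v == v[1]))
  out <- data.frame(gene = genes[concordant],
                    call = if (any(concordant)) per_rep[concordant, 1] else character(0),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, discordant = genes[!concordant],
            class = c("robust_interactions", "data.frame"))
}

#' Fraction of negative interactors in a gene-set hub
#'
#' Counts how many robust negative interactors fall in a supplied hub
#' gene list and reports the percentage, truncated to one decimal place.
#'
#' @param negatives character vector of negative-interactor genes, or a
#'   `robust_interactions` frame (its negative calls are used).
#' @param hub_genes character vector of hub members.
#' @return List `n_in_hub`, `n_negative`, `percent`.
#' @examples
#' hub_fraction(sprintf("g%03d", 1:131), sprintf("g%03d", 1:39))
#' @export
hub_fraction <- function(negatives, hub_genes) {
  if (inherits(negatives, "robust_interactions") || is.data.frame(negatives))
    negatives <- negatives$gene[negatives$call == "negative"]
  negatives <- unique(negatives)
  if (!length(negatives)) stop("empty negative-interactor set", call. = FALSE)
  n <- length(intersect(negatives, hub_genes))
  list(n_in_hub = n, n_negative = length(negatives),
       percent = floor(1000 * n / length(negatives)) / 10)
}

#' Score a synthetic genetic array screen
#'
#' The screen-level fitting function: normalizes every plate to its
#' median colony size, forms per-isolate query/control ratios, averages
#' them into a mean ratio per gene, classifies interactions by the ratio
#' thresholds, and intersects the calls across biological replicates.
#'
#' @param screen an [simulate_screen()] result, or a list of
#'   [plate_grid()] objects carrying `replicate`, `isolate` and
#'   `array_role` metadata (each isolate needs a query and a control
#'   plate per plate index).
#' @param low,high classification thresholds (defaults 0.8, 1.2).
#' @param min_isolates minimum defined per-isolate ratios per gene
#'   (default 2).
#' @param control_floor smallest usable normalized control value
#'   (default 0.05).
#' @return Object of class `sga_screen` with elements
#'   \describe{
#'     \item{scores}{per-replicate data frames: `gene`, `mean_ratio`,
#'       `n_used`, `dropped`, `reason`, `call`.}
#'     \item{ratios}{per-replicate genes x isolates ratio matrices.}
#'     \item{robust}{[intersect_replicates()] result (single-replicate
#'       screens return that replicate's calls instead).}
#'     \item{thresholds, min_isolates, control_floor}{parameters used.}
#'   }
#'   Methods: `print`, `summary`, `coef` (genes x replicates mean-ratio
#'   matrix), `plot` (mean-ratio histogram with thresholds).
#' @examples
#' sim <- simulate_screen(screen_config(n_genes = 96, rows = 8, cols = 12,
#'                                      seed = 42))
#' fit <- sga_score(sim)
#' fit
#' head(coef(fit))
#' @export
sga_score <- function(screen, low = 0.8, high = 1.2, min_isolates = 2L,
                      control_floor = 0.05) {
  plates <- if (inherits(screen, "sga_sim")) screen$plates else screen
  if (!length(plates) || !all(vapply(plates, inherits, TRUE, "plate_grid")))
    stop("`screen` must be an sga_sim or a list of plate_grid objects",
         call. = FALSE)
  reps <- sort(unique(vapply(plates, `[[`, 1L, "replicate")))
  ratios <- list(); scores <- list()
  for (r in reps) {
    pr <- plates[vapply(plates, function(p) p$replicate == r, TRUE)]
    isolates <- sort(unique(vapply(pr, `[[`, 1L, "isolate")))
    per_iso <- lapply(isolates, function(i) {
      pi_ <- pr[vapply(pr, function(p) p$isolate == i, TRUE)]
      qs <- pi_[vapply(pi_, function(p) p$array_role == "query", TRUE)]
      cs <- pi_[vapply(pi_, function(p) p$array_role == "control", TRUE)]
      if (!length(qs) || length(qs) != length(cs))
        stop(sprintf("replicate %d isolate %d: need matching query and control plates",
                     r, i), call. = FALSE)
      qs <- qs[order(vapply(qs, `[[`, "", "plate_id"))]
      cs <- cs[order(vapply(cs, `[[`, "", "plate_id"))]
      unlist(lapply(seq_along(qs), function(k)
        compute_ratios(normalize_plate(qs[[k]]), normalize_plate(cs[[k]]),
                       control_floor = control_floor)))
    })
    names(per_iso) <- paste0("isolate", isolates)
    rid <- paste0("replicate", r)
    ratios[[rid]] <- local({
      genes <- sort(unique(unlist(lapply(per_iso, names))))
      m <- vapply(per_iso, function(v) unname(v[genes]), numeric(length(genes)))
      rownames(m) <- genes
      m
    })
    sc <- mean_over_isolates(ratios[[rid]], min_isolates = min_isolates)
    scores[[rid]] <- classify_interactions(sc, low = low, high = high)
  }
  robust <- if (length(reps) >= 2L) intersect_replicates(scores) else {
    d <- scores[[1]][!is.na(scores[[1]]$call) & scores[[1]]$call != "none",
                     c("gene", "call")]
    d$call <- as.character(d$call)
    structure(d, discordant = character(0),
              class = c("robust_interactions", "data.frame"))
  }
  structure(list(scores = scores, ratios = ratios, robust = robust,
                 thresholds = c(low = low, high = high),
                 min_isolates = min_isolates, control_floor = control_floor),
            class = "sga_screen")
}

#' @export
print.sga_screen <- function(x, ...) {
  cat(sprintf("<sga_screen> %d replicate(s); thresholds < %.2f negative, > %.2f positive\n",
              length(x$scores), x$thresholds[["low"]], x$thresholds[["high"]]))
  for (r in names(x$scores)) {
    tab <- table(x$scores[[r]]$call)
    cat(sprintf("  %s: %d negative, %d positive, %d none\n", r,
                tab[["negative"]], tab[["positive"]], tab[["none"]]))
  }
  tab <- table(factor(x$robust$call, c("negative", "positive")))
  cat(sprintf("  robust (all replicates, same sign): %d negative, %d positive\n",
              tab[["negative"]], tab[["positive"]]))
  invisible(x)
}

#' @export
summary.sga_screen <- function(object, ...) {
  print(object)
  disc <- attr(object$robust, "discordant")
  if (length(disc)) cat("  discordant genes:", paste(disc, collapse = ", "), "\n")
  dropped <- lapply(object$scores, function(d) d$gene[d$dropped])
  nd <- sum(lengths(dropped))
  if (nd) cat(sprintf("  genes dropped (too few isolate ratios): %d\n", nd))
  invisible(object)
}

#' @export
coef.sga_screen <- function(object, ...) {
  genes <- sort(unique(unlist(lapply(object$scores, `[[`, "gene"))))
  m <- vapply(object$scores, function(d) setNames(d$mean_ratio, d$gene)[genes],
              numeric(length(genes)))
  rownames(m) <- genes
  m
}

#' @export
plot.sga_screen <- function(x, breaks = 60, ...) {
  m <- coef(x)
  graphics::hist(as.vector(m), breaks = breaks,
                 main = "Mean query/control colony-size ratios",
                 xlab = "mean ratio", ...)
  graphics::abline(v = x$thresholds, lty = 2, col = "red3")
  invisible(x)
}
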