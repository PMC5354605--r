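# End-to-end orchestration: simulate -> quantify -> score -> phenotype ->
# stats, from one config and one root seed, with an output manifest.

default_run_config <- function() {
  list(
    stages = c("simulate_screen", "score", "simulate_cells", "phenotype"),
    screen = list(n_genes = 384, rows = 16, cols = 24, noise_cv = 0.1),
    score = list(low = 0.8, high = 1.2, min_isolates = 2),
    cells = list(n_cells = 30, dead_fraction = 0.1, n_datasets = 3),
    phenotype = list(n_per_dataset = 30, pixel_size = 0.05)
  )
}

read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cf <- utils::modifyList(default_run_config(), config)
  cf
}

#' Run the screen pipeline end to end
#'
#' Executes the selected stages in dependency order from a single config
#' and root seed, writing tables and a manifest (inputs, outputs, seed,
#' package version, MD5 checksums) into `outdir`. Reruns with the same
#' config and seed produce identical outputs.
#'
#' Stages: `simulate_screen` (colony tables + truth), `score`
#' (interaction calls; needs screen tables from this run or
#' `config$score$tables` pointing at an existing TSV), `simulate_cells`
#' (`n_datasets` cell fields), `phenotype` (elongation, viability and
#' vacuole summaries over those fields).
#'
#' @param config a named list or path to a YAML file; unspecified
#'   entries fall back to defaults (see the pipeline section of the
#'   vignette).
#' @param outdir output directory (created if missing).
#' @param seed root seed; stage seeds are derived from it.
#' @param quiet suppress progress messages.
#' @return The manifest, invisibly (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = list(), outdir, seed = 1L, quiet = FALSE) {
  cf <- read_run_config(config)
  stages <- cf$stages
  known <- c("simulate_screen", "score", "simulate_cells", "phenotype")
  if (length(bad <- setdiff(stages, known)))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if ("score" %in% stages && !("simulate_screen" %in% stages)) {
    if (is.null(cf$score$tables) || !file.exists(cf$score$tables))
      stop("score stage needs simulated tables or an existing `score$tables` TSV",
           call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  outputs <- character(0)
  seed <- as.integer(seed)

  sim <- NULL
  if ("simulate_screen" %in% stages) {
    say("simulating screen")
    args <- cf$screen; args$seed <- seed
    sim <- simulate_screen(do.call(screen_config, args))
    write_plate_tsv(sim$plates, file.path(outdir, "screen_plates.tsv"))
    write.table(sim$truth, file.path(outdir, "screen_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, "screen_plates.tsv", "screen_truth.tsv")
  }
  if ("score" %in% stages) {
    say("scoring interactions")
    plates <- if (!is.null(sim)) sim$plates else read_plate_tsv(cf$score$tables)
    fit <- sga_score(plates, low = cf$score$low, high = cf$score$high,
                     min_isolates = cf$score$min_isolates)
    calls <- do.call(rbind, lapply(names(fit$scores), function(r)
      cbind(replicate = r, fit$scores[[r]])))
    write.table(calls, file.path(outdir, "interaction_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(fit$robust),
                file.path(outdir, "robust_interactions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, "interaction_scores.tsv", "robust_interactions.tsv")
  }
  fields <- NULL
  if ("simulate_cells" %in% stages) {
    say("simulating cell fields")
    nd <- cf$cells$n_datasets %||% 3L
    args <- cf$cells; args$n_datasets <- NULL
    fields <- lapply(seq_len(nd), function(i) {
      args$seed <- seed + i
      simulate_cell_field(do.call(cell_field_config, args))
    })
    truth <- do.call(rbind, lapply(seq_along(fields), function(i)
      cbind(dataset = i, fields[[i]]$truth)))
    write.table(truth, file.path(outdir, "cell_truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (i in seq_along(fields)) for (ch in c("wall", "dead", "vacuole"))
      write_gray_image(fields[[i]][[ch]],
                       file.path(outdir, sprintf("cells_d%d_%s.tif", i, ch)))
    outputs <- c(outputs, "cell_truth.tsv",
                 as.vector(outer(seq_along(fields), c("wall", "dead", "vacuole"),
                                 function(i, ch) sprintf("cells_d%d_%s.tif", i, ch))))
  }
  if ("phenotype" %in% stages) {
    if (is.null(fields)) stop("phenotype stage needs simulate_cells", call. = FALSE)
    say("quantifying phenotypes")
    px <- cf$phenotype$pixel_size %||% 0.05
    elo <- lapply(fields, function(f)
      vapply(segment_cells(f$wall), elongation_score, 0))
    es <- summarize_elongation(elo, n_per_dataset = min(
      cf$phenotype$n_per_dataset %||% 30L, min(lengths(elo))))
    via <- lapply(fields, function(f)
      score_viability(f$wall, f$dead, n_scored = cf$phenotype$n_viability %||% 500L))
    vac <- lapply(fields, function(f)
      tryCatch(measure_vacuoles(f$vacuole, px)$diameter_um,
               error = function(e) numeric(0)))
    vs <- if (any(lengths(vac) > 0))
      summarize_vacuoles(vac, n_per_dataset = min(
        cf$phenotype$n_vacuoles %||% 300L, max(lengths(vac)))) else NULL
    summary_tab <- data.frame(
      metric = c("elongation_mean", "elongation_sem",
                 "viability_mean_percent", "viability_sem",
                 "vacuole_diameter_mean_um", "vacuole_diameter_sem_um"),
      value = c(es$mean, es$sem,
                mean(vapply(via, `[[`, 0, "viability")),
                sem(vapply(via, `[[`, 0, "viability")),
                if (is.null(vs)) NA_real_ else vs$mean,
                if (is.null(vs)) NA_real_ else vs$sem))
    write.table(summary_tab, file.path(outdir, "phenotype_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, "phenotype_summary.tsv")
  }

  paths <- file.path(outdir, outputs)
  manifest <- list(
    package = "pombescreen",
    version = as.character(utils::packageVersion("pombescreen")),
    seed = seed, stages = stages,
    config = cf[setdiff(names(cf), "stages")],
    outputs = lapply(seq_along(outputs), function(i)
      list(file = outputs[i], md5 = unname(tools::md5sum(paths[i])))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("wrote ", length(outputs), " outputs + manifest.json to ", outdir)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
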