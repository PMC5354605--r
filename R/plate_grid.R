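#' Colony-array plate
#'
#' A `plate_grid` holds one plate of an arrayed screen: a rows x cols
#' matrix of colony sizes (foreground pixel counts or generated
#' px^2-equivalents), the gene occupying each position, per-position QC
#' flags, and plate-level metadata. Positions are 0-based, row-major
#' `(row, col)` in all tabular output; matrices use R's native 1-based
#' indexing internally.
#'
#' @param sizes numeric rows x cols matrix of colony sizes, all `>= 0`.
#' @param genes character matrix of the same shape giving the gene at each
#'   position (`NA` for unused positions). Defaults to all-`NA`.
#' @param plate_id plate identifier string.
#' @param replicate biological replicate index (independent screen repeat).
#' @param isolate query-isolate index (independent strain construction).
#' @param array_role `"query"` or `"control"`.
#' @param flags character matrix of per-position QC marks (`""` = retained;
#'   e.g. `"empty"`, `"touching_edge"`). Defaults to all-`""`.
#'
#' @return An object of class `plate_grid`.
#' @seealso [normalize_plate()], [quantify_colonies()], [write_plate_tsv()]
#' @export
plate_grid <- function(sizes, genes = NULL, plate_id = "plate1",
                       replicate = 1L, isolate = 1L,
                       array_role = c("query", "control"), flags = NULL) {
  if (!is.matrix(sizes) || !is.numeric(sizes))
    stop("`sizes` must be a numeric matrix", call. = FALSE)
  if (any(sizes < 0, na.rm = TRUE)) stop("colony sizes must be >= 0", call. = FALSE)
  array_role <- match.arg(array_role)
  if (is.null(genes)) genes <- matrix(NA_character_, nrow(sizes), ncol(sizes))
  if (is.null(flags)) flags <- matrix("", nrow(sizes), ncol(sizes))
  if (!identical(dim(genes), dim(sizes)) || !identical(dim(flags), dim(sizes)))
    stop("`genes` and `flags` must match the shape of `sizes`", call. = FALSE)
  structure(
    list(sizes = sizes, genes = genes, flags = flags, plate_id = plate_id,
         replicate = as.integer(replicate), isolate = as.integer(isolate),
         array_role = array_role),
    class = "plate_grid")
}

#' @export
print.plate_grid <- function(x, ...) {
  cat(sprintf("<plate_grid> %s  %dx%d  replicate %d, isolate %d, role %s\n",
              x$plate_id, nrow(x$sizes), ncol(x$sizes),
              x$replicate, x$isolate, x$array_role))
  ok <- x$flags == "" & x$sizes > 0
  cat(sprintf("  retained positions: %d/%d; size median %.1f\n",
              sum(ok), length(ok), stats::median(x$sizes[ok])))
  invisible(x)
}

#' @export
as.data.frame.plate_grid <- function(x, ...) {
  rows <- nrow(x$sizes); cols <- ncol(x$sizes)
  data.frame(
    plate_id = x$plate_id, replicate = x$replicate, isolate = x$isolate,
    array_role = x$array_role,
    row = rep(0:(rows - 1L), times = cols),
    col = rep(0:(cols - 1L), each = rows),
    gene = as.vector(x$genes), size = as.vector(x$sizes),
    flag = as.vector(x$flags),
    stringsAsFactors = FALSE)
}

#' Read and write colony tables
#'
#' Plates are serialized as tab-separated tables with columns `plate_id`,
#' `replicate`, `isolate`, `array_role`, `row`, `col`, `gene`, `size`,
#' `flag` (0-based row/col). One file may hold many plates.
#'
#' @param plates a `plate_grid` or list of them.
#' @param path file path.
#' @return `write_plate_tsv()` returns `path` invisibly;
#'   `read_plate_tsv()` returns a named list of `plate_grid` objects.
#' @export
write_plate_tsv <- function(plates, path) {
  if (inherits(plates, "plate_grid")) plates <- list(plates)
  tab <- do.call(rbind, lapply(plates, as.data.frame))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_tsv
#' @export
read_plate_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "replicate", "isolate", "array_role", "row", "col",
            "gene", "size", "flag")
  if (!all(need %in% names(tab)))
    stop("colony table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  tab$flag[is.na(tab$flag)] <- ""
  out <- lapply(split(tab, tab$plate_id), function(d) {
    rows <- max(d$row) + 1L; cols <- max(d$col) + 1L
    idx <- cbind(d$row + 1L, d$col + 1L)
    sizes <- matrix(0, rows, cols); sizes[idx] <- d$size
    genes <- matrix(NA_character_, rows, cols); genes[idx] <- d$gene
    flags <- matrix("", rows, cols); flags[idx] <- d$flag
    plate_grid(sizes, genes, plate_id = d$plate_id[1],
               replicate = d$replicate[1], isolate = d$isolate[1],
               array_role = d$array_role[1], flags = flags)
  })
  out[order(names(out))]
}
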