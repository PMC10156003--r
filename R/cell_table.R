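#' Construct a cell table
#'
#' The common currency of images and simulations: one row per cell, with
#' continuous 2-D coordinates in micrometers, a class label, and optional
#' continuous per-cell properties (e.g. ligand expression).
#'
#' @param x,y numeric coordinates, micrometers; must be finite.
#' @param kind character class labels.
#' @param ... optional named numeric property columns (non-negative).
#' @return An object of class `cell_table` (a data frame).
#' @export
cell_table <- function(x, y, kind, ...) {
  if (length(kind) == 1) kind <- rep(kind, length(x))
  if (length(x) != length(y) || length(x) != length(kind))
    stop("'x', 'y' and 'kind' must have equal length")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("cell coordinates must be finite")
  props <- list(...)
  df <- data.frame(id = seq_along(x), kind = as.character(kind), x = x, y = y,
                   stringsAsFactors = FALSE)
  for (nm in names(props)) {
    p <- props[[nm]]
    if (length(p) == 1) p <- rep(p, length(x))
    if (length(p) != length(x)) stop(sprintf("property '%s' has wrong length", nm))
    df[[nm]] <- p
  }
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Read a cell table from delimited text
#'
#' Consumes particle-analysis output (e.g. an ImageJ "Results" table with
#' `X`, `Y`, `Mean` columns) or any CSV with per-cell centroids. Column names
#' are mapped through `column_map`; coordinates are taken as micrometers
#' unless a pixel-size `scale` (micrometers per pixel) is supplied.
#'
#' @param path path to a delimited text file.
#' @param column_map named list mapping cell-table fields to file columns;
#'   must name `x` and `y`, and may name `kind` plus property columns (any
#'   other entries, e.g. `list(x = "X", y = "Y", pdl1 = "Mean")`).
#' @param kind if the file has no class column, a single label assigned to
#'   every cell (typical for one-file-per-stain exports).
#' @param schema optional [channel_schema()]; when supplied, cell classes not
#'   used by any channel are rejected with an error naming the class.
#' @param scale micrometers per coordinate unit (default 1).
#' @param sep field separator.
#' @return A `cell_table`.
#' @export
read_cell_table <- function(path, column_map = list(x = "X", y = "Y"),
                            kind = NULL, schema = NULL, scale = 1,
                            sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  for (field in c("x", "y")) {
    if (is.null(column_map[[field]]))
      stop(sprintf("column_map must name a '%s' column", field))
  }
  missing_cols <- setdiff(unlist(column_map), names(raw))
  if (length(missing_cols) > 0)
    stop("mapped column(s) not in file: ", paste(missing_cols, collapse = ", "))
  get_num <- function(col) {
    v <- raw[[col]]
    vn <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(vn) & !is.na(v))
    if (length(bad) > 0)
      stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                   col, bad[1], v[bad[1]]))
    vn
  }
  x <- get_num(column_map$x) * scale
  y <- get_num(column_map$y) * scale
  kinds <- if (!is.null(column_map$kind)) {
    as.character(raw[[column_map$kind]])
  } else if (!is.null(kind)) {
    rep(kind, nrow(raw))
  } else {
    rep("cell", nrow(raw))
  }
  ct <- cell_table(x, y, kinds)
  prop_fields <- setdiff(names(column_map), c("x", "y", "kind"))
  for (nm in prop_fields) ct[[nm]] <- get_num(column_map[[nm]])
  if (!is.null(schema)) {
    known <- unique(unlist(lapply(schema$channels, function(ch) ch$kind)))
    unknown <- setdiff(unique(ct$kind), known)
    if (length(unknown) > 0)
      stop("cell class not in channel schema: ",
           paste(unknown, collapse = ", "))
  }
  ct
}

#' Write a cell table to CSV (with optional JSON sidecar)
#'
#' Coordinates are written at full double precision so that a write/read
#' round trip reproduces the table exactly. When the table was produced by
#' [simulate_abm()], a JSON sidecar `<path>.json` records the generating
#' parameters, configuration and seed.
#'
#' @param ct a `cell_table`.
#' @param path output CSV path.
#' @param sidecar write the JSON provenance sidecar if metadata is present.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(ct, path, sidecar = TRUE) {
  df <- as.data.frame(ct)
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  for (nm in names(df)[num]) out[[nm]] <- sprintf("%.17g", df[[nm]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (sidecar && !is.null(attr(ct, "params"))) {
    meta <- list(params = unclass(attr(ct, "params")),
                 variant = attr(attr(ct, "params"), "variant"),
                 config = unclass(attr(ct, "config")),
                 seed = attr(ct, "seed"),
                 extinct = isTRUE(attr(ct, "extinct")))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
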