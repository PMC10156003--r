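#' Channel schema
#'
#' Declares how cell classes and properties map to the channels of a
#' simplified image: one grid per cell type or property. A `presence` channel
#' is 0/1 (is any cell of the given kind(s) in the grid site); a `continuous`
#' channel accumulates a per-cell property over the site and is scaled so the
#' grid maximum is one.
#'
#' @param ... channels built with [channel()].
#' @return An object of class `channel_schema`.
#' @examples
#' channel_schema(channel("tumor", kind = "tumor_live"),
#'                channel("pdl1", mode = "continuous", kind = "tumor_live",
#'                        property = "pdl1"))
#' @export
channel_schema <- function(...) {
  channels <- list(...)
  if (length(channels) == 0) stop("a schema needs at least one channel")
  if (!all(vapply(channels, inherits, logical(1), "abmcal_channel")))
    stop("all arguments must be created with channel()")
  nms <- vapply(channels, function(ch) ch$name, character(1))
  if (anyDuplicated(nms)) stop("channel names must be unique")
  structure(list(channels = channels, names = nms),
            class = "channel_schema")
}

#' @rdname channel_schema
#' @param name channel name (unique within a schema).
#' @param mode `"presence"` or `"continuous"`.
#' @param kind cell class label(s) feeding this channel; for continuous
#'   channels `NULL` means all classes.
#' @param property for continuous channels, the cell-table property column
#'   to accumulate.
#' @param aggregate for continuous channels, `"sum"` (default; per-site sum of
#'   the property before max-normalization) or `"mean"`.
#' @export
channel <- function(name, mode = c("presence", "continuous"), kind = NULL,
                    property = NULL, aggregate = c("sum", "mean")) {
  mode <- match.arg(mode)
  aggregate <- match.arg(aggregate)
  if (mode == "presence" && is.null(kind))
    stop("a presence channel needs a 'kind'")
  if (mode == "continuous" && is.null(property))
    stop("a continuous channel needs a 'property'")
  structure(list(name = name, mode = mode, kind = kind, property = property,
                 aggregate = aggregate),
            class = "abmcal_channel")
}

#' Stock schemas for the example models
#'
#' `schema_ex1()` is the four-channel layout of the PD-L1 model snapshot:
#' live tumor cells, active T cells, suppressed T cells, and PD-L1 expression.
#' `schema_ex2()` holds live and dead tumor cells; `schema_ex2_dead()` is the
#' single dead-cell channel used for fitting to a live/dead stain where only
#' dead-cell locations are compared.
#'
#' @return A [channel_schema()].
#' @export
schema_ex1 <- function() {
  channel_schema(
    channel("tumor", kind = "tumor_live"),
    channel("tcell_active", kind = "tcell_active"),
    channel("tcell_suppressed", kind = "tcell_suppressed"),
    channel("pdl1", mode = "continuous", kind = "tumor_live",
            property = "pdl1"))
}

#' @rdname schema_ex1
#' @export
schema_ex2 <- function() {
  channel_schema(channel("tumor_live", kind = "tumor_live"),
                 channel("tumor_dead", kind = "tumor_dead"))
}

#' @rdname schema_ex1
#' @export
schema_ex2_dead <- function() {
  channel_schema(channel("tumor_dead", kind = "tumor_dead"))
}

#' Rasterize a cell table to per-channel grids
#'
#' Discretizes continuous cell coordinates to a grid whose sites are one cell
#' diameter across: site `(i, j)` covers the half-open square
#' `[min + (i-1)*d, min + i*d)` in each axis, measured from the minimum cell
#' coordinate. Presence channels are set to 1 wherever at least one matching
#' cell falls; continuous channels accumulate the property per site and are
#' scaled to a maximum of one. Rows index y (increasing downward), columns x.
#'
#' @param cells a `cell_table` with at least one cell.
#' @param schema a [channel_schema()].
#' @param cell_diameter grid spacing, micrometers (> 0).
#' @return A `grid_stack`: a 3-D array (rows x cols x channels) with
#'   attributes `channels`, `cell_diameter` and `origin`.
#' @export
rasterize_cells <- function(cells, schema, cell_diameter) {
  if (!inherits(schema, "channel_schema")) stop("'schema' must be a channel_schema")
  if (nrow(cells) == 0) stop("cannot rasterize an empty cell table")
  if (!is.numeric(cell_diameter) || cell_diameter <= 0)
    stop("'cell_diameter' must be positive")
  origin <- c(x = min(cells$x), y = min(cells$y))
  col <- floor((cells$x - origin[["x"]]) / cell_diameter) + 1L
  row <- floor((cells$y - origin[["y"]]) / cell_diameter) + 1L
  nr <- max(row)
  nc <- max(col)
  g <- array(0, dim = c(nr, nc, length(schema$channels)))
  for (k in seq_along(schema$channels)) {
    ch <- schema$channels[[k]]
    sel <- if (is.null(ch$kind)) rep(TRUE, nrow(cells)) else cells$kind %in% ch$kind
    if (!any(sel)) next
    lin <- (col[sel] - 1L) * nr + row[sel]
    if (ch$mode == "presence") {
      plane <- numeric(nr * nc)
      plane[lin] <- 1
    } else {
      if (is.null(cells[[ch$property]]))
        stop(sprintf("cell table has no property '%s' for channel '%s'",
                     ch$property, ch$name))
      v <- cells[[ch$property]][sel]
      agg <- rowsum(v, lin)
      plane <- numeric(nr * nc)
      plane[as.integer(rownames(agg))] <- agg[, 1]
      if (ch$aggregate == "mean") {
        cnt <- rowsum(rep(1, length(lin)), lin)
        plane[as.integer(rownames(cnt))] <-
          plane[as.integer(rownames(cnt))] / cnt[, 1]
      }
      mx <- max(plane)
      if (mx > 0) plane <- plane / mx
    }
    g[, , k] <- plane
  }
  structure(g, channels = schema$names, cell_diameter = cell_diameter,
            origin = origin, class = "grid_stack")
}

#' Crop a grid stack to the tumor bounding box
#'
#' Returns the minimal sub-array over rows and columns where any of the named
#' tumor channels is nonzero; all channels are cropped identically, so the
#' crop removes the absolute position of the tumor in the frame.
#'
#' @param grids a `grid_stack` from [rasterize_cells()].
#' @param tumor_channels channel names defining the tumor extent.
#' @return A cropped `grid_stack`.
#' @export
crop_to_tumor <- function(grids, tumor_channels) {
  chs <- attr(grids, "channels")
  idx <- match(tumor_channels, chs)
  if (anyNA(idx))
    stop("unknown tumor channel(s): ",
         paste(tumor_channels[is.na(idx)], collapse = ", "))
  mask <- apply(grids[, , idx, drop = FALSE], c(1, 2), function(v) any(v > 0))
  if (!any(mask)) stop("all tumor channels are empty; cannot crop")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  out <- grids[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  structure(out, channels = chs,
            cell_diameter = attr(grids, "cell_diameter"),
            origin = attr(grids, "origin"), class = "grid_stack")
}

# exact area-overlap weights for resampling a length-n_in axis to n_out:
# W[i, j] is the fraction of output interval i covered by input interval j,
# so W %*% x is the area-weighted mean (rows sum to one)
area_weights <- function(n_in, n_out) {
  scale <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    j0 <- floor(lo) + 1
    j1 <- min(n_in, ceiling(hi))
    for (j in j0:j1) {
      ov <- max(0, min(hi, j) - max(lo, j - 1))
      if (ov > 0) W[i, j] <- ov / scale
    }
  }
  W
}

#' Downsample a grid stack to a fixed-size simplified image
#'
#' Per-channel area-weighted average resampling (area interpolation) to the
#' target size, aggregating discrete cell locations into regions of cell
#' density, followed by a per-channel rescale so every value lies in \[0, 1\]
#' and each nonzero channel attains 1. Non-square inputs are resized
#' anisotropically, so relative shape rather than absolute size is what the
#' output represents.
#'
#' @param grids a `grid_stack`.
#' @param target integer `(height, width)` of the output, both >= 1.
#' @return A `simplified_image`: 3-D array (H x W x channels) in \[0, 1\] with
#'   a `channels` attribute.
#' @export
downsample_grid <- function(grids, target = c(32, 32)) {
  if (length(target) != 2 || any(target < 1))
    stop("'target' must be two positive integers")
  d <- dim(grids)
  if (target[1] > d[1] || target[2] > d[2])
    message(sprintf("upsampling grid %dx%d to %dx%d", d[1], d[2],
                    target[1], target[2]))
  Wr <- area_weights(d[1], target[1])
  Wc <- area_weights(d[2], target[2])
  out <- array(0, dim = c(target[1], target[2], d[3]))
  for (k in seq_len(d[3])) {
    plane <- Wr %*% grids[, , k] %*% t(Wc)
    mx <- max(plane)
    if (mx > 0) plane <- plane / mx
    out[, , k] <- plane
  }
  structure(out, channels = attr(grids, "channels"),
            class = "simplified_image")
}

#' Processing specification
#'
#' Bundles everything needed to turn a cell table into a simplified image:
#' the channel schema, the grid spacing, which channels define the tumor
#' extent for cropping, the output size, and (optionally) the subset of
#' channels retained for fitting.
#'
#' @param schema a [channel_schema()].
#' @param cell_diameter grid spacing, micrometers.
#' @param tumor_channels channel names defining the tumor extent; defaults to
#'   channels whose kinds start with `"tumor"`.
#' @param target output `(height, width)`, default `c(32, 32)`.
#' @param fit_channels channel names kept in the final image (`NULL` = all).
#' @return An object of class `process_spec`.
#' @export
process_spec <- function(schema, cell_diameter = 20, tumor_channels = NULL,
                         target = c(32, 32), fit_channels = NULL) {
  if (is.null(tumor_channels)) {
    is_tumor <- vapply(schema$channels, function(ch) {
      ch$mode == "presence" && any(startsWith(ch$kind, "tumor"))
    }, logical(1))
    tumor_channels <- schema$names[is_tumor]
    if (length(tumor_channels) == 0) tumor_channels <- schema$names[1]
  }
  if (!is.null(fit_channels) && !all(fit_channels %in% schema$names))
    stop("fit_channels must be a subset of the schema channel names")
  structure(list(schema = schema, cell_diameter = cell_diameter,
                 tumor_channels = tumor_channels, target = target,
                 fit_channels = fit_channels),
            class = "process_spec")
}

#' @rdname process_spec
#' @export
process_spec_ex1 <- function(cell_diameter = 20, target = c(32, 32)) {
  process_spec(schema_ex1(), cell_diameter = cell_diameter,
               tumor_channels = "tumor", target = target)
}

#' @rdname process_spec
#' @export
process_spec_ex2_dead <- function(cell_diameter = 20, target = c(32, 32)) {
  sch <- schema_ex2()
  process_spec(sch, cell_diameter = cell_diameter,
               tumor_channels = c("tumor_live", "tumor_dead"),
               target = target, fit_channels = "tumor_dead")
}

#' Cell table to simplified image
#'
#' The full processing pipeline: rasterize to per-channel grids, crop to the
#' tumor bounding box, area-interpolate down to the target size, rescale each
#' channel to \[0, 1\], and restrict to the fitting channels. Deterministic,
#' translation-invariant (the crop removes any constant offset of the
#' coordinates) and invariant to scaling coordinates and grid spacing by a
#' common integer factor.
#'
#' @param cells a `cell_table`.
#' @param spec a [process_spec()].
#' @return A `simplified_image`.
#' @examples
#' ct <- cell_table(x = runif(200, 0, 400), y = runif(200, 0, 400),
#'                  kind = "tumor_live", pdl1 = runif(200, 0, 0.01))
#' img <- process_cells(ct, process_spec_ex1(target = c(8, 8)))
#' range(img)
#' @export
process_cells <- function(cells, spec) {
  if (!inherits(spec, "process_spec")) stop("'spec' must be a process_spec")
  g <- rasterize_cells(cells, spec$schema, spec$cell_diameter)
  g <- crop_to_tumor(g, spec$tumor_channels)
  img <- downsample_grid(g, spec$target)
  if (!is.null(spec$fit_channels)) {
    keep <- match(spec$fit_channels, attr(img, "channels"))
    img <- structure(img[, , keep, drop = FALSE],
                     channels = spec$fit_channels,
                     class = "simplified_image")
  }
  img
}

#' @export
print.simplified_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<simplified_image> %dx%d, %d channel(s): %s; range [%.3g, %.3g]\n",
              d[1], d[2], d[3],
              paste(attr(x, "channels"), collapse = ", "),
              min(x), max(x)))
  invisible(x)
}

#' Write / read a simplified image as JSON
#'
#' Portable plain-text container for simplified images: dimensions, channel
#' names and values (column-major) with full numeric precision.
#'
#' @param img a `simplified_image`.
#' @param path output path.
#' @return `path` (write) or a `simplified_image` (read).
#' @export
write_simplified_image <- function(img, path) {
  obj <- list(dim = dim(img), channels = attr(img, "channels"),
              values = as.vector(img))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname write_simplified_image
#' @export
read_simplified_image <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(array(obj$values, dim = obj$dim), channels = obj$channels,
            class = "simplified_image")
}
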