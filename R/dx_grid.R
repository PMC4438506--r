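#' Construct a scalar grid
#'
#' Regular 3-D scalar field on an axis-aligned grid, the in-memory form of an
#' OpenDX scalar file (APBS dialect).
#'
#' @param origin 3-vector, position of the first grid node (Angstrom).
#' @param spacing 3-vector (or scalar) of node spacings per axis (Angstrom).
#' @param values 3-D array of node values, dimension = grid shape, or a
#'   vector together with `shape`. Storage order follows the OpenDX
#'   convention: the LAST index (z) varies fastest.
#' @param shape integer 3-vector; required when `values` is not an array.
#' @return Object of class `scalar_grid` with fields `origin`, `spacing`,
#'   `shape` and `values` (array indexed `[ix, iy, iz]`).
#' @export
scalar_grid <- function(origin, spacing, values, shape = dim(values)) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  stopifnot(length(origin) == 3L, all(spacing > 0), length(shape) == 3L)
  shape <- as.integer(shape)
  if (!is.array(values)) {
    stopifnot(length(values) == prod(shape))
    ## z-fastest (OpenDX) order -> R array (x-fastest) by filling the
    ## transposed array and flipping
    values <- aperm(array(values, dim = rev(shape)), 3:1)
  }
  stopifnot(identical(dim(values), shape))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 shape = shape, values = values),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("scalar grid %d x %d x %d, origin (%g, %g, %g) A, spacing (%g, %g, %g) A\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$origin[1], x$origin[2], x$origin[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Read an OpenDX scalar grid (APBS dialect)
#'
#' Parses the ASCII OpenDX scalar-grid format written by APBS: a
#' `gridpositions counts` object giving the shape, `origin` and three `delta`
#' lines giving the geometry, and a `class array` object whose data stream
#' lists node values (three per line, z index varying fastest). Comment lines
#' (`#`) are ignored.
#'
#' @param path file path.
#' @return A `scalar_grid`.
#' @export
read_dx_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines)
  lines <- lines[keep]
  lineno <- which(keep)  # original line numbers for error messages

  hit <- grep("object\\s+\\S+\\s+class\\s+gridpositions\\s+counts", lines)
  if (!length(hit))
    stop("not an OpenDX grid: no 'gridpositions counts' object", call. = FALSE)
  shape <- as.integer(strsplit(trimws(sub(".*counts", "", lines[hit[1]])),
                               "\\s+")[[1]])
  if (length(shape) != 3L || anyNA(shape))
    stop(sprintf("dx parse error at line %d: bad counts", lineno[hit[1]]),
         call. = FALSE)

  ohit <- grep("^\\s*origin\\s", lines)
  if (!length(ohit))
    stop("dx parse error: missing 'origin' line", call. = FALSE)
  origin <- as.numeric(strsplit(trimws(sub("^\\s*origin", "", lines[ohit[1]])),
                                "\\s+")[[1]])

  dhit <- grep("^\\s*delta\\s", lines)
  if (length(dhit) < 3L)
    stop("dx parse error: expected three 'delta' lines", call. = FALSE)
  deltas <- t(vapply(lines[dhit[1:3]], function(l)
    as.numeric(strsplit(trimws(sub("^\\s*delta", "", l)), "\\s+")[[1]]),
    numeric(3)))
  if (any(abs(deltas[upper.tri(deltas) | lower.tri(deltas)]) > 0))
    stop("dx grids with non-axis-aligned deltas are not supported", call. = FALSE)
  spacing <- diag(deltas)

  ahit <- grep("object\\s+\\S+\\s+class\\s+array", lines)
  if (!length(ahit))
    stop("dx parse error: missing data array object", call. = FALSE)
  nexp <- prod(shape)
  data_lines <- lines[(ahit[1] + 1L):length(lines)]
  stop_at <- grep("^\\s*(attribute|object|component)", data_lines)
  if (length(stop_at)) data_lines <- data_lines[seq_len(stop_at[1] - 1L)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(data_lines), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != nexp)
    stop(sprintf("dx parse error near line %d: expected %d values, found %d",
                 lineno[ahit[1]], nexp, length(vals)), call. = FALSE)
  scalar_grid(origin, spacing, vals, shape)
}

#' Write an OpenDX scalar grid (APBS dialect)
#'
#' Inverse of [read_dx_grid()]; values round-trip bit-identically at the
#' default 17 significant digits.
#'
#' @param grid a `scalar_grid`.
#' @param path output file path.
#' @param digits significant digits for the data stream.
#' @return `path`, invisibly.
#' @export
write_dx_grid <- function(grid, path, digits = 17) {
  stopifnot(inherits(grid, "scalar_grid"))
  sh <- grid$shape
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid",
    sprintf("object 1 class gridpositions counts %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("origin %.10g %.10g %.10g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.10g 0 0", grid$spacing[1]),
    sprintf("delta 0 %.10g 0", grid$spacing[2]),
    sprintf("delta 0 0 %.10g", grid$spacing[3]),
    sprintf("object 2 class gridconnections counts %d %d %d", sh[1], sh[2], sh[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(sh))), con)
  ## z varies fastest in the stream
  v <- as.vector(aperm(grid$values, 3:1))
  fmt <- formatC(v, digits = digits, format = "g")
  pad <- (3 - length(fmt) %% 3) %% 3
  if (pad) fmt <- c(fmt, rep("", pad))
  writeLines(apply(matrix(fmt, ncol = 3, byrow = TRUE), 1, paste, collapse = " "),
             con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Trilinear interpolation of a scalar grid
#'
#' Standard trilinear interpolation among the 8 nodes of the enclosing grid
#' cell; exact for fields that are (tri)linear in the coordinates.
#'
#' @param grid a `scalar_grid`.
#' @param points N x 3 coordinate matrix (Angstrom).
#' @param out_of_box `"error"` to refuse points outside the grid bounding
#'   box, `"clamp"` to project them onto the nearest face/edge/corner (the
#'   count of clamped points is reported with a message).
#' @return Numeric vector of interpolated values.
#' @export
trilinear_sample <- function(grid, points, out_of_box = c("error", "clamp")) {
  stopifnot(inherits(grid, "scalar_grid"))
  out_of_box <- match.arg(out_of_box)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  u <- sweep(sweep(points, 2L, grid$origin), 2L, grid$spacing, "/")
  hi <- grid$shape - 1L
  outside <- u[, 1] < 0 | u[, 1] > hi[1] |
             u[, 2] < 0 | u[, 2] > hi[2] |
             u[, 3] < 0 | u[, 3] > hi[3]
  if (any(outside)) {
    if (out_of_box == "error")
      stop(sprintf("%d point(s) outside the grid bounding box", sum(outside)),
           call. = FALSE)
    message(sprintf("trilinear_sample: clamped %d point(s) to the grid boundary",
                    sum(outside)))
    for (ax in 1:3) u[, ax] <- pmin(pmax(u[, ax], 0), hi[ax])
  }
  i0 <- pmin(floor(u), matrix(hi - 1L, nrow(u), 3L, byrow = TRUE))
  i0 <- pmax(i0, 0)
  f <- u - i0
  i0 <- i0 + 1L  # 1-based
  v <- grid$values
  idx <- function(ox, oy, oz)
    v[cbind(i0[, 1] + ox, i0[, 2] + oy, i0[, 3] + oz)]
  (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) * idx(0L, 0L, 0L) +
    f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) * idx(1L, 0L, 0L) +
    (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) * idx(0L, 1L, 0L) +
    (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] * idx(0L, 0L, 1L) +
    f[, 1] * f[, 2] * (1 - f[, 3]) * idx(1L, 1L, 0L) +
    f[, 1] * (1 - f[, 2]) * f[, 3] * idx(1L, 0L, 1L) +
    (1 - f[, 1]) * f[, 2] * f[, 3] * idx(0L, 1L, 1L) +
    f[, 1] * f[, 2] * f[, 3] * idx(1L, 1L, 1L)
}
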