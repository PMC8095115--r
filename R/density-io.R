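#' Construct a density map
#'
#' A regular axis-aligned 3D grid of nonnegative values. The voxel center of
#' 0-based index `(i, j, k)` is `origin + spacing * (i, j, k)`.
#'
#' @param origin numeric length-3 grid origin in Angstrom.
#' @param spacing positive voxel edge length in Angstrom (uniform).
#' @param values 3D numeric array of finite, nonnegative values.
#' @param weight_mode `"mass"` or `"occupancy"`.
#' @param n_frames_averaged number of frames averaged into the map.
#' @return an object of class `density_map`.
#' @export
density_map <- function(origin, spacing, values,
                        weight_mode = c("occupancy", "mass"),
                        n_frames_averaged = 1L) {
  weight_mode <- match.arg(weight_mode)
  if (length(origin) != 3) stop("density_map: origin must have length 3")
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("density_map: spacing must be a positive scalar")
  if (!is.array(values) || length(dim(values)) != 3)
    stop("density_map: values must be a 3D array")
  if (!all(is.finite(values)) || any(values < 0))
    stop("density_map: values must be finite and >= 0")
  if (n_frames_averaged < 1) stop("density_map: n_frames_averaged must be >= 1")
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = dim(values), values = values, weight_mode = weight_mode,
                 n_frames_averaged = as.integer(n_frames_averaged)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Density map: %d x %d x %d voxels, spacing %.3g A, %s-weighted, %d frame(s) averaged\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing, x$weight_mode,
              x$n_frames_averaged))
  cat(sprintf("  origin (%.2f, %.2f, %.2f), integral %.4g\n", x$origin[1],
              x$origin[2], x$origin[3], map_integral(x)))
  invisible(x)
}

#' Integral of a density map (sum of values times voxel volume)
#' @param map a `density_map`.
#' @return numeric scalar.
#' @export
map_integral <- function(map) sum(map$values) * map$spacing^3

#' Write a density map as an OpenDX scalar grid
#'
#' Standard `gridpositions`/`gridconnections`/`array` OpenDX layout with the
#' data ordered z-fastest; `weight_mode` and `n_frames_averaged` are
#' recorded in comment lines so maps round-trip.
#'
#' @param map a `density_map`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  d <- map$dims
  writeLines(c(sprintf("# weight_mode: %s", map$weight_mode),
               sprintf("# n_frames_averaged: %d", map$n_frames_averaged),
               sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
               sprintf("origin %.9g %.9g %.9g", map$origin[1], map$origin[2], map$origin[3]),
               sprintf("delta %.9g 0 0", map$spacing),
               sprintf("delta 0 %.9g 0", map$spacing),
               sprintf("delta 0 0 %.9g", map$spacing),
               sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
               sprintf("object 3 class array type double rank 0 items %d data follows",
                       prod(d))), con)
  vals <- as.vector(aperm(map$values, c(3, 2, 1)))   # z fastest, x slowest
  n3 <- (length(vals) %/% 3) * 3
  if (n3 > 0) {
    m <- matrix(sprintf("%.9g", vals[seq_len(n3)]), ncol = 3, byrow = TRUE)
    writeLines(paste(m[, 1], m[, 2], m[, 3]), con)
  }
  if (n3 < length(vals))
    writeLines(paste(sprintf("%.9g", vals[(n3 + 1):length(vals)]), collapse = " "), con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"density\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' Read an OpenDX scalar grid
#'
#' Accepts axis-aligned grids with uniform, equal spacing on all three axes
#' (anything else raises an unsupported-dialect error). `weight_mode`
#' defaults to `"occupancy"` unless annotated in a comment line.
#'
#' @param path OpenDX file path.
#' @return a [density_map()].
#' @export
read_density_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta_mode <- sub("^# weight_mode: *", "", grep("^# weight_mode:", lines, value = TRUE))
  meta_nf <- sub("^# n_frames_averaged: *", "",
                 grep("^# n_frames_averaged:", lines, value = TRUE))
  gp <- grep("class gridpositions counts", lines)
  if (length(gp) == 0) stop("not an OpenDX grid: no gridpositions object in ", path)
  counts <- as.integer(strsplit(trimws(sub(".*counts", "", lines[gp[1]])), "[ \t]+")[[1]])
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 1))
    stop(sprintf("line %d: malformed gridpositions counts", gp[1]))
  og <- grep("^origin", lines)
  if (length(og) == 0) stop("no origin record in ", path)
  origin <- as.numeric(strsplit(trimws(sub("^origin", "", lines[og[1]])), "[ \t]+")[[1]])
  dl <- grep("^delta", lines)
  if (length(dl) < 3) stop("expected 3 delta records in ", path)
  deltas <- t(vapply(lines[dl[1:3]], function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), "[ \t]+")[[1]]),
    numeric(3), USE.NAMES = FALSE))
  offdiag <- deltas; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-12) ||
      abs(deltas[1, 1] - deltas[2, 2]) > 1e-9 * abs(deltas[1, 1]) ||
      abs(deltas[1, 1] - deltas[3, 3]) > 1e-9 * abs(deltas[1, 1]))
    stop("unsupported OpenDX dialect: grid spacing must be uniform and axis-aligned")
  spacing <- deltas[1, 1]
  da <- grep("data follows", lines)
  if (length(da) == 0) stop("no data section in ", path)
  items <- as.integer(sub(".*items +([0-9]+) +data follows.*", "\\1", lines[da[1]]))
  if (is.na(items) || items != prod(counts))
    stop(sprintf("line %d: item count does not match grid dimensions", da[1]))
  body <- lines[seq.int(da[1] + 1, length.out = length(lines) - da[1])]
  stop_at <- grep("^[[:space:]]*(attribute|object)", body)
  end <- if (length(stop_at) > 0) stop_at[1] - 1 else length(body)
  txt <- trimws(body[seq_len(end)])
  vals <- suppressWarnings(as.numeric(unlist(strsplit(txt[nzchar(txt)], "[ \t]+"))))
  if (anyNA(vals)) stop("non-numeric value in data section of ", path)
  if (length(vals) < items)
    stop(sprintf("line %d: truncated data section (%d of %d values read)",
                 da[1] + end, length(vals), items))
  if (length(vals) > items) stop("more data values than declared items in ", path)
  values <- aperm(array(vals, dim = rev(counts)), c(3, 2, 1))
  density_map(origin, spacing, values,
              weight_mode = if (length(meta_mode) > 0) meta_mode[1] else "occupancy",
              n_frames_averaged = if (length(meta_nf) > 0) as.integer(meta_nf[1]) else 1L)
}

# Trilinear interpolation of a density map at arbitrary points (n x 3).
# Points outside the grid domain return NA.
sample_map <- function(map, pts) {
  pts <- as.matrix(pts)
  d <- map$dims
  f <- sweep(pts, 2, map$origin) / map$spacing
  ok <- f[, 1] >= 0 & f[, 1] <= d[1] - 1 &
    f[, 2] >= 0 & f[, 2] <= d[2] - 1 &
    f[, 3] >= 0 & f[, 3] <= d[3] - 1
  out <- rep(NA_real_, nrow(pts))
  if (!any(ok)) return(out)
  fo <- f[ok, , drop = FALSE]
  i0 <- pmin(floor(fo), matrix(rep(d - 2, each = nrow(fo)), ncol = 3))
  i0 <- pmax(i0, 0)
  fr <- fo - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
      (if (dy) fr[, 2] else 1 - fr[, 2]) *
      (if (dz) fr[, 3] else 1 - fr[, 3])
    acc <- acc + w * map$values[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1,
                                      i0[, 3] + dz + 1)]
  }
  out[ok] <- acc
  out
}

# Voxel-center coordinates of a map, as an (n_voxel x 3) matrix in x-fastest
# order matching as.vector(map$values).
voxel_centers <- function(map) {
  d <- map$dims
  cbind(map$origin[1] + map$spacing * (rep.int(seq_len(d[1]), d[2] * d[3]) - 1),
        map$origin[2] + map$spacing * (rep.int(rep(seq_len(d[2]), each = d[1]), d[3]) - 1),
        map$origin[3] + map$spacing * (rep(seq_len(d[3]), each = d[1] * d[2]) - 1))
}
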