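#' Box-counting fractal dimension of a time-activity curve
#'
#' Measures the temporal heterogeneity ("chaotic-ness") of a tracer curve
#' as a box-counting dimension. The piecewise-linear TAC is normalized into
#' the unit square (time min-max mapped to `[0,1]`, value min-max mapped to
#' `[0,1]`; a constant curve maps to the horizontal mid-line `y = 0.5` and
#' is flagged degenerate). For each dyadic level `k` the square is
#' partitioned into `2^k x 2^k` boxes and the number `N(k)` of boxes
#' intersected by the curve is counted exactly by walking each segment
#' through the grid. The fractal dimension is the least-squares slope of
#' `log N` versus `log(1/eps)`, clamped to `[0, 2]` (with a warning if the
#' raw slope falls outside). A straight line — constant or diagonal — has
#' dimension 1; increasingly irregular curves approach 2.
#'
#' Box membership convention: a point belongs to box
#' `(floor(x * 2^k), floor(y * 2^k))`, with indices clamped to the top row /
#' right column so that the square's upper and right edges are included.
#'
#' @param tac A [tissue_tac()], or a numeric vector of frame values (then
#'   `times` must be given).
#' @param levels Integer vector of dyadic subdivision levels (default
#'   `1:4`, i.e. box sizes 1/2 ... 1/16); at least 3 levels.
#' @param times Frame times (any monotone unit) when `tac` is a bare
#'   numeric vector.
#' @return A list of class `fd_result`: `fd` (unitless, in `[0, 2]`),
#'   `box_counts` (named `N` per level), `degenerate` (`TRUE` for a
#'   zero-dynamic-range curve), `raw_slope`.
#' @examples
#' p <- default_protocol()
#' fd_boxcount(tissue_tac(p, seq_len(24)))$fd   # straight line: 1
#' @export
fd_boxcount <- function(tac, levels = 1:4, times = NULL) {
  if (inherits(tac, "tissue_tac")) {
    values <- tac$values
    times <- frame_mid_times(tac$protocol)
  } else {
    values <- as.numeric(tac)
    if (is.null(times)) stop("times must be supplied for a bare value vector")
    times <- as.numeric(times)
  }
  if (length(values) < 4L) stop("at least 4 frames are required")
  if (length(times) != length(values)) stop("times/values length mismatch")
  if (any(!is.finite(values)) || any(!is.finite(times)))
    stop("non-finite values in TAC")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  levels <- sort(unique(as.integer(levels)))
  if (length(levels) < 3L || any(levels < 1L))
    stop("at least 3 dyadic levels >= 1 are required")

  x <- (times - times[1]) / (times[length(times)] - times[1])
  rng <- range(values)
  degenerate <- (rng[2] - rng[1]) == 0
  y <- if (degenerate) rep(0.5, length(values)) else
    (values - rng[1]) / (rng[2] - rng[1])

  counts <- vapply(levels, function(k) count_boxes_polyline(x, y, k),
                   numeric(1))
  names(counts) <- paste0("k", levels)
  raw <- stats::cov(log(2^levels), log(counts)) / stats::var(log(2^levels))
  fd <- raw
  if (raw < 0 || raw > 2) {
    warning("raw box-count slope ", format(raw), " outside [0, 2]; clamped")
    fd <- min(max(raw, 0), 2)
  }
  structure(list(fd = fd, box_counts = counts, degenerate = degenerate,
                 raw_slope = raw, levels = levels),
            class = "fd_result")
}

# Exact occupied-box count for a polyline in the unit square at dyadic
# level k: split every segment at all gridline crossings and assign each
# non-degenerate sub-segment by its midpoint (interior of exactly one box
# unless the sub-segment lies on a gridline, where floor() gives the upper
# neighbour consistently).
count_boxes_polyline <- function(x, y, k) {
  nb <- 2L^k
  eps <- 1 / nb
  clamp <- function(i) pmin(pmax(i, 0L), nb - 1L)
  cells <- integer(0)
  for (s in seq_len(length(x) - 1L)) {
    x0 <- x[s]; x1 <- x[s + 1L]; y0 <- y[s]; y1 <- y[s + 1L]
    ts <- c(0, 1)
    if (x1 != x0) {
      g <- seq_len(nb - 1L) * eps
      g <- g[g > min(x0, x1) & g < max(x0, x1)]
      ts <- c(ts, (g - x0) / (x1 - x0))
    }
    if (y1 != y0) {
      g <- seq_len(nb - 1L) * eps
      g <- g[g > min(y0, y1) & g < max(y0, y1)]
      ts <- c(ts, (g - y0) / (y1 - y0))
    }
    ts <- sort(unique(ts))
    keep <- diff(ts) > 1e-14
    if (!any(keep)) next
    tm <- (ts[-length(ts)][keep] + ts[-1][keep]) / 2
    ci <- clamp(as.integer(floor((x0 + tm * (x1 - x0)) / eps)))
    cj <- clamp(as.integer(floor((y0 + tm * (y1 - y0)) / eps)))
    cells <- c(cells, ci * nb + cj)
  }
  length(unique(cells))
}

#' A VOI of voxel-level dynamic curves
#'
#' @param protocol The shared [acquisition_protocol()].
#' @param voxel_values Numeric matrix, voxels x frames.
#' @param voxel_ids Optional integer voxel labels (default row index).
#' @return An object of class `voxel_dynamic_voi`.
#' @export
voxel_dynamic_voi <- function(protocol, voxel_values, voxel_ids = NULL) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  voxel_values <- as.matrix(voxel_values)
  if (nrow(voxel_values) < 1L) stop("at least 1 voxel is required")
  if (ncol(voxel_values) != protocol$n_frames)
    stop("voxel matrix must have one column per frame")
  if (any(!is.finite(voxel_values))) stop("voxel values must be finite")
  if (is.null(voxel_ids)) voxel_ids <- seq_len(nrow(voxel_values))
  if (length(voxel_ids) != nrow(voxel_values))
    stop("voxel_ids length mismatch")
  structure(list(protocol = protocol, voxel_values = voxel_values,
                 voxel_ids = as.integer(voxel_ids)),
            class = "voxel_dynamic_voi")
}

#' Fractal dimension of a VOI
#'
#' Computes [fd_boxcount()] for each voxel curve of the VOI and summarizes
#' the VOI by the arithmetic mean of the per-voxel dimensions (the
#' aggregation is isolated here so an alternative summary can be swapped
#' in).
#'
#' @param voi A [voxel_dynamic_voi()].
#' @param levels Dyadic levels passed to [fd_boxcount()].
#' @return A list of class `fractal_result`: `per_voxel_fd`, `voi_fd`
#'   (mean), `box_counts` (voxels x levels matrix), `degenerate` (per
#'   voxel).
#' @export
voi_fd <- function(voi, levels = 1:4) {
  stopifnot(inherits(voi, "voxel_dynamic_voi"))
  times <- frame_mid_times(voi$protocol)
  res <- lapply(seq_len(nrow(voi$voxel_values)), function(i)
    fd_boxcount(voi$voxel_values[i, ], levels = levels, times = times))
  per_voxel <- vapply(res, `[[`, numeric(1), "fd")
  structure(list(
    per_voxel_fd = stats::setNames(per_voxel, voi$voxel_ids),
    voi_fd = mean(per_voxel),
    box_counts = do.call(rbind, lapply(res, `[[`, "box_counts")),
    degenerate = vapply(res, `[[`, logical(1), "degenerate")),
    class = "fractal_result")
}
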