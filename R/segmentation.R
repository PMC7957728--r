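#' Isocontour volume-of-interest extraction
#'
#' Simplified fraction-of-maximum isocontour segmentation used to delimit
#' lesions and reference organs on a summed or single-frame image. From
#' the seed voxel the positive-valued connected region is grown
#' (face-adjacency: 4-connectivity in 2D, 6 in 3D), its peak intensity is
#' located, the threshold is set to `fraction x peak`, and the returned
#' mask is the face-connected component of voxels `>= threshold` that
#' contains the peak. With the default `fraction = 0.5` this reproduces
#' the 50%-of-maximum semantics of clinical isocontour VOI tools.
#'
#' The mask is invariant under multiplication of the image by any positive
#' scalar, and raising `fraction` never grows it.
#'
#' @param grid Numeric vector, matrix or 3D array of voxel intensities
#'   (finite).
#' @param seed Integer voxel index: position for a vector, `c(row, col)`
#'   for a matrix, `c(i, j, k)` for an array. Must index a positive voxel.
#' @param fraction Threshold fraction of the peak, in `(0, 1)`;
#'   default 0.5.
#' @return A list of class `voi_mask`: `mask` (logical, congruent with
#'   `grid`), `seed`, `peak` (index of the peak voxel), `threshold`.
#' @examples
#' profile <- c(1, 2, 10, 6, 4, 1)
#' which(isocontour_voi(profile, seed = 3)$mask)  # 3 4
#' @export
isocontour_voi <- function(grid, seed, fraction = 0.5) {
  if (!is.numeric(grid) || any(!is.finite(grid)))
    stop("grid must be numeric and finite")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  dims <- if (is.null(dim(grid))) length(grid) else dim(grid)
  nd <- length(dims)
  if (nd > 3L) stop("grid must be 1D, 2D or 3D")
  seed <- as.integer(seed)
  if (length(seed) != nd || any(seed < 1L) || any(seed > dims))
    stop("seed must be a valid voxel index")
  arr <- array(as.numeric(grid), dim = dims)
  seed_lin <- lin_index(seed, dims)
  if (arr[seed_lin] <= 0) stop("seed voxel must be positive")

  region <- flood_fill(arr > 0, seed_lin, dims)
  peak_lin <- which(region)[which.max(arr[region])]
  threshold <- fraction * arr[peak_lin]
  mask_lin <- flood_fill(arr >= threshold, peak_lin, dims)

  mask <- array(mask_lin, dim = dims)
  if (is.null(dim(grid))) mask <- as.vector(mask)
  structure(list(mask = mask, seed = seed,
                 peak = arr_index(peak_lin, dims), threshold = threshold),
            class = "voi_mask")
}

lin_index <- function(idx, dims) {
  mult <- cumprod(c(1, dims[-length(dims)]))
  as.integer(sum((idx - 1L) * mult) + 1L)
}

arr_index <- function(lin, dims) {
  out <- integer(length(dims))
  lin <- lin - 1L
  for (d in seq_along(dims)) {
    out[d] <- lin %% dims[d] + 1L
    lin <- lin %/% dims[d]
  }
  out
}

# Face-connected component of TRUE voxels containing the (TRUE) start
# voxel; breadth-first search on linear indices.
flood_fill <- function(ok, start_lin, dims) {
  stopifnot(ok[start_lin])
  n <- prod(dims)
  visited <- logical(n)
  visited[start_lin] <- TRUE
  queue <- start_lin
  mult <- cumprod(c(1, dims[-length(dims)]))
  while (length(queue) > 0L) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    ci <- arr_index(cur, dims)
    for (d in seq_along(dims)) {
      for (step in c(-1L, 1L)) {
        v <- ci[d] + step
        if (v < 1L || v > dims[d]) next
        nb <- cur + step * as.integer(mult[d])
        if (!visited[nb] && ok[nb]) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
  }
  visited
}
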