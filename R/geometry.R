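#' Tiling geometry for overlapping sub-patch windows
#'
#' Describes how a square input patch is tiled into overlapping square
#' sub-patch windows, one per level-1 module. The default (30-pixel patch,
#' 12-pixel windows, 3-pixel overlap) yields nine windows with top-left
#' corners at rows/columns 1, 10, 19 (1-based), ordered row-major (the
#' column index varies fastest). Window 5 is the central ("BS") module.
#'
#' @param patch_size side length of the full input patch, pixels.
#' @param sub_size side length of each sub-patch window, pixels.
#' @param overlap number of pixels shared by adjacent windows.
#' @return An object of class `tiling_geometry`: a list with elements
#'   `patch_size`, `sub_size`, `overlap`, `starts` (integer vector of
#'   window start coordinates along one axis), `windows` (n x 2 integer
#'   matrix of (row_start, col_start) pairs, 1-based) and `n_windows`.
#' @examples
#' g <- tiling_geometry()
#' g$n_windows # 9
#' @export
tiling_geometry <- function(patch_size = 30L, sub_size = 12L, overlap = 3L) {
  patch_size <- as.integer(patch_size)
  sub_size <- as.integer(sub_size)
  overlap <- as.integer(overlap)
  if (patch_size < sub_size || sub_size <= overlap || overlap < 0L)
    stop_invalid("need patch_size >= sub_size > overlap >= 0")
  stride <- sub_size - overlap
  if ((patch_size - sub_size) %% stride != 0L)
    stop_invalid("(patch_size - sub_size) must be divisible by (sub_size - overlap)")
  starts <- seq.int(1L, patch_size - sub_size + 1L, by = stride)
  windows <- as.matrix(expand.grid(col = starts, row = starts))[, c("row", "col")]
  dimnames(windows) <- NULL
  structure(
    list(patch_size = patch_size, sub_size = sub_size, overlap = overlap,
         starts = starts, windows = windows, n_windows = nrow(windows)),
    class = "tiling_geometry")
}

window_indices <- function(geometry, m) {
  if (m < 1L || m > geometry$n_windows) stop_invalid("window index %d out of range", m)
  rs <- geometry$windows[m, 1L]
  cs <- geometry$windows[m, 2L]
  list(rows = rs:(rs + geometry$sub_size - 1L),
       cols = cs:(cs + geometry$sub_size - 1L))
}

#' Tile a patch into overlapping sub-patches
#'
#' Cuts a `patch_size` x `patch_size` matrix into the geometry's windows,
#' in row-major window order.
#'
#' @param patch numeric matrix of size `patch_size` x `patch_size`.
#' @param geometry a [tiling_geometry()].
#' @return A list of `n_windows` matrices of size `sub_size` x `sub_size`.
#' @export
tile_patch <- function(patch, geometry = tiling_geometry()) {
  if (!is.matrix(patch) || nrow(patch) != geometry$patch_size ||
      ncol(patch) != geometry$patch_size)
    stop_invalid("patch must be a %d x %d matrix", geometry$patch_size,
                 geometry$patch_size)
  lapply(seq_len(geometry$n_windows), function(m) {
    w <- window_indices(geometry, m)
    patch[w$rows, w$cols, drop = FALSE]
  })
}

# vectorize sub-patches into the columns of a (sub_size^2 x n_windows) matrix
tile_to_matrix <- function(patch, geometry = tiling_geometry()) {
  subs <- tile_patch(patch, geometry)
  vapply(subs, as.vector, numeric(geometry$sub_size^2))
}

# number of windows covering each pixel of the full patch
coverage_map <- function(geometry) {
  cov <- matrix(0, geometry$patch_size, geometry$patch_size)
  for (m in seq_len(geometry$n_windows)) {
    w <- window_indices(geometry, m)
    cov[w$rows, w$cols] <- cov[w$rows, w$cols] + 1
  }
  cov
}

#' Reassemble a patch from overlapping sub-patches
#'
#' Inverse of [tile_patch()] up to overlap handling: each output pixel is the
#' arithmetic mean of its value over every window that covers it. Used to
#' render level-1 predictions ("perceptual images") in pixel space.
#'
#' @param sub_images list of `n_windows` matrices (`sub_size` x `sub_size`),
#'   or a `sub_size^2` x `n_windows` matrix of vectorized sub-patches.
#' @param geometry a [tiling_geometry()].
#' @return A `patch_size` x `patch_size` numeric matrix.
#' @export
untile <- function(sub_images, geometry = tiling_geometry()) {
  if (is.matrix(sub_images)) {
    if (nrow(sub_images) != geometry$sub_size^2 ||
        ncol(sub_images) != geometry$n_windows)
      stop_invalid("expected a %d x %d matrix of vectorized sub-patches",
                   geometry$sub_size^2, geometry$n_windows)
    sub_images <- lapply(seq_len(geometry$n_windows), function(m)
      matrix(sub_images[, m], geometry$sub_size, geometry$sub_size))
  }
  if (length(sub_images) != geometry$n_windows)
    stop_invalid("expected %d sub-images", geometry$n_windows)
  acc <- matrix(0, geometry$patch_size, geometry$patch_size)
  for (m in seq_len(geometry$n_windows)) {
    w <- window_indices(geometry, m)
    s <- sub_images[[m]]
    if (!is.matrix(s) || any(dim(s) != geometry$sub_size))
      stop_invalid("sub-image %d has wrong shape", m)
    acc[w$rows, w$cols] <- acc[w$rows, w$cols] + s
  }
  acc / coverage_map(geometry)
}
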