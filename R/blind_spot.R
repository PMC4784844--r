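#' Blind-spot mask
#'
#' Builds the per-pixel indicator that severs the feed-forward error
#' pathway over the blind spot: zeros on a contiguous `bs_size` x
#' `bs_size` square centred in the `patch_size` x `patch_size` input frame
#' (rows/cols 12-19, 1-based, for the defaults), ones elsewhere.
#'
#' @param patch_size input frame side length, pixels.
#' @param bs_size blind-spot side length, pixels (`(patch_size - bs_size)`
#'   must be even; 0 gives an all-ones mask).
#' @return Object of class `bs_mask`: a 0/1 matrix with attributes
#'   `bs_rows` and `bs_cols` (1-based inclusive index ranges, empty when
#'   `bs_size = 0`).
#' @export
make_bs_mask <- function(patch_size = 30L, bs_size = 8L) {
  patch_size <- as.integer(patch_size); bs_size <- as.integer(bs_size)
  if (bs_size < 0L || bs_size >= patch_size)
    stop_invalid("need 0 <= bs_size < patch_size")
  if ((patch_size - bs_size) %% 2L != 0L)
    stop_invalid("(patch_size - bs_size) must be even to centre the blind spot")
  m <- matrix(1, patch_size, patch_size)
  if (bs_size > 0L) {
    margin <- (patch_size - bs_size) %/% 2L
    idx <- (margin + 1L):(margin + bs_size)
    m[idx, idx] <- 0
  } else {
    idx <- integer(0)
  }
  structure(m, bs_rows = idx, bs_cols = idx, class = c("bs_mask", "matrix"))
}

#' Restrict the blind-spot mask to one module's window
#'
#' The 8 x 8 blind spot overlaps several of the nine overlapping windows,
#' so the global mask must be projected into each module's local frame.
#'
#' @param mask a [make_bs_mask()] (or any 0/1 matrix of the patch size).
#' @param geometry a [tiling_geometry()].
#' @param m module index in `1..n_windows`.
#' @return `sub_size` x `sub_size` 0/1 matrix.
#' @export
module_local_mask <- function(mask, geometry = tiling_geometry(), m) {
  w <- window_indices(geometry, m)
  unclass(mask)[w$rows, w$cols, drop = FALSE]
}

# all module-local masks as columns of a (sub_size^2 x n_windows) matrix
mask_matrix <- function(mask, geometry) {
  vapply(seq_len(geometry$n_windows),
         function(m) as.vector(module_local_mask(mask, geometry, m)),
         numeric(geometry$sub_size^2))
}

#' Lesion a network's feed-forward pathway over the blind spot
#'
#' Returns a copy of a pre-trained network whose level-1 bottom-up error
#' flow is zeroed on the masked pixels (equivalent to zeroing the
#' corresponding rows of the feed-forward efficacy in every module's local
#' frame). The generative/feedback pathway (the stored `U` matrices and
#' the predictions `U r`) is untouched, and so is the original network.
#'
#' @param network an [hpc_network()] trained with an all-ones mask.
#' @param mask a [make_bs_mask()].
#' @return The lesioned (BS) network.
#' @export
apply_blind_spot <- function(network, mask = make_bs_mask()) {
  stopifnot(inherits(network, "hpc_network"))
  if (!all(dim(mask) == network$geometry$patch_size))
    stop_invalid("mask size does not match the network's patch size")
  network$ff_mask <- mask
  network$id <- paste0(network$id, "_bs")
  network
}
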