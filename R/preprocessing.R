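#' Remove the DC component of an image
#'
#' Subtracts the mean intensity, the first step of the LGN-like
#' preprocessing applied to all inputs.
#'
#' @param image numeric matrix.
#' @return Matrix of the same shape with mean exactly 0.
#' @export
remove_dc <- function(image) {
  if (!is.numeric(image)) stop_invalid("image must be numeric")
  image - mean(image)
}

# radial whitening/lowpass profile W(f) = f * exp(-(f/f0)^4)
whitening_profile <- function(f, f0) {
  f * exp(-(f / f0)^4)
}

#' Build the whitening/lowpass frequency filter
#'
#' Constructs the circularly symmetric LGN-like filter with radial gain
#' profile W(f) = f * exp(-(f/f0)^4), where f is radial spatial frequency
#' in cycles/image. The zero-frequency gain is 0, so filtering removes DC.
#' Gains are stored in unshifted FFT order, ready for elementwise
#' multiplication with `fft(image)`.
#'
#' @param n grid side length, pixels.
#' @param f0 cutoff frequency, cycles/image (200 for the 512-pixel
#'   training images; scale proportionally for other sizes).
#' @return Object of class `freq_filter`: an `n` x `n` gain matrix with
#'   attributes `n` and `f0`.
#' @export
build_whitening_filter <- function(n, f0 = 200) {
  n <- as.integer(n)
  if (n < 2L) stop_invalid("n must be >= 2")
  if (f0 <= 0) stop_invalid("f0 must be positive")
  f <- radial_frequency_grid(n, n)
  gains <- whitening_profile(f, f0)
  gains[f == 0] <- 0
  structure(gains, n = n, f0 = f0, class = c("freq_filter", "matrix"))
}

#' Whiten an image in the frequency domain
#'
#' Multiplies the image's Fourier transform elementwise by the filter
#' gains and inverts. Linear; output mean is exactly 0 because the filter
#' has zero DC gain.
#'
#' @param image square numeric matrix, same size as the filter grid.
#' @param filter a [build_whitening_filter()].
#' @return Whitened matrix of the same size.
#' @export
whiten <- function(image, filter) {
  if (!is.matrix(image) || nrow(image) != ncol(image))
    stop_invalid("image must be a square matrix")
  n <- attr(filter, "n")
  if (nrow(image) != n)
    stop_invalid("image size %d does not match filter grid %d", nrow(image), n)
  out <- Re(fft(fft(image) * unclass(filter), inverse = TRUE)) / n^2
  out
}

#' LGN-like preprocessing of training images
#'
#' DC removal followed by whitening. `f0` is interpreted in cycles/image
#' relative to a `ref_size`-pixel image and scaled proportionally for
#' images of other sizes, keeping the filter shape fixed in normalized
#' frequency.
#'
#' @param images list of square numeric matrices.
#' @param f0 cutoff frequency for a `ref_size`-pixel image.
#' @param ref_size reference image size for `f0`.
#' @return List of preprocessed matrices.
#' @export
preprocess_images <- function(images, f0 = 200, ref_size = 512L) {
  lapply(images, function(img) {
    n <- nrow(img)
    filt <- build_whitening_filter(n, f0 * n / ref_size)
    whiten(remove_dc(img), filt)
  })
}

#' Sample a batch of variance-normalized patches
#'
#' Extracts `count` patches of size `patch_size` x `patch_size` from
#' randomly selected locations of randomly selected images, subtracts each
#' patch's mean and scales it to unit (population) variance. Degenerate
#' zero-variance patches are resampled, never emitted.
#'
#' @param images list of preprocessed images (each at least
#'   `patch_size` x `patch_size`).
#' @param count batch size (>= 1).
#' @param seed integer seed; the batch is a pure function of
#'   `(images, count, seed)`.
#' @param patch_size patch side length, pixels.
#' @return Object of class `patch_batch`: a list of `count` matrices.
#' @export
sample_patch_batch <- function(images, count, seed, patch_size = 30L) {
  count <- as.integer(count)
  if (count < 1L) stop_invalid("count must be >= 1")
  patch_size <- as.integer(patch_size)
  for (img in images)
    if (nrow(img) < patch_size || ncol(img) < patch_size)
      stop_invalid("every image must be at least %d x %d", patch_size, patch_size)
  patches <- withr::with_seed(as.integer(seed), {
    out <- vector("list", count)
    k <- 0L
    while (k < count) {
      img <- images[[sample.int(length(images), 1L)]]
      r0 <- sample.int(nrow(img) - patch_size + 1L, 1L)
      c0 <- sample.int(ncol(img) - patch_size + 1L, 1L)
      p <- img[r0:(r0 + patch_size - 1L), c0:(c0 + patch_size - 1L)]
      p <- p - mean(p)
      v <- mean(p^2)
      if (v <= 0) next  # resample degenerate patch
      k <- k + 1L
      out[[k]] <- p / sqrt(v)
    }
    out
  })
  structure(patches, class = "patch_batch")
}
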