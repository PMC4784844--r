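#' Bar stimulus geometry
#'
#' Parameterizes the horizontal dark bars used in the filling-in
#' experiments. All coordinates are 1-based pixel indices into the 30 x 30
#' stimulus frame. The defaults place a 2-pixel-thick bar of amplitude -1
#' (a dark bar on a zero background) at rows 15-16, crossing the centre of
#' the 8 x 8 blind-spot region (rows/cols 12-19), with its fixed end at
#' column 3.
#'
#' @param row topmost row of the bar centreline.
#' @param thickness bar thickness, pixels.
#' @param amplitude bar pixel value (nonzero); background is exactly 0.
#' @param col_start,col_end horizontal extent, inclusive.
#' @param frame side length of the stimulus frame, pixels.
#' @return Object of class `bar_spec`.
#' @export
bar_spec <- function(row = 15L, thickness = 2L, amplitude = -1,
                     col_start = 3L, col_end = 28L, frame = 30L) {
  row <- as.integer(row); thickness <- as.integer(thickness)
  col_start <- as.integer(col_start); col_end <- as.integer(col_end)
  frame <- as.integer(frame)
  if (thickness < 1L) stop_invalid("thickness must be >= 1")
  if (amplitude == 0) stop_invalid("amplitude must be nonzero")
  if (col_start < 1L || col_end > frame || col_start > col_end)
    stop_invalid("need 1 <= col_start <= col_end <= %d", frame)
  if (row < 1L || row + thickness - 1L > frame)
    stop_invalid("bar rows fall outside the %d-pixel frame", frame)
  structure(list(row = row, thickness = thickness, amplitude = amplitude,
                 col_start = col_start, col_end = col_end, frame = frame),
            class = "bar_spec")
}

new_stimulus <- function(pixels, label) {
  attr(pixels, "label") <- label
  class(pixels) <- c("stimulus", class(pixels))
  pixels
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus '%s': %d x %d, %d nonzero px>\n",
              attr(x, "label"), nrow(x), ncol(x), sum(x != 0)))
  invisible(x)
}

stimulus_label <- function(x) attr(x, "label")

bar_rows <- function(spec) spec$row:(spec$row + spec$thickness - 1L)

paint_bar <- function(pixels, spec, cols, row = spec$row) {
  if (length(cols) == 0L) return(pixels)
  rows <- row:(row + spec$thickness - 1L)
  if (min(rows) < 1L || max(rows) > nrow(pixels) ||
      min(cols) < 1L || max(cols) > ncol(pixels))
    stop_invalid("bar segment falls outside the %d x %d frame",
                 nrow(pixels), ncol(pixels))
  pixels[rows, cols] <- spec$amplitude
  pixels
}

#' Generate a surrogate natural image
#'
#' Stand-in for grayscale natural photographs: random-phase noise with an
#' amplitude spectrum proportional to 1/f (the hallmark second-order
#' statistic of natural scenes), with `n_segments` opaque elongated
#' segments of random orientation, length, width and intensity painted on
#' top, dead-leaves style (later segments occlude earlier ones and the
#' noise). The segments supply the oriented edge/bar structure that sparse
#' coding needs to develop localized, oriented receptive fields.
#'
#' The defaults emulate a photograph of a natural environment at the
#' statistics that matter for sparse coding: segment intensities are
#' drawn from +/- Uniform(0.5, 2.5), the background texture is scaled to
#' `noise_amplitude` standard deviations, and 200 segments on a 512 x 512
#' frame cover roughly a third of the image, so a typical 12 x 12
#' analysis window contains a small number of distinct high-contrast
#' edges over low-amplitude texture (see the methods vignette).
#'
#' @param width,height image size in pixels (both >= 64).
#' @param n_segments number of opaque segments (>= 0); 0 gives pure
#'   1/f noise.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param noise_amplitude standard deviation of the 1/f background
#'   relative to the unit segment-amplitude scale.
#' @return A `height` x `width` numeric matrix.
#' @export
generate_surrogate_image <- function(width = 512L, height = 512L,
                                     n_segments = 200L, seed = 1L,
                                     noise_amplitude = 0.3) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 64L || height < 64L)
    stop_invalid("width and height must be >= 64")
  if (n_segments < 0L) stop_invalid("n_segments must be >= 0")
  withr::with_seed(as.integer(seed), {
    img <- one_over_f_noise(height, width)
    img <- noise_amplitude * (img - mean(img)) / sd(as.vector(img))
    if (n_segments > 0L) {
      xg <- matrix(rep(seq_len(width), each = height), height, width)
      yg <- matrix(rep(seq_len(height), times = width), height, width)
      for (i in seq_len(n_segments)) {
        cx <- runif(1, 1, width)
        cy <- runif(1, 1, height)
        theta <- runif(1, 0, pi)
        len <- runif(1, 0.1, 0.5) * min(width, height)
        wid <- runif(1, 1, 6)
        val <- sample(c(-1, 1), 1) * runif(1, 0.5, 2.5)
        u <- (xg - cx) * cos(theta) + (yg - cy) * sin(theta)
        v <- -(xg - cx) * sin(theta) + (yg - cy) * cos(theta)
        img[abs(u) <= len / 2 & abs(v) <= wid / 2] <- val
      }
    }
    img
  })
}

# random-phase noise with amplitude spectrum proportional to 1/f
one_over_f_noise <- function(nr, nc) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  f <- radial_frequency_grid(nr, nc)
  gains <- ifelse(f == 0, 0, 1 / f)
  Re(fft(fft(w) * gains, inverse = TRUE)) / (nr * nc)
}

# radial frequency (cycles/image along the shorter axis convention:
# integer frequency indices in fft order)
radial_frequency_grid <- function(nr, nc) {
  kr <- ((seq_len(nr) - 1 + floor(nr / 2)) %% nr) - floor(nr / 2)
  kc <- ((seq_len(nc) - 1 + floor(nc / 2)) %% nc) - floor(nc / 2)
  sqrt(outer(kr^2, kc^2, `+`))
}

#' Shifting-bar stimulus
#'
#' A horizontal bar whose left end is fixed at `spec$col_start` (outside
#' the blind spot) and whose right end sits at `end_col`; sweeping
#' `end_col` one pixel at a time drives the bar across the blind spot.
#'
#' @param spec a [bar_spec()].
#' @param end_col column of the drifting end (1..30, `>= spec$col_start`).
#' @return A 30 x 30 `stimulus` labelled `"shift_<end_col>"`.
#' @export
make_shifting_bar <- function(spec = bar_spec(), end_col) {
  end_col <- as.integer(end_col)
  if (end_col < 1L || end_col > spec$frame)
    stop_invalid("end_col must lie in 1..%d", spec$frame)
  if (end_col < spec$col_start)
    stop_invalid("end_col (%d) must be >= col_start (%d)", end_col, spec$col_start)
  px <- paint_bar(matrix(0, spec$frame, spec$frame), spec,
                  spec$col_start:end_col)
  new_stimulus(px, sprintf("shift_%02d", end_col))
}

#' Misaligned bar-pair stimulus
#'
#' Two bar segments abutting the blind spot from opposite sides: the left
#' segment is fixed at `spec$row`, the right one is shifted vertically by
#' `vertical_offset` pixels (negative = up). Both segments terminate at the
#' blind-spot border, so the blind-spot columns contain no bar pixels.
#'
#' @param spec a [bar_spec()].
#' @param vertical_offset integer in -3..3 (the seven probe positions).
#' @param mask a [make_bs_mask()] defining the blind-spot columns.
#' @return A 30 x 30 `stimulus` labelled `"offset_<k>"`.
#' @export
make_bar_pair <- function(spec = bar_spec(), vertical_offset = 0L,
                          mask = make_bs_mask()) {
  vertical_offset <- as.integer(vertical_offset)
  if (abs(vertical_offset) > 3L)
    stop_invalid("vertical_offset must lie in -3..3")
  bs_cols <- attr(mask, "bs_cols")
  left_cols <- spec$col_start:(min(bs_cols) - 1L)
  right_cols <- (max(bs_cols) + 1L):(spec$frame - spec$col_start + 1L)
  right_row <- spec$row + vertical_offset
  if (right_row < 1L || right_row + spec$thickness - 1L > spec$frame)
    stop_invalid("vertical_offset %d pushes the right segment outside the frame",
                 vertical_offset)
  px <- matrix(0, spec$frame, spec$frame)
  px <- paint_bar(px, spec, left_cols)
  px <- paint_bar(px, spec, right_cols, row = right_row)
  new_stimulus(px, sprintf("offset_%+d", vertical_offset))
}

#' Nonlinearity (AND-gate) stimulus set
#'
#' Builds the four conditions of the supra-additivity test:
#' * `a` — left segment ending at the blind-spot border,
#' * `b` — right segment starting at the border,
#' * `c` — short control segment confined strictly inside the blind-spot
#'   columns, stimulating neither flank,
#' * `ab` — the pixelwise union of `a` and `b`.
#'
#' @param spec a [bar_spec()].
#' @param mask a [make_bs_mask()].
#' @return Named list of `stimulus` objects `a`, `b`, `c`, `ab`.
#' @export
make_nonlinearity_stimuli <- function(spec = bar_spec(),
                                      mask = make_bs_mask()) {
  bs_cols <- attr(mask, "bs_cols")
  frame <- spec$frame
  zero <- matrix(0, frame, frame)
  a_cols <- spec$col_start:(min(bs_cols) - 1L)
  b_cols <- (max(bs_cols) + 1L):(frame - spec$col_start + 1L)
  c_cols <- (min(bs_cols) + 1L):(max(bs_cols) - 1L)
  a <- paint_bar(zero, spec, a_cols)
  b <- paint_bar(zero, spec, b_cols)
  list(a = new_stimulus(a, "a"),
       b = new_stimulus(b, "b"),
       c = new_stimulus(paint_bar(zero, spec, c_cols), "c"),
       ab = new_stimulus(a + b, "ab"))
}

#' Shifting-bar battery
#'
#' Convenience builder for the full one-pixel sweep of the drifting end.
#'
#' @param spec a [bar_spec()].
#' @param end_cols columns of the drifting end; the default sweeps from
#'   well before to well past the blind spot.
#' @return List of `stimulus` objects.
#' @export
shifting_bar_battery <- function(spec = bar_spec(), end_cols = 5:28) {
  lapply(end_cols, function(ec) make_shifting_bar(spec, ec))
}
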