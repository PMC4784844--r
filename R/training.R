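#' One learning step for an efficacy matrix
#'
#' Discrete form of the Hebbian-type learning rule
#' dU/dt = (k2/sigma2) (I - U r) r^T - k2 lambda U, batch-averaged:
#' U <- U + (k2/sigma2) <(I - U r) r^T>_batch - k2 lambda U, where <.> is
#' the mean of the outer products over the batch (not the outer product
#' of batch means, which would vanish for symmetric response
#' distributions).
#'
#' @param inputs input vectors, one per column (`d` x `n`).
#' @param states steady-state responses, one per column (`K` x `n`).
#' @param U efficacy matrix (`d` x `K`).
#' @param params a [network_params()].
#' @param sigma2 noise variance weighting the residual term; the level-2
#'   update passes `params$sigma2_td` here.
#' @return Updated efficacy matrix.
#' @export
efficacy_update <- function(inputs, states, U, params,
                            sigma2 = params$sigma2) {
  if (!is.matrix(inputs) || !is.matrix(states) || ncol(inputs) == 0L)
    stop_invalid("inputs and states must be nonempty matrices")
  if (ncol(inputs) != ncol(states) || nrow(inputs) != nrow(U) ||
      nrow(states) != ncol(U))
    stop_invalid("shape mismatch between inputs (%dx%d), states (%dx%d) and U (%dx%d)",
                 nrow(inputs), ncol(inputs), nrow(states), ncol(states),
                 nrow(U), ncol(U))
  n <- ncol(inputs)
  hebb <- (inputs - U %*% states) %*% t(states) / n
  U + (params$k2 / sigma2) * hebb - params$k2 * params$lambda * U
}

#' Gain adaptation of basis-column norms
#'
#' Rescales each column i of U so that its gain (L2 norm) becomes
#' l_new = l_old * (<r_i^2> / sigma2_goal)^gamma, keeping column
#' directions unchanged. Driving the response second moments toward
#' `sigma2_goal` prevents the efficacy vectors from growing without bound
#' during training.
#'
#' @param U efficacy matrix.
#' @param response_second_moments per-neuron `<r_i^2>` (length `ncol(U)`).
#' @param params a [network_params()].
#' @param floor small positive floor replacing zero second moments.
#' @return Rescaled efficacy matrix.
#' @export
adapt_gains <- function(U, response_second_moments, params, floor = 1e-8) {
  if (length(response_second_moments) != ncol(U))
    stop_invalid("need one second moment per column of U")
  if (any(response_second_moments < 0))
    stop_invalid("second moments must be >= 0")
  sm <- pmax(response_second_moments, floor)
  scale <- (sm / params$sigma2_goal)^params$gamma
  sweep(U, 2L, scale, `*`)
}

init_efficacy <- function(d, K) {
  U <- matrix(runif(d * K, -0.1, 0.1), d, K)
  sweep(U, 2L, sqrt(colSums(U^2)), `/`)
}

check_divergence <- function(curve, window, what) {
  n <- length(curve)
  if (n > window && all(diff(curve[(n - window):n]) > 0))
    stop_invalid("training diverged: %s increased over %d consecutive batches (last values: %s)",
                 what, window, paste(signif(utils::tail(curve, 3), 4), collapse = ", "))
}

#' Train the level-1 efficacy matrix
#'
#' For each batch: sample variance-normalized patches from the
#' preprocessed images, tile each into the nine sub-patches (all nine are
#' training vectors for the shared `U1`), relax the level-1 states to
#' steady state with no top-down term (level 2 does not exist yet), apply
#' [efficacy_update()] and then [adapt_gains()] with that batch's
#' response second moments. `U1` starts from small i.i.d. uniform values
#' with unit column gains. Bit-reproducible given `seed`.
#'
#' @param images list of preprocessed (DC-removed, whitened) images.
#' @param config list with `n_batches`, `batch_size`, `seed`, `n_neurons`
#'   (level-1 neurons per module, default 64), `params`
#'   (a [network_params()]), `geometry` (a [tiling_geometry()]), and the
#'   relaxation controls `step`, `tol`, `max_iter` (training defaults
#'   0.5 / 1e-3 / 600).
#' @return List of class `hpc_fit`: `U` (the learned matrix), `curve`
#'   (data frame with per-batch mean coding length per training vector
#'   and mean response second moment), `second_moments` (final batch's
#'   per-neuron `<r_i^2>`).
#' @export
train_level1 <- function(images, config = list()) {
  cfg <- training_config(config)
  g <- cfg$geometry; p <- cfg$params
  d <- g$sub_size^2
  withr::with_seed(cfg$seed, {
    U <- init_efficacy(d, cfg$n_neurons)
    batch_seeds <- sample.int(.Machine$integer.max, cfg$n_batches)
    curve <- data.frame(batch = seq_len(cfg$n_batches), mean_E = NA_real_,
                        mean_r2 = NA_real_)
    sm <- NULL
    for (b in seq_len(cfg$n_batches)) {
      batch <- sample_patch_batch(images, cfg$batch_size, batch_seeds[b],
                                  g$patch_size)
      I <- do.call(cbind, lapply(batch, tile_to_matrix, geometry = g))
      fit <- relax_l1_cpp(I, U, matrix(1, nrow(I), ncol(I)), p$alpha1,
                          p$prior_scale,
                          p$k1, p$sigma2, cfg$step, cfg$tol, cfg$max_iter,
                          FALSE, matrix(0, ncol(U), ncol(I)))
      R <- fit$R
      U <- efficacy_update(I, R, U, p)
      sm <- rowMeans(R^2)
      # one-sided gain adaptation: the rule exists to stop unbounded
      # growth, so it is applied only when a neuron's variance exceeds
      # the goal (the weight-prior decay supplies the downward pressure;
      # two-sided application collapses weakly-driven units to zero)
      U <- adapt_gains(U, pmax(sm, p$sigma2_goal), p)
      curve$mean_E[b] <- fit$energy / ncol(I)
      curve$mean_r2[b] <- mean(R^2)
      check_divergence(curve$mean_E[seq_len(b)], 10L, "batch-mean coding length")
    }
    structure(list(U = U, curve = curve, second_moments = sm),
              class = "hpc_fit")
  })
}

#' Train the level-2 efficacy matrix on top of a frozen level 1
#'
#' For each batch, the joint steady states of all nine level-1 modules
#' (with top-down input from the current level-2 estimate; `U1` frozen)
#' and the level-2 module are computed; the concatenated level-1 state
#' `r_cat` is the level-2 input, and `U2` is updated via
#' [efficacy_update()] with `sigma2_td` in place of `sigma2`, followed by
#' [adapt_gains()].
#'
#' @param images list of preprocessed images.
#' @param U1 trained, frozen level-1 efficacy matrix.
#' @param config as in [train_level1()], plus `n2_neurons` (level-2
#'   neurons, default 169).
#' @return List of class `hpc_fit`: `U`, `curve` (per-batch mean coding
#'   length per patch and mean top-down error `||r_cat - U2 r2||^2`),
#'   `second_moments`.
#' @export
train_level2 <- function(images, U1, config = list()) {
  cfg <- training_config(config)
  g <- cfg$geometry; p <- cfg$params
  d <- g$sub_size^2
  if (!is.matrix(U1) || nrow(U1) != d)
    stop_invalid("U1 must have %d rows", d)
  K1 <- ncol(U1)
  withr::with_seed(cfg$seed + 1L, {
    U2 <- init_efficacy(g$n_windows * K1, cfg$n2_neurons)
    batch_seeds <- sample.int(.Machine$integer.max, cfg$n_batches)
    curve <- data.frame(batch = seq_len(cfg$n_batches), mean_E = NA_real_,
                        mean_td_err = NA_real_)
    sm <- NULL
    for (b in seq_len(cfg$n_batches)) {
      batch <- sample_patch_batch(images, cfg$batch_size, batch_seeds[b],
                                  g$patch_size)
      n <- length(batch)
      I <- do.call(cbind, lapply(batch, tile_to_matrix, geometry = g))
      fit <- relax_joint_cpp(I, U1, U2, matrix(1, nrow(I), ncol(I)),
                             p$alpha1, p$alpha2, p$prior_scale, p$prior_scale2,
                             p$k1, p$sigma2, p$sigma2_td,
                             cfg$step, cfg$tol, cfg$max_iter, FALSE,
                             matrix(0, K1, ncol(I)),
                             matrix(0, cfg$n2_neurons, n))
      Rcat <- matrix(fit$R, K1 * g$n_windows, n)
      R2 <- fit$R2
      U2 <- efficacy_update(Rcat, R2, U2, p, sigma2 = p$sigma2_td)
      sm <- rowMeans(R2^2)
      U2 <- adapt_gains(U2, pmax(sm, p$sigma2_goal), p) # one-sided, as at level 1
      curve$mean_E[b] <- fit$energy / n
      curve$mean_td_err[b] <- mean(colSums((Rcat - U2 %*% R2)^2))
      check_divergence(curve$mean_E[seq_len(b)], 10L, "batch-mean coding length")
    }
    structure(list(U = U2, curve = curve, second_moments = sm),
              class = "hpc_fit")
  })
}

training_config <- function(config) {
  defaults <- list(n_batches = 200L, batch_size = 50L, seed = 1L,
                   n_neurons = 64L, n2_neurons = 169L,
                   params = network_params(), geometry = tiling_geometry(),
                   step = 0.5, tol = 1e-3, max_iter = 600L)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_invalid("unknown training config key(s): %s",
                 paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (nm in c("n_batches", "batch_size", "n_neurons", "n2_neurons", "max_iter"))
    if (cfg[[nm]] < 1L) stop_invalid("config '%s' must be positive", nm)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Train a full two-level network
#'
#' [train_level1()] followed by [train_level2()] (level 1 first, then
#' level 2 on the frozen `U1`), assembled into an intact
#' [hpc_network()]. Training curves are attached as the `curves`
#' attribute.
#'
#' @inheritParams train_level1
#' @param id network id tag.
#' @return An intact (all-ones mask) `hpc_network`.
#' @export
train_network <- function(images, config = list(), id = "trained") {
  cfg <- training_config(config)
  fit1 <- train_level1(images, config)
  fit2 <- train_level2(images, fit1$U, config)
  net <- hpc_network(fit1$U, fit2$U, cfg$geometry, cfg$params, id = id)
  attr(net, "curves") <- list(level1 = fit1$curve, level2 = fit2$curve)
  net
}

#' Receptive-field shape metrics
#'
#' Quantifies how Gabor-like the learned basis columns are:
#' * `localization` — spatial-energy participation ratio
#'   (sum e)^2 / (n sum e^2) with e the squared pixel values; 1/n for a
#'   delta function, 1 for a flat field (lower = more localized).
#' * `orientation_selectivity` — the resultant length of the
#'   power-weighted doubled-angle distribution of 2-D spectral energy
#'   (1 - circular variance); near 1 for an ideal oriented grating, 0 for
#'   an isotropic field.
#' * `orientation` — the preferred spectral angle in radians (0 = energy
#'   on the horizontal frequency axis, i.e. structure varying along image
#'   rows; pi/2 = energy on the vertical frequency axis, i.e. horizontal
#'   image structure like a horizontal bar).
#'
#' Zero columns get `(localization, orientation_selectivity) = (1, 0)`.
#'
#' @param U efficacy matrix whose columns reshape to square grids.
#' @return Data frame with one row per neuron: `neuron`, `gain`,
#'   `localization`, `orientation_selectivity`, `orientation`.
#' @export
rf_gaborness <- function(U) {
  d <- nrow(U)
  side <- as.integer(round(sqrt(d)))
  if (side^2 != d) stop_invalid("columns of U must reshape to square grids")
  kr <- ((seq_len(side) - 1 + floor(side / 2)) %% side) - floor(side / 2)
  # element [row, col] of a spectrum corresponds to (ky = kr[row], kx = kr[col])
  ang <- atan2(outer(kr, rep(1, side)), outer(rep(1, side), kr))
  res <- lapply(seq_len(ncol(U)), function(i) {
    x <- matrix(U[, i], side, side)
    gain <- sqrt(sum(x^2))
    if (gain == 0)
      return(data.frame(neuron = i, gain = 0, localization = 1,
                        orientation_selectivity = 0, orientation = NA_real_))
    e <- x^2
    loc <- sum(e)^2 / (d * sum(e^2))
    P <- Mod(fft(x))^2
    P[1, 1] <- 0  # discard DC
    if (sum(P) == 0)  # constant column: no orientation content
      return(data.frame(neuron = i, gain = gain, localization = loc,
                        orientation_selectivity = 0, orientation = NA_real_))
    z <- sum(P * exp(2i * ang))
    osel <- Mod(z) / sum(P)
    data.frame(neuron = i, gain = gain, localization = loc,
               orientation_selectivity = osel,
               orientation = (Arg(z) / 2) %% pi)
  })
  do.call(rbind, res)
}
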