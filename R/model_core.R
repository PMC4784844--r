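#' Network parameters
#'
#' The model's tunable constants. Defaults are the values used throughout:
#' `k1 = 1` (state descent rate), `k2 = 3` (learning rate), `sigma2 = 3`
#' (bottom-up noise variance), `sigma2_td = 10` (top-down noise variance),
#' sparse-prior scales `alpha1 = 0.05` (level 1) and `alpha2 = 0.1`
#' (level 2), Gaussian weight-prior scale `lambda = 0.0025`, target
#' response variance `sigma2_goal = 0.05`, and gain-adaptation rate
#' `gamma = 0.02`.
#'
#' `sigma2_goal` defaults to 1: gain adaptation holds responses at the
#' unit scale, which is the heavy-tail knee of the printed Cauchy prior
#' g(r) = alpha * sum(log(1 + r_i^2)). This is the one regime in which
#' the printed parameters are mutually consistent: the prior sparsifies
#' the code (Gabor-like fields emerge), level 2 neither collapses nor
#' linearizes, and the top-down pull (1/sigma2_td) exceeds the prior's
#' slope at rest so lesioned modules can be driven by predictions (see
#' the methods vignette). `prior_scale`/`prior_scale2` expose the knees
#' of the two levels' priors; both default to the printed unit scale.
#'
#' @param k1,k2,sigma2,sigma2_td,alpha1,alpha2,lambda,sigma2_goal,gamma
#'   strictly positive scalars; see Description.
#' @param prior_scale,prior_scale2 heavy-tail knees of the level-1 and
#'   level-2 sparse priors; default 1 (the printed form).
#' @return Object of class `hpc_params`.
#' @export
network_params <- function(k1 = 1, k2 = 3, sigma2 = 3, sigma2_td = 10,
                           alpha1 = 0.05, alpha2 = 0.1, lambda = 0.0025,
                           sigma2_goal = 1, gamma = 0.02,
                           prior_scale = 1, prior_scale2 = 1) {
  p <- list(k1 = k1, k2 = k2, sigma2 = sigma2, sigma2_td = sigma2_td,
            alpha1 = alpha1, alpha2 = alpha2, lambda = lambda,
            sigma2_goal = sigma2_goal, gamma = gamma,
            prior_scale = prior_scale, prior_scale2 = prior_scale2)
  nonneg <- c("alpha1", "alpha2", "lambda")  # zero disables that prior
  for (nm in names(p)) {
    v <- p[[nm]]
    ok <- is.numeric(v) && length(v) == 1L && is.finite(v) &&
      (v > 0 || (v == 0 && nm %in% nonneg))
    if (!ok)
      stop_invalid("parameter '%s' must be a %s scalar", nm,
                   if (nm %in% nonneg) "non-negative" else "strictly positive")
  }
  structure(p, class = "hpc_params")
}

#' Hierarchical predictive-coding network
#'
#' Bundles the shared level-1 efficacy matrix `U1` (one column per
#' predictive-estimator neuron, `sub_size^2` rows), the optional level-2
#' efficacy matrix `U2` (`n_windows * ncol(U1)` rows), the tiling
#' geometry, the parameters, and the feed-forward mask (all-ones for an
#' intact network; see [apply_blind_spot()]).
#'
#' @param U1 level-1 efficacy matrix, shared by all modules.
#' @param U2 level-2 efficacy matrix, or `NULL` for a single-level network.
#' @param geometry a [tiling_geometry()].
#' @param params a [network_params()].
#' @param ff_mask `patch_size` x `patch_size` 0/1 matrix, or `NULL` for
#'   all-ones.
#' @param id character tag used to key response tables.
#' @return Object of class `hpc_network`.
#' @export
hpc_network <- function(U1, U2 = NULL, geometry = tiling_geometry(),
                        params = network_params(), ff_mask = NULL,
                        id = "net") {
  if (!is.matrix(U1) || nrow(U1) != geometry$sub_size^2)
    stop_invalid("U1 must have sub_size^2 = %d rows", geometry$sub_size^2)
  if (!is.null(U2)) {
    if (!is.matrix(U2) || nrow(U2) != geometry$n_windows * ncol(U1))
      stop_invalid("U2 must have n_windows * ncol(U1) = %d rows",
                   geometry$n_windows * ncol(U1))
  }
  if (is.null(ff_mask)) {
    ff_mask <- matrix(1, geometry$patch_size, geometry$patch_size)
  } else if (!all(dim(ff_mask) == geometry$patch_size)) {
    stop_invalid("ff_mask must be %d x %d", geometry$patch_size,
                 geometry$patch_size)
  }
  structure(list(U1 = U1, U2 = U2, geometry = geometry, params = params,
                 ff_mask = ff_mask, id = id),
            class = "hpc_network")
}

#' @export
print.hpc_network <- function(x, ...) {
  cat(sprintf(
    "<hpc_network '%s': U1 %dx%d shared over %d modules%s, %s>\n",
    x$id, nrow(x$U1), ncol(x$U1), x$geometry$n_windows,
    if (is.null(x$U2)) "" else sprintf(", U2 %dx%d", nrow(x$U2), ncol(x$U2)),
    if (any(unclass(x$ff_mask) == 0)) "lesioned" else "intact"))
  invisible(x)
}

network_mask_matrix <- function(network) {
  mask_matrix(network$ff_mask, network$geometry)
}

#' Sparse-prior penalty and its gradient
#'
#' The kurtotic (Cauchy-shaped) prior
#' P(r_i) = exp(-alpha log(1 + (r_i/scale)^2)) contributes
#' g(r) = alpha * sum(log(1 + (r_i/scale)^2)) to the coding length; its
#' gradient is g'(r_i) = 2 alpha r_i / (scale^2 + r_i^2). With
#' `scale = 1` (the default, and the printed form) the heavy tail starts
#' at the unit response scale that gain adaptation maintains.
#'
#' @param r numeric vector or matrix of responses.
#' @param alpha sparseness strength.
#' @param scale knee of the heavy tail.
#' @return `sparse_prior`: scalar penalty; `sparse_prior_deriv`:
#'   elementwise gradient, same shape as `r`.
#' @export
sparse_prior <- function(r, alpha, scale = 1) {
  alpha * sum(log1p((r / scale)^2))
}

#' @rdname sparse_prior
#' @export
sparse_prior_deriv <- function(r, alpha, scale = 1) {
  2 * alpha * r / (scale^2 + r^2)
}

# coerce r1 to a (ncol(U1) x n_windows) matrix
as_r1_matrix <- function(r1, network) {
  K1 <- ncol(network$U1); M <- network$geometry$n_windows
  if (is.list(r1)) r1 <- do.call(cbind, r1)
  if (is.null(dim(r1))) r1 <- matrix(r1, K1, M)
  if (!all(dim(r1) == c(K1, M)))
    stop_invalid("r1 must be %d x %d (neurons x modules)", K1, M)
  r1
}

#' Total coding length (the model's energy function)
#'
#' E = sum_m (1/sigma2) ||M_m (I_m - U1 r1_m)||^2
#'   + (1/sigma2_td) ||r_cat - U2 r2||^2
#'   + sum_m g(r1_m; alpha1) + g(r2; alpha2)
#'   + lambda (||U1||^2 + ||U2||^2),
#' where I_m is sub-patch m, M_m the module-local feed-forward mask, and
#' r_cat the concatenation of the nine r1 vectors in window order. For a
#' single-level network the top-down and r2 terms are absent. E is the
#' Lyapunov function of [state_derivative()]: inference descends it.
#'
#' @param input `patch_size` x `patch_size` stimulus matrix.
#' @param r1 level-1 states: `ncol(U1)` x `n_windows` matrix (or list of
#'   column vectors in window order).
#' @param r2 level-2 state vector, or `NULL` for a single-level network.
#' @param network an [hpc_network()].
#' @return Scalar E.
#' @export
coding_length <- function(input, r1, r2, network) {
  g <- network$geometry; p <- network$params
  I <- tile_to_matrix(unclass(input), g)
  r1 <- as_r1_matrix(r1, network)
  M <- network_mask_matrix(network)
  res1 <- M * (I - network$U1 %*% r1)
  E <- sum(res1^2) / p$sigma2 + sparse_prior(r1, p$alpha1, p$prior_scale) +
    p$lambda * sum(network$U1^2)
  if (!is.null(network$U2)) {
    if (is.null(r2)) stop_invalid("network has a level 2 but r2 is NULL")
    rcat <- as.vector(r1)
    res2 <- rcat - as.vector(network$U2 %*% r2)
    E <- E + sum(res2^2) / p$sigma2_td + sparse_prior(r2, p$alpha2, p$prior_scale2) +
      p$lambda * sum(network$U2^2)
  }
  E
}

#' Joint state derivative (gradient-flow dynamics)
#'
#' dr/dt = -(k1/2) dE/dr for every state component:
#' level-1 modules receive the masked bottom-up error
#' (k1/sigma2) U1^T M_m (I_m - U1 r1_m), the top-down pull
#' (k1/sigma2_td) (r_td_m - r1_m) with r_td the module's slice of U2 r2,
#' minus (k1/2) g'(r1_m). The topmost level has no top-down term:
#' dr2 = (k1/sigma2_td) U2^T (r_cat - U2 r2) - (k1/2) g'(r2).
#'
#' @inheritParams coding_length
#' @return List with `dr1` (`ncol(U1)` x `n_windows` matrix) and `dr2`
#'   (vector, or `NULL` for single-level networks).
#' @export
state_derivative <- function(input, r1, r2, network) {
  g <- network$geometry; p <- network$params
  I <- tile_to_matrix(unclass(input), g)
  r1 <- as_r1_matrix(r1, network)
  M <- network_mask_matrix(network)
  res1 <- M * (I - network$U1 %*% r1)
  dr1 <- (p$k1 / p$sigma2) * crossprod(network$U1, res1) -
    (p$k1 / 2) * sparse_prior_deriv(r1, p$alpha1, p$prior_scale)
  dr2 <- NULL
  if (!is.null(network$U2)) {
    if (is.null(r2)) stop_invalid("network has a level 2 but r2 is NULL")
    res2 <- as.vector(r1) - as.vector(network$U2 %*% r2)
    dr1 <- dr1 - (p$k1 / p$sigma2_td) * matrix(res2, ncol(network$U1), g$n_windows)
    dr2 <- (p$k1 / p$sigma2_td) * as.vector(crossprod(network$U2, res2)) -
      (p$k1 / 2) * sparse_prior_deriv(r2, p$alpha2, p$prior_scale2)
  }
  list(dr1 = dr1, dr2 = dr2)
}

#' Relax the network to a steady state
#'
#' Forward-Euler co-evolution of all level-1 states and the level-2 state
#' under [state_derivative()], from stimulus onset until the derivative
#' max-norm falls below `tol` or `max_iter` accepted steps are taken. A
#' backtracking guard halves any step that would increase the coding
#' length, so the recorded `E_trace` is non-increasing by construction
#' (gradient flow on E).
#'
#' @param input `patch_size` x `patch_size` stimulus matrix.
#' @param network an [hpc_network()].
#' @param init_r1,init_r2 initial states; default zeros (stimulus onset).
#' @param step Euler step size.
#' @param tol convergence tolerance on the derivative max-norm.
#' @param max_iter maximum number of accepted steps.
#' @param record_energy record the coding length at every iteration.
#' @return Object of class `hpc_inference`: list with `r1`
#'   (`ncol(U1)` x `n_windows`), `r2` (vector or `NULL`), `E_trace`,
#'   `energy` (final E including the weight-prior term), `iterations`,
#'   `converged`, `grad_norm`.
#' @export
relax_to_steady_state <- function(input, network, init_r1 = NULL,
                                  init_r2 = NULL, step = 0.2, tol = 1e-4,
                                  max_iter = 2000L, record_energy = TRUE) {
  if (step <= 0 || tol <= 0) stop_invalid("step and tol must be positive")
  g <- network$geometry; p <- network$params
  K1 <- ncol(network$U1)
  I <- tile_to_matrix(unclass(input), g)
  M <- network_mask_matrix(network)
  r1 <- if (is.null(init_r1)) matrix(0, K1, g$n_windows) else
    as_r1_matrix(init_r1, network)
  hU <- p$lambda * sum(network$U1^2)
  if (is.null(network$U2)) {
    fit <- relax_l1_cpp(I, network$U1, M, p$alpha1, p$prior_scale,
                        p$k1, p$sigma2,
                        step, tol, as.integer(max_iter), record_energy, r1)
    r2 <- NULL
  } else {
    hU <- hU + p$lambda * sum(network$U2^2)
    r2 <- if (is.null(init_r2)) numeric(ncol(network$U2)) else init_r2
    fit <- relax_joint_cpp(I, network$U1, network$U2, M,
                           p$alpha1, p$alpha2, p$prior_scale, p$prior_scale2,
                           p$k1, p$sigma2, p$sigma2_td,
                           step, tol, as.integer(max_iter), record_energy,
                           r1, matrix(r2, ncol = 1L))
    r2 <- as.vector(fit$R2)
  }
  structure(list(
    r1 = fit$R, r2 = r2,
    E_trace = if (record_energy) fit$E_trace + hU else NULL,
    energy = fit$energy + hU,
    iterations = fit$iterations, converged = fit$converged,
    grad_norm = fit$grad_norm), class = "hpc_inference")
}

#' @export
print.hpc_inference <- function(x, ...) {
  cat(sprintf("<hpc_inference: E = %.6g after %d steps (%s, |grad| = %.3g)>\n",
              x$energy, x$iterations,
              if (x$converged) "converged" else "not converged", x$grad_norm))
  invisible(x)
}

#' Perceptual image (pixel-space rendering of the level-1 prediction)
#'
#' Untiles the nine level-1 predictions `U1 r1_m`, averaging overlaps.
#' This is the generative model's reconstruction of what the network
#' "perceives", including any filled-in content over the blind spot.
#'
#' @param network an [hpc_network()].
#' @param result an [relax_to_steady_state()] result (or any object with
#'   an `r1` matrix).
#' @return `patch_size` x `patch_size` matrix.
#' @export
perceptual_image <- function(network, result) {
  r1 <- as_r1_matrix(result$r1, network)
  untile(network$U1 %*% r1, network$geometry)
}

#' Project a level-2 basis vector into image space
#'
#' Column `j` of `U2` prescribes, per module, a pattern of level-1
#' responses; composing with `U1` and untiling renders the level-2
#' neuron's effective receptive field on the full input frame.
#'
#' @param network an [hpc_network()] with a trained `U2`.
#' @param j level-2 neuron index.
#' @return `patch_size` x `patch_size` matrix.
#' @export
level2_rf_in_image_space <- function(network, j) {
  if (is.null(network$U2)) stop_invalid("network has no level 2")
  j <- as.integer(j)
  if (j < 1L || j > ncol(network$U2))
    stop_invalid("neuron index %d out of range 1..%d", j, ncol(network$U2))
  K1 <- ncol(network$U1)
  slice <- matrix(network$U2[, j], K1, network$geometry$n_windows)
  untile(network$U1 %*% slice, network$geometry)
}
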