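# Small-instance fixtures and numerical-gradient oracles shared by the
# unit tests. The "small" network uses a 10x10 patch tiled into nine 4x4
# windows (U1 is 16x8, U2 is 72x12), mirroring the full architecture at a
# size where finite differences are fast.

small_geometry <- function() tiling_geometry(10L, 4L, 1L)

small_network <- function(seed = 1L, with_U2 = TRUE, mask = NULL,
                          params = network_params(), id = "small") {
  g <- small_geometry()
  withr::with_seed(seed, {
    U1 <- matrix(rnorm(16 * 8, sd = 0.3), 16, 8)
    U2 <- if (with_U2) matrix(rnorm(72 * 12, sd = 0.3), 72, 12) else NULL
    hpc_network(U1, U2, g, params, ff_mask = mask, id = id)
  })
}

random_small_states <- function(seed = 1L, with_U2 = TRUE) {
  withr::with_seed(seed, list(
    input = matrix(rnorm(100), 10, 10),
    r1 = matrix(rnorm(8 * 9, sd = 0.5), 8, 9),
    r2 = if (with_U2) rnorm(12, sd = 0.5) else NULL))
}

# central finite differences of coding_length w.r.t. every state entry,
# scaled by -(k1/2): the independent oracle for state_derivative
num_state_gradient <- function(input, r1, r2, network, eps = 1e-5) {
  k1 <- network$params$k1
  g1 <- r1
  for (i in seq_along(r1)) {
    rp <- r1; rp[i] <- rp[i] + eps
    rm <- r1; rm[i] <- rm[i] - eps
    g1[i] <- -(k1 / 2) *
      (coding_length(input, rp, r2, network) -
         coding_length(input, rm, r2, network)) / (2 * eps)
  }
  g2 <- NULL
  if (!is.null(r2)) {
    g2 <- r2
    for (i in seq_along(r2)) {
      rp <- r2; rp[i] <- rp[i] + eps
      rm <- r2; rm[i] <- rm[i] - eps
      g2[i] <- -(k1 / 2) *
        (coding_length(input, r1, rp, network) -
           coding_length(input, r1, rm, network)) / (2 * eps)
    }
  }
  list(dr1 = g1, dr2 = g2)
}

# level-1-only energy for a single (input vector, state) pair, used as the
# finite-difference oracle for efficacy_update
l1_energy <- function(ivec, r, U, params) {
  res <- ivec - U %*% r
  sum(res^2) / params$sigma2 +
    sparse_prior(r, params$alpha1, params$prior_scale) +
    params$lambda * sum(U^2)
}

rel_err <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-12)

# a couple of small surrogate images for quick training runs
tiny_training_images <- function(n = 2L, size = 128L, segments = 40L,
                                 seed = 99L) {
  imgs <- lapply(seq_len(n), function(i)
    generate_surrogate_image(size, size, segments, seed + i))
  preprocess_images(imgs)
}
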