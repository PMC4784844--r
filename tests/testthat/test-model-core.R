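test_that("sparse prior matches its printed form and its gradient", {
  expect_equal(sparse_prior(numeric(5), 0.05), 0)
  expect_equal(sparse_prior_deriv(numeric(5), 0.05), numeric(5))
  expect_equal(sparse_prior_deriv(1, 0.05), 0.05) # 2*0.05*1/(1+1)
  r <- c(-2, -0.3, 0.1, 1.7)
  expect_equal(sparse_prior_deriv(-r, 0.3), -sparse_prior_deriv(r, 0.3))
  expect_equal(sparse_prior(r, 0.2), 2 * sparse_prior(r, 0.1))
  for (s in c(1, sqrt(0.05))) {
    num <- vapply(seq_along(r), function(i) {
      eps <- 1e-6
      rp <- r; rp[i] <- rp[i] + eps
      rm <- r; rm[i] <- rm[i] - eps
      (sparse_prior(rp, 0.3, s) - sparse_prior(rm, 0.3, s)) / (2 * eps)
    }, numeric(1))
    expect_lt(rel_err(num, sparse_prior_deriv(r, 0.3, s)), 1e-6)
  }
})

test_that("network_params validates and bar constructors reject bad input", {
  p <- network_params()
  expect_equal(p$k1, 1); expect_equal(p$sigma2, 3)
  expect_equal(p$prior_scale, 1)
  expect_equal(p$sigma2_goal, 1)
  expect_error(network_params(k1 = -1), "k1")
  expect_error(network_params(sigma2 = 0), "sigma2")
  expect_silent(network_params(alpha1 = 0, lambda = 0))
  expect_error(hpc_network(matrix(0, 10, 8), geometry = small_geometry()),
               "16")
  expect_error(hpc_network(matrix(0, 16, 8), matrix(0, 60, 5),
                           geometry = small_geometry()), "72")
})

test_that("coding length vanishes in the degenerate cases", {
  p0 <- network_params(alpha1 = 0, alpha2 = 0, lambda = 0)
  net <- small_network(1, params = p0)
  zero_r1 <- matrix(0, 8, 9)
  expect_equal(coding_length(matrix(0, 10, 10), zero_r1, numeric(12), net), 0)
  # perfect reconstruction at both levels (non-overlapping tiling so the
  # level-1 predictions can be assembled into one consistent input)
  g0 <- tiling_geometry(12L, 4L, 0L)
  set.seed(20)
  U1 <- matrix(rnorm(16 * 8, sd = 0.3), 16, 8)
  U2 <- matrix(rnorm(72 * 12, sd = 0.3), 72, 12)
  net0 <- hpc_network(U1, U2, g0, p0, id = "noov")
  r2 <- rnorm(12, sd = 0.3)
  r1 <- matrix(U2 %*% r2, 8, 9)
  input <- untile(U1 %*% r1, g0) # exact: no overlaps to average
  expect_equal(coding_length(input, r1, r2, net0), 0, tolerance = 1e-20)
})

test_that("unmasked coding length equals a direct evaluation", {
  net <- small_network(2)
  st <- random_small_states(3)
  p <- net$params
  I <- hpcfill:::tile_to_matrix(st$input, net$geometry)
  direct <- sum((I - net$U1 %*% st$r1)^2) / p$sigma2 +
    sum((as.vector(st$r1) - net$U2 %*% st$r2)^2) / p$sigma2_td +
    p$alpha1 * sum(log1p((st$r1 / p$prior_scale)^2)) +
    p$alpha2 * sum(log1p((st$r2 / p$prior_scale)^2)) +
    p$lambda * (sum(net$U1^2) + sum(net$U2^2))
  expect_equal(coding_length(st$input, st$r1, st$r2, net), direct)
})

test_that("state_derivative matches the finite-difference oracle", {
  mask10 <- make_bs_mask(10L, 4L)
  cases <- list(
    list(net = small_network(1, with_U2 = TRUE), with_U2 = TRUE),
    list(net = small_network(2, with_U2 = FALSE), with_U2 = FALSE),
    list(net = small_network(3, with_U2 = TRUE, mask = mask10),
         with_U2 = TRUE))
  for (k in seq_along(cases)) {
    net <- cases[[k]]$net
    st <- random_small_states(10 + k, with_U2 = cases[[k]]$with_U2)
    d <- state_derivative(st$input, st$r1, st$r2, net)
    num <- num_state_gradient(st$input, st$r1, st$r2, net)
    expect_lt(rel_err(d$dr1, num$dr1), 1e-5)
    if (cases[[k]]$with_U2) expect_lt(rel_err(d$dr2, num$dr2), 1e-5)
  }
})

test_that("an all-zero mask removes the bottom-up drive entirely", {
  net <- small_network(4, mask = matrix(0, 10, 10))
  st <- random_small_states(5)
  d <- state_derivative(st$input, st$r1, st$r2, net)
  p <- net$params
  td <- matrix(net$U2 %*% st$r2, 8, 9)
  expected <- (p$k1 / p$sigma2_td) * (td - st$r1) -
    (p$k1 / 2) * sparse_prior_deriv(st$r1, p$alpha1, p$prior_scale)
  expect_equal(d$dr1, expected)
})

test_that("relaxation descends the energy and is idempotent at rest", {
  net <- small_network(6)
  # zero input, zero init: already at the fixed point
  res0 <- relax_to_steady_state(matrix(0, 10, 10), net)
  expect_true(res0$converged)
  expect_equal(res0$iterations, 0L)
  expect_equal(res0$r1, matrix(0, 8, 9))
  # random input: E_trace non-increasing, derivative norm below tol
  st <- random_small_states(7)
  res <- relax_to_steady_state(st$input, net, tol = 1e-5, max_iter = 5000)
  expect_true(res$converged)
  expect_true(all(diff(res$E_trace) <= 1e-10))
  expect_lte(res$grad_norm, 1e-5)
  # energy trace is the coding length of the visited states at the end
  expect_equal(coding_length(st$input, res$r1, res$r2, net),
               res$energy, tolerance = 1e-10)
  # re-entering the converged state reconverges within one step
  res2 <- relax_to_steady_state(st$input, net, init_r1 = res$r1,
                                init_r2 = res$r2, tol = 1e-5)
  expect_lte(res2$iterations, 1L)
})

test_that("a single accepted Euler step equals step * derivative", {
  net <- small_network(8)
  st <- random_small_states(9)
  d <- state_derivative(st$input, st$r1, st$r2, net)
  res <- relax_to_steady_state(st$input, net, init_r1 = st$r1,
                               init_r2 = st$r2, step = 1e-4, max_iter = 1,
                               record_energy = FALSE)
  expect_equal((res$r1 - st$r1) / 1e-4, d$dr1, tolerance = 1e-6)
  expect_equal((res$r2 - st$r2) / 1e-4, d$dr2, tolerance = 1e-6)
})

test_that("with no priors and invertible U1 the steady state reconstructs", {
  g <- small_geometry()
  set.seed(10)
  U1 <- qr.Q(qr(matrix(rnorm(256), 16, 16))) # orthonormal, well-conditioned
  p0 <- network_params(alpha1 = 0, alpha2 = 0, lambda = 0)
  net <- hpc_network(U1, NULL, g, p0, id = "inv")
  x <- matrix(rnorm(100), 10, 10)
  res <- relax_to_steady_state(x, net, tol = 1e-8, max_iter = 20000)
  I <- hpcfill:::tile_to_matrix(x, g)
  expect_lt(max(abs(U1 %*% res$r1 - I)), 1e-5)
})

test_that("perceptual image is the untiled level-1 prediction", {
  net <- small_network(11)
  st <- random_small_states(12)
  res <- list(r1 = st$r1)
  img <- perceptual_image(net, res)
  expect_equal(dim(img), c(10L, 10L))
  expect_equal(perceptual_image(net, list(r1 = 2 * st$r1)), 2 * img)
  expect_equal(perceptual_image(net, list(r1 = matrix(0, 8, 9))),
               matrix(0, 10, 10))
  expect_equal(img, untile(net$U1 %*% st$r1, net$geometry))
})

test_that("level-2 receptive fields compose U1 with a U2 column", {
  net <- small_network(13)
  # one-hot column: neuron i of module m pastes U1 column i at window m
  U2 <- matrix(0, 72, 12)
  U2[(5 - 1) * 8 + 3, 1] <- 1 # module 5, level-1 neuron 3
  net$U2 <- U2
  img <- level2_rf_in_image_space(net, 1)
  subs <- replicate(9, matrix(0, 4, 4), simplify = FALSE)
  subs[[5]] <- matrix(net$U1[, 3], 4, 4)
  expect_equal(img, untile(subs, net$geometry))
  # linearity in the column
  net$U2[, 2] <- 2 * net$U2[, 1]
  expect_equal(level2_rf_in_image_space(net, 2), 2 * img)
  expect_error(level2_rf_in_image_space(net, 13), "range")
  expect_error(level2_rf_in_image_space(small_network(1, with_U2 = FALSE), 1),
               "level 2")
})
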