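# stimuli shrunk to the 10x10 small-network frame
small_stim <- function(vals, label) {
  m <- matrix(0, 10, 10)
  m[vals] <- 1
  hpcfill:::new_stimulus(m, label)
}

test_that("a battery records every neuron and flags its runs", {
  net <- small_network(31, id = "A")
  net2 <- small_network(32, id = "B")
  stims <- list(small_stim(11:14, "s1"), small_stim(51:58, "s2"))
  tab <- run_stimulus_battery(list(net, net2), stims)
  # counting contract: networks x stimuli x (9 modules x 8 + 12) rows
  expect_equal(nrow(tab$responses), 2 * 2 * (9 * 8 + 12))
  expect_equal(nrow(tab$runs), 4)
  expect_true(all(c("A", "B") %in% tab$responses$network))
  expect_equal(dim(tab$percepts[["A"]][["s1"]]), c(10L, 10L))
  # zero stimulus: all responses zero (fixed point at rest)
  tz <- run_stimulus_battery(net, list(small_stim(integer(0), "z")))
  expect_true(all(tz$responses$response == 0))
  # duplicate labels and duplicate ids are rejected
  expect_error(run_stimulus_battery(net, list(small_stim(1, "x"),
                                              small_stim(2, "x"))),
               "duplicate")
  expect_error(run_stimulus_battery(list(net, net), stims), "distinct")
})

test_that("normalization fixes max |response| to 1 and preserves structure", {
  net <- small_network(33, id = "A")
  stims <- list(small_stim(11:14, "s1"), small_stim(51:58, "s2"))
  tab <- normalize_responses(run_stimulus_battery(net, stims))
  df <- tab$responses
  for (lv in unique(df$level))
    expect_equal(max(abs(df$normalized[df$level == lv])), 1)
  # sign preservation and scale invariance
  expect_true(all(sign(df$normalized) == sign(df$response)))
  tab3 <- tab
  tab3$responses$response <- 3 * tab3$responses$response
  tab3$responses$normalized <- NULL
  tab3 <- normalize_responses(tab3)
  expect_equal(tab3$responses$normalized, df$normalized)
  # all-zero scope is flagged, not divided
  tz <- normalize_responses(
    run_stimulus_battery(net, list(small_stim(integer(0), "z"))))
  expect_false(is.null(tz$norm_flags))
  expect_equal(tz$responses$normalized, tz$responses$response)
})

test_that("top_k_neurons ranks by peak magnitude with index tie-break", {
  # constructed table: neuron 7 dominates, neurons 2 and 5 tie
  df <- expand.grid(network = "A", stimulus = c("s1", "s2"), level = 1L,
                    module = 5L, neuron = 1:8, stringsAsFactors = FALSE)
  df$response <- 0.1
  df$response[df$neuron == 7] <- c(-0.9, 0.2)
  df$response[df$neuron == 2] <- 0.5
  df$response[df$neuron == 5] <- c(0.5, -0.5)
  tab <- structure(list(responses = df, runs = NULL, percepts = list(),
                        traces = list(), stimulus_order = c("s1", "s2")),
                   class = "response_table")
  expect_equal(top_k_neurons(tab, "A", module = 5, k = 3), c(7L, 2L, 5L))
  expect_equal(top_k_neurons(tab, "A", module = 5, k = 8)[1:3], c(7L, 2L, 5L))
  expect_error(top_k_neurons(tab, "A", module = 5, k = 9), "exceeds")
  expect_error(top_k_neurons(tab, "Z", module = 5, k = 2), "no responses")
})

test_that("a linear single-level pipeline is exactly additive", {
  # alpha = 0, no hierarchy, no mask: superposition must hold through the
  # entire battery + nonlinearity pipeline, isolating the AND-gate to the
  # priors/hierarchy
  g <- tiling_geometry()
  set.seed(35)
  U1 <- matrix(rnorm(144 * 16, sd = 0.3), 144, 16)
  p0 <- network_params(alpha1 = 0, alpha2 = 0)
  net <- hpc_network(U1, NULL, g, p0, id = "lin")
  st <- make_nonlinearity_stimuli()
  tab <- run_stimulus_battery(net, st,
                              options = list(tol = 1e-9, max_iter = 50000))
  tab <- normalize_responses(tab)
  df <- tab$responses
  resp <- function(lab) df$response[df$stimulus == lab]
  expect_lt(max(abs(resp("ab") - resp("a") - resp("b"))), 1e-6)
  # blank a and b give zero means and a failing gate
  blank <- list(a = small_stim(integer(0), "a"),
                b = small_stim(integer(0), "b"),
                c = small_stim(integer(0), "c"),
                ab = small_stim(integer(0), "ab"))
  netS <- small_network(36, id = "S")
  nl0 <- nonlinearity_test(
    normalize_responses(run_stimulus_battery(netS, blank)), "S", k = 4)
  expect_equal(nl0$mean_ab, 0)
  expect_false(nl0$passes)
  expect_error(nonlinearity_test(tab, "lin"), NA) # a,b,c,ab all present
})

test_that("completion_index matches its template contract", {
  spec <- bar_spec()
  mask <- make_bs_mask()
  template <- hpcfill:::paint_bar(matrix(0, 30, 30), spec, 1:30)
  expect_equal(completion_index(template, spec, mask), 1)
  expect_equal(completion_index(-template, spec, mask), -1)
  blank <- matrix(0, 30, 30)
  expect_equal(completion_index(blank, spec, mask), 0) # constant-side rule
  expect_error(completion_index(matrix(NA_real_, 30, 30), spec, mask))
})

test_that("misalignment curves have seven deterministic entries", {
  g <- tiling_geometry()
  set.seed(37)
  U1 <- matrix(rnorm(144 * 16, sd = 0.3), 144, 16)
  U2 <- matrix(rnorm(9 * 16 * 10, sd = 0.2), 9 * 16, 10)
  net <- hpc_network(U1, U2, g, id = "toy")
  bs <- apply_blind_spot(net)
  mc <- misalignment_curve(bs, options = list(max_iter = 500))
  expect_s3_class(mc, "completion_curve")
  expect_equal(mc$offset, -3:3)
  expect_equal(nrow(mc), 7L)
  mc2 <- misalignment_curve(bs, options = list(max_iter = 500))
  expect_identical(mc$index, mc2$index) # deterministic given weights
})

test_that("percept similarity is 1 for identical networks, flagged at zero", {
  net <- small_network(38, id = "A")
  netB <- net; netB$id <- "B"
  stims <- list(small_stim(11:14, "s1"), small_stim(integer(0), "z"))
  tab <- run_stimulus_battery(list(net, netB), stims)
  ps <- percept_similarity(tab, "A", "B")
  expect_equal(ps$correlation[ps$stimulus == "s1"], 1)
  expect_true(ps$flag[ps$stimulus == "z"])
  expect_equal(ps$correlation[ps$stimulus == "z"], 0)
  expect_equal(percept_cor(tab, "A", "s1", "B", "s1"), 1)
  expect_error(percept_cor(tab, "A", "nope", "B", "s1"), "not found")
})
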