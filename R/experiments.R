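#' Index of the central ("BS") module
#'
#' @param geometry a [tiling_geometry()].
#' @return Integer index of the window covering the patch centre.
#' @export
central_module <- function(geometry = tiling_geometry()) {
  k <- length(geometry$starts)
  mid <- (k + 1L) %/% 2L
  (mid - 1L) * k + mid
}

battery_options <- function(options = list()) {
  defaults <- list(whiten = FALSE, f0 = 200, ref_size = 512L,
                   step = 0.2, tol = 1e-4, max_iter = 2000L,
                   record_energy = TRUE)
  unknown <- setdiff(names(options), names(defaults))
  if (length(unknown))
    stop_invalid("unknown battery option(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, options)
}

preprocess_stimulus <- function(stim, opts) {
  x <- remove_dc(unclass(stim))
  if (isTRUE(opts$whiten)) {
    n <- nrow(x)
    x <- whiten(x, build_whitening_filter(n, opts$f0 * n / opts$ref_size))
  }
  x
}

#' Run a stimulus battery on one or more networks
#'
#' For each (network, stimulus) pair: preprocess the stimulus (DC removal
#' by default; full whitening via `options$whiten = TRUE`), relax to
#' steady state from zero initial states, and record every level-1 and
#' level-2 response, the perceptual image, the final coding length and
#' the convergence flag. Non-convergent runs are flagged, not dropped.
#'
#' @param networks an [hpc_network()] or list of them (distinct `id`s).
#' @param stimuli list of `stimulus` objects with distinct labels.
#' @param options list; see `battery_options`: `whiten`, `f0`, `ref_size`,
#'   `step`, `tol`, `max_iter`, `record_energy`.
#' @return Object of class `response_table`: list with `responses` (long
#'   data frame: network, stimulus, level, module, neuron, response),
#'   `runs` (per network x stimulus: energy, iterations, converged,
#'   grad_norm), `percepts` (`percepts[[network]][[stimulus]]` matrices),
#'   `traces` (energy traces, if recorded) and `stimulus_order`.
#' @export
run_stimulus_battery <- function(networks, stimuli, options = list()) {
  if (inherits(networks, "hpc_network")) networks <- list(networks)
  ids <- vapply(networks, function(n) n$id, character(1))
  if (anyDuplicated(ids)) stop_invalid("networks must have distinct ids")
  names(networks) <- ids
  labels <- vapply(stimuli, stimulus_label, character(1))
  if (anyDuplicated(labels))
    stop_invalid("duplicate stimulus label(s): %s",
                 paste(unique(labels[duplicated(labels)]), collapse = ", "))
  opts <- battery_options(options)
  responses <- list()
  runs <- list()
  percepts <- list()
  traces <- list()
  for (id in ids) {
    net <- networks[[id]]
    percepts[[id]] <- list()
    traces[[id]] <- list()
    for (j in seq_along(stimuli)) {
      lab <- labels[j]
      x <- preprocess_stimulus(stimuli[[j]], opts)
      res <- relax_to_steady_state(x, net, step = opts$step, tol = opts$tol,
                                   max_iter = opts$max_iter,
                                   record_energy = opts$record_energy)
      K1 <- ncol(net$U1); M <- net$geometry$n_windows
      df1 <- data.frame(network = id, stimulus = lab, level = 1L,
                        module = rep(seq_len(M), each = K1),
                        neuron = rep(seq_len(K1), times = M),
                        response = as.vector(res$r1),
                        row.names = NULL)
      responses[[length(responses) + 1L]] <- df1
      if (!is.null(res$r2))
        responses[[length(responses) + 1L]] <-
          data.frame(network = id, stimulus = lab, level = 2L, module = 1L,
                     neuron = seq_along(res$r2), response = res$r2,
                     row.names = NULL)
      runs[[length(runs) + 1L]] <-
        data.frame(network = id, stimulus = lab, energy = res$energy,
                   iterations = res$iterations, converged = res$converged,
                   grad_norm = res$grad_norm, row.names = NULL)
      percepts[[id]][[lab]] <- perceptual_image(net, res)
      if (opts$record_energy) traces[[id]][[lab]] <- res$E_trace
    }
  }
  structure(list(responses = do.call(rbind, responses),
                 runs = do.call(rbind, runs),
                 percepts = percepts, traces = traces,
                 stimulus_order = labels),
            class = "response_table")
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("<response_table: %d networks x %d stimuli, %d response rows%s>\n",
              length(x$percepts), length(x$stimulus_order),
              nrow(x$responses),
              if ("normalized" %in% names(x$responses)) ", normalized" else ""))
  invisible(x)
}

#' Normalize recorded responses
#'
#' Within each (network, level) scope of the battery, divides responses
#' by the maximum absolute response over all neurons, modules and
#' stimuli in that scope, so the largest normalized magnitude is exactly
#' 1. Signs and orderings are preserved. An all-zero scope is left
#' unnormalized and flagged.
#'
#' @param table a [run_stimulus_battery()] result.
#' @return The table with a `normalized` column added to `responses` and
#'   a `norm_flags` data frame of degenerate scopes.
#' @export
normalize_responses <- function(table) {
  stopifnot(inherits(table, "response_table"))
  df <- table$responses
  if (nrow(df) == 0L) stop_invalid("response table is empty")
  df$normalized <- df$response
  flags <- list()
  for (id in unique(df$network)) {
    for (lv in unique(df$level[df$network == id])) {
      sel <- df$network == id & df$level == lv
      mx <- max(abs(df$response[sel]))
      if (mx > 0) {
        df$normalized[sel] <- df$response[sel] / mx
      } else {
        flags[[length(flags) + 1L]] <-
          data.frame(network = id, level = lv, reason = "all-zero scope")
      }
    }
  }
  table$responses <- df
  table$norm_flags <- if (length(flags)) do.call(rbind, flags) else NULL
  table
}

ensure_normalized <- function(table) {
  if (!"normalized" %in% names(table$responses)) normalize_responses(table)
  else table
}

#' Most responsive neurons in a module
#'
#' Ranks neurons by their maximum absolute (normalized) response over the
#' whole battery; ties are broken by lower neuron index.
#'
#' @param table a [run_stimulus_battery()] result.
#' @param network network id.
#' @param module module index (default: the central module at level 1).
#' @param k number of neurons to return.
#' @param level hierarchy level.
#' @return Integer vector of `k` neuron indices, most responsive first.
#' @export
top_k_neurons <- function(table, network, module = 5L, k = 8L, level = 1L) {
  table <- ensure_normalized(table)
  df <- table$responses
  sel <- df$network == network & df$level == level & df$module == module
  if (!any(sel)) stop_invalid("no responses for network '%s' module %d level %d",
                              network, module, level)
  df <- df[sel, ]
  mx <- tapply(abs(df$normalized), df$neuron, max)
  idx <- as.integer(names(mx))
  if (k > length(idx)) stop_invalid("k = %d exceeds neuron count %d", k, length(idx))
  idx[order(-mx, idx)][seq_len(k)]
}

#' AND-gate nonlinearity test
#'
#' Compares the mean absolute normalized response of the `k` most
#' responsive central-module neurons across the `a`, `b`, `c` and `ab`
#' conditions. The signature supra-additive (AND-gate) behaviour is
#' `mean_ab > mean_a + mean_b`; the control `c` is reported but not part
#' of the pass criterion.
#'
#' @param table battery result containing stimuli `a`, `b`, `c`, `ab`.
#' @param network network id (normally the lesioned BS network).
#' @param k number of top neurons to average.
#' @param module module index (default central).
#' @return List: `mean_a`, `mean_b`, `mean_c`, `mean_ab`,
#'   `mean_a_plus_b`, `top_neurons`, `passes`.
#' @export
nonlinearity_test <- function(table, network, k = 8L, module = 5L) {
  table <- ensure_normalized(table)
  need <- c("a", "b", "c", "ab")
  have <- unique(table$responses$stimulus[table$responses$network == network])
  if (!all(need %in% have))
    stop_invalid("missing condition(s): %s", paste(setdiff(need, have), collapse = ", "))
  top <- top_k_neurons(table, network, module = module, k = k, level = 1L)
  df <- table$responses
  cond_mean <- function(lab) {
    sel <- df$network == network & df$level == 1L & df$module == module &
      df$stimulus == lab & df$neuron %in% top
    mean(abs(df$normalized[sel]))
  }
  m <- vapply(need, cond_mean, numeric(1))
  list(mean_a = m[["a"]], mean_b = m[["b"]], mean_c = m[["c"]],
       mean_ab = m[["ab"]], mean_a_plus_b = m[["a"]] + m[["b"]],
       top_neurons = top, passes = m[["ab"]] > m[["a"]] + m[["b"]])
}

#' Response-vs-end-position curves for the shifting bar
#'
#' @param table battery result for a shifting-bar sweep (labels
#'   `shift_<end_col>`).
#' @param network network id.
#' @param neurons neuron indices (e.g. from [top_k_neurons()]).
#' @param module module index (default central).
#' @param mask a [make_bs_mask()] used to annotate the blind-spot
#'   interior end positions.
#' @return Matrix of absolute normalized responses (neurons x end
#'   positions, columns named by end column) with attributes `end_cols`
#'   and `inside_bs` (logical per position: drifting end strictly inside
#'   the blind-spot columns).
#' @export
shifting_bar_profile <- function(table, network, neurons, module = 5L,
                                 mask = make_bs_mask()) {
  table <- ensure_normalized(table)
  df <- table$responses
  labs <- grep("^shift_", table$stimulus_order, value = TRUE)
  if (length(labs) == 0L) stop_invalid("no shifting-bar stimuli in this battery")
  end_cols <- as.integer(sub("^shift_", "", labs))
  ord <- order(end_cols)
  labs <- labs[ord]; end_cols <- end_cols[ord]
  prof <- vapply(labs, function(lab) {
    sel <- df$network == network & df$level == 1L & df$module == module &
      df$stimulus == lab & df$neuron %in% neurons
    sub <- df[sel, ]
    abs(sub$normalized[match(neurons, sub$neuron)])
  }, numeric(length(neurons)))
  prof <- matrix(prof, nrow = length(neurons),
                 dimnames = list(neurons, end_cols))
  bs_cols <- attr(mask, "bs_cols")
  attr(prof, "end_cols") <- end_cols
  attr(prof, "inside_bs") <- end_cols %in% bs_cols
  prof
}

#' Completion index of a perceptual image
#'
#' Pearson correlation, restricted to the blind-spot pixels, between the
#' perceptual image and the ideal completed-bar template (the aligned bar
#' drawn straight through the blind spot at the fixed segment's row).
#' Returns 0 when either side is constant over the blind-spot pixels.
#'
#' @param image `patch_size` x `patch_size` perceptual image.
#' @param bar a [bar_spec()] giving the fixed segment's row/thickness/
#'   amplitude.
#' @param mask a [make_bs_mask()].
#' @return Scalar in `[-1, 1]`.
#' @export
completion_index <- function(image, bar = bar_spec(), mask = make_bs_mask()) {
  if (!all(is.finite(image))) stop_invalid("image must be finite")
  template <- paint_bar(matrix(0, nrow(image), ncol(image)), bar,
                        seq_len(ncol(image)))
  sel <- unclass(mask) == 0
  x <- image[sel]; y <- template[sel]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

#' Misaligned-bar completion curve
#'
#' For each vertical offset, builds the bar-pair stimulus, relaxes the
#' (lesioned) network, and computes the [completion_index()] of its
#' perceptual image against the aligned-bar template.
#'
#' @param network a lesioned [hpc_network()].
#' @param spec a [bar_spec()].
#' @param offsets integer vector of vertical offsets (default -3..3, the
#'   seven probe positions).
#' @param mask a [make_bs_mask()].
#' @param options battery options (see [run_stimulus_battery()]).
#' @return Object of class `completion_curve`: data frame with columns
#'   `offset` and `index`, with the underlying `response_table` attached
#'   as attribute `table`.
#' @export
misalignment_curve <- function(network, spec = bar_spec(), offsets = -3:3,
                               mask = make_bs_mask(), options = list()) {
  stimuli <- lapply(offsets, function(o) make_bar_pair(spec, o, mask))
  tab <- run_stimulus_battery(network, stimuli, options)
  idx <- vapply(seq_along(offsets), function(i) {
    completion_index(tab$percepts[[network$id]][[stimulus_label(stimuli[[i]])]],
                     spec, mask)
  }, numeric(1))
  structure(data.frame(offset = as.integer(offsets), index = idx),
            table = tab, class = c("completion_curve", "data.frame"))
}

#' Perceptual-image similarity between two networks
#'
#' Per stimulus, the Pearson correlation between the two networks'
#' perceptual images over the whole frame. Degenerate (constant) images
#' yield correlation 0 with `flag = TRUE`.
#'
#' @param table a battery result containing both networks.
#' @param network_a,network_b network ids.
#' @return Data frame: `stimulus`, `correlation`, `flag`.
#' @export
percept_similarity <- function(table, network_a, network_b) {
  stopifnot(inherits(table, "response_table"))
  pa <- table$percepts[[network_a]]; pb <- table$percepts[[network_b]]
  if (is.null(pa) || is.null(pb))
    stop_invalid("both networks must have run the same battery")
  out <- lapply(table$stimulus_order, function(lab) {
    x <- pa[[lab]]; y <- pb[[lab]]
    if (sd(as.vector(x)) == 0 || sd(as.vector(y)) == 0)
      data.frame(stimulus = lab, correlation = 0, flag = TRUE)
    else
      data.frame(stimulus = lab, correlation = cor(as.vector(x), as.vector(y)),
                 flag = FALSE)
  })
  do.call(rbind, out)
}

#' Correlation between two specific percepts
#'
#' Helper for comparing a lesioned network's percept of one stimulus with
#' an intact network's percepts of alternative stimuli (e.g. the full
#' versus the truncated bar).
#'
#' @param table a battery result.
#' @param network_a,network_b network ids.
#' @param stimulus_a,stimulus_b stimulus labels.
#' @return Scalar Pearson correlation (0 if either percept is constant).
#' @export
percept_cor <- function(table, network_a, stimulus_a, network_b, stimulus_b) {
  x <- table$percepts[[network_a]][[stimulus_a]]
  y <- table$percepts[[network_b]][[stimulus_b]]
  if (is.null(x) || is.null(y)) stop_invalid("percept not found in table")
  if (sd(as.vector(x)) == 0 || sd(as.vector(y)) == 0) return(0)
  cor(as.vector(x), as.vector(y))
}
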