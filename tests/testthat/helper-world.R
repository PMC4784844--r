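# The shared "acceptance world": six surrogate natural images, a level-1
# matrix trained to receptive-field convergence (2000 batches x 100
# patches; the printed-scale 1000 x 100 run leaves orientation emergence
# incomplete under surrogate images), a level-2 matrix trained with the
# same 150k-patch budget spent as 6000 x 25 (more update steps learn a
# measurably better dictionary at equal compute), and the intact/lesioned
# network pair. Built once per test run and cached; ~7 minutes.

acceptance_world <- local({
  cache <- NULL
  function(seed = 1L) {
    if (!is.null(cache)) return(cache)
    imgs <- lapply(seq_len(6), function(i)
      generate_surrogate_image(512L, 512L, 200L, seed * 1000L + i))
    pre <- preprocess_images(imgs)
    fit1 <- train_level1(pre, list(n_batches = 2000L, batch_size = 100L,
                                   seed = seed))
    fit2 <- train_level2(pre, fit1$U, list(n_batches = 6000L,
                                           batch_size = 25L, seed = seed))
    net <- hpc_network(fit1$U, fit2$U, id = "nonbs")
    cache <<- list(images = pre, fit1 = fit1, fit2 = fit2, net = net,
                   bs = apply_blind_spot(net), seed = seed)
    cache
  }
})

# batteries shared by several acceptance criteria, cached alongside
acceptance_batteries <- local({
  cache <- NULL
  function(world) {
    if (!is.null(cache)) return(cache)
    spec <- bar_spec()
    mask <- make_bs_mask()
    sweep_tab <- normalize_responses(run_stimulus_battery(
      list(world$net, world$bs), shifting_bar_battery(spec)))
    nl_tab <- normalize_responses(run_stimulus_battery(
      world$bs, make_nonlinearity_stimuli(spec, mask)))
    cache <<- list(spec = spec, mask = mask, sweep = sweep_tab, nl = nl_tab)
    cache
  }
})
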