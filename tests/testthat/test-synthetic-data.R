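test_that("likelihood generation is deterministic and phone-driven", {
  strings <- list(w1 = c("p", "aa", "t"), w2 = c("p", "aa", "t"),
                  w3 = c("s", "ih", "n"), w4 = c("s", "ih", "n"))
  inv <- c("p", "t", "s", "n", "aa", "ih")
  cfg <- searchlight_config(20, 60, 10, 100, 120)
  # identical phone strings with zero noise give exactly zero model distance
  same <- synthetic_spec(phone_strings = list(w1 = c("p", "aa", "t"),
                                              w2 = c("p", "aa", "t"),
                                              w3 = c("p", "aa", "t")),
                         inventory = inv, epoch_ms = 120,
                         loglik_noise_sd = 0, seed = 1)
  gs <- suppressWarnings(gen_likelihood_streams(same))
  d_aa <- suppressWarnings(build_phone_drdm(gs$streams, "aa",
                                            config_window_onsets(cfg)))
  for (fr in d_aa$frames) expect_equal(max(abs(fr)), 0)
  # with mixed strings, zero noise leaves phones absent from some condition
  # with constant (all-low) vectors: the degenerate-input guard fires
  spec0 <- synthetic_spec(phone_strings = strings, inventory = inv,
                          epoch_ms = 120, loglik_noise_sd = 0, seed = 1)
  g <- suppressWarnings(gen_likelihood_streams(spec0))
  g2 <- suppressWarnings(gen_likelihood_streams(spec0))
  expect_identical(g$streams$streams, g2$streams$streams)  # same seed, same bits
  expect_error(suppressWarnings(
    build_model_set(g$streams, NULL, config_window_onsets(cfg), 60)),
    class = "ssrsa_degenerate_input")
  # disjoint phone strings: in phone "aa"'s model, words carrying [aa]
  # pattern together against words that never do
  noisy <- synthetic_spec(phone_strings = strings, inventory = inv,
                          epoch_ms = 120, loglik_noise_sd = 0.5, seed = 2)
  gn <- suppressWarnings(gen_likelihood_streams(noisy))
  msn <- suppressWarnings(build_model_set(gn$streams, NULL,
                                          config_window_onsets(cfg), 60))
  fr <- msn$drdms[["aa"]]$frames[[1]]
  expect_lt(fr["w1", "w2"], fr["w1", "w3"])
  expect_lt(fr["w3", "w4"], fr["w1", "w3"])
})

test_that("different seeds give different streams", {
  spec_a <- synthetic_spec(n_conditions = 4, phones_per_word = 3,
                           epoch_ms = 60, seed = 1)
  spec_b <- synthetic_spec(n_conditions = 4, phones_per_word = 3,
                           epoch_ms = 60, seed = 2)
  ga <- gen_likelihood_streams(spec_a)
  gb <- gen_likelihood_streams(spec_b)
  expect_false(identical(ga$streams$streams, gb$streams$streams))
})

test_that("embedded responses realise the target correlation geometry", {
  # all-zero target: rows near perfectly correlated
  z <- rdm(matrix(0, 5, 5))
  X <- embed_target_rdm(z, 5000, seed = 3)
  emp <- 1 - cor(t(X))
  expect_lt(max(abs(emp)), 0.05)
  # random valid target at large m converges within Monte-Carlo tolerance
  target <- random_rdm(8, 33)
  Xl <- embed_target_rdm(target, 10000, seed = 4)
  empl <- 1 - cor(t(Xl))
  expect_lt(max(abs(empl - unclass(target))), 0.05)
  # fixed seed reproducibility
  expect_identical(embed_target_rdm(target, 100, seed = 5),
                   embed_target_rdm(target, 100, seed = 5))
  expect_error(embed_target_rdm(rdm(matrix(0, 4, 4)) , 2, seed = 1),
               class = "ssrsa_invalid_input")
})

test_that("source epoch generation is deterministic with amplitude-0 = pure noise", {
  strings <- lapply(1:6, function(i) c("p", "aa", "t"))
  names(strings) <- sprintf("w%02d", 1:6)
  spec <- synthetic_spec(phone_strings = strings,
                         inventory = c("p", "t", "aa"),
                         epoch_ms = 80, grid_dims = c(3, 3, 1),
                         n_subjects = 2, seed = 11,
                         implants = list(list(centre = "v0001", source = "p",
                                              amplitude = 0)))
  g <- gen_likelihood_streams(spec)
  cfg <- searchlight_config(10, 60, 10, 50, 80)
  ms <- suppressWarnings(build_model_set(g$streams, NULL,
                                         config_window_onsets(cfg), 60))
  se1 <- gen_source_epochs(spec, ms, cfg)
  se2 <- gen_source_epochs(spec, ms, cfg)
  expect_identical(se1$epochs$epochs, se2$epochs$epochs)
  spec_none <- spec; spec_none$implants <- list()
  se0 <- gen_source_epochs(spec_none, ms, cfg)
  expect_equal(se1$epochs$epochs, se0$epochs$epochs, tolerance = 1e-12)
  # overlapping implants are ambiguous ground truth
  spec_bad <- spec
  spec_bad$implants <- list(list(centre = "v0001", source = "p", amplitude = 1),
                            list(centre = "v0002", source = "t", amplitude = 1))
  expect_error(gen_source_epochs(spec_bad, ms, cfg),
               class = "ssrsa_invalid_input")
})

test_that("implanted geometry is recovered at the implant patch", {
  set.seed(99)
  inv <- c("p", "t", "s", "aa", "ih", "n")
  strings <- lapply(1:10, function(i) sample(inv, 3, replace = TRUE))
  names(strings) <- sprintf("w%02d", 1:10)
  spec <- synthetic_spec(phone_strings = strings, inventory = inv,
                         epoch_ms = 150, grid_dims = c(4, 4, 1),
                         grid_spacing_mm = 10, n_subjects = 2,
                         noise_sd = 1, seed = 12,
                         implants = list(list(centre = "v0001", source = "p",
                                              amplitude = 1.5)))
  g <- gen_likelihood_streams(spec)
  cfg <- searchlight_config(10, 60, 10, 100, 150)
  ms <- suppressWarnings(build_model_set(g$streams, NULL,
                                         config_window_onsets(cfg), 60))
  se <- gen_source_epochs(spec, ms, cfg)
  dd <- build_data_drdms(se$epochs, se$mesh, cfg)
  fit <- fit_drdms(dd, ms)
  eb <- epoch_average_betas(fit)
  expect_equal(names(which.max(eb$betas[, "v0001"])), "p")
  # fit decays away from the implant: the far corner shows less of it
  expect_gt(eb$betas["p", "v0001"], eb$betas["p", "v0016"] + 0.05)
})

test_that("synthetic specs round-trip through YAML", {
  spec <- synthetic_spec(n_conditions = 6, epoch_ms = 90, seed = 4,
                         implants = list(list(centre = "v0001", source = "p",
                                              amplitude = 2)))
  f <- tempfile(fileext = ".yaml")
  write_synthetic_yaml(spec, f)
  back <- read_synthetic_yaml(f)
  expect_equal(back$n_conditions, 6)
  expect_equal(back$epoch_ms, 90)
  expect_equal(back$seed, 4)
  expect_equal(back$implants[[1]]$amplitude, 2)
  unlink(f)
})
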