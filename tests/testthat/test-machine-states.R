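test_that("centre-phone grouping selects exactly the matching columns", {
  s <- toy_streams()
  expect_equal(central_phone_columns(s, "a"), c(1L, 2L))
  expect_equal(central_phone_columns(s, "t"), c(4L, 5L))
  err <- tryCatch(central_phone_columns(s, "q"), error = identity)
  expect_s3_class(err, "ssrsa_empty_model")
  # randomized table vs an exhaustive filter oracle
  set.seed(9)
  ph <- letters[1:6]
  tt <- triphone_table(sample(ph, 50, TRUE), sample(ph, 50, TRUE),
                       sample(ph, 50, TRUE))
  big <- likelihood_streams(list(w1 = matrix(rnorm(500), 10, 50),
                                 w2 = matrix(rnorm(500), 10, 50),
                                 w3 = matrix(rnorm(500), 10, 50)), tt)
  for (p in ph) {
    oracle <- which(vapply(seq_len(50), function(k) tt$centre[k] == p, TRUE))
    if (length(oracle) == 0)
      expect_error(central_phone_columns(big, p), class = "ssrsa_empty_model")
    else expect_equal(central_phone_columns(big, p), oracle)
  }
})

test_that("windowed likelihood vectors concatenate 6 frames frame-major", {
  s <- toy_streams(n_frames = 27)
  expect_equal(frames_per_window(60, 10), 6L)
  v <- windowed_likelihood_vector(s, "w01", c(1, 2, 4), 0)
  expect_length(v, 18)  # six 10 ms frames x three columns
  m <- s$streams[["w01"]]
  oracle <- as.vector(sapply(1:6, function(f) m[f, c(1, 2, 4)]))
  expect_equal(v, oracle)
  v2 <- windowed_likelihood_vector(s, "w01", c(3, 5), 210)
  expect_equal(v2, as.vector(sapply(22:27, function(f) m[f, c(3, 5)])))
  expect_error(windowed_likelihood_vector(s, "w01", 1:2, 220),
               class = "ssrsa_window_bounds")
})

test_that("phone dRDMs: identical streams give zero distance, shared structure gives blocks", {
  s <- toy_streams(n_cond = 3, n_frames = 12)
  s$streams[[2]] <- s$streams[[1]]
  s$streams[[3]] <- s$streams[[1]]
  d <- suppressWarnings(build_phone_drdm(s, "a", c(0, 20, 60)))
  for (fr in d$frames) expect_equal(max(abs(fr)), 0)
  # conditions 1-5 share one centre-phone activity pattern, 6-10 another:
  # within-block distances small, between-block large
  set.seed(21)
  tt <- triphone_table(rep("p", 4), rep("a", 4), c("p", "a", "t", "t"))
  pat1 <- matrix(rnorm(12 * 4), 12, 4)
  pat2 <- matrix(rnorm(12 * 4), 12, 4)
  streams <- c(lapply(1:5, function(i) pat1 + 0.05 * matrix(rnorm(48), 12, 4)),
               lapply(1:5, function(i) pat2 + 0.05 * matrix(rnorm(48), 12, 4)))
  names(streams) <- sprintf("w%02d", 1:10)
  ls <- likelihood_streams(streams, tt)
  bl <- build_phone_drdm(ls, "a", c(0, 30))
  fr <- unclass(bl$frames[[1]])
  within <- c(fr[1:5, 1:5][lower.tri(fr[1:5, 1:5])],
              fr[6:10, 6:10][lower.tri(fr[6:10, 6:10])])
  between <- as.vector(fr[1:5, 6:10])
  expect_lt(max(within), min(between))
  expect_true(all(fr >= 0 & fr <= 2))
})

test_that("model RDMs are invariant to triphone column order within a phone", {
  s <- toy_streams(n_cond = 5, n_frames = 12, seed = 4)
  d1 <- build_phone_drdm(s, "a", c(0, 40))
  perm <- c(2, 1, 3, 5, 4)
  s2 <- s
  s2$streams <- lapply(s$streams, function(m) m[, perm])
  s2$triphones <- s$triphones[perm, ]
  d2 <- build_phone_drdm(s2, "a", c(0, 40))
  for (k in 1:2)
    expect_equal(unclass(d1$frames[[k]]), unclass(d2$frames[[k]]),
                 tolerance = 1e-12)
})

test_that("model sets cover every phone with triphones and count frames", {
  s <- toy_streams(n_cond = 4, n_frames = 10)
  ms <- build_model_set(s, c("p", "a", "t"), c(0, 30), window_ms = 60)
  expect_equal(ms$phones, c("p", "a", "t"))
  expect_equal(n_model_frames(ms), 3 * 2)
  for (d in ms$drdms) {
    expect_length(d$frames, 2)
    expect_equal(dim(unclass(d$frames[[1]])), c(4L, 4L))
  }
  expect_warning(build_model_set(s, c("p", "a", "t", "q"), c(0, 30)),
                 "dropped")
  # frames equal the brute-force two-step oracle: group, window, correlate
  for (ph in ms$phones) {
    cols <- which(s$triphones$centre == ph)
    for (k in 1:2) {
      onset <- c(0, 30)[k]
      vecs <- t(sapply(names(s$streams), function(cond)
        as.vector(t(s$streams[[cond]][(onset / 10 + 1):(onset / 10 + 6),
                                      cols, drop = FALSE]))))
      fr <- unclass(ms$drdms[[ph]]$frames[[k]])
      for (i in 1:3) for (j in (i + 1):4)
        expect_equal(fr[i, j], 1 - oracle_pearson(vecs[i, ], vecs[j, ]),
                     tolerance = 1e-12)
    }
  }
})

test_that("likelihood CSV reader reconstructs streams and triphones", {
  s <- toy_streams(n_cond = 3, n_frames = 5, seed = 8)
  f <- tempfile(fileext = ".csv")
  rows <- do.call(rbind, lapply(names(s$streams), function(cond) {
    do.call(rbind, lapply(seq_len(s$n_frames), function(fr)
      data.frame(condition = cond, frame = fr,
                 left = s$triphones$left, centre = s$triphones$centre,
                 right = s$triphones$right,
                 loglik = s$streams[[cond]][fr, ])))
  }))
  write.csv(rows, f, row.names = FALSE)
  back <- read_likelihood_csv(f)
  expect_equal(sort(names(back$streams)), sort(names(s$streams)))
  for (cond in names(s$streams)) {
    reord <- match(back$triphones$label, s$triphones$label)
    expect_equal(back$streams[[cond]], s$streams[[cond]][, reord],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  unlink(f)
})

test_that("structural helpers report capacity and frame geometry", {
  expect_equal(triphone_capacity(letters[1:5]), 125)
  expect_equal(acoustic_frame_dim(), 39)
  expect_equal(frames_per_window(60, 10), 6L)
  expect_error(frames_per_window(65, 10), class = "ssrsa_invalid_input")
})
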