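test_that("correlation distance matches its definition and bounds", {
  expect_equal(correlation_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(correlation_distance(c(1, 2, 3), c(3, 2, 1)), 2)
  x <- c(1, 2, 4); y <- c(1, 3, 5)
  expect_equal(correlation_distance(x, y), 1 - oracle_pearson(x, y),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(7); b <- rnorm(7)
    d <- correlation_distance(a, b)
    expect_gte(d, 0); expect_lte(d, 2)
    expect_equal(d, correlation_distance(b, a))
    # invariant under positive affine transforms of either argument
    expect_equal(d, correlation_distance(2.5 * a + 3, b), tolerance = 1e-10)
  }
})

test_that("degenerate (zero-variance) vectors raise identifying errors", {
  expect_error(correlation_distance(c(1, 1, 1), c(1, 2, 3)),
               class = "ssrsa_degenerate_input")
  m <- rbind(a = c(1, 1, 1, 1), b = c(1, 2, 3, 4), c = c(2, 1, 4, 3))
  err <- tryCatch(rdm_from_response_matrix(m), error = identity)
  expect_s3_class(err, "ssrsa_degenerate_input")
  expect_match(conditionMessage(err), "a")
})

test_that("RDMs from response matrices are symmetric, zero-diagonal, oracle-exact", {
  m <- matrix(rep(c(1, 2, 5, 3), 3), 3, 4, byrow = TRUE)
  r0 <- suppressWarnings(rdm_from_response_matrix(m))
  expect_true(all(r0 == 0))  # identical rows
  set.seed(3)
  resp <- matrix(rnorm(40), 5, 8)
  r <- suppressWarnings(rdm_from_response_matrix(resp))
  expect_equal(dim(unclass(r)), c(5L, 5L))
  expect_equal(unclass(r), t(unclass(r)))
  expect_equal(diag(unclass(r)), rep(0, 5), ignore_attr = TRUE)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(r[i, j], 1 - oracle_pearson(resp[i, ], resp[j, ]),
                 tolerance = 1e-12)
  expect_true(all(r >= 0 & r <= 2))
})

test_that("upper-triangle vectorization uses the documented row-major order", {
  m <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) m[i, j] <- m[j, i] <- 10 * i + j
  expect_equal(upper_triangle_vector(m), c(12, 13, 14, 23, 24, 34))
  expect_equal(nrow(upper_triangle_pairs(4)), 6)
  expect_equal(upper_triangle_pairs(4),
               cbind(i = c(1, 1, 1, 2, 2, 3), j = c(2, 3, 4, 3, 4, 4)),
               ignore_attr = TRUE)
  # a 2x2 matrix vectorizes to a single entry
  expect_equal(upper_triangle_vector(matrix(c(0, 7, 7, 0), 2)), 7)
  # the standard full-scale condition count gives a 79,800-length vector
  expect_equal(length(upper_triangle_vector(rdm(matrix(0, 400, 400)))), 79800)
})

test_that("vector length is n(n-1)/2 and the round trip is lossless", {
  for (n in c(3, 5, 17, 50, 211, 500))
    expect_equal(length(upper_triangle_vector(diag(n) * 0)), n * (n - 1) / 2)
  for (n in c(3, 8, 23, 50)) {
    r <- random_rdm(n, seed = n)
    back <- rdm_from_upper_triangle(upper_triangle_vector(r), rdm_conditions(r))
    expect_equal(unclass(back), unclass(r), tolerance = 1e-15)
  }
})

test_that("Spearman RDM correlation is a rank statistic matching an oracle", {
  a <- random_rdm(6, 1); b <- random_rdm(6, 2)
  expect_equal(spearman_rdm_correlation(a, a), 1)
  # invariant under strictly monotone transforms of one RDM's entries
  mono <- rdm(sqrt(unclass(b)) * 1.7, rdm_conditions(b))
  expect_equal(spearman_rdm_correlation(a, mono),
               spearman_rdm_correlation(a, b), tolerance = 1e-12)
  # rank-then-Pearson oracle
  va <- rank(upper_triangle_vector(a)); vb <- rank(upper_triangle_vector(b))
  expect_equal(spearman_rdm_correlation(a, b), oracle_pearson(va, vb),
               tolerance = 1e-12)
  const <- rdm(matrix(1, 4, 4) - diag(4), sprintf("c%02d", 1:4))
  expect_error(spearman_rdm_correlation(const, const),
               class = "ssrsa_degenerate_input")
})

test_that("averaging RDMs is the entrywise mean and validates inputs", {
  a <- random_rdm(5, 1); b <- random_rdm(5, 2); c <- random_rdm(5, 3)
  expect_equal(unclass(average_rdms(list(a))), unclass(a))
  expect_equal(unclass(average_rdms(list(a, a))), unclass(a))
  expect_equal(unclass(average_rdms(list(a, b, c))),
               (unclass(a) + unclass(b) + unclass(c)) / 3, tolerance = 1e-15)
  expect_error(average_rdms(list()), class = "ssrsa_invalid_input")
  d <- random_rdm(5, 4, labels = sprintf("x%02d", 1:5))
  expect_error(average_rdms(list(a, d)), class = "ssrsa_invalid_input")
})

test_that("condition sets enforce uniqueness and minimum size", {
  expect_error(condition_set(c("a", "a", "b")), class = "ssrsa_invalid_conditions")
  expect_error(condition_set(c("a", "b")), class = "ssrsa_invalid_conditions")
  expect_warning(condition_set(letters[1:5]), "coarse")
})

test_that("dRDM CSV persistence round-trips exactly", {
  frames <- lapply(1:3, function(k) random_rdm(5, k))
  d <- dynamic_rdm(frames, 60, 10)
  f <- tempfile(fileext = ".csv")
  write_drdm_csv(d, f)
  back <- suppressWarnings(read_drdm_csv(f, 60, 10))
  expect_equal(length(back$frames), 3)
  for (k in 1:3)
    expect_equal(unclass(back$frames[[k]]), unclass(frames[[k]]),
                 tolerance = 1e-12)
  unlink(f)
})
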