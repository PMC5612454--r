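make_mesh <- function(dims = c(4, 4, 2), spacing = 5, mask = TRUE) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  source_mesh(sprintf("v%03d", seq_len(nrow(g))), g$x * spacing,
              g$y * spacing, g$z * spacing, in_mask = mask)
}

make_epochs <- function(mesh, n_cond = 4, n_samples = 200, n_subj = 2,
                        seed = 1) {
  set.seed(seed)
  conds <- sprintf("c%02d", seq_len(n_cond))
  ep <- lapply(seq_len(n_subj), function(s) {
    out <- lapply(conds, function(cc)
      matrix(rnorm(nrow(mesh) * n_samples), nrow(mesh), n_samples))
    names(out) <- conds
    out
  })
  names(ep) <- sprintf("s%02d", seq_len(n_subj))
  source_epochs(ep, mesh$vertex_id)
}

test_that("patch membership follows Euclidean distance and the mask", {
  mesh <- make_mesh()
  expect_equal(patch_members(mesh, "v001", 0), "v001")
  expect_setequal(patch_members(mesh, "v001", 1000), mesh$vertex_id)
  # 20 mm on a 5 mm grid vs a brute-force scan
  for (centre in c("v001", "v011", "v022")) {
    i <- match(centre, mesh$vertex_id)
    d <- sqrt((mesh$x_mm - mesh$x_mm[i])^2 + (mesh$y_mm - mesh$y_mm[i])^2 +
                (mesh$z_mm - mesh$z_mm[i])^2)
    expect_setequal(patch_members(mesh, centre, 20),
                    mesh$vertex_id[d <= 20])
  }
  # membership is symmetric at equal radius
  for (u in c("v001", "v007")) for (v in c("v013", "v030"))
    expect_equal(u %in% patch_members(mesh, v, 12),
                 v %in% patch_members(mesh, u, 12))
  # masked-out vertices are excluded and cannot be centres
  mesh2 <- make_mesh(mask = c(FALSE, rep(TRUE, 31)))
  expect_false("v001" %in% patch_members(mesh2, "v002", 1000))
  expect_error(patch_members(mesh2, "v001", 10), class = "ssrsa_invalid_input")
})

test_that("window positions enumerate onsets with the two conventions", {
  expect_length(window_positions(270, 60, 10, "standard"), 21)
  expect_length(window_positions(270, 60, 10, "all"), 22)
  expect_equal(window_positions(60, 60, 10, "standard"), 0)
  set.seed(17)
  for (i in 1:20) {
    w <- sample(2:10, 1) * 10; s <- sample(1:5, 1) * 10
    T <- w + sample(0:20, 1) * 10
    # brute force: every onset on the step grid whose window fits
    oracle <- Filter(function(on) on + w <= T, seq(0, T, by = s))
    expect_equal(window_positions(T, w, s, "all"), oracle)
  }
  expect_error(window_positions(50, 60, 10), class = "ssrsa_invalid_input")
})

test_that("searchlight data RDMs equal the direct correlation-distance oracle", {
  mesh <- make_mesh(c(3, 1, 1))
  cfg <- searchlight_config(radius_mm = 5, window_ms = 60, step_ms = 10,
                            lag_ms = 100, epoch_ms = 100)
  ep <- make_epochs(mesh, n_cond = 3, n_samples = 200, n_subj = 1)
  patch <- patch_members(mesh, "v001", 5)
  expect_length(patch, 2)
  r <- searchlight_data_rdm(ep, patch, 0, cfg)
  rows <- match(patch, mesh$vertex_id)
  m <- ep$epochs[["s01"]]
  vecs <- t(sapply(ep$conditions, function(cc)
    as.vector(t(m[[cc]][rows, 101:160]))))  # 100 ms lag, 60 samples
  expect_length(vecs[1, ], 120)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(r[i, j], 1 - oracle_pearson(vecs[i, ], vecs[j, ]),
                 tolerance = 1e-12)
  # identical conditions for every subject give the zero RDM
  ep0 <- ep
  for (cc in ep0$conditions) ep0$epochs[["s01"]][[cc]] <- m[[ep$conditions[1]]]
  expect_equal(max(abs(searchlight_data_rdm(ep0, patch, 0, cfg))), 0)
  # lagged window must stay inside the epoch
  expect_error(searchlight_data_rdm(ep, patch, 50, cfg),
               class = "ssrsa_window_bounds")
})

test_that("per-subject RDMs are averaged and doubling amplitudes changes nothing", {
  mesh <- make_mesh(c(2, 2, 1))
  cfg <- searchlight_config(5, 60, 10, 0, 80)
  ep <- make_epochs(mesh, n_cond = 4, n_samples = 80, n_subj = 3, seed = 3)
  patch <- mesh$vertex_id
  r <- searchlight_data_rdm(ep, patch, 0, cfg)
  per_subj <- lapply(names(ep$epochs), function(s) {
    one <- ep; one$epochs <- ep$epochs[s]; one$subjects <- s
    searchlight_data_rdm(one, patch, 0, cfg)
  })
  expect_equal(unclass(r), unclass(average_rdms(per_subj)), tolerance = 1e-12)
  ep2 <- ep
  for (s in names(ep2$epochs)) for (cc in ep2$conditions)
    ep2$epochs[[s]][[cc]] <- ep2$epochs[[s]][[cc]] * 2
  expect_equal(unclass(searchlight_data_rdm(ep2, patch, 0, cfg)), unclass(r),
               tolerance = 1e-12)
})

test_that("the data dRDM map covers every masked vertex and window", {
  mesh <- make_mesh(c(2, 2, 1))
  mesh$in_mask <- c(TRUE, TRUE, TRUE, FALSE)
  cfg <- searchlight_config(5, 60, 10, 0, 90)  # 3 windows in paper mode
  ep <- make_epochs(mesh, n_cond = 4, n_samples = 90, n_subj = 1, seed = 4)
  dd <- build_data_drdms(ep, mesh, cfg)
  expect_equal(names(dd), c("v001", "v002", "v003"))
  expect_equal(sum(vapply(dd, length, 0L)), 3 * 3)
  for (v in names(dd)) for (fr in dd[[v]]$frames) {
    expect_true(all(fr >= 0 & fr <= 2))
    expect_equal(unclass(fr), t(unclass(fr)))
  }
  # each vertex equals an explicit per-vertex loop
  for (v in names(dd)) {
    patch <- patch_members(mesh, v, cfg$radius_mm)
    for (k in 1:3)
      expect_equal(unclass(dd[[v]]$frames[[k]]),
                   unclass(searchlight_data_rdm(ep, patch, (k - 1) * 10, cfg)),
                   tolerance = 1e-14)
  }
})

test_that("mesh TSV round-trips", {
  mesh <- make_mesh(c(3, 2, 1), mask = c(rep(TRUE, 5), FALSE))
  f <- tempfile(fileext = ".tsv")
  write_mesh_tsv(mesh, f)
  back <- read_mesh_tsv(f)
  expect_equal(as.data.frame(back), as.data.frame(mesh))
  unlink(f)
})
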