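# Shared fixtures: everything is generated in code at test time.

# random valid correlation-distance RDM over n conditions
random_rdm <- function(n, seed, labels = sprintf("c%02d", seq_len(n))) {
  set.seed(seed)
  suppressWarnings(rdm_from_response_matrix(
    matrix(rnorm(n * 8), n, 8), labels))
}

# small likelihood-stream set with a fixed triphone layout
toy_streams <- function(n_cond = 4, n_frames = 10, seed = 1,
                        inventory = c("p", "a", "t")) {
  set.seed(seed)
  tt <- triphone_table(
    left = c("p", "t", "a", "p", "a"),
    centre = c("a", "a", "p", "t", "t"),
    right = c("t", "p", "t", "a", "p"),
    inventory = inventory)
  streams <- lapply(seq_len(n_cond), function(i)
    matrix(rnorm(n_frames * nrow(tt)), n_frames, nrow(tt)))
  names(streams) <- sprintf("w%02d", seq_len(n_cond))
  likelihood_streams(streams, tt, frame_ms = 10)
}

# tiny feature matrix over a 6-phone inventory
toy_fm <- function() {
  ind <- rbind(stop = c(p = 1, t = 1, k = 1, s = 0, aa = 0, ih = 0),
               fric = c(p = 0, t = 0, k = 0, s = 1, aa = 0, ih = 0),
               vowel = c(p = 0, t = 0, k = 0, s = 0, aa = 1, ih = 1),
               coronal = c(p = 0, t = 1, k = 0, s = 1, aa = 0, ih = 0))
  feature_matrix(ind, c("manner", "manner", "broad", "place"))
}

# model set over `phones` with random but reproducible frames
toy_model_set <- function(phones = c("p", "t", "k", "s", "aa", "ih"),
                          n_cond = 8, n_win = 3, seed = 5) {
  labels <- sprintf("c%02d", seq_len(n_cond))
  drdms <- lapply(seq_along(phones), function(k) {
    frames <- lapply(seq_len(n_win), function(w)
      random_rdm(n_cond, seed + 100 * k + w, labels))
    dynamic_rdm(frames, window_ms = 60, step_ms = 10,
                onsets_ms = (seq_len(n_win) - 1) * 10)
  })
  names(drdms) <- phones
  structure(list(phones = phones, drdms = drdms, dropped = character(0),
                 window_ms = 60, onsets_ms = (seq_len(n_win) - 1) * 10),
            class = "phone_model_set")
}

# independent textbook Pearson correlation (sum formula), as an oracle
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}
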