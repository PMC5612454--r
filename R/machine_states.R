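# Model dRDMs from frame-level triphone log-likelihood streams.
#
# An automatic speech recogniser annotates each 10 ms frame of a speech
# stimulus with log likelihoods over context-dependent triphone units
# (left-context, centre phone, right-context). Grouping triphone columns by
# centre phone and concatenating frames over a sliding window gives, per
# phone and per window position, one likelihood vector per stimulus; the
# pairwise correlation distances between those vectors form that phone's
# model RDM at that window. Repeating over windows yields one dynamic RDM
# per phone.

#' Triphone label table
#'
#' @param left,centre,right character vectors of phone symbols, one triple
#'   per triphone column of the likelihood streams.
#' @param inventory declared phone inventory the symbols must come from.
#' @return data.frame with columns left, centre, right and a `label` of the
#'   conventional `l-c+r` form.
#' @export
triphone_table <- function(left, centre, right, inventory = NULL) {
  if (length(left) != length(centre) || length(centre) != length(right))
    ssrsa_error("left/centre/right must have equal length", "ssrsa_invalid_input")
  if (!is.null(inventory)) {
    bad <- setdiff(unique(c(left, centre, right)), inventory)
    if (length(bad) > 0)
      ssrsa_error(sprintf("phone symbols not in inventory: %s",
                          paste(bad, collapse = ", ")), "ssrsa_invalid_input")
  }
  data.frame(left = left, centre = centre, right = right,
             label = paste0(left, "-", centre, "+", right),
             stringsAsFactors = FALSE)
}

#' Full contextual triphone capacity of a phone inventory
#'
#' The number of distinct (left, centre, right) triples expressible over an
#' inventory: |inventory|^3. Far more triples are expressible than occur in
#' any stimulus set; streams carry only the observed columns.
#'
#' @param inventory character vector of phone symbols.
#' @return integer count.
#' @export
triphone_capacity <- function(inventory) {
  length(unique(inventory))^3
}

#' Dimensionality of a standard acoustic observation vector
#'
#' Recognisers of the kind whose likelihood streams this package consumes
#' describe each frame by cepstral coefficients plus an energy term together
#' with their temporal derivatives: (n_cepstra + energy) blocks repeated for
#' the static features and each derivative order. The conventional 12
#' cepstra + energy with first and second derivatives gives 39 dimensions.
#'
#' @param n_cepstra number of cepstral coefficients per frame.
#' @param energy whether an energy term is appended.
#' @param n_derivatives number of derivative blocks appended to the statics.
#' @return integer dimensionality.
#' @export
acoustic_frame_dim <- function(n_cepstra = 12, energy = TRUE, n_derivatives = 2) {
  (n_cepstra + as.integer(energy)) * (1 + n_derivatives)
}

#' Construct a likelihood stream set
#'
#' @param streams named list (one element per condition) of frame x triphone
#'   numeric matrices of log likelihoods, all with identical shape.
#' @param triphones a [triphone_table()] with one row per column of the
#'   stream matrices.
#' @param frame_ms frame step in ms (10 ms in the standard configuration).
#' @return object of class `likelihood_streams`.
#' @export
likelihood_streams <- function(streams, triphones, frame_ms = 10) {
  if (length(streams) == 0)
    ssrsa_error("no streams supplied", "ssrsa_invalid_input")
  if (is.null(names(streams)) || anyDuplicated(names(streams)))
    ssrsa_error("streams must be a uniquely named list (one per condition)",
                "ssrsa_invalid_input")
  shape <- dim(streams[[1]])
  for (s in streams) {
    if (!is.matrix(s) || !identical(dim(s), shape))
      ssrsa_error("all streams must be matrices of identical shape",
                  "ssrsa_invalid_input")
  }
  if (shape[2] != nrow(triphones))
    ssrsa_error("triphone table rows must match stream columns",
                "ssrsa_invalid_input")
  structure(list(streams = streams, triphones = triphones,
                 frame_ms = frame_ms,
                 n_frames = shape[1]),
            class = "likelihood_streams")
}

#' @export
print.likelihood_streams <- function(x, ...) {
  cat(sprintf("likelihood streams: %d conditions, %d frames x %d triphones (%d ms frames)\n",
              length(x$streams), x$n_frames, nrow(x$triphones), x$frame_ms))
  invisible(x)
}

#' Read likelihood streams from a long-format CSV
#'
#' Columns: condition, frame (1-based), left, centre, right, loglik. Every
#' (condition, frame, triphone) cell must be present.
#'
#' @param path CSV file path.
#' @param frame_ms frame step in ms.
#' @return a `likelihood_streams` object.
#' @export
read_likelihood_csv <- function(path, frame_ms = 10) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "frame", "left", "centre", "right", "loglik")
  if (!all(need %in% names(rows)))
    ssrsa_error(sprintf("likelihood CSV needs columns: %s",
                        paste(need, collapse = ", ")), "ssrsa_invalid_input")
  lab <- paste0(rows$left, "-", rows$centre, "+", rows$right)
  tri_lab <- sort(unique(lab))
  parts <- do.call(rbind, strsplit(tri_lab, "[-+]"))
  tt <- triphone_table(parts[, 1], parts[, 2], parts[, 3])
  frames <- sort(unique(rows$frame))
  streams <- lapply(split(rows, rows$condition), function(d) {
    m <- matrix(NA_real_, length(frames), length(tri_lab),
                dimnames = list(NULL, tri_lab))
    m[cbind(match(d$frame, frames),
            match(paste0(d$left, "-", d$centre, "+", d$right), tri_lab))] <- d$loglik
    if (anyNA(m))
      ssrsa_error("likelihood CSV has missing (condition, frame, triphone) cells",
                  "ssrsa_invalid_input")
    m
  })
  likelihood_streams(streams, tt, frame_ms)
}

#' Columns whose triphone has a given centre phone
#'
#' @param streams a `likelihood_streams` object.
#' @param phone a phone symbol.
#' @return integer column indices in ascending order.
#' @export
central_phone_columns <- function(streams, phone) {
  idx <- which(streams$triphones$centre == phone)
  if (length(idx) == 0)
    ssrsa_error(sprintf("no triphone has centre phone '%s': no model for it", phone),
                "ssrsa_empty_model")
  sort(idx)
}

#' Number of frames spanned by one sliding window
#' @param window_ms window width in ms.
#' @param frame_ms frame step in ms.
#' @return integer frame count (6 for a 60 ms window of 10 ms frames).
#' @export
frames_per_window <- function(window_ms = 60, frame_ms = 10) {
  if (window_ms %% frame_ms != 0)
    ssrsa_error("window_ms must be a multiple of frame_ms", "ssrsa_invalid_input")
  as.integer(window_ms / frame_ms)
}

#' Windowed likelihood vector for one condition
#'
#' Concatenates the selected triphone columns over the frames falling in
#' [onset, onset + window_ms), frame-major: all selected columns of the first
#' frame, then of the second, and so on. Correlation distance is invariant to
#' this order; it is fixed so every module flattens identically.
#'
#' @param streams a `likelihood_streams` object.
#' @param condition condition id.
#' @param columns integer column indices (from [central_phone_columns()]).
#' @param window_onset_ms window onset in ms from epoch start.
#' @param window_ms window width in ms.
#' @return numeric vector of length `frames_per_window * length(columns)`.
#' @export
windowed_likelihood_vector <- function(streams, condition, columns,
                                       window_onset_ms, window_ms = 60) {
  m <- streams$streams[[condition]]
  if (is.null(m))
    ssrsa_error(sprintf("no stream for condition '%s'", condition),
                "ssrsa_invalid_input")
  nf <- frames_per_window(window_ms, streams$frame_ms)
  if (window_onset_ms %% streams$frame_ms != 0)
    ssrsa_error("window onset must align to the frame grid", "ssrsa_invalid_input")
  first <- window_onset_ms / streams$frame_ms + 1
  last <- first + nf - 1
  if (first < 1 || last > streams$n_frames)
    ssrsa_error(sprintf("window [%d, %d) ms extends outside the %d-frame epoch",
                        window_onset_ms, window_onset_ms + window_ms,
                        streams$n_frames), "ssrsa_window_bounds")
  as.vector(t(m[first:last, columns, drop = FALSE]))
}

#' Build one phone's dynamic model RDM
#'
#' At each window onset, every condition is represented by its windowed
#' likelihood vector over the phone's centre-matched triphone columns; the
#' RDM entry for a condition pair is the correlation distance between the
#' two vectors.
#'
#' @param streams a `likelihood_streams` object.
#' @param phone phone symbol.
#' @param window_onsets_ms numeric vector of window onsets in ms.
#' @param window_ms window width in ms.
#' @return a `dynamic_rdm` with one frame per onset.
#' @export
build_phone_drdm <- function(streams, phone, window_onsets_ms, window_ms = 60) {
  cols <- central_phone_columns(streams, phone)
  conds <- names(streams$streams)
  frames <- lapply(window_onsets_ms, function(onset) {
    vecs <- t(vapply(conds, function(cond)
      windowed_likelihood_vector(streams, cond, cols, onset, window_ms),
      numeric(frames_per_window(window_ms, streams$frame_ms) * length(cols))))
    sds <- apply(vecs, 1, stats::sd)
    if (any(sds == 0))
      ssrsa_error(sprintf(
        "constant likelihood vector for phone '%s', window %d ms, condition(s): %s",
        phone, onset, paste(conds[sds == 0], collapse = ", ")),
        "ssrsa_degenerate_input")
    rdm_from_response_matrix(vecs, conds)
  })
  step <- if (length(window_onsets_ms) > 1) diff(window_onsets_ms)[1] else window_ms
  dynamic_rdm(frames, window_ms, step, window_onsets_ms)
}

#' Build the full phone model set
#'
#' One dynamic model RDM per phone in the inventory that has at least one
#' centre-matched triphone column; phones with none are dropped with a
#' warning (an analysis typically retains only the phones common enough in
#' the stimulus set to be modelled).
#'
#' @param streams a `likelihood_streams` object.
#' @param inventory phone symbols to attempt models for (default: all centre
#'   phones present in the triphone table).
#' @param window_onsets_ms window onsets in ms.
#' @param window_ms window width in ms.
#' @return object of class `phone_model_set`: list with `phones` (modelled
#'   symbols), `drdms` (named list of `dynamic_rdm`), `dropped` (symbols
#'   without any triphone).
#' @export
build_model_set <- function(streams, inventory = NULL, window_onsets_ms,
                            window_ms = 60) {
  if (is.null(inventory)) inventory <- sort(unique(streams$triphones$centre))
  present <- inventory[inventory %in% streams$triphones$centre]
  dropped <- setdiff(inventory, present)
  if (length(dropped) > 0)
    warning(sprintf("no triphones for phone(s) %s: dropped from the model set",
                    paste(dropped, collapse = ", ")))
  if (length(present) == 0)
    ssrsa_error("no phone in the inventory has any triphone column",
                "ssrsa_empty_model")
  drdms <- lapply(present, function(ph)
    build_phone_drdm(streams, ph, window_onsets_ms, window_ms))
  names(drdms) <- present
  structure(list(phones = present, drdms = drdms, dropped = dropped,
                 window_ms = window_ms, onsets_ms = window_onsets_ms),
            class = "phone_model_set")
}

#' @export
print.phone_model_set <- function(x, ...) {
  cat(sprintf("phone model set: %d phones x %d windows = %d model RDM frames (%d conditions)\n",
              length(x$phones), length(x$onsets_ms), n_model_frames(x),
              length(rdm_conditions(x$drdms[[1]]))))
  if (length(x$dropped) > 0)
    cat(sprintf("  dropped (no triphones): %s\n", paste(x$dropped, collapse = ", ")))
  invisible(x)
}

#' Total number of model RDM frames in a model set
#'
#' |modelled phones| x |window positions|; the standard full-scale
#' configuration (40 phones, 21 windows) has 840 frames.
#'
#' @param model_set a `phone_model_set`.
#' @return integer count.
#' @export
n_model_frames <- function(model_set) {
  sum(vapply(model_set$drdms, function(d) length(d$frames), integer(1)))
}
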