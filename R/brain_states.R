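# Data dRDMs from source-space epochs via the spatiotemporal searchlight.
#
# Source reconstruction yields, per subject and per condition (word), a
# vertex x time matrix of cortical current estimates at 1 ms sampling. A
# searchlight patch of fixed radius is centred on each vertex of the masked
# mesh; within each sliding temporal window the patch's samples form one
# response vector per condition, giving a per-subject RDM which is averaged
# across subjects into the data RDM for that (vertex, window). A fixed
# processing lag offsets the neural window relative to the speech-input
# window it is compared with: with the standard 100 ms lag and a 0-270 ms
# model epoch, the neural analysis epoch runs 100-370 ms from acoustic
# onset.

#' Source mesh constructor
#'
#' @param vertex_id character or integer vertex identifiers.
#' @param x_mm,y_mm,z_mm vertex coordinates in mm.
#' @param hemisphere hemisphere labels (e.g. "lh"/"rh").
#' @param in_mask logical: vertex inside the analysis mask.
#' @return object of class `source_mesh` (a data.frame).
#' @export
source_mesh <- function(vertex_id, x_mm, y_mm, z_mm,
                        hemisphere = "lh", in_mask = TRUE) {
  d <- data.frame(vertex_id = as.character(vertex_id),
                  hemisphere = hemisphere,
                  x_mm = x_mm, y_mm = y_mm, z_mm = z_mm,
                  in_mask = in_mask, stringsAsFactors = FALSE)
  if (anyDuplicated(d$vertex_id))
    ssrsa_error("vertex ids must be unique", "ssrsa_invalid_input")
  if (!all(is.finite(c(d$x_mm, d$y_mm, d$z_mm))))
    ssrsa_error("vertex coordinates must be finite", "ssrsa_invalid_input")
  if (!any(d$in_mask))
    ssrsa_error("mask is empty", "ssrsa_invalid_input")
  class(d) <- c("source_mesh", "data.frame")
  d
}

#' Read a source mesh from TSV
#'
#' Columns: vertex_id, hemisphere, x_mm, y_mm, z_mm, in_mask (0/1 or
#' TRUE/FALSE).
#'
#' @param path TSV file path.
#' @return a `source_mesh`.
#' @export
read_mesh_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("vertex_id", "hemisphere", "x_mm", "y_mm", "z_mm", "in_mask")
  if (!all(need %in% names(d)))
    ssrsa_error(sprintf("mesh TSV needs columns: %s", paste(need, collapse = ", ")),
                "ssrsa_invalid_input")
  source_mesh(d$vertex_id, d$x_mm, d$y_mm, d$z_mm, d$hemisphere,
              as.logical(d$in_mask))
}

#' Write a source mesh to TSV
#' @param mesh a `source_mesh`.
#' @param path TSV file path.
#' @return `path`, invisibly.
#' @export
write_mesh_tsv <- function(mesh, path) {
  utils::write.table(as.data.frame(mesh), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Masked vertex ids of a mesh, in file order
#' @param mesh a `source_mesh`.
#' @return character vector.
#' @export
masked_vertices <- function(mesh) mesh$vertex_id[mesh$in_mask]

#' Searchlight configuration
#'
#' The standard configuration: 20 mm patch radius, 60 ms window, 10 ms
#' step, 100 ms processing lag, 21 window positions over a 270 ms model
#' epoch.
#'
#' @param radius_mm spatial patch radius in mm.
#' @param window_ms temporal window width in ms.
#' @param step_ms window step in ms.
#' @param lag_ms fixed model-to-brain processing lag in ms.
#' @param epoch_ms model epoch length in ms.
#' @param window_mode "standard" (drop the final fitting onset; 270/60/10
#'   gives 21 positions) or "all" (every window that fits; 270/60/10 gives 22).
#' @return object of class `searchlight_config`.
#' @export
searchlight_config <- function(radius_mm = 20, window_ms = 60, step_ms = 10,
                               lag_ms = 100, epoch_ms = 270,
                               window_mode = c("standard", "all")) {
  window_mode <- match.arg(window_mode)
  if (radius_mm < 0 || window_ms <= 0 || step_ms <= 0 || epoch_ms <= 0 || lag_ms < 0)
    ssrsa_error("searchlight geometry must be positive (lag >= 0)",
                "ssrsa_invalid_input")
  structure(list(radius_mm = radius_mm, window_ms = window_ms,
                 step_ms = step_ms, lag_ms = lag_ms, epoch_ms = epoch_ms,
                 window_mode = window_mode),
            class = "searchlight_config")
}

#' Sliding-window onset times
#'
#' Mode "all" returns every onset at which a full window fits the epoch:
#' 0, step, ..., floor((T - w)/s) * s. Mode "standard" additionally drops the
#' final onset when more than one position exists, matching the convention
#' of 21 positions for a 270 ms epoch with 60 ms windows at 10 ms steps.
#'
#' @param epoch_len_ms epoch length in ms.
#' @param window_ms window width in ms.
#' @param step_ms step in ms.
#' @param mode "standard" or "all".
#' @return numeric vector of onset times in ms.
#' @export
window_positions <- function(epoch_len_ms, window_ms = 60, step_ms = 10,
                             mode = c("standard", "all")) {
  mode <- match.arg(mode)
  if (window_ms > epoch_len_ms)
    ssrsa_error("window longer than epoch", "ssrsa_invalid_input")
  if (window_ms <= 0 || step_ms <= 0)
    ssrsa_error("window and step must be positive", "ssrsa_invalid_input")
  onsets <- seq(0, floor((epoch_len_ms - window_ms) / step_ms) * step_ms,
                by = step_ms)
  if (mode == "standard" && length(onsets) > 1)
    onsets <- onsets[-length(onsets)]
  onsets
}

#' @rdname window_positions
#' @param cfg a `searchlight_config`.
#' @export
config_window_onsets <- function(cfg) {
  window_positions(cfg$epoch_ms, cfg$window_ms, cfg$step_ms, cfg$window_mode)
}

#' Source epoch set constructor
#'
#' @param epochs nested named list: `epochs[[subject]][[condition]]` is a
#'   vertex x time numeric matrix (1 ms sampling), identical shape for every
#'   subject/condition pair, rows ordered as the mesh's vertices.
#' @param vertex_id vertex identifiers matching the matrix rows.
#' @param sample_ms sampling step in ms (1 in the standard configuration).
#' @param t0_ms time of the first sample, relative to stimulus onset.
#' @return object of class `source_epochs`.
#' @export
source_epochs <- function(epochs, vertex_id, sample_ms = 1, t0_ms = 0) {
  if (length(epochs) == 0)
    ssrsa_error("no subjects supplied", "ssrsa_invalid_input")
  conds <- names(epochs[[1]])
  shape <- dim(epochs[[1]][[1]])
  for (subj in names(epochs)) {
    if (!identical(names(epochs[[subj]]), conds))
      ssrsa_error("all subjects must hold the same conditions in the same order",
                  "ssrsa_invalid_input")
    for (m in epochs[[subj]])
      if (!identical(dim(m), shape))
        ssrsa_error("all epoch matrices must share one shape", "ssrsa_invalid_input")
  }
  if (shape[1] != length(vertex_id))
    ssrsa_error("epoch rows must match the vertex ids", "ssrsa_invalid_input")
  structure(list(epochs = epochs, subjects = names(epochs),
                 conditions = conds, vertex_id = as.character(vertex_id),
                 sample_ms = sample_ms, t0_ms = t0_ms,
                 n_samples = shape[2]),
            class = "source_epochs")
}

#' @export
print.source_epochs <- function(x, ...) {
  cat(sprintf("source epochs: %d subjects x %d conditions, %d vertices x %d samples (%g ms), t0 = %g ms\n",
              length(x$subjects), length(x$conditions), length(x$vertex_id),
              x$n_samples, x$sample_ms, x$t0_ms))
  invisible(x)
}

#' Vertices within a searchlight patch
#'
#' All masked vertices within `radius_mm` (3D Euclidean distance) of the
#' centre vertex; the centre is always a member. Distance is straight-line
#' between coordinates, not geodesic along the cortical surface.
#'
#' @param mesh a `source_mesh`.
#' @param centre centre vertex id (must be inside the mask).
#' @param radius_mm patch radius in mm.
#' @return character vector of member vertex ids, in mesh order.
#' @export
patch_members <- function(mesh, centre, radius_mm) {
  i <- match(as.character(centre), mesh$vertex_id)
  if (is.na(i) || !mesh$in_mask[i])
    ssrsa_error(sprintf("centre vertex '%s' is not a masked mesh vertex", centre),
                "ssrsa_invalid_input")
  d2 <- (mesh$x_mm - mesh$x_mm[i])^2 + (mesh$y_mm - mesh$y_mm[i])^2 +
    (mesh$z_mm - mesh$z_mm[i])^2
  mesh$vertex_id[mesh$in_mask & d2 <= radius_mm^2 + 1e-9]
}

#' Data RDM for one patch and window
#'
#' Per subject, each condition's response vector is the patch-by-window
#' block of its epoch, flattened vertex-major (all window samples of vertex
#' 1, then vertex 2, ...); the per-subject RDMs are then averaged. The
#' window is taken at `window_onset_ms + lag_ms` on the epoch's own time
#' axis.
#'
#' @param epochs a `source_epochs`.
#' @param patch vertex ids forming the patch.
#' @param window_onset_ms model-epoch window onset in ms.
#' @param cfg a `searchlight_config`.
#' @return an `rdm` (averaged over subjects).
#' @export
searchlight_data_rdm <- function(epochs, patch, window_onset_ms, cfg) {
  rows <- match(as.character(patch), epochs$vertex_id)
  if (anyNA(rows))
    ssrsa_error("patch contains vertices absent from the epochs",
                "ssrsa_invalid_input")
  t_start_ms <- window_onset_ms + cfg$lag_ms
  first <- round((t_start_ms - epochs$t0_ms) / epochs$sample_ms) + 1
  nsamp <- round(cfg$window_ms / epochs$sample_ms)
  last <- first + nsamp - 1
  if (first < 1 || last > epochs$n_samples)
    ssrsa_error(sprintf(
      "lagged window [%g, %g) ms is outside the epoch time axis [%g, %g) ms",
      t_start_ms, t_start_ms + cfg$window_ms, epochs$t0_ms,
      epochs$t0_ms + epochs$n_samples * epochs$sample_ms),
      "ssrsa_window_bounds")
  per_subject <- lapply(epochs$subjects, function(subj) {
    resp <- t(vapply(epochs$conditions, function(cond) {
      block <- epochs$epochs[[subj]][[cond]][rows, first:last, drop = FALSE]
      as.vector(t(block))  # vertex-major: vertex 1's samples, then vertex 2's
    }, numeric(length(rows) * nsamp)))
    sds <- apply(resp, 1, stats::sd)
    if (any(sds == 0))
      ssrsa_error(sprintf(
        "constant searchlight response: subject %s, condition(s) %s, window %g ms",
        subj, paste(epochs$conditions[sds == 0], collapse = ", "), window_onset_ms),
        "ssrsa_degenerate_input")
    rdm_from_response_matrix(resp, epochs$conditions)
  })
  average_rdms(per_subject)
}

#' Build the per-vertex data dRDM map
#'
#' Moves the searchlight patch to every masked vertex and the temporal
#' window through every onset, producing one subject-averaged RDM per
#' (vertex, window). Output vertices follow the mesh's masked-vertex order.
#'
#' @param epochs a `source_epochs`.
#' @param mesh a `source_mesh`.
#' @param cfg a `searchlight_config`.
#' @param verbose print progress.
#' @return named list (by vertex id) of `dynamic_rdm`.
#' @export
build_data_drdms <- function(epochs, mesh, cfg, verbose = FALSE) {
  onsets <- config_window_onsets(cfg)
  vids <- masked_vertices(mesh)
  out <- lapply(vids, function(v) {
    patch <- patch_members(mesh, v, cfg$radius_mm)
    frames <- lapply(onsets, function(on)
      searchlight_data_rdm(epochs, patch, on, cfg))
    if (verbose) message(sprintf("vertex %s: %d frames (patch size %d)",
                                 v, length(frames), length(patch)))
    dynamic_rdm(frames, cfg$window_ms, cfg$step_ms, onsets)
  })
  names(out) <- vids
  out
}
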