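#' Run the DPD integrator
#'
#' Advances a frame by `n_steps` of the modified velocity-Verlet scheme
#' (lambda = 0.5 velocity prediction, dissipative-force re-evaluation after
#' the velocity correction).  The pairwise random stream is keyed on
#' `(seed, absolute step, pair)`, so runs are bit-reproducible for a fixed
#' seed and a checkpointed run continues exactly as the uninterrupted one.
#'
#' With `shear_rate != 0` the box is deformed continuously: the Lees-Edwards
#' tilt grows by `rate * Lz * dt` per step (re-wrapped into `(-Lx/2, Lx/2]`),
#' strain accumulates as `rate * dt` per step, and pair interactions across
#' the z boundary see the moving-image velocity offset, which drives the
#' fluid toward a linear shear flow.
#'
#' @param frame Starting `dpd_frame`.
#' @param interactions Matrix from [interaction_matrix()].
#' @param params A [dpd_params()].
#' @param n_steps Number of steps (>= 0).
#' @param seed Integer seed for the thermostat's random stream.
#' @param report_every Snapshot interval in steps (0 = final frame only).
#' @param shear_rate Constant strain rate (default 0, no shear).
#' @param gaussian Use Gaussian rather than uniform random draws.
#' @param use_cells Use the cell-list neighbour search (default TRUE).
#' @return A `dpd_traj` object: list with `frames` (snapshots including the
#'   final state), `temperature` (per-step kinetic temperature), `final`
#'   (the final `dpd_frame`), and the run settings.
#' @examples
#' fr <- init_velocities(solvent_system(4, seed = 1), 1, seed = 2)
#' tr <- dpd_run(fr, interaction_matrix(26, 26), dpd_params(), 10, seed = 3)
#' mean(tr$temperature)
#' @export
dpd_run <- function(frame, interactions, params, n_steps, seed,
                    report_every = 0, shear_rate = 0, gaussian = FALSE,
                    use_cells = TRUE) {
  if (n_steps < 0) stop("'n_steps' must be non-negative")
  if (n_steps == 0) {
    return(structure(list(frames = list(frame), temperature = numeric(0),
                          final = frame, seed = seed, params = params,
                          shear_rate = shear_rate),
                     class = "dpd_traj"))
  }
  a <- interactions[DPD_SPECIES, DPD_SPECIES]
  res <- cpp_run(frame$positions, frame$velocities,
                 species_index(frame$species), a, frame$bonds - 1L,
                 frame$box, frame$tilt, frame$strain, 0L, 2L,
                 params$rc, params$gamma, params$sigma, params$dt,
                 params$spring_C, params$r_eq, as.integer(n_steps),
                 frame$step, seed, shear_rate, as.integer(report_every),
                 gaussian, 0.5, use_cells)
  if (res$n_zero_dist > 0)
    warning(sprintf("%d coincident pair(s) encountered: zero force applied",
                    res$n_zero_dist))
  mk <- function(p, v, tilt, step, strain) {
    f <- frame
    f$positions <- p; f$velocities <- v
    f$tilt <- tilt; f$step <- step; f$strain <- strain
    f
  }
  frames <- lapply(res$snapshots, function(s)
    mk(s$positions, s$velocities, s$tilt, s$step, s$strain))
  final <- mk(res$positions, res$velocities, res$tilt, res$step, res$strain)
  if (length(frames) == 0 || frames[[length(frames)]]$step != final$step)
    frames <- c(frames, list(final))
  structure(list(frames = frames, temperature = as.numeric(res$temperature),
                 final = final, seed = seed, params = params,
                 shear_rate = shear_rate),
            class = "dpd_traj")
}

#' Advance a frame by a single integration step
#'
#' Convenience wrapper around [dpd_run()] with `n_steps = 1`, returning the
#' frame rather than a trajectory.
#'
#' @inheritParams dpd_run
#' @return The advanced `dpd_frame`.
#' @export
integrate_step <- function(frame, interactions, params, seed,
                           shear_rate = 0, gaussian = FALSE) {
  dpd_run(frame, interactions, params, 1, seed = seed,
          shear_rate = shear_rate, gaussian = gaussian)$final
}

#' @export
print.dpd_traj <- function(x, ...) {
  cat(sprintf("DPD trajectory: %d snapshot(s), %d step(s) integrated\n",
              length(x$frames), length(x$temperature)))
  if (length(x$temperature))
    cat(sprintf("  final step %g, mean kinetic temperature %.4f\n",
                x$final$step, mean(x$temperature)))
  if (x$shear_rate != 0)
    cat(sprintf("  shear rate %g, accumulated strain %.4g\n",
                x$shear_rate, x$final$strain))
  invisible(x)
}
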