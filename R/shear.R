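#' Bulk shear state
#'
#' Book-keeping for constant-rate box deformation in the xz plane: the offset
#' (Lees-Edwards tilt) is the x displacement of the +z image row, the strain
#' is the cumulative offset divided by the reference (z) box length, and the
#' tilt itself is re-wrapped into `(-Lx/2, Lx/2]` without affecting the
#' strain account.
#'
#' @param rate Strain rate (1/time; the production value is 0.001).
#' @param plane Ordered axis pair: offset axis then gradient axis.  Only
#'   `"xz"` is supported (offset in x, gradient in z); rotate the system for
#'   other planes.
#' @return An object of class `shear_state`.
#' @export
shear_state <- function(rate = 0.001, plane = "xz") {
  if (!identical(plane, "xz"))
    stop("only the xz shear plane is supported; rotate the frame instead")
  structure(list(rate = rate, plane = plane, offset = 0, strain = 0),
            class = "shear_state")
}

#' Apply one shear increment to a frame
#'
#' Advances the moving boundary by one timestep: the tilt offset grows by
#' `rate * Lz * dt`, the cumulative strain by `rate * dt`, and positions are
#' re-wrapped under the new boundary.  (During dynamics the engine performs
#' this internally each step; this operation exposes the same update for
#' stand-alone use.)
#'
#' @param frame A `dpd_frame`.
#' @param state A [shear_state()].
#' @param dt Timestep.
#' @return List with the updated `frame` and `state`.
#' @export
apply_shear_step <- function(frame, state, dt) {
  if (!inherits(state, "shear_state")) stop("'state' must be a shear_state")
  if (any(frame$box <= 0)) stop("cannot shear a degenerate box")
  L_ref <- frame$box[3]
  state$offset <- state$offset + state$rate * L_ref * dt
  state$strain <- state$strain + state$rate * dt
  tilt <- state$offset
  half <- frame$box[1] / 2
  tilt <- tilt - frame$box[1] * round(tilt / frame$box[1])
  if (tilt > half) tilt <- tilt - frame$box[1]
  frame$tilt <- tilt
  frame$strain <- state$strain
  frame <- wrap_frame(frame)
  list(frame = frame, state = state)
}

#' Time-averaged shear velocity profile
#'
#' Bins the x velocity of every bead by its z coordinate across the frames of
#' a trajectory and fits a straight line; under steady Lees-Edwards shear the
#' slope approaches the applied strain rate.
#'
#' @param traj A `dpd_traj` from [dpd_run()] (snapshots are the samples).
#' @param n_bins Number of z bins (default 10).
#' @param discard_frames Number of leading snapshots to drop as transient.
#' @return List with `z` (bin centres), `vx` (mean x velocity per bin), and
#'   `slope` (fitted d<vx>/dz).
#' @export
velocity_profile <- function(traj, n_bins = 10, discard_frames = 0) {
  frames <- traj$frames
  if (discard_frames > 0 && discard_frames < length(frames))
    frames <- frames[-seq_len(discard_frames)]
  Lz <- frames[[1]]$box[3]
  edges <- seq(0, Lz, length.out = n_bins + 1)
  sums <- numeric(n_bins)
  cnts <- numeric(n_bins)
  for (f in frames) {
    b <- findInterval(f$positions[, 3], edges, rightmost.closed = TRUE)
    b[b < 1] <- 1; b[b > n_bins] <- n_bins
    sums <- sums + tapply(f$velocities[, 1], factor(b, levels = seq_len(n_bins)),
                          sum, default = 0)
    cnts <- cnts + tabulate(b, n_bins)
  }
  vx <- sums / pmax(cnts, 1)
  z <- (edges[-1] + edges[-length(edges)]) / 2
  fit <- lm(vx ~ z, weights = cnts)
  list(z = z, vx = as.numeric(vx), slope = unname(coef(fit)[2]))
}
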