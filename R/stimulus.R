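#' Generate a binary moving-bar frame
#'
#' Emulates one camera snapshot after binarization and downsampling: a 6 x
#' 1000 matrix of 0/1 pixels in which row `i` is the input to unit `i` and
#' column `t` is millisecond `t - 1` of the direction step. A vertical bar of
#' `bar_width` columns, starting at the 0-based column offset `bar_position`,
#' is set to 1 in every row (wrapping around the right edge); every remaining
#' pixel is independently flipped to 1 with probability `noise_prob`,
#' emulating the luminance noise of real camera images.
#'
#' @param bar_position 0-based column offset of the left edge of the bar
#'   (must be `< n_cols`).
#' @param bar_width Bar width in columns (>= 1).
#' @param noise_prob Probability that an off-bar pixel is flipped to 1, in
#'   \[0, 1).
#' @param rng_seed Integer seed making the noise reproducible; ignored when
#'   `noise_prob = 0`. The caller's RNG state is left untouched.
#' @param n_rows,n_cols Frame dimensions (defaults 6 x 1000).
#' @return A `binary_frame`: an integer matrix of 0/1 with `n_rows` rows and
#'   `n_cols` columns.
#' @examples
#' f <- make_bar_frame(bar_position = 100, bar_width = 10)
#' rowSums(f)  # 10 ones per row
#' @export
make_bar_frame <- function(bar_position, bar_width, noise_prob = 0,
                           rng_seed = NULL, n_rows = 6, n_cols = 1000) {
  check_number(bar_position, "bar_position", lower = 0)
  check_number(bar_width, "bar_width", lower = 1)
  check_number(noise_prob, "noise_prob", lower = 0, upper = 1,
               strict_upper = TRUE)
  if (bar_position >= n_cols) {
    stopf("`bar_position` must be < %d (got %g)", n_cols, bar_position)
  }
  frame <- matrix(0L, n_rows, n_cols)
  cols <- (bar_position + seq_len(bar_width) - 1L) %% n_cols + 1L
  frame[, unique(cols)] <- 1L
  if (noise_prob > 0) {
    off <- frame == 0L
    flips <- with_seed(rng_seed, {
      stats::runif(sum(off)) < noise_prob
    })
    frame[off][flips] <- 1L
  }
  class(frame) <- c("binary_frame", class(frame))
  frame
}

validate_frame <- function(frame, n_rows = NULL, n_cols = NULL) {
  if (!is.matrix(frame)) stopf("a frame must be a matrix of 0/1")
  if (!all(frame %in% c(0L, 1L))) stopf("frame entries must be 0 or 1")
  if (!is.null(n_rows) && nrow(frame) != n_rows) {
    stopf("frame must have exactly %d rows (got %d)", n_rows, nrow(frame))
  }
  if (!is.null(n_cols) && ncol(frame) != n_cols) {
    stopf("frame must have exactly %d columns (got %d)", n_cols, ncol(frame))
  }
  invisible(frame)
}

#' Release-probability schedule for a bidirectional sweep
#'
#' Builds the per-step pairs of initial release probabilities `(U1, U2)`
#' recruited by the two subpopulations. On right-motion steps subpopulation 1
#' is assigned values from the preferred (upper) band and subpopulation 2 from
#' the null (lower) band; on left-motion steps the pair is swapped. The bands
#' are linear ramps:
#' preferred from `U_max` down to `c + w/4` and null from `U_min` up to
#' `c - w/4`, where `c = (U_min + U_max)/2` and `w = U_max - U_min`. This
#' construction guarantees, exactly:
#'
#' * mean `U1` over right steps > mean `U1` over left steps (and vice versa
#'   for `U2`);
#' * an elementwise gap of at least `w/4` between the preferred and the null
#'   value of every step, so each step remains individually discriminable;
#' * the mirror property: the multiset of `U1` values over right steps equals
#'   the multiset of `U2` values over left steps (and vice versa), so the
#'   subpopulation-1/right and subpopulation-2/left release-probability
#'   trajectories are identical.
#'
#' @param n_steps Even number of direction steps (first half right, second
#'   half left).
#' @param U_min,U_max Bounds of the schedule, `0 < U_min < U_max <= 1`.
#' @return A data frame with columns `step`, `direction` (`"right"` /
#'   `"left"`), `U1` and `U2`.
#' @examples
#' u_schedule(4)
#' u_schedule(2)  # the minimal mirrored schedule
#' @export
u_schedule <- function(n_steps = 200, U_min = 0.05, U_max = 0.6) {
  check_number(n_steps, "n_steps", lower = 2)
  if (n_steps %% 2 != 0) stopf("`n_steps` must be even (got %d)", n_steps)
  check_number(U_min, "U_min", lower = 0, strict_lower = TRUE)
  check_number(U_max, "U_max", upper = 1)
  if (U_min >= U_max) stopf("`U_min` must be < `U_max`")
  m <- n_steps %/% 2
  centre <- (U_min + U_max) / 2
  quarter <- (U_max - U_min) / 4
  pref <- seq(U_max, centre + quarter, length.out = m)
  null <- seq(U_min, centre - quarter, length.out = m)
  data.frame(
    step = seq_len(n_steps),
    direction = rep(c("right", "left"), each = m),
    U1 = c(pref, null),
    U2 = c(null, pref)
  )
}

#' Generate a full bidirectional stimulus sweep
#'
#' Produces the default experiment input: `n_steps` binary frames in which the
#' bar shifts rightward by `shift_per_step` columns per step for the first
#' half of the sweep and then retraces leftward for the second half (positions
#' wrap around the 1000-column axis so the spike count per step is constant),
#' together with per-step direction labels and the release-probability pairs
#' from [u_schedule()].
#'
#' @param n_steps Even number of direction steps (default 200: 100 right then
#'   100 left).
#' @param bar_width Bar width in columns (default 10; the bar is a thin
#'   vertical line, ~1\% of the field width, and its width equals the number
#'   of presynaptic spikes each unit receives per step).
#' @param shift_per_step Columns the bar moves per direction step (>= 1).
#' @param noise_prob Off-bar pixel flip probability (default 0: noise-free
#'   "hypothetical" stimuli; use > 0 to emulate the noisy real-world camera
#'   condition).
#' @param rng_seed Integer seed for the frame noise.
#' @param U_min,U_max Release-probability schedule bounds.
#' @param start_position 0-based column of the bar on the first step.
#' @param step_duration Step duration in ms; equals the number of frame
#'   columns.
#' @param n_rows Number of frame rows / network units (default 6).
#' @return A `direction_sequence`: a list with elements `frames` (list of
#'   `binary_frame`), `directions` (character), `u_pairs` (n_steps x 2
#'   matrix), `positions`, and `step_duration`.
#' @examples
#' seq2 <- make_direction_sequence(n_steps = 2)
#' seq2$directions
#' @export
make_direction_sequence <- function(n_steps = 200, bar_width = 10,
                                    shift_per_step = 5, noise_prob = 0,
                                    rng_seed = NULL, U_min = 0.05,
                                    U_max = 0.6, start_position = 0,
                                    step_duration = 1000, n_rows = 6) {
  if (n_steps %% 2 != 0) stopf("`n_steps` must be even (got %d)", n_steps)
  check_number(shift_per_step, "shift_per_step", lower = 1)
  m <- n_steps %/% 2
  positions <- numeric(n_steps)
  p <- start_position
  for (i in seq_len(m)) {                      # rightward sweep
    positions[i] <- p %% step_duration
    p <- p + shift_per_step
  }
  p <- positions[m]
  for (i in seq_len(m)) {                      # leftward retrace
    p <- p - shift_per_step
    positions[m + i] <- p %% step_duration
  }
  sched <- u_schedule(n_steps, U_min, U_max)
  frames <- lapply(seq_len(n_steps), function(i) {
    seed_i <- if (is.null(rng_seed)) NULL else {
      (rng_seed + 7919L * i) %% .Machine$integer.max
    }
    make_bar_frame(positions[i], bar_width, noise_prob, seed_i,
                   n_rows = n_rows, n_cols = step_duration)
  })
  structure(
    list(frames = frames, directions = sched$direction,
         u_pairs = as.matrix(sched[, c("U1", "U2")]),
         positions = positions, step_duration = step_duration),
    class = "direction_sequence")
}

#' @export
print.direction_sequence <- function(x, ...) {
  n <- length(x$frames)
  cat(sprintf(
    "Direction sequence: %d steps (%d right, %d left), %d x %d frames, %g ms/step\n",
    n, sum(x$directions == "right"), sum(x$directions == "left"),
    nrow(x$frames[[1]]), ncol(x$frames[[1]]), x$step_duration))
  invisible(x)
}

#' Reduce a 100 x 1000 camera image to a 6 x 1000 frame
#'
#' Emulates the second downsampling stage of the camera pipeline: the 100
#' camera rows are partitioned into 6 nearly equal contiguous blocks
#' (17/17/17/17/16/16 rows) and each block is collapsed by a logical OR, so a
#' black pixel anywhere in a unit's receptive strip activates that unit. A
#' vertical bar spanning all camera rows therefore activates all 6 units.
#'
#' @param raw A 100 x 1000 matrix of 0/1.
#' @return A 6 x 1000 `binary_frame`.
#' @export
downsample_camera <- function(raw) {
  validate_frame(raw, n_rows = 100, n_cols = 1000)
  sizes <- c(17L, 17L, 17L, 17L, 16L, 16L)
  block <- rep(seq_len(6), times = sizes)
  out <- matrix(0L, 6L, 1000L)
  for (b in seq_len(6)) {
    out[b, ] <- as.integer(colSums(raw[block == b, , drop = FALSE]) > 0)
  }
  class(out) <- c("binary_frame", class(out))
  out
}

#' Convert a binary frame to presynaptic spike trains
#'
#' Unit `j` receives a spike at time `t` ms (0-based, within `[0, T)`) if and
#' only if pixel `[j, t + 1]` is 1, so the spike count per unit equals the row
#' sum of the frame ("all-or-none" encoding: the number of presynaptic spikes
#' equals the number of 1s in the image).
#'
#' @param frame A `binary_frame` (any number of rows).
#' @return A list with one sorted numeric vector of spike times (ms) per row.
#' @examples
#' f <- make_bar_frame(0, 3)
#' frame_to_spikes(f)[[1]]  # spikes at 0, 1, 2 ms
#' @export
frame_to_spikes <- function(frame) {
  validate_frame(frame)
  lapply(seq_len(nrow(frame)), function(j) as.numeric(which(frame[j, ] == 1L) - 1L))
}
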