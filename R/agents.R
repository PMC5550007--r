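#' Reference agents for the cognitive protocols
#'
#' Scriptable stand-ins for the human participant, used as test instruments
#' (they make no claim about human strategy). Continuous agents are called at
#' every control tick with `(feedback_history, orientation, elapsed_tr)` and
#' return a rotation command in \{-1, 0, +1\}; intermittent agents are called
#' once per trial with the data frame of previous trials and return the next
#' orientation to select.
#'
#' * `agent_jump_to_target(target)`: omniscient oracle -- rotates straight to
#'   the target and holds (continuous).
#' * `agent_hold_still()`: never presses a key (continuous).
#' * `agent_greedy()`: hill-climber -- keeps rotating in one direction while
#'   the per-TR feedback increases and reverses when it decreases
#'   (continuous; carries its own state, so build a fresh one per search).
#' * `agent_fixed_orientation(orientation)`: always selects the same
#'   orientation (intermittent).
#' * `agent_binary_search(step)`: distance-bisection search over the class
#'   orientations -- each trial it selects the midpoint candidate, converts
#'   the observed score back to an orientation distance through the feedback
#'   tuning curve, and discards candidates inconsistent with that distance
#'   (intermittent; fresh instance per search).
#'
#' @param target,orientation Orientation in degrees.
#' @param step Orientation grid step of the candidate set (degrees).
#' @return A function usable as the `agent` argument of
#'   [run_continuous_search()] or [run_intermittent_search()].
#' @name agents
NULL

#' @rdname agents
#' @export
agent_jump_to_target <- function(target) {
  function(feedback_history, orientation, elapsed_tr) {
    d <- signed_orientation_step(orientation, target)
    if (abs(d) < 0.5) 0 else sign(d)
  }
}

#' @rdname agents
#' @export
agent_hold_still <- function() {
  function(feedback_history, orientation, elapsed_tr) 0
}

#' @rdname agents
#' @export
agent_greedy <- function() {
  direction <- 1
  last_fb <- -Inf
  last_len <- 0
  function(feedback_history, orientation, elapsed_tr) {
    n <- length(feedback_history)
    if (n > last_len) {            # a new TR of feedback arrived
      if (feedback_history[n] < last_fb) direction <<- -direction
      last_fb <<- feedback_history[n]
      last_len <<- n
    }
    direction
  }
}

#' @rdname agents
#' @export
agent_fixed_orientation <- function(orientation) {
  function(history) orientation
}

#' @rdname agents
#' @export
agent_binary_search <- function(step = 22.5) {
  candidates <- seq(0, 180 - step, by = step)
  function(history) {
    if (nrow(history) > 0) {
      last <- history[nrow(history), ]
      # invert the tuning curve: score (1/16)^(d/90) -> distance d
      d_hat <- 90 * log(1 / max(last$score, 1e-12)) / log(16)
      d_hat <- round(d_hat / step) * step
      keep <- abs(circular_orientation_distance(candidates, last$orientation) -
                    d_hat) < step / 2
      if (any(keep)) candidates <<- candidates[keep]
    }
    candidates[ceiling(length(candidates) / 2)]
  }
}
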