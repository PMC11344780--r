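#' Gaming-behaviour measures of one trial
#'
#' Per trial third (20 s = 1200 frames): number of targets collected, the
#' fraction of frames the ball spent on any active obstacle, and the total
#' distance covered by the ball. Thirds cover frames [0, 1200), [1200, 2400)
#' and [2400, 3600); path length is the sum of frame-to-frame displacements
#' within the third.
#'
#' @param trial_log a complete \code{dg_trial_log}.
#' @return Data frame with columns \code{segment} (1:3), \code{targets},
#'   \code{obstacle_time}, \code{path_length}.
#' @export
trial_behaviour <- function(trial_log) {
  f <- trial_log$frames
  n <- nrow(f)
  if (n %% 3 != 0)
    stop("truncated trial log: ", n, " frames (need a multiple of 3)")
  third <- n / 3
  seg_of <- function(frame) pmin(3, frame %/% third + 1)
  seg <- seg_of(f$frame)
  dx <- c(diff(f$ball_x), 0)
  dy <- c(diff(f$ball_y), 0)
  step_len <- sqrt(dx^2 + dy^2)
  ## displacement from frame i to i+1 belongs to the segment of frame i
  step_len[n] <- 0
  ev_seg <- if (nrow(trial_log$events)) seg_of(trial_log$events$frame)
            else integer(0)
  data.frame(
    segment = 1:3,
    targets = vapply(1:3, function(s) sum(ev_seg == s), numeric(1)),
    obstacle_time = vapply(1:3, function(s)
      mean(f$on_obstacle[seg == s]), numeric(1)),
    path_length = vapply(1:3, function(s)
      sum(step_len[seg == s]), numeric(1)))
}

#' Target sequence complexity index
#'
#' The fraction of target-collection events that are not part of a
#' back-and-forth between the same two targets. Event i (1-based, from the
#' third event on) counts as back-and-forth when its target equals the
#' target of event i - 2. Trials with fewer than 3 collections (including
#' none) score 1.0; the \code{no_events} attribute flags empty sequences so
#' they can be excluded from aggregates.
#'
#' @param target_sequence integer/character vector of collected target ids,
#'   in collection order.
#' @return Value in [0, 1], with attribute \code{no_events}.
#' @export
complexity_index <- function(target_sequence) {
  n <- length(target_sequence)
  if (n < 3) {
    return(structure(1.0, no_events = n == 0))
  }
  bf <- c(FALSE, FALSE,
          target_sequence[3:n] == target_sequence[1:(n - 2)])
  structure(sum(!bf) / n, no_events = FALSE)
}

#' Basic finger-movement measures
#'
#' From per-frame 2-axis finger positions: \emph{movement}, the integrated
#' absolute finger velocity (sum over both axes of absolute per-frame
#' position change), and \emph{n_moves}, the number of direction changes
#' (sign changes of the per-frame position delta on either axis, with
#' zero-delta runs collapsed), both per trial third.
#'
#' @param pos_x,pos_y per-frame finger positions along the two axes.
#' @param n_segments number of equal segments to cut the trial into.
#' @return Data frame with \code{segment}, \code{movement}, \code{n_moves}.
#' @export
finger_basics <- function(pos_x, pos_y, n_segments = 3) {
  n <- length(pos_x)
  stopifnot(length(pos_y) == n, n %% n_segments == 0)
  third <- n / n_segments
  seg <- pmin(n_segments, (seq_len(n) - 1) %/% third + 1)
  count_flips <- function(d) {
    s <- sign(d)
    s <- s[s != 0]
    if (length(s) < 2) return(0)
    sum(s[-1] != s[-length(s)])
  }
  out <- lapply(seq_len(n_segments), function(k) {
    ix <- which(seg == k)
    dx <- diff(pos_x[ix]); dy <- diff(pos_y[ix])
    data.frame(segment = k,
               movement = sum(abs(dx)) + sum(abs(dy)),
               n_moves = count_flips(dx) + count_flips(dy))
  })
  do.call(rbind, out)
}
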