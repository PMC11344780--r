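#' Physics configuration
#'
#' Defaults: 60 Hz frame rate, drag 2.0 s^-1, force gain 3.0 units s^-2,
#' per-player input cap 0.5 in both modes, accumulated force cap 0.6 in joint
#' play versus 0.5 in individual play, maximal ball speed 0.6 units/s in
#' joint versus 0.55 in individual play, and a 10 percent speed factor while
#' the ball overlaps an active obstacle. The slowdown multiplies the frame
#' displacement by default, leaving stored velocity intact so the ball
#' resumes speed on exit; \code{slowdown = "velocity"} damps the velocity
#' itself instead.
#'
#' @param dt frame duration in seconds.
#' @param drag linear drag coefficient (1/s).
#' @param gain force-to-acceleration gain (units/s^2 per force unit).
#' @param cap_player per-player input magnitude cap.
#' @param cap_joint,cap_individual accumulated force caps.
#' @param vmax_joint,vmax_individual speed caps (units/s).
#' @param obstacle_factor speed factor while overlapping an obstacle.
#' @param slowdown \code{"displacement"} or \code{"velocity"}.
#' @param arena_half,ball_radius,target_radius geometry (game units).
#' @return A list of class \code{dg_physics}.
#' @export
default_physics <- function(dt = 1 / 60, drag = 2.0, gain = 3.0,
                            cap_player = 0.5, cap_joint = 0.6,
                            cap_individual = 0.5, vmax_joint = 0.6,
                            vmax_individual = 0.55, obstacle_factor = 0.1,
                            slowdown = c("displacement", "velocity"),
                            arena_half = 1, ball_radius = 0.03,
                            target_radius = 0.06) {
  out <- list(dt = dt, drag = drag, gain = gain, cap_player = cap_player,
              cap_joint = cap_joint, cap_individual = cap_individual,
              vmax_joint = vmax_joint, vmax_individual = vmax_individual,
              obstacle_factor = obstacle_factor,
              slowdown = match.arg(slowdown), arena_half = arena_half,
              ball_radius = ball_radius, target_radius = target_radius)
  class(out) <- "dg_physics"
  out
}

physics_for_mode <- function(physics, mode) {
  joint <- identical(mode, "joint")
  list(dt = physics$dt, drag = physics$drag, gain = physics$gain,
       cap_player = physics$cap_player,
       cap_force = if (joint) physics$cap_joint else physics$cap_individual,
       vmax = if (joint) physics$vmax_joint else physics$vmax_individual,
       obstacle_factor = physics$obstacle_factor,
       arena_half = physics$arena_half, ball_radius = physics$ball_radius,
       target_radius = physics$target_radius)
}

clamp_mag <- function(v, m) {
  n <- sqrt(sum(v^2))
  if (n > m && n > 0) v * (m / n) else v
}

#' Advance the ball by one 60 Hz frame
#'
#' Applies the two players' 2-D inputs (each clamped to the per-player cap),
#' accumulates and clamps the resulting force (0.6 in joint, 0.5 in
#' individual play), integrates velocity with linear drag, clamps speed to
#' the mode's maximum, and moves the ball; while the ball overlaps an active
#' obstacle the frame displacement is reduced to 10 percent. Walls clamp the
#' position and zero the offending velocity component.
#'
#' @param state list with \code{pos}, \code{vel} (numeric length-2),
#'   \code{frame} (0-based).
#' @param input_p1,input_p2 player inputs; \code{input_p2} is ignored in
#'   individual mode.
#' @param mode \code{"joint"} or \code{"individual"}.
#' @param landscape a \code{dg_landscape} (for obstacle geometry).
#' @param physics a [default_physics()] object.
#' @return Updated state, with \code{on_obstacle} (flag at frame start) and
#'   \code{force} (the applied accumulated force).
#' @export
step_physics <- function(state, input_p1, input_p2 = c(0, 0),
                         mode = c("joint", "individual"),
                         landscape, physics = default_physics()) {
  mode <- match.arg(mode)
  if (!all(is.finite(input_p1)) || !all(is.finite(input_p2)))
    stop("non-finite player input at frame ", state$frame)
  pp <- physics_for_mode(physics, mode)

  i1 <- clamp_mag(input_p1, pp$cap_player)
  force <- if (mode == "joint") {
    i2 <- clamp_mag(input_p2, pp$cap_player)
    clamp_mag(i1 + i2, pp$cap_force)
  } else {
    clamp_mag(i1, pp$cap_force)
  }

  pos <- state$pos
  vel <- state$vel
  d <- min(vapply(seq_len(nrow(landscape$obstacles)), function(k)
    rect_distance(pos[1], pos[2], landscape$obstacles[k, ]), numeric(1)))
  on_obs <- d <= pp$ball_radius

  vel <- vel + (pp$gain * force - pp$drag * vel) * pp$dt
  vel <- clamp_mag(vel, pp$vmax)
  if (on_obs && physics$slowdown == "velocity")
    vel <- vel * pp$obstacle_factor
  fac <- if (on_obs && physics$slowdown == "displacement")
    pp$obstacle_factor else 1
  pos <- pos + vel * pp$dt * fac

  lim <- pp$arena_half - pp$ball_radius
  for (i in 1:2) {
    if (pos[i] > lim) { pos[i] <- lim; vel[i] <- 0 }
    if (pos[i] < -lim) { pos[i] <- -lim; vel[i] <- 0 }
  }
  list(pos = pos, vel = vel, frame = state$frame + 1L,
       on_obstacle = on_obs, force = force)
}

#' Run one trial with arbitrary R controllers
#'
#' Pure-R reference path of the engine: controllers are functions
#' \code{function(frame, state)} returning a 2-D input (frame is 0-based;
#' state carries \code{pos}, \code{vel} and the current \code{active}
#' target ids). A target is collected when the ball-target centre distance
#' falls below \code{target_radius + ball_radius}; the collected target
#' deactivates and the previously inactive target activates.
#'
#' @param landscape a \code{dg_landscape}.
#' @param controller_p1,controller_p2 controller functions;
#'   \code{controller_p2} is ignored in individual mode.
#' @param mode \code{"joint"} or \code{"individual"}.
#' @param seed optional seed set before the loop (for stochastic
#'   controllers).
#' @param physics a [default_physics()] object.
#' @param n_frames number of frames (default 3600 = 60 s).
#' @return A \code{dg_trial_log}: list with \code{frames} (data frame with
#'   frame, t, ball/velocity/input/force columns, \code{on_obstacle},
#'   \code{nearest_slot}, \code{nearest_dist}, \code{nearest_vis}),
#'   \code{events} (data frame frame, target), \code{mode},
#'   \code{condition}, \code{landscape_index}.
#' @export
run_trial <- function(landscape, controller_p1, controller_p2 = NULL,
                      mode = c("joint", "individual"), seed = NULL,
                      physics = default_physics(), n_frames = 3600) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  state <- list(pos = c(0, 0), vel = c(0, 0), frame = 0L)
  active <- landscape$initial_active
  inact <- landscape$inactive
  collect_r <- physics$target_radius + physics$ball_radius

  M <- matrix(0, n_frames, 11)
  ev_frame <- integer(0); ev_target <- integer(0)
  for (t in seq_len(n_frames) - 1L) {
    st <- list(pos = state$pos, vel = state$vel, frame = t, active = active)
    i1 <- controller_p1(t, st)
    i2 <- if (mode == "joint") controller_p2(t, st) else c(0, 0)
    if (!all(is.finite(c(i1, i2))))
      stop("controller returned non-finite input at frame ", t)
    new <- step_physics(state, i1, i2, mode, landscape, physics)
    M[t + 1L, ] <- c(state$pos, state$vel, i1, i2, new$force,
                     as.numeric(new$on_obstacle))
    state <- new
    dists <- sqrt(colSums((t(landscape$targets[active, , drop = FALSE]) -
                             state$pos)^2))
    if (any(dists < collect_r)) {
      k <- which.min(dists)
      collected <- active[k]
      active[k] <- inact
      inact <- collected
      ev_frame <- c(ev_frame, t)
      ev_target <- c(ev_target, collected)
    }
  }
  finalize_trial_log(M, ev_frame, ev_target, landscape, mode)
}

## shared assembly of the tidy frame table (+ nearest-obstacle cache)
finalize_trial_log <- function(M, ev_frame, ev_target, landscape, mode,
                               nearest = NULL) {
  n <- nrow(M)
  if (is.null(nearest)) {
    nd <- matrix(Inf, n, nrow(landscape$obstacles))
    for (k in seq_len(nrow(landscape$obstacles)))
      nd[, k] <- rect_distance_vec(M[, 1], M[, 2], landscape$obstacles[k, ])
    nk <- max.col(-nd, ties.method = "first")
    nearest <- cbind(nk, nd[cbind(seq_len(n), nk)])
  }
  cond <- if (mode == "individual") "individual" else landscape$condition
  if (is.na(cond)) cond <- "SAME"
  vis <- landscape_visibility(landscape, cond)
  vis <- ifelse(vis %in% c("p1_only", "p2_only"), "one", vis)
  frames <- data.frame(
    frame = seq_len(n) - 1L, t = (seq_len(n) - 1L) / 60,
    ball_x = M[, 1], ball_y = M[, 2], vx = M[, 3], vy = M[, 4],
    p1_in_x = M[, 5], p1_in_y = M[, 6], p2_in_x = M[, 7], p2_in_y = M[, 8],
    force_x = M[, 9], force_y = M[, 10], on_obstacle = M[, 11] > 0,
    nearest_slot = landscape$active_slots[nearest[, 1]],
    nearest_dist = nearest[, 2], nearest_vis = vis[nearest[, 1]])
  out <- list(frames = frames,
              events = data.frame(frame = as.integer(ev_frame),
                                  target = as.integer(ev_target)),
              mode = mode, condition = landscape$condition,
              landscape_index = landscape$trial_index)
  class(out) <- "dg_trial_log"
  out
}

rect_distance_vec <- function(px, py, rect) {
  ca <- cos(rect[3]); sa <- sin(rect[3])
  dx <- px - rect[1]; dy <- py - rect[2]
  lx <- abs(ca * dx + sa * dy) - rect[4]
  ly <- abs(-sa * dx + ca * dy) - rect[5]
  sqrt(pmax(lx, 0)^2 + pmax(ly, 0)^2)
}
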