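#' Agent parameter set
#'
#' The built-in steering agent follows a potential-field law: its input is a
#' capped unit blend of a goal-attraction term (towards its current target),
#' a partner-following term (the partner's input `delay` frames back), and a
#' repulsion term from every obstacle it knows about, with von-Mises-like
#' angular noise applied to the resultant. Agents only know the obstacles
#' they can see, plus obstacles they have inferred within the trial: when the
#' ball is slowed by an obstacle the agent cannot see, the agent learns its
#' location with per-frame probability \code{p_learn} (memory resets every
#' trial). With probability \code{exploration} the agent picks a non-nearest
#' active target after each collection.
#'
#' @param goal_gain,partner_gain non-negative blend weights.
#' @param delay partner-following reaction delay in frames (>= 1 effective).
#' @param skill stationary SD of the steering wobble in radians (smaller =
#'   more skilled).
#' @param noise_phi per-frame AR(1) correlation of the steering wobble
#'   (0.97 at 60 Hz gives a ~0.5 s correlation time); 0 gives white noise.
#' @param exploration probability of choosing a non-nearest target.
#' @param p_learn per-frame probability of inferring a hidden obstacle the
#'   ball is currently stuck on.
#' @param avoid_gain,avoid_radius obstacle repulsion weight and range.
#' @param cap input magnitude (matches the per-player force cap).
#' @return A list of class \code{dg_agent_params}.
#' @export
agent_params <- function(goal_gain = 1.0, partner_gain = 0.4, delay = 8L,
                         skill = 0.35, exploration = 0.1, p_learn = 0.02,
                         avoid_gain = 1.2, avoid_radius = 0.18, cap = 0.5,
                         noise_phi = 0.97) {
  stopifnot(goal_gain + partner_gain > 0, delay >= 0,
            exploration >= 0, exploration <= 1, abs(noise_phi) < 1)
  out <- list(goal_gain = goal_gain, partner_gain = partner_gain,
              delay = as.integer(delay), skill = skill,
              exploration = exploration, p_learn = p_learn,
              avoid_gain = avoid_gain, avoid_radius = avoid_radius,
              cap = cap, noise_phi = noise_phi)
  class(out) <- "dg_agent_params"
  out
}

## inverse-CDF truncated normal (deterministic given the RNG stream)
rtnorm <- function(n, mean, sd, lower, upper) {
  u <- runif(n, pnorm(lower, mean, sd), pnorm(upper, mean, sd))
  qnorm(u, mean, sd)
}

#' Sample a pair profile
#'
#' Draws the two agents' steering parameters under a named scenario together
#' with synthetic personality trait scores. Trait instruments and ranges:
#' five-factor personality scales scored 0-48, autism quotient 0-50, and an
#' empathy aggregate (mean of perspective-taking, fantasy and empathic
#' concern, excluding personal distress) on a 1-5 scale.
#'
#' Scenarios: \code{"coupled"} (both agents follow each other moderately),
#' \code{"uncoupled"} (no partner term), \code{"leader_follower"} (one agent
#' follows the other strongly with reaction delay \code{tau}),
#' \code{"heterogeneous"} (skill, coupling, delay and exploration drawn from
#' truncated normals).
#'
#' @param seed integer seed.
#' @param scenario scenario name.
#' @param tau follower reaction delay in frames (leader_follower only).
#' @param pair_id integer id stored on the profile.
#' @param condition_order \code{"SAME-first"} or \code{"DIFF-first"}.
#' @return A list of class \code{dg_pair_profile} with \code{pair_id},
#'   \code{agents} (list of two [agent_params()]), \code{traits} (2 x 7
#'   matrix: neuroticism, extraversion, openness, agreeableness,
#'   conscientiousness, AQ, empathy), \code{scenario},
#'   \code{condition_order}.
#' @export
sample_pair_profile <- function(seed, scenario = c("coupled", "uncoupled",
                                                   "leader_follower",
                                                   "heterogeneous"),
                                tau = 12L, pair_id = 1L,
                                condition_order = c("SAME-first",
                                                    "DIFF-first")) {
  scenario <- match.arg(scenario)
  condition_order <- match.arg(condition_order)
  set.seed(seed)
  agents <- switch(scenario,
    coupled = list(agent_params(), agent_params()),
    uncoupled = list(agent_params(partner_gain = 0),
                     agent_params(partner_gain = 0)),
    leader_follower = list(
      agent_params(partner_gain = 0, skill = 0.4),
      agent_params(goal_gain = 0, partner_gain = 1,
                   delay = as.integer(tau), skill = 0.08,
                   exploration = 0, avoid_gain = 0, p_learn = 0)),
    heterogeneous = lapply(1:2, function(i)
      agent_params(partner_gain = rtnorm(1, 0.4, 0.15, 0, 1),
                   delay = sample(4:15, 1),
                   skill = rtnorm(1, 0.35, 0.1, 0.05, 0.8),
                   exploration = rtnorm(1, 0.1, 0.05, 0, 0.4))))
  traits <- rbind(
    c(rtnorm(5, 24, 7, 0, 48), rtnorm(1, 17, 6, 0, 50),
      rtnorm(1, 3.5, 0.5, 1, 5)),
    c(rtnorm(5, 24, 7, 0, 48), rtnorm(1, 17, 6, 0, 50),
      rtnorm(1, 3.5, 0.5, 1, 5)))
  colnames(traits) <- c("neuroticism", "extraversion", "openness",
                        "agreeableness", "conscientiousness", "AQ",
                        "empathy")
  out <- list(pair_id = as.integer(pair_id), agents = agents,
              traits = traits, scenario = scenario,
              condition_order = condition_order)
  class(out) <- "dg_pair_profile"
  out
}

#' One step of the steering policy
#'
#' Computes the 2-D input an agent with the given parameters produces for a
#' single game state: the capped unit blend of goal attraction, delayed
#' partner following, and repulsion-plus-slide away from known obstacles.
#' This is the same law the compiled engine applies every frame, exposed
#' for inspection and testing; the deterministic part only (no steering
#' wobble is added).
#'
#' @param params an [agent_params()].
#' @param ball_pos ball position, numeric length-2.
#' @param goal_pos position of the agent's current target.
#' @param known_obstacles matrix of obstacle rectangles
#'   (\code{cx, cy, angle, hx, hy} rows) the agent can see or has
#'   inferred; may have zero rows.
#' @param partner_force the partner's input \code{delay} frames ago, or
#'   NULL when unavailable.
#' @return Numeric length-2 input with magnitude \code{params$cap} (or 0
#'   for a degenerate zero resultant).
#' @export
agent_input <- function(params, ball_pos, goal_pos,
                        known_obstacles = NULL, partner_force = NULL) {
  g <- goal_pos - ball_pos
  gn <- sqrt(sum(g^2))
  g <- if (gn > 1e-12) g / gn else c(0, 0)
  av <- c(0, 0)
  if (!is.null(known_obstacles) && nrow(known_obstacles)) {
    for (k in seq_len(nrow(known_obstacles))) {
      rect <- known_obstacles[k, ]
      d <- rect_distance(ball_pos[1], ball_pos[2], rect)
      if (d >= params$avoid_radius) next
      ca <- cos(rect[3]); sa <- sin(rect[3])
      dx <- ball_pos[1] - rect[1]; dy <- ball_pos[2] - rect[2]
      lx <- max(-rect[4], min(rect[4], ca * dx + sa * dy))
      ly <- max(-rect[5], min(rect[5], -sa * dx + ca * dy))
      q <- c(rect[1] + ca * lx - sa * ly, rect[2] + sa * lx + ca * ly)
      rv <- ball_pos - q
      rn <- sqrt(sum(rv^2))
      if (rn < 1e-12) {
        rv <- ball_pos - rect[1:2]
        rn <- sqrt(sum(rv^2))
      }
      if (rn > 1e-12) {
        w <- params$avoid_gain * (1 - d / params$avoid_radius)
        rv <- rv / rn
        tv <- c(-rv[2], rv[1])
        if (sum(tv * g) < 0) tv <- -tv
        av <- av + w * (0.6 * rv + 0.8 * tv)
      }
    }
  }
  p <- c(0, 0)
  if (!is.null(partner_force) && params$partner_gain > 0) {
    pn <- sqrt(sum(partner_force^2))
    if (pn > 1e-12) p <- partner_force / pn
  }
  raw <- params$goal_gain * g + params$partner_gain * p + av
  rn <- sqrt(sum(raw^2))
  if (rn > 1e-12) params$cap * raw / rn else c(0, 0)
}

agent_cpp_spec <- function(params, visible9) {
  list(goal_gain = params$goal_gain, partner_gain = params$partner_gain,
       delay = params$delay, skill = params$skill,
       exploration = params$exploration, p_learn = params$p_learn,
       avoid_gain = params$avoid_gain, avoid_radius = params$avoid_radius,
       cap = params$cap, noise_phi = params$noise_phi, visible = visible9)
}

visible_for_player <- function(landscape, condition, player) {
  vis <- landscape_visibility(landscape, condition)
  if (player == 1) vis %in% c("both", "p1_only") else
    vis %in% c("both", "p2_only")
}

run_trial_agents <- function(landscape, params1, params2 = NULL,
                             mode = "joint", condition = "SAME",
                             physics = default_physics(), n_frames = 3600,
                             player = 1L) {
  joint <- identical(mode, "joint")
  pp <- physics_for_mode(physics, mode)
  if (joint) {
    v1 <- visible_for_player(landscape, condition, 1)
    v2 <- visible_for_player(landscape, condition, 2)
  } else {
    v1 <- visible_for_player(landscape, "individual", 1)
    v2 <- v1
    if (is.null(params2)) params2 <- params1
  }
  res <- cpp_run_trial(landscape$targets, landscape$initial_active,
                       landscape$inactive, landscape$obstacles, pp, joint,
                       agent_cpp_spec(params1, v1),
                       agent_cpp_spec(params2, v2), as.integer(n_frames))
  M <- res$frames[, 1:11, drop = FALSE]
  nearest <- cbind(res$frames[, 12], res$frames[, 13])
  ls2 <- landscape
  ls2$condition <- if (joint) condition else NA
  log <- finalize_trial_log(M, res$event_frame, res$event_target, ls2,
                            mode, nearest = nearest)
  log$player <- if (joint) NA_integer_ else as.integer(player)
  log
}

#' Simulate a full 60-trial session for one pair
#'
#' Runs the fast engine for every trial of the schedule: joint trials couple
#' the two agents with condition-appropriate obstacle views; individual
#' trials are run once per player (each player steers alone, seeing the six
#' team-visible obstacles). Agents' inferred-obstacle memory resets every
#' trial.
#'
#' @param profile a [sample_pair_profile()].
#' @param schedule a [make_schedule()] for this pair.
#' @param landscapes the shared landscape list.
#' @param seed integer seed (one RNG stream for the whole session).
#' @param physics engine configuration.
#' @return A \code{dg_session}: list with \code{profile}, \code{schedule},
#'   and \code{trials}, a list of 60 entries each holding \code{mode},
#'   \code{condition}, \code{block}, \code{session}, \code{landscape_index}
#'   and \code{logs} (one trial log for joint play, two for individual).
#' @export
simulate_session <- function(profile, schedule, landscapes, seed = 1,
                             physics = default_physics(),
                             n_frames = 3600) {
  set.seed(seed)
  trials <- vector("list", nrow(schedule$trials))
  for (i in seq_len(nrow(schedule$trials))) {
    tr <- schedule$trials[i, ]
    ls <- landscapes[[tr$landscape]]
    if (tr$mode == "joint") {
      logs <- list(run_trial_agents(ls, profile$agents[[1]],
                                    profile$agents[[2]], "joint",
                                    tr$condition, physics, n_frames))
    } else {
      logs <- list(run_trial_agents(ls, profile$agents[[1]],
                                    mode = "individual", physics = physics,
                                    n_frames = n_frames, player = 1L),
                   run_trial_agents(ls, profile$agents[[2]],
                                    mode = "individual", physics = physics,
                                    n_frames = n_frames, player = 2L))
    }
    trials[[i]] <- list(trial = tr$trial, mode = tr$mode,
                        condition = tr$condition, block = tr$block,
                        session = tr$session,
                        landscape_index = tr$landscape, logs = logs)
  }
  out <- list(profile = profile, schedule = schedule, trials = trials)
  class(out) <- "dg_session"
  out
}
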