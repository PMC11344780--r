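mk_state <- function() list(pos = c(0, 0), vel = c(0, 0), frame = 0L)

open_landscape <- function() {
  ## one far-away obstacle so physics tests run obstacle-free at the centre
  L <- generate_landscapes(3, n = 1)[[1]]
  L$obstacles <- matrix(c(0.9, 0.9, 0, 0.05, 0.02), 1, 5,
                        dimnames = list(NULL,
                                        c("cx", "cy", "angle", "hx", "hy")))
  L$active_slots <- 1L
  L$groups <- list(1L, integer(0), integer(0))
  L
}

test_that("opposite joint inputs cancel and velocity decays by drag only", {
  L <- open_landscape()
  st <- mk_state(); st$vel <- c(0.3, 0)
  new <- step_physics(st, c(0.5, 0), c(-0.5, 0), "joint", L)
  expect_equal(new$force, c(0, 0))
  expect_equal(new$vel[1], 0.3 * (1 - 2.0 / 60), tolerance = 1e-12)
  ## zero input, drag > 0: speed non-increasing over many frames
  st <- mk_state(); st$vel <- c(0.2, 0.1)
  speeds <- numeric(50)
  for (i in 1:50) {
    st <- step_physics(st, c(0, 0), c(0, 0), "joint", L)
    speeds[i] <- sqrt(sum(st$vel^2))
  }
  expect_true(all(diff(speeds) <= 1e-14))
})

test_that("accumulated joint force caps at 0.6, individual at 0.5", {
  L <- open_landscape()
  new <- step_physics(mk_state(), c(0.5, 0), c(0.5, 0), "joint", L)
  expect_equal(sqrt(sum(new$force^2)), 0.6, tolerance = 1e-12)
  new_i <- step_physics(mk_state(), c(0.9, 0), mode = "individual",
                        landscape = L)
  expect_equal(sqrt(sum(new_i$force^2)), 0.5, tolerance = 1e-12)
})

test_that("on-obstacle displacement is 10% of off-obstacle displacement", {
  L <- open_landscape()
  run_displacement <- function(on_obstacle) {
    ## arena-covering bar keeps the ball on-obstacle for the whole run
    if (on_obstacle) L$obstacles[1, ] <- c(0, 0, 0, 0.95, 0.95)
    st <- mk_state()
    for (i in 1:60) st <- step_physics(st, c(0.5, 0), c(0.5, 0), "joint", L)
    p1 <- st$pos
    st <- step_physics(st, c(0.5, 0), c(0.5, 0), "joint", L)
    sqrt(sum((st$pos - p1)^2))
  }
  ## at terminal speed the per-frame displacement ratio is exactly 0.1
  d_on <- run_displacement(TRUE)
  d_off <- run_displacement(FALSE)
  expect_equal(d_on / d_off, 0.1, tolerance = 1e-9)
})

test_that("speed never exceeds the mode cap and walls clamp", {
  L <- open_landscape()
  st <- mk_state()
  for (i in 1:1200) {
    st <- step_physics(st, c(0.5, 0), c(0.5, 0), "joint", L)
    expect_lte(sqrt(sum(st$vel^2)), 0.6 + 1e-12)
  }
  expect_equal(st$pos[1], 1 - 0.03, tolerance = 1e-12)
  expect_equal(st$vel[1], 0)
})

test_that("run_trial collects a straight-ahead target and logs nothing for
           idle controllers", {
  L <- open_landscape()
  aim <- function(frame, state) {
    d <- L$targets[state$active[1], ] - state$pos
    0.5 * d / sqrt(sum(d^2))
  }
  log <- run_trial(L, aim, aim, "joint", n_frames = 900)
  expect_gte(nrow(log$events), 1)
  zero <- function(frame, state) c(0, 0)
  log0 <- run_trial(L, zero, zero, "joint", n_frames = 300)
  expect_equal(nrow(log0$events), 0)
  expect_equal(sum(sqrt(diff(log0$frames$ball_x)^2 +
                          diff(log0$frames$ball_y)^2)), 0)
  bad <- function(frame, state) c(NaN, 0)
  expect_error(run_trial(L, bad, zero, "joint", n_frames = 10), "frame")
})

test_that("after every collection exactly 3 targets are active and
           collection frames increase", {
  log <- get_joint_trial(1, 1)
  expect_true(all(diff(log$events$frame) > 0))
  ## reconstruct the active set over events
  active <- 1:3; inact <- 4L
  for (tg in log$events$target) {
    expect_true(tg %in% active)
    active[active == tg] <- inact
    inact <- tg
    expect_length(unique(active), 3)
  }
})

test_that("the engine is deterministic given identical seeds", {
  fx1 <- get_fixture()
  fx2 <- make_fixture(42)
  expect_identical(fx1$sessions[[1]]$trials[[3]]$logs[[1]]$frames,
                   fx2$sessions[[1]]$trials[[3]]$logs[[1]]$frames)
  expect_identical(fx1$measures$trial, fx2$measures$trial)
})

test_that("the compiled engine matches the pure-R mirror frame for frame", {
  L <- generate_landscapes(5, n = 1)[[1]]
  a1 <- agent_params(skill = 0, exploration = 0, p_learn = 0)
  a2 <- agent_params(skill = 0, exploration = 0, p_learn = 0,
                     partner_gain = 0.6, delay = 5L)
  cpp <- dyadgame:::run_trial_agents(L, a1, a2, "joint", "SAME",
                                     n_frames = 600)
  ref <- r_engine_trial(L, a1, a2, "SAME", n_frames = 600)
  M_cpp <- as.matrix(cpp$frames[, c("ball_x", "ball_y", "vx", "vy",
                                    "p1_in_x", "p1_in_y", "p2_in_x",
                                    "p2_in_y", "force_x", "force_y")])
  expect_equal(unname(M_cpp), unname(ref$M[, 1:10]), tolerance = 1e-12)
  expect_equal(cpp$events$frame, ref$ev_frame)
  expect_equal(cpp$events$target, ref$ev_target)
})
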