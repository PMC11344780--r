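test_that("scenario profiles set the advertised coupling structure", {
  un <- sample_pair_profile(1, "uncoupled")
  expect_equal(un$agents[[1]]$partner_gain, 0)
  expect_equal(un$agents[[2]]$partner_gain, 0)
  lf <- sample_pair_profile(2, "leader_follower", tau = 12)
  expect_equal(lf$agents[[2]]$delay, 12L)
  expect_gt(lf$agents[[2]]$partner_gain, lf$agents[[1]]$partner_gain)
  expect_identical(sample_pair_profile(3, "heterogeneous"),
                   sample_pair_profile(3, "heterogeneous"))
  expect_error(sample_pair_profile(1, "telepathic"))
  ## traits stay within instrument ranges
  het <- sample_pair_profile(4, "heterogeneous")
  expect_true(all(het$traits[, 1:5] >= 0 & het$traits[, 1:5] <= 48))
  expect_true(all(het$traits[, "AQ"] >= 0 & het$traits[, "AQ"] <= 50))
  expect_true(all(het$traits[, "empathy"] >= 1 &
                    het$traits[, "empathy"] <= 5))
})

test_that("injected leader-follower delays are recovered by the WLCC time
           lag within one lag step", {
  ls <- generate_landscapes(1, n = 3)
  for (tau in c(6L, 12L, 30L)) {
    p <- sample_pair_profile(7, "leader_follower", tau = tau)
    set.seed(100 + tau)
    lags <- vapply(1:3, function(i) {
      log <- dyadgame:::run_trial_agents(ls[[i]], p$agents[[1]],
                                         p$agents[[2]], "joint", "SAME",
                                         n_frames = 1800)
      wlcc_measures(wlcc(steering_direction(log, 1),
                         steering_direction(log, 2)))$time_lag
    }, numeric(1))
    expect_lt(abs(mean(lags) - tau), 1)
  }
})

test_that("coordination strengthens with partner gain (rank test across
           seeded trials)", {
  ls <- generate_landscapes(2, n = 8)
  gains <- c(0, 0.3, 0.6, 1.0)
  set.seed(123)
  out <- NULL
  for (g in gains) {
    for (i in 1:8) {
      a <- agent_params(partner_gain = g)
      log <- dyadgame:::run_trial_agents(ls[[i]], a, a, "joint", "DIFF",
                                         n_frames = 1800)
      m <- wlcc_measures(wlcc(steering_direction(log, 1),
                              steering_direction(log, 2)))
      out <- rbind(out, c(g, m$strength_of_relation, m$synchrony))
    }
  }
  kt <- suppressWarnings(cor.test(out[, 1], out[, 2], method = "kendall",
                                  alternative = "greater"))
  expect_lt(kt$p.value, 0.05)
  sync_mean <- tapply(out[, 3], out[, 1], mean)
  expect_gt(sync_mean[["1"]], sync_mean[["0"]])
  expect_gt(suppressWarnings(cor(out[, 1], out[, 3],
                                 method = "kendall")), 0)
})

test_that("zero-noise ratings equal the rounded linear predictor", {
  sm <- data.frame(block = 1:12,
                   condition = rep(c("SAME", "DIFF"), each = 6),
                   targets = seq(-1, 1, length.out = 12),
                   variability_of_relation = 0, synchrony = 0,
                   path_length = 0)
  cf <- default_rating_coeffs(sigma_u = 0, rho = 0, sigma_e = 0,
                              jitter_sd = 0)
  pr <- sample_pair_profile(1, "coupled")
  rs <- synthesize_ratings(sm, pr, cf, seed = 1,
                           scale = list(mean = c(targets = 0,
                                                 variability_of_relation = 0,
                                                 synchrony = 0,
                                                 path_length = 0),
                                        sd = c(targets = 1,
                                               variability_of_relation = 1,
                                               synchrony = 1,
                                               path_length = 1)))
  eng <- rs[rs$construct == "engagement" & !is.na(rs$block) &
              rs$player == 1, ]
  cc <- cf$constructs$engagement
  time_z <- (1:12 - 6.5) / sd(1:12)
  cond <- as.numeric(sm$condition == "SAME") - 0.5
  lp <- cc$intercept + cc$coef[["targets"]] * sm$targets +
    cc$coef[["time"]] * time_z + cc$coef[["condition_same"]] * cond
  expect_equal(eng$value, pmin(100, pmax(0, round(50 + 12 * lp))))
  ## both players identical when jitter is off
  eng2 <- rs[rs$construct == "engagement" & !is.na(rs$block) &
               rs$player == 2, ]
  expect_equal(eng$value, eng2$value)
})

test_that("rating constructs appear at the right moments and stay in
           range", {
  fxm <- data.frame(block = 1:12, condition = rep(c("SAME", "DIFF"), 6),
                    targets = rnorm(12), variability_of_relation = rnorm(12),
                    synchrony = rnorm(12), path_length = rnorm(12))
  rs <- synthesize_ratings(fxm, sample_pair_profile(2, "coupled"), seed = 4)
  expect_true(all(rs$value >= 0 & rs$value <= 100))
  expect_true(all(rs$value == round(rs$value)))
  expect_setequal(unique(rs$construct[is.na(rs$block)]),
                  c("engagement", "ball_control"))
  expect_setequal(unique(rs$construct[!is.na(rs$block)]),
                  c("engagement", "agreement", "predictability"))
  expect_equal(sort(unique(rs$trial[is.na(rs$block)])), c(5, 10, 55, 60))
  expect_error(synthesize_ratings(fxm[-3, ],
                                  sample_pair_profile(2, "coupled")),
               "block")
})

test_that("rating coefficients propagate their sign into simulated
           cohorts", {
  set.seed(60)
  prs <- lapply(1:23, function(i) sample_pair_profile(i, "coupled",
                                                      pair_id = i))
  cors <- vapply(1:23, function(i) {
    sm <- data.frame(block = 1:12, condition = rep(c("SAME", "DIFF"), 6),
                     targets = rnorm(12),
                     variability_of_relation = rnorm(12),
                     synchrony = rnorm(12), path_length = rnorm(12))
    rs <- synthesize_ratings(sm, prs[[i]], seed = 200 + i,
                             scale = list(mean = sapply(sm[3:6], function(x) 0),
                                          sd = sapply(sm[3:6], function(x) 1)))
    eng <- rs[rs$construct == "engagement" & !is.na(rs$block), ]
    eng <- aggregate(value ~ block, eng, mean)
    cor(sm$targets, eng$value)
  }, numeric(1))
  expect_gt(mean(cors), 0)
  expect_gt(t.test(cors)$statistic, 2)
})

test_that("AR(1) residual noise raises lag-1 autocorrelation", {
  set.seed(61)
  lag1 <- function(rho) {
    mean(replicate(40, {
      e <- dyadgame:::ar1_noise(12, rho, 1)
      cor(e[-1], e[-12])
    }))
  }
  expect_gt(lag1(0.8), lag1(0) + 0.3)
})

test_that("an empty-input cohort collects nothing", {
  ls <- generate_landscapes(4, n = 2)
  a <- agent_params(goal_gain = 0, partner_gain = 1e-9, skill = 0,
                    exploration = 0, p_learn = 0, avoid_gain = 0)
  log <- dyadgame:::run_trial_agents(ls[[1]], a, a, "joint", "SAME",
                                     n_frames = 600)
  expect_equal(nrow(log$events), 0)
  expect_lt(sum(sqrt(diff(log$frames$ball_x)^2 +
                       diff(log$frames$ball_y)^2)), 1e-6)
})

test_that("the steering policy points at the goal at full cap, follows a
           delayed partner, and steers away from known obstacles", {
  a <- agent_params(partner_gain = 0, exploration = 0, skill = 0)
  inp <- agent_input(a, c(0, 0), c(0.5, 0))
  expect_equal(inp, c(a$cap, 0), tolerance = 1e-12)
  ## pure follower: input direction equals partner's earlier force
  f <- agent_params(goal_gain = 0, partner_gain = 1)
  pf <- c(-0.2, 0.3)
  inp_f <- agent_input(f, c(0, 0), c(0.5, 0), partner_force = pf)
  expect_equal(inp_f / sqrt(sum(inp_f^2)), pf / sqrt(sum(pf^2)),
               tolerance = 1e-12)
  ## avoidance: brute-force potential-field oracle on a 3-obstacle toy
  ## layout (only the first obstacle is within avoidance range): the input
  ## must deviate from the plain goal heading in the direction of the
  ## numerical negative gradient of the proximity potential
  obst <- rbind(c(0.15, 0.0, 0, 0.1, 0.03),
                c(0.0, 0.5, pi / 4, 0.1, 0.03),
                c(-0.5, -0.3, 0, 0.1, 0.03))
  pot <- function(pt) {
    sum(apply(obst, 1, function(r) {
      d <- dyadgame:::rect_distance(pt[1], pt[2], r)
      max(0, 1 - d / a$avoid_radius)
    }))
  }
  pos <- c(0.05, 0.05)  # 0.02 above obstacle 1, goal straight past it
  inp_a <- agent_input(a, pos, c(0.9, 0.05), known_obstacles = obst)
  dir_a <- inp_a / sqrt(sum(inp_a^2))
  eps <- 1e-4
  grad <- c(pot(pos + c(eps, 0)) - pot(pos - c(eps, 0)),
            pot(pos + c(0, eps)) - pot(pos - c(0, eps))) / (2 * eps)
  deviation <- dir_a - c(1, 0)
  expect_gt(sum(deviation * (-grad)), 0)
  ## the deviated step ends farther from the obstacle than a straight one
  d_avoid <- dyadgame:::rect_distance(pos[1] + 0.02 * dir_a[1],
                                      pos[2] + 0.02 * dir_a[2], obst[1, ])
  d_straight <- dyadgame:::rect_distance(pos[1] + 0.02, pos[2], obst[1, ])
  expect_gt(d_avoid, d_straight)
  ## and it still makes progress towards the goal half-plane
  expect_gt(inp_a[1], 0)
})
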