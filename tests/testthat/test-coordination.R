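test_that("steering direction is the input angle, masked at zero input", {
  log <- get_joint_trial(1, 1)
  log$frames$p1_in_x[1:3] <- c(1, 0, 0)
  log$frames$p1_in_y[1:3] <- c(0, 1, 0)
  s <- steering_direction(log, 1)
  expect_equal(s$theta[1], 0)
  expect_equal(s$theta[2], pi / 2)
  expect_true(is.na(s$theta[3]) && !s$valid[3])
})

test_that("wlcc matches the naive double-loop Spearman oracle to 1e-12", {
  log <- get_joint_trial(1, 1)
  a <- steering_direction(log, 1)
  b <- steering_direction(log, 2)
  a$theta <- a$theta[1:300]; b$theta <- b$theta[1:300]
  a$valid <- a$valid[1:300]; b$valid <- b$valid[1:300]
  pr <- wlcc_params(window_len = 60, window_step = 20, max_lag = 15)
  wl <- wlcc(a, b, pr)
  ref <- naive_wlcc(a$theta, b$theta, 60, 20, 15)
  expect_equal(dim(wl$r), dim(ref))
  expect_lt(max(abs(wl$r - ref), na.rm = TRUE), 1e-12)
  expect_identical(is.na(wl$r), is.na(ref))
})

test_that("wlcc of a series with itself peaks at lag zero with r = 1", {
  set.seed(4)
  th <- cumsum(rnorm(600, 0, 0.2))
  th <- (th + pi) %% (2 * pi) - pi
  s <- structure(list(theta = th, magnitude = rep(1, 600),
                      valid = rep(TRUE, 600)), class = "dg_steering")
  wl <- wlcc(s, s, wlcc_params(window_len = 60, window_step = 30,
                               max_lag = 12))
  expect_true(all(abs(wl$r[, wl$lags == 0] - 1) < 1e-12))
  m <- wlcc_measures(wl)
  expect_equal(m$strength_of_relation, 1, tolerance = 1e-12)
  expect_equal(m$time_lag, 0)
  expect_equal(m$switching, 0)
})

test_that("a shifted copy is recovered at the shift lag", {
  set.seed(5)
  n <- 900; k <- 7
  th <- cumsum(rnorm(n + k, 0, 0.25))
  a <- structure(list(theta = ((th[1:n] + pi) %% (2 * pi)) - pi,
                      valid = rep(TRUE, n)), class = "dg_steering")
  ## b reads a k frames later: b(t) = a(t - k), so player 1 leads by k
  b <- structure(list(theta = ((th[(1:n) + k] + pi) %% (2 * pi)) - pi,
                      valid = rep(TRUE, n)), class = "dg_steering")
  wl <- wlcc(b, a, wlcc_params(window_len = 90, window_step = 30,
                               max_lag = 15))
  m <- wlcc_measures(wl)
  expect_equal(m$time_lag, k, tolerance = 1e-9)
  interior <- 2:(nrow(wl$r) - 1)
  expect_true(all(abs(wl$r[interior, wl$lags == k] - 1) < 1e-9))
})

test_that("independent random walks give near-zero mean coefficient", {
  set.seed(6)
  mk <- function() {
    th <- cumsum(rnorm(6300, 0, 0.3))
    structure(list(theta = (th + pi) %% (2 * pi) - pi,
                   valid = rep(TRUE, 6300)), class = "dg_steering")
  }
  wl <- wlcc(mk(), mk(), wlcc_params(window_len = 120, window_step = 30,
                                     max_lag = 30))
  expect_gte(nrow(wl$r), 200)
  expect_lt(abs(mean(wl$r, na.rm = TRUE)), 0.05)
})

test_that("wlcc measure arithmetic matches hand-computed peaks", {
  ## two windows with constructed peaks (0.9, +6) and (0.5, -6)
  wl <- structure(list(
    r = rbind(c(0.1, 0.9, 0.1, 0.0, 0.2), c(0.5, 0.2, 0.1, 0.0, 0.2)),
    lags = c(-6, -3, 0, 3, 6), centers = c(60, 90),
    params = wlcc_params()), class = "dg_wlcc")
  ## row 1: interior local max 0.9 at lag -3? construct explicitly instead
  wl$r <- rbind(c(0.2, 0.3, 0.5, 0.9, 0.3), c(0.5, 0.3, 0.2, 0.1, 0.05))
  wl$lags <- c(-6, -3, 0, 6, 9)
  m <- wlcc_measures(wl)
  ## peaks: (0.9, +6) and (0.5, -6)
  expect_equal(m$strength_of_relation, 0.7)
  expect_equal(m$variability_of_relation, sd(c(0.9, 0.5)))
  expect_equal(m$time_lag, 6)
  expect_equal(m$switching, sd(c(6, -6)))
  expect_equal(m$synchrony, mean(wl$r))
  ## constant matrix: synchrony equals the constant
  wl$r <- matrix(0.4, 3, 5)
  expect_equal(wlcc_measures(wl)$synchrony, 0.4)
  ## all-missing matrix errors
  wl$r <- matrix(NA_real_, 3, 5)
  expect_error(wlcc_measures(wl), "missing")
})

test_that("peak picking prefers the largest local maximum, ties to the
           smaller lag", {
  wl <- structure(list(r = rbind(c(0.2, 0.8, 0.3, 0.8, 0.1)),
                       lags = c(-10, -5, 0, 5, 10), centers = 1,
                       params = wlcc_params()), class = "dg_wlcc")
  pk <- dyadgame:::pick_peaks(wl)
  expect_equal(abs(pk[1, 2]), 5)   # tie between lags -5 and +5
  ## monotone row: no interior local maximum -> global maximum
  wl$r <- rbind(c(0.1, 0.2, 0.3, 0.4, 0.9))
  pk <- dyadgame:::pick_peaks(wl)
  expect_equal(pk[1, 1], 0.9)
  expect_equal(pk[1, 2], 10)
  ## nearest rule: equidistant local maxima resolve to the higher r
  wl$r <- rbind(c(0.2, 0.8, 0.3, 0.5, 0.1))
  pk <- dyadgame:::pick_peaks(wl, rule = "nearest")
  expect_equal(pk[1, 1], 0.8)
  expect_equal(pk[1, 2], -5)
  wl$r <- rbind(c(0.2, 0.8, 0.3, 0.9, 0.1))
  pk <- dyadgame:::pick_peaks(wl, rule = "largest")
  expect_equal(pk[1, 2], 5)
})

test_that("mutual information is exact for identical series and invariant
           to monotone bijections", {
  set.seed(7)
  n <- 4800
  th <- runif(n, -pi, pi)
  a <- structure(list(theta = th, valid = rep(TRUE, n)),
                 class = "dg_steering")
  expect_equal(mutual_information(a, a, n_bins = 8), 3.0,
               tolerance = 1e-12)
  ## monotone bijection of the values leaves equiprobable binning alone
  b <- a; b$theta <- tanh(th / 2)
  expect_equal(mutual_information(a, b, 8), 3.0, tolerance = 1e-12)
  ## symmetry
  set.seed(8)
  c_ <- structure(list(theta = runif(n, -pi, pi), valid = rep(TRUE, n)),
                  class = "dg_steering")
  expect_equal(mutual_information(a, c_, 8), mutual_information(c_, a, 8),
               tolerance = 1e-12)
  ## independence: corrected estimate is near zero
  expect_lt(mutual_information(a, c_, 8, corrected = TRUE), 0.05)
  expect_gte(mutual_information(a, c_, 8), 0)
  short <- structure(list(theta = th[1:50], valid = rep(TRUE, 50)),
                     class = "dg_steering")
  expect_error(mutual_information(short, short, 8), "too few")
})

test_that("phase slope index is antisymmetric and finds a delayed driver", {
  log <- get_joint_trial(1, 1)
  a <- steering_direction(log, 1)
  b <- steering_direction(log, 2)
  p_ab <- phase_slope_index(a, b, seg_len = 180)
  p_ba <- phase_slope_index(b, a, seg_len = 180)
  expect_equal(p_ab, -p_ba, tolerance = 1e-12)
  ## known driver: b echoes a 10 frames later -> psi(a, b) > 0
  set.seed(9)
  hits <- 0
  for (r in 1:20) {
    th <- cumsum(rnorm(1210, 0, 0.3))
    a2 <- structure(list(theta = (th[1:1200] + pi) %% (2 * pi) - pi,
                         valid = rep(TRUE, 1200)), class = "dg_steering")
    b2 <- structure(list(theta = ((th[11:1210] + rnorm(1200, 0, 0.1)) +
                                    pi) %% (2 * pi) - pi,
                         valid = rep(TRUE, 1200)), class = "dg_steering")
    ## b2 at time t equals a2 at time t + 10...: a2 lags, so psi(b2,a2) > 0
    hits <- hits + (phase_slope_index(b2, a2) > 0)
  }
  expect_gte(hits, 19)
  expect_error(phase_slope_index(a, b, band = c(0.05, 40)), "Nyquist")
})

test_that("surrogate dyads enumerate ordered cross-pairings", {
  fx <- get_fixture()
  sur <- surrogate_synchrony(fx$sessions,
                             params = wlcc_params(window_len = 90,
                                                  window_step = 30,
                                                  max_lag = 30))
  ## 2 pairs, 4 shared joint landscape x condition combinations,
  ## 2 ordered pairings each
  expect_equal(nrow(sur), 8)
  expect_true(all(sur$pair1 != sur$pair2))
  expect_error(surrogate_synchrony(fx$sessions[1]), "2 pairs")
})

test_that("segment-restricted measures aggregate the matching windows", {
  log <- get_joint_trial(1, 1)
  wl <- wlcc(steering_direction(log, 1), steering_direction(log, 2),
             wlcc_params(window_len = 90, window_step = 30, max_lag = 30))
  n <- nrow(log$frames)
  seg <- pmin(3, wl$centers %/% (n / 3) + 1)
  m1 <- wlcc_measures(wl, windows = seg == 1)
  pk <- dyadgame:::pick_peaks(wl)
  expect_equal(m1$strength_of_relation, mean(pk[seg == 1, 1]))
  expect_equal(m1$synchrony, mean(wl$r[seg == 1, ], na.rm = TRUE))
})
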