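## Independent oracles used across test files. These deliberately share no
## code with the implementation paths they check.

## naive double-loop WLCC: plain cor(method = "spearman") on per-window
## seam-adjusted angles
naive_wlcc <- function(theta_a, theta_b, w, step, max_lag,
                       min_valid_fraction = 0.75, circular = "rotate") {
  n <- length(theta_a)
  starts <- seq(1, n - w + 1, by = step)
  lags <- -max_lag:max_lag
  adj <- function(x) {
    if (circular == "rotate") {
      mu <- atan2(mean(sin(x)), mean(cos(x)))
      (x - mu + pi) %% (2 * pi) - pi
    } else {
      d <- diff(x); d <- (d + pi) %% (2 * pi) - pi
      x[1] + c(0, cumsum(d))
    }
  }
  r <- matrix(NA_real_, length(starts), length(lags))
  for (i in seq_along(starts)) {
    for (j in seq_along(lags)) {
      s <- starts[i]; l <- lags[j]
      ia <- s:(s + w - 1)
      ib <- ia + l
      keep <- ib >= 1 & ib <= n
      xa <- theta_a[ia[keep]]; xb <- theta_b[ib[keep]]
      ok <- !is.na(xa) & !is.na(xb)
      if (sum(ok) < max(3, ceiling(min_valid_fraction * w))) next
      xa <- adj(xa[ok]); xb <- adj(xb[ok])
      if (sd(xa) == 0 || sd(xb) == 0) next
      r[i, j] <- suppressWarnings(cor(xa, xb, method = "spearman"))
    }
  }
  r
}

## brute-force point-to-rectangle-border distance by dense border sampling
border_sample_distance <- function(p, rect, n = 20000) {
  ca <- cos(rect[3]); sa <- sin(rect[3])
  hx <- rect[4]; hy <- rect[5]
  tt <- seq(0, 1, length.out = n)
  per <- 4 * (hx + hy)
  d <- tt * per
  lx <- ly <- numeric(n)
  for (i in seq_len(n)) {
    s <- d[i]
    if (s < 2 * hx) { lx[i] <- -hx + s; ly[i] <- -hy }
    else if (s < 2 * hx + 2 * hy) { lx[i] <- hx; ly[i] <- -hy + (s - 2 * hx) }
    else if (s < 4 * hx + 2 * hy) {
      lx[i] <- hx - (s - 2 * hx - 2 * hy); ly[i] <- hy
    } else { lx[i] <- -hx; ly[i] <- hy - (s - 4 * hx - 2 * hy) }
  }
  wx <- rect[1] + ca * lx - sa * ly
  wy <- rect[2] + sa * lx + ca * ly
  min(sqrt((wx - p[1])^2 + (wy - p[2])^2))
}

## exhaustive back-and-forth flagging by direct pattern matching
enum_complexity <- function(seq_ids) {
  n <- length(seq_ids)
  if (n < 3) return(1.0)
  flagged <- logical(n)
  for (i in 3:n)
    if (seq_ids[i] == seq_ids[i - 2]) flagged[i] <- TRUE
  sum(!flagged) / n
}

## GLS closed form for known covariance V0 (per-pair block diagonal)
gls_closed_form <- function(X, y, pair, V0_block) {
  idx <- split(seq_along(y), pair)
  XtVX <- matrix(0, ncol(X), ncol(X)); XtVy <- numeric(ncol(X))
  for (ix in idx) {
    Vi <- solve(V0_block[seq_along(ix), seq_along(ix)])
    XtVX <- XtVX + t(X[ix, , drop = FALSE]) %*% Vi %*% X[ix, , drop = FALSE]
    XtVy <- XtVy + t(X[ix, , drop = FALSE]) %*% Vi %*% y[ix]
  }
  drop(solve(XtVX, XtVy))
}

## brute-force rmcorr via explicit projection: residualise y and x on the
## group dummies, then Pearson correlation of residuals
brute_rmcorr <- function(x, y, g) {
  G <- model.matrix(~ factor(g))
  P <- diag(length(x)) - G %*% solve(crossprod(G)) %*% t(G)
  rx <- drop(P %*% x); ry <- drop(P %*% y)
  sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
}

## pure-R mirror of the built-in agent + physics loop (displacement
## slowdown, no RNG: requires skill = exploration = p_learn = 0)
r_engine_trial <- function(landscape, params1, params2, condition = "SAME",
                           physics = default_physics(), n_frames = 600) {
  pp <- dyadgame:::physics_for_mode(physics, "joint")
  vis <- landscape_visibility(landscape, condition)
  known <- list(vis %in% c("both", "p1_only"), vis %in% c("both", "p2_only"))
  prm <- list(params1, params2)
  targets <- landscape$targets
  active <- landscape$initial_active
  inact <- landscape$inactive
  obst <- landscape$obstacles
  rectd <- function(p, k) dyadgame:::rect_distance(p[1], p[2], obst[k, ])
  closest_pt <- function(p, k) {
    r <- obst[k, ]; ca <- cos(r[3]); sa <- sin(r[3])
    dx <- p[1] - r[1]; dy <- p[2] - r[2]
    lx <- max(-r[4], min(r[4], ca * dx + sa * dy))
    ly <- max(-r[5], min(r[5], -sa * dx + ca * dy))
    c(r[1] + ca * lx - sa * ly, r[2] + sa * lx + ca * ly)
  }
  goal <- c(NA, NA)
  pick <- function(a, pos) {
    d <- colSums((t(targets[active, , drop = FALSE]) - pos)^2)
    active[which.min(d)]
  }
  pos <- c(0, 0); vel <- c(0, 0)
  goal <- c(pick(1, pos), pick(2, pos))
  hist <- list(matrix(0, n_frames, 2), matrix(0, n_frames, 2))
  M <- matrix(0, n_frames, 11)
  ev_frame <- integer(0); ev_target <- integer(0)
  for (t in 0:(n_frames - 1)) {
    nd <- vapply(seq_len(nrow(obst)), function(k) rectd(pos, k), numeric(1))
    nk <- which.min(nd)
    on_obs <- nd[nk] <= pp$ball_radius
    inputs <- list()
    for (a in 1:2) {
      pr <- prm[[a]]
      g <- targets[goal[a], ] - pos
      gn <- sqrt(sum(g^2)); g <- if (gn > 1e-12) g / gn else c(0, 0)
      av <- c(0, 0)
      for (k in seq_len(nrow(obst))) {
        if (!known[[a]][k]) next
        d <- nd[k]
        if (d < pr$avoid_radius) {
          q <- closest_pt(pos, k)
          rv <- pos - q; rn <- sqrt(sum(rv^2))
          if (rn < 1e-12) { rv <- pos - obst[k, 1:2]; rn <- sqrt(sum(rv^2)) }
          if (rn > 1e-12) {
            w <- pr$avoid_gain * (1 - d / pr$avoid_radius)
            rv <- rv / rn
            tv <- c(-rv[2], rv[1])
            if (sum(tv * g) < 0) tv <- -tv
            av <- av + w * (0.6 * rv + 0.8 * tv)
          }
        }
      }
      partner <- c(0, 0)
      s <- t - max(pr$delay, 1)
      if (s >= 0 && pr$partner_gain > 0) {
        pf <- hist[[3 - a]][s + 1, ]
        pn <- sqrt(sum(pf^2))
        if (pn > 1e-12) partner <- pf / pn
      }
      raw <- pr$goal_gain * g + pr$partner_gain * partner + av
      rn <- sqrt(sum(raw^2))
      inputs[[a]] <- if (rn > 1e-12) pr$cap * raw / rn else c(0, 0)
    }
    i1 <- dyadgame:::clamp_mag(inputs[[1]], pp$cap_player)
    i2 <- dyadgame:::clamp_mag(inputs[[2]], pp$cap_player)
    force <- dyadgame:::clamp_mag(i1 + i2, pp$cap_force)
    M[t + 1, ] <- c(pos, vel, i1, i2, force, as.numeric(on_obs))
    hist[[1]][t + 1, ] <- i1; hist[[2]][t + 1, ] <- i2
    vel <- vel + (pp$gain * force - pp$drag * vel) * pp$dt
    vel <- dyadgame:::clamp_mag(vel, pp$vmax)
    fac <- if (on_obs) pp$obstacle_factor else 1
    pos <- pos + vel * pp$dt * fac
    lim <- pp$arena_half - pp$ball_radius
    for (i in 1:2) {
      if (pos[i] > lim) { pos[i] <- lim; vel[i] <- 0 }
      if (pos[i] < -lim) { pos[i] <- -lim; vel[i] <- 0 }
    }
    dt2 <- sqrt(colSums((t(targets[active, , drop = FALSE]) - pos)^2))
    if (any(dt2 < pp$target_radius + pp$ball_radius)) {
      k <- which.min(dt2)
      collected <- active[k]
      active[k] <- inact; inact <- collected
      ev_frame <- c(ev_frame, t); ev_target <- c(ev_target, collected)
      goal <- c(pick(1, pos), pick(2, pos))
    }
  }
  list(M = M, ev_frame = ev_frame, ev_target = ev_target)
}

## generator for pair-by-block tables with known mixed-model structure
gen_lmm_data <- function(n_pair = 23, nb = 12, beta = c(x1 = 0.3),
                         n_x = 3, sigma_u = 0.5, rho = 0.5,
                         sigma_e = 0.7) {
  do.call(rbind, lapply(seq_len(n_pair), function(i) {
    X <- matrix(rnorm(nb * n_x), nb)
    colnames(X) <- paste0("x", seq_len(n_x))
    e <- numeric(nb)
    e[1] <- rnorm(1)
    for (t in 2:nb) e[t] <- rho * e[t - 1] + rnorm(1, 0, sqrt(1 - rho^2))
    lp <- drop(X[, names(beta), drop = FALSE] %*% beta)
    data.frame(pair = i, block = 1:nb, X,
               y = lp + rnorm(1, 0, sigma_u) + sigma_e * e)
  }))
}
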