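#' Default slot layout for the ball-steering game
#'
#' Builds the static geometry the landscape generator draws from: a square
#' arena, a ring of three outer target positions plus one central (initially
#' inactive) target, and 15 candidate obstacle slots. Nine of the slots sit on
#' the chords connecting the outer targets (three per chord, with small fixed
#' jitter) so that every subset of active slots can block all direct
#' target-to-target lines; the remaining six sit on an inner ring, oriented
#' tangentially.
#'
#' All lengths are in game units; the arena is \eqn{[-1, 1]^2} with the origin
#' at its centre and the y axis pointing up.
#'
#' @param arena_half half-width of the square arena (default 1).
#' @param ball_radius,target_radius radii of ball and targets.
#' @param ring_radius radius of the outer target ring.
#' @param bar_length,bar_width obstacle bar dimensions (long and short side).
#' @param inner_ring_radius radius of the ring carrying the six non-chord
#'   slots.
#'
#' @return An object of class \code{dg_layout}: a list with \code{arena_half},
#'   the radii, \code{targets} (4 x 2 matrix, rows = 3 ring targets then the
#'   central target) and \code{slots}, a data frame of 15 rows with columns
#'   \code{cx}, \code{cy}, \code{angle} (orientation of the bar's long axis,
#'   radians), \code{hx}, \code{hy} (half-length, half-width).
#' @export
default_layout <- function(arena_half = 1, ball_radius = 0.03,
                           target_radius = 0.06, ring_radius = 0.7,
                           bar_length = 0.3, bar_width = 0.06,
                           inner_ring_radius = 0.45) {
  ta <- pi / 2 + c(0, 1, 2) * 2 * pi / 3
  targets <- rbind(ring_radius * cbind(cos(ta), sin(ta)), c(0, 0))

  hx <- bar_length / 2
  hy <- bar_width / 2

  ## chord slots: 3 per chord, at fixed fractions with fixed small jitter
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  fracs <- c(0.35, 0.5, 0.65)
  jit_along <- c(0.04, -0.04, 0.04)   # along the chord
  jit_perp  <- c(0.06, -0.06, 0.06)   # along the bar's long axis
  slots <- NULL
  for (k in seq_len(3)) {
    a <- targets[pairs[k, 1], ]
    b <- targets[pairs[k, 2], ]
    d <- (b - a) / sqrt(sum((b - a)^2))
    perp <- c(-d[2], d[1])
    for (j in seq_len(3)) {
      ctr <- a + fracs[j] * (b - a) + jit_along[j] * d + jit_perp[j] * perp
      slots <- rbind(slots, c(ctr, atan2(perp[2], perp[1])))
    }
  }
  ## inner-ring slots, tangential orientation
  ra <- pi / 6 + c(0, 1, 2, 3, 4, 5) * pi / 3
  for (a in ra) {
    ctr <- inner_ring_radius * c(cos(a), sin(a))
    slots <- rbind(slots, c(ctr, a + pi / 2))
  }
  slots <- data.frame(cx = slots[, 1], cy = slots[, 2], angle = slots[, 3],
                      hx = hx, hy = hy)

  out <- list(arena_half = arena_half, ball_radius = ball_radius,
              target_radius = target_radius, ring_radius = ring_radius,
              targets = targets, slots = slots)
  class(out) <- "dg_layout"
  validate_layout(out)
  out
}

validate_layout <- function(layout) {
  stopifnot(nrow(layout$slots) >= 1, layout$arena_half > 0)
  ring <- sqrt(rowSums(layout$targets[1:3, , drop = FALSE]^2))
  if (max(abs(ring - ring[1])) > 1e-9)
    stop("outer targets must be equidistant from the arena centre")
  ext <- max(abs(layout$slots$cx), abs(layout$slots$cy)) +
    sqrt(layout$slots$hx[1]^2 + layout$slots$hy[1]^2)
  if (ext > layout$arena_half)
    stop("obstacle slots extend outside the arena")
  invisible(layout)
}

rotate_xy <- function(xy, theta) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  xy %*% t(R)
}

#' Distance from a point to the border of a rotated rectangle
#'
#' Returns 0 when the point lies inside the rectangle.
#'
#' @param px,py point coordinates.
#' @param rect numeric vector \code{c(cx, cy, angle, hx, hy)}.
#' @return Non-negative distance in game units.
#' @keywords internal
rect_distance <- function(px, py, rect) {
  ca <- cos(rect[3]); sa <- sin(rect[3])
  dx <- px - rect[1]; dy <- py - rect[2]
  lx <- abs(ca * dx + sa * dy) - rect[4]
  ly <- abs(-sa * dx + ca * dy) - rect[5]
  sqrt(max(lx, 0)^2 + max(ly, 0)^2)
}

#' Does a segment intersect a rotated rectangle?
#'
#' Liang-Barsky clip of the segment against the rectangle in its own frame.
#'
#' @param p,q segment endpoints, numeric length-2.
#' @param rect numeric vector \code{c(cx, cy, angle, hx, hy)}.
#' @return Logical scalar.
#' @keywords internal
segment_intersects_rect <- function(p, q, rect) {
  ca <- cos(rect[3]); sa <- sin(rect[3])
  tr <- function(v) {
    dx <- v[1] - rect[1]; dy <- v[2] - rect[2]
    c(ca * dx + sa * dy, -sa * dx + ca * dy)
  }
  a <- tr(p); b <- tr(q)
  d <- b - a
  t0 <- 0; t1 <- 1
  for (i in 1:2) {
    h <- rect[3 + i]
    if (abs(d[i]) < 1e-15) {
      if (abs(a[i]) > h) return(FALSE)
    } else {
      ta <- (-h - a[i]) / d[i]
      tb <- (h - a[i]) / d[i]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}
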