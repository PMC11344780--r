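#' Generate the 60 game landscapes
#'
#' Each landscape rotates the whole layout (target ring and obstacle slots)
#' by a trial-dependent angle and activates 9 of the 15 obstacle slots,
#' rejection-sampled until every straight segment between the three initially
#' active target centres is intersected by at least one active obstacle
#' rectangle. The 9 active slots are split into three groups of three, which
#' the visibility rules map onto per-player visibility depending on the game
#' condition (see [landscape_visibility()]).
#'
#' @param seed integer seed; identical seeds give identical landscape sets.
#' @param layout a [default_layout()] object.
#' @param n number of landscapes (default 60).
#' @param max_attempts maximum rejection-sampling attempts per landscape
#'   before an infeasible-layout error is raised.
#' @return A list of \code{n} objects of class \code{dg_landscape}, each with
#'   \code{trial_index}, \code{rotation}, \code{targets} (4 x 2, row 4 = the
#'   central initially inactive target), \code{initial_active} (1:3),
#'   \code{inactive} (4), \code{active_slots} (9 slot ids), \code{groups}
#'   (list of 3 id triplets), \code{obstacles} (9 x 5 matrix
#'   \code{cx, cy, angle, hx, hy} of the rotated active rectangles) and
#'   \code{condition} (NA until a schedule assigns one).
#' @export
generate_landscapes <- function(seed, layout = default_layout(), n = 60,
                                max_attempts = 1000) {
  set.seed(seed)
  n_slots <- nrow(layout$slots)
  if (n_slots < 9)
    stop("layout is infeasible: fewer than 9 obstacle slots")
  golden <- (sqrt(5) - 1) / 2
  lapply(seq_len(n), function(i) {
    rot <- 2 * pi * ((i - 1) * golden %% 1)
    tg <- layout$targets
    tg[1:3, ] <- rotate_xy(tg[1:3, , drop = FALSE], rot)
    slot_ctr <- rotate_xy(cbind(layout$slots$cx, layout$slots$cy), rot)
    slot_ang <- layout$slots$angle + rot

    active <- NULL
    for (att in seq_len(max_attempts)) {
      cand <- sort(sample.int(n_slots, 9))
      rects <- cbind(slot_ctr[cand, 1], slot_ctr[cand, 2], slot_ang[cand],
                     layout$slots$hx[cand], layout$slots$hy[cand])
      ok <- all(apply(rbind(c(1, 2), c(1, 3), c(2, 3)), 1, function(pr) {
        any(vapply(seq_len(9), function(k)
          segment_intersects_rect(tg[pr[1], ], tg[pr[2], ], rects[k, ]),
          logical(1)))
      }))
      if (ok) { active <- cand; break }
    }
    if (is.null(active))
      stop("layout is infeasible: no 9-slot subset blocks all target pairs ",
           "after ", max_attempts, " attempts (trial ", i, ")")

    grp <- split(active[sample.int(9)], rep(1:3, each = 3))
    obstacles <- cbind(cx = slot_ctr[active, 1], cy = slot_ctr[active, 2],
                       angle = slot_ang[active],
                       hx = layout$slots$hx[active],
                       hy = layout$slots$hy[active])
    rownames(obstacles) <- active
    out <- list(trial_index = i, rotation = rot, targets = tg,
                initial_active = 1:3, inactive = 4L,
                active_slots = active, groups = unname(grp),
                obstacles = obstacles, layout = layout, condition = NA)
    class(out) <- "dg_landscape"
    out
  })
}

#' Per-slot visibility under a game condition
#'
#' In joint play SAME the two players see the same six obstacles and three
#' remain invisible to the team; in joint play DIFF three obstacles are
#' visible to both, three only to player 1 and three only to player 2 (all
#' nine are visible to the team). Individual play uses the SAME rule for the
#' single player.
#'
#' @param landscape a \code{dg_landscape}.
#' @param condition one of \code{"SAME"}, \code{"DIFF"}, \code{"individual"}.
#' @return Character vector of length 9 (one entry per active obstacle, in
#'   \code{active_slots} order) with values in
#'   \code{c("both", "p1_only", "p2_only", "none")}.
#' @export
landscape_visibility <- function(landscape, condition = landscape$condition) {
  condition <- match.arg(condition, c("SAME", "DIFF", "individual"))
  vis <- character(9)
  for (g in 1:3) {
    members <- match(landscape$groups[[g]], landscape$active_slots)
    vis[members] <- if (condition == "DIFF") {
      c("both", "p1_only", "p2_only")[g]
    } else {
      c("both", "both", "none")[g]
    }
  }
  vis
}

#' Nearest active obstacle to a point
#'
#' Minimal Euclidean distance from a point to the border of any of the nine
#' active obstacle rectangles (0 if the point is inside one). Ties are broken
#' by the lower slot id. The visibility class collapses one-sided visibility:
#' \code{"one"} covers both \code{p1_only} and \code{p2_only}.
#'
#' @param point numeric length-2.
#' @param landscape a \code{dg_landscape}.
#' @param condition game condition used to classify visibility; defaults to
#'   the condition stored on the landscape.
#' @return List with \code{slot} (slot id), \code{distance}, and
#'   \code{visibility} in \code{c("both", "one", "none")}.
#' @export
nearest_obstacle <- function(point, landscape,
                             condition = landscape$condition) {
  d <- vapply(seq_len(nrow(landscape$obstacles)), function(k)
    rect_distance(point[1], point[2], landscape$obstacles[k, ]), numeric(1))
  k <- which.min(d)  # which.min takes the first, i.e. lowest slot id
  vis <- landscape_visibility(landscape, condition)[k]
  vis <- switch(vis, p1_only = "one", p2_only = "one", vis)
  list(slot = landscape$active_slots[k], distance = d[k], visibility = vis)
}
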