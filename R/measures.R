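#' Measure one simulated session
#'
#' Computes every game-concurrent observation for one pair's session:
#' gaming behaviour (targets, obstacle time, path length per trial third;
#' complexity per trial), finger-movement basics per player (movement,
#' direction changes per third, computed on the player's input series), and
#' for joint trials the seven interpersonal coordination measures (five
#' WLCC statistics per trial and per trial third, mutual information and
#' phase slope index per trial). Trial-level values of per-third measures
#' are the mean over thirds.
#'
#' @param session a [simulate_session()] result.
#' @param params [wlcc_params()].
#' @param mi_bins equiprobable bins for mutual information.
#' @param psi_band,psi_seg_len phase-slope-index band (Hz) and Welch
#'   segment length (frames).
#' @return List with \code{trial} (tidy data frame: pair, trial, mode,
#'   player, condition, block, session, measure, value), \code{segment}
#'   (same plus \code{segment}), and \code{windows} (per joint-play WLCC
#'   window: centre frame, peak coefficient and lag, target-cycle phase,
#'   nearest-obstacle visibility class at the centre frame).
#' @export
measure_session <- function(session, params = wlcc_params(), mi_bins = 8,
                            psi_band = c(0.05, 5), psi_seg_len = 240) {
  pair <- session$profile$pair_id
  trial_rows <- list(); seg_rows <- list(); win_rows <- list()
  emit <- function(store, trial, mode, player, condition, block, sess,
                   measure, value, segment = NULL) {
    row <- data.frame(pair = pair, trial = trial, mode = mode,
                      player = player, condition = condition,
                      block = block, session = sess, measure = measure,
                      value = value)
    if (!is.null(segment)) row$segment <- segment
    row
  }

  for (tr in session$trials) {
    cond <- if (is.na(tr$condition)) "individual" else tr$condition
    for (li in seq_along(tr$logs)) {
      log <- tr$logs[[li]]
      player <- if (tr$mode == "joint") NA_integer_ else log$player
      beh <- trial_behaviour(log)
      for (m in c("targets", "obstacle_time", "path_length")) {
        seg_rows[[length(seg_rows) + 1]] <- emit(
          NULL, tr$trial, tr$mode, player, cond, tr$block, tr$session,
          m, beh[[m]], segment = beh$segment)
        trial_rows[[length(trial_rows) + 1]] <- emit(
          NULL, tr$trial, tr$mode, player, cond, tr$block, tr$session,
          m, mean(beh[[m]]))
      }
      ci <- complexity_index(log$events$target)
      trial_rows[[length(trial_rows) + 1]] <- emit(
        NULL, tr$trial, tr$mode, player, cond, tr$block, tr$session,
        "complexity", as.numeric(ci))

      players <- if (tr$mode == "joint") 1:2 else li
      for (p in players) {
        fx <- if (p == 1) log$frames$p1_in_x else log$frames$p2_in_x
        fy <- if (p == 1) log$frames$p1_in_y else log$frames$p2_in_y
        fb <- finger_basics(fx, fy)
        for (m in c("movement", "n_moves")) {
          seg_rows[[length(seg_rows) + 1]] <- emit(
            NULL, tr$trial, tr$mode, p, cond, tr$block, tr$session,
            m, fb[[m]], segment = fb$segment)
          trial_rows[[length(trial_rows) + 1]] <- emit(
            NULL, tr$trial, tr$mode, p, cond, tr$block, tr$session,
            m, mean(fb[[m]]))
        }
      }

      if (tr$mode == "joint") {
        s1 <- steering_direction(log, 1)
        s2 <- steering_direction(log, 2)
        wl <- wlcc(s1, s2, params)
        cm <- wlcc_measures(wl)
        for (m in c("synchrony", "strength_of_relation",
                    "variability_of_relation", "time_lag", "switching"))
          trial_rows[[length(trial_rows) + 1]] <- emit(
            NULL, tr$trial, tr$mode, NA_integer_, cond, tr$block,
            tr$session, m, cm[[m]])
        n_frames <- nrow(log$frames)
        seg_id <- pmin(3, wl$centers %/% (n_frames / 3) + 1)
        for (s in 1:3) {
          sm <- tryCatch(wlcc_measures(wl, windows = seg_id == s),
                         error = function(e) NULL)
          if (is.null(sm)) next
          for (m in c("synchrony", "strength_of_relation",
                      "variability_of_relation", "time_lag", "switching"))
            seg_rows[[length(seg_rows) + 1]] <- emit(
              NULL, tr$trial, tr$mode, NA_integer_, cond, tr$block,
              tr$session, m, sm[[m]], segment = s)
        }
        trial_rows[[length(trial_rows) + 1]] <- emit(
          NULL, tr$trial, tr$mode, NA_integer_, cond, tr$block,
          tr$session, "mutual_information",
          mutual_information(s1, s2, mi_bins))
        trial_rows[[length(trial_rows) + 1]] <- emit(
          NULL, tr$trial, tr$mode, NA_integer_, cond, tr$block,
          tr$session, "psi",
          phase_slope_index(s1, s2, band = psi_band,
                            seg_len = psi_seg_len))

        peaks <- pick_peaks(wl)
        phase <- window_phases(wl$centers, log$events$frame)
        cfr <- pmin(n_frames, round(wl$centers) + 1)
        win_rows[[length(win_rows) + 1]] <- data.frame(
          pair = pair, trial = tr$trial, condition = cond,
          block = tr$block, session = tr$session, center = wl$centers,
          peak_r = peaks[, 1], peak_lag = peaks[, 2], phase = phase,
          nearest_vis = log$frames$nearest_vis[cfr])
      }
    }
  }
  list(trial = do.call(rbind, trial_rows),
       segment = do.call(rbind, seg_rows),
       windows = if (length(win_rows)) do.call(rbind, win_rows) else NULL)
}

## target-cycle phase of each window centre: fraction of the interval
## between the two surrounding collections that has elapsed. Windows before
## the first or after the last collection get NA (interior intervals only);
## a centre exactly at a collection frame starts the next interval (phase 0).
window_phases <- function(centers, event_frames) {
  phase <- rep(NA_real_, length(centers))
  ev <- sort(event_frames)
  if (length(ev) < 2) return(phase)
  for (i in seq_along(centers)) {
    ct <- centers[i]
    prev <- ev[ev <= ct]
    nxt <- ev[ev > ct]
    if (!length(prev) || !length(nxt)) next
    p <- prev[length(prev)]; q <- nxt[1]
    phase[i] <- (ct - p) / (q - p)
  }
  phase
}

#' Measure a whole cohort
#'
#' Applies [measure_session()] to every session and binds the results.
#'
#' @param sessions list of \code{dg_session}.
#' @param ... passed to [measure_session()].
#' @return List with combined \code{trial}, \code{segment}, \code{windows}
#'   tables.
#' @export
measure_cohort <- function(sessions, ...) {
  res <- lapply(sessions, measure_session, ...)
  list(trial = do.call(rbind, lapply(res, `[[`, "trial")),
       segment = do.call(rbind, lapply(res, `[[`, "segment")),
       windows = do.call(rbind, lapply(res, `[[`, "windows")))
}
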