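#' Assemble the pair-by-block analysis table
#'
#' One row per pair and joint block (12 blocks; 23 pairs give 276 rows).
#' Outcomes are the block's experience ratings averaged over the two
#' players, with engagement arcsine-transformed (asin(sqrt(r/100))) before
#' averaging. Predictors are the block means (over the block's trials,
#' trial values being third-averages) of the 4 gaming-behaviour and 9
#' finger-movement measures (basics averaged across players), plus the 7
#' absolute within-pair personality-difference scores, a continuous time
#' covariate (block 1-12), the game condition and the session. All
#' predictors are z-scored over the table's rows; the scaling is stored in
#' \code{attr(, "scale")}.
#'
#' @param measures a [measure_cohort()] result (or one session's measures).
#' @param ratings combined [synthesize_ratings()] rows for all pairs.
#' @param profiles list of [sample_pair_profile()] objects.
#' @param z_score z-score the predictors (default TRUE).
#' @return Data frame of class \code{dg_block_table}.
#' @export
assemble_block_table <- function(measures, ratings, profiles,
                                 z_score = TRUE) {
  tm <- measures$trial
  tm <- tm[tm$mode == "joint", , drop = FALSE]
  behaviour_m <- c("targets", "obstacle_time", "path_length", "complexity")
  finger_m <- c("movement", "n_moves", "synchrony", "strength_of_relation",
                "variability_of_relation", "time_lag", "switching",
                "mutual_information", "psi")
  trait_names <- c("neuroticism", "extraversion", "openness",
                   "agreeableness", "conscientiousness", "AQ", "empathy")
  prof_by_id <- stats::setNames(profiles,
                                vapply(profiles, function(p)
                                  as.character(p$pair_id), character(1)))

  rows <- list()
  for (pid in sort(unique(tm$pair))) {
    pm <- tm[tm$pair == pid, , drop = FALSE]
    prof <- prof_by_id[[as.character(pid)]]
    tdiff <- abs(prof$traits[1, trait_names] - prof$traits[2, trait_names])
    pr <- ratings[ratings$pair == pid & !is.na(ratings$block), ,
                  drop = FALSE]
    for (b in 1:12) {
      bm <- pm[pm$block %in% b, , drop = FALSE]
      if (!nrow(bm))
        stop("missing measures for pair ", pid, " block ", b)
      vals <- vapply(c(behaviour_m, finger_m), function(m)
        mean(bm$value[bm$measure == m]), numeric(1))
      br <- pr[pr$block == b, , drop = FALSE]
      if (!nrow(br))
        stop("missing ratings for pair ", pid, " block ", b)
      eng <- mean(asin(sqrt(br$value[br$construct == "engagement"] / 100)))
      agr <- mean(br$value[br$construct == "agreement"])
      pre <- mean(br$value[br$construct == "predictability"])
      rows[[length(rows) + 1]] <- data.frame(
        pair = pid, block = b, time = b,
        condition = bm$condition[1], session = bm$session[1],
        engagement = eng, agreement = agr, predictability = pre,
        as.list(vals), as.list(tdiff))
    }
  }
  out <- do.call(rbind, rows)
  out$condition <- factor(out$condition, levels = c("DIFF", "SAME"))
  pred_cols <- c(behaviour_m, finger_m, trait_names, "time")
  scale <- list(mean = numeric(0), sd = numeric(0))
  if (z_score) {
    for (m in pred_cols) {
      mu <- mean(out[[m]]); sd_ <- stats::sd(out[[m]])
      scale$mean[m] <- mu; scale$sd[m] <- sd_
      out[[m]] <- if (is.finite(sd_) && sd_ > 0) (out[[m]] - mu) / sd_
                  else out[[m]] - mu
    }
  }
  attr(out, "scale") <- scale
  attr(out, "predictors") <- c(pred_cols, "condition")
  class(out) <- c("dg_block_table", class(out))
  out
}
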