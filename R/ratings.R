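#' Generative coefficients for synthetic experience ratings
#'
#' The generative twin of the rating analysis: block-level latent experience
#' is a linear combination of (z-scored) game measures plus a pair random
#' intercept and AR(1) residual noise over blocks, mapped to the 0-100
#' rating scale as \code{round(50 + 12 * latent)} with per-player jitter
#' added before rounding. Default coefficients carry the signs of the
#' engagement/agreement/predictability models this package's analysis layer
#' is designed to recover (targets +, variability of relation +, synchrony +
#' and path length / time / condition-SAME - for engagement), at moderate
#' standardised magnitudes.
#'
#' @param sigma_u pair random-intercept SD (latent scale).
#' @param rho AR(1) correlation of block-level residuals, |rho| < 1.
#' @param sigma_e marginal residual SD (latent scale).
#' @param jitter_sd per-player rating jitter SD (rating points).
#' @return A list of class \code{dg_rating_coeffs}; element \code{constructs}
#'   maps each construct to an intercept and named coefficient vector.
#' @export
default_rating_coeffs <- function(sigma_u = 0.5, rho = 0.5, sigma_e = 0.7,
                                  jitter_sd = 3) {
  stopifnot(abs(rho) < 1, sigma_u >= 0, sigma_e >= 0)
  constructs <- list(
    engagement = list(intercept = 0.3, coef = c(
      targets = 0.5, variability_of_relation = 0.35, synchrony = 0.3,
      path_length = -0.35, time = -0.3, condition_same = -0.2)),
    agreement = list(intercept = 0.2, coef = c(
      targets = 0.5, variability_of_relation = 0.3, path_length = 0.3)),
    predictability = list(intercept = 0.2, coef = c(
      targets = 0.5, variability_of_relation = 0.3)),
    ball_control = list(intercept = 0, coef = c(time = 0.5)))
  out <- list(constructs = constructs, sigma_u = sigma_u, rho = rho,
              sigma_e = sigma_e, jitter_sd = jitter_sd,
      scale_centre = 50, scale_slope = 12)
  class(out) <- "dg_rating_coeffs"
  out
}

## stationary AR(1) noise of length n, marginal SD sigma
ar1_noise <- function(n, rho, sigma) {
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sigma)
  if (n > 1)
    for (t in 2:n) e[t] <- rho * e[t - 1] + rnorm(1, 0, sigma *
                                                    sqrt(1 - rho^2))
  e
}

to_rating <- function(latent, coeffs, jitter) {
  pmin(100, pmax(0, round(coeffs$scale_centre +
                            coeffs$scale_slope * latent + jitter)))
}

#' Synthesize one pair's experience ratings
#'
#' Generates integer 0-100 ratings at the 16 rating moments: ball control at
#' the four individual-play moments (trials 5, 10, 55, 60), agreement and
#' predictability at the twelve joint moments (block ends), and engagement
#' at all moments. Joint-moment latents are driven by the pair's block-level
#' game measures; individual-moment latents use only the intercept, time
#' trend and pair effect.
#'
#' @param session_measures data frame with one row per joint block (column
#'   \code{block} = 1..12, plus \code{condition} and the measure columns
#'   named in the coefficients, e.g. \code{targets},
#'   \code{variability_of_relation}, \code{synchrony}, \code{path_length}).
#' @param profile the pair's [sample_pair_profile()].
#' @param coeffs a [default_rating_coeffs()] object.
#' @param seed integer seed.
#' @param scale optional list of \code{mean}/\code{sd} named vectors used to
#'   z-score the measure columns (pass cohort-level scaling when generating
#'   many pairs); when NULL the pair's own rows are used.
#' @return Data frame (\code{dg_rating_set}) with columns \code{pair},
#'   \code{trial}, \code{block}, \code{player}, \code{construct},
#'   \code{value}.
#' @export
synthesize_ratings <- function(session_measures, profile,
                               coeffs = default_rating_coeffs(), seed = 1,
                               scale = NULL) {
  missing_blocks <- setdiff(1:12, session_measures$block)
  if (length(missing_blocks))
    stop("missing block measures for block(s) ",
         paste(missing_blocks, collapse = ", "))
  sm <- session_measures[order(session_measures$block), , drop = FALSE]
  set.seed(seed)

  measure_cols <- unique(unlist(lapply(coeffs$constructs, function(cc)
    setdiff(names(cc$coef), c("time", "condition_same")))))
  measure_cols <- intersect(measure_cols, names(sm))
  z <- sm[measure_cols]
  for (m in measure_cols) {
    mu <- if (is.null(scale)) mean(z[[m]]) else scale$mean[[m]]
    sd_ <- if (is.null(scale)) stats::sd(z[[m]]) else scale$sd[[m]]
    z[[m]] <- if (is.finite(sd_) && sd_ > 0) (z[[m]] - mu) / sd_ else 0
  }
  time_z <- (sm$block - 6.5) / stats::sd(1:12)
  cond_same <- as.numeric(sm$condition == "SAME") - 0.5

  joint_trials <- c(14, 17, 20, 24, 27, 30, 34, 37, 40, 44, 47, 50)
  ind_trials <- c(5, 10, 55, 60)
  ind_time <- (c(3, 8, 53, 58) - 30.5) / (stats::sd(1:12) * 40 / 12)

  rows <- list()
  for (construct in names(coeffs$constructs)) {
    cc <- coeffs$constructs[[construct]]
    u <- rnorm(1, 0, coeffs$sigma_u)
    if (construct %in% c("engagement", "agreement", "predictability")) {
      lp <- rep(cc$intercept, 12)
      for (m in names(cc$coef)) {
        xm <- switch(m, time = time_z, condition_same = cond_same,
                     if (m %in% names(z)) z[[m]] else NULL)
        if (!is.null(xm)) lp <- lp + cc$coef[[m]] * xm
      }
      latent <- lp + u + ar1_noise(12, coeffs$rho, coeffs$sigma_e)
      for (p in 1:2)
        rows[[length(rows) + 1]] <- data.frame(
          pair = profile$pair_id, trial = joint_trials, block = 1:12,
          player = p, construct = construct,
          value = to_rating(latent, coeffs,
                            rnorm(12, 0, coeffs$jitter_sd)))
    }
    if (construct %in% c("engagement", "ball_control")) {
      tc <- if ("time" %in% names(cc$coef)) cc$coef[["time"]] else 0
      latent <- cc$intercept + tc * ind_time + u +
        rnorm(4, 0, coeffs$sigma_e)
      for (p in 1:2)
        rows[[length(rows) + 1]] <- data.frame(
          pair = profile$pair_id, trial = ind_trials, block = NA_integer_,
          player = p, construct = construct,
          value = to_rating(latent, coeffs,
                            rnorm(4, 0, coeffs$jitter_sd)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dg_rating_set", class(out))
  out
}
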