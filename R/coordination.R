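#' Steering direction series of one player
#'
#' The angle of the player's 2-D input, theta = atan2(in_y, in_x), in
#' (-pi, pi]. Frames with input magnitude at or below \code{eps} carry no
#' direction and are masked invalid.
#'
#' @param trial_log a \code{dg_trial_log}.
#' @param player 1 or 2.
#' @param eps magnitude threshold below which the direction is undefined.
#' @return A \code{dg_steering}: list with \code{theta}, \code{magnitude},
#'   \code{valid} (logical), all of trial length.
#' @export
steering_direction <- function(trial_log, player = 1, eps = 1e-6) {
  fx <- if (player == 1) trial_log$frames$p1_in_x else trial_log$frames$p2_in_x
  fy <- if (player == 1) trial_log$frames$p1_in_y else trial_log$frames$p2_in_y
  mag <- sqrt(fx^2 + fy^2)
  valid <- mag > eps
  theta <- ifelse(valid, atan2(fy, fx), NA_real_)
  structure(list(theta = theta, magnitude = mag, valid = valid),
            class = "dg_steering")
}

#' WLCC parameters
#'
#' Defaults: 2 s windows (120 frames) advanced in 0.5 s steps (30 frames),
#' lags up to +-1 s (60 frames), and windows computed only when at least 75
#' percent of the overlapping frames are valid.
#'
#' @param window_len,window_step,max_lag in frames.
#' @param min_valid_fraction minimum fraction of valid overlapping frames.
#' @param circular per-window treatment of the angular seam before ranking:
#'   \code{"rotate"} (default) centres each window at its circular mean and
#'   re-wraps to (-pi, pi], which is robust to noisy dwelling near the seam;
#'   \code{"unwrap"} cumulatively unwraps the window instead.
#' @export
wlcc_params <- function(window_len = 120, window_step = 30, max_lag = 60,
                        min_valid_fraction = 0.75,
                        circular = c("rotate", "unwrap")) {
  stopifnot(window_len >= 8, max_lag >= 1, window_step >= 1,
            min_valid_fraction > 0, min_valid_fraction <= 1)
  structure(list(window_len = window_len, window_step = window_step,
                 max_lag = max_lag,
                 min_valid_fraction = min_valid_fraction,
                 circular = match.arg(circular)),
            class = "dg_wlcc_params")
}

## centre each column at its circular mean and wrap to (-pi, pi]
circ_rotate_cols <- function(m) {
  mu <- atan2(colMeans(sin(m)), colMeans(cos(m)))
  d <- sweep(m, 2, mu)
  (d + pi) %% (2 * pi) - pi
}

circ_transform_cols <- function(m, circular) {
  if (circular == "rotate") circ_rotate_cols(m) else unwrap_cols(m)
}

circ_transform <- function(x, circular) {
  if (circular == "rotate") {
    mu <- atan2(mean(sin(x)), mean(cos(x)))
    (x - mu + pi) %% (2 * pi) - pi
  } else unwrap_angle(x)
}

## unwrap an angle series (gaps treated as contiguous)
unwrap_angle <- function(theta) {
  ok <- !is.na(theta)
  x <- theta[ok]
  if (length(x) > 1) {
    d <- diff(x)
    d <- (d + pi) %% (2 * pi) - pi
    x <- x[1] + c(0, cumsum(d))
  }
  theta[ok] <- x
  theta
}

## columnwise unwrap of an angle matrix without NAs
unwrap_cols <- function(m) {
  if (nrow(m) < 2) return(m)
  d <- m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE]
  d <- (d + pi) %% (2 * pi) - pi
  first <- m[1, ]
  rbind(first, matrix(first, nrow(m) - 1, ncol(m), byrow = TRUE) +
          apply(d, 2, cumsum))
}

## columnwise rank then standardize to zero mean / unit sum of squares
rank_std_cols <- function(m) {
  r <- cpp_colranks(m)
  r <- sweep(r, 2, colMeans(r))
  ss <- sqrt(colSums(r^2))
  ss[ss == 0] <- NA
  sweep(r, 2, ss, "/")
}

spearman_pair <- function(x, y, min_n, circular = "rotate") {
  v <- !is.na(x) & !is.na(y)
  if (sum(v) < min_n) return(NA_real_)
  xu <- circ_transform(x[v], circular)
  yu <- circ_transform(y[v], circular)
  if (stats::sd(xu) == 0 || stats::sd(yu) == 0) return(NA_real_)
  stats::cor(xu, yu, method = "spearman")
}

#' Windowed lagged cross-correlation of two steering series
#'
#' For each window start (advancing by \code{window_step}) and each lag in
#' \code{-max_lag:max_lag}, the Spearman rank correlation between the first
#' series over the window and the second series shifted by the lag. Each
#' window is first centred at its circular mean and re-wrapped (or
#' cumulatively unwrapped, see [wlcc_params()]) so the -pi/pi seam does not
#' corrupt the ranks. A positive lag means the second series
#' is read later in time, i.e. the first player leads. Cells whose valid
#' overlap is below \code{min_valid_fraction * window_len} (including
#' shifted windows running off the trial edges) are missing.
#'
#' @param a,b \code{dg_steering} series of equal length.
#' @param params a [wlcc_params()].
#' @return A \code{dg_wlcc}: list with \code{r} (windows x lags matrix),
#'   \code{centers} (0-based window centre frames), \code{lags},
#'   \code{params}.
#' @export
wlcc <- function(a, b, params = wlcc_params()) {
  ta <- a$theta; tb <- b$theta
  if (length(ta) != length(tb)) stop("series lengths differ")
  n <- length(ta)
  w <- params$window_len
  if (n < w) stop("series shorter than window_len")
  L <- params$max_lag
  starts <- seq(1, n - w + 1, by = params$window_step)
  lags <- -L:L
  min_n <- max(3, ceiling(params$min_valid_fraction * w))

  ## pad b so shifted windows run off the edge into NA
  tbp <- c(rep(NA_real_, L), tb, rep(NA_real_, L))

  amat <- vapply(starts, function(s) ta[s:(s + w - 1)], numeric(w))
  amat <- matrix(amat, nrow = w)
  a_clean <- colSums(is.na(amat)) == 0
  astd <- matrix(NA_real_, w, length(starts))
  if (any(a_clean))
    astd[, a_clean] <- rank_std_cols(circ_transform_cols(
      amat[, a_clean, drop = FALSE], params$circular))

  b_starts <- sort(unique(as.vector(outer(starts, lags, "+")))) # in tb frame
  bmat <- vapply(b_starts, function(s) tbp[(s + L):(s + L + w - 1)],
                 numeric(w))
  bmat <- matrix(bmat, nrow = w)
  b_clean <- colSums(is.na(bmat)) == 0
  bstd <- matrix(NA_real_, w, length(b_starts))
  if (any(b_clean))
    bstd[, b_clean] <- rank_std_cols(circ_transform_cols(
      bmat[, b_clean, drop = FALSE], params$circular))

  r <- matrix(NA_real_, length(starts), length(lags))
  for (j in seq_along(lags)) {
    cols <- match(starts + lags[j], b_starts)
    fast <- a_clean & b_clean[cols] & !is.na(astd[1, ]) & !is.na(bstd[1, cols])
    if (any(fast))
      r[fast, j] <- colSums(astd[, fast, drop = FALSE] *
                              bstd[, cols[fast], drop = FALSE])
    slow <- which(!fast)
    for (i in slow) {
      s <- starts[i]
      r[i, j] <- spearman_pair(ta[s:(s + w - 1)],
                               tbp[(s + lags[j] + L):(s + lags[j] + L + w - 1)],
                               min_n, params$circular)
    }
  }
  structure(list(r = r, centers = (starts - 1) + (w - 1) / 2, lags = lags,
                 params = params), class = "dg_wlcc")
}

## per-window peak picking: among interior local maxima of the signed
## coefficient take the largest (ties -> smaller |lag|); with no interior
## local maximum, the global maximum. rule = "nearest" instead picks the
## local maximum closest to lag zero.
pick_peaks <- function(wl, rule = c("largest", "nearest")) {
  rule <- match.arg(rule)
  lags <- wl$lags
  t(apply(wl$r, 1, function(row) {
    ok <- which(!is.na(row))
    if (length(ok) < 1) return(c(NA_real_, NA_real_))
    cand <- ok[ok > 1 & ok < length(row)]
    cand <- cand[!is.na(row[cand - 1]) & !is.na(row[cand + 1]) &
                   row[cand] >= row[cand - 1] & row[cand] >= row[cand + 1]]
    if (!length(cand)) cand <- ok
    o <- if (rule == "largest") {
      order(-row[cand], abs(lags[cand]))
    } else {
      order(abs(lags[cand]), -row[cand])
    }
    j <- cand[o[1]]
    c(row[j], lags[j])
  }))
}

#' Aggregate WLCC statistics
#'
#' The five WLCC-derived coordination measures: \emph{synchrony} (grand mean
#' coefficient across all windows and lags), \emph{strength of relation}
#' (mean peak-picked coefficient), \emph{variability of relation} (sample SD
#' of peak coefficients), \emph{time lag} (mean absolute peak lag, frames)
#' and \emph{switching} (sample SD of signed peak lags, frames).
#'
#' @param wl a [wlcc()] result.
#' @param windows optional logical/integer subset of windows (e.g. those
#'   whose centres fall in one trial segment).
#' @param peak_rule peak-picking rule, see Details in [wlcc()].
#' @return Named list with \code{synchrony}, \code{strength_of_relation},
#'   \code{variability_of_relation}, \code{time_lag}, \code{switching},
#'   \code{n_windows}.
#' @export
wlcc_measures <- function(wl, windows = NULL,
                          peak_rule = c("largest", "nearest")) {
  r <- wl$r
  wl2 <- wl
  if (!is.null(windows)) {
    r <- r[windows, , drop = FALSE]
    wl2$r <- r
  }
  if (!nrow(r) || all(is.na(r))) stop("all WLCC cells missing")
  peaks <- pick_peaks(wl2, match.arg(peak_rule))
  pc <- peaks[, 1]; pl <- peaks[, 2]
  ok <- !is.na(pc)
  if (sum(ok) < 2) stop("need at least 2 non-missing windows")
  list(synchrony = mean(r, na.rm = TRUE),
       strength_of_relation = mean(pc[ok]),
       variability_of_relation = stats::sd(pc[ok]),
       time_lag = mean(abs(pl[ok])),
       switching = stats::sd(pl[ok]),
       n_windows = sum(ok))
}

#' Mutual information between two steering series
#'
#' Plug-in estimate on equiprobable marginal bins (each series cut at its own
#' empirical quantiles so every marginal bin holds the same count), base 2.
#' The optional Miller-Madow flag adds the first-order bias correction
#' \eqn{(m_x + m_y - m_{xy} - 1) / (2 N \ln 2)} with \eqn{m} the occupied
#' bin counts.
#'
#' @param a,b \code{dg_steering} series.
#' @param n_bins marginal bins (default 8).
#' @param corrected apply the Miller-Madow correction.
#' @return MI in bits (non-negative up to the correction).
#' @export
mutual_information <- function(a, b, n_bins = 8, corrected = FALSE) {
  v <- a$valid & b$valid
  x <- a$theta[v]; y <- b$theta[v]
  n <- length(x)
  if (n < 10 * n_bins)
    stop("too few jointly valid frames (", n, ") for ", n_bins, " bins")
  bx <- ceiling(rank(x, ties.method = "first") * n_bins / n)
  by <- ceiling(rank(y, ties.method = "first") * n_bins / n)
  jt <- table(bx, by) / n
  px <- rowSums(jt); py <- colSums(jt)
  nz <- jt > 0
  mi <- sum(jt[nz] * log2(jt[nz] / outer(px, py)[nz]))
  if (corrected)
    mi <- mi + (sum(px > 0) + sum(py > 0) - sum(nz) - 1) / (2 * n * log(2))
  mi
}

#' Phase slope index between two steering series
#'
#' Directed coupling from Welch cross-spectra of the globally unwrapped
#' steering angles: the imaginary part of the frequency-slope of complex
#' coherency summed over the analysis band. Positive values mean the first
#' series leads the second (the second is a delayed copy/echo of the first).
#' Masked frames are linearly interpolated before unwrapping.
#'
#' @param a,b \code{dg_steering} series.
#' @param band analysis band in Hz (must lie inside (0, fs/2]).
#' @param seg_len Welch segment length in frames (default 240 = 4 s).
#' @param overlap segment overlap fraction (default 0.5).
#' @param fs sampling rate, Hz.
#' @param jackknife normalise by the jackknife SD over segments.
#' @return Signed scalar (unitless; jackknifed value is a z-like score).
#' @export
phase_slope_index <- function(a, b, band = c(0.05, 5), seg_len = 240,
                              overlap = 0.5, fs = 60, jackknife = FALSE) {
  if (band[2] > fs / 2 || band[1] <= 0 || band[1] >= band[2])
    stop("band outside (0, Nyquist]")
  x <- interp_na(unwrap_angle(a$theta))
  y <- interp_na(unwrap_angle(b$theta))
  n <- length(x)
  step <- max(1, round(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  if (length(starts) < 4) stop("series shorter than 4 Welch segments")
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  nf <- seg_len %/% 2 + 1
  cross <- function(idx) {
    Sxy <- complex(real = numeric(nf), imaginary = numeric(nf))
    Sxx <- Syy <- numeric(nf)
    for (s in starts[idx]) {
      xs <- x[s:(s + seg_len - 1)]; ys <- y[s:(s + seg_len - 1)]
      X <- stats::fft(win * (xs - mean(xs)))[1:nf]
      Y <- stats::fft(win * (ys - mean(ys)))[1:nf]
      Sxy <- Sxy + X * Conj(Y)
      Sxx <- Sxx + Mod(X)^2
      Syy <- Syy + Mod(Y)^2
    }
    C <- Sxy / sqrt(Sxx * Syy)
    freq <- (seq_len(nf) - 1) * fs / seg_len
    bi <- which(freq >= band[1] & freq <= band[2])
    bi <- bi[bi < nf]
    sum(Im(Conj(C[bi[-length(bi)]]) * C[bi[-1]]))
  }
  psi <- cross(seq_along(starts))
  if (jackknife) {
    jk <- vapply(seq_along(starts), function(k)
      cross(setdiff(seq_along(starts), k)), numeric(1))
    m <- length(jk)
    se <- sqrt((m - 1) / m * sum((jk - mean(jk))^2))
    if (se > 0) psi <- psi / se
  }
  psi
}

interp_na <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (!length(idx)) stop("all frames masked")
  stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
}

#' Surrogate-dyad synchrony baseline
#'
#' Pairs player 1 of one pair with player 2 of a different pair on trials
#' where both navigated the same landscape under the same joint condition,
#' and computes the WLCC measures for every such surrogate dyad. This
#' isolates the part of movement similarity induced by the shared landscape
#' rather than by real-time mutual coupling.
#'
#' @param sessions list of \code{dg_session} objects (all pairs).
#' @param params a [wlcc_params()].
#' @param seed seed used when subsampling pairings.
#' @param max_pairings cap on ordered pairings per landscape x condition;
#'   beyond it a random subset is drawn.
#' @return Data frame with landscape, condition, the two source pairs and
#'   the five WLCC measures per surrogate dyad.
#' @export
surrogate_synchrony <- function(sessions, params = wlcc_params(), seed = 1,
                                max_pairings = 50) {
  if (length(sessions) < 2) stop("need at least 2 pairs")
  set.seed(seed)
  ## index joint trials by landscape x condition
  key_tab <- list()
  for (si in seq_along(sessions)) {
    for (tr in sessions[[si]]$trials) {
      if (tr$mode != "joint") next
      key <- paste(tr$landscape_index, tr$condition, sep = "|")
      key_tab[[key]] <- rbind(key_tab[[key]], c(si, tr$trial))
    }
  }
  rows <- list()
  for (key in names(key_tab)) {
    entries <- key_tab[[key]]
    if (nrow(entries) < 2) next
    prs <- expand.grid(i = seq_len(nrow(entries)), j = seq_len(nrow(entries)))
    prs <- prs[prs$i != prs$j, , drop = FALSE]
    if (nrow(prs) > max_pairings)
      prs <- prs[sample.int(nrow(prs), max_pairings), , drop = FALSE]
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    for (k in seq_len(nrow(prs))) {
      e1 <- entries[prs$i[k], ]; e2 <- entries[prs$j[k], ]
      log1 <- sessions[[e1[1]]]$trials[[e1[2]]]$logs[[1]]
      log2 <- sessions[[e2[1]]]$trials[[e2[2]]]$logs[[1]]
      m <- wlcc_measures(wlcc(steering_direction(log1, 1),
                              steering_direction(log2, 2), params))
      rows[[length(rows) + 1]] <- data.frame(
        landscape = as.integer(parts[1]), condition = parts[2],
        pair1 = sessions[[e1[1]]]$profile$pair_id,
        pair2 = sessions[[e2[1]]]$profile$pair_id,
        synchrony = m$synchrony,
        strength_of_relation = m$strength_of_relation,
        variability_of_relation = m$variability_of_relation,
        time_lag = m$time_lag, switching = m$switching)
    }
  }
  if (!length(rows)) stop("no landscape/condition shared by 2+ pairs")
  do.call(rbind, rows)
}
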