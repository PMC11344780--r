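#' Fit a linear mixed model with pair random intercept and AR(1) residuals
#'
#' Restricted maximum likelihood fit of
#' \deqn{y_{ib} = x_{ib}' \beta + u_i + e_{ib}}
#' with pair random intercepts \eqn{u_i \sim N(0, \sigma_u^2)} and residuals
#' following a first-order autoregressive correlation over blocks within
#' pair, i.e. per-pair marginal covariance
#' \eqn{\sigma_u^2 J + \sigma_e^2 R(\rho)} with
#' \eqn{R_{bc} = \rho^{|t_b - t_c|}}. The restricted likelihood is profiled
#' over \eqn{\sigma_e^2} and optimised over
#' \eqn{(\rho, \lambda = \sigma_u^2/\sigma_e^2)}. Fixed-effect t tests use
#' the residual degrees-of-freedom approximation \eqn{N - p}.
#'
#' @param data data frame; must contain \code{pair}, the ordering column
#'   \code{time_col}, the outcome and all predictors.
#' @param outcome outcome column name.
#' @param predictors character vector of fixed-effect columns (factors
#'   allowed).
#' @param time_col column giving within-pair temporal position (AR(1)
#'   distances), default \code{"block"}.
#' @param rho_fix,lambda_fix optionally fix the correlation and/or variance
#'   ratio instead of estimating them.
#' @return Object of class \code{dg_lmm}: coefficient table
#'   (\code{estimate}, \code{se}, \code{t}, \code{p}), \code{sigma_e},
#'   \code{sigma_u}, \code{rho}, \code{logREML}, \code{df}, convergence
#'   info, and the pieces needed for fixed-effect prediction.
#' @export
fit_lmm_ar1 <- function(data, outcome, predictors, time_col = "block",
                        rho_fix = NULL, lambda_fix = NULL) {
  data <- data[order(data$pair, data[[time_col]]), , drop = FALSE]
  trm <- stats::terms(stats::reformulate(predictors))
  mf <- stats::model.frame(trm, data)
  X <- stats::model.matrix(trm, mf)
  y <- data[[outcome]]
  if (anyNA(y) || anyNA(X)) stop("missing values in outcome or predictors")
  pairs <- split(seq_len(nrow(data)), data$pair)
  times <- data[[time_col]]
  N <- length(y); p <- ncol(X)

  profile_fit <- function(rho, lambda) {
    XtVX <- matrix(0, p, p); XtVy <- numeric(p); ytVy <- 0; logdet <- 0
    for (ix in pairs) {
      ti <- times[ix]
      R <- rho^abs(outer(ti, ti, "-"))
      V0 <- lambda + R   # lambda * J + R
      U <- tryCatch(chol(V0), error = function(e) NULL)
      if (is.null(U)) return(NULL)
      logdet <- logdet + 2 * sum(log(diag(U)))
      Xi <- backsolve(U, X[ix, , drop = FALSE], transpose = TRUE)
      yi <- backsolve(U, y[ix], transpose = TRUE)
      XtVX <- XtVX + crossprod(Xi)
      XtVy <- XtVy + crossprod(Xi, yi)
      ytVy <- ytVy + sum(yi^2)
    }
    ch <- tryCatch(chol(XtVX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, backsolve(ch, XtVy, transpose = TRUE))
    rss <- ytVy - sum(beta * XtVy)
    if (rss <= 0) return(NULL)
    sigma2 <- rss / (N - p)
    crit <- (N - p) * log(sigma2) + logdet + 2 * sum(log(diag(ch)))
    list(crit = crit, beta = drop(beta), sigma2 = sigma2, XtVX = XtVX)
  }

  obj <- function(par) {
    rho <- if (is.null(rho_fix)) tanh(par[["z"]]) else rho_fix
    lambda <- if (is.null(lambda_fix)) exp(par[["l"]]) else lambda_fix
    f <- profile_fit(rho, lambda)
    if (is.null(f)) 1e10 else f$crit
  }

  free <- c(if (is.null(rho_fix)) "z", if (is.null(lambda_fix)) "l")
  trace <- NULL
  if (length(free) == 0) {
    rho <- rho_fix; lambda <- lambda_fix; converged <- TRUE
  } else {
    starts <- expand.grid(z = atanh(c(0, 0.5)), l = log(c(0.2, 1)))
    best <- NULL
    for (k in seq_len(nrow(starts))) {
      par0 <- unlist(starts[k, free, drop = FALSE])
      op <- tryCatch(
        stats::optim(par0, obj, method = if (length(free) == 1) "Brent"
                     else "Nelder-Mead",
                     lower = if (length(free) == 1) -8 else -Inf,
                     upper = if (length(free) == 1) 8 else Inf),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value))
        best <- op
    }
    if (is.null(best) || best$value >= 1e10)
      stop("REML optimisation failed to converge; trace: ",
           paste(utils::capture.output(str(best)), collapse = " "))
    trace <- best
    converged <- best$convergence == 0
    rho <- if (is.null(rho_fix)) tanh(best$par[["z"]]) else rho_fix
    lambda <- if (is.null(lambda_fix)) exp(best$par[["l"]]) else lambda_fix
  }
  f <- profile_fit(rho, lambda)
  if (is.null(f)) stop("REML fit failed at the optimum")
  vcov_beta <- f$sigma2 * solve(f$XtVX)
  se <- sqrt(diag(vcov_beta))
  tval <- f$beta / se
  df <- N - p
  coef_tab <- data.frame(term = colnames(X), estimate = f$beta, se = se,
                         t = tval, p = 2 * stats::pt(-abs(tval), df),
                         row.names = NULL)
  ## map coefficient rows to predictor terms (for elimination)
  assign <- attr(X, "assign")
  term_labels <- attr(trm, "term.labels")
  coef_tab$predictor <- c("(Intercept)", term_labels)[assign + 1]
  out <- list(coefficients = coef_tab, sigma_e = sqrt(f$sigma2),
              sigma_u = sqrt(lambda * f$sigma2), rho = rho,
              lambda = lambda, logREML = -0.5 * f$crit, df = df, N = N,
              converged = converged, trace = trace, outcome = outcome,
              predictors = predictors, terms = trm,
              xlevels = stats::.getXlevels(trm, mf))
  class(out) <- "dg_lmm"
  out
}

#' @export
print.dg_lmm <- function(x, ...) {
  cat("AR(1) random-intercept LMM (REML), outcome:", x$outcome, "\n")
  cat(sprintf("sigma_u = %.4f, sigma_e = %.4f, rho = %.3f, df = %d\n",
              x$sigma_u, x$sigma_e, x$rho, x$df))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Fixed-effects prediction from a fitted LMM
#'
#' @param object a \code{dg_lmm}.
#' @param newdata data frame with the predictor columns.
#' @param ... unused.
#' @return Numeric vector of X beta (no random effects).
#' @export
predict.dg_lmm <- function(object, newdata, ...) {
  X <- stats::model.matrix(object$terms,
                           stats::model.frame(object$terms, newdata,
                                              xlev = object$xlevels))
  drop(X %*% object$coefficients$estimate)
}

#' Backward elimination of fixed effects
#'
#' Iteratively refits the model, dropping the fixed-effect term with the
#' largest p value above \code{alpha}, until every remaining term is
#' significant. The random intercept and the AR(1) structure are never
#' eliminated; the intercept is always retained.
#'
#' @param data,outcome,predictors,time_col as in [fit_lmm_ar1()].
#' @param alpha retention threshold (default 0.05).
#' @return List with \code{fit} (final \code{dg_lmm}), \code{retained}
#'   (character), \code{trace} (data frame: step, dropped term, its p).
#' @export
backward_eliminate <- function(data, outcome, predictors, alpha = 0.05,
                               time_col = "block") {
  current <- predictors
  trace <- data.frame(step = integer(0), dropped = character(0),
                      p = numeric(0))
  step <- 0L
  repeat {
    fit <- fit_lmm_ar1(data, outcome, current, time_col = time_col)
    ct <- fit$coefficients[fit$coefficients$predictor != "(Intercept)", ]
    worst <- ct[which.max(ct$p), ]
    if (!nrow(worst) || worst$p <= alpha) break
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step,
                                     dropped = worst$predictor,
                                     p = worst$p))
    current <- setdiff(current, worst$predictor)
    if (!length(current)) {
      fit <- fit_lmm_ar1(data, outcome, "1", time_col = time_col)
      break
    }
  }
  list(fit = fit, retained = setdiff(current, "1"), trace = trace)
}

#' Repeated-measures correlation
#'
#' Common within-group linear association after removing group intercepts:
#' an ANCOVA of \code{y} on the group factor plus \code{x}, with
#' \eqn{r = sign(b) \sqrt{SS_x / (SS_x + SS_{error})}} and
#' \eqn{df = N - k - 1} for \eqn{k} groups.
#'
#' @param x,y numeric vectors.
#' @param group group labels (the repeated-measures unit).
#' @return List with \code{r}, \code{df}, \code{p}.
#' @export
rm_corr <- function(x, y, group) {
  g <- factor(group)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(tapply(x, g, function(v) stats::sd(v) == 0)))
    stop("zero within-group variance in x")
  fit <- stats::lm(y ~ g + x)
  if (is.na(stats::coef(fit)[["x"]]))
    stop("x is collinear with the group factor")
  a <- stats::anova(fit)
  ss_x <- a["x", "Sum Sq"]; ss_e <- a["Residuals", "Sum Sq"]
  r <- sign(stats::coef(fit)[["x"]]) * sqrt(ss_x / (ss_x + ss_e))
  df <- length(y) - nlevels(g) - 1
  tval <- r * sqrt(df / max(1e-300, 1 - r^2))
  list(r = unname(r), df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Leave-one-pair-out validation of a fitted model specification
#'
#' For each pair, refits the model on the remaining pairs and predicts the
#' held-out pair's blocks from fixed effects only, then reports the
#' repeated-measures correlation between observed and predicted values over
#' all pooled rows, and the mean within-pair Pearson correlation.
#'
#' @param data,outcome,predictors,time_col as in [fit_lmm_ar1()].
#' @return List with \code{rmcorr} (list r/df/p, or NA with
#'   \code{degenerate = TRUE} when predictions are constant within pairs),
#'   \code{pair_mean_r}, and the \code{predictions} table.
#' @export
loo_validate <- function(data, outcome, predictors, time_col = "block") {
  preds <- lapply(sort(unique(data$pair)), function(pid) {
    train <- data[data$pair != pid, , drop = FALSE]
    test <- data[data$pair == pid, , drop = FALSE]
    fit <- fit_lmm_ar1(train, outcome, predictors, time_col = time_col)
    data.frame(pair = pid, observed = test[[outcome]],
               predicted = predict(fit, test))
  })
  preds <- do.call(rbind, preds)
  per_pair_r <- tapply(seq_len(nrow(preds)), preds$pair, function(ix) {
    o <- preds$observed[ix]; p <- preds$predicted[ix]
    if (stats::sd(p) == 0 || stats::sd(o) == 0) NA_real_
    else stats::cor(o, p)
  })
  rc <- tryCatch(rm_corr(preds$predicted, preds$observed, preds$pair),
                 error = function(e) list(r = NA_real_, df = NA, p = NA,
                                          degenerate = TRUE))
  list(rmcorr = rc, pair_mean_r = mean(unlist(per_pair_r), na.rm = TRUE),
       predictions = preds)
}
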