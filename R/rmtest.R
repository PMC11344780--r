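## ANOVA-type (ATS) and modified ANOVA-type (MATS) statistics for
## repeated-measures designs, with parametric-bootstrap p values. The MATS
## accommodates heteroscedastic and singular covariance matrices; both are
## computed from per-subject cell-mean vectors, so no sphericity or
## normality-of-residual assumptions enter beyond the bootstrap's.

mp_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 1e-300)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

## symmetric square root for (possibly singular) covariance sampling
cov_sqrt <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% (t(e$vectors) * sqrt(pmax(e$values, 0)))
}

centering <- function(k) diag(k) - 1 / k
averaging <- function(k) matrix(1 / k, k, k)

## projection matrix for one effect as a Kronecker product over
## (between factor, within factors...), x identity over response dims
effect_projection <- function(effect, between_levels, within_levels, q) {
  mats <- list()
  if (!is.null(between_levels))
    mats[[length(mats) + 1]] <-
      if ("between" %in% effect) centering(between_levels)
      else averaging(between_levels)
  for (nm in names(within_levels))
    mats[[length(mats) + 1]] <-
      if (nm %in% effect) centering(length(within_levels[[nm]]))
      else averaging(length(within_levels[[nm]]))
  mats[[length(mats) + 1]] <- diag(q)
  Reduce(`%x%`, mats)
}

rm_stat <- function(mu, SigN, N, Tm, method) {
  if (method == "ATS") {
    den <- sum(diag(Tm %*% SigN))
    if (den <= 0) return(NA_real_)
    N * drop(t(mu) %*% Tm %*% mu) / den
  } else {
    Tmu <- Tm %*% mu
    D <- diag(diag(SigN), nrow = nrow(SigN))
    N * drop(t(Tmu) %*% mp_ginv(Tm %*% D %*% Tm) %*% Tmu)
  }
}

#' Bootstrap repeated-measures (M)ANOVA with ATS/MATS statistics
#'
#' Arranges the data as one cell-mean vector per subject over the crossed
#' within-subject factors (times the response dimensions for multivariate
#' responses), computes the ANOVA-type statistic (ATS) or the modified
#' ANOVA-type statistic (MATS) for every main effect and interaction, and
#' obtains p values from a parametric bootstrap: subject vectors are
#' redrawn from centred multivariate normals with the groups' empirical
#' covariances and the statistic's null distribution is the bootstrap
#' distribution.
#'
#' @param data long-format data frame.
#' @param dv response column name(s); more than one gives a multivariate
#'   (MANOVA-type) test.
#' @param within character vector of within-subject factor columns.
#' @param between optional between-subject factor column.
#' @param subject subject (pair) identifier column.
#' @param method \code{"MATS"} or \code{"ATS"}.
#' @param n_boot bootstrap samples (>= 199).
#' @param seed bootstrap seed; identical seeds give identical p values.
#' @return Data frame of class \code{dg_rm_test} with one row per effect:
#'   \code{effect}, \code{statistic}, \code{p}, \code{method},
#'   \code{n_boot}, \code{seed}.
#' @export
rm_anova_boot <- function(data, dv, within, between = NULL,
                          subject = "pair", method = c("MATS", "ATS"),
                          n_boot = 1999, seed = 1) {
  method <- match.arg(method)
  stopifnot(n_boot >= 199, length(within) >= 1)
  for (w in within)
    if (length(unique(data[[w]])) < 2)
      stop("within factor '", w, "' has fewer than 2 levels")

  within_levels <- lapply(within, function(w) sort(unique(data[[w]])))
  names(within_levels) <- within
  cells <- expand.grid(rev(within_levels), stringsAsFactors = FALSE)
  cells <- cells[, rev(seq_along(within)), drop = FALSE]
  names(cells) <- within
  d <- nrow(cells); q <- length(dv)

  subjects <- sort(unique(data[[subject]]))
  grp_of <- if (is.null(between)) rep("all", length(subjects)) else
    vapply(subjects, function(s)
      as.character(data[[between]][data[[subject]] == s][1]), character(1))
  groups <- sort(unique(grp_of))

  ## per-subject stacked cell-mean vector (cell-major, dv fastest)
  Y <- t(vapply(subjects, function(s) {
    ds <- data[data[[subject]] == s, , drop = FALSE]
    unlist(lapply(seq_len(d), function(ci) {
      sel <- rep(TRUE, nrow(ds))
      for (w in within) sel <- sel & ds[[w]] == cells[ci, w]
      if (!any(sel))
        stop("unbalanced design: subject ", s, " missing cell ",
             paste(sprintf("%s=%s", within, unlist(cells[ci, ])),
                   collapse = ", "))
      vapply(dv, function(v) mean(ds[[v]][sel]), numeric(1))
    }))
  }, numeric(d * q)))

  g <- length(groups)
  ng <- table(factor(grp_of, levels = groups))
  if (any(ng < 2)) stop("each group needs >= 2 subjects")
  N <- length(subjects)
  mu <- unlist(lapply(groups, function(gr)
    colMeans(Y[grp_of == gr, , drop = FALSE])))
  covs <- lapply(groups, function(gr) stats::cov(Y[grp_of == gr, ,
                                                   drop = FALSE]))
  SigN <- matrix(0, g * d * q, g * d * q)
  for (k in seq_len(g)) {
    ix <- ((k - 1) * d * q + 1):(k * d * q)
    SigN[ix, ix] <- N * covs[[k]] / ng[k]
  }

  effects <- list()
  wnames <- within
  for (r in seq_along(wnames))
    effects <- c(effects, utils::combn(wnames, r, simplify = FALSE))
  if (!is.null(between)) {
    effects <- c(list("between"),
                 effects, lapply(effects, function(e) c("between", e)))
  }
  projections <- lapply(effects, effect_projection,
                        between_levels = if (is.null(between)) NULL else g,
                        within_levels = within_levels, q = q)

  obs <- vapply(projections, function(Tm)
    rm_stat(mu, SigN, N, Tm, method), numeric(1))

  set.seed(seed)
  sqrts <- lapply(covs, cov_sqrt)
  exceed <- numeric(length(effects))
  for (b in seq_len(n_boot)) {
    mu_b <- numeric(0)
    covs_b <- vector("list", g)
    for (k in seq_len(g)) {
      Z <- matrix(stats::rnorm(ng[k] * d * q), ng[k]) %*% t(sqrts[[k]])
      mu_b <- c(mu_b, colMeans(Z))
      covs_b[[k]] <- stats::cov(Z)
    }
    SigN_b <- matrix(0, g * d * q, g * d * q)
    for (k in seq_len(g)) {
      ix <- ((k - 1) * d * q + 1):(k * d * q)
      SigN_b[ix, ix] <- N * covs_b[[k]] / ng[k]
    }
    stat_b <- vapply(projections, function(Tm)
      rm_stat(mu_b, SigN_b, N, Tm, method), numeric(1))
    exceed <- exceed + (!is.na(stat_b) & !is.na(obs) & stat_b >= obs)
  }
  labels <- vapply(effects, function(e)
    paste(sub("^between$", between %||% "between", e), collapse = ":"),
    character(1))
  out <- data.frame(effect = labels, statistic = obs,
                    p = (exceed + 1) / (n_boot + 1), method = method,
                    n_boot = n_boot, seed = seed)
  class(out) <- c("dg_rm_test", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Post-hoc pairwise within-factor comparisons
#'
#' Reruns the bootstrap test on every pair of levels of a (3+ level)
#' within-subject factor.
#'
#' @inheritParams rm_anova_boot
#' @param factor_name the within factor to compare pairwise.
#' @return Data frame with one row per level pair.
#' @export
rm_posthoc_pairwise <- function(data, dv, factor_name, subject = "pair",
                                method = "ATS", n_boot = 1999, seed = 1) {
  levels_ <- sort(unique(data[[factor_name]]))
  combs <- utils::combn(levels_, 2, simplify = FALSE)
  rows <- lapply(combs, function(lv) {
    sub <- data[data[[factor_name]] %in% lv, , drop = FALSE]
    res <- rm_anova_boot(sub, dv, within = factor_name, subject = subject,
                         method = method, n_boot = n_boot, seed = seed)
    data.frame(level1 = lv[1], level2 = lv[2],
               statistic = res$statistic[1], p = res$p[1])
  })
  do.call(rbind, rows)
}

#' Grouped Benjamini-Hochberg FDR correction
#'
#' Applies the BH step-up procedure independently within each named group of
#' p values, so decisions in one group never depend on another group's
#' content.
#'
#' @param p named numeric vector of p values.
#' @param groups character vector (same length/names) assigning every p to
#'   exactly one group.
#' @param q FDR level for the returned decisions.
#' @return Data frame: \code{name}, \code{group}, \code{p}, \code{p_adj},
#'   \code{reject}.
#' @export
fdr_groups <- function(p, groups, q = 0.05) {
  if (length(p) != length(groups) || anyNA(groups))
    stop("every p value must be assigned to exactly one group")
  nm <- names(p) %||% as.character(seq_along(p))
  out <- data.frame(name = nm, group = groups, p = unname(p),
                    p_adj = NA_real_)
  for (g in unique(groups)) {
    ix <- which(groups == g)
    out$p_adj[ix] <- stats::p.adjust(out$p[ix], method = "BH")
  }
  out$reject <- out$p_adj <= q
  out
}
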