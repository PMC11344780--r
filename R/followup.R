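#' Split pairs into strongly and weakly coordinated halves
#'
#' Ranks every pair on each of the seven movement-coordination measures
#' (joint-play pair-level values), using the orientation in which larger
#' ranks mean stronger coordination: synchrony, strength of relation and
#' mutual information count upwards; variability of relation, time lag,
#' switching and the absolute phase slope index count downwards. The
#' aggregate rank is the sum over measures; with an odd number of pairs the
#' pair at the median aggregate is excluded and the remaining pairs are
#' split at the median. Ties in the aggregate are broken by pair id (lower
#' id treated as less coordinated), deterministically.
#'
#' @param pair_records data frame with column \code{pair} and the seven
#'   measure columns (\code{synchrony}, \code{strength_of_relation},
#'   \code{variability_of_relation}, \code{time_lag}, \code{switching},
#'   \code{mutual_information}, \code{psi}).
#' @param orientation named numeric vector of +1/-1 per measure; the
#'   default encodes the orientation above (psi is ranked on |psi|).
#' @return Data frame of class \code{dg_coord_split}: \code{pair},
#'   \code{aggregate_rank}, \code{label} in
#'   \code{c("strong", "weak", "excluded-median")}.
#' @export
coordination_split <- function(pair_records,
                               orientation = c(
                                 synchrony = 1, strength_of_relation = 1,
                                 mutual_information = 1,
                                 variability_of_relation = -1,
                                 time_lag = -1, switching = -1, psi = -1)) {
  n <- nrow(pair_records)
  if (n < 3) stop("need at least 3 pairs")
  agg <- numeric(n)
  for (m in names(orientation)) {
    v <- pair_records[[m]]
    if (m == "psi") v <- abs(v)
    agg <- agg + rank(orientation[[m]] * v, ties.method = "average")
  }
  ord <- order(agg, pair_records$pair)   # ascending: weakest first
  label <- rep(NA_character_, n)
  if (n %% 2 == 1) {
    med <- ord[(n + 1) / 2]
    label[med] <- "excluded-median"
    rest <- setdiff(ord, med)
    label[rest[seq_len((n - 1) / 2)]] <- "weak"
    label[rest[(n - 1) / 2 + seq_len((n - 1) / 2)]] <- "strong"
  } else {
    label[ord[seq_len(n / 2)]] <- "weak"
    label[ord[n / 2 + seq_len(n / 2)]] <- "strong"
  }
  out <- data.frame(pair = pair_records$pair, aggregate_rank = agg,
                    label = label)
  class(out) <- c("dg_coord_split", class(out))
  out
}

#' Joint-to-individual transition analyses
#'
#' Three bootstrap ATS tests contrasting strongly versus weakly coordinated
#' pairs at the shift from joint back to individual play: (1) targets
#' collected in session 2, joint versus final individual play (mode within,
#' coordination level between); (2) sense of ball control, early versus
#' late individual play; (3) engagement, session-2 joint versus final
#' individual moments.
#'
#' @param trial_measures trial-scope measures table ([measure_cohort()]).
#' @param ratings combined ratings table.
#' @param split a [coordination_split()].
#' @param n_boot,seed bootstrap settings.
#' @return Named list of \code{dg_rm_test} tables:
#'   \code{targets}, \code{ball_control}, \code{engagement}.
#' @export
transition_analysis <- function(trial_measures, ratings, split,
                                n_boot = 1999, seed = 1) {
  lab <- stats::setNames(split$label, split$pair)
  keep <- names(lab)[lab %in% c("strong", "weak")]

  tm <- trial_measures
  tgt <- tm[tm$measure == "targets" & tm$pair %in% keep &
              ((tm$mode == "joint" & !is.na(tm$session) & tm$session == 2) |
                 (tm$mode == "individual" & tm$trial > 50)), , drop = FALSE]
  tgt$phase_mode <- ifelse(tgt$mode == "joint", "joint", "individual")
  tgt$level <- lab[as.character(tgt$pair)]
  if (length(unique(tgt$phase_mode)) < 2)
    stop("need both joint and individual trials in session 2")
  res_targets <- rm_anova_boot(tgt, "value", within = "phase_mode",
                               between = "level", method = "ATS",
                               n_boot = n_boot, seed = seed)

  rt <- ratings[ratings$pair %in% keep, , drop = FALSE]
  bc <- rt[rt$construct == "ball_control", , drop = FALSE]
  bc$period <- ifelse(bc$trial <= 10, "early", "late")
  bc$level <- lab[as.character(bc$pair)]
  names(bc)[names(bc) == "value"] <- "rating"
  res_bc <- rm_anova_boot(bc, "rating", within = "period",
                          between = "level", method = "ATS",
                          n_boot = n_boot, seed = seed)

  en <- rt[rt$construct == "engagement" &
             (rt$trial %in% c(55, 60) |
                (!is.na(rt$block) & rt$block >= 7)), , drop = FALSE]
  en$phase_mode <- ifelse(is.na(en$block), "individual", "joint")
  en$level <- lab[as.character(en$pair)]
  names(en)[names(en) == "value"] <- "rating"
  res_en <- rm_anova_boot(en, "rating", within = "phase_mode",
                          between = "level", method = "ATS",
                          n_boot = n_boot, seed = seed)

  list(targets = res_targets, ball_control = res_bc, engagement = res_en)
}

#' Within-trial (trial-segment) analysis
#'
#' Repeated-measures tests of joint-play measures over the three 20 s trial
#' segments: a multivariate MATS test per measure family, per-measure ATS
#' tests, and pairwise segment contrasts, with BH correction applied within
#' the family's group of per-measure and post-hoc p values. Measures with no
#' per-segment values (experience ratings, target sequence complexity, PSI
#' and MI) are refused.
#'
#' @param segment_measures segment-scope measures table (joint trials).
#' @param families named list of measure-name vectors; the default tests
#'   the coordination family (five WLCC measures) and the gaming-behaviour
#'   family.
#' @param n_boot,seed bootstrap settings.
#' @return Named list per family: \code{manova} (MATS), \code{anova}
#'   (per-measure ATS), \code{posthoc}, \code{fdr} (grouped adjustments of
#'   the per-family tests).
#' @export
segment_analysis <- function(segment_measures,
                             families = list(
                               coordination = c(
                                 "synchrony", "strength_of_relation",
                                 "variability_of_relation", "time_lag",
                                 "switching"),
                               behaviour = c("targets", "obstacle_time",
                                             "path_length")),
                             n_boot = 1999, seed = 1) {
  excluded <- c("complexity", "mutual_information", "psi", "engagement",
                "agreement", "predictability", "ball_control")
  bad <- intersect(unlist(families), excluded)
  if (length(bad))
    stop("measure(s) not defined at trial-segment resolution: ",
         paste(bad, collapse = ", "))
  sm <- segment_measures[segment_measures$mode == "joint", , drop = FALSE]

  out <- list()
  for (fam in names(families)) {
    ms <- families[[fam]]
    ## wide: one column per measure, pair x segment cell means
    sub <- sm[sm$measure %in% ms, , drop = FALSE]
    agg <- stats::aggregate(value ~ pair + segment + measure, sub, mean)
    wide <- stats::reshape(agg, idvar = c("pair", "segment"),
                           timevar = "measure", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    man <- rm_anova_boot(wide, ms, within = "segment", method = "MATS",
                         n_boot = n_boot, seed = seed)
    anovas <- lapply(ms, function(m)
      rm_anova_boot(wide, m, within = "segment", method = "ATS",
                    n_boot = n_boot, seed = seed))
    names(anovas) <- ms
    ph <- lapply(ms, function(m)
      rm_posthoc_pairwise(wide, m, "segment", n_boot = n_boot,
                          seed = seed))
    names(ph) <- ms
    pvec <- c(vapply(anovas, function(a) a$p[1], numeric(1)),
              unlist(lapply(names(ph), function(m)
                stats::setNames(ph[[m]]$p,
                                paste0(m, ":", ph[[m]]$level1, "v",
                                       ph[[m]]$level2)))))
    out[[fam]] <- list(manova = man, anova = anovas, posthoc = ph,
                       fdr = fdr_groups(pvec, rep(fam, length(pvec))))
  }
  out
}

#' Coordination over the target-collection cycle
#'
#' Pools all joint-play WLCC windows that fall between two consecutive
#' target collections, assigns each its elapsed phase within the interval
#' (0 at a collection, approaching 1 just before the next), cuts the pooled
#' phases into 20 equal-count bins, and reports per bin and condition the
#' across-pair mean and SEM of the peak-picked coefficient, with a paired
#' per-bin condition test BH-corrected over the 20 bins.
#'
#' @param windows joint-play window table from [measure_cohort()].
#' @param n_bins number of equal-count phase bins (default 20).
#' @return Data frame of class \code{dg_cycle_profile}: \code{bin},
#'   \code{phase_mid}, \code{condition}, \code{mean}, \code{sem},
#'   \code{n_pairs}, plus per-bin \code{p} and \code{p_adj} for the
#'   SAME-DIFF contrast (repeated on both condition rows of a bin).
#' @export
target_cycle_profile <- function(windows, n_bins = 20) {
  w <- windows[!is.na(windows$phase) & !is.na(windows$peak_r), ,
               drop = FALSE]
  if (!nrow(w)) stop("no interior windows with a defined cycle phase")
  br <- stats::quantile(w$phase, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- -Inf; br[n_bins + 1] <- Inf
  w$bin <- cut(w$phase, breaks = br, labels = FALSE)
  mids <- tapply(w$phase, w$bin, stats::median)

  rows <- list(); pvals <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    wb <- w[w$bin == b, , drop = FALSE]
    pm <- stats::aggregate(peak_r ~ pair + condition, wb, mean)
    for (cond in sort(unique(pm$condition))) {
      v <- pm$peak_r[pm$condition == cond]
      rows[[length(rows) + 1]] <- data.frame(
        bin = b, phase_mid = unname(mids[as.character(b)]),
        condition = cond, mean = mean(v),
        sem = stats::sd(v) / sqrt(length(v)), n_pairs = length(v))
    }
    wide <- stats::reshape(pm, idvar = "pair", timevar = "condition",
                           direction = "wide")
    if (all(c("peak_r.SAME", "peak_r.DIFF") %in% names(wide))) {
      cc <- stats::complete.cases(wide[c("peak_r.SAME", "peak_r.DIFF")])
      pvals[b] <- if (sum(cc) >= 3)
        stats::t.test(wide$peak_r.SAME[cc], wide$peak_r.DIFF[cc],
                      paired = TRUE)$p.value else NA_real_
    } else pvals[b] <- NA_real_
  }
  prof <- do.call(rbind, rows)
  adj <- rep(NA_real_, n_bins)
  ok <- !is.na(pvals)
  adj[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  prof$p <- pvals[prof$bin]
  prof$p_adj <- adj[prof$bin]
  class(prof) <- c("dg_cycle_profile", class(prof))
  prof
}

#' Coordination by nearest-obstacle visibility
#'
#' Classifies every joint-play WLCC window by the visibility (both / one /
#' none of the players) of the obstacle closest to the ball at the window
#' centre, averages the peak-picked coefficient per pair, condition and
#' visibility class, and runs a bootstrap ATS test over the structurally
#' available condition-by-visibility cells (SAME trials only produce
#' classes both/none, DIFF trials both/one) as a one-way within factor,
#' plus the condition contrast within the shared "both" class.
#'
#' @param windows joint-play window table from [measure_cohort()].
#' @param n_boot,seed bootstrap settings.
#' @return List with \code{cell_means} (pair x condition x visibility),
#'   \code{test} (ATS over available cells), \code{both_condition_test}.
#' @export
obstacle_visibility_profile <- function(windows, n_boot = 1999, seed = 1) {
  w <- windows[!is.na(windows$peak_r), , drop = FALSE]
  cm <- stats::aggregate(peak_r ~ pair + condition + nearest_vis, w, mean)
  cm$cell <- paste(cm$condition, cm$nearest_vis, sep = ":")
  counts <- table(cm$cell)
  full <- names(counts)[counts == length(unique(cm$pair))]
  avail <- cm[cm$cell %in% full, , drop = FALSE]
  test <- rm_anova_boot(avail, "peak_r", within = "cell", method = "ATS",
                        n_boot = n_boot, seed = seed)
  both <- cm[cm$nearest_vis == "both", , drop = FALSE]
  bt <- if (length(unique(both$condition)) == 2)
    rm_anova_boot(both, "peak_r", within = "condition", method = "ATS",
                  n_boot = n_boot, seed = seed) else NULL
  list(cell_means = cm[, c("pair", "condition", "nearest_vis", "peak_r")],
       test = test, both_condition_test = bt)
}
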