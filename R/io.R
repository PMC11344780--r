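#' Default run configuration
#'
#' A single list drives the whole pipeline; every default is materialised
#' here so the resolved configuration can be serialised next to the
#' outputs. Seeds are split by pipeline stage.
#'
#' @param n_pairs cohort size (default 23).
#' @param scenario agent scenario for [sample_pair_profile()].
#' @param seed base seed; the per-stage seeds derive from it.
#' @param n_boot bootstrap samples for the test layer.
#' @param alpha backward-elimination retention threshold.
#' @param n_frames frames per trial (default 3600 = 60 s at 60 Hz).
#' @return A list of class \code{dg_config}.
#' @export
default_config <- function(n_pairs = 23, scenario = "heterogeneous",
                           seed = 1, n_boot = 1999, alpha = 0.05,
                           n_frames = 3600) {
  seed <- as.integer(seed)
  out <- list(
    n_pairs = as.integer(n_pairs), scenario = scenario,
    n_frames = as.integer(n_frames),
    seeds = list(landscape = seed, profiles = seed + 1000L,
                 sessions = seed + 2000L, ratings = seed + 3000L,
                 bootstrap = seed + 4000L, surrogate = seed + 5000L),
    physics = unclass(default_physics()),
    wlcc = unclass(wlcc_params()),
    mi_bins = 8, psi_band = c(0.05, 5), psi_seg_len = 240,
    rating = unclass(default_rating_coeffs()),
    n_boot = as.integer(n_boot), alpha = alpha)
  class(out) <- "dg_config"
  out
}

## tiny FNV-1a content hash for tagging outputs with their configuration
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(utils::capture.output(utils::str(
    config, digits.d = 12, list.len = 1000)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write pipeline tables and results
#'
#' Data frames go to CSV (12 significant digits, "." decimal separator
#' regardless of locale) and lists to JSON. Each file starts with a comment
#' line embedding the configuration hash; [read_dg_csv()] skips it.
#'
#' @param objects named list of data frames / lists.
#' @param dir output directory (created if needed).
#' @param config the run configuration (for the hash tag).
#' @return Invisibly, the written paths.
#' @export
write_tables <- function(objects, dir, config = default_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  paths <- character(0)
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (is.data.frame(obj)) {
      path <- file.path(dir, paste0(nm, ".csv"))
      num <- vapply(obj, is.numeric, logical(1))
      obj[num] <- lapply(obj[num], signif, digits = 12)
      con <- file(path, "w", encoding = "UTF-8")
      writeLines(paste0("# config_hash: ", hash), con)
      utils::write.csv(obj, con, row.names = FALSE)
      close(con)
    } else {
      path <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(list(config_hash = hash, data = obj), path,
                           digits = 12, auto_unbox = TRUE, force = TRUE)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a CSV written by [write_tables()]
#' @param path file path.
#' @return Data frame.
#' @export
read_dg_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Simulate a cohort of pairs
#'
#' Shared landscapes, per-pair schedules (condition order alternating with
#' pair parity), profiles and full session simulations.
#'
#' @param config a [default_config()].
#' @return List with \code{landscapes}, \code{profiles}, \code{schedules},
#'   \code{sessions}.
#' @export
simulate_cohort <- function(config = default_config()) {
  landscapes <- generate_landscapes(config$seeds$landscape)
  profiles <- lapply(seq_len(config$n_pairs), function(i)
    sample_pair_profile(config$seeds$profiles + i, config$scenario,
                        pair_id = i,
                        condition_order = if (i %% 2 == 1) "SAME-first"
                        else "DIFF-first"))
  schedules <- lapply(profiles, function(pr)
    make_schedule(pr$pair_id, pr$condition_order,
                  seed = config$seeds$sessions, landscapes = landscapes))
  physics <- do.call(default_physics, config$physics[
    setdiff(names(config$physics), character(0))])
  sessions <- lapply(seq_along(profiles), function(i)
    simulate_session(profiles[[i]], schedules[[i]], landscapes,
                     seed = config$seeds$sessions + i, physics = physics,
                     n_frames = config$n_frames))
  list(landscapes = landscapes, profiles = profiles,
       schedules = schedules, sessions = sessions)
}

## per-pair x block wide table of the measures driving the rating generator
block_measures_wide <- function(trial_measures) {
  tm <- trial_measures[trial_measures$mode == "joint", , drop = FALSE]
  agg <- stats::aggregate(value ~ pair + block + condition + measure, tm,
                          mean)
  wide <- stats::reshape(agg, idvar = c("pair", "block", "condition"),
                         timevar = "measure", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide[order(wide$pair, wide$block), , drop = FALSE]
}

#' Synthesize ratings for a whole cohort
#'
#' Z-scores the driving block measures over the cohort, then generates each
#' pair's rating set with a pair-specific seed.
#'
#' @param measures a [measure_cohort()] result.
#' @param profiles list of pair profiles.
#' @param coeffs [default_rating_coeffs()].
#' @param seed base seed.
#' @return Combined ratings data frame.
#' @export
synthesize_cohort_ratings <- function(measures, profiles,
                                      coeffs = default_rating_coeffs(),
                                      seed = 1) {
  wide <- block_measures_wide(measures$trial)
  mcols <- setdiff(names(wide), c("pair", "block", "condition"))
  scale <- list(mean = vapply(wide[mcols], mean, numeric(1)),
                sd = vapply(wide[mcols], stats::sd, numeric(1)))
  out <- lapply(profiles, function(pr)
    synthesize_ratings(wide[wide$pair == pr$pair_id, , drop = FALSE], pr,
                       coeffs, seed = seed + pr$pair_id, scale = scale))
  do.call(rbind, out)
}

#' Run the full pipeline
#'
#' simulate -> measure -> ratings -> block table -> mixed models with
#' backward elimination and leave-one-pair-out validation -> family
#' (M)ANOVAs with grouped FDR -> follow-up analyses.
#'
#' @param config a [default_config()].
#' @param steps subset of pipeline stages to run (later stages need the
#'   earlier ones).
#' @return Named list of all intermediate and final objects.
#' @export
run_pipeline <- function(config = default_config(),
                         steps = c("simulate", "measure", "analyze",
                                   "followup")) {
  res <- list(config = config)
  res$cohort <- simulate_cohort(config)
  if (!"measure" %in% steps) return(res)
  res$measures <- measure_cohort(
    res$cohort$sessions, params = do.call(wlcc_params, config$wlcc),
    mi_bins = config$mi_bins, psi_band = config$psi_band,
    psi_seg_len = config$psi_seg_len)
  coeffs <- default_rating_coeffs(
    sigma_u = config$rating$sigma_u, rho = config$rating$rho,
    sigma_e = config$rating$sigma_e, jitter_sd = config$rating$jitter_sd)
  res$ratings <- synthesize_cohort_ratings(res$measures,
                                           res$cohort$profiles, coeffs,
                                           seed = config$seeds$ratings)
  res$block_table <- assemble_block_table(res$measures, res$ratings,
                                          res$cohort$profiles)
  if (!"analyze" %in% steps) return(res)
  predictors <- attr(res$block_table, "predictors")
  res$models <- lapply(c(engagement = "engagement",
                         agreement = "agreement",
                         predictability = "predictability"),
                       function(oc) {
    el <- backward_eliminate(res$block_table, oc, predictors,
                             alpha = config$alpha)
    loo <- if (length(el$retained))
      loo_validate(res$block_table, oc, el$retained) else NULL
    list(elimination = el, loo = loo)
  })
  res$family_tests <- family_anovas(res$block_table,
                                    n_boot = config$n_boot,
                                    seed = config$seeds$bootstrap)
  if (!"followup" %in% steps) return(res)
  pair_rec <- pair_coordination_records(res$measures$trial)
  res$split <- coordination_split(pair_rec)
  res$followup <- list(
    transition = transition_analysis(res$measures$trial, res$ratings,
                                     res$split, n_boot = config$n_boot,
                                     seed = config$seeds$bootstrap),
    segments = segment_analysis(res$measures$segment,
                                n_boot = config$n_boot,
                                seed = config$seeds$bootstrap),
    cycle = target_cycle_profile(res$measures$windows),
    visibility = obstacle_visibility_profile(
      res$measures$windows, n_boot = config$n_boot,
      seed = config$seeds$bootstrap))
  res
}

#' Pair-level coordination records (joint play)
#'
#' Mean of each of the seven coordination measures over all joint trials,
#' per pair; input to [coordination_split()].
#'
#' @param trial_measures trial-scope measures table.
#' @return Wide data frame, one row per pair.
#' @export
pair_coordination_records <- function(trial_measures) {
  ms <- c("synchrony", "strength_of_relation", "variability_of_relation",
          "time_lag", "switching", "mutual_information", "psi")
  tm <- trial_measures[trial_measures$mode == "joint" &
                         trial_measures$measure %in% ms, , drop = FALSE]
  agg <- stats::aggregate(value ~ pair + measure, tm, mean)
  wide <- stats::reshape(agg, idvar = "pair", timevar = "measure",
                         direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide
}

#' Family (M)ANOVAs over session, condition and block position
#'
#' For each observation family (experience ratings, gaming behaviour,
#' finger-movement basics, movement coordination) a multivariate MATS test
#' with the three within-pair factors session (1/2), condition (SAME/DIFF)
#' and block position within the condition set (1-3), followed by
#' per-measure ATS tests. BH-FDR is applied in five groups: a meta group of
#' the four MANOVAs, and one sub-group per family for its per-measure
#' tests.
#'
#' @param block_table a [assemble_block_table()].
#' @param n_boot,seed bootstrap settings.
#' @return List with \code{manova} (per family), \code{anova} (per family,
#'   per measure), \code{fdr}.
#' @export
family_anovas <- function(block_table, n_boot = 1999, seed = 1) {
  bt <- as.data.frame(block_table)
  bt$block3 <- (bt$block - 1) %% 3 + 1
  fams <- list(
    experience = c("engagement", "agreement", "predictability"),
    behaviour = c("targets", "obstacle_time", "path_length", "complexity"),
    basics = c("movement", "n_moves"),
    coordination = c("synchrony", "strength_of_relation",
                     "variability_of_relation", "time_lag", "switching",
                     "mutual_information", "psi"))
  manovas <- list(); anovas <- list()
  for (fam in names(fams)) {
    manovas[[fam]] <- rm_anova_boot(bt, fams[[fam]],
                                    within = c("session", "condition",
                                               "block3"),
                                    method = "MATS", n_boot = n_boot,
                                    seed = seed)
    anovas[[fam]] <- lapply(stats::setNames(fams[[fam]], fams[[fam]]),
                            function(m)
      rm_anova_boot(bt, m, within = c("session", "condition", "block3"),
                    method = "ATS", n_boot = n_boot, seed = seed))
  }
  meta_p <- unlist(lapply(names(manovas), function(fam)
    stats::setNames(manovas[[fam]]$p,
                    paste0("manova:", fam, ":", manovas[[fam]]$effect))))
  sub_p <- unlist(lapply(names(anovas), function(fam)
    unlist(lapply(names(anovas[[fam]]), function(m)
      stats::setNames(anovas[[fam]][[m]]$p,
                      paste0(fam, ":", m, ":",
                             anovas[[fam]][[m]]$effect))))))
  groups <- c(rep("meta", length(meta_p)),
              vapply(strsplit(names(sub_p), ":"), `[[`, character(1), 1))
  fdr <- fdr_groups(c(meta_p, sub_p), groups)
  list(manova = manovas, anova = anovas, fdr = fdr)
}

#' Deterministic miniature cohort fixture
#'
#' Two pairs playing six short (15 s) trials each -- two individual and
#' four joint (two per condition) -- with measures computed. The canonical
#' small instance for oracle-equivalence tests; bit-identical across runs
#' for a fixed seed.
#'
#' @param seed integer seed.
#' @param n_frames frames per trial (default 900 = 15 s).
#' @return List with \code{landscapes}, \code{profiles}, \code{sessions},
#'   \code{measures}.
#' @export
make_fixture <- function(seed = 1, n_frames = 900) {
  landscapes <- generate_landscapes(seed, n = 6)
  trials <- data.frame(
    trial = 1:6,
    mode = c("individual", "individual", rep("joint", 4)),
    condition = c(NA, NA, "SAME", "SAME", "DIFF", "DIFF"),
    landscape = 1:6,
    block = c(NA, NA, 1L, 1L, 2L, 2L),
    session = c(NA, NA, 1L, 1L, 2L, 2L),
    rating = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  profiles <- lapply(1:2, function(i)
    sample_pair_profile(seed + i, "coupled", pair_id = i))
  sessions <- lapply(1:2, function(i) {
    sched <- list(pair_id = i, condition_order = "SAME-first",
                  rating_moments = c(2, 4, 6), trials = trials,
                  landscapes = landscapes)
    class(sched) <- "dg_schedule"
    simulate_session(profiles[[i]], sched, landscapes, seed = seed + 10 * i,
                     n_frames = n_frames)
  })
  measures <- measure_cohort(sessions,
                             params = wlcc_params(window_len = 90,
                                                  window_step = 30,
                                                  max_lag = 30),
                             psi_seg_len = 180)
  list(landscapes = landscapes, profiles = profiles, sessions = sessions,
       measures = measures)
}
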