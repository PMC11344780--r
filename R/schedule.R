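#' Build a pair's session schedule
#'
#' A session consists of 10 trials of individual play, 40 trials of joint
#' play, and a final 10 trials of individual play. Joint play is organised in
#' four 10-trial sets whose obstacle-visibility condition alternates between
#' SAME and DIFF, starting with the pair's assigned first condition; sets
#' 1-2 form session 1 and sets 3-4 session 2. Each 10-trial set is cut into
#' three blocks of 4, 3 and 3 trials whose last trials coincide with the
#' rating moments, giving 12 joint blocks in total. Experience ratings are
#' collected after trials 5, 10, 14, 17, 20, 24, 27, 30, 34, 37, 40, 44, 47,
#' 50, 55 and 60.
#'
#' All pairs play the same 60 landscapes; the landscape order is shuffled
#' only within each 10-trial set, independently per pair.
#'
#' @param pair_id integer pair identifier.
#' @param condition_order \code{"SAME-first"} or \code{"DIFF-first"}.
#' @param seed integer seed for the within-set landscape shuffles.
#' @param landscapes the shared list of 60 landscapes from
#'   [generate_landscapes()].
#' @return An object of class \code{dg_schedule}: a list with \code{pair_id},
#'   \code{condition_order}, \code{rating_moments}, and \code{trials}, a
#'   60-row data frame with columns \code{trial}, \code{mode}
#'   (\code{"individual"}/\code{"joint"}), \code{condition} (\code{"SAME"},
#'   \code{"DIFF"} or \code{NA} for individual play), \code{landscape}
#'   (index into \code{landscapes}), \code{block} (1-12 for joint trials,
#'   \code{NA} otherwise), \code{session} (1 or 2 for joint trials) and
#'   \code{rating} (is a rating collected after this trial).
#' @export
make_schedule <- function(pair_id, condition_order = c("SAME-first",
                                                       "DIFF-first"),
                          seed = 1, landscapes = NULL) {
  condition_order <- match.arg(condition_order)
  rating_moments <- c(5, 10, 14, 17, 20, 24, 27, 30, 34, 37, 40, 44, 47,
                      50, 55, 60)
  first <- if (condition_order == "SAME-first") "SAME" else "DIFF"
  second <- if (first == "SAME") "DIFF" else "SAME"

  mode <- c(rep("individual", 10), rep("joint", 40), rep("individual", 10))
  condition <- rep(NA_character_, 60)
  condition[11:50] <- rep(c(first, second, first, second), each = 10)

  block <- rep(NA_integer_, 60)
  for (s in 0:3) {
    trials <- 11:20 + 10 * s
    block[trials] <- 3 * s + rep(1:3, times = c(4, 3, 3))
  }
  session <- ifelse(is.na(block), NA_integer_, ifelse(block <= 6, 1L, 2L))

  set.seed(as.integer(seed) + 7919L * (as.integer(pair_id) %% 10000L))
  landscape <- integer(60)
  for (s in 0:5) {
    idx <- (10 * s + 1):(10 * s + 10)
    landscape[idx] <- idx[sample.int(10)]
  }

  trials <- data.frame(trial = 1:60, mode = mode, condition = condition,
                       landscape = landscape, block = block,
                       session = session,
                       rating = (1:60) %in% rating_moments)
  out <- list(pair_id = pair_id, condition_order = condition_order,
              rating_moments = rating_moments, trials = trials,
              landscapes = landscapes)
  class(out) <- "dg_schedule"
  out
}
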