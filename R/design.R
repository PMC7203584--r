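#' The 12-step manipulation-point schedule
#'
#' Twelve equally spaced manipulation points spanning \[-0.3, +0.3\]:
#' -0.3000, -0.2455, ..., +0.2455, +0.3000. Negative values make the LF
#' option subjectively superior, positive values the SN option.
#'
#' @param direction "LF_to_SN" (ascending, the default ordering of the raw
#'   schedule) or "SN_to_LF" (descending).
#' @return Numeric vector of length 12.
#' @export
manipulation_schedule <- function(direction = c("LF_to_SN", "SN_to_LF")) {
  direction <- match.arg(direction)
  s <- seq(-0.3, 0.3, length.out = 12)
  if (direction == "SN_to_LF") rev(s) else s
}

# design constants
.ratio_levels <- c(0.20, 0.50, 0.70, 0.80, 0.88, 0.93, 0.97, 0.99)
.interval_levels <- c(1, 4, 8, 12)
.sn_distances <- c(2, 3)
.lf_reward_range <- 55:99
.max_distance <- 15

# sample() safe for length-1 candidate vectors
.resample <- function(x, size = 1) x[sample.int(length(x), size)]

.clip_reward <- function(r, lo, hi) pmin(pmax(round(r), lo), hi)

.trial_cols <- c("block", "sequence_id", "trial_idx", "direction",
                 "sn_reward", "sn_distance", "lf_reward", "lf_distance",
                 "reward_ratio", "interval", "manipulation_point",
                 "target_ratio")

.make_trials <- function(block, sequence_id, direction, sn_reward,
                         sn_distance, lf_reward, interval,
                         manipulation_point, target_ratio = NA_real_) {
  n <- length(sn_reward)
  data.frame(block = rep_len(block, n),
             sequence_id = rep_len(sequence_id, n),
             trial_idx = seq_len(n),
             direction = rep_len(direction, n),
             sn_reward = sn_reward,
             sn_distance = rep_len(sn_distance, n),
             lf_reward = rep_len(lf_reward, n),
             lf_distance = rep_len(sn_distance, n) + interval,
             reward_ratio = sn_reward / rep_len(lf_reward, n),
             interval = interval,
             manipulation_point = manipulation_point,
             target_ratio = rep_len(target_ratio, n),
             stringsAsFactors = FALSE)
}

#' Generate one full-factorial assessment set
#'
#' Crosses 8 reward ratios (0.20 to 0.99), 2 SN distances (2, 3 fields) and
#' 4 intervals (1, 4, 8, 12 fields) into 64 trials, one per cell, in random
#' order. The LF reward of each trial is drawn uniformly from 55..99 and the
#' SN reward is the rounded product of the cell's ratio and the LF reward,
#' clipped into \[1, lf_reward - 1\].
#'
#' @param set_id Integer label recorded in `sequence_id`.
#' @return A 64-row trial data frame.
#' @export
generate_assessment_set <- function(set_id = 1L) {
  cells <- expand.grid(ratio = .ratio_levels, sn_distance = .sn_distances,
                       interval = .interval_levels)
  cells <- cells[sample.int(nrow(cells)), ]
  lf_reward <- sample(.lf_reward_range, nrow(cells), replace = TRUE)
  sn_reward <- .clip_reward(cells$ratio * lf_reward, 1, lf_reward - 1)
  .make_trials("assessment", set_id, "none", sn_reward, cells$sn_distance,
               lf_reward, cells$interval, NA_real_,
               target_ratio = cells$ratio)
}

#' Generate the assessment block
#'
#' Concatenates full-factorial assessment sets (default 5, i.e. 320 trials),
#' each internally randomised, optionally truncated to a fixed trial count
#' to emulate the time-limited block.
#'
#' @param n_sets Number of 64-trial sets.
#' @param n_trials Optional cap on the total number of trials (e.g. 134, the
#'   average completed in the 8-minute human block).
#' @return A trial data frame.
#' @export
generate_assessment_block <- function(n_sets = 5L, n_trials = NULL) {
  sets <- lapply(seq_len(n_sets), generate_assessment_set)
  out <- do.call(rbind, sets)
  out$trial_idx <- seq_len(nrow(out))
  if (!is.null(n_trials)) out <- out[seq_len(min(n_trials, nrow(out))), ]
  out
}

#' Participant profile of indifference points
#'
#' @param indifference_points Named numeric vector mapping interval to the
#'   indifference reward ratio p*(I), each in (0, 1).
#' @param discount_rate Generating hyperbolic discount rate, for synthetic
#'   profiles only.
#' @param flagged Logical: TRUE when the assessment data did not support a
#'   usable fit (mirrors the exclusion of participants whose choices did not
#'   allow a sufficient sequential manipulation).
#' @param diagnostics Optional per-interval fit diagnostics.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(indifference_points, discount_rate = NULL,
                                flagged = FALSE, diagnostics = NULL) {
  ip <- indifference_points[!is.na(indifference_points)]
  if (!flagged) {
    stopifnot(all(ip > 0), all(ip < 1))
  }
  structure(list(indifference_points = indifference_points,
                 discount_rate = discount_rate, flagged = flagged,
                 diagnostics = diagnostics),
            class = "participant_profile")
}

#' Synthetic profile from a hyperbolic discount rate
#'
#' Evaluates the analytic indifference points of a hyperbolic discounter at
#' the assessment intervals. The SN distance is fixed at the midpoint of the
#' design's two SN distances, so p*(I) is a function of the interval alone.
#'
#' @param discount_rate Hyperbolic discount rate k > 0.
#' @param intervals Intervals at which to tabulate p*.
#' @param sn_distance Reference SN distance.
#' @return A `participant_profile` carrying the generating rate.
#' @export
synthetic_profile <- function(discount_rate, intervals = .interval_levels,
                              sn_distance = 2.5) {
  p <- analytic_indifference(discount_rate, intervals, sn_distance)
  names(p) <- intervals
  participant_profile(p, discount_rate = discount_rate)
}

# Logistic fit of P(SN) against reward ratio for one interval.
# Returns list(p_star, slope, separated, usable).
.fit_one_interval <- function(ratio, choice_sn) {
  if (length(unique(choice_sn)) < 2L || length(unique(ratio)) < 2L) {
    return(list(p_star = NA_real_, slope = NA_real_, separated = FALSE,
                usable = FALSE))
  }
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(choice_sn ~ ratio, family = stats::binomial()),
    warning = function(w) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  a <- stats::coef(fit)[[1]]
  b <- stats::coef(fit)[[2]]
  if (separated || abs(b) > 50) {
    # ridge-penalised ML keeps the inflection identified under separation
    nll <- function(par) {
      eta <- par[1] + par[2] * ratio
      -sum(choice_sn * eta - log1p(exp(eta))) + 1e-3 * sum(par^2)
    }
    opt <- stats::optim(c(0, 1), nll, method = "BFGS")
    a <- opt$par[1]
    b <- opt$par[2]
  }
  if (b < 1e-6) {
    # flat or decreasing psychometric function: no identifiable inflection
    return(list(p_star = NA_real_, slope = b, separated = separated,
                usable = FALSE))
  }
  list(p_star = min(max(-a / b, 0.01), 0.99), slope = b,
       separated = separated, usable = TRUE)
}

#' Fit indifference points from assessment choices
#'
#' For each interval, fits a logistic psychometric function of the SN-choice
#' probability against the reward ratio by maximum likelihood and takes its
#' inflection point, `p* = -a/b`, as the indifference point (clamped to
#' (0.01, 0.99)). Complete separation falls back to a lightly
#' ridge-penalised fit and is recorded in the diagnostics. Intervals where
#' only one option was ever chosen yield no estimate; a profile with fewer
#' than two estimated intervals is flagged as unusable.
#'
#' @param records Data frame with columns `interval`, `reward_ratio` and
#'   `choice` ("SN"/"LF"; timeouts are dropped).
#' @return A `participant_profile`.
#' @export
fit_indifference_points <- function(records) {
  records <- records[records$choice %in% c("SN", "LF"), ]
  intervals <- sort(unique(records$interval))
  fits <- lapply(intervals, function(I) {
    sub <- records[records$interval == I, ]
    .fit_one_interval(sub$reward_ratio, as.integer(sub$choice == "SN"))
  })
  p <- vapply(fits, `[[`, numeric(1), "p_star")
  names(p) <- intervals
  diag <- data.frame(interval = intervals,
                     p_star = p,
                     slope = vapply(fits, `[[`, numeric(1), "slope"),
                     separated = vapply(fits, `[[`, logical(1), "separated"),
                     usable = vapply(fits, `[[`, logical(1), "usable"))
  flagged <- sum(diag$usable) < 2L
  participant_profile(p, flagged = flagged, diagnostics = diag)
}

#' Indifference-point curve over intervals
#'
#' Piecewise-linear interpolation of the fitted indifference points over the
#' assessment intervals, with constant extrapolation beyond the end knots.
#' Gives the indifference points "at the medium intervals" (6, 7) needed by
#' the distance block and the post-hoc manipulation points of its analysis.
#'
#' @param profile A `participant_profile`.
#' @return A function mapping interval to indifference reward ratio.
#' @export
indifference_curve <- function(profile) {
  stopifnot(inherits(profile, "participant_profile"))
  p <- profile$indifference_points
  p <- p[!is.na(p)]
  if (length(p) < 2L) stop("need at least two fitted indifference points")
  stats::approxfun(as.numeric(names(p)), p, rule = 2)
}

#' Intervals at which a manipulation point is realisable
#'
#' An interval is valid for a manipulation point m when the target reward
#' ratio `p*(I) + m` lies strictly inside (0, 1) and the implied LF distance
#' stays on the board for both SN distances.
#'
#' @param profile A `participant_profile`.
#' @param m Manipulation point(s); with several, only intervals valid for
#'   all of them are returned.
#' @param intervals Candidate intervals (default 1..12).
#' @param sn_distance SN distance(s) the design may use.
#' @return Integer vector of valid intervals; error when empty.
#' @export
valid_intervals <- function(profile, m, intervals = 1:12,
                            sn_distance = .sn_distances) {
  p <- indifference_curve(profile)(intervals)
  ok <- vapply(seq_along(intervals), function(i) {
    all(p[i] + m > 0 & p[i] + m < 1)
  }, logical(1))
  ok <- ok & (intervals + max(sn_distance) <= .max_distance)
  out <- intervals[ok]
  if (length(out) == 0L) {
    stop("no interval supports manipulation point(s) ",
         paste(signif(m, 3), collapse = ", "), " for this profile")
  }
  out
}

#' Generate one reward-manipulation sequence
#'
#' Twelve trials in which only the SN reward changes: the interval, the SN
#' distance and the LF reward are drawn once and held constant, and the SN
#' reward per trial is `round((p*(I) + m_t) * lf_reward)` following the
#' manipulation schedule in the given direction.
#'
#' @param profile A fitted or synthetic `participant_profile`.
#' @param direction "SN_to_LF" (schedule descending) or "LF_to_SN".
#' @param sequence_id Label for the sequence.
#' @return A 12-row trial data frame; the unrounded target ratio is kept in
#'   `target_ratio`.
#' @export
generate_value_sequence <- function(profile, direction, sequence_id = 1L) {
  sched <- manipulation_schedule(direction)
  sn_distance <- .resample(.sn_distances)
  lf_reward <- .resample(.lf_reward_range)
  I <- .resample(valid_intervals(profile, sched, sn_distance = sn_distance))
  p <- indifference_curve(profile)(I)
  target <- p + sched
  sn_reward <- .clip_reward(target * lf_reward, 1, lf_reward - 1)
  .make_trials("reward", sequence_id, direction, sn_reward, sn_distance,
               lf_reward, rep(I, 12L), sched, target_ratio = target)
}

#' Generate one distance-manipulation sequence
#'
#' Twelve trials in which only the LF distance changes: the SN distance, LF
#' reward and the reward ratio (drawn uniformly between the indifference
#' points at the medium intervals 6 and 7) are held constant while the
#' interval steps through 1..12, descending for SN_to_LF (the SN option is
#' superior at large intervals) and ascending for LF_to_SN. The realised
#' manipulation points `r - p*(I_t)` are computed post hoc from the
#' indifference curve.
#'
#' @inheritParams generate_value_sequence
#' @return A 12-row trial data frame.
#' @export
generate_distance_sequence <- function(profile, direction,
                                       sequence_id = 1L) {
  stopifnot(direction %in% c("SN_to_LF", "LF_to_SN"))
  curve <- indifference_curve(profile)
  sn_distance <- .resample(.sn_distances)
  lf_reward <- .resample(.lf_reward_range)
  p67 <- curve(c(6, 7))
  r_target <- stats::runif(1, min(p67), max(p67))
  sn_reward <- .clip_reward(r_target * lf_reward, 1, lf_reward - 1)
  intervals <- if (direction == "SN_to_LF") 12:1 else 1:12
  if (sn_distance + max(intervals) > .max_distance) {
    stop("LF distance would leave the board")
  }
  m <- r_target - curve(intervals)
  .make_trials("distance", sequence_id, direction, rep(sn_reward, 12L),
               sn_distance, lf_reward, intervals, m,
               target_ratio = r_target)
}

#' Generate one combined-manipulation sequence
#'
#' Twelve trials in which both the LF distance and the SN reward change so
#' that the manipulation points follow the schedule exactly: the SN distance
#' and LF reward are drawn once; per trial an interval is drawn from the set
#' valid for that trial's manipulation point and the SN reward is computed
#' as in the reward block.
#'
#' @inheritParams generate_value_sequence
#' @return A 12-row trial data frame.
#' @export
generate_combined_sequence <- function(profile, direction,
                                       sequence_id = 1L) {
  sched <- manipulation_schedule(direction)
  curve <- indifference_curve(profile)
  sn_distance <- .resample(.sn_distances)
  lf_reward <- .resample(.lf_reward_range)
  I <- vapply(sched, function(m) {
    .resample(valid_intervals(profile, m, sn_distance = sn_distance))
  }, numeric(1))
  target <- curve(I) + sched
  sn_reward <- .clip_reward(target * lf_reward, 1, lf_reward - 1)
  .make_trials("combined", sequence_id, direction, sn_reward, sn_distance,
               lf_reward, I, sched, target_ratio = target)
}

#' Generate a full experimental block design
#'
#' Eight sequences per direction (16 sequences, 192 trials) of the requested
#' kind, in shuffled sequence order with trials kept contiguous and ordered
#' within each sequence.
#'
#' @param kind "distance", "reward" or "combined".
#' @param profile A `participant_profile`.
#' @param n_per_direction Sequences per direction (default 8).
#' @return A trial data frame of `24 * n_per_direction` rows.
#' @export
generate_block <- function(kind = c("distance", "reward", "combined"),
                           profile, n_per_direction = 8L) {
  kind <- match.arg(kind)
  gen <- switch(kind,
                distance = generate_distance_sequence,
                reward = generate_value_sequence,
                combined = generate_combined_sequence)
  dirs <- rep(c("SN_to_LF", "LF_to_SN"), each = n_per_direction)
  dirs <- dirs[sample.int(length(dirs))]
  seqs <- lapply(seq_along(dirs), function(i) gen(profile, dirs[i], i))
  do.call(rbind, seqs)
}
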