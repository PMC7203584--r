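#' Construct a choice option
#'
#' An option in the foraging task is a coin with a printed reward (credits)
#' lying at some city-block distance (grid fields) from the avatar.
#'
#' @param reward Integer reward in credits, in \[1, 99\].
#' @param distance Integer distance in fields, in \[2, 15\].
#' @return An object of class `choice_option`.
#' @export
option <- function(reward, distance) {
  stopifnot(length(reward) == 1L, length(distance) == 1L)
  if (reward < 1 || reward > 99) {
    stop("reward must lie in [1, 99] credits, got ", reward)
  }
  if (distance < 2 || distance > 15) {
    stop("distance must lie in [2, 15] fields, got ", distance)
  }
  structure(list(reward = as.numeric(reward), distance = as.numeric(distance)),
            class = "choice_option")
}

#' Construct a trial (SN vs LF option pair)
#'
#' Every trial offers one small-and-near (SN) option and one large-and-far
#' (LF) option: the SN reward is strictly smaller and the SN distance
#' strictly shorter.
#'
#' @param sn,lf `choice_option` objects.
#' @return An object of class `choice_trial`.
#' @export
trial <- function(sn, lf) {
  stopifnot(inherits(sn, "choice_option"), inherits(lf, "choice_option"))
  if (sn$reward >= lf$reward) {
    stop("SN reward must be strictly smaller than LF reward")
  }
  if (sn$distance >= lf$distance) {
    stop("SN distance must be strictly shorter than LF distance")
  }
  structure(list(sn = sn, lf = lf), class = "choice_trial")
}

#' Reward ratio of a trial
#'
#' The ratio of the SN reward to the LF reward, in (0, 1).
#'
#' @param x A `choice_trial`.
#' @return Numeric scalar.
#' @export
reward_ratio <- function(x) {
  stopifnot(inherits(x, "choice_trial"))
  x$sn$reward / x$lf$reward
}

#' Interval of a trial
#'
#' The LF distance minus the SN distance, in grid fields.
#'
#' @param x A `choice_trial`.
#' @return Numeric scalar, at least 1 for a valid trial.
#' @export
trial_interval <- function(x) {
  stopifnot(inherits(x, "choice_trial"))
  x$lf$distance - x$sn$distance
}

#' Subjective value of an option under hyperbolic discounting
#'
#' Combines reward and distance into one overall value,
#' `reward / (1 + k * distance)`: the analogue of hyperbolic delay
#' discounting with distance playing the role of delay. Vectorised over
#' `reward` and `distance`.
#'
#' @param reward Reward in credits (or a `choice_option`, in which case
#'   `distance` is ignored).
#' @param distance Distance in fields.
#' @param discount_rate Nonnegative discount rate k per field.
#' @return Numeric subjective value.
#' @export
subjective_value <- function(reward, distance = NULL, discount_rate) {
  if (inherits(reward, "choice_option")) {
    distance <- reward$distance
    reward <- reward$reward
  }
  if (any(discount_rate < 0)) stop("discount_rate must be nonnegative")
  reward / (1 + discount_rate * distance)
}

#' Analytic indifference point for a hyperbolic discounter
#'
#' The reward ratio at which the subjective values of the SN and the LF
#' option are exactly equal, for a given interval: with SN distance d and
#' interval I, `p*(I) = (1 + k d) / (1 + k (d + I))`. Strictly decreasing in
#' the interval for k > 0.
#'
#' @param discount_rate Discount rate k (nonnegative).
#' @param interval Interval I in fields (vectorised).
#' @param sn_distance SN distance d in fields; defaults to 2.5, the midpoint
#'   of the two SN distances used in the designs.
#' @return Indifference reward ratio(s) in (0, 1\].
#' @export
analytic_indifference <- function(discount_rate, interval, sn_distance = 2.5) {
  if (any(discount_rate < 0)) stop("discount_rate must be nonnegative")
  (1 + discount_rate * sn_distance) /
    (1 + discount_rate * (sn_distance + interval))
}

#' Manipulation point of a trial for a participant
#'
#' The signed distance of the trial's reward ratio from the participant's
#' indifference point at the trial's interval: `m = r - p*(I)`. Negative m
#' means the LF option is subjectively superior; positive m means the SN
#' option is superior.
#'
#' @param x A `choice_trial`.
#' @param profile A `participant_profile` (see [fit_indifference_points()]
#'   or [synthetic_profile()]).
#' @return Signed numeric scalar.
#' @export
manipulation_point <- function(x, profile) {
  stopifnot(inherits(x, "choice_trial"))
  p <- indifference_curve(profile)
  reward_ratio(x) - p(trial_interval(x))
}

#' Map a manipulation point to the attractor control parameter
#'
#' Linear map `c = gain * m`: the manipulation point of the empirical design
#' plays the role of the control parameter tilting the attractor landscape.
#'
#' @param m Manipulation point(s).
#' @param gain Positive scaling factor (default 1).
#' @return Control parameter value(s).
#' @export
control_parameter <- function(m, gain = 1) {
  if (gain <= 0) stop("gain must be positive")
  gain * m
}
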