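#' Parameters of the one-dimensional attractor model
#'
#' Bundles the tunable constants of the within-trial double-well dynamics and
#' the inter-trial relaxation.
#'
#' @param noise_sd Diffusion coefficient sigma of the within-trial dynamics,
#'   per sqrt(second).
#' @param noise_sd_iti Diffusion coefficient during the inter-trial interval;
#'   defaults to `noise_sd`.
#' @param threshold Decision bound theta on |x|, in (0, 1\].
#' @param dt Euler-Maruyama time step in seconds.
#' @param tau_trial Time constant of the within-trial dynamics, seconds.
#' @param tau_iti Time constant of the inter-trial relaxation, seconds.
#' @param t_max Trial deadline in seconds; exceeding it records a timeout.
#' @param iti_duration Inter-trial interval in seconds (task value 1.3 s).
#' @param control_gain Gain of the linear manipulation-point to
#'   control-parameter map.
#' @param ceiling Hard bound on |x| preventing numerical escape.
#' @return A list of class `attractor_params`.
#' @export
attractor_params <- function(noise_sd = 0.35, noise_sd_iti = noise_sd,
                             threshold = 0.8, dt = 1e-3, tau_trial = 0.1,
                             tau_iti = 2.0, t_max = 10, iti_duration = 1.3,
                             control_gain = 1.0, ceiling = 1.5) {
  stopifnot(dt > 0, threshold > 0, threshold <= 1, t_max > 0,
            iti_duration >= 0, tau_trial > 0, tau_iti > 0,
            noise_sd >= 0, noise_sd_iti >= 0, control_gain > 0,
            ceiling >= 1)
  if (dt > min(tau_trial, tau_iti) / 10) {
    stop("dt must be much smaller than the time constants")
  }
  structure(list(noise_sd = noise_sd, noise_sd_iti = noise_sd_iti,
                 threshold = threshold, dt = dt, tau_trial = tau_trial,
                 tau_iti = tau_iti, t_max = t_max,
                 iti_duration = iti_duration, control_gain = control_gain,
                 ceiling = ceiling),
            class = "attractor_params")
}

#' Double-well potential of the decision variable
#'
#' `V(x, c) = x^4/4 - x^2/2 - c x`. For c = 0 the landscape has two equally
#' deep minima at x = +1 (SN) and x = -1 (LF); c tilts the landscape so that
#' the well on the side of sign(c) is deeper.
#'
#' @param x Decision-variable value(s).
#' @param c Control parameter.
#' @return Potential value(s).
#' @export
potential <- function(x, c = 0) {
  x^4 / 4 - x^2 / 2 - c * x
}

#' One Euler-Maruyama step of the within-trial dynamics
#'
#' Advances the state by `x' = x + (-x^3 + x + c) * dt / tau_trial +
#' sigma * sqrt(dt) * eta`, with eta standard normal, then clips |x| at the
#' configured ceiling. Uses R's global RNG.
#'
#' @param x Current decision-variable value.
#' @param c Control parameter.
#' @param params An `attractor_params` object.
#' @return The new value of x.
#' @export
attractor_step <- function(x, c, params = attractor_params()) {
  eta <- if (params$noise_sd > 0) stats::rnorm(1) else 0
  x_new <- x + (-x^3 + x + c) * params$dt / params$tau_trial +
    params$noise_sd * sqrt(params$dt) * eta
  max(min(x_new, params$ceiling), -params$ceiling)
}

#' Simulate one decision trial
#'
#' Integrates the within-trial dynamics from a starting state until |x|
#' crosses the decision bound (choice = "SN" if x > 0, "LF" if x < 0) or the
#' deadline is reached (choice = "TIMEOUT").
#'
#' @param x0 Starting value of the decision variable; |x0| must be below the
#'   bound.
#' @param c Control parameter for the trial.
#' @param params An `attractor_params` object.
#' @return A list with elements `choice`, `rt` (seconds) and `end_x`.
#' @export
run_trial <- function(x0, c, params = attractor_params()) {
  if (abs(x0) >= params$threshold) {
    stop("starting state already beyond the decision bound")
  }
  out <- cpp_run_trial(x0, c, params$noise_sd, params$threshold, params$dt,
                       params$tau_trial, params$t_max, params$ceiling)
  list(choice = c("LF", "TIMEOUT", "SN")[out$choice + 2L],
       rt = out$rt, end_x = out$end_x)
}

#' Relax the decision variable over the inter-trial interval
#'
#' With the options off, the state decays linearly toward the neutral point:
#' `dx = -(x / tau_iti) dt + sigma_iti sqrt(dt) eta`. For sigma_iti = 0 the
#' closed form is `x(T) = x(0) exp(-T / tau_iti)`; for the task's 1.3-s ITI
#' and tau_iti = 2 s the state retains roughly half of its pre-ITI value,
#' which is the carryover that produces perseveration.
#'
#' @param x0 State at the end of the previous trial.
#' @param params An `attractor_params` object.
#' @param duration ITI duration in seconds; defaults to
#'   `params$iti_duration`.
#' @return The relaxed state.
#' @export
relax_iti <- function(x0, params = attractor_params(),
                      duration = params$iti_duration) {
  cpp_relax_iti(x0, duration, params$noise_sd_iti, params$dt,
                params$tau_iti)
}

#' Simulate a sequence of trials with inter-trial carryover
#'
#' Alternates ITI relaxation and within-trial integration over a schedule of
#' control-parameter values, threading the end state of each trial into the
#' start of the next. This is the mechanism behind hysteresis: after a run
#' of SN choices the residual positive state biases the next decision toward
#' SN even when the control parameter already favours LF.
#'
#' @param c_values Ordered control-parameter schedule, one per trial.
#' @param params An `attractor_params` object.
#' @param x0 State before the first ITI (default 0, the neutral point).
#' @return A data frame with one row per trial: `choice` ("SN", "LF" or
#'   "TIMEOUT"), `rt` and `end_x`.
#' @export
simulate_sequence <- function(c_values, params = attractor_params(),
                              x0 = 0) {
  stopifnot(length(c_values) >= 1)
  out <- cpp_simulate_sequence(as.numeric(c_values), x0, params$noise_sd,
                               params$noise_sd_iti, params$threshold,
                               params$dt, params$tau_trial, params$tau_iti,
                               params$t_max, params$iti_duration,
                               params$ceiling)
  out$choice <- c("LF", "TIMEOUT", "SN")[out$choice + 2L]
  out
}

#' Simulate an experimental block with the attractor model
#'
#' Maps each trial's manipulation point to a control parameter via the
#' configured gain and runs the whole block as one continuous sequence
#' (state threads across sequences within the block, as in the task, where
#' trials follow each other without reset).
#'
#' @param design A block design data frame (see [generate_block()]) carrying
#'   a `manipulation_point` column, in presentation order. An optional
#'   `m_subjective` column, when present, drives the dynamics instead (the
#'   design column then records what the experimenter intended).
#' @param params An `attractor_params` object.
#' @param seed Optional integer seed applied before simulation.
#' @return The design with `choice`, `rt` and `end_x` columns appended.
#' @export
simulate_block <- function(design, params = attractor_params(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- if (!is.null(design$m_subjective)) design$m_subjective
       else design$manipulation_point
  if (is.null(m) || anyNA(m)) {
    stop("every trial needs a defined manipulation point")
  }
  if (nrow(design) == 0L) {
    design$choice <- character(0)
    design$rt <- numeric(0)
    design$end_x <- numeric(0)
    return(design)
  }
  out <- simulate_sequence(control_parameter(m, params$control_gain),
                           params, x0 = 0)
  design$choice <- out$choice
  design$rt <- out$rt
  design$end_x <- out$end_x
  design
}
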