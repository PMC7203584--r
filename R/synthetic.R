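#' Lagged-logistic choice probability
#'
#' Simple parametric chooser used as the null / alternative generative model
#' in pipeline validation: `P(SN) = plogis(s * m + b * h)` where h is +1
#' after an SN choice, -1 after an LF choice and 0 with no history. With
#' b = 0 the chooser is memoryless (the null model for the perseveration
#' index); b > 0 injects lag-one perseveration directly.
#'
#' @param m Manipulation point(s).
#' @param last_choice "SN", "LF" or "none".
#' @param sensitivity Slope s > 0 on the manipulation point.
#' @param perseveration Weight b >= 0 on the previous choice.
#' @return Probability of choosing SN.
#' @export
lagged_logistic_choice <- function(m, last_choice = "none",
                                   sensitivity = 8, perseveration = 0) {
  stopifnot(sensitivity > 0, perseveration >= 0)
  h <- c(SN = 1, LF = -1, none = 0)[[last_choice]]
  stats::plogis(sensitivity * m + perseveration * h)
}

#' Chooser specifications for synthetic participants
#'
#' A chooser turns a block design into choices. Three mechanisms are
#' available: the memoryless / lagged logistic chooser (closed-form
#' psychometric function on the manipulation point), the one-dimensional
#' attractor model, and the PCS network.
#'
#' @param sensitivity,perseveration Parameters of the lagged-logistic rule.
#' @return A chooser specification list.
#' @export
chooser_logistic <- function(sensitivity = 8, perseveration = 0) {
  structure(list(kind = "logistic", sensitivity = sensitivity,
                 perseveration = perseveration), class = "chooser")
}

#' @rdname chooser_logistic
#' @param params An [attractor_params()] object.
#' @export
chooser_attractor <- function(params = attractor_params()) {
  structure(list(kind = "attractor", params = params), class = "chooser")
}

#' @rdname chooser_logistic
#' @param pcs A [pcs_params()] object.
#' @export
chooser_pcs <- function(pcs = pcs_params()) {
  structure(list(kind = "pcs", params = pcs), class = "chooser")
}

# simulate a block with the lagged-logistic chooser, threading the lag state
.simulate_logistic_block <- function(design, chooser) {
  n <- nrow(design)
  choice <- character(n)
  last <- "none"
  p_sn <- numeric(n)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    p <- lagged_logistic_choice(design$m_subjective[i], last,
                                chooser$sensitivity,
                                chooser$perseveration)
    choice[i] <- if (u[i] < p) "SN" else "LF"
    last <- choice[i]
    p_sn[i] <- p
  }
  design$choice <- choice
  design$rt <- NA_real_
  design$end_x <- p_sn
  design
}

.simulate_chooser_block <- function(design, chooser) {
  switch(chooser$kind,
         logistic = .simulate_logistic_block(design, chooser),
         attractor = simulate_block(design, chooser$params),
         pcs = simulate_pcs_block(design, chooser$params),
         stop("unknown chooser kind: ", chooser$kind))
}

#' Simulate one synthetic participant through the full experiment
#'
#' Runs the complete per-participant pipeline exactly as in the study:
#' generate the assessment block, simulate its choices, fit indifference
#' points from them, generate the three experimental blocks from the
#' *fitted* profile, and simulate their choices. The logistic and attractor
#' choosers respond to the subjective manipulation point computed from the
#' participant's true (discount-rate) valuation; the PCS chooser responds to
#' the raw trial features.
#'
#' @param discount_rate True hyperbolic discount rate of the participant
#'   (used by the logistic and attractor choosers, and reported as ground
#'   truth; ignored by the PCS chooser's decisions).
#' @param chooser A chooser specification (see [chooser_logistic()]).
#' @param seed Integer seed for all of this participant's randomness.
#' @param n_assessment Assessment trials completed (default 134, the average
#'   of the time-limited human block; use 320 for the full five sets).
#' @param block_order Character permutation of
#'   `c("distance", "reward", "combined")`.
#' @param n_per_direction Sequences per direction in each block.
#' @param participant Identifier recorded in the output.
#' @return A list with `records` (all four blocks' choice records),
#'   `profile` (the fitted `participant_profile`) and `flagged`.
#' @export
simulate_participant <- function(discount_rate, chooser = chooser_attractor(),
                                 seed = 1L, n_assessment = 134L,
                                 block_order = c("distance", "reward",
                                                 "combined"),
                                 n_per_direction = 8L, participant = 1L) {
  stopifnot(setequal(block_order, c("distance", "reward", "combined")))
  set.seed(seed)
  assess <- generate_assessment_block(5L, n_trials = n_assessment)
  assess$m_subjective <- assess$reward_ratio -
    analytic_indifference(discount_rate, assess$interval)
  assess <- .simulate_chooser_block(assess, chooser)
  profile <- fit_indifference_points(assess)
  profile$discount_rate <- discount_rate
  if (profile$flagged) {
    return(list(records = NULL, profile = profile, flagged = TRUE))
  }
  blocks <- lapply(block_order, function(kind) {
    design <- generate_block(kind, profile,
                             n_per_direction = n_per_direction)
    design$m_subjective <- design$reward_ratio -
      analytic_indifference(discount_rate, design$interval)
    .simulate_chooser_block(design, chooser)
  })
  records <- rbind(assess, do.call(rbind, blocks))
  records$block_pos <- match(records$block,
                             c("assessment", block_order)) - 1L
  records <- cbind(participant = participant, records)
  list(records = records, profile = profile, flagged = FALSE)
}

#' Simulate a synthetic cohort
#'
#' Generates a cohort of participants with heterogeneous hyperbolic discount
#' rates (log-normal across participants), balanced experimental block
#' orders, and per-participant seeds derived deterministically from the
#' master seed. Participants whose assessment choices do not allow a usable
#' indifference-point fit, or whose profile makes the sequential
#' manipulation infeasible, are flagged and replaced by a fresh draw,
#' mirroring the study's exclusion and replacement of participants.
#'
#' @param n_participants Cohort size (default 40).
#' @param chooser A chooser specification.
#' @param master_seed Integer master seed.
#' @param discount_meanlog,discount_sdlog Log-normal parameters of the
#'   discount-rate distribution (defaults log(0.15) and 0.4, which keep the
#'   indifference points at the design intervals inside the assessment
#'   ratio range for most draws).
#' @param n_assessment Assessment trials per participant.
#' @param n_per_direction Sequences per direction per block.
#' @return A list of class `cohort_dataset` with elements `records` (one
#'   data frame over all participants), `truth` (per-participant ground
#'   truth), `profiles` (fitted profiles) and `n_replaced`.
#' @export
simulate_cohort <- function(n_participants = 40L,
                            chooser = chooser_attractor(),
                            master_seed = 1L,
                            discount_meanlog = log(0.15),
                            discount_sdlog = 0.4,
                            n_assessment = 134L, n_per_direction = 8L) {
  set.seed(master_seed)
  pool_size <- n_participants * 4L
  k_pool <- stats::rlnorm(pool_size, discount_meanlog, discount_sdlog)
  seed_pool <- sample.int(.Machine$integer.max, pool_size)
  orders <- .balanced_block_orders(pool_size)
  records <- vector("list", n_participants)
  profiles <- vector("list", n_participants)
  truth <- vector("list", n_participants)
  draw <- 0L
  n_replaced <- 0L
  for (i in seq_len(n_participants)) {
    repeat {
      draw <- draw + 1L
      if (draw > pool_size) stop("too many infeasible participants")
      res <- tryCatch(
        simulate_participant(k_pool[draw], chooser, seed = seed_pool[draw],
                             n_assessment = n_assessment,
                             block_order = orders[[draw]],
                             n_per_direction = n_per_direction,
                             participant = i),
        error = function(e) list(flagged = TRUE, error = conditionMessage(e)))
      if (!res$flagged) break
      n_replaced <- n_replaced + 1L
    }
    records[[i]] <- res$records
    profiles[[i]] <- res$profile
    truth[[i]] <- data.frame(participant = i, discount_rate = k_pool[draw],
                             seed = seed_pool[draw],
                             block_order = paste(orders[[draw]],
                                                 collapse = ","))
  }
  structure(list(records = do.call(rbind, records),
                 truth = do.call(rbind, truth),
                 profiles = profiles, n_replaced = n_replaced,
                 chooser = chooser, master_seed = master_seed),
            class = "cohort_dataset")
}

# cycle through the six permutations of the three experimental blocks
.balanced_block_orders <- function(n) {
  perms <- list(c("distance", "reward", "combined"),
                c("reward", "combined", "distance"),
                c("combined", "distance", "reward"),
                c("distance", "combined", "reward"),
                c("reward", "distance", "combined"),
                c("combined", "reward", "distance"))
  perms[((seq_len(n) - 1L) %% 6L) + 1L]
}
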