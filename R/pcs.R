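#' Parameters of the parallel constraint satisfaction network
#'
#' The network has a clamped general-validity node, four feature nodes
#' (distance and reward of each option) and two mutually inhibiting option
#' nodes. The validity node activates each feature node with a weight equal
#' to the feature dimension's importance times the trial's scaled feature
#' value; each feature node excites its own option and inhibits the other.
#'
#' @param importance Named vector with elements `distance` and `reward`: the
#'   validity-to-feature-layer weights encoding feature importance.
#' @param w_feature_option Magnitude of the feature-to-option weights.
#' @param w_inhibition Magnitude of the (negative) option-to-option weight.
#' @param decay Activation decay per cycle, in (0, 1).
#' @param stability_threshold Stop when the absolute change in the network
#'   energy falls below this value.
#' @param max_iters Cycle budget; exhausting it records a timeout.
#' @param retention Fraction of post-decision activation retained across the
#'   inter-trial interval (default `exp(-1.3 / 2)`, paralleling the
#'   attractor model's ITI relaxation over 1.3 s with a 2-s time constant).
#' @return A list of class `pcs_params`.
#' @export
pcs_params <- function(importance = c(distance = 0.3, reward = 0.3),
                       w_feature_option = 0.15, w_inhibition = 0.1,
                       decay = 0.2, stability_threshold = 1e-7,
                       max_iters = 2000L,
                       retention = exp(-1.3 / 2)) {
  stopifnot(all(c("distance", "reward") %in% names(importance)),
            all(importance > 0), w_feature_option > 0, w_inhibition > 0,
            decay > 0, decay < 1, stability_threshold > 0,
            retention >= 0, retention < 1)
  structure(list(importance = importance,
                 w_feature_option = w_feature_option,
                 w_inhibition = w_inhibition, decay = decay,
                 stability_threshold = stability_threshold,
                 max_iters = as.integer(max_iters), retention = retention,
                 floor = -1, ceiling = 1),
            class = "pcs_params")
}

.pcs_nodes <- c("validity", "dist_sn", "dist_lf", "rew_sn", "rew_lf",
                "opt_sn", "opt_lf")

# min-max feature scaling over the design ranges: rewards 1..99 mapped to
# [-1, 1]; distances 2..15 mapped to proximity in [-1, 1] (near = +1).
.scale_reward <- function(r) 2 * (r - 1) / 98 - 1
.scale_proximity <- function(d) 1 - 2 * (d - 2) / 13

#' Build a PCS network for one trial
#'
#' @param sn_reward,sn_distance,lf_reward,lf_distance Trial features.
#' @param params A `pcs_params` object.
#' @param carry Optional activation vector from the previous decision
#'   (already multiplied by the retention factor).
#' @return A list of class `pcs_network` with activations `a` and the
#'   symmetric weight matrix `W`.
#' @export
pcs_network <- function(sn_reward, sn_distance, lf_reward, lf_distance,
                        params = pcs_params(), carry = NULL) {
  n <- length(.pcs_nodes)
  W <- matrix(0, n, n, dimnames = list(.pcs_nodes, .pcs_nodes))
  wd <- params$importance[["distance"]]
  wr <- params$importance[["reward"]]
  W["validity", "dist_sn"] <- wd * .scale_proximity(sn_distance)
  W["validity", "dist_lf"] <- wd * .scale_proximity(lf_distance)
  W["validity", "rew_sn"] <- wr * .scale_reward(sn_reward)
  W["validity", "rew_lf"] <- wr * .scale_reward(lf_reward)
  wf <- params$w_feature_option
  for (f in c("dist_sn", "rew_sn")) {
    W[f, "opt_sn"] <- wf
    W[f, "opt_lf"] <- -wf
  }
  for (f in c("dist_lf", "rew_lf")) {
    W[f, "opt_lf"] <- wf
    W[f, "opt_sn"] <- -wf
  }
  W["opt_sn", "opt_lf"] <- -params$w_inhibition
  W <- W + t(W) - diag(diag(W))
  a <- stats::setNames(numeric(n), .pcs_nodes)
  if (!is.null(carry)) a[names(carry)] <- carry
  a["validity"] <- 1
  structure(list(a = a, W = W, params = params), class = "pcs_network")
}

#' One update cycle of the PCS network
#'
#' Interactive-activation rule: every non-clamped node i receives net input
#' `n_i = sum_j w_ij a_j` and updates to
#' `a_i (1 - decay) + n_i (ceiling - a_i)` for positive net input, or
#' `a_i (1 - decay) + n_i (a_i - floor)` for negative net input; activations
#' are kept inside \[floor, ceiling\] and the validity node stays clamped
#' at 1.
#'
#' @param net A `pcs_network`.
#' @return The updated network.
#' @export
pcs_step <- function(net) {
  p <- net$params
  a <- net$a
  n_in <- drop(net$W %*% a)
  up <- a * (1 - p$decay) +
    ifelse(n_in > 0, n_in * (p$ceiling - a), n_in * (a - p$floor))
  up <- pmin(pmax(up, p$floor), p$ceiling)
  up["validity"] <- 1
  net$a <- up
  net
}

#' Network energy (weighted sum of activation products)
#'
#' `E = sum_{i<j} w_ij a_i a_j`; the decision criterion watches successive
#' differences of this quantity.
#'
#' @param net A `pcs_network`.
#' @return Numeric scalar.
#' @export
pcs_energy <- function(net) {
  sum(net$W[upper.tri(net$W)] * tcrossprod(net$a)[upper.tri(net$W)])
}

#' Run the PCS network to a decision
#'
#' Iterates [pcs_step()] until the change in [pcs_energy()] falls below the
#' stability threshold (a decision) or the cycle budget is exhausted (a
#' timeout). The chosen option is the option node with the higher
#' activation; an exact tie is broken by a coin flip drawn from R's RNG and
#' counted in the result.
#'
#' @inheritParams pcs_network
#' @return A list with `choice` ("SN", "LF" or "TIMEOUT"), `iterations`,
#'   the final `activations`, the option-activation difference `margin`,
#'   and `tie` (logical).
#' @export
pcs_decide <- function(sn_reward, sn_distance, lf_reward, lf_distance,
                       params = pcs_params(), carry = NULL) {
  net <- pcs_network(sn_reward, sn_distance, lf_reward, lf_distance,
                     params, carry)
  out <- cpp_pcs_settle(net$W, net$a, params$decay, params$floor,
                        params$ceiling, params$stability_threshold,
                        params$max_iters)
  net$a <- stats::setNames(out$a, .pcs_nodes)
  iters <- out$iterations
  converged <- out$converged
  margin <- net$a[["opt_sn"]] - net$a[["opt_lf"]]
  tie <- converged && abs(margin) < 1e-12
  choice <- if (!converged) "TIMEOUT"
            else if (tie) c("LF", "SN")[1L + (stats::runif(1) < 0.5)]
            else if (margin > 0) "SN" else "LF"
  list(choice = choice, iterations = iters, activations = net$a,
       margin = margin, tie = tie)
}

#' Simulate an experimental block with the PCS chooser
#'
#' Runs [pcs_decide()] trial by trial in presentation order, carrying the
#' post-decision activations of the option layer into the next trial after
#' multiplying them by the retention factor (the feature layer is reset by
#' the new stimulus). Residual option-layer activation is the PCS
#' perseveration mechanism: it tips near-tie trials toward the previous
#' choice while strong feature evidence overrides it.
#'
#' @param design A block-design data frame (see [generate_block()]).
#' @param params A `pcs_params` object.
#' @param seed Optional integer seed (only tie-breaks consume randomness).
#' @return The design with `choice`, `rt` (settling cycles) and `end_x`
#'   (option-activation margin) columns appended.
#' @export
simulate_pcs_block <- function(design, params = pcs_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(design)
  choice <- character(n)
  iters <- numeric(n)
  margin <- numeric(n)
  carry <- NULL
  for (i in seq_len(n)) {
    out <- pcs_decide(design$sn_reward[i], design$sn_distance[i],
                      design$lf_reward[i], design$lf_distance[i],
                      params, carry)
    choice[i] <- out$choice
    iters[i] <- out$iterations
    margin[i] <- out$margin
    carry <- out$activations[c("opt_sn", "opt_lf")] * params$retention
  }
  design$choice <- choice
  design$rt <- iters
  design$end_x <- margin
  design
}
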