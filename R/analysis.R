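#' Perseveration index of one participant in one block
#'
#' The difference between the participant's SN-choice ratios in the two
#' sequence directions: `PI = P(SN | SN_to_LF) - P(SN | LF_to_SN)`. With
#' perseveration, choices stick with the option that was superior at the
#' start of the sequence, so the SN ratio is higher in sequences that start
#' SN-superior and the index is positive. Timeouts are excluded from both
#' ratios.
#'
#' @param records Choice records of one participant in one experimental
#'   block (columns `direction` and `choice`).
#' @return Signed fraction in \[-1, 1\]; `NA` with a warning if either
#'   direction has no valid trial.
#' @export
perseveration_index <- function(records) {
  records <- records[records$choice %in% c("SN", "LF"), ]
  sn <- records$choice == "SN"
  i_fwd <- records$direction == "SN_to_LF"
  i_rev <- records$direction == "LF_to_SN"
  if (!any(i_fwd) || !any(i_rev)) {
    warning("a direction has no valid trials; perseveration index undefined")
    return(NA_real_)
  }
  mean(sn[i_fwd]) - mean(sn[i_rev])
}

#' Perseveration indices for all participants and blocks
#'
#' @param records Choice records of a cohort (or a `cohort_dataset`);
#'   assessment trials are ignored.
#' @return Data frame with columns `participant`, `block`, `pi`.
#' @export
perseveration_indices <- function(records) {
  if (inherits(records, "cohort_dataset")) records <- records$records
  records <- records[records$block != "assessment", ]
  cells <- unique(records[, c("participant", "block")])
  cells$pi <- mapply(function(p, b) {
    perseveration_index(records[records$participant == p &
                                  records$block == b, ])
  }, cells$participant, cells$block)
  rownames(cells) <- NULL
  cells
}

#' One-sample t test with effect size
#'
#' Tests whether the mean of the supplied indices exceeds zero (one-sided by
#' default) and reports Cohen's d = mean / sd.
#'
#' @param x Numeric vector (e.g. per-participant perseveration indices).
#' @param alternative Passed to [stats::t.test()]; default "greater".
#' @return A list with `mean`, `sd`, `n`, `t`, `df`, `p` and `cohen_d`.
#' @export
one_sample_test <- function(x, alternative = "greater") {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least two observations")
  if (stats::sd(x) == 0) stop("zero variance: test undefined")
  tt <- stats::t.test(x, mu = 0, alternative = alternative)
  list(mean = mean(x), sd = stats::sd(x), n = length(x),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, cohen_d = mean(x) / stats::sd(x))
}

#' Direction-split choice curves
#'
#' For each direction, the mean percentage of LF choices per bin across
#' participants, with standard errors. Reward- and combined-block trials bin
#' on the scheduled manipulation points; distance-block trials can be binned
#' either on the interval (the manipulated variable) or on the post-hoc
#' manipulation points mapped to the nearest schedule step. Empty bins are
#' dropped with a warning. Under perseveration the two directions' curves
#' separate in the mid-schedule bins.
#'
#' @param records Cohort choice records or a `cohort_dataset`.
#' @param block "distance", "reward" or "combined".
#' @param by "manipulation_point" or "interval" (intervals only make sense
#'   for the distance block).
#' @return Data frame with columns `direction`, `bin`, `pct_lf`, `se`, `n`.
#' @export
perseveration_curves <- function(records,
                                 block = c("distance", "reward", "combined"),
                                 by = c("manipulation_point", "interval")) {
  if (inherits(records, "cohort_dataset")) records <- records$records
  block <- match.arg(block)
  by <- match.arg(by)
  rec <- records[records$block == block &
                   records$choice %in% c("SN", "LF"), ]
  if (by == "interval") {
    rec$bin <- rec$interval
  } else {
    sched <- manipulation_schedule()
    rec$bin <- sched[apply(abs(outer(rec$manipulation_point, sched, "-")),
                           1, which.min)]
  }
  # per-participant percentage of LF choices in each direction x bin cell
  agg <- stats::aggregate(
    list(pct_lf = 100 * (rec$choice == "LF")),
    by = list(direction = rec$direction, bin = rec$bin,
              participant = rec$participant),
    FUN = mean)
  out <- stats::aggregate(
    agg$pct_lf, by = list(direction = agg$direction, bin = agg$bin),
    FUN = function(v) c(mean = mean(v),
                        se = stats::sd(v) / sqrt(length(v)),
                        n = length(v)))
  out <- cbind(out[, c("direction", "bin")], as.data.frame(out$x))
  names(out) <- c("direction", "bin", "pct_lf", "se", "n")
  full_bins <- if (by == "interval") 1:12 else manipulation_schedule()
  missing_bins <- setdiff(round(full_bins, 4), round(unique(out$bin), 4))
  if (length(missing_bins) > 0) {
    warning("empty bins omitted: ", paste(missing_bins, collapse = ", "))
  }
  out[order(out$direction, out$bin), ]
}

#' Descriptive comparison of perseveration across blocks
#'
#' Per-block mean, SD and SE of the perseveration index, and pairwise
#' between-block mean differences with seeded bootstrap percentile
#' intervals (participants resampled with replacement).
#'
#' @param pi_df Output of [perseveration_indices()].
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Seed for the resampling.
#' @param conf Confidence level of the percentile interval.
#' @return A list with `summary` (per block) and `pairwise` (differences).
#' @export
compare_blocks <- function(pi_df, n_boot = 2000L, seed = 1L, conf = 0.95) {
  wide <- stats::reshape(pi_df, idvar = "participant", timevar = "block",
                         direction = "wide")
  blocks <- sub("^pi\\.", "", grep("^pi\\.", names(wide), value = TRUE))
  mat <- as.matrix(wide[, paste0("pi.", blocks), drop = FALSE])
  colnames(mat) <- blocks
  summary <- data.frame(
    block = blocks,
    mean = colMeans(mat, na.rm = TRUE),
    sd = apply(mat, 2, stats::sd, na.rm = TRUE),
    se = apply(mat, 2, function(v) {
      stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    }),
    row.names = NULL)
  set.seed(seed)
  pairs <- utils::combn(blocks, 2, simplify = FALSE)
  alpha <- (1 - conf) / 2
  pairwise <- do.call(rbind, lapply(pairs, function(pr) {
    d_obs <- mean(mat[, pr[1]] - mat[, pr[2]], na.rm = TRUE)
    boots <- replicate(n_boot, {
      idx <- sample.int(nrow(mat), replace = TRUE)
      mean(mat[idx, pr[1]] - mat[idx, pr[2]], na.rm = TRUE)
    })
    data.frame(block_a = pr[1], block_b = pr[2], diff = d_obs,
               ci_lower = stats::quantile(boots, alpha, names = FALSE),
               ci_upper = stats::quantile(boots, 1 - alpha, names = FALSE))
  }))
  list(summary = summary, pairwise = pairwise)
}
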