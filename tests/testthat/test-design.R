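test_that("the manipulation schedule has 12 antisymmetric steps", {
  s <- manipulation_schedule()
  expect_length(s, 12)
  expect_equal(round(s, 4),
               c(-0.3000, -0.2455, -0.1909, -0.1364, -0.0818, -0.0273,
                 0.0273, 0.0818, 0.1364, 0.1909, 0.2455, 0.3000))
  expect_equal(s, -rev(s))
  expect_equal(manipulation_schedule("SN_to_LF"), rev(s))
})

test_that("an assessment set is one complete factorial crossing", {
  set.seed(1)
  a <- generate_assessment_set()
  expect_equal(nrow(a), 64)
  cells <- unique(a[, c("target_ratio", "sn_distance", "interval")])
  expect_equal(nrow(cells), 64)
  expect_setequal(unique(a$target_ratio),
                  c(0.20, 0.50, 0.70, 0.80, 0.88, 0.93, 0.97, 0.99))
  expect_setequal(unique(a$interval), c(1, 4, 8, 12))
  expect_setequal(unique(a$sn_distance), c(2, 3))
  expect_true(all(a$lf_reward >= 55 & a$lf_reward <= 99))
})

test_that("all generated trials satisfy the task invariants", {
  set.seed(2)
  prof <- fixed_profile()
  designs <- rbind(generate_assessment_block(5),
                   generate_block("distance", prof),
                   generate_block("reward", prof),
                   generate_block("combined", prof))
  expect_true(all(designs$sn_reward >= 1 & designs$lf_reward <= 99))
  expect_true(all(designs$sn_reward < designs$lf_reward))
  expect_true(all(designs$sn_distance >= 2 &
                    designs$lf_distance <= 15))
  expect_true(all(designs$sn_distance < designs$lf_distance))
  expect_true(all(designs$interval ==
                    designs$lf_distance - designs$sn_distance))
  expect_equal(designs$reward_ratio,
               designs$sn_reward / designs$lf_reward)
})

test_that("the assessment block stacks sets and honours a trial cap", {
  set.seed(3)
  full <- generate_assessment_block(5)
  expect_equal(nrow(full), 320)
  capped <- generate_assessment_block(5, n_trials = 134)
  expect_equal(nrow(capped), 134)
})

test_that("logistic fits recover a known indifference point", {
  set.seed(7)
  levels <- c(0.20, 0.50, 0.70, 0.80, 0.88, 0.93, 0.97, 0.99)
  r <- rep(levels, each = 20) # 160 choices per interval
  make_records <- function(p_star, interval) {
    data.frame(interval = interval, reward_ratio = r,
               choice = ifelse(stats::runif(length(r)) <
                                 stats::plogis(8 * (r - p_star)),
                               "SN", "LF"))
  }
  rec <- rbind(make_records(0.70, 4), make_records(0.55, 8))
  prof <- fit_indifference_points(rec)
  expect_false(prof$flagged)
  expect_lt(abs(prof$indifference_points[["4"]] - 0.70), 0.03)
  expect_lt(abs(prof$indifference_points[["8"]] - 0.55), 0.03)
})

test_that("deterministic step data put the inflection at the step", {
  r0 <- 0.75
  levels <- c(0.20, 0.50, 0.70, 0.80, 0.88, 0.93, 0.97, 0.99)
  rec <- data.frame(interval = 4, reward_ratio = rep(levels, each = 10),
                    choice = ifelse(rep(levels, each = 10) > r0,
                                    "SN", "LF"))
  rec2 <- rec
  rec2$interval <- 8
  prof <- fit_indifference_points(rbind(rec, rec2))
  p_hat <- prof$indifference_points[["4"]]
  # within one ratio-level gap of the step location
  expect_gt(p_hat, 0.70)
  expect_lt(p_hat, 0.80)
  expect_true(prof$diagnostics$separated[prof$diagnostics$interval == 4])
  # brute-force grid over the same penalised likelihood finds the same p*
  y <- as.integer(rec$choice == "SN")
  rr <- rec$reward_ratio
  grid <- expand.grid(a = seq(-40, 40, 0.25), b = seq(0.5, 50, 0.25))
  nll <- function(a, b) {
    eta <- a + b * rr
    -sum(y * eta - log1p(exp(eta))) + 1e-3 * (a^2 + b^2)
  }
  vals <- mapply(nll, grid$a, grid$b)
  best <- grid[which.min(vals), ]
  expect_lt(abs(p_hat - (-best$a / best$b)), 0.02)
})

test_that("symmetric half-half choices give an indifference point of 0.5", {
  levels <- seq(0.1, 0.9, by = 0.1)
  rec <- data.frame(interval = 4,
                    reward_ratio = rep(levels, each = 2),
                    choice = rep(c("SN", "LF"), length(levels)))
  rec2 <- rec
  rec2$interval <- 8
  prof <- fit_indifference_points(rbind(rec, rec2))
  expect_true(prof$flagged || is.na(prof$indifference_points[["4"]]) ||
                abs(prof$indifference_points[["4"]] - 0.5) < 0.05)
})

test_that("all-one-option intervals are unusable and flag the profile", {
  rec <- data.frame(interval = rep(c(1, 4), each = 20),
                    reward_ratio = rep(seq(0.2, 0.99, length.out = 20), 2),
                    choice = "SN")
  prof <- fit_indifference_points(rec)
  expect_true(prof$flagged)
  expect_true(all(is.na(prof$indifference_points)))
})

test_that("the indifference curve interpolates linearly between knots", {
  prof <- fixed_profile(c(`4` = 0.8, `8` = 0.6))
  curve <- indifference_curve(prof)
  expect_equal(curve(4), 0.8)
  expect_equal(curve(8), 0.6)
  expect_equal(curve(6), 0.7)
  # constant extrapolation beyond the end knots
  expect_equal(curve(1), 0.8)
  expect_equal(curve(12), 0.6)
  # monotone knots give a monotone curve
  full <- indifference_curve(fixed_profile())
  expect_true(all(diff(full(1:12)) <= 0))
  expect_error(indifference_curve(participant_profile(c(`4` = 0.5))),
               "at least two")
})

test_that("valid intervals respect the (0, 1) target-ratio rule", {
  prof <- fixed_profile(c(`1` = 0.9, `4` = 0.8, `8` = 0.55, `12` = 0.25))
  ok0 <- valid_intervals(prof, 0)
  expect_setequal(ok0, 1:12)
  # p* = 0.8 at interval 4: +0.3 pushes the target to 1.1, invalid
  expect_false(4 %in% valid_intervals(prof, 0.3))
  # p* = 0.25 at interval 12: -0.3 pushes the target to -0.05, invalid
  expect_false(12 %in% valid_intervals(prof, -0.3))
  expect_error(valid_intervals(fixed_profile(c(`1` = 0.95, `4` = 0.95,
                                               `8` = 0.95, `12` = 0.95)),
                               0.3),
               "no interval")
})

test_that("reward sequences vary only the SN reward and hit the schedule", {
  set.seed(5)
  prof <- fixed_profile()
  for (dir in c("SN_to_LF", "LF_to_SN")) {
    s <- generate_value_sequence(prof, dir)
    expect_equal(nrow(s), 12)
    expect_equal(length(unique(s$interval)), 1)
    expect_equal(length(unique(s$lf_reward)), 1)
    expect_equal(length(unique(s$sn_distance)), 1)
    expect_equal(s$manipulation_point, manipulation_schedule(dir))
    # pre-rounding round trip reproduces the schedule exactly
    p <- indifference_curve(prof)
    expect_equal(max(abs((s$target_ratio - p(s$interval)) -
                           manipulation_schedule(dir))), 0,
                 tolerance = 1e-12)
    # post-rounding, within half a credit of the target
    expect_true(all(abs(s$reward_ratio - s$target_ratio) <=
                      0.5 / s$lf_reward + 1e-9))
  }
  s <- generate_value_sequence(prof, "SN_to_LF")
  expect_true(all(diff(s$sn_reward) <= 0))
})

test_that("distance sequences vary only the LF distance", {
  set.seed(6)
  prof <- fixed_profile()
  for (dir in c("SN_to_LF", "LF_to_SN")) {
    s <- generate_distance_sequence(prof, dir)
    expect_equal(nrow(s), 12)
    expect_equal(length(unique(s$sn_reward)), 1)
    expect_equal(length(unique(s$lf_reward)), 1)
    expect_equal(length(unique(s$sn_distance)), 1)
    expect_setequal(s$interval, 1:12)
    # constant ratio drawn between the medium-interval indifference points
    p <- indifference_curve(prof)
    expect_true(all(s$target_ratio >= p(7) & s$target_ratio <= p(6)))
    # larger interval makes LF worse: m non-decreasing in the interval
    ord <- order(s$interval)
    expect_true(all(diff(s$manipulation_point[ord]) >= 0))
    # schedule direction: m monotone in presentation order
    expect_true(all(diff(s$manipulation_point) *
                      ifelse(dir == "SN_to_LF", -1, 1) >= 0))
  }
})

test_that("combined sequences vary both features and hit the schedule", {
  set.seed(7)
  prof <- fixed_profile()
  p <- indifference_curve(prof)
  varied <- FALSE
  for (i in 1:20) {
    s <- generate_combined_sequence(prof, "LF_to_SN")
    expect_equal(s$manipulation_point, manipulation_schedule("LF_to_SN"))
    expect_equal(max(abs((s$target_ratio - p(s$interval)) -
                           s$manipulation_point)), 0, tolerance = 1e-12)
    if (length(unique(s$interval)) > 1 &&
          length(unique(s$sn_reward)) > 1) {
      varied <- TRUE
    }
  }
  expect_true(varied)
})

test_that("a block has 16 sequences, 192 trials, balanced directions", {
  prof <- fixed_profile()
  for (kind in c("distance", "reward", "combined")) {
    set.seed(8)
    b <- generate_block(kind, prof)
    expect_equal(nrow(b), 192)
    expect_equal(length(unique(b$sequence_id)), 16)
    expect_equal(as.integer(table(b$direction)), c(96L, 96L))
    set.seed(8)
    expect_identical(generate_block(kind, prof), b)
  }
})
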