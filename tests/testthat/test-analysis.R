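make_records <- function(sn_fwd, n_fwd, sn_rev, n_rev, participant = 1,
                         block = "reward") {
  data.frame(
    participant = participant, block = block,
    direction = rep(c("SN_to_LF", "LF_to_SN"), c(n_fwd, n_rev)),
    choice = c(rep(c("SN", "LF"), c(sn_fwd, n_fwd - sn_fwd)),
               rep(c("SN", "LF"), c(sn_rev, n_rev - sn_rev))))
}

test_that("the perseveration index is the direction gap in SN ratios", {
  # identical ratios in both directions: no history effect
  expect_equal(perseveration_index(make_records(6, 12, 6, 12)), 0)
  # perfect persistence
  expect_equal(perseveration_index(make_records(12, 12, 0, 12)), 1)
  # counted example: 8/12 - 5/12
  expect_equal(perseveration_index(make_records(8, 12, 5, 12)), 0.25)
  # timeouts are excluded from the ratios
  rec <- make_records(8, 12, 5, 12)
  rec$choice[rec$choice == "LF" & rec$direction == "SN_to_LF"][1] <-
    "TIMEOUT"
  expect_equal(perseveration_index(rec), 8 / 11 - 5 / 12)
  # a direction without valid trials is undefined
  one_dir <- rec[rec$direction == "SN_to_LF", ]
  expect_warning(res <- perseveration_index(one_dir), "undefined")
  expect_true(is.na(res))
})

test_that("per-cohort indices are assembled participant by participant", {
  rec <- rbind(make_records(8, 12, 5, 12, participant = 1),
               make_records(3, 12, 9, 12, participant = 2))
  rec2 <- rec
  rec2$block <- "distance"
  pis <- perseveration_indices(rbind(rec, rec2))
  expect_equal(nrow(pis), 4)
  expect_equal(pis$pi[pis$participant == 1 & pis$block == "reward"], 0.25)
  expect_equal(pis$pi[pis$participant == 2 & pis$block == "reward"], -0.5)
})

test_that("the one-sample test matches the textbook formulas", {
  res <- one_sample_test(c(0.1, 0.2, 0.3))
  expect_equal(res$mean, 0.2)
  expect_equal(res$sd, 0.1)
  expect_equal(res$t, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$cohen_d, 2)
  expect_equal(res$df, 2)
  # negating the data negates t and d
  neg <- one_sample_test(-c(0.1, 0.2, 0.3))
  expect_equal(neg$t, -res$t)
  expect_equal(neg$cohen_d, -res$cohen_d)
  # agrees with the one-sided t distribution tail
  expect_equal(res$p, stats::pt(res$t, df = 2, lower.tail = FALSE))
  expect_error(one_sample_test(rep(0.1, 5)), "variance")
  expect_error(one_sample_test(0.3), "at least two")
})

test_that("choice curves split by direction and sum to 100% per bin", {
  set.seed(10)
  prof <- fixed_profile()
  coh <- simulate_cohort(6, chooser_attractor(), master_seed = 10)
  cur <- perseveration_curves(coh, "reward")
  expect_true(all(cur$pct_lf >= 0 & cur$pct_lf <= 100))
  expect_equal(nrow(cur), 24) # 12 bins x 2 directions
  # complementarity: recomputing SN percentages mirrors the LF curve
  rec <- coh$records[coh$records$block == "reward" &
                       coh$records$choice != "TIMEOUT", ]
  rec$choice <- ifelse(rec$choice == "SN", "LF", "SN")
  coh_flipped <- coh
  coh_flipped$records[coh_flipped$records$block == "reward" &
                        coh_flipped$records$choice != "TIMEOUT", ] <- rec
  cur_sn <- perseveration_curves(coh_flipped, "reward")
  expect_equal(cur$pct_lf + cur_sn$pct_lf, rep(100, 24))
})

test_that("a memoryless deterministic chooser gives identical curves in
           both directions", {
  set.seed(11)
  prof <- fixed_profile()
  design <- generate_block("reward", prof)
  design$choice <- ifelse(design$manipulation_point > 0, "SN", "LF")
  design <- cbind(participant = 1, design)
  cur <- perseveration_curves(design, "reward")
  fwd <- cur[cur$direction == "SN_to_LF", ]
  rev_ <- cur[cur$direction == "LF_to_SN", ]
  expect_equal(fwd$pct_lf[order(fwd$bin)], rev_$pct_lf[order(rev_$bin)])
})

test_that("the index equals the mean direction gap across schedule bins", {
  set.seed(12)
  coh <- simulate_cohort(4, chooser_logistic(8, 1), master_seed = 12)
  rec <- coh$records[coh$records$block == "combined" &
                       coh$records$participant == 2, ]
  pi_direct <- perseveration_index(rec)
  cur <- perseveration_curves(rec, "combined")
  # SN-coded curves: gap per bin, averaged over the 12 schedule bins
  gap <- (100 - cur$pct_lf[cur$direction == "SN_to_LF"]) -
    (100 - cur$pct_lf[cur$direction == "LF_to_SN"])
  expect_equal(mean(gap) / 100, pi_direct, tolerance = 1e-9)
})

test_that("block comparison is descriptive, seeded and self-consistent", {
  pis <- data.frame(participant = rep(1:10, 3),
                    block = rep(c("distance", "reward", "combined"),
                                each = 10),
                    pi = rep(c(0.1, 0.2, 0.05), each = 10) +
                      rep(seq(-0.05, 0.04, by = 0.01), 3))
  out <- compare_blocks(pis, n_boot = 200, seed = 4)
  expect_equal(nrow(out$summary), 3)
  expect_equal(nrow(out$pairwise), 3)
  out2 <- compare_blocks(pis, n_boot = 200, seed = 4)
  expect_identical(out, out2)
  # identical index vectors across blocks: all differences zero
  pis0 <- pis
  pis0$pi <- rep(seq(0, 0.9, 0.1), 3)
  out0 <- compare_blocks(pis0, n_boot = 200, seed = 4)
  expect_true(all(out0$pairwise$diff == 0))
  expect_true(all(out0$pairwise$ci_lower <= 0 & out0$pairwise$ci_upper >= 0))
  # intervals contain the observed difference
  expect_true(all(out$pairwise$ci_lower <= out$pairwise$diff &
                    out$pairwise$diff <= out$pairwise$ci_upper))
})
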