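test_that("regime tables carry the printed task parameters", {
  ro <- strategy_table("reward_only")
  expect_equal(ro$reward_prob, c(.2, .4, .6, .8))
  expect_equal(ro$delay_trials, rep(1L, 4))
  do <- strategy_table("delay_only")
  expect_equal(do$reward_prob, rep(.6, 4))
  expect_equal(do$delay_trials, 1:4)
  ba <- strategy_table("balanced")
  expect_equal(ba$reward_prob, c(.4, .6, .6, .8))
  expect_equal(ba$delay_trials, as.integer(round(c(.2, .4, .6, .8) * 5)))
})

test_that("OFC updates only on DONE trials and is a delta rule", {
  vs <- value_stripes()
  vs$ofc <- rep(0.5, 4)
  up <- ofc_update(vs, 2, 1, mode = "DONE")
  expect_equal(up$ofc[3], 0.55)
  expect_equal(up$ofc[-3], vs$ofc[-3])
  expect_identical(ofc_update(vs, 0, 0.5)$ofc, vs$ofc) # reward == estimate
  expect_error(ofc_update(vs, 0, 1, mode = "PERF"), "DONE")
})

test_that("ACC effort averaging converges to a constant delay", {
  vs <- value_stripes(alpha = 1)
  vs <- acc_update(vs, 1, 4)
  expect_equal(vs$acc[2], 4)
  vs0 <- acc_update(value_stripes(), 0, 0)
  expect_equal(vs0$acc[1], 0)
  vs2 <- value_stripes(alpha = 0.1)
  for (i in 1:200) vs2 <- acc_update(vs2, 3, 3)
  expect_equal(vs2$acc[4], 3, tolerance = 0.01)
})

test_that("coarse codes encode and decode scalars to within a bin", {
  mid <- encode_scalar(0.5, c(0, 1), 7)
  expect_equal(which.max(mid), 4L)
  set.seed(17)
  for (v in runif(100)) {
    code <- encode_scalar(v, c(0, 1), 7)
    expect_lt(abs(decode_scalar(code) - v), 1 / 6)
  }
  # adjacent bins produce distinct winners
  expect_true(which.max(encode_scalar(0.2, c(0, 1), 7)) !=
                which.max(encode_scalar(0.2 + 1 / 6, c(0, 1), 7)))
  expect_warning(encode_scalar(1.4, c(0, 1), 7), "clipped")
})

test_that("forced weights and symmetric weights drive strategy choice as expected", {
  set.seed(19)
  vs <- value_stripes()
  vs$ofc <- c(0.1, 0.2, 0.3, 0.9)
  cue <- task_cues(1, seed = 4)[1, ]
  nf <- 20 + 14
  # Go loaded on the high-reward code region, sigma = 0
  stripes <- lapply(1:4, function(i)
    stripe(nf, sigma = 0, go_w = rep(0, nf), nogo_w = rep(0, nf)))
  hi_region <- 20 + 5:7 # upper OFC code units
  for (i in 1:4) stripes[[i]]$go_w[hi_region] <- 1
  ch <- choose_strategy(stripes, cue, vs)
  expect_equal(ch$strategy, 3L)

  # all-equal weights and noise: choices uniform within binomial error
  stripes_eq <- lapply(1:4, function(i)
    stripe(nf, sigma = 0.1, go_w = rep(0.6, nf), nogo_w = rep(0.4, nf)))
  picks <- integer(2000)
  for (t in seq_len(2000)) {
    picks[t] <- choose_strategy(stripes_eq, cue, vs)$strategy
  }
  freq <- table(factor(picks, levels = 0:3)) / 2000
  expect_true(all(abs(freq - 0.25) < 0.04))
})

test_that("value stripes recover the true reward and effort parameters", {
  # the running averages fluctuate by design (fixed-rate updates), so the
  # recovered parameter is the time-average of each stripe's estimate
  res <- run_pbdm("delay_only", n_batches = 2, episodes = 500, seed = 6)
  strat <- strategy_table("delay_only")
  for (b in 1:2) {
    log_b <- res$choices[res$choices$batch == b, ]
    for (s in 0:3) {
      rows <- log_b[log_b$strategy == s, ]
      rows <- rows[-seq_len(min(20, nrow(rows))), ] # drop burn-in
      if (nrow(rows) >= 100) {
        expect_lt(abs(mean(rows$ofc_est) - strat$reward_prob[s + 1]), 0.05)
        expect_lt(abs(mean(rows$acc_est) - strat$delay_trials[s + 1]), 0.5)
      }
    }
  }
})

test_that("strategy preference transfers to novel task cues", {
  hits <- 0L
  for (sd in 1:10) {
    res <- run_pbdm("reward_only", n_batches = 1, episodes = 500,
                    n_tasks = 20, seed = 200 + sd)
    st <- res$states[[1]]
    trained_pref <- res$batches$preference[1]
    set.seed(999) # novel cue never seen in training
    novel_cue <- as.numeric(seq_len(20) %in% sample.int(20, 5))
    stripes0 <- lapply(st$stripes, function(s) { s$sigma <- 0; s })
    ch <- choose_strategy(stripes0, novel_cue, st$vs)
    if (ch$strategy == trained_pref) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("each episode carries exactly one strategy choice", {
  res <- run_pbdm("reward_only", n_batches = 1, episodes = 50, seed = 10)
  per_ep <- dplyr::count(res$choices, batch, episode)
  expect_true(all(per_ep$n == 1L))
  expect_equal(nrow(res$choices), 50L)
})

test_that("pbdm results are reproducible and expose tidy summaries", {
  r1 <- run_pbdm("reward_only", n_batches = 2, episodes = 100, seed = 12)
  r2 <- run_pbdm("reward_only", n_batches = 2, episodes = 100, seed = 12)
  expect_identical(r1$choices, r2$choices)
  expect_identical(r1$batches$preference, r2$batches$preference)
  gl <- glance(r1)
  expect_equal(gl$n_batches, 2L)
  expect_s3_class(autoplot(r1), "ggplot")
  counts <- r1$preference_counts
  expect_equal(sum(counts$n_batches), 2L)
})
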