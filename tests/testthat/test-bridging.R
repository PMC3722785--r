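test_that("state graphs validate their triads", {
  g <- default_state_graph()
  expect_equal(g$n_states, 5L)
  expect_equal(g$n_actions, 4L)
  expect_error(state_graph(tibble::tibble(before = 0, action = 0, after = 9),
                           n_states = 2), "outside")
  empty <- state_graph(tibble::tibble(before = 0L, action = 0L, after = 1L))
  empty$triads <- empty$triads[0, ]
  expect_error(train_triads(bridging_network(empty)), "empty")
})

test_that("trained role mappings recall actions and outcomes for adjacent triads", {
  set.seed(1)
  chain <- state_graph(tibble::tibble(before = c(0L, 1L), action = c(0L, 1L),
                                      after = c(1L, 2L)))
  bn <- train_triads(bridging_network(chain))
  Wba <- bn$net$projections[[cogseq:::proj_index(bn$net, "BeforeState",
                                                 "ActionBetween")]]$W
  Wab <- bn$net$projections[[cogseq:::proj_index(bn$net, "ActionBetween",
                                                 "AfterState")]]$W
  # before S0 predicts action a0; action a1 predicts after S2
  expect_equal(which.max(Wba %*% cogseq:::onehot(0, 3)), 1L)
  expect_equal(which.max(Wab %*% cogseq:::onehot(1, 2)), 3L)
})

test_that("the default query settles on the intermediate state and its action", {
  set.seed(2)
  bn <- train_triads(bridging_network(default_state_graph()))
  br <- find_bridge(bn, 0, 2)
  expect_true(br$converged)
  expect_equal(br$bridge_state, 1L)
  expect_equal(br$first_action, 0L)
  # exactly one AfterState winner above 0.5
  expect_equal(sum(br$settle$final_act$AfterState > 0.5), 1L)
  # the semantic area keeps current, goal, and bridge co-active
  sem <- br$settle$final_act$StateNodes
  expect_true(all(sem[c(1, 2, 3)] > 0.5))
  # clamped layers are never overridden
  expect_identical(br$settle$final_act$BeforeState, cogseq:::onehot(0, 5))
  expect_identical(br$settle$final_act$GoalIn, cogseq:::onehot(2, 5))
})

test_that("early settling shows all three available actions before one wins", {
  set.seed(3)
  bn <- train_triads(bridging_network(default_state_graph()))
  br <- find_bridge(bn, 0, 2, trace = TRUE)
  ph <- settling_phases(br)
  early_ab <- ph[ph$phase == "early" & ph$layer == "ActionBetween", ]
  expect_equal(early_ab$n_active, 3L)
  expect_setequal(early_ab$active[[1]], c(0L, 2L, 3L))
  late_ab <- ph[ph$phase == "late" & ph$layer == "ActionBetween", ]
  expect_equal(late_ab$active[[1]], 0L)
  # mid phase: the intermediate state has come on in the semantic area
  mid_sem <- ph[ph$phase == "mid" & ph$layer == "StateNodes", ]
  expect_true(all(c(0L, 1L, 2L) %in% mid_sem$active[[1]]))
})

test_that("an adjacent query returns the direct neighbour and its action", {
  set.seed(4)
  bn <- train_triads(bridging_network(default_state_graph()))
  br <- find_bridge(bn, 0, 1)
  expect_true(br$converged)
  expect_equal(br$bridge_state, 1L)
  expect_equal(br$first_action, 0L)
})

test_that("an untrained network produces no confident winner", {
  set.seed(5)
  bn <- bridging_network(default_state_graph())
  expect_warning(br <- find_bridge(bn, 0, 2), "not been trained")
  # semantic weights are zero before training, so no state can reach a
  # confident single-winner configuration driven by the query alone
  expect_true(is.na(br$bridge_state) ||
                max(br$settle$final_act$StateNodes[-c(1, 3)]) < 0.6)
})

test_that("bridge and first action match breadth-first search on random DAGs", {
  suite <- bridging_oracle_suite(n_dags = 50, seed = 123)
  expect_gt(suite$total, 30)
  expect_gte(suite$ok / suite$total, 0.9)
})

test_that("bridge results are deterministic and tidy-able", {
  set.seed(6)
  bn <- train_triads(bridging_network(default_state_graph()))
  b1 <- find_bridge(bn, 0, 2)
  b2 <- find_bridge(bn, 0, 2)
  expect_identical(b1$settle$final_act, b2$settle$final_act)
  td <- tidy(b1)
  expect_true(all(c("cycle", "layer", "unit", "act") %in% names(td)))
  expect_s3_class(autoplot(b1), "ggplot")
  gl <- glance(b1)
  expect_equal(gl$bridge_state, 1L)
  expect_error(find_bridge(bn, 2, 2), "must differ")
})
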