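test_that("parameter validation enforces the documented bounds", {
  expect_s3_class(agent_params(), "stgt_params")
  expect_error(agent_params(alpha = 1.2), "alpha")
  expect_error(agent_params(gamma = 1), "gamma")
  expect_error(agent_params(tau = 0), "tau")
  expect_error(agent_params(u_iti = -0.1), "u_iti")
  expect_error(agent_params(omega = 2), "omega")
})

test_that("integration recovers each system at the omega endpoints", {
  adv <- c(goL = -0.128, goM = 0, goE = -0.128)
  vals <- c(goL = 0.5, goM = 0.3, goE = 0.1)
  expect_equal(integrate_values(adv, vals, omega = 1), vals[names(adv)])
  expect_equal(integrate_values(adv, vals, omega = 0), adv)
  expect_equal(
    unname(integrate_values(
      c(goL = -0.128), c(goL = 0.3), omega = 0.5
    )),
    0.086
  )
  expect_error(
    integrate_values(adv, c(goL = 1, goM = 0), 0.5),
    "same actions"
  )
})

test_that("softmax probabilities are normalized, positive and monotone", {
  p <- softmax_probs(c(0.64, 0.512), tau = 0.15)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[1] / p[2], exp(0.128 / 0.15))
  # equal preferences: uniform choice
  expect_equal(softmax_probs(c(1, 1, 1), 0.15), rep(1 / 3, 3))
  # very high temperature flattens towards uniform
  expect_equal(softmax_probs(c(0, 5), tau = 1e6), c(0.5, 0.5),
    tolerance = 1e-5
  )
  # raising one preference strictly raises its probability
  p_lo <- softmax_probs(c(a = 0.2, b = 0.5), 0.15)["a"]
  p_hi <- softmax_probs(c(a = 0.3, b = 0.5), 0.15)["a"]
  expect_gt(p_hi, p_lo)
  # overflow safety and strict positivity over the model's preference range
  expect_equal(sum(softmax_probs(c(1e5, 1e5 - 1), 0.15)), 1)
  expect_true(all(softmax_probs(c(-1, 0, 1), 0.15) > 0))
})

test_that("a trial runs to eat with the tagged errors and updated state", {
  set.seed(1)
  agent <- stgt_agent(task_standard("magazine"), agent_params(omega = 1))
  out <- run_trial(agent)
  rec <- out$record
  expect_equal(nrow(rec), 1)
  expect_true(rec$cs_choice %in% c("goL", "goM", "goE"))
  expect_true(rec$path %in% c("sign", "goal", "explore"))
  # exactly one CS- and one eat-tagged error per trial
  expect_false(is.na(rec$delta_cs))
  expect_false(is.na(rec$delta_eat))
  expect_false(is.na(rec$delta_us))
  # the first trial's eat error under the magazine feature is 1 - V(M) = 1
  expect_equal(rec$delta_eat, 1)
  # the model learned from every transition on the path it took
  expect_gt(sum(out$agent$state$t > 0), 2)
  expect_equal(out$agent$state$r[out$agent$task$compiled$eat_edge], 0.03)
})

test_that("the CS-tagged error follows the discounted best CS feature", {
  # seed the agent with known values, then check delta_cs on the next trial:
  # the CS transition is directed at E, the best CS-onset feature is max(L, M)
  params <- agent_params(omega = 1, u_iti = 0)
  agent <- stgt_agent(task_standard("magazine"), params)
  agent$state$V <- c(E = 0.1, L = 0.5, M = 0.2, F = 1)
  set.seed(2)
  rec <- run_trial(agent)$record
  expect_equal(rec$delta_cs, 0.8 * max(0.5, 0.2) - 0.1)
})

test_that("decisions use the estimates from before the trial's own updates", {
  # with omega = 1 and tau small, the recorded CS probabilities must equal
  # the softmax of the PRE-trial feature values, even though the CS
  # transition updates V(E) before the choice is sampled... the s0 step
  # happens first, so the decision at s1 sees V(E) already revised by that
  # step but V(L), V(M) untouched
  v0 <- c(E = 0.1, L = 0.5, M = 0.2, F = 1)
  params <- agent_params(omega = 1)
  agent <- stgt_agent(task_standard("magazine"), params)
  agent$state$V <- v0
  set.seed(3)
  rec <- run_trial(agent)$record
  delta0 <- unname(0.8 * max(v0["L"], v0["M"]) - v0["E"])
  v_e_at_choice <- v0[["E"]] + 0.03 * delta0
  expected <- softmax_probs(
    c(goL = v0[["L"]], goE = v_e_at_choice, goM = v0[["M"]]), 0.15
  )
  expect_equal(rec$p_goL, unname(expected["goL"]))
  expect_equal(rec$p_goM, unname(expected["goM"]))
  expect_equal(rec$p_goE, unname(expected["goE"]))
})

test_that("omega endpoints reproduce the single-system controllers", {
  # omega = 1: probabilities equal the softmax of feature values alone;
  # omega = 0: the softmax of advantages alone
  task <- task_standard("magazine")
  for (om in c(0, 1)) {
    agent <- stgt_agent(task, agent_params(omega = om))
    agent$state$V <- c(E = 0.2, L = 0.6, M = 0.4, F = 1)
    agent$state$t[] <- 1
    agent$state$r[task$compiled$eat_edge] <- 1
    set.seed(4)
    rec <- run_trial(agent)$record
    q <- mb_solve_q(world_model_ideal(task), 0.8)
    adv <- mb_advantage(q, "s1")
    v_at_choice <- c(goL = 0.6, goE = NA, goM = 0.4)
    v_at_choice["goE"] <- 0.2 + 0.03 * (0.8 * 0.6 - 0.2) # post-CS-step V(E)
    pref <- if (om == 1) v_at_choice else adv[names(v_at_choice)]
    expected <- softmax_probs(pref, 0.15)
    expect_equal(rec$p_goL, unname(expected["goL"]), tolerance = 1e-9)
    expect_equal(rec$p_goM, unname(expected["goM"]), tolerance = 1e-9)
  }
})
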