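test_that("transition updates follow the exponential approach to 1", {
  m <- world_model(task_standard())
  m <- mb_update_transition(m, "s0", "goE", "s1", alpha = 0.03)
  expect_equal(mb_transition(m, "s0", "goE", "s1"), 0.03)
  for (i in 2:50) m <- mb_update_transition(m, "s0", "goE", "s1", alpha = 0.03)
  expect_equal(mb_transition(m, "s0", "goE", "s1"), 1 - (1 - 0.03)^50)
  # degenerate learning rate: one observation is enough
  m2 <- mb_update_transition(world_model(task_standard()), "s1", "goL", "s2", 1)
  expect_equal(mb_transition(m2, "s1", "goL", "s2"), 1)
  # unobserved and impossible triples stay at 0
  expect_equal(mb_transition(m, "s1", "goL", "s2"), 0)
  expect_equal(mb_transition(m, "s0", "goE", "s7"), 0)
  expect_error(mb_update_transition(m, "s0", "goE", "s7", 0.03), "impossible")
})

test_that("reward updates converge to the observed reward", {
  m <- world_model(task_standard())
  m <- mb_update_reward(m, "s7", "eat", 1, alpha = 0.03)
  expect_equal(mb_reward(m, "s7", "eat"), 0.03)
  for (i in 2:100) m <- mb_update_reward(m, "s7", "eat", 1, alpha = 0.03)
  expect_equal(mb_reward(m, "s7", "eat"), 1 - (1 - 0.03)^100)
  # a reward equal to the current estimate is a fixed point
  m2 <- mb_update_reward(world_model(task_standard()), "s1", "goL", 0, 0.5)
  expect_equal(mb_reward(m2, "s1", "goL"), 0)
})

test_that("the ideal model's Bellman values match the hand backup", {
  q <- mb_solve_q(world_model_ideal(task_standard()), gamma = 0.8)
  qv <- function(s, a) q$q[q$state == s & q$action == a]
  expect_equal(qv("s7", "eat"), 1)
  expect_equal(qv("s4", "eng"), 0.8)
  expect_equal(qv("s1", "goM"), 0.64)
  expect_equal(qv("s2", "eng"), 0.64)
  expect_equal(qv("s1", "goL"), 0.512)
  expect_equal(qv("s1", "goE"), 0.512)
  # halving gamma halves the one-step-from-terminal value
  q2 <- mb_solve_q(world_model_ideal(task_standard()), gamma = 0.4)
  expect_equal(q2$q[q2$state == "s4" & q2$action == "eng"], 0.4)
  # the all-zero model has the zero fixed point
  q0 <- mb_solve_q(world_model(task_standard()), gamma = 0.8)
  expect_true(all(q0$q == 0))
})

test_that("the solver agrees with an independent brute-force iteration", {
  set.seed(42)
  for (build in list(task_standard, task_split_cs)) {
    task <- build("magazine")
    model <- world_model(task)
    model$t <- runif(nrow(task_edges(task)))
    model$r <- numeric(nrow(task_edges(task)))
    model$r[task$compiled$eat_edge] <- runif(1)
    q <- mb_solve_q(model, gamma = 0.8)
    oracle <- brute_force_q(model, gamma = 0.8)
    expect_equal(q$q, unname(oracle[paste(q$state, q$action)]),
      tolerance = 1e-9
    )
  }
})

test_that("advantages are non-positive with a zero maximum in every state", {
  set.seed(7)
  task <- task_standard("magazine")
  model <- world_model(task)
  model$t <- runif(nrow(task_edges(task)))
  model$r[task$compiled$eat_edge] <- 1
  q <- mb_solve_q(model, gamma = 0.8)
  for (s in unique(q$state)) {
    a <- mb_advantage(q, s)
    expect_true(all(a <= 0))
    expect_equal(max(a), 0)
  }
  # ideal-model CS-onset advantages: goM best, the longer routes penalized
  a1 <- mb_advantage(mb_solve_q(world_model_ideal(task), 0.8), "s1")
  expect_equal(unname(a1["goM"]), 0)
  expect_equal(unname(a1["goL"]), -0.128)
  # the structural source of MB goal preference holds for any gamma
  for (g in c(0.1, 0.5, 0.9)) {
    a <- mb_advantage(mb_solve_q(world_model_ideal(task), g), "s1")
    expect_lt(a[["goL"]], a[["goM"]])
    expect_equal(a[["goM"]], 0)
  }
})

test_that("long training converges T to 1 on every traversed transition", {
  log <- run_subject(
    agent_params(omega = 0.5),
    protocol(n_sessions = 10, trials_per_session = 50, seed = 5,
      feature_variant = "magazine")
  )
  model <- agent_world_model(final_agent(log))
  # the CS transition and the eat action occur on every one of 500 trials
  expect_equal(mb_transition(model, "s0", "goE", "s1"), 1, tolerance = 1e-6)
  expect_equal(mb_reward(model, "s7", "eat"), 1, tolerance = 1e-6)
  expect_true(all(model$t >= 0 & model$t <= 1))
  expect_true(all(model$r >= 0 & model$r <= 1))
})

test_that("the advantage function is untouched by the ITI revision", {
  # the revision acts on FMF feature values only; a world model built from
  # the same experience yields identical advantages whatever u_iti does
  task <- task_standard("magazine")
  model <- world_model_ideal(task)
  q_before <- mb_solve_q(model, 0.8)
  v <- fmf_values(E = 0.5, L = 0.5, M = 0.5)
  v <- fmf_iti_revision(v, 0.1)
  q_after <- mb_solve_q(model, 0.8)
  expect_identical(q_before, q_after)
  expect_lt(v[["M"]], 0.5)
})
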