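test_that("protocols validate their fields and encode the ITI conditions", {
  expect_equal(protocol(iti = "short")$u_iti, 0.01)
  expect_equal(protocol(iti = "long")$u_iti, 0.1)
  expect_equal(protocol()$n_sessions, 10L)
  expect_equal(protocol()$trials_per_session, 50L)
  expect_error(protocol(iti = "medium"))
  expect_error(protocol(n_sessions = 0))
  expect_error(protocol(u_iti = 2))
})

test_that("a subject run is a complete, reproducible trial log", {
  proto <- protocol(n_sessions = 3, trials_per_session = 20, seed = 10)
  log <- run_subject(agent_params(omega = 0.7), proto)
  expect_s3_class(log, "stgt_log")
  expect_equal(nrow(log), 60)
  expect_equal(range(log$session), c(1, 3))
  # per-session accounting: every trial makes exactly one CS choice
  counts <- approach_summary(log)
  expect_true(all(counts$n_goL + counts$n_goM + counts$n_goE == 20))
  # determinism under a fixed seed
  log2 <- run_subject(agent_params(omega = 0.7), proto)
  expect_identical(as.data.frame(log), as.data.frame(log2))
})

test_that("learning persists across session boundaries", {
  # the same seed with a different session partition yields the identical
  # trial sequence: sessions are bookkeeping, not resets
  p1 <- protocol(n_sessions = 2, trials_per_session = 25, seed = 3)
  p2 <- protocol(n_sessions = 1, trials_per_session = 50, seed = 3)
  log1 <- run_subject(agent_params(omega = 0.5), p1)
  log2 <- run_subject(agent_params(omega = 0.5), p2)
  drop_idx <- function(x) as.data.frame(x[setdiff(names(x), c("session", "trial"))])
  expect_identical(drop_idx(log1), drop_idx(log2))
})

test_that("the rewarded-transition estimates follow the closed-form curves", {
  proto <- protocol(n_sessions = 4, trials_per_session = 25, seed = 8)
  log <- run_subject(agent_params(omega = 0.3), proto)
  model <- agent_world_model(final_agent(log))
  # eat and the CS transition occur exactly once per trial
  expect_equal(mb_reward(model, "s7", "eat"), 1 - (1 - 0.03)^100)
  expect_equal(mb_transition(model, "s0", "goE", "s1"), 1 - (1 - 0.03)^100)
})

test_that("omega sampling is reproducible and matches its distributions", {
  expect_equal(sample_omegas(5, dist = "fixed", value = 1), rep(1, 5))
  expect_identical(
    sample_omegas(10, dist = "uniform", seed = 4),
    sample_omegas(10, dist = "uniform", seed = 4)
  )
  x <- sample_omegas(20000, dist = "beta", shape1 = 2, shape2 = 1, seed = 5)
  expect_true(all(x >= 0 & x <= 1))
  expect_equal(mean(x), 2 / 3, tolerance = 0.01)
  expect_gt(mean(x > 0.5), 0.5) # mass biased towards 1
  expect_error(sample_omegas(5, dist = "beta", shape1 = -1), "positive")
  expect_error(sample_omegas(5, dist = "fixed"), "value")
})

test_that("paired populations reuse omegas and align subjects", {
  om <- sample_omegas(4, seed = 6)
  proto <- tiny_protocol(seed = 7, feature_variant = "magazine")
  log <- run_paired_population(om, proto)
  expect_equal(sort(unique(log$condition)), c("long", "short"))
  wide <- log |>
    dplyr::distinct(subject_id, condition, omega) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "omega")
  expect_equal(wide$short, wide$long)
  expect_equal(wide$short, om)
  # each condition holds the full protocol for every subject
  expect_equal(nrow(log), 4 * 2 * 20)
  # u_iti follows the condition
  expect_equal(unique(log$u_iti[log$condition == "short"]), 0.01)
  expect_equal(unique(log$u_iti[log$condition == "long"]), 0.1)
  # a single subject reduces to two single-subject runs
  log1 <- run_paired_population(om[1], proto)
  expect_equal(nrow(log1), 2 * 20)
  expect_equal(unique(log1$subject_id), 1L)
  # full determinism of the paired runner
  log_again <- run_paired_population(om, proto)
  expect_identical(as.data.frame(log), as.data.frame(log_again))
})

test_that("presets bind the stock experiments", {
  p <- preset("fig3_fmf_only")
  expect_equal(p$omega_dist$dist, "fixed")
  expect_equal(p$omega_dist$value, 1)
  expect_equal(preset("fig3_mb_only")$omega_dist$value, 0)
  p4 <- preset("fig4_population")
  expect_equal(p4$n_subjects, 20L)
  expect_equal(p4$omega_dist$dist, "beta")
  expect_equal(preset("supp_uniform")$omega_dist$dist, "uniform")
  expect_equal(preset("fig6_split_cs")$task_variant, "split_cs")
  expect_gt(preset("supp_extended_sessions")$n_sessions, 10)
  expect_equal(preset("fig5_rpe")$feature_variant, "magazine")
  expect_error(preset("fig7_nope"))
  # overrides scale the run down without touching the rest
  small <- preset("fig4_population", n_sessions = 2, n_subjects = 3)
  expect_equal(small$n_sessions, 2L)
  expect_equal(small$n_subjects, 3L)
  log <- run_preset(small, seed = 9)
  expect_equal(dplyr::n_distinct(log$subject_id), 3)
  expect_identical(
    as.data.frame(run_preset(small, seed = 9)),
    as.data.frame(log)
  )
})
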