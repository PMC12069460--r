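test_that("mean ensembles average member values, terminals stay at zero", {
  m1 <- arg_value_fn(function(s) -2)
  m2 <- arg_value_fn(function(s) -4)
  ens <- arg_ensemble(list(m1, m2), "mean")
  s <- fix$worked_state
  expect_identical(state_value(ens, s), -3)
  expect_identical(state_value(arg_ensemble(list(m1, m1, m1), "mean"), s),
                   state_value(m1, s))
  expect_identical(state_value(ens, arg_state("0000")), 0)
  expect_error(arg_ensemble(list(), "mean"), "at least one")
})

test_that("majority voting takes the plurality and breaks ties fairly", {
  s <- arg_state(c("01", "10"))
  prefer <- function(key) {
    arg_value_fn(function(st) if (state_key(st) == key) -1 else -5)
  }
  a <- prefer("00 10")   # votes for mutation of 01
  b <- prefer("00 01")   # votes for mutation of 10
  step <- ensemble_action(arg_ensemble(list(a, a, b), "majority"), s, seed = 1)
  expect_identical(action_key(step$action), "M 01 2")
  one <- ensemble_action(arg_ensemble(list(b), "majority"), s, seed = 1)
  expect_identical(action_key(one$action), "M 10 1")
  # 2-2 plurality tie: close to 50/50 over seeded draws
  tie <- arg_ensemble(list(a, a, b, b), "majority")
  set.seed(31)
  picks <- replicate(400, action_key(ensemble_action(tie, s)$action))
  expect_gt(mean(picks == "M 01 2"), 0.40)
  expect_lt(mean(picks == "M 01 2"), 0.60)
})

test_that("minimum-method ensembles keep the shortest member rollout", {
  vt <- value_iteration(fix$sample_a, 9)
  ens <- arg_ensemble(list(loop_stub, vt), "minimum")
  a <- ensemble_build_min(ens, fix$sample_a, stepmax = 60, seed = 1)
  expect_false(is_infinite_arg(a))
  expect_identical(a$length, 9L)
  all_loop <- arg_ensemble(list(loop_stub, loop_stub), "minimum")
  expect_true(is_infinite_arg(ensemble_build_min(all_loop, fix$sample_a,
                                                 stepmax = 30, seed = 1)))
})

test_that("minimum ensembles never exceed any member on random toy samples", {
  set.seed(53)
  sch <- make_scheme(4, 2, 1)
  members <- lapply(1:3, function(i) init_network(sch, seed = 200 + i))
  ens <- arg_ensemble(members, "minimum")
  for (rep in 1:20) {
    s <- random_sample(n = sample(2:4, 1), L = 4L)
    member_len <- vapply(seq_along(members), function(i) {
      a <- build_arg(s, members[[i]], stepmax = 60,
                     seed = argrl:::derive_seed(1000 + rep, i))
      if (is_infinite_arg(a)) Inf else a$length
    }, numeric(1))
    e <- ensemble_build_min(ens, s, stepmax = 60, seed = 1000 + rep)
    elen <- if (is_infinite_arg(e)) Inf else e$length
    expect_lte(elen, min(member_len))
  }
})

test_that("evaluation reports aggregate lengths and infinite proportions", {
  vt <- value_iteration(fix$sample_a, 9)
  samples <- rep(list(fix$sample_a), 5)
  rep_ok <- evaluate_policy(vt, samples, stepmax = 50, seed = 1)
  expect_identical(rep_ok$proportion_infinite, 0)
  expect_identical(rep_ok$mean_finite, 9)
  rep_bad <- evaluate_policy(loop_stub, samples, stepmax = 30, seed = 1)
  expect_identical(rep_bad$proportion_infinite, 1)
  expect_true(is.nan(rep_bad$mean_finite))
})

test_that("checkpoint selection is lexicographic in (infinite, mean length)", {
  mk <- function(prop, mean_len) {
    structure(list(lengths = numeric(0), proportion_infinite = prop,
                   mean_finite = mean_len, K = 20, stepmax = 300),
              class = "arg_eval_report")
  }
  expect_identical(best_report_index(list(mk(0.10, 50), mk(0.05, 60))), 2L)
  expect_identical(best_report_index(list(mk(0.05, 60), mk(0.05, 55))), 2L)
  expect_identical(best_report_index(list(mk(0.05, 55), mk(0.05, 55))), 1L)
  expect_identical(best_report_index(list(mk(0.3, 10))), 1L)
})

test_that("select_best_checkpoint evaluates and applies the rule", {
  vt <- value_iteration(fix$sample_a, 9)
  cps <- list(list(episode = 1, net = loop_stub),
              list(episode = 2, net = vt))
  sel <- select_best_checkpoint(cps, rep(list(fix$sample_a), 3),
                                stepmax = 40, seed = 5)
  expect_identical(sel$index, 2L)
  expect_identical(sel$checkpoint$episode, 2)
  expect_error(select_best_checkpoint(list(), list()), "no checkpoints")
})
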