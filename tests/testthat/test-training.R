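exact_table <- function(s, cap = min_arg_length(s)) value_iteration(s, cap)

test_that("greedy selection prefers terminal-reaching actions and exact values", {
  # terminal successor is worth exactly 0 and dominates
  net <- init_network(make_scheme(4, 2, 1), seed = 1)
  step <- select_action_greedy(net, arg_state(c("0000", "0000")), seed = 1)
  expect_true(is_terminal_state(step$state))
  # with exact values loaded, the toy state picks a mutation
  s <- arg_state(c("01", "10"))
  vt <- exact_table(s, 5)
  step2 <- select_action_greedy(vt, s, seed = 3)
  expect_identical(step2$action$kind, "mutation")
})

test_that("greedy ties are broken uniformly", {
  s <- arg_state(c("01", "10"))
  vt <- exact_table(s, 5)
  set.seed(42)
  picks <- replicate(1000, action_key(select_action_greedy(vt, s)$action))
  frac <- mean(picks == "M 01 2")
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("epsilon controls the exploration rate", {
  s <- fix$worked_state
  net <- init_network(make_scheme(4, 2, 1), seed = 2)
  # epsilon = 0 reproduces greedy draw for draw
  set.seed(7)
  g <- replicate(20, action_key(select_action_greedy(net, s)$action))
  set.seed(7)
  e0 <- replicate(20, action_key(select_action_epsilon(net, s, 0)$action))
  expect_identical(e0, g)
  # epsilon = 1 is uniform over the 14 legal actions (3 sigma at 10000)
  set.seed(8)
  e1 <- replicate(10000, action_key(select_action_epsilon(net, s, 1)$action))
  counts <- table(e1)
  expect_identical(length(counts), 14L)
  p <- 1 / 14
  expect_true(all(abs(counts / 10000 - p) < 3 * sqrt(p * (1 - p) / 10000)))
})

test_that("episodes terminate, truncate at the cap, and log their lengths", {
  s <- arg_state(c("01", "10"))
  vt <- exact_table(s, 5)
  cfg <- train_config(epsilon = 0, episodes = 1, seed = 1)
  traj <- generate_episode(s, vt, cfg, seed = 1)
  expect_true(traj$terminal)
  expect_identical(length(traj$actions), 3L)
  capped <- train_config(epsilon = 1, episodes = 1, train_cap = 2, seed = 1)
  t2 <- generate_episode(fix$sample_a, init_network(make_scheme(4, 2, 1), 1),
                         capped, seed = 5)
  expect_false(t2$terminal)
  expect_identical(length(t2$actions), 2L)
  expect_null(t2$returns)
})

test_that("same-sample training is reproducible and keeps its history", {
  cfg <- train_config(episodes = 40, seed = 11)
  r1 <- train_same_sample(fix$sample_a, cfg)
  r2 <- train_same_sample(fix$sample_a, cfg)
  expect_identical(r1$net$W1, r2$net$W1)
  expect_identical(r1$history, r2$history)
  expect_length(r1$history, 40L)
  r0 <- train_same_sample(fix$sample_a, train_config(episodes = 0, seed = 11))
  expect_identical(r0$net$W1, init_network(r0$net$scheme,
                                           argrl:::derive_seed(11, 1))$W1)
})

test_that("rollouts with exact values recover minimal genealogies", {
  vt <- exact_table(fix$sample_a, 9)
  a <- build_arg(fix$sample_a, vt, stepmax = 300, seed = 1)
  expect_false(is_infinite_arg(a))
  expect_identical(a$length, 9L)
  v <- validate_arg(a)
  expect_true(v$legal && v$complete && v$tallies_consistent)
  # stepmax 1 cannot complete
  expect_true(is_infinite_arg(build_arg(fix$sample_a, vt, stepmax = 1)))
  # a stub rewarding ever-larger states loops forever
  expect_true(is_infinite_arg(build_arg(fix$sample_a, loop_stub,
                                        stepmax = 50, seed = 1)))
})

test_that("pool rotation draws without replacement and refills on exhaustion", {
  pool <- sprintf("%04d", c(11, 100, 110, 1000, 1001, 1010, 1100, 1101,
                            111, 10)) # ten 4-SNP sequences
  pool <- gsub("2", "1", pool)
  cfg <- train_config(episodes = 6, n_tr = 3, train_cap = 60,
                      alpha = 1e-4, seed = 13,
                      checkpoint_start = 1e6)
  r1 <- train_generalize(pool, cfg)
  r2 <- train_generalize(pool, cfg)
  expect_identical(r1$net$W1, r2$net$W1)       # same seed, same stream
  expect_length(r1$history, 6L)
  # 10 sequences, n_tr = 3: refills after every 3 episodes, and a final
  # checkpoint is always kept
  expect_gte(length(r1$checkpoints), 2L)
  expect_error(train_generalize(pool[1:2], cfg), "n_tr")
})

test_that("softened policies interpolate between greedy and uniform", {
  s <- arg_state(c("01", "10"))
  vt <- exact_table(s, 5)
  sp1 <- soften_policy(vt, s, g = 1)
  expect_identical(sp1$probs, 1)
  expect_identical(sp1$actions[[1]]$action$kind, "mutation")
  # two successor values -2 (mutations); keep both: uniform by symmetry
  sp2 <- soften_policy(vt, s, g = 2)
  expect_equal(sp2$probs, c(0.5, 0.5))
  # closed-form softmax on values (-1, -2) at temperature 1
  stub <- arg_value_fn(function(st) if (state_key(st) == "00 10") -1 else -2)
  sp3 <- soften_policy(stub, s, g = 2, temperature = 1)
  expect_equal(sp3$probs, c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-3)
  expect_error(soften_policy(vt, s, g = 0), "at least 1")
  expect_error(soften_policy(vt, s, g = 2, temperature = 0), "positive")
})

test_that("trained-policy rollouts always satisfy the parity law", {
  cfg <- train_config(episodes = 150, seed = 21)
  run <- train_same_sample(fix$sample_b, cfg)
  a <- build_arg(fix$sample_b, run$net, stepmax = 300, seed = 2)
  if (!is_infinite_arg(a)) {
    S <- n_segregating(fix$sample_b)
    n <- length(fix$sample_b)
    expect_identical((a$length - S - n + 1L) %% 2L, 0L)
    expect_true(validate_arg(a)$tallies_consistent)
  }
})
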