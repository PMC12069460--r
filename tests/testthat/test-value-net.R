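flatten_w <- function(net) c(as.vector(net$W1), net$b1, net$w2, net$b2)

unflatten_w <- function(net, w) {
  h <- nrow(net$W1); cc <- ncol(net$W1)
  net$W1 <- matrix(w[seq_len(h * cc)], nrow = h)
  i <- h * cc
  net$b1 <- w[(i + 1):(i + h)]; i <- i + h
  net$w2 <- w[(i + 1):(i + h)]; i <- i + h
  net$b2 <- w[i + 1]
  net
}

test_that("parameter count identity holds across schemes", {
  for (spec in list(list(10L, 3L, 216L), list(4L, 2L, 27L),
                    list(10L, 2L, 81L))) {
    sch <- make_scheme(spec[[1]], spec[[2]], 1)
    expect_identical(sch$c, spec[[3]])
    net <- init_network(sch, seed = 1)
    h <- sch$c %/% 2L
    expect_identical(net_n_params(net), (sch$c + 1L) * h + h + 1L)
  }
  expect_identical(net_n_params(init_network(make_scheme(10, 3, 1), 1)),
                   23545L)
})

test_that("initialization is seed-deterministic", {
  sch <- make_scheme(4, 2, 1)
  n1 <- init_network(sch, seed = 5)
  n2 <- init_network(sch, seed = 5)
  n3 <- init_network(sch, seed = 6)
  expect_identical(flatten_w(n1), flatten_w(n2))
  expect_false(identical(flatten_w(n1), flatten_w(n3)))
})

test_that("estimates are non-positive, zero on terminals, zero for zero nets", {
  sch <- make_scheme(4, 2, 1)
  set.seed(3)
  net <- init_network(sch, seed = 9)
  for (rep in 1:10) {
    s <- random_sample(n = sample(2:4, 1), L = 4L)
    expect_lte(state_value(net, s), 0)
  }
  expect_identical(state_value(net, arg_state("0000")), 0)
  zero <- unflatten_w(net, numeric(net_n_params(net)))
  expect_identical(state_value(zero, fix$worked_state), 0)
})

test_that("analytic gradient matches central finite differences", {
  sch <- make_scheme(4, 2, 1)
  set.seed(21)
  worst <- 0
  for (rep in 1:20) {
    net <- init_network(sch, seed = 100 + rep)
    s <- random_sample(n = sample(2:4, 1), L = 4L)
    g <- net_gradient(net, s)
    w0 <- flatten_w(net)
    eps <- 1e-6
    num <- vapply(seq_along(w0), function(j) {
      wp <- w0; wp[j] <- wp[j] + eps
      wm <- w0; wm[j] <- wm[j] - eps
      (state_value(unflatten_w(net, wp), s) -
         state_value(unflatten_w(net, wm), s)) / (2 * eps)
    }, numeric(1))
    rel <- max(abs(g - num) / pmax(abs(num), 1e-4))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("gradient structure: output-bias entry is 0 or -1, zero net is flat", {
  sch <- make_scheme(4, 2, 1)
  net <- init_network(sch, seed = 2)
  g <- net_gradient(net, fix$worked_state)
  expect_true(g[length(g)] %in% c(0, -1))
  zero <- unflatten_w(net, numeric(net_n_params(net)))
  gz <- net_gradient(zero, fix$worked_state)
  # output ReLU inactive at 0: nothing propagates to the hidden layer
  expect_identical(gz[seq_len(length(zero$W1) + length(zero$b1))],
                   numeric(length(zero$W1) + length(zero$b1)))
  expect_warning(net_gradient(net, arg_state("0000")), "terminal")
})

test_that("Monte Carlo update follows the gradient rule step by step", {
  sch <- make_scheme(4, 2, 1)
  net <- init_network(sch, seed = 4)
  s0 <- arg_state(c("0000", "0000"))
  # single-step episode: Delta w = alpha * (-1 - v(s0)) * grad
  traj <- list(states = list(s0, arg_state("0000")), terminal = TRUE)
  alpha <- 0.01
  v0 <- state_value(net, s0)
  g0 <- net_gradient(net, s0)
  upd <- mc_update(net, traj, alpha)
  expect_equal(flatten_w(upd), flatten_w(net) + alpha * (-1 - v0) * g0,
               tolerance = 1e-12)
  expect_identical(upd$episodes_trained, net$episodes_trained + 1L)
  # alpha = 0 and truncated trajectories leave the weights untouched
  expect_identical(flatten_w(mc_update(net, traj, 0)), flatten_w(net))
  trunc <- list(states = list(s0, s0), terminal = FALSE)
  expect_identical(flatten_w(mc_update(net, trunc, alpha)), flatten_w(net))
})

test_that("returns of a completed episode are -(T - t)", {
  cfg <- train_config(episodes = 1, seed = 1)
  traj <- generate_episode(arg_state(c("0000", "0000")),
                           init_network(make_scheme(4, 2, 1), 1), cfg,
                           seed = 1)
  expect_true(traj$terminal)
  expect_identical(length(traj$actions), 1L)
  expect_identical(traj$returns, -1L)
  s <- arg_state(c("01", "10"))
  vt <- value_iteration(s, depth_cap = 5)
  cfg0 <- train_config(epsilon = 0, episodes = 1, seed = 2)
  t2 <- generate_episode(s, vt, cfg0, seed = 2)
  expect_identical(t2$returns, c(-3L, -2L, -1L))
})

test_that("network serialization round-trips exactly and rejects mismatches", {
  sch <- make_scheme(4, 2, 1)
  net <- init_network(sch, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  save_network(net, path)
  back <- load_network(path)
  expect_identical(flatten_w(back), flatten_w(net))
  expect_identical(back$seed, net$seed)
  set.seed(9)
  for (rep in 1:10) {
    s <- random_sample(n = 3L, L = 4L)
    expect_identical(state_value(back, s), state_value(net, s))
  }
  expect_error(load_network(path, scheme = make_scheme(10, 3, 1)),
               "does not match")
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(load_network(bad), "parse|cannot")
})
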