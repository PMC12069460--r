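test_that("states canonicalize: order-independent equality, hashing, actions", {
  a <- arg_state(c("0100", "1000", "1010", "0011"))
  b <- arg_state(c("0011", "1010", "0100", "1000"))
  expect_identical(a, b)
  expect_identical(state_key(a), state_key(b))
  expect_identical(action_keys(legal_actions(a)), action_keys(legal_actions(b)))
})

test_that("state construction rejects malformed input", {
  expect_error(arg_state(c("01", "001")), "same length")
  expect_error(arg_state("01a0"), "symbols")
  expect_error(arg_state(c("00", "**")), "ancestral material")
  expect_error(arg_state(character(0)), "at least one")
})

test_that("coalescence merges ancestral material and detects conflicts", {
  expect_identical(coalesce_result("1000", "1***"), "1000")
  expect_identical(coalesce_result("0000", "0000"), "0000")
  expect_null(coalesce_result("0100", "0011"))   # marker 2 disagrees
  # disjoint ancestral material: allowed by default, refusable by flag
  expect_identical(coalesce_result("1***", "***1"), "1**1")
  expect_null(coalesce_result("1***", "***1", allow_disjoint = FALSE))
  expect_error(coalesce_result("10", "100"), "equal length")
})

test_that("the worked four-sequence state has 2 mutations and 12 recombinations", {
  acts <- legal_actions(fix$worked_state)
  kinds <- vapply(acts, `[[`, character(1), "kind")
  expect_length(acts, 14L)
  expect_identical(sum(kinds == "mutation"), 2L)
  expect_identical(sum(kinds == "recombination"), 12L)
  expect_identical(sum(kinds == "coalescence"), 0L)
  expect_setequal(action_keys(acts[kinds == "mutation"]),
                  c("M 0100 2", "M 0011 4"))
})

test_that("terminal state detection and empty action set", {
  expect_true(is_terminal_state(arg_state("0000")))
  expect_false(is_terminal_state(arg_state(c("0000", "0010"))))
  expect_false(is_terminal_state(arg_state("*000")))
  expect_identical(legal_actions(arg_state("0000")), list())
})

test_that("a duplicated identical type can coalesce with itself", {
  s6 <- arg_state(c("0000", "0000", "0010"))
  keys <- action_keys(legal_actions(s6))
  expect_true("C 0000 0000" %in% keys)
  r <- apply_action(s6, legal_actions(s6)[[1]])
  expect_identical(as.character(r$state), sort(c("0000", "0010")))
})

test_that("L = 2 toy state has exactly two mutations and two recombinations", {
  acts <- legal_actions(arg_state(c("01", "10")))
  expect_setequal(action_keys(acts),
                  c("M 01 2", "M 10 1", "R 01 1", "R 10 1"))
})

test_that("transitions follow the event semantics", {
  s0 <- fix$worked_state
  m <- apply_action(s0, list(kind = "mutation", seq = "0100", marker = 2))
  expect_identical(as.character(m$state), sort(c("0000", "1000", "1010", "0011")))
  r <- apply_action(m$state, list(kind = "recombination", seq = "1010", gap = 1))
  expect_identical(as.character(r$state),
                   sort(c("0000", "1000", "1***", "*010", "0011")))
  co <- apply_action(arg_state(c("0000", "0000")),
                     list(kind = "coalescence", pair = c("0000", "0000")))
  expect_identical(as.character(co$state), "0000")
})

test_that("illegal actions are rejected with reasons", {
  s <- fix$worked_state
  expect_error(apply_action(s, list(kind = "coalescence",
                                    pair = c("0100", "0011"))),
               "incompatible")
  expect_error(apply_action(s, list(kind = "mutation", seq = "1010",
                                    marker = 1)),
               "present on 2 copies")
  expect_error(apply_action(arg_state("0000"),
                            list(kind = "recombination", seq = "0000",
                                 gap = 1)),
               "never split")
  expect_error(apply_action(s, list(kind = "recombination", seq = "1010",
                                    gap = 4)),
               "breakpoint")
})

test_that("recombination breakpoints need ancestral material on both sides", {
  # *01* can only split in the middle gap
  acts <- legal_actions(arg_state(c("*01*", "1000", "0011")))
  recs <- grep("^R \\*01\\*", action_keys(acts), value = TRUE)
  expect_identical(recs, "R *01* 2")
})

test_that("the three-gamete test flags the samples that need recombination", {
  expect_true(recombination_required(fix$worked_state))
  expect_true(recombination_required(fix$sample_a))
  expect_true(recombination_required(fix$sample_b))
  expect_false(recombination_required(arg_state(c("00", "10", "11"))))
  expect_error(recombination_required(arg_state(c("0*", "10"))),
               "fully ancestral")
})

test_that("structural invariants hold along random trajectories", {
  set.seed(101)
  for (rep in 1:8) {
    s0 <- random_sample(n = 3L, L = 3L)
    states <- random_walk_states(s0, steps = 5L)
    for (i in seq_along(states)) {
      s <- states[[i]]
      m <- argrl:::seq_matrix(s)
      # column coverage: every marker ancestral somewhere
      expect_true(all(apply(m, 2, function(col) any(col != "*"))))
      # no all-* sequence
      expect_true(all(apply(m, 1, function(row) any(row != "*"))))
      if (i > 1) {
        expect_true(abs(length(s) - length(states[[i - 1]])) <= 1L)
      }
    }
  }
})

test_that("validate_arg replays, tallies, and pinpoints violations", {
  # complete minimal genealogy of the worked initial state
  arg <- enumerate_min_args(fix$worked_state, limit = 1)[[1]]
  v <- validate_arg(arg)
  expect_true(v$legal)
  expect_true(v$complete)
  expect_true(v$tallies_consistent)
  expect_identical(v$tallies[["mutation"]], n_segregating(fix$worked_state))
  expect_identical(v$tallies[["coalescence"]],
                   v$tallies[["recombination"]] + length(fix$worked_state) - 1L)

  empty <- new_arg(arg_state("000"))
  v0 <- validate_arg(empty)
  expect_true(v0$legal && v0$complete && v0$length == 0L)

  bad <- new_arg(fix$worked_state, list(structure(list(
    action = list(kind = "coalescence", pair = c("0100", "0011")),
    consumed = c("0100", "0011"), produced = "0111"), class = "arg_event")))
  vb <- validate_arg(bad)
  expect_false(vb$legal)
  expect_identical(vb$first_illegal, 1L)
})
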