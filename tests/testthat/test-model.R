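fig1 <- make_single_channel_calcium(k_open = 0.2, k_close = 0.4, k_in = 3,
                                    k_pump = 0.5)

test_that("the gated-channel model has the expected inventory and is valid", {
  expect_equal(nrow(fig1$places), 3)
  expect_equal(sum(fig1$places$kind == "discrete"), 2)
  expect_equal(nrow(fig1$transitions), 4)
  expect_equal(sum(fig1$transitions$kind == "stochastic"), 2)
  expect_equal(nrow(validate_hpn(fig1)), 0)
})

test_that("structural errors are rejected at construction", {
  net <- hpn() |> add_place("A") |> add_place("B") |>
    add_transition("t", "stochastic", rate = "1")
  expect_error(add_arc(net, "A", "B"), "bipartite")
  expect_error(add_place(net, "A"), "duplicate")
  expect_error(add_transition(net, "t", "stochastic", rate = "1"), "duplicate")
  expect_error(add_arc(net, "A", "nope"), "dangling")
  expect_error(add_transition(net, "t2", "stochastic"), "needs a rate")
  expect_error(add_transition(net, "t2", "immediate", rate = "1"), "must not carry")
})

test_that("large nets can be built programmatically", {
  net <- hpn("big")
  for (i in seq_len(10006)) net <- add_place(net, paste0("p", i))
  expect_equal(nrow(net$places), 10006)
})

test_that("validate reports regime violations as data, not errors", {
  # continuous transition writing a discrete place through a standard arc
  net <- hpn(parameters = c(k = 1)) |>
    add_place("D", "discrete", 1) |>
    add_transition("flow", "continuous", rate = "k") |>
    add_arc("flow", "D")
  v <- validate_hpn(net)
  expect_true("continuous_transition_discrete_place" %in% v$rule)

  # discrete place written by both regimes
  net2 <- hpn(parameters = c(k = 1)) |>
    add_place("D", "discrete", 1) |>
    add_place("C", "continuous", 1) |>
    add_transition("s", "stochastic", rate = "k") |>
    add_transition("c", "continuous", rate = "k * C") |>
    add_arc("s", "D") |> add_arc("D", "c") |> add_arc("C", "c", kind = "read")
  v2 <- validate_hpn(net2)
  expect_true("both_regimes_continuous" %in% v2$rule)

  # reset arcs are only defined on discrete places
  net3 <- hpn(parameters = c(k = 1)) |>
    add_place("C", "continuous", 1) |>
    add_transition("s", "stochastic", rate = "k") |>
    add_arc("C", "s", kind = "reset")
  expect_true("reset_equal_discrete_only" %in% validate_hpn(net3)$rule)

  # a rate reading an unconnected place
  net4 <- hpn(parameters = c(k = 1)) |>
    add_place("A", "discrete", 1) |> add_place("B", "discrete", 1) |>
    add_transition("t", "stochastic", rate = "k * B") |>
    add_arc("A", "t")
  expect_true("rate_place_unconnected" %in% validate_hpn(net4)$rule)
})

test_that("validation is idempotent and insertion-order independent", {
  build <- function(order) {
    net <- hpn(parameters = c(k = 1)) |>
      add_place("D", "discrete", 1) |>
      add_place("C", "continuous", 0)
    for (o in order) {
      net <- switch(o,
        a = add_transition(net, "flow", "continuous", rate = "k"),
        b = add_transition(net, "jump", "stochastic", rate = "k"))
    }
    net |> add_arc("flow", "D") |> add_arc("jump", "D")
  }
  v1 <- validate_hpn(build(c("a", "b")))
  v2 <- validate_hpn(build(c("b", "a")))
  expect_equal(v1, v2)
  expect_equal(v1, validate_hpn(build(c("a", "b"))))
})

test_that("stoichiometry reports signed changes, zeros and resets", {
  expect_equal(stoichiometry(fig1, "ch_open"),
               c(close = -1, open = 1), ignore_attr = TRUE)
  # read-only transition has an all-zero map
  net <- hpn(parameters = c(k = 1)) |>
    add_place("A", "discrete", 1) |>
    add_transition("t", "stochastic", rate = "k * A") |>
    add_arc("A", "t", kind = "read")
  expect_length(stoichiometry(net, "t"), 0)
  # A -> 2B
  net2 <- hpn(parameters = c(k = 1)) |>
    add_place("A", "discrete", 1) |> add_place("B", "discrete", 0) |>
    add_transition("t", "stochastic", rate = "MassAction(k)") |>
    add_arc("A", "t", weight = 1) |> add_arc("t", "B", weight = 2)
  expect_equal(stoichiometry(net2, "t"), c(A = -1, B = 2), ignore_attr = TRUE)
  # reset arcs are flagged separately
  net3 <- hpn(parameters = c(k = 1)) |>
    add_place("A", "discrete", 3) |>
    add_transition("t", "stochastic", rate = "k") |>
    add_arc("A", "t", kind = "reset")
  expect_equal(attr(stoichiometry(net3, "t"), "resets"), "A")
  # non-integer net change on a discrete place is an error
  net4 <- hpn(parameters = c(k = 1)) |>
    add_place("A", "discrete", 1) |>
    add_transition("t", "stochastic", rate = "k") |>
    add_arc("t", "A", weight = 0.5)
  expect_error(stoichiometry(net4, "t"), "non-integer")
})

test_that("enabledness follows the arc rules, inhibitors strictly", {
  expect_true(is_enabled(fig1, "ch_open", c(close = 1, open = 0, Ca = 0)))
  expect_false(is_enabled(fig1, "ch_open", c(close = 0, open = 1, Ca = 0)))
  net <- hpn(parameters = c(k = 1)) |>
    add_place("P", "discrete", 2) |>
    add_transition("t", "stochastic", rate = "k") |>
    add_arc("P", "t", kind = "inhibitor", weight = 2)
  expect_false(is_enabled(net, "t", c(P = 2)))  # at the bound: blocked
  expect_true(is_enabled(net, "t", c(P = 1)))
})

test_that("enabledness matches a brute-force checker on random nets and markings", {
  for (seed in 1:12) {
    net <- random_net(seed)
    grid <- expand.grid(P1 = 0:3, P2 = 0:3, P3 = 0:3)
    for (r in seq_len(nrow(grid))) {
      m <- unlist(grid[r, ])
      for (tid in net$transitions$id) {
        expect_equal(is_enabled(net, tid, m), brute_enabled(net, tid, m),
                     info = paste("seed", seed, tid, paste(m, collapse = ",")))
      }
    }
  }
})
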