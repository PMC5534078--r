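test_that("with constant slow propensities the jump equation reduces to the direct method", {
  net <- make_immigration_death()
  cfg <- function(alg) sim_config(alg, t_end = 20, grid_points = 41, seed = 3,
                                  record_events = TRUE)
  ssa <- pure_ssa_run(net, cfg("pure_ssa"), rng = random_stream(3))
  hr <- hr_exact_run(net, config = cfg("hr_exact"), rng = random_stream(3))
  acc <- accelerated_run(net, config = cfg("accelerated"), rng = random_stream(3))
  expect_identical(attr(ssa, "event_log"), attr(hr, "event_log"))
  expect_identical(attr(ssa, "event_log"), attr(acc, "event_log"))
  expect_identical(ssa$X, hr$X)
  expect_identical(ssa$X, acc$X)
})

test_that("a degenerate partition with no stochastic reactions equals pure ODE", {
  net <- make_decay(0.7, 10)
  cfg <- function(alg) sim_config(alg, t_end = 3, grid_points = 31, seed = 1)
  ode <- pure_ode_run(net, cfg("pure_ode"))
  part <- make_partition(net, deterministic = "decay")
  for (f in list(hr_exact_run, accelerated_run, hrssa_run)) {
    tr <- f(net, partition = part, config = cfg("hr_exact"))
    expect_equal(tr$X, ode$X, tolerance = 1e-8)
  }
})

test_that("decoupled slow reactions: exact and accelerated agree event-by-event", {
  net <- make_decoupled_hybrid()
  cfg <- function(alg) sim_config(alg, t_end = 12, grid_points = 25, seed = 11,
                                  record_events = TRUE)
  hr <- hr_exact_run(net, config = cfg("hr_exact"), rng = random_stream(11))
  acc <- accelerated_run(net, config = cfg("accelerated"), rng = random_stream(11))
  e1 <- attr(hr, "event_log"); e2 <- attr(acc, "event_log")
  expect_gt(nrow(e1), 50)
  expect_equal(nrow(e1), nrow(e2))
  expect_identical(e1$transition, e2$transition)
  expect_lt(max(abs(e1$time - e2$time)), 10 * cfg("hr_exact")$ode$root_tol)
  # reinitialisation-avoidance: the mechanism behind the reported speedups
  expect_equal(attr(hr, "reinits"), attr(hr, "events"))
  expect_equal(attr(acc, "reinits"), 0L)
  hrs <- hrssa_run(net, config = cfg("hrssa"))
  expect_equal(attr(hrs, "reinits"), 0L)
  # monotonicity of the counters
  expect_lte(attr(acc, "reinits"), attr(hr, "reinits"))
  expect_lte(attr(hrs, "reinits"), attr(hr, "reinits"))
})

test_that("hybrid ensemble mean of the gated model recovers k_in p_open / k_pump", {
  net <- make_single_channel_calcium(k_open = 1, k_close = 1, k_in = 4, k_pump = 1)
  e <- run_ensemble(net, sim_config("accelerated", t_end = 25, grid_points = 51,
                                    seed = 9, runs = 150))
  tails <- vapply(e$runs, function(tr) mean(tr$Ca[tr$time >= 12]), double(1))
  se <- stats::sd(tails) / sqrt(length(tails))
  expect_lt(abs(mean(tails) - 4 * 0.5 / 1), 3.5 * se)
})

test_that("pure modes respect their preconditions and closed forms", {
  net <- make_decay(1, 100)
  tr <- pure_ode_run(net, sim_config("pure_ode", t_end = 1, grid_points = 11))
  expect_equal(tr$X[11], 100 * exp(-1), tolerance = 1e-5)
  # pure SSA on a continuous place with non-integer marking is an error
  netc <- make_decay(1, 0.5)
  expect_error(pure_ssa_run(netc, sim_config("pure_ssa", t_end = 1)),
               "integer markings")
  # pure SSA stationary mean/variance of immigration-death
  id <- make_immigration_death(10, 1)
  tr2 <- pure_ssa_run(id, sim_config("pure_ssa", t_end = 600, grid_points = 601,
                                     seed = 4))
  xs <- tr2$X[tr2$time >= 20]
  se <- batch_se(xs, 20)
  expect_lt(abs(mean(xs) - 10), 3 * se)
})

test_that("discrete species stay integer-valued at every output point", {
  net <- make_single_channel_calcium()
  for (alg in c("hr_exact", "accelerated", "hrssa")) {
    tr <- simulate_hpn(net, alg, t_end = 8, grid_points = 33, seed = 2)
    expect_true(all(tr$open == round(tr$open)))
    expect_true(all(tr$close == round(tr$close)))
    expect_true(all(tr$open + tr$close == 1))
  }
})

test_that("immediate transitions pre-empt stochastic events and resolve by weight", {
  # the immediate transition consumes the token before any stochastic firing
  net <- hpn(parameters = c(k = 100)) |>
    add_place("S", "discrete", 1) |> add_place("Done", "discrete", 0) |>
    add_place("Never", "discrete", 0) |>
    add_transition("grab", "immediate") |>
    add_transition("slow_grab", "stochastic", rate = "MassAction(k)") |>
    add_arc("S", "grab") |> add_arc("grab", "Done") |>
    add_arc("S", "slow_grab") |> add_arc("slow_grab", "Never")
  tr <- pure_ssa_run(net, sim_config("pure_ssa", t_end = 1, grid_points = 3, seed = 1))
  expect_equal(tr$Done[3], 1)
  expect_equal(tr$Never[3], 0)
  # weighted conflict: frequencies approach w/(sum w)
  net2 <- hpn() |>
    add_place("S", "discrete", 1) |> add_place("A", "discrete", 0) |>
    add_place("B", "discrete", 0) |>
    add_transition("ta", "immediate", weight = 1) |>
    add_transition("tb", "immediate", weight = 3) |>
    add_arc("S", "ta") |> add_arc("ta", "A") |>
    add_arc("S", "tb") |> add_arc("tb", "B")
  hits <- vapply(1:800, function(s) {
    tr <- pure_ssa_run(net2, sim_config("pure_ssa", t_end = 1, grid_points = 2,
                                        seed = s))
    tr$B[2]
  }, double(1))
  se <- sqrt(0.75 * 0.25 / length(hits))
  expect_lt(abs(mean(hits) - 0.75), 3.5 * se)
})

test_that("scheduled and delayed transitions fire at their programmed times", {
  net <- hpn() |> add_place("A", "discrete", 0) |>
    add_transition("ts", "scheduled", schedule = c(5, 0, 5)) |>
    add_arc("ts", "A")
  tr <- pure_ssa_run(net, sim_config("pure_ssa", t_end = 10, grid_points = 21,
                                     seed = 1))
  expect_equal(tr$A[tr$time < 5], rep(0, sum(tr$time < 5)))
  expect_equal(tr$A[tr$time >= 5], rep(1, sum(tr$time >= 5)))
  # periodic schedule fires (end - start)/interval + 1 times
  net2 <- hpn() |> add_place("A", "discrete", 0) |>
    add_transition("ts", "scheduled", schedule = c(1, 2, 9)) |>
    add_arc("ts", "A")
  tr2 <- pure_ssa_run(net2, sim_config("pure_ssa", t_end = 10, grid_points = 21,
                                       seed = 1))
  expect_equal(tr2$A[21], 5)
  # deterministic delay: enabled at t=0, fires at t=delay
  net3 <- hpn() |> add_place("S", "discrete", 1) |> add_place("A", "discrete", 0) |>
    add_transition("td", "deterministic_delay", delay = 2.5) |>
    add_arc("S", "td") |> add_arc("td", "A")
  tr3 <- pure_ssa_run(net3, sim_config("pure_ssa", t_end = 5, grid_points = 21,
                                       seed = 1))
  expect_equal(tr3$A[tr3$time < 2.5], rep(0, sum(tr3$time < 2.5)))
  expect_equal(tr3$A[21], 1)
})

test_that("dynamic partitioning follows the two-predicate rule and its degenerate limits", {
  net <- make_immigration_death(1000, 1, x0 = 1000)
  p <- dynamic_partition(net, c(X = 1000), lambda_prop = 10, n_substrate = 100)
  expect_setequal(p$deterministic, c("immigrate", "die"))
  # empty substrate with n_substrate > 0 stays stochastic
  p2 <- dynamic_partition(net, c(X = 0), lambda_prop = 1e-9, n_substrate = 1)
  expect_true("die" %in% p2$stochastic)
  # randomized states against a direct re-evaluation of the rule
  set.seed(8)
  cm <- hpnsim:::compile_hpn(net, check = FALSE)
  for (rep in 1:50) {
    x <- sample(0:2000, 1)
    lp <- runif(1, 1, 100); ns <- sample(0:200, 1)
    p3 <- dynamic_partition(net, c(X = x), lambda_prop = lp, n_substrate = ns)
    for (tid in c("immigrate", "die")) {
      a <- unname(compute_propensities(net, c(X = x))$a[tid])
      subs <- cm$tr[[tid]]$pre_place
      expected <- a >= lp && all(c(X = x)[subs] >= ns)
      expect_equal(tid %in% p3$deterministic, expected,
                   info = paste(rep, tid, x, lp, ns))
    }
  }
  # thresholds that keep everything stochastic reproduce pure-SSA statistics
  id <- make_immigration_death(10, 1)
  d <- dynamic_run(id, sim_config("dynamic", t_end = 400, grid_points = 401,
                                  seed = 13, lambda_prop = 1e9,
                                  n_substrate = 1e9))
  xs <- d$X[d$time >= 20]
  expect_lt(abs(mean(xs) - 10), 3 * batch_se(xs, 19))
  # thresholds (~0, 0) turn everything deterministic
  dec <- make_decay(1, 100)
  d2 <- dynamic_run(dec, sim_config("dynamic", t_end = 1, grid_points = 11,
                                    seed = 1, lambda_prop = 1e-9, n_substrate = 0))
  expect_equal(d2$X[11], 100 * exp(-1), tolerance = 1e-4)
})

test_that("ensembles are deterministic, worker-invariant and average correctly", {
  net <- make_immigration_death(10, 1)
  cfg1 <- sim_config("pure_ssa", t_end = 10, grid_points = 21, seed = 21,
                     runs = 40, workers = 1)
  cfg4 <- sim_config("pure_ssa", t_end = 10, grid_points = 21, seed = 21,
                     runs = 40, workers = 4)
  e1 <- run_ensemble(net, cfg1)
  e4 <- run_ensemble(net, cfg4)
  expect_identical(as.data.frame(e1$mean), as.data.frame(e4$mean))
  # runs = 1: the average equals the single trace
  s1 <- run_ensemble(net, sim_config("pure_ssa", t_end = 10, grid_points = 21,
                                     seed = 21, runs = 1))
  single <- pure_ssa_run(net, sim_config("pure_ssa", t_end = 10, grid_points = 21,
                                         seed = 21),
                         rng = substream(random_stream(21), 0))
  expect_equal(s1$mean$X, single$X)
  # pointwise mean is the mean of the runs
  expect_equal(e1$mean$X,
               rowMeans(vapply(e1$runs, function(tr) tr$X,
                               double(nrow(e1$mean)))))
  # transient ensemble mean matches the birth-death moment ODE
  e <- run_ensemble(net, sim_config("pure_ssa", t_end = 10, grid_points = 11,
                                    seed = 33, runs = 400))
  finals <- vapply(e$runs, function(tr) tr$X[11], double(1))
  se <- stats::sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 10 * (1 - exp(-10))), 3 * se)
})

test_that("tidiers and plots expose trace structure", {
  net <- make_immigration_death()
  tr <- simulate_hpn(net, "pure_ssa", t_end = 2, grid_points = 5, seed = 1)
  long <- tidy(tr)
  expect_setequal(names(long), c("time", "node", "value"))
  expect_equal(nrow(long), 5)
  g <- glance(tr)
  expect_equal(g$algorithm, "pure_ssa")
  p <- autoplot(tr)
  expect_s3_class(p, "ggplot")
  ens <- simulate_hpn(net, "pure_ssa", t_end = 2, grid_points = 5, seed = 1,
                      runs = 3)
  expect_s3_class(ens, "hpn_ensemble")
  expect_equal(max(tidy(ens)$run), 3)
  expect_s3_class(autoplot(ens), "ggplot")
})
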