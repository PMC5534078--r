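test_that("propensities are rate values gated by enabledness", {
  net <- make_single_channel_calcium(k_open = 0.7, k_close = 0.3)
  ps <- compute_propensities(net, c(close = 1, open = 0, Ca = 0))
  expect_equal(unname(ps$a["ch_open"]), 0.7)
  expect_equal(unname(ps$a["ch_close"]), 0)
  expect_equal(ps$a0, 0.7)
  # all-disabled net
  net2 <- make_immigration_death(0, 1, x0 = 0)
  ps2 <- compute_propensities(net2, c(X = 0))
  expect_equal(ps2$a0, 0)
})

test_that("propensities match per-transition brute-force recomputation", {
  for (seed in 1:10) {
    net <- random_net(seed)
    m <- setNames(sample(0:3, 3, replace = TRUE), paste0("P", 1:3))
    ps <- compute_propensities(net, m)
    cm <- hpnsim:::compile_hpn(net, check = FALSE)
    for (tid in names(ps$a)) {
      expected <- if (brute_enabled(net, tid, m))
        eval_expression(cm$tr[[tid]]$rate, c(as.list(m), as.list(net$parameters)))
      else 0
      expect_equal(unname(ps$a[tid]), expected, info = paste(seed, tid))
    }
  }
})

test_that("direct method draws tau = -log(r)/a0 and selects by cumulative sum", {
  # replay the same stream to predict the draw exactly
  probe <- random_stream(123)
  r <- draw_uniform(probe, 2)
  ps <- compute_propensities(make_immigration_death(10, 1), c(X = 5))
  st <- direct_method_step(ps, random_stream(123))
  expect_equal(st$tau, -log(r[1]) / ps$a0)
  expect_equal(st$index, hpnsim:::select_index(ps$a, r[2] * ps$a0))
  # cumulative-sum arithmetic: a = (2,3,5), target 0.45 * 10 = 4.5 -> second
  expect_equal(hpnsim:::select_index(c(2, 3, 5), 4.5), 2)
  expect_equal(hpnsim:::select_index(c(10), 5), 1)
  # a0 = 0 signals no stochastic event
  expect_true(direct_method_step(list(a = numeric(), a0 = 0), random_stream(1))$no_event)
})

test_that("waiting times and selection frequencies follow the exponential/multinomial law", {
  a <- c(t1 = 2, t2 = 3, t3 = 5)
  ps <- structure(list(a = a, a0 = sum(a), transitions = names(a)),
                  class = "hpn_propensities")
  rng <- random_stream(99)
  n <- 1e5
  taus <- double(n); sel <- integer(n)
  for (i in seq_len(n)) {
    st <- direct_method_step(ps, rng)
    taus[i] <- st$tau; sel[i] <- st$index
  }
  se <- stats::sd(taus) / sqrt(n)
  expect_lt(abs(mean(taus) - 1 / 10), 3 * se)
  chi <- stats::chisq.test(tabulate(sel, 3), p = a / sum(a))
  expect_gt(chi$p.value, 0.001)
})

test_that("the dependency graph classifies gated-channel reactions as dependent", {
  net <- make_single_channel_calcium()
  dg <- build_dependency_graph(net)
  # ch_open changes `open`, which the deterministic inflow rate reads
  expect_true(dg$dependent[["ch_open"]])
  expect_true(dg$dependent[["ch_close"]])
  # an isolated reaction touching nothing read elsewhere is independent
  dh <- make_decoupled_hybrid()
  dg2 <- build_dependency_graph(dh)
  expect_false(any(dg2$dependent))
})

test_that("dependency graph matches pairwise recomputation on random nets", {
  for (seed in 1:10) {
    net <- random_net(seed)
    part <- make_partition(net)
    dg <- build_dependency_graph(net, part)
    cm <- hpnsim:::compile_hpn(net, check = FALSE)
    stoch <- part$stochastic
    for (j in stoch) {
      ch <- unique(c(names(cm$tr[[j]]$stoich), cm$tr[[j]]$resets))
      expected <- stoch[vapply(stoch, function(k) {
        length(intersect(cm$tr[[k]]$dep_places, ch)) > 0
      }, logical(1))]
      expect_setequal(dg$graph[[j]], expected)
    }
  }
})

test_that("after firing j, updating only graph[j] reproduces full recomputation", {
  for (seed in 1:8) {
    net <- random_net(seed)
    part <- make_partition(net)
    dg <- build_dependency_graph(net, part)
    cm <- hpnsim:::compile_hpn(net, check = FALSE)
    m <- initial_marking(net)
    ps <- compute_propensities(net, m, part$stochastic)
    for (j in part$stochastic) {
      if (ps$a[[j]] <= 0) next
      m2 <- hpnsim:::fire_cm(cm, cm$tr[[j]], m)
      full <- compute_propensities(net, m2, part$stochastic)
      partial <- ps$a
      upd <- compute_propensities(net, m2, dg$graph[[j]])
      partial[dg$graph[[j]]] <- upd$a
      expect_equal(partial, full$a, info = paste(seed, j))
    }
  }
})

test_that("fluctuation intervals bracket the state with floors and clamping", {
  net <- make_immigration_death()
  fi <- make_fluctuation_interval(net, c(X = 100), delta = 0.1, floor = 2)
  expect_equal(unname(fi$lo["X"]), 90)
  expect_equal(unname(fi$hi["X"]), 110)
  fi0 <- make_fluctuation_interval(net, c(X = 0), delta = 0.1, floor = 2)
  expect_equal(unname(fi0$lo["X"]), 0)
  expect_equal(unname(fi0$hi["X"]), 2)
  # propensity bounds contain sampled propensities inside the interval
  set.seed(31)
  fi5 <- make_fluctuation_interval(net, c(X = 5), delta = 0.3, floor = 2)
  for (x in seq(fi5$lo[["X"]], fi5$hi[["X"]])) {
    ps <- compute_propensities(net, c(X = x))
    expect_true(all(ps$a >= fi5$a_lo - 1e-12 & ps$a <= fi5$a_hi + 1e-12))
  }
})

test_that("rssa_select with tight bounds reproduces the direct method exactly", {
  # constant propensities: lower and upper bounds coincide, squeeze always
  # accepts, so waiting times are plain exponentials at a0
  net <- make_immigration_death(10, 1, x0 = 0)  # X=0: only immigration enabled
  fi <- make_fluctuation_interval(net, c(X = 0), delta = 0.1, floor = 0)
  expect_equal(unname(fi$a_lo["immigrate"]), unname(fi$a_hi["immigrate"]))
  rng <- random_stream(5)
  n <- 2000
  waits <- double(n)
  for (i in seq_len(n)) {
    res <- rssa_select(fi, function(t) c(X = 0), rng, net, t0 = 0)
    expect_equal(res$status, "fire")
    waits[i] <- res$t
  }
  se <- stats::sd(waits) / sqrt(n)
  expect_lt(abs(mean(waits) - 1 / fi$abar0), 3 * se)
  # two-sample KS against the direct method waiting times
  rng2 <- random_stream(6)
  ps <- compute_propensities(net, c(X = 0))
  dwaits <- vapply(seq_len(n), function(i) direct_method_step(ps, rng2)$tau,
                   double(1))
  ks <- stats::ks.test(waits, dwaits)
  expect_gt(ks$p.value, 0.001)
})

test_that("with loose bounds the acceptance rate approaches a_j / a_hi_j", {
  net <- make_immigration_death(10, 1)
  x <- 20
  fi <- make_fluctuation_interval(net, c(X = x), delta = 0.5, floor = 2)
  # expected acceptance probability for candidate j is a_j(x)/a_hi_j
  ps <- compute_propensities(net, c(X = x))
  p_acc <- sum(fi$a_hi / fi$abar0 * ps$a / fi$a_hi)
  rng <- random_stream(42)
  n_try <- 0; n_fire <- 0
  cm <- hpnsim:::compile_hpn(net, check = FALSE)
  for (i in 1:4000) {
    u <- draw_uniform(rng, 3)
    j <- hpnsim:::select_index(fi$a_hi, u[2] * fi$abar0)
    tid <- fi$transitions[j]
    acc <- u[3] * fi$a_hi[[tid]] <= ps$a[[tid]]
    n_try <- n_try + 1; n_fire <- n_fire + acc
  }
  se <- sqrt(p_acc * (1 - p_acc) / n_try)
  expect_lt(abs(n_fire / n_try - p_acc), 3.5 * se)
})

test_that("fixed seeds give bit-identical event sequences", {
  net <- make_immigration_death()
  cfg <- sim_config("pure_ssa", t_end = 20, grid_points = 41, seed = 77,
                    record_events = TRUE)
  t1 <- pure_ssa_run(net, cfg)
  t2 <- pure_ssa_run(net, cfg)
  expect_identical(attr(t1, "event_log"), attr(t2, "event_log"))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # identical seed, identical draw sequence across stream objects
  expect_identical(draw_uniform(random_stream(1), 10),
                   draw_uniform(random_stream(1), 10))
})
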