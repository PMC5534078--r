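test_that("the ODE system of the gated model is dCa/dt = k_in*open - k_pump*Ca", {
  net <- make_single_channel_calcium(k_in = 3, k_pump = 0.5)
  sys <- build_ode_system(net)
  expect_equal(sys$species, "Ca")
  cfg <- integrator_config(rtol = 1e-8, atol = 1e-10)
  # channel frozen open: Ca(t) = (k_in/k_pump) (1 - exp(-k_pump t))
  res <- integrate_ode_system(sys, y0 = c(Ca = 0), t0 = 0, t1 = 2, config = cfg,
                              frozen = c(as.list(net$parameters),
                                         list(open = 1, close = 0)))
  expect_equal(unname(res$y_stop), 6 * (1 - exp(-0.5 * 2)), tolerance = 1e-6)
  # channel frozen shut: nothing flows
  res0 <- integrate_ode_system(sys, y0 = c(Ca = 0), t0 = 0, t1 = 2, config = cfg,
                               frozen = c(as.list(net$parameters),
                                          list(open = 0, close = 1)))
  expect_equal(unname(res0$y_stop), 0)
  # no deterministic transitions -> zero-dimensional system
  sys0 <- build_ode_system(make_immigration_death())
  expect_length(sys0$species, 0)
})

test_that("the rhs equals the dense stoichiometry-matrix product S v(y)", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 3
    k <- runif(n, 0.2, 2); names(k) <- paste0("k", 1:n)
    net <- hpn("lin", parameters = k)
    for (i in 1:n) net <- add_place(paste0("C", i), net = net, kind = "continuous",
                                    initial = runif(1, 1, 5))
    S <- matrix(sample(-1:1, n * n, replace = TRUE), n, n)
    for (j in 1:n) {
      tid <- paste0("v", j)
      src <- sample(1:n, 1)
      net <- add_transition(net, tid, "continuous",
                            rate = sprintf("k%d * C%d", j, src))
      for (i in 1:n) {
        if (S[i, j] < 0) net <- add_arc(net, paste0("C", i), tid, weight = -S[i, j])
        if (S[i, j] > 0) net <- add_arc(net, tid, paste0("C", i), weight = S[i, j])
      }
      net <- add_arc(net, paste0("C", src), tid, kind = "modifier")
    }
    sys <- build_ode_system(net)
    rhs <- hpnsim:::make_rhs(sys, c(as.list(net$parameters)))
    y <- runif(n, 0, 4); names(y) <- sys$species
    got <- rhs(0, unname(y[sys$species]), NULL)[[1]]
    v <- vapply(1:n, function(j) {
      src <- hpnsim:::expr_dependencies(
        hpnsim:::compile_hpn(net, check = FALSE)$tr[[paste0("v", j)]]$rate,
        net$places$id)
      k[[paste0("k", j)]] * y[[src]]
    }, double(1))
    Sm <- S[match(sys$species, paste0("C", 1:n)), , drop = FALSE]
    expect_equal(got, as.numeric(Sm %*% v), tolerance = 1e-12)
  }
})

test_that("integration hits closed forms and localises event roots", {
  cfg <- integrator_config(rtol = 1e-8, atol = 1e-12)
  net <- make_decay(1, 1)
  sys <- build_ode_system(net, make_partition(net, deterministic = "decay"))
  res <- integrate_ode_system(sys, y0 = c(X = 1), t0 = 0, t1 = 1, config = cfg)
  expect_equal(unname(res$y_stop), exp(-1), tolerance = 10 * cfg$rtol)
  # event at y - 0.5 stops at ln 2
  ev <- integrate_ode_system(sys, y0 = c(X = 1), t0 = 0, t1 = 5, config = cfg,
                             events = list(function(t, y) y[1] - 0.5))
  expect_equal(ev$stop, "event")
  expect_equal(ev$t_stop, log(2), tolerance = 1e-6)
})

test_that("a stiff two-scale linear system matches the matrix exponential", {
  net <- hpn("stiff", parameters = c(kf = 1000, ks = 0.1)) |>
    add_place("A", "continuous", 1) |> add_place("B", "continuous", 0) |>
    add_transition("fast", "continuous", rate = "kf * A") |>
    add_transition("slow", "continuous", rate = "ks * B") |>
    add_arc("A", "fast") |> add_arc("fast", "B") |> add_arc("B", "slow")
  sys <- build_ode_system(net)
  cfg <- integrator_config(rtol = 1e-8, atol = 1e-12)
  res <- integrate_ode_system(sys, y0 = c(A = 1, B = 0), t0 = 0, t1 = 2,
                              config = cfg)
  A <- matrix(c(-1000, 0, 1000, -0.1), 2, 2, byrow = TRUE)
  ref <- as.numeric(Matrix::expm(A * 2) %*% c(1, 0))
  expect_equal(unname(res$y_stop[sys$species]),
               ref[match(sys$species, c("A", "B"))],
               tolerance = 10 * cfg$rtol)
})

test_that("reinitialisation restarts cleanly and counts once per call", {
  net <- make_decay(1, 1)
  sys <- build_ode_system(net, make_partition(net, deterministic = "decay"))
  cfg <- integrator_config(rtol = 1e-8, atol = 1e-12)
  s <- ode_session(sys, y0 = c(X = 1), t0 = 0, config = cfg)
  ode_integrate(s, 0.5)
  expect_equal(s$reinits, 0L)
  ode_reinitialise(s, s$y, 0.5)  # unchanged state
  expect_equal(s$reinits, 1L)
  ode_integrate(s, 1)
  expect_equal(unname(s$y), exp(-1), tolerance = 10 * cfg$rtol)
  ode_reinitialise(s)
  expect_equal(s$reinits, 2L)
})

test_that("mass is conserved for continuous A <-> B", {
  net <- make_ab_equilibrium(2, 1, a0 = 3, b0 = 1)
  cfg <- sim_config("pure_ode", t_end = 10, grid_points = 101, atol = 1e-9)
  tr <- pure_ode_run(net, cfg)
  expect_lt(max(abs(tr$A + tr$B - 4)), 100 * cfg$ode$atol)
})

test_that("tightening rtol monotonically reduces the error against the closed form", {
  net <- make_decay(1, 1)
  sys <- build_ode_system(net, make_partition(net, deterministic = "decay"))
  errs <- vapply(c(1e-4, 1e-6, 1e-8), function(rt) {
    res <- integrate_ode_system(sys, y0 = c(X = 1), t0 = 0, t1 = 3,
                                config = integrator_config(rtol = rt, atol = 1e-14))
    abs(unname(res$y_stop) - exp(-3))
  }, double(1))
  expect_true(all(diff(errs) < 0))
})

test_that("negative round-off markings are clamped, larger ones raise", {
  expect_equal(hpnsim:::clamp_nonneg(c(a = -1e-12), atol = 1e-9), c(a = 0))
  expect_error(hpnsim:::clamp_nonneg(c(a = -1), atol = 1e-9), "negative")
})
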