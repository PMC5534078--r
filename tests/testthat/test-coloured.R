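# a channel-only coloured net (the discrete subnet of the spatial model)
channel_net <- function(n = 3) {
  coloured_hpn("channels", parameters = c(k_open = 1, k_close = 1)) |>
    add_colourset("chCS", 1, n) |>
    add_coloured_place("closed", "discrete", colset = "chCS", initial = 1) |>
    add_coloured_place("open", "discrete", colset = "chCS", initial = 0) |>
    add_coloured_transition("ch_open", "stochastic", rate = "MassAction(k_open)",
                            variables = c(m = "chCS")) |>
    add_coloured_transition("ch_close", "stochastic", rate = "MassAction(k_close)",
                            variables = c(m = "chCS")) |>
    add_coloured_arc("closed", "ch_open", colour = list("m")) |>
    add_coloured_arc("ch_open", "open", colour = list("m")) |>
    add_coloured_arc("open", "ch_close", colour = list("m")) |>
    add_coloured_arc("ch_close", "closed", colour = list("m"))
}

test_that("binding enumeration solves the guard constraints in canonical order", {
  cn <- channel_net(3)
  b <- enumerate_bindings(cn, "ch_open")
  expect_equal(nrow(b), 3)
  expect_equal(b$m, 1:3)
  # guard false -> no bindings
  cn2 <- channel_net(3) |>
    add_coloured_transition("never", "stochastic", rate = "k_open",
                            variables = c(m = "chCS"), guard = "m > 3")
  expect_equal(nrow(enumerate_bindings(cn2, "never")), 0)
  # 4-neighbour diffusion guard: 2*(2*W*H - W - H) directed edges
  cc <- make_coloured_calcium(1, 5, 4, c(2, 2))
  expect_equal(nrow(enumerate_bindings(cc, "diffuse")), 2 * (2 * 5 * 4 - 5 - 4))
  expect_equal(nrow(enumerate_bindings(cc, "Ca_inflow")), 1)
})

test_that("the channel subnet unfolds to three identical copies", {
  fl <- unfold(channel_net(3))
  expect_equal(nrow(fl$places), 6)
  expect_equal(nrow(fl$transitions), 6)
  expect_setequal(fl$places$id,
                  c(paste0("closed__", 1:3), paste0("open__", 1:3)))
  expect_equal(nrow(validate_hpn(fl)), 0)
  # rates expand per colour after unfolding
  cm <- hpnsim:::compile_hpn(fl)
  expect_equal(cm$tr[["ch_open__2"]]$rate, quote(k_open * closed__2))
})

test_that("the small spatial model unfolds with the derived instance counts", {
  cc <- make_coloured_calcium(1, 2, 2, c(1, 1))
  fl <- unfold(cc)
  expect_equal(nrow(fl$places), 6)                       # 2 channel-state + 4 grid
  expect_equal(sum(grepl("^diffuse", fl$transitions$id)), 8)  # 2x2 directed edges
  expect_equal(nrow(validate_hpn(fl)), 0)
  # inflow is a single instance with the constant cluster colour
  expect_equal(sum(grepl("^Ca_inflow", fl$transitions$id)), 1)
  expect_equal(stoichiometry(fl, "Ca_inflow"), c(Ca__1_1 = 1), ignore_attr = TRUE)
})

test_that("singleton colour sets unfold to the base net up to renaming", {
  cn <- coloured_hpn("single", parameters = c(k = 2)) |>
    add_colourset("one", 1, 1) |>
    add_coloured_place("A", "discrete", colset = "one", initial = 3) |>
    add_coloured_place("B", "discrete", colset = "one", initial = 0) |>
    add_coloured_transition("t", "stochastic", rate = "MassAction(k)",
                            variables = c(m = "one")) |>
    add_coloured_arc("A", "t", colour = list("m")) |>
    add_coloured_arc("t", "B", colour = list("m"))
  fl <- unfold(cn)
  expect_equal(nrow(fl$places), 2)
  expect_equal(nrow(fl$transitions), 1)
  expect_equal(unname(initial_marking(fl)), c(3, 0))
  expect_equal(stoichiometry(fl, "t__1"),
               c(A__1 = -1, B__1 = 1), ignore_attr = TRUE)
})

test_that("out-of-range colour arithmetic is a hard error unless guarded away", {
  bad <- coloured_hpn("bad", parameters = c(k = 1)) |>
    add_colourset("G", 1, 3) |>
    add_coloured_place("P", "discrete", colset = "G", initial = 1) |>
    add_coloured_transition("shift", "stochastic", rate = "MassAction(k)",
                            variables = c(m = "G")) |>
    add_coloured_arc("P", "shift", colour = list("m")) |>
    add_coloured_arc("shift", "P", colour = list("m + 1"))
  expect_error(unfold(bad), "out of range.*shift.*guard")
  guarded <- coloured_hpn("ok", parameters = c(k = 1)) |>
    add_colourset("G", 1, 3) |>
    add_coloured_place("P", "discrete", colset = "G", initial = 1) |>
    add_coloured_transition("shift", "stochastic", rate = "MassAction(k)",
                            variables = c(m = "G"), guard = "m < 3") |>
    add_coloured_arc("P", "shift", colour = list("m")) |>
    add_coloured_arc("shift", "P", colour = list("m + 1"))
  fl <- unfold(guarded)
  expect_equal(nrow(fl$transitions), 2)
})

test_that("unfolding counts and names are declaration-order independent", {
  base <- make_coloured_calcium(2, 3, 3, c(2, 2))
  fl1 <- unfold(base)
  # rebuild with places/transitions declared in a different order
  alt <- coloured_hpn("coloured_calcium", parameters = base$parameters) |>
    add_colourset("OS", -1, 1) |>
    add_colourset("GY", 1, 3) |>
    add_colourset("GX", 1, 3) |>
    add_colourset_product("Grid2D", c("GX", "GY")) |>
    add_colourset("chCS", 1, 2)
  for (i in rev(seq_len(nrow(base$places))))
    alt <- add_coloured_place(alt, base$places$id[i], base$places$kind[i],
                              colset = base$places$colset[i],
                              initial = base$places$initial[i])
  for (i in rev(seq_len(nrow(base$transitions)))) {
    tr <- base$transitions[i, ]
    alt$transitions <- dplyr::bind_rows(alt$transitions, tr)
  }
  alt$arcs <- base$arcs[rev(seq_len(nrow(base$arcs))), ]
  fl2 <- unfold(alt)
  expect_setequal(fl1$places$id, fl2$places$id)
  expect_setequal(fl1$transitions$id, fl2$transitions$id)
  expect_equal(nrow(fl1$arcs), nrow(fl2$arcs))
})

test_that("size_report matches the materialised unfold", {
  for (args in list(list(1, 2, 2, c(1, 1)), list(3, 4, 3, c(2, 2)),
                    list(0, 3, 3, c(1, 1)))) {
    cc <- do.call(make_coloured_calcium, args)
    sr <- size_report(cc)
    fl <- unfold(cc)
    expect_equal(sum(sr$instances[sr$class == "place"]), nrow(fl$places))
    expect_equal(sum(sr$instances[sr$class == "transition"]), nrow(fl$transitions))
  }
  # a channel-free model still unfolds to a valid net
  cc0 <- make_coloured_calcium(0, 3, 3, c(1, 1))
  fl0 <- unfold(cc0)
  expect_equal(sum(fl0$places$kind == "discrete"), 0)
  expect_equal(nrow(validate_hpn(fl0)), 0)
})

test_that("diffusion on the unfolded grid conserves total calcium (channels shut, no pump)", {
  cc <- make_coloured_calcium(0, 6, 6, c(1, 1), D = 1, k_pump = 0,
                              ca_init = c("3_3" = 12, "4_3" = 3))
  fl <- unfold(cc)
  cfg <- sim_config("pure_ode", t_end = 2, grid_points = 21, atol = 1e-9)
  tr <- pure_ode_run(fl, cfg)
  totals <- rowSums(as.matrix(tr[grepl("^Ca__", names(tr))]))
  expect_lt(max(abs(totals - 15)), 100 * cfg$ode$atol)
  # and it spreads: the loaded cell loses mass to its neighbours
  expect_lt(tr$Ca__3_3[21], 12)
  expect_gt(tr$Ca__2_3[21], 0)
})
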