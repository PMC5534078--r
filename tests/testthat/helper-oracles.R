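# Independent oracles used across the suite. These deliberately re-derive
# results by the most naive route available (recursive evaluation, full
# recomputation, exhaustive enumeration) so that they share no code with the
# implementation paths they check.

# naive recursive expression evaluator
naive_eval <- function(e, env) {
  if (is.numeric(e)) return(as.double(e))
  if (is.name(e)) return(as.double(env[[as.character(e)]]))
  op <- as.character(e[[1]])
  a <- lapply(as.list(e)[-1], naive_eval, env = env)
  switch(op,
         "(" = a[[1]],
         "+" = if (length(a) == 1) a[[1]] else a[[1]] + a[[2]],
         "-" = if (length(a) == 1) -a[[1]] else a[[1]] - a[[2]],
         "*" = a[[1]] * a[[2]],
         "/" = a[[1]] / a[[2]],
         "^" = a[[1]]^a[[2]],
         "exp" = exp(a[[1]]),
         "log" = log(a[[1]]),
         "sqrt" = sqrt(a[[1]]),
         "abs" = abs(a[[1]]),
         "min" = do.call(min, a),
         "max" = do.call(max, a),
         "floor" = floor(a[[1]]),
         "ceiling" = ceiling(a[[1]]),
         stop("naive_eval: unknown op ", op))
}

# leaf-walk dependency oracle
leaf_vars <- function(e) {
  if (is.numeric(e)) return(character())
  if (is.name(e)) return(as.character(e))
  if (is.call(e)) return(unique(unlist(lapply(as.list(e)[-1], leaf_vars))))
  character()
}

# brute-force enabledness straight from the arc table
brute_enabled <- function(net, tid, marking) {
  data <- c(as.list(marking), as.list(net$parameters))
  a <- net$arcs[net$arcs$target == tid & net$arcs$source %in% net$places$id, ]
  for (k in seq_len(nrow(a))) {
    w <- eval_expression(a$weight[[k]], data)
    m <- marking[[a$source[k]]]
    ok <- switch(a$kind[k],
                 standard = m >= w, read = m >= w,
                 equal = m == w, inhibitor = m < w,
                 reset = TRUE, modifier = TRUE)
    if (!ok) return(FALSE)
  }
  trow <- net$transitions[net$transitions$id == tid, ]
  if (trow$kind == "continuous") {
    cmx <- hpnsim:::compile_hpn(net, check = FALSE)
    return(eval_expression(cmx$tr[[tid]]$rate, data) > 0)
  }
  TRUE
}

# small random mass-action nets for property tests
random_net <- function(seed, n_places = 3, n_trans = 3) {
  set.seed(seed)
  k <- stats::runif(n_trans, 0.2, 2)
  names(k) <- paste0("k", seq_len(n_trans))
  net <- hpn(paste0("rand", seed), parameters = k)
  pids <- paste0("P", seq_len(n_places))
  for (p in pids) net <- add_place(net, p, "discrete", initial = sample(0:3, 1))
  for (j in seq_len(n_trans)) {
    tid <- paste0("T", j)
    net <- add_transition(net, tid, "stochastic",
                          rate = sprintf("MassAction(k%d)", j))
    ins <- sample(pids, sample(1:2, 1))
    outs <- sample(pids, sample(0:2, 1))
    for (p in ins)
      net <- add_arc(net, p, tid,
                     kind = sample(c("standard", "read", "inhibitor"), 1,
                                   prob = c(0.6, 0.3, 0.1)),
                     weight = sample(1:2, 1))
    for (p in outs) net <- add_arc(net, tid, p, weight = sample(1:2, 1))
  }
  net
}

# order-insensitive structural equality of two flat nets
expect_net_equal <- function(a, b) {
  ord <- function(x) {
    list(places = x$places[order(x$places$id), ],
         transitions = x$transitions[order(x$transitions$id), ],
         arcs = x$arcs[order(x$arcs$source, x$arcs$target, x$arcs$kind), ],
         parameters = x$parameters[order(names(x$parameters))])
  }
  oa <- ord(a); ob <- ord(b)
  expect_equal(oa$places, ob$places, ignore_attr = TRUE)
  expect_equal(oa$parameters, ob$parameters)
  expect_equal(oa$transitions$id, ob$transitions$id)
  expect_equal(oa$transitions$kind, ob$transitions$kind)
  expect_equal(oa$transitions$rate, ob$transitions$rate)
  expect_equal(oa$arcs$source, ob$arcs$source)
  expect_equal(oa$arcs$kind, ob$arcs$kind)
  expect_equal(lapply(oa$arcs$weight, function(w) eval_expression(w, c(a$parameters, setNames(rep(1, nrow(a$places)), a$places$id)))),
               lapply(ob$arcs$weight, function(w) eval_expression(w, c(b$parameters, setNames(rep(1, nrow(b$places)), b$places$id)))))
}

# batch-means standard error for autocorrelated stationary samples
batch_se <- function(x, n_batches = 50) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), double(1))
  stats::sd(means) / sqrt(n_batches)
}
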