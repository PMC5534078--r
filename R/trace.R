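#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_line labs
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a simulation trace into long format
#'
#' @param x An `hpn_trace`.
#' @param ... Unused.
#' @return A tibble with columns `time`, `node`, `value`.
#' @export
tidy.hpn_trace <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"time",
                      names_to = "node", values_to = "value")
}

#' One-row summary of a trace
#'
#' @inheritParams tidy.hpn_trace
#' @return A tibble with the algorithm, seed, horizon, stochastic event
#'   count and solver reinitialisation count.
#' @export
glance.hpn_trace <- function(x, ...) {
  tibble(algorithm = attr(x, "algorithm"), seed = attr(x, "seed"),
         run = attr(x, "run"), t_end = max(x$time),
         n_grid = nrow(x), events = attr(x, "events"),
         reinits = attr(x, "reinits"),
         rejects = attr(x, "rejects") %||% NA_integer_,
         timed_fired = attr(x, "timed_fired") %||% NA_integer_)
}

#' @export
tidy.hpn_ensemble <- function(x, ...) {
  out <- purrr::imap(x$runs, function(tr, i) mutate(tidy(tr), run = i))
  bind_rows(out)
}

#' @export
glance.hpn_ensemble <- function(x, ...) {
  tibble(algorithm = x$config$algorithm, seed = x$config$seed,
         runs = length(x$runs),
         events = sum(vapply(x$runs, function(t) attr(t, "events"), integer(1))),
         reinits = sum(vapply(x$runs, function(t) attr(t, "reinits"), integer(1))))
}

#' Plot a trace
#'
#' @param object An `hpn_trace` or `hpn_ensemble`.
#' @param nodes Optional character vector restricting the plotted columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hpn_trace <- function(object, nodes = NULL, ...) {
  d <- tidy(object)
  if (!is.null(nodes)) d <- filter(d, .data$node %in% nodes)
  ggplot(d, aes(x = .data$time, y = .data$value, colour = .data$node)) +
    geom_line() +
    labs(x = "time", y = "marking", colour = NULL,
         title = paste0(attr(object, "model") %||% "", " (",
                        attr(object, "algorithm") %||% "trace", ")"))
}

#' @export
autoplot.hpn_ensemble <- function(object, nodes = NULL, ...) {
  autoplot(object$mean, nodes = nodes, ...) +
    ggplot2::labs(subtitle = paste0("mean of ", length(object$runs), " runs"))
}

#' @export
print.hpn_trace <- function(x, ...) {
  cat("<hpn_trace> algorithm=", attr(x, "algorithm") %||% "?",
      " events=", attr(x, "events") %||% NA,
      " reinits=", attr(x, "reinits") %||% NA, "\n", sep = "")
  NextMethod()
}

# ---------------------------------------------------------------------------
# views

#' Result views over node-name patterns
#'
#' A view selects trace columns by a regular expression over flat node
#' names and optionally aggregates the matches (`sum` or `mean`) into a
#' single curve -- e.g. total calcium over an unfolded spatial grid with
#' `view("total_Ca", "^Ca__")` and `aggregate = "sum"`.
#'
#' @param name View name (becomes the output column name when
#'   aggregating).
#' @param pattern Regular expression matched against node names.
#' @param aggregate `"none"`, `"sum"` or `"mean"`.
#' @return An `hpn_view`.
#' @export
view <- function(name, pattern, aggregate = c("none", "sum", "mean")) {
  aggregate <- match.arg(aggregate)
  structure(list(name = name, pattern = pattern, aggregate = aggregate),
            class = "hpn_view")
}

#' Register a view on a model
#'
#' Validates that the pattern matches at least one node of the net and
#' attaches the view; registered views are applied by the command-line
#' `simulate` subcommand when exporting CSV.
#'
#' @inheritParams add_place
#' @param v An [view()].
#' @return The updated net.
#' @export
register_view <- function(net, v) {
  stopifnot(inherits(net, "hpn"), inherits(v, "hpn_view"))
  nodes <- node_ids(net)
  if (!any(grepl(v$pattern, nodes)))
    stop_hpn(paste0("view `", v$name, "` matches no node (pattern: ",
                    v$pattern, ")"), "hpn_view_error")
  net$views <- c(net$views %||% list(), list(v))
  net
}

#' Apply a view to a trace
#'
#' @param trace An `hpn_trace`.
#' @param v An [view()].
#' @return An `hpn_trace` restricted to (or aggregated over) the matching
#'   columns.
#' @export
apply_view <- function(trace, v) {
  stopifnot(inherits(v, "hpn_view"))
  cols <- setdiff(names(trace), "time")
  hit <- cols[grepl(v$pattern, cols)]
  if (!length(hit))
    stop_hpn(paste0("view `", v$name, "` matches no trace column"), "hpn_view_error")
  out <- if (v$aggregate == "none") {
    trace[c("time", hit)]
  } else {
    m <- as.matrix(trace[hit])
    val <- if (v$aggregate == "sum") rowSums(m) else rowMeans(m)
    res <- tibble(time = trace$time)
    res[[v$name]] <- val
    res
  }
  attributes(out)[c("algorithm", "seed", "run", "events", "reinits")] <-
    attributes(trace)[c("algorithm", "seed", "run", "events", "reinits")]
  class(out) <- unique(c("hpn_trace", class(out)))
  out
}

# ---------------------------------------------------------------------------
# CSV export

#' Export a trace to CSV
#'
#' Writes `time,<node...>` with one row per output grid point, `.` decimal
#' point, no thousands separators, LF line endings and full double
#' precision (`%.17g`, which round-trips doubles exactly). Output is
#' byte-identical across repeated runs with identical configuration and
#' seed.
#'
#' @param trace An `hpn_trace` (or any data frame whose first column is
#'   time).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(trace, path) {
  if (nrow(trace) == 0) stop_hpn("trace is empty", "hpn_io_error")
  df <- as.data.frame(trace)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con, sep = "\n")
  cols <- lapply(df, function(x) sprintf("%.17g", as.double(x)))
  lines <- do.call(paste, c(cols, sep = ","))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read back a CSV trace written by [export_csv()]
#'
#' @param path File path.
#' @return A tibble with a `time` column and one column per node.
#' @export
read_csv_trace <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
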