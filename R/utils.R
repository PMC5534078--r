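#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr filter mutate select arrange bind_rows left_join group_by summarise ungroup
#' @importFrom purrr map imap
#' @importFrom stats runif setNames
NULL

`%||%` <- rlang::`%||%`

stop_hpn <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "hpnsim_error"), ...)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_whole <- function(x, tol = 1e-9) {
  is.numeric(x) & abs(x - round(x)) <= tol
}
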