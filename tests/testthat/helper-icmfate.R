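# Shared fixtures, built in code.

# a small embryo state assembled by hand (no simulation), for composition
# and ablation arithmetic; x levels sit squarely in the three identity bands
make_state <- function(x_levels, status = NULL, alive = NULL) {
  n <- length(x_levels)
  structure(list(
    id = seq_len(n),
    pos = matrix(stats::rnorm(3 * n), ncol = 3),
    radius = rep(1, n),
    x = x_levels,
    status = status %||% rep("DP", n),
    birth_time = rep(0, n),
    next_division = rep(10, n),
    alive = alive %||% rep(TRUE, n),
    beyond_since = rep(NA_real_, n),
    beyond_dir = rep(0L, n),
    t = 0,
    dimensionality = 3,
    n_divisions = 0L,
    next_id = n + 1L,
    config = NULL
  ), class = "embryo_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default circuit equilibria, computed once per test run
default_eq <- local({
  eq <- NULL
  function() {
    if (is.null(eq)) eq <<- find_equilibria(circuit_params())
    eq
  }
})

x_high <- function() max(default_eq()$xa)
x_low <- function() min(default_eq()$xa[default_eq()$stability == "stable"])
x_saddle <- function() {
  eq <- default_eq()
  eq$xa[eq$stability != "stable"][1]
}
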