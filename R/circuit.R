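# Core dynamical system: per-cell NANOG dynamics under mean-field repression,
# the two-cluster reduction, nullclines, equilibria and stability.

#' Circuit parameters for the NANOG lateral-inhibition model
#'
#' The model tracks one dimensionless variable per cell, the NANOG level
#' \eqn{x_i}, which is produced under self-activation and repressed by the
#' average NANOG level \eqn{\langle x \rangle_i} over the cell's signalling
#' neighbourhood (including the cell itself):
#' \deqn{\frac{dx_i}{dt} =
#'   \alpha \frac{(1+x_i^n)^m}{(1+x_i^n)^m + (\langle x\rangle_i/K)^{2m}}
#'   - x_i}
#' The neighbourhood mean stands in for local growth-factor (FGF4)
#' concentration, so that high-NANOG cells push their neighbours towards the
#' low-NANOG (primitive endoderm) state: lateral inhibition through a secreted
#' signal.
#'
#' The defaults (`alpha = 4.5`, `K = 0.9`, `n = 2`, `m = 2`) were calibrated
#' by a numerical scan, first for the bistable regime of the two-cluster
#' reduction (two stable mirror equilibria, one cluster high and the other
#' low, well separated, plus a single unstable symmetric state), then within
#' that regime for a balanced mean epiblast:PrE split of the full agent-based
#' wild type -- the same two-free-parameter calibration to wild-type
#' behaviour that defines the model. See the package vignette.
#'
#' @param alpha Maximal production rate (dimensionless), > 0.
#' @param K Mean-field repression threshold (dimensionless concentration), > 0.
#' @param n NANOG self-activation Hill exponent, integer >= 1.
#' @param m Cooperativity exponent of the production/repression terms,
#'   integer >= 1.
#' @return An object of class `circuit_params` (a named list).
#' @examples
#' p <- circuit_params()
#' production(0, 0, p)        # alpha: no repression
#' production(0, p$K, p)      # alpha / 2
#' @export
circuit_params <- function(alpha = 4.5, K = 0.9, n = 2, m = 2) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0,
            is.numeric(K), length(K) == 1, K > 0,
            n >= 1, n == round(n), m >= 1, m == round(m))
  structure(list(alpha = alpha, K = K, n = as.integer(n), m = as.integer(m)),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("<circuit_params> alpha = %g, K = %g, n = %d, m = %d\n",
              x$alpha, x$K, x$n, x$m))
  invisible(x)
}

check_params <- function(p) {
  if (!inherits(p, "circuit_params")) {
    stop("`p` must be a `circuit_params` object; see circuit_params()",
         call. = FALSE)
  }
  p
}

#' NANOG production rate
#'
#' Production term of the circuit: self-activated synthesis repressed by the
#' neighbourhood mean-field. Always in `(0, alpha]`.
#'
#' @param x NANOG level(s), >= 0. Vectorised.
#' @param field Neighbourhood mean NANOG (the repression signal), >= 0.
#' @param p A [circuit_params()] object.
#' @return Production rate(s), same length as the longer of `x`/`field`.
#' @export
production <- function(x, field, p = circuit_params()) {
  check_params(p)
  if (any(x < 0) || any(field < 0)) {
    stop("`x` and `field` must be non-negative", call. = FALSE)
  }
  act <- (1 + x^p$n)^p$m
  p$alpha * act / (act + (field / p$K)^(2 * p$m))
}

#' Right-hand side of the per-cell NANOG equation
#'
#' `production(x, field, p) - x`: synthesis minus linear turnover.
#'
#' @inheritParams production
#' @return Signed rate(s) of change of `x`.
#' @export
nanog_rhs <- function(x, field, p = circuit_params()) {
  production(x, field, p) - x
}

#' Two-cluster reduction of the population model
#'
#' Under perfect mixing (as suggested by the salt-and-pepper arrangement of
#' the two ICM fates), a population split into two internally uniform clusters
#' with NANOG levels `xa` and `xb` reduces to a planar system in which both
#' clusters see the shared field `(xa + xb)/2`. The system is symmetric under
#' swapping the cluster labels.
#'
#' @param xa,xb Cluster NANOG levels, >= 0. Vectorised.
#' @param p A [circuit_params()] object.
#' @return A tibble with columns `dxa`, `dxb`.
#' @export
two_cluster_rhs <- function(xa, xb, p = circuit_params()) {
  if (any(xa < 0) || any(xb < 0)) {
    stop("cluster states must be non-negative", call. = FALSE)
  }
  field <- (xa + xb) / 2
  tibble::tibble(dxa = nanog_rhs(xa, field, p),
                 dxb = nanog_rhs(xb, field, p))
}

two_cluster_vec <- function(s, p) {
  r <- two_cluster_rhs(s[1], s[2], p)
  c(r$dxa, r$dxb)
}

two_cluster_jacobian <- function(s, p, h = 1e-7) {
  f0 <- two_cluster_vec(s, p)
  cbind((two_cluster_vec(s + c(h, 0), p) - f0) / h,
        (two_cluster_vec(s + c(0, h), p) - f0) / h)
}

#' Nullclines of the two-cluster system
#'
#' Loci in the `(xa, xb)` plane where `dxa/dt = 0` (component `"xa"`) or
#' `dxb/dt = 0` (component `"xb"`). By the swap symmetry the two sets are
#' mirror images across the diagonal. The curves are extracted as contour
#' polylines of the respective right-hand-side component on a regular grid.
#'
#' @param p A [circuit_params()] object.
#' @param n_grid Grid resolution per axis.
#' @param upper Upper limit of the grid in both axes; defaults to `alpha`
#'   (the invariant range of the dynamics).
#' @return A tibble with columns `component` ("xa"/"xb"), `branch` (polyline
#'   id), `xa`, `xb`, ordered along each polyline.
#' @export
nullclines <- function(p = circuit_params(), n_grid = 201, upper = NULL) {
  check_params(p)
  if (n_grid < 2) stop("`n_grid` must be at least 2", call. = FALSE)
  upper <- upper %||% p$alpha
  g <- seq(0, upper, length.out = n_grid)
  rhs <- two_cluster_rhs(rep(g, times = n_grid), rep(g, each = n_grid), p)
  f1 <- matrix(rhs$dxa, n_grid, n_grid)
  f2 <- matrix(rhs$dxb, n_grid, n_grid)
  contour_tbl <- function(f, comp) {
    cl <- grDevices::contourLines(g, g, f, levels = 0)
    purrr::imap_dfr(cl, function(br, i) {
      tibble::tibble(component = comp, branch = i, xa = br$x, xb = br$y)
    })
  }
  dplyr::bind_rows(contour_tbl(f1, "xa"), contour_tbl(f2, "xb"))
}

#' Equilibria of the two-cluster system
#'
#' Locates all roots of [two_cluster_rhs()] in `[0, alpha]^2` by a sign-change
#' scan on a regular grid followed by Newton refinement, then classifies each
#' equilibrium from the real parts of the Jacobian eigenvalues. At the default
#' (bistable) parameters there are exactly three: a stable mirror pair off the
#' diagonal (the two-cluster fate-split states) and one unstable symmetric
#' state on the diagonal.
#'
#' Eigenvalues whose real part lies within `marginal_tol` of zero yield the
#' stability label `"marginal"` rather than a silent call either way.
#'
#' @param p A [circuit_params()] object.
#' @param n_grid Scan resolution per axis.
#' @param tol Residual tolerance for accepting a refined root.
#' @param marginal_tol Half-width of the "marginal" band around zero for
#'   eigenvalue real parts.
#' @return A tibble with columns `xa`, `xb`, `stability` (stable / unstable /
#'   saddle / marginal), `eig1`, `eig2` (complex), `residual`, `converged`.
#' @export
find_equilibria <- function(p = circuit_params(), n_grid = 200, tol = 1e-9,
                            marginal_tol = 1e-8) {
  check_params(p)
  g <- seq(0, p$alpha, length.out = n_grid)
  rhs <- two_cluster_rhs(rep(g, times = n_grid), rep(g, each = n_grid), p)
  f1 <- matrix(rhs$dxa, n_grid, n_grid)
  f2 <- matrix(rhs$dxb, n_grid, n_grid)
  # cells where both components change sign among the four corners
  cell_change <- function(f) {
    a <- f[-n_grid, -n_grid]; b <- f[-1, -n_grid]
    c_ <- f[-n_grid, -1]; d <- f[-1, -1]
    lo <- pmin(a, b, c_, d); hi <- pmax(a, b, c_, d)
    lo <= 0 & hi >= 0
  }
  hits <- which(cell_change(f1) & cell_change(f2), arr.ind = TRUE)
  roots <- list()
  for (r in seq_len(nrow(hits))) {
    s <- c(mean(g[hits[r, 1] + 0:1]), mean(g[hits[r, 2] + 0:1]))
    conv <- FALSE
    for (it in 1:100) {
      f0 <- two_cluster_vec(s, p)
      if (max(abs(f0)) < tol) { conv <- TRUE; break }
      J <- two_cluster_jacobian(s, p)
      step <- tryCatch(solve(J, f0), error = function(e) NULL)
      if (is.null(step)) break
      s <- pmax(s - step, 0)
    }
    roots[[r]] <- list(s = s, converged = conv,
                       residual = max(abs(two_cluster_vec(s, p))))
  }
  if (!length(roots)) {
    return(tibble::tibble(xa = numeric(), xb = numeric(),
                          stability = character(), eig1 = complex(),
                          eig2 = complex(), residual = numeric(),
                          converged = logical()))
  }
  out <- purrr::map_dfr(roots, function(rt) {
    ev <- eigen(two_cluster_jacobian(rt$s, p), only.values = TRUE)$values
    re <- Re(ev)
    stab <- if (any(abs(re) < marginal_tol)) {
      "marginal"
    } else if (all(re < 0)) {
      "stable"
    } else if (all(re > 0)) {
      "unstable"
    } else {
      "saddle"
    }
    tibble::tibble(xa = rt$s[1], xb = rt$s[2], stability = stab,
                   eig1 = as.complex(ev[1]), eig2 = as.complex(ev[2]),
                   residual = rt$residual, converged = rt$converged)
  })
  # deduplicate refined roots that landed on the same point
  out <- dplyr::distinct(
    dplyr::arrange(out, round(.data$xa, 6), round(.data$xb, 6)),
    round(.data$xa, 6), round(.data$xb, 6), .keep_all = TRUE
  )
  dplyr::select(out, "xa", "xb", "stability", "eig1", "eig2",
                "residual", "converged")
}

#' @method tidy circuit_params
#' @export
tidy.circuit_params <- function(x, ...) {
  tibble::tibble(term = c("alpha", "K", "n", "m"),
                 value = c(x$alpha, x$K, x$n, x$m))
}

#' Integrate the population model on a signalling graph
#'
#' Fixed-step explicit Euler integration of the per-cell NANOG equation, with
#' each cell's repression field computed as the mean of `x` over its
#' neighbourhood on `graph` (self-loops are enforced: the mean includes the
#' cell itself). The agent-based simulator uses the same update interleaved
#' with mechanics and division; this function exposes it on a static graph.
#'
#' @param x0 Numeric vector of initial NANOG levels, all in `[0, alpha]`.
#' @param graph Square adjacency matrix (`N x N`), symmetric, interpreted as
#'   0/1; the diagonal is forced to 1.
#' @param p A [circuit_params()] object.
#' @param dt Euler step, > 0. The scheme is validated against an adaptive
#'   integrator for `dt <= 0.01`.
#' @param t_end Final time.
#' @param record_every Record the state every this many time units (rounded
#'   to a multiple of `dt`); default records every step.
#' @return A tibble with columns `time`, `cell_id`, `x` (a tidy trajectory).
#' @export
integrate_population <- function(x0, graph, p = circuit_params(), dt = 0.01,
                                 t_end = 10, record_every = dt) {
  check_params(p)
  stopifnot(dt > 0, t_end >= 0)
  n <- length(x0)
  if (any(x0 < 0)) stop("initial state must be non-negative", call. = FALSE)
  graph <- as.matrix(graph)
  if (!all(dim(graph) == n)) {
    stop("`graph` must be an N x N adjacency matrix matching `x0`",
         call. = FALSE)
  }
  A <- (graph != 0) * 1
  diag(A) <- 1
  deg <- rowSums(A)
  n_steps <- round(t_end / dt)
  keep <- max(1L, round(record_every / dt))
  x <- x0
  cap <- p$alpha * 1.05
  n_rec <- floor(n_steps / keep) + 2L
  snaps <- vector("list", n_rec + 1)
  times <- numeric(n_rec + 1)
  snaps[[1]] <- x0
  ri <- 1L
  for (s in seq_len(n_steps)) {
    field <- as.vector(A %*% x) / deg
    x <- x + dt * (production(x, field, p) - x)
    if (any(x < 0) || any(x > cap)) {
      stop("state left [0, 1.05 * alpha]: `dt` too large for stability",
           call. = FALSE)
    }
    if (s %% keep == 0 || s == n_steps) {
      ri <- ri + 1L
      snaps[[ri]] <- x
      times[ri] <- s * dt
    }
  }
  snaps <- snaps[seq_len(ri)]
  times <- times[seq_len(ri)]
  tibble::tibble(
    time = rep(times, each = n),
    cell_id = rep(seq_len(n), times = length(times)),
    x = unlist(snaps, use.names = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
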