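test_that("production follows the mean-field repression law", {
  p <- circuit_params()
  # no repression and half-maximal repression points
  expect_equal(production(0, 0, p), p$alpha)
  expect_equal(production(0, p$K, p), p$alpha / 2)
  # repression dominates in the strong-field limit
  expect_lt(production(1, 1e6, p), 1e-6)
  # frozen value computed independently from the printed formula
  # (exact rational arithmetic: 59049/18122 at alpha=4.5, K=0.9, n=m=2)
  expect_equal(production(1, 1, p), 59049 / 18122, tolerance = 1e-12)
  expect_true(all(production(seq(0, 4, 0.5), seq(0, 4, 0.5), p) > 0))
  expect_true(all(production(seq(0, 4, 0.5), seq(0, 4, 0.5), p) <= p$alpha))
  expect_error(production(-1, 0, p), "non-negative")
  expect_error(production(0, -1, p), "non-negative")
})

test_that("nanog_rhs is production minus turnover", {
  p <- circuit_params()
  expect_equal(nanog_rhs(0, 0, p), p$alpha)
  expect_equal(nanog_rhs(p$alpha, 1e9, p), -p$alpha, tolerance = 1e-6)
  # bisection on the diagonal locates the symmetric fixed point, which must
  # agree with the saddle reported by find_equilibria
  f <- function(x) nanog_rhs(x, x, p)
  lo <- 0.5; hi <- p$alpha
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, x_saddle(), tolerance = 1e-6)
})

test_that("two-cluster reduction shares the field and swaps symmetrically", {
  p <- circuit_params()
  # diagonal: equal components
  r <- two_cluster_rhs(1.3, 1.3, p)
  expect_equal(r$dxa, r$dxb)
  expect_equal(unlist(two_cluster_rhs(0, 0, p), use.names = FALSE),
               c(p$alpha, p$alpha))
  # swap symmetry on a grid, and agreement with a direct transcription of
  # the printed equations evaluated here independently of the package code
  g <- seq(0.2, 4, length.out = 5)
  direct <- function(xa, xb) {
    fld <- (xa + xb) / 2
    pr <- function(x) {
      a <- (1 + x^p$n)^p$m
      p$alpha * a / (a + (fld / p$K)^(2 * p$m))
    }
    c(pr(xa) - xa, pr(xb) - xb)
  }
  for (xa in g) for (xb in g) {
    r <- two_cluster_rhs(xa, xb, p)
    expect_equal(c(r$dxa, r$dxb), direct(xa, xb), tolerance = 1e-12)
    rs <- two_cluster_rhs(xb, xa, p)
    expect_equal(c(rs$dxa, rs$dxb), c(r$dxb, r$dxa))
  }
  expect_error(two_cluster_rhs(-0.1, 1, p), "non-negative")
})

test_that("nullclines vanish on their component and mirror across diagonal", {
  p <- circuit_params()
  nc <- nullclines(p, n_grid = 301)
  expect_setequal(unique(nc$component), c("xa", "xb"))
  r <- two_cluster_rhs(nc$xa, nc$xb, p)
  resid <- ifelse(nc$component == "xa", r$dxa, r$dxb)
  expect_lt(max(abs(resid)), 0.02)  # contour interpolation on the grid
  # reflecting one nullcline across the diagonal reproduces the other
  a <- nc[nc$component == "xa", c("xa", "xb")]
  b <- nc[nc$component == "xb", c("xa", "xb")]
  d_min <- vapply(seq_len(nrow(a)), function(i) {
    min(sqrt((b$xb - a$xa[i])^2 + (b$xa - a$xb[i])^2))
  }, numeric(1))
  expect_lt(max(d_min), 0.05)
  expect_error(nullclines(p, n_grid = 1), "n_grid")
})

test_that("equilibria: bistable portrait with a symmetric saddle", {
  p <- circuit_params()
  eq <- find_equilibria(p)
  expect_equal(nrow(eq), 3)
  expect_equal(sum(eq$stability == "stable"), 2)
  expect_equal(sum(eq$stability != "stable"), 1)
  expect_true(all(eq$residual < 1e-8))
  # one equilibrium on the diagonal; stable pair mirrored across it
  diag_eq <- eq[abs(eq$xa - eq$xb) < 1e-8, ]
  expect_equal(nrow(diag_eq), 1)
  expect_false(diag_eq$stability == "stable")
  st <- eq[eq$stability == "stable", ]
  expect_equal(sort(st$xa), sort(st$xb))
  # stability labels agree with the eigenvalues reported
  expect_true(all(Re(c(st$eig1, st$eig2)) < 0))
  # nullcline intersections coincide with the equilibria
  nc <- nullclines(p, n_grid = 401)
  a <- nc[nc$component == "xa", ]
  b <- nc[nc$component == "xb", ]
  for (k in seq_len(nrow(eq))) {
    expect_lt(min(sqrt((a$xa - eq$xa[k])^2 + (a$xb - eq$xb[k])^2)), 0.05)
    expect_lt(min(sqrt((b$xa - eq$xa[k])^2 + (b$xb - eq$xb[k])^2)), 0.05)
  }
})

test_that("stability labels agree with direct simulation near equilibria", {
  p <- circuit_params()
  eq <- find_equilibria(p)
  st <- eq[eq$stability == "stable", ][1, ]
  sd_ <- eq[eq$stability != "stable", ][1, ]
  step2 <- function(xa, xb, t_end, dt = 0.005) {
    for (i in seq_len(round(t_end / dt))) {
      r <- two_cluster_rhs(xa, xb, p)
      xa <- xa + dt * r$dxa; xb <- xb + dt * r$dxb
    }
    c(xa, xb)
  }
  # perturbation of a stable equilibrium decays
  out <- step2(st$xa + 0.05, st$xb - 0.05, 8)
  expect_equal(out, c(st$xa, st$xb), tolerance = 1e-3)
  # off-diagonal perturbation of the saddle grows
  out <- step2(sd_$xa + 0.02, sd_$xb - 0.02, 8)
  expect_gt(abs(out[1] - out[2]), 1)
})

test_that("population integrator: fixed points, blocks, bounds, symmetry", {
  p <- circuit_params()
  # single cell on a self-only graph converges to the diagonal root
  tr <- integrate_population(1.0, matrix(1, 1, 1), p, dt = 0.01, t_end = 60,
                             record_every = 60)
  expect_equal(tr$x[nrow(tr)], x_saddle(), tolerance = 1e-4)
  # two equal blocks at the stable pair stay there on the complete graph
  x0 <- c(rep(x_high(), 3), rep(x_low(), 3))
  A <- matrix(1, 6, 6)
  tr <- integrate_population(x0, A, p, dt = 0.01, t_end = 5,
                             record_every = 5)
  expect_equal(tr$x[tr$time == 5], x0, tolerance = 1e-6)
  # boundedness for random starts in [0, alpha]
  set.seed(1)
  x0 <- runif(8, 0, p$alpha)
  A <- (matrix(runif(64), 8, 8) > 0.5) * 1
  A <- ((A + t(A)) > 0) * 1
  tr <- integrate_population(x0, A, p, dt = 0.01, t_end = 20)
  expect_true(all(tr$x >= 0 & tr$x <= p$alpha + 1e-9))
  # permutation equivariance
  perm <- c(3, 1, 2, 5, 4, 8, 6, 7)
  tr1 <- integrate_population(x0, A, p, dt = 0.01, t_end = 2,
                              record_every = 2)
  tr2 <- integrate_population(x0[perm], A[perm, perm], p, dt = 0.01,
                              t_end = 2, record_every = 2)
  f1 <- tr1$x[tr1$time == 2]
  f2 <- tr2$x[tr2$time == 2]
  expect_equal(f2, f1[perm], tolerance = 1e-12)
  # oversized steps are caught
  expect_error(integrate_population(rep(0.1, 2), matrix(1, 2, 2), p, dt = 3,
                                    t_end = 9), "dt")
})
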