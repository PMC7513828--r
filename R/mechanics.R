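# Soft-sphere mechanics for the growing ICM aggregate: pairwise forces,
# overdamped position updates, the signalling neighbour graph, and division.

#' Mechanical parameters of the cell aggregate
#'
#' Cells are overdamped soft spheres: linear-spring repulsion when two cells
#' overlap, a weak tent-shaped adhesion out to `interaction_cutoff` times the
#' summed radii, and a weak central spring standing in for the confinement the
#' ICM experiences inside the blastocyst (no explicit trophectoderm or cavity
#' is modelled). Division times are drawn per daughter as
#' `mean_cycle * (1 + U(-cycle_jitter, +cycle_jitter))`; this jitter is the
#' model's source of division asynchrony.
#'
#' Lengths are in units of the cell radius; time in simulation hours (one
#' circuit time unit = one hour).
#'
#' @param repulsion_stiffness Spring constant of the overlap repulsion.
#' @param adhesion_strength Peak magnitude of the adhesive force.
#' @param interaction_cutoff Interaction range, in multiples of summed radii.
#' @param drag Drag coefficient of the overdamped update.
#' @param mean_cycle Mean cell-cycle length (hours).
#' @param cycle_jitter Half-width of the relative division-time perturbation,
#'   in `[0, 1)`.
#' @param confinement Stiffness of the central confinement spring.
#' @return A `mechanics_params` object (named list).
#' @export
mechanics_params <- function(repulsion_stiffness = 5,
                             adhesion_strength = 0.5,
                             interaction_cutoff = 1.5,
                             drag = 1,
                             mean_cycle = 10,
                             cycle_jitter = 0.3,
                             confinement = 0.2) {
  stopifnot(repulsion_stiffness > 0, adhesion_strength >= 0,
            interaction_cutoff > 1, drag > 0, mean_cycle > 0,
            cycle_jitter >= 0, cycle_jitter < 1, confinement >= 0)
  structure(list(repulsion_stiffness = repulsion_stiffness,
                 adhesion_strength = adhesion_strength,
                 interaction_cutoff = interaction_cutoff,
                 drag = drag, mean_cycle = mean_cycle,
                 cycle_jitter = cycle_jitter, confinement = confinement),
            class = "mechanics_params")
}

#' Pairwise central force between two soft spheres
#'
#' Positive values push the cells apart. For `distance < r1 + r2` the force is
#' repulsive and proportional to the overlap; between contact and
#' `interaction_cutoff * (r1 + r2)` it is weakly adhesive with a tent profile
#' that vanishes at both ends, so the law is continuous at contact and at the
#' cutoff; beyond the cutoff it is zero.
#'
#' @param distance Centre-to-centre distance, > 0. Vectorised.
#' @param r1,r2 Cell radii.
#' @param mp A [mechanics_params()] object.
#' @return Signed scalar force along the centre line (positive = repulsion).
#' @export
pairwise_force <- function(distance, r1, r2, mp = mechanics_params()) {
  if (any(distance <= 0)) {
    stop("`distance` must be positive (coincident centres are singular)",
         call. = FALSE)
  }
  k <- length(distance)
  rc <- rep_len(r1 + r2, k)
  cut <- rep_len(mp$interaction_cutoff * rc, k)
  f <- numeric(k)
  rep_i <- distance < rc
  f[rep_i] <- mp$repulsion_stiffness * (rc[rep_i] - distance[rep_i])
  adh_i <- distance >= rc & distance < cut
  if (any(adh_i)) {
    s <- (distance[adh_i] - rc[adh_i]) / (cut[adh_i] - rc[adh_i])
    f[adh_i] <- -4 * mp$adhesion_strength * s * (1 - s)
  }
  f
}

# net force matrix (N x 3) on live cells from pairwise law + confinement
net_forces <- function(pos, radius, mp) {
  n <- nrow(pos)
  F <- -mp$confinement * pos
  if (n < 2) return(F)
  d2 <- as.matrix(stats::dist(pos))
  rc <- outer(radius, radius, "+")
  cut <- mp$interaction_cutoff * rc
  act <- d2 < cut & upper.tri(d2)
  idx <- which(act, arr.ind = TRUE)
  if (nrow(idx)) {
    i <- idx[, 1]; j <- idx[, 2]
    dij <- d2[act]
    dij[dij < 1e-9] <- 1e-9
    fmag <- pairwise_force(dij, radius[i], radius[j], mp)
    dirv <- (pos[i, , drop = FALSE] - pos[j, , drop = FALSE]) / dij
    fv <- dirv * fmag
    for (k in seq_along(i)) {
      F[i[k], ] <- F[i[k], ] + fv[k, ]
      F[j[k], ] <- F[j[k], ] - fv[k, ]
    }
  }
  F
}

#' Advance cell positions by one overdamped step
#'
#' Moves each live cell by `net force / drag * dt`. By default any
#' displacement beyond a tenth of a cell radius raises a step-size error;
#' with `clamp = TRUE` displacements are instead capped at that length
#' (velocity clamping), which keeps the update stable across transients such
#' as freshly placed cells. The growth loop uses the clamped form.
#'
#' @param e An [embryo_state] object.
#' @param mp A [mechanics_params()] object.
#' @param dt Time step (hours).
#' @param clamp Cap displacements at 0.1 radius instead of erroring.
#' @return The updated `embryo_state`.
#' @export
step_positions <- function(e, mp = mechanics_params(), dt = 0.01,
                           clamp = FALSE) {
  live <- which(e$alive)
  if (!length(live)) return(e)
  pos <- e$pos[live, , drop = FALSE]
  if (e$dimensionality == 2) pos[, 3] <- 0
  F <- net_forces(pos, e$radius[live], mp)
  if (e$dimensionality == 2) F[, 3] <- 0
  disp <- F / mp$drag * dt
  cap <- 0.1 * min(e$radius[live])
  mag <- sqrt(rowSums(disp^2))
  if (any(mag > cap)) {
    if (!clamp) {
      stop("displacement exceeded 0.1 cell radius in one step; reduce `dt`",
           call. = FALSE)
    }
    over <- mag > cap
    disp[over, ] <- disp[over, , drop = FALSE] * (cap / mag[over])
  }
  e$pos[live, ] <- pos + disp
  e$t <- e$t + dt
  e
}

#' Signalling neighbour graph
#'
#' Two live cells are neighbours when their centre distance is at most
#' `cutoff` times the sum of their radii; every cell is its own neighbour
#' (self-loops), so neighbourhood means include the cell itself.
#' `cutoff = "global"` returns the complete graph, the limit in which every
#' cell in the embryo sees every other (growth factor spread without
#' restriction).
#'
#' @param e An [embryo_state] object.
#' @param cutoff Positive multiple of summed radii, or `"global"`.
#' @return Adjacency matrix over live cells (dimnames = cell ids).
#' @export
neighbor_graph <- function(e, cutoff = 1.5) {
  live <- which(e$alive)
  n <- length(live)
  ids <- e$id[live]
  if (identical(cutoff, "global") || is.infinite(cutoff)) {
    A <- matrix(1, n, n)
  } else {
    stopifnot(is.numeric(cutoff), cutoff > 0)
    pos <- e$pos[live, , drop = FALSE]
    d <- as.matrix(stats::dist(pos))
    rc <- outer(e$radius[live], e$radius[live], "+")
    A <- (d <= cutoff * rc) * 1
    diag(A) <- 1
  }
  dimnames(A) <- list(ids, ids)
  A
}

#' Divide one cell
#'
#' Replaces a live cell due for division by two daughters placed at
#' `+-0.5 radius` along a uniform random direction (in-plane for 2D states).
#' Each daughter redraws its next division time and inherits the mother's
#' NANOG level with a small multiplicative jitter `exp(N(0, x_jitter^2))`
#' clipped to `[0, alpha]`; this heritable variability is what seeds the
#' symmetry breaking of the fate decision. ESC daughters stay frozen at the
#' ESC NANOG level.
#'
#' @param e An [embryo_state] object.
#' @param i Index (position in the state vectors) of the dividing cell.
#' @param mp A [mechanics_params()] object.
#' @param x_jitter Standard deviation of the log-normal inheritance jitter.
#' @param x_max Clip value for inherited x (the production maximum `alpha`).
#' @return The updated `embryo_state` (live count + 1).
#' @export
divide_cell <- function(e, i, mp = mechanics_params(), x_jitter = 0.05,
                        x_max = Inf) {
  stopifnot(e$alive[i], e$t >= e$next_division[i] - 1e-9)
  dir <- stats::rnorm(3)
  if (e$dimensionality == 2) dir[3] <- 0
  dir <- dir / sqrt(sum(dir^2))
  off <- 0.5 * e$radius[i] * dir
  jit <- function() {
    stats::runif(1, -mp$cycle_jitter, mp$cycle_jitter)
  }
  inherit_x <- function() {
    if (e$status[i] == "ESC") return(e$x[i])
    min(max(e$x[i] * exp(stats::rnorm(1, 0, x_jitter)), 0), x_max)
  }
  mother_pos <- e$pos[i, ]
  # mother becomes daughter 1 in place
  e$pos[i, ] <- mother_pos + off
  e$x[i] <- inherit_x()
  e$birth_time[i] <- e$t
  e$next_division[i] <- e$t + mp$mean_cycle * (1 + jit())
  # daughter 2 appended
  e$id <- c(e$id, e$next_id)
  e$next_id <- e$next_id + 1L
  e$pos <- rbind(e$pos, mother_pos - off)
  e$radius <- c(e$radius, e$radius[i])
  e$x <- c(e$x, inherit_x())
  e$status <- c(e$status, e$status[i])
  e$birth_time <- c(e$birth_time, e$t)
  e$next_division <- c(e$next_division, e$t + mp$mean_cycle * (1 + jit()))
  e$alive <- c(e$alive, TRUE)
  e$beyond_since[i] <- NA_real_
  e$beyond_dir[i] <- 0L
  e$beyond_since <- c(e$beyond_since, NA_real_)
  e$beyond_dir <- c(e$beyond_dir, 0L)
  e$n_divisions <- e$n_divisions + 1L
  e
}
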