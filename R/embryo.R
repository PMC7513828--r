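# Embryo state container and the growth loop that interleaves mechanics,
# division and the NANOG circuit.

#' Simulation configuration
#'
#' Bundles circuit, mechanics and run settings for the agent-based ICM
#' simulator. The defaults are the package's wild-type study conditions:
#' growth from `n_init` progenitors to a `target_icm` of 27 cells, with the
#' gene-regulatory circuit switched on once the aggregate reaches `grn_on`
#' cells (before that, NANOG levels only drift through division inheritance).
#' The run stops when the live target count is reached, mirroring a blastocyst
#' developing to a staged cell number.
#'
#' `signaling_range` sets the neighbour-graph cutoff (multiples of summed
#' radii) or `"global"` for all-to-all coupling. `esc_x` is the frozen NANOG
#' level of embryonic stem cells; by default the high-NANOG coordinate of the
#' stable two-cluster equilibrium, computed from `circuit`.
#'
#' @param circuit A [circuit_params()] object.
#' @param mechanics A [mechanics_params()] object.
#' @param n_init Initial number of progenitor cells.
#' @param target_icm Live-cell count at which the run stops.
#' @param grn_on Live-cell count at which the circuit activates.
#' @param dt Shared time step (hours) for mechanics and circuit updates.
#' @param x_init_mean,x_init_sd Initial NANOG distribution of progenitors
#'   (defaults: the unstable symmetric state of the circuit, sd 0.1).
#' @param division_x_jitter Multiplicative inheritance jitter (sd of log).
#' @param signaling_range Neighbour cutoff (numeric) or `"global"`.
#' @param dimensionality 3 (default) or 2 (a cell monolayer).
#' @param settle_time Extra simulation hours after the target is reached
#'   (default 0: the run stops at the target count).
#' @param record_every Trajectory recording interval (hours).
#' @param esc_x Frozen ESC NANOG level; `NULL` computes it from `circuit`.
#' @param irreversible Commit cells irreversibly: once a cell's NANOG level
#'   has stayed beyond an identity threshold for `commit_persistence_hr`
#'   hours, its lineage status locks and its level can no longer cross back
#'   (a ratchet). Matches the irreversible, asynchronous adoption of
#'   epiblast/PrE identity seen in vivo; recovery from perturbations then
#'   flows through uncommitted progenitors (and not-yet-locked cells) only.
#' @param commit_persistence_hr Time a cell must spend continuously beyond a
#'   threshold before its fate locks (hours).
#' @return A list of class `icm_config`.
#' @export
embryo_config <- function(circuit = circuit_params(),
                          mechanics = mechanics_params(),
                          n_init = 2,
                          target_icm = 27,
                          grn_on = 8,
                          dt = 0.01,
                          x_init_mean = NULL,
                          x_init_sd = 0.1,
                          division_x_jitter = 0.05,
                          signaling_range = 1.5,
                          dimensionality = 3,
                          settle_time = 0,
                          record_every = 0.5,
                          esc_x = NULL,
                          irreversible = TRUE,
                          commit_persistence_hr = 6) {
  check_params(circuit)
  stopifnot(inherits(mechanics, "mechanics_params"),
            n_init >= 1, target_icm >= n_init, grn_on >= 1, dt > 0,
            dimensionality %in% c(2, 3), settle_time >= 0)
  eq <- find_equilibria(circuit)
  saddle <- eq[eq$stability != "stable", ]
  stable <- eq[eq$stability == "stable", ]
  if (is.null(x_init_mean)) {
    x_init_mean <- if (nrow(saddle)) saddle$xa[1] else circuit$alpha / 2
  }
  if (is.null(esc_x)) {
    esc_x <- if (nrow(stable)) max(stable$xa, stable$xb) else circuit$alpha
  }
  thresholds <- if (nrow(stable) && nrow(saddle)) {
    identity_thresholds(circuit,
                        lo = (min(stable$xa, stable$xb) + saddle$xa[1]) / 2,
                        hi = (saddle$xa[1] + max(stable$xa, stable$xb)) / 2)
  } else {
    NULL
  }
  structure(list(circuit = circuit, mechanics = mechanics, n_init = n_init,
                 target_icm = target_icm, grn_on = grn_on, dt = dt,
                 x_init_mean = x_init_mean, x_init_sd = x_init_sd,
                 division_x_jitter = division_x_jitter,
                 signaling_range = signaling_range,
                 dimensionality = dimensionality,
                 settle_time = settle_time, record_every = record_every,
                 esc_x = esc_x, irreversible = irreversible,
                 commit_persistence_hr = commit_persistence_hr,
                 thresholds = thresholds),
            class = "icm_config")
}

#' Create a fresh embryo state
#'
#' @param config An [embryo_config()] object.
#' @param seed Optional integer seed; when given, the global RNG is seeded
#'   (all randomness in the simulator flows through R's RNG).
#' @return An object of class `embryo_state`: parallel per-cell vectors
#'   (`id`, `pos`, `radius`, `x`, `status`, `birth_time`, `next_division`,
#'   `alive`) plus the clock `t` and bookkeeping fields.
#' @export
new_embryo <- function(config = embryo_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_init
  mp <- config$mechanics
  pos <- matrix(stats::rnorm(3 * n, sd = 0.5), ncol = 3)
  if (config$dimensionality == 2) pos[, 3] <- 0
  x0 <- pmax(stats::rnorm(n, config$x_init_mean, config$x_init_sd), 0)
  e <- structure(list(
    id = seq_len(n),
    pos = pos,
    radius = rep(1, n),
    x = x0,
    status = rep("DP", n),
    birth_time = rep(0, n),
    # stagger first divisions uniformly across one cycle
    next_division = mp$mean_cycle * stats::runif(n),
    alive = rep(TRUE, n),
    beyond_since = rep(NA_real_, n),
    beyond_dir = rep(0L, n),
    t = 0,
    dimensionality = config$dimensionality,
    n_divisions = 0L,
    next_id = n + 1L,
    config = config
  ), class = "embryo_state")
  e
}

n_live <- function(e) sum(e$alive)

#' @export
print.embryo_state <- function(x, ...) {
  cat(sprintf(
    "<embryo_state> t = %.2f h, %d live cells (%d ESC), %d division events\n",
    x$t, n_live(x), sum(x$alive & x$status == "ESC"), x$n_divisions))
  invisible(x)
}

#' Snapshot an embryo state as a tibble
#'
#' @param x An `embryo_state`.
#' @param ... Unused.
#' @param live_only Drop dead (ablated) cells; default TRUE.
#' @return A tibble with one row per cell: `cell_id`, `t`, `x_pos`, `y_pos`,
#'   `z_pos`, `x_level`, `status`, `alive`.
#' @method as_tibble embryo_state
#' @export
as_tibble.embryo_state <- function(x, ..., live_only = TRUE) {
  keep <- if (live_only) which(x$alive) else seq_along(x$id)
  tibble::tibble(
    cell_id = x$id[keep],
    t = x$t,
    x_pos = x$pos[keep, 1],
    y_pos = x$pos[keep, 2],
    z_pos = x$pos[keep, 3],
    x_level = x$x[keep],
    status = x$status[keep],
    alive = x$alive[keep]
  )
}

# one simulation step: mechanics, divisions, circuit. `div_cap` stops
# division events once the counted live population reaches the target, so a
# run ends at exactly the requested cell count.
step_embryo <- function(e, config, div_cap = Inf, count_esc = FALSE) {
  mp <- config$mechanics
  counted <- function(e) {
    if (count_esc) n_live(e) else sum(e$alive & e$status != "ESC")
  }
  e <- step_positions(e, mp, config$dt, clamp = TRUE)
  due <- which(e$alive & e$t >= e$next_division)
  for (i in due) {
    if (counted(e) >= div_cap) break
    e <- divide_cell(e, i, mp, x_jitter = config$division_x_jitter,
                     x_max = config$circuit$alpha)
  }
  if (n_live(e) >= config$grn_on) {
    live <- which(e$alive)
    A <- neighbor_graph(e, config$signaling_range)
    xl <- e$x[live]
    field <- as.vector(A %*% xl) / rowSums(A)
    upd <- e$status[live] != "ESC"
    xl[upd] <- xl[upd] +
      config$dt * nanog_rhs(xl[upd], field[upd], config$circuit)
    xl <- pmin(pmax(xl, 0), config$circuit$alpha)
    if (config$irreversible && !is.null(config$thresholds)) {
      th <- config$thresholds
      st <- e$status[live]
      dir_now <- ifelse(xl > th$hi, 1L, ifelse(xl < th$lo, -1L, 0L))
      bs <- e$beyond_since[live]
      bd <- e$beyond_dir[live]
      changed <- dir_now != bd
      bs[changed & dir_now != 0L] <- e$t
      bs[changed & dir_now == 0L] <- NA_real_
      bd <- dir_now
      dwell <- e$t - bs
      lock <- st == "DP" & !is.na(dwell) &
        dwell >= config$commit_persistence_hr
      st[lock & bd == 1L] <- "EPI"
      st[lock & bd == -1L] <- "PrE"
      xl[st == "EPI"] <- pmax(xl[st == "EPI"], th$hi)
      xl[st == "PrE"] <- pmin(xl[st == "PrE"], th$lo)
      e$status[live] <- st
      e$beyond_since[live] <- bs
      e$beyond_dir[live] <- bd
    }
    e$x[live] <- xl
  }
  e
}

#' Grow an embryo to a target cell count
#'
#' The main simulation loop: interleaves overdamped soft-sphere mechanics,
#' stochastic cell division and, once the aggregate has at least `grn_on`
#' cells, Euler updates of the NANOG circuit on the current signalling
#' neighbour graph. Growth stops the first time the live count of counted
#' cells reaches `target` (plus an optional `settle_time`). Fully reproducible
#' given `seed`.
#'
#' @param config An [embryo_config()] object.
#' @param seed Integer seed, or `NULL` to continue the current RNG stream
#'   (used when resuming from `state`).
#' @param state Resume from an existing `embryo_state` instead of creating a
#'   fresh one.
#' @param target Override `config$target_icm` (e.g. to pause at an ablation
#'   trigger size).
#' @param count_esc Should ESCs count towards the stopping target? Default
#'   FALSE: in chimeras the host compartment grows to its normal size and the
#'   ESC compartment rides on top.
#' @param record Record a trajectory of compositions (see
#'   [composition()]) every `config$record_every` hours, returned as the
#'   `"trajectory"` attribute.
#' @return The final `embryo_state`; when `record = TRUE`, with a tibble
#'   attribute `"trajectory"`.
#' @export
grow_embryo <- function(config = embryo_config(), seed = NULL, state = NULL,
                        target = NULL, count_esc = FALSE, record = FALSE) {
  target <- target %||% config$target_icm
  if (is.null(state)) {
    e <- new_embryo(config, seed)
  } else {
    e <- state
    if (!is.null(seed)) set.seed(seed)
  }
  counted <- function(e) {
    if (count_esc) n_live(e) else sum(e$alive & e$status != "ESC")
  }
  if (target < counted(e)) {
    stop("`target` is smaller than the current live cell count", call. = FALSE)
  }
  th <- config$thresholds %||% identity_thresholds(config$circuit)
  rec <- list()
  next_rec <- e$t
  max_t <- e$t + 10 * config$mechanics$mean_cycle *
    (log2(max(target / max(counted(e), 1), 2)) + 1)
  while (counted(e) < target) {
    e <- step_embryo(e, config, div_cap = target, count_esc = count_esc)
    if (record && e$t >= next_rec - 1e-9) {
      rec[[length(rec) + 1]] <- composition(e, th)
      next_rec <- next_rec + config$record_every
    }
    if (e$t > max_t) stop("growth failed to reach target", call. = FALSE)
  }
  if (config$settle_time > 0) {
    t_stop <- e$t + config$settle_time
    while (e$t < t_stop - 1e-9) {
      e <- step_embryo(e, config, div_cap = target, count_esc = count_esc)
      if (record && e$t >= next_rec - 1e-9) {
        rec[[length(rec) + 1]] <- composition(e, th)
        next_rec <- next_rec + config$record_every
      }
    }
  }
  if (record) {
    rec[[length(rec) + 1]] <- composition(e, th)
    attr(e, "trajectory") <- dplyr::bind_rows(rec)
  }
  e
}
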