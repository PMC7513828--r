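# In-silico experiment suite: identity calls, composition metrics, wild-type
# runs, scaling, ESC chimeras, staged lineage ablation, sensitivity sweeps.

#' Identity thresholds for mapping NANOG levels to lineages
#'
#' The continuous NANOG level is mapped to the three ICM classes by two
#' thresholds bracketing the unstable symmetric state of the circuit:
#' `x > hi` is epiblast (EPI), `x < lo` primitive endoderm (PrE), anything in
#' between an uncommitted double-positive progenitor (DP). Defaults place
#' `lo`/`hi` midway between the saddle and the low/high stable equilibrium,
#' so a cell is only called committed once it has crossed clearly into one
#' basin.
#'
#' @param p A [circuit_params()] object (used to locate the equilibria when
#'   `lo`/`hi` are not given).
#' @param lo,hi Optional explicit thresholds, `0 < lo < hi < alpha`.
#' @return A list of class `identity_thresholds` with fields `lo`, `hi`.
#' @export
identity_thresholds <- function(p = circuit_params(), lo = NULL, hi = NULL) {
  if (is.null(lo) || is.null(hi)) {
    eq <- find_equilibria(p)
    stable <- eq[eq$stability == "stable", ]
    saddle <- eq[eq$stability != "stable" & abs(eq$xa - eq$xb) < 1e-6, ]
    if (!nrow(stable) || !nrow(saddle)) {
      stop("circuit is not bistable at these parameters; ",
           "supply `lo` and `hi` explicitly", call. = FALSE)
    }
    x_lo <- min(stable$xa, stable$xb)
    x_hi <- max(stable$xa, stable$xb)
    xs <- saddle$xa[1]
    lo <- lo %||% (x_lo + xs) / 2
    hi <- hi %||% (xs + x_hi) / 2
  }
  stopifnot(lo > 0, hi > lo, hi < p$alpha)
  structure(list(lo = lo, hi = hi), class = "identity_thresholds")
}

#' Assign a lineage identity from a NANOG level
#'
#' @param x NANOG level(s), >= 0. Vectorised.
#' @param th An [identity_thresholds()] object.
#' @return Character vector in `{"EPI", "DP", "PrE"}`.
#' @export
assign_identity <- function(x, th = identity_thresholds()) {
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  dplyr::case_when(x > th$hi ~ "EPI", x < th$lo ~ "PrE", TRUE ~ "DP")
}

#' Effective identity of each live cell
#'
#' Committed cells (status `"EPI"`, `"PrE"`, `"ESC"`) keep their status;
#' uncommitted progenitors are classified from their current NANOG level by
#' [assign_identity()].
#'
#' @param e An [embryo_state] object.
#' @param th An [identity_thresholds()] object.
#' @return Character vector over live cells.
#' @export
cell_identity <- function(e, th = identity_thresholds()) {
  live <- which(e$alive)
  st <- e$status[live]
  uncommitted <- !st %in% c("EPI", "PrE", "ESC")
  st[uncommitted] <- assign_identity(e$x[live][uncommitted], th)
  st
}

#' Lineage composition of an embryo state
#'
#' Counts live cells by [cell_identity()] (ESCs are counted separately and,
#' for the fractional composition and the PrE:epiblast ratio, pooled with the
#' epiblast compartment, since ESCs are lineage-restricted epiblast
#' equivalents). `ln_ratio` is the natural log of PrE:epiblast counts, `NA`
#' when either count is zero.
#'
#' @param e An [embryo_state] object.
#' @param th An [identity_thresholds()] object.
#' @param esc_as_epi Pool ESCs with EPI for fractions and `ln_ratio`
#'   (default TRUE).
#' @return One-row tibble: `t`, `n_live`, `n_epi` (host EPI), `n_pre`,
#'   `n_dp`, `n_esc`, `frac_epi`, `frac_pre`, `frac_dp`, `ln_ratio`.
#' @export
composition <- function(e, th = identity_thresholds(), esc_as_epi = TRUE) {
  live <- which(e$alive)
  all_ident <- cell_identity(e, th)
  is_esc <- all_ident == "ESC"
  ident <- all_ident[!is_esc]
  n_esc <- sum(is_esc)
  n_epi <- sum(ident == "EPI")
  n_pre <- sum(ident == "PrE")
  n_dp <- sum(ident == "DP")
  n_tot <- length(live)
  epi_all <- n_epi + if (esc_as_epi) n_esc else 0
  denom <- if (esc_as_epi) n_tot else n_tot - n_esc
  tibble::tibble(
    t = e$t, n_live = n_tot,
    n_epi = n_epi, n_pre = n_pre, n_dp = n_dp, n_esc = n_esc,
    frac_epi = epi_all / denom,
    frac_pre = n_pre / denom,
    frac_dp = n_dp / denom,
    ln_ratio = ifelse(n_pre > 0 & epi_all > 0, log(n_pre / epi_all), NA_real_)
  )
}

#' Simulate wild-type ICM development
#'
#' Grows an embryo from the configured starting size to the target ICM size
#' with the circuit switching on at `grn_on` cells. Progenitors (DP) deplete
#' as cells commit to the epiblast or PrE attractor; at symmetric default
#' parameters the split is balanced (close to 50:50) on average.
#'
#' @param config An [embryo_config()] object.
#' @param seed Integer seed.
#' @return A tibble trajectory of [composition()] rows (recorded every
#'   `config$record_every` hours), with the final `embryo_state` as attribute
#'   `"final_state"` and `config` as attribute `"config"`.
#' @export
run_wildtype <- function(config = embryo_config(), seed = 1) {
  e <- grow_embryo(config, seed = seed, record = TRUE)
  traj <- attr(e, "trajectory")
  attr(e, "trajectory") <- NULL
  structure(traj, final_state = e, config = config,
            class = c("icm_trajectory", class(traj)))
}

#' Simulate an embryo scaled to a fraction or multiple of normal size
#'
#' Multiplies the target ICM size by `factor` (e.g. 0.5 or 2, emulating half
#' and double embryos) and runs the wild-type protocol. Fractional
#' composition is expected to be independent of the absolute size while
#' absolute lineage counts scale with it.
#'
#' @param factor Size factor, > 0; the scaled target must be at least 4.
#' @inheritParams run_wildtype
#' @return As [run_wildtype()].
#' @export
run_scaling <- function(factor = 1, config = embryo_config(), seed = 1) {
  target <- round(config$target_icm * factor)
  if (target < 4) stop("scaled target must be at least 4 cells", call. = FALSE)
  config$target_icm <- target
  run_wildtype(config, seed)
}

#' Simulate an ESC-aggregation chimera
#'
#' Grows the embryo normally until the circuit-activation size is reached,
#' then adds `n_esc` embryonic stem cells at random positions on the
#' aggregate surface. ESCs are frozen at the high-NANOG level (`config$esc_x`)
#' so they signal like epiblast cells (a localised FGF4 source) but never
#' change fate; they divide like host cells. The host compartment grows to
#' its normal target on top of the ESC load.
#'
#' @param n_esc Number of ESCs added (at the time of circuit activation).
#' @inheritParams run_wildtype
#' @return As [run_wildtype()]; composition columns report host lineages and
#'   the ESC compartment separately.
#' @export
run_chimera <- function(n_esc = 0, config = embryo_config(), seed = 1) {
  stopifnot(n_esc >= 0)
  if (n_esc == 0) return(run_wildtype(config, seed))
  e <- grow_embryo(config, seed = seed, target = config$grn_on,
                   record = TRUE)
  traj1 <- attr(e, "trajectory")
  e <- add_escs(e, n_esc, config)
  e <- grow_embryo(config, seed = NULL, state = e, record = TRUE)
  traj <- dplyr::bind_rows(traj1, attr(e, "trajectory"))
  attr(e, "trajectory") <- NULL
  structure(traj, final_state = e, config = config,
            class = c("icm_trajectory", class(traj)))
}

# place n ESCs at random directions just outside the current aggregate
add_escs <- function(e, n_esc, config) {
  live <- which(e$alive)
  centre <- colMeans(e$pos[live, , drop = FALSE])
  r_agg <- max(sqrt(rowSums(sweep(e$pos[live, , drop = FALSE],
                                  2, centre)^2))) + 1
  mp <- config$mechanics
  for (k in seq_len(n_esc)) {
    dir <- stats::rnorm(3)
    if (e$dimensionality == 2) dir[3] <- 0
    dir <- dir / sqrt(sum(dir^2))
    e$id <- c(e$id, e$next_id)
    e$next_id <- e$next_id + 1L
    e$pos <- rbind(e$pos, centre + dir * r_agg)
    e$radius <- c(e$radius, 1)
    e$x <- c(e$x, config$esc_x)
    e$status <- c(e$status, "ESC")
    e$birth_time <- c(e$birth_time, e$t)
    e$next_division <- c(e$next_division,
                         e$t + mp$mean_cycle *
                           (1 + stats::runif(1, -mp$cycle_jitter,
                                             mp$cycle_jitter)))
    e$alive <- c(e$alive, TRUE)
    e$beyond_since <- c(e$beyond_since, NA_real_)
    e$beyond_dir <- c(e$beyond_dir, 0L)
  }
  e
}

#' Remove cells from an embryo in silico
#'
#' Marks `round(fraction * lineage size)` uniformly chosen live cells of the
#' targeted lineage as dead (minimum one cell when `fraction > 0`); dead
#' cells are excluded from the neighbour graph, the repression field and the
#' mechanics from that moment on. `lineage = "all"` removes the fraction from
#' each of EPI, DP and PrE separately; `"random"` ignores identity. Rounding
#' is half-away-from-zero so a 30% cut of 9 cells removes 3.
#'
#' @param e An [embryo_state] object.
#' @param lineage One of "EPI", "PrE", "DP", "all", "random".
#' @param fraction Fraction of the targeted lineage to remove, in (0, 1].
#' @param th An [identity_thresholds()] object used to classify cells at the
#'   moment of ablation.
#' @return The updated `embryo_state` (live count reduced).
#' @export
ablate <- function(e, lineage = c("all", "EPI", "PrE", "DP", "random"),
                   fraction = 0.3, th = identity_thresholds()) {
  lineage <- match.arg(lineage)
  stopifnot(fraction > 0, fraction <= 1)
  live <- which(e$alive)
  all_ident <- cell_identity(e, th)
  host <- live[all_ident != "ESC"]
  ident <- all_ident[all_ident != "ESC"]
  pick_from <- function(pool) {
    if (!length(pool)) {
      stop("targeted lineage has no live cells", call. = FALSE)
    }
    k <- max(1L, floor(fraction * length(pool) + 0.5))
    k <- min(k, length(pool))
    if (length(pool) == 1) pool else sample(pool, k)
  }
  victims <- switch(
    lineage,
    random = pick_from(host),
    all = unlist(lapply(c("EPI", "DP", "PrE"), function(l) {
      pool <- host[ident == l]
      if (length(pool)) pick_from(pool) else integer()
    })),
    pick_from(host[ident == lineage])
  )
  if (!length(victims)) {
    stop("targeted lineage has no live cells", call. = FALSE)
  }
  e$alive[victims] <- FALSE
  e
}

#' Staged lineage ablation experiment
#'
#' For each seed: grow the embryo until the live ICM first reaches
#' `at_icm_size` (the developmental stage of the perturbation), remove the
#' requested fraction of the targeted lineage, then resume growth to the
#' normal target. Division parameters are untouched, so any recovery is due
#' to re-routed progenitor fate choice, not compensatory proliferation.
#'
#' @param lineage Passed to [ablate()].
#' @param fraction Passed to [ablate()].
#' @param at_icm_size Live-cell count that triggers the ablation.
#' @param config An [embryo_config()] object.
#' @param seeds Integer vector of seeds (one simulation each).
#' @return A tibble of final [composition()] rows, one per seed, with columns
#'   `seed`, `lineage`, `fraction`, `at_icm_size` prepended, plus
#'   `divisions_per_cell` for the no-compensatory-proliferation check.
#' @export
run_ablation_series <- function(lineage = "all", fraction = 0.3,
                                at_icm_size = 27,
                                config = embryo_config(),
                                seeds = 1:10) {
  if (at_icm_size > config$target_icm) {
    stop("`at_icm_size` must be reachable before the target", call. = FALSE)
  }
  th <- config$thresholds %||% identity_thresholds(config$circuit)
  purrr::map_dfr(seeds, function(s) {
    e <- grow_embryo(config, seed = s, target = at_icm_size)
    e <- ablate(e, lineage, fraction, th)
    e <- grow_embryo(config, seed = NULL, state = e)
    dplyr::bind_cols(
      tibble::tibble(seed = s, lineage = lineage, fraction = fraction,
                     at_icm_size = at_icm_size),
      composition(e, th),
      tibble::tibble(divisions_per_cell = e$n_divisions / n_live(e))
    )
  })
}

#' Final compositions over a batch of seeds
#'
#' Convenience wrapper running one of the experiment protocols across seeds
#' and returning the final composition per run.
#'
#' @param seeds Integer vector of seeds.
#' @param runner A function `(config, seed)` returning an `icm_trajectory`
#'   (e.g. [run_wildtype()], or a partial of [run_scaling()] /
#'   [run_chimera()]).
#' @param config An [embryo_config()] object.
#' @return Tibble of final compositions with a `seed` column.
#' @export
batch_composition <- function(seeds, runner = run_wildtype,
                              config = embryo_config()) {
  purrr::map_dfr(seeds, function(s) {
    traj <- runner(config, s)
    dplyr::bind_cols(tibble::tibble(seed = s), dplyr::slice_tail(traj, n = 1))
  })
}

#' Parameter sensitivity sweep
#'
#' Runs batches of wild-type simulations over a grid of circuit/mechanics
#' parameter perturbations and summarises the final composition per grid
#' cell. Used to establish that the balanced fate split is robust within
#' +-50% of the default parameters (wherever bistability holds) and that
#' global coupling behaves like nearest-neighbour coupling.
#'
#' @param param_grid A data frame whose columns name config entries among
#'   `alpha`, `K`, `signaling_range`, `mean_cycle`, `repulsion_stiffness`,
#'   `adhesion_strength`; one row per grid cell.
#' @param config Baseline [embryo_config()].
#' @param seeds Seeds per grid cell.
#' @return Tidy tibble: grid columns + `n_runs`, `mean_frac_epi`,
#'   `sd_frac_epi`, `mean_frac_pre`, `mean_frac_dp`.
#' @export
sensitivity_sweep <- function(param_grid, config = embryo_config(),
                              seeds = 1:10) {
  param_grid <- tibble::as_tibble(param_grid)
  purrr::map_dfr(seq_len(nrow(param_grid)), function(i) {
    row <- param_grid[i, ]
    cfg <- config
    for (nm in names(row)) {
      val <- row[[nm]][[1]]
      if (nm %in% c("alpha", "K", "n", "m")) {
        cfg$circuit[[nm]] <- val
        # thresholds and ESC level depend on the circuit; recompute lazily
        cfg$x_init_mean <- NULL
        cfg$esc_x <- NULL
      } else if (nm %in% names(cfg$mechanics)) {
        cfg$mechanics[[nm]] <- val
      } else if (nm %in% names(cfg)) {
        cfg[[nm]] <- val
      } else {
        stop("unknown sweep parameter: ", nm, call. = FALSE)
      }
    }
    cfg <- embryo_config(circuit = cfg$circuit, mechanics = cfg$mechanics,
                         n_init = cfg$n_init, target_icm = cfg$target_icm,
                         grn_on = cfg$grn_on, dt = cfg$dt,
                         x_init_mean = cfg$x_init_mean,
                         x_init_sd = cfg$x_init_sd,
                         division_x_jitter = cfg$division_x_jitter,
                         signaling_range = cfg$signaling_range,
                         dimensionality = cfg$dimensionality,
                         settle_time = cfg$settle_time,
                         record_every = cfg$record_every,
                         esc_x = cfg$esc_x)
    fin <- batch_composition(seeds, run_wildtype, cfg)
    dplyr::bind_cols(
      row,
      tibble::tibble(n_runs = nrow(fin),
                     mean_frac_epi = mean(fin$frac_epi),
                     sd_frac_epi = stats::sd(fin$frac_epi),
                     mean_frac_pre = mean(fin$frac_pre),
                     mean_frac_dp = mean(fin$frac_dp))
    )
  })
}

#' @method glance icm_trajectory
#' @export
glance.icm_trajectory <- function(x, ...) {
  fin <- dplyr::slice_tail(tibble::as_tibble(x), n = 1)
  dplyr::bind_cols(tibble::tibble(t_final = fin$t), fin[-1])
}
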