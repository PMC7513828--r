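# Synthetic-data generators with known ground truth: segmented-embryo
# fluorescence tables (the shape of MINS output) and post-ablation time-lapse
# GFP tracks. Everything is a pure function of (config, seed).

#' Configuration for synthetic segmented-embryo tables
#'
#' Emulates the tabular output of nuclear segmentation: one row per cell with
#' XYZ position and per-channel fluorescence. Channel intensities are
#' log-normal with identity-specific locations (separated by several scale
#' units, so classification is solvable but noisy) plus a linear log-scale
#' decay along Z. The default composition is the late-blastocyst wild type:
#' 60% PrE, 40% epiblast among committed cells, no remaining progenitors.
#'
#' @param n_icm Cells per embryo.
#' @param composition Named fractions `c(EPI=, PrE=, DP=)` summing to 1.
#' @param meanlog Named list per identity of `c(nanog=, gata6=)` log-scale
#'   locations.
#' @param sdlog Log-scale noise (shared across channels).
#' @param z_range Imaging depth range (microns).
#' @param z_decay_slope Per-micron log-intensity slope (negative = decay).
#' @param litter_sdlog Log-scale spread of litter-level intensity factors.
#' @return A list of class `embryo_gen_config`.
#' @export
synth_embryo_config <- function(n_icm = 25,
                                composition = c(EPI = 0.4, PrE = 0.6,
                                                DP = 0),
                                meanlog = list(
                                  EPI = c(nanog = 6.2, gata6 = 4.0),
                                  PrE = c(nanog = 4.0, gata6 = 6.2),
                                  DP = c(nanog = 5.9, gata6 = 5.9)
                                ),
                                sdlog = 0.4,
                                z_range = c(0, 60),
                                z_decay_slope = -0.01,
                                litter_sdlog = 0.3) {
  stopifnot(n_icm >= 1, abs(sum(composition) - 1) < 1e-8,
            all(composition >= 0), sdlog > 0)
  structure(list(n_icm = n_icm, composition = composition,
                 meanlog = meanlog, sdlog = sdlog, z_range = z_range,
                 z_decay_slope = z_decay_slope,
                 litter_sdlog = litter_sdlog),
            class = "embryo_gen_config")
}

#' Generate one synthetic segmented-embryo cell table
#'
#' @param cfg A [synth_embryo_config()] object.
#' @param seed Integer seed (`NULL` continues the current RNG stream).
#' @param embryo_id,litter_id Identifiers written into the table.
#' @param id_offset Offset added to cell ids (for multi-embryo tables).
#' @param litter_factor Multiplicative litter intensity factor.
#' @return A tibble of cell records: `cell_id`, `embryo_id`, `litter_id`,
#'   `z`, `nanog_raw`, `gata6_raw`, `gfp_raw`, `ti_flag`, `identity`
#'   (unassigned), and `true_identity` (the generator truth).
#' @export
synth_embryo_table <- function(cfg = synth_embryo_config(), seed = NULL,
                               embryo_id = 1L, litter_id = 1L,
                               id_offset = 0L, litter_factor = 1) {
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_icm
  ids <- names(cfg$composition)
  truth <- ids[sample.int(length(ids), n, replace = TRUE,
                          prob = cfg$composition)]
  z <- stats::runif(n, cfg$z_range[1], cfg$z_range[2])
  draw <- function(ch) {
    ml <- vapply(truth, function(id) cfg$meanlog[[id]][[ch]], numeric(1))
    exp(ml + cfg$z_decay_slope * z + stats::rnorm(n, 0, cfg$sdlog) +
          log(litter_factor))
  }
  tibble::tibble(
    cell_id = id_offset + seq_len(n),
    embryo_id = embryo_id,
    litter_id = litter_id,
    z = z,
    nanog_raw = draw("nanog"),
    gata6_raw = draw("gata6"),
    gfp_raw = draw("gata6"),  # Pdgfra-GFP tracks the PrE programme
    ti_flag = "ICM",
    identity = NA_character_,
    true_identity = truth
  )
}

#' Generate a multi-embryo, multi-litter synthetic cell table
#'
#' Embryos within a litter share a litter-level intensity scale factor
#' (log-normal across litters), so per-litter rescaling is meaningful.
#'
#' @param cfg A [synth_embryo_config()] object.
#' @param n_embryos Embryos per litter.
#' @param n_litters Number of litters.
#' @param seed Integer seed.
#' @return A tibble of cell records with consecutive embryo and litter ids.
#' @export
synth_litter <- function(cfg = synth_embryo_config(), n_embryos = 5,
                         n_litters = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_embryos >= 1, n_litters >= 1)
  out <- list()
  eid <- 0L
  offset <- 0L
  for (l in seq_len(n_litters)) {
    fac <- exp(stats::rnorm(1, 0, cfg$litter_sdlog))
    for (j in seq_len(n_embryos)) {
      eid <- eid + 1L
      tb <- synth_embryo_table(cfg, seed = NULL, embryo_id = eid,
                               litter_id = l, id_offset = offset,
                               litter_factor = fac)
      offset <- offset + nrow(tb)
      out[[length(out) + 1]] <- tb
    }
  }
  dplyr::bind_rows(out)
}

#' Configuration for synthetic time-lapse GFP tracks
#'
#' Emulates manually tracked *Pdgfra*-GFP movies after a laser-ablation
#' experiment: 15-min frames over a 16-20 hr movie. Intact cells follow
#' fate-specific GFP dynamics on a 0-1 normalised scale (PrE drift upward,
#' epiblast stay on a low plateau, progenitors start intermediate and drift
#' towards a fate); targeted cells die with exponential (memoryless) timing
#' at a configurable half-life, censored at the movie end.
#'
#' @param frame_interval Frame spacing, hours.
#' @param duration Movie length, hours.
#' @param death_half_life Half-life of targeted cells, hours.
#' @param gfp_noise Per-frame Gaussian noise on GFP.
#' @param dp_commit_hr Mean time at which a progenitor starts drifting.
#' @return A list of class `track_gen_config`.
#' @export
synth_track_config <- function(frame_interval = 0.25, duration = 18,
                               death_half_life = 3.4, gfp_noise = 0.05,
                               dp_commit_hr = 4) {
  stopifnot(frame_interval > 0, duration > 0, death_half_life > 0)
  structure(list(frame_interval = frame_interval, duration = duration,
                 death_half_life = death_half_life, gfp_noise = gfp_noise,
                 dp_commit_hr = dp_commit_hr),
            class = "track_gen_config")
}

#' Generate synthetic time-lapse GFP tracks
#'
#' @param cfg A [synth_track_config()] object.
#' @param n_cells Number of cells to track.
#' @param targeted_ids Cell ids (subset of `1:n_cells`) that were targeted;
#'   these draw an exponential death time and their track is truncated at
#'   death (event `"death"` on the final frame) or censored at the movie end.
#' @param fates Fate of each intact cell: `"PrE"`, `"EPI"` or `"DP"`;
#'   recycled. Progenitors (`"DP"`) drift towards `dp_fate`.
#' @param dp_fate Fate that progenitor GFP drifts towards (`"PrE"` drifts
#'   up, `"EPI"` down).
#' @param seed Integer seed.
#' @return A tibble of track records: `cell_id`, `frame`, `gfp`, `event`,
#'   `identity_start`, `group` (`"targeted"`/`"intact"`), `true_fate`,
#'   `true_death_time` (`NA` for intact or censored cells).
#' @export
synth_timelapse <- function(cfg = synth_track_config(), n_cells = 50,
                            targeted_ids = integer(), fates = "DP",
                            dp_fate = "PrE", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(targeted_ids %in% seq_len(n_cells)))
  frames <- seq(0, cfg$duration, by = cfg$frame_interval)
  nf <- length(frames)
  fates <- rep(fates, length.out = n_cells)
  rate <- log(2) / cfg$death_half_life
  purrr::map_dfr(seq_len(n_cells), function(i) {
    targeted <- i %in% targeted_ids
    death <- if (targeted && is.finite(rate) && rate > 0) {
      stats::rexp(1, rate)
    } else {
      Inf
    }
    last <- if (death < cfg$duration) {
      max(which(frames <= death))
    } else {
      nf
    }
    fr <- frames[seq_len(last)]
    fate <- fates[i]
    base <- switch(fate,
      PrE = pmin(0.45 + 0.035 * fr, 0.95),
      EPI = rep(0.15, length(fr)),
      DP = {
        commit <- stats::rexp(1, 1 / cfg$dp_commit_hr)
        drift <- pmax(fr - commit, 0)
        if (dp_fate == "PrE") {
          pmin(0.4 + 0.05 * drift, 0.95)
        } else {
          pmax(0.4 - 0.05 * drift, 0.1)
        }
      }
    )
    gfp <- pmax(base + stats::rnorm(length(fr), 0, cfg$gfp_noise), 0)
    event <- rep("none", length(fr))
    if (death < cfg$duration) event[length(event)] <- "death"
    tibble::tibble(
      cell_id = i,
      frame = seq_len(length(fr)),
      gfp = gfp,
      event = event,
      identity_start = if (fate == "DP") "DP" else fate,
      group = if (targeted) "targeted" else "intact",
      true_fate = fate,
      true_death_time = if (death < cfg$duration) death else NA_real_
    )
  })
}
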