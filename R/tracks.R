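# Time-lapse GFP track processing: smoothing, the persistence-rule identity
# classifier, and Kaplan-Meier survival / half-life estimation.

#' Moving-average smoothing of a GFP track
#'
#' Centred moving average with the window shrinking at the track edges (the
#' mean is taken over whichever of the `window` frames fall inside the
#' track). The default window of 4 frames spans 1 hr at 15-min spacing.
#'
#' @param tracks A track table with columns `cell_id`, `frame`, `gfp`.
#' @param window Window width in frames, >= 1 (1 = identity).
#' @return The table with a `smoothed_gfp` column added, ordered by cell and
#'   frame.
#' @export
smooth_gfp <- function(tracks, window = 4) {
  stopifnot(window >= 1, window == round(window))
  tracks <- dplyr::arrange(tibble::as_tibble(tracks),
                           .data$cell_id, .data$frame)
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::mutate(smoothed_gfp = {
      n <- dplyr::n()
      vapply(seq_len(n), function(i) {
        mean(.data$gfp[max(1, i - half_lo):min(n, i + half_hi)])
      }, numeric(1))
    }) |>
    dplyr::ungroup()
}

#' Classify cell identity along a GFP track
#'
#' Assigns a per-frame identity to tracked ICM cells from (smoothed)
#' *Pdgfra*-GFP levels, following two rules: (1) permanence - a cell
#' classified as PrE or epiblast keeps that identity for the remainder of the
#' movie; (2) persistence - a progenitor (DP) switches to PrE (or epiblast)
#' at the first frame of the earliest run of at least `persistence_hr` hours
#' (8 frames at 15-min spacing) spent continuously above the PrE threshold
#' (or below the epiblast threshold). Thresholds are specified at the movie
#' start and end and interpolated linearly across frames (the threshold
#' slope). A cell whose first qualifying runs for both fates start on the
#' same frame is flagged ambiguous and left DP.
#'
#' @param tracks Track table with `cell_id`, `frame`, and `smoothed_gfp`
#'   (computed by [smooth_gfp()] if absent, from `gfp`). An optional
#'   `identity_start` column (or attribute-free default `"DP"`) gives each
#'   cell's identity at the first frame.
#' @param th_pre Length-2 numeric: PrE (upper) threshold at movie start and
#'   end.
#' @param th_epi Length-2 numeric: epiblast (lower) threshold at start/end.
#' @param persistence_hr Required persistence, hours.
#' @param frame_interval Frame spacing, hours (default 0.25 = 15 min).
#' @return The table with `identity_at_frame` and a logical `ambiguous`
#'   column.
#' @export
classify_track <- function(tracks, th_pre = c(0.55, 0.65),
                           th_epi = c(0.25, 0.20),
                           persistence_hr = 2, frame_interval = 0.25) {
  tracks <- tibble::as_tibble(tracks)
  if (!"smoothed_gfp" %in% names(tracks)) tracks <- smooth_gfp(tracks)
  if (!"identity_start" %in% names(tracks)) tracks$identity_start <- "DP"
  need <- max(1L, ceiling(persistence_hr / frame_interval))
  f_all <- range(tracks$frame)
  interp <- function(th, frame) {
    if (diff(f_all) == 0) return(rep(th[1], length(frame)))
    th[1] + (th[2] - th[1]) * (frame - f_all[1]) / diff(f_all)
  }
  tracks |>
    dplyr::arrange(.data$cell_id, .data$frame) |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(d, key) {
      n <- nrow(d)
      start_id <- d$identity_start[1]
      d$ambiguous <- FALSE
      if (start_id %in% c("PrE", "EPI")) {
        d$identity_at_frame <- start_id     # rule 1: permanence
        return(d)
      }
      up <- d$smoothed_gfp > interp(th_pre, d$frame)
      down <- d$smoothed_gfp < interp(th_epi, d$frame)
      first_run <- function(cond) {
        r <- rle(cond)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        ok <- which(r$values & r$lengths >= need)
        if (length(ok)) starts[ok[1]] else NA_integer_
      }
      s_pre <- first_run(up)
      s_epi <- first_run(down)
      ident <- rep("DP", n)
      if (!is.na(s_pre) && !is.na(s_epi) && s_pre == s_epi) {
        d$ambiguous <- TRUE
      } else if (!is.na(s_pre) && (is.na(s_epi) || s_pre < s_epi)) {
        ident[s_pre:n] <- "PrE"
      } else if (!is.na(s_epi)) {
        ident[s_epi:n] <- "EPI"
      }
      d$identity_at_frame <- ident
      d
    }) |>
    dplyr::ungroup()
}

#' Kaplan-Meier survival curves and half-life per group
#'
#' Product-limit survival estimate from per-cell event times (death events;
#' cells without a death are right-censored at their last observed frame).
#' The half-life of a group is the first time its survival function drops to
#' or below 0.5 (the Kaplan-Meier median), undefined (`NA`) when survival
#' never reaches 0.5.
#'
#' @param tracks Track table with `cell_id`, `frame`, `event` (`"none"`,
#'   `"death"`, `"division"`) and optionally a `group` column.
#' @param group Name of the grouping column (default `"group"`; a constant
#'   group is assumed when absent).
#' @param frame_interval Frame spacing in hours.
#' @return A tibble with one row per group: `group`, `n`, `n_deaths`,
#'   `half_life`, `half_life_lcl`, `half_life_ucl` (95% CI). The
#'   `survival::survfit` object is attached as attribute `"fit"`, and the
#'   stepwise curves as attribute `"curve"` (tibble: group, time, surv,
#'   lower, upper).
#' @export
survival_curve <- function(tracks, group = "group", frame_interval = 0.25) {
  tracks <- tibble::as_tibble(tracks)
  if (!nrow(tracks)) stop("no cells in `tracks`", call. = FALSE)
  if (!group %in% names(tracks)) tracks[[group]] <- "all"
  per_cell <- tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      time = max(.data$frame) * frame_interval,
      status = as.integer(any(.data$event == "death")),
      group = .data[[group]][1],
      .groups = "drop"
    )
  if (!nrow(per_cell)) stop("no cells in `tracks`", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(time, status) ~ group, data = per_cell,
    conf.type = "log-log"
  )
  smry <- summary(fit)$table
  if (is.null(dim(smry))) smry <- t(as.matrix(smry))
  grp_names <- if (is.null(rownames(smry))) {
    unique(per_cell$group)
  } else {
    sub("^group=", "", rownames(smry))
  }
  out <- tibble::tibble(
    group = grp_names,
    n = as.numeric(smry[, "records"]),
    n_deaths = as.numeric(smry[, "events"]),
    half_life = as.numeric(smry[, "median"]),
    half_life_lcl = as.numeric(smry[, "0.95LCL"]),
    half_life_ucl = as.numeric(smry[, "0.95UCL"])
  )
  strata <- if (is.null(fit$strata)) {
    rep(out$group[1], length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curve <- tibble::tibble(group = strata, time = fit$time, surv = fit$surv,
                          lower = fit$lower, upper = fit$upper)
  attr(out, "fit") <- fit
  attr(out, "curve") <- curve
  class(out) <- c("icm_survival", class(out))
  out
}

#' @method tidy icm_survival
#' @export
tidy.icm_survival <- function(x, ...) attr(x, "curve")

#' @method glance icm_survival
#' @export
glance.icm_survival <- function(x, ...) tibble::as_tibble(unclass(x))
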