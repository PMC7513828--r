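# Quantitative processing of segmented-fluorescence cell tables: Z-decay
# correction (with optional empirical-Bayes slope shrinkage), antibody
# harmonisation, per-litter rescaling and UPGMA identity classification.

channel_cols <- c("nanog", "gata6", "gfp")

raw_col <- function(ch) paste0(ch, "_raw")
corr_col <- function(ch) paste0(ch, "_corr")

#' Correct fluorescence decay along the imaging Z axis
#'
#' Fluorescence attenuates with imaging depth. For each embryo and channel
#' the log-transformed intensity is regressed on the Z position and the
#' fitted slope component is subtracted, so that the corrected log intensity
#' has (near-)zero residual dependence on Z. With `mode = "eb"` the
#' per-embryo slopes are first shrunk towards their litter mean by
#' normal-normal precision weighting (weight proportional to the precision of
#' each embryo's slope estimate), which stabilises slopes from embryos with
#' few cells; this is the empirical-Bayes variant.
#'
#' @param table A cell table with columns `embryo_id`, `litter_id`, `z` and
#'   raw channel columns (`nanog_raw`, `gata6_raw`, optionally `gfp_raw`).
#' @param mode `"linear"` (independent per-embryo fits) or `"eb"`
#'   (litter-shrunk slopes).
#' @param channels Channels to correct; defaults to those present.
#' @return The table with added corrected linear-scale columns
#'   (`nanog_corr`, ...) and an attribute `"z_slopes"`: a tibble of the
#'   fitted (and, for `"eb"`, shrunk) slopes per embryo and channel.
#' @export
zdecay_correct <- function(table, mode = c("linear", "eb"),
                           channels = NULL) {
  mode <- match.arg(mode)
  table <- tibble::as_tibble(table)
  channels <- channels %||%
    channel_cols[raw_col(channel_cols) %in% names(table)]
  stopifnot(all(c("embryo_id", "z") %in% names(table)))
  if (mode == "eb" && !"litter_id" %in% names(table)) {
    stop("`litter_id` is required for empirical-Bayes correction",
         call. = FALSE)
  }
  slopes <- purrr::map_dfr(channels, function(ch) {
    vals <- table[[raw_col(ch)]]
    if (any(vals <= 0)) {
      stop("intensities must be positive for log transformation",
           call. = FALSE)
    }
    dat <- tibble::tibble(embryo_id = table$embryo_id,
                          litter_id = if ("litter_id" %in% names(table))
                            table$litter_id else 1L,
                          z = table$z, y = log(vals))
    dat |>
      dplyr::group_by(.data$litter_id, .data$embryo_id) |>
      dplyr::group_modify(function(d, key) {
        if (nrow(d) < 5) {
          stop("need at least 5 cells per embryo and channel to fit the ",
               "Z-decay model", call. = FALSE)
        }
        fit <- stats::lm(y ~ z, data = d)
        sm <- summary(fit)$coefficients
        tibble::tibble(channel = ch,
                       slope = sm["z", "Estimate"],
                       slope_se = sm["z", "Std. Error"])
      }) |>
      dplyr::ungroup()
  })
  if (mode == "eb") {
    slopes <- slopes |>
      dplyr::group_by(.data$litter_id, .data$channel) |>
      dplyr::mutate(slope = eb_shrink(.data$slope, .data$slope_se)) |>
      dplyr::ungroup()
  }
  for (ch in channels) {
    sl <- slopes[slopes$channel == ch, ]
    s_by_embryo <- sl$slope[match(table$embryo_id, sl$embryo_id)]
    table[[corr_col(ch)]] <-
      exp(log(table[[raw_col(ch)]]) - s_by_embryo * table$z)
  }
  attr(table, "z_slopes") <- slopes
  table
}

# normal-normal precision-weighted shrinkage of per-embryo slopes towards
# the litter mean; tau^2 estimated by method of moments (0 -> full pooling)
eb_shrink <- function(slope, se) {
  if (length(slope) == 1) return(slope)
  mu <- mean(slope)
  tau2 <- max(0, stats::var(slope) - mean(se^2))
  if (tau2 == 0) return(rep(mu, length(slope)))
  (slope / se^2 + mu / tau2) / (1 / se^2 + 1 / tau2)
}

#' Fit a linear map between two antibody scales
#'
#' Different antibodies against the same marker produce different intensity
#' scales. From records double-stained with both antibodies a linear
#' regression maps the alternative scale onto the reference one.
#'
#' @param reference,alternative Paired intensity vectors from double-stained
#'   cells.
#' @return A list of class `calibration_map` with `slope` and `intercept`
#'   mapping alternative -> reference.
#' @export
fit_calibration <- function(reference, alternative) {
  stopifnot(length(reference) == length(alternative),
            length(reference) >= 3)
  fit <- stats::lm(reference ~ alternative)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) {
    stop("calibration slope must be positive; check channel pairing",
         call. = FALSE)
  }
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1])),
            class = "calibration_map")
}

#' Transform a channel onto the reference antibody scale
#'
#' Applies the affine map of a [fit_calibration()] object to one column of a
#' cell table (in place). `inverse = TRUE` undoes the transform.
#'
#' @param table A cell table.
#' @param calib A `calibration_map` (or a list with `slope`, `intercept`).
#' @param channel Column to transform (e.g. `"nanog_raw"`).
#' @param inverse Apply the inverse map.
#' @return The table with the channel transformed.
#' @export
harmonize_antibody <- function(table, calib, channel = "nanog_raw",
                               inverse = FALSE) {
  stopifnot(channel %in% names(table), calib$slope > 0)
  v <- table[[channel]]
  table[[channel]] <- if (inverse) {
    (v - calib$intercept) / calib$slope
  } else {
    calib$slope * v + calib$intercept
  }
  table
}

#' Rescale channels against their per-litter maxima
#'
#' Litters are the experimental unit; staining intensity varies between
#' them. Each channel is divided by its maximum within the litter, yielding
#' values in (0, 1] that are comparable across litters. Operates on the
#' corrected columns when present, otherwise on the raw ones, and writes
#' plain channel columns (`nanog`, `gata6`, `gfp`).
#'
#' @param table A cell table with `litter_id`.
#' @param channels Channels to rescale; defaults to those present.
#' @return The table with rescaled `[0, 1]` channel columns added.
#' @export
rescale_by_litter <- function(table, channels = NULL) {
  stopifnot("litter_id" %in% names(table))
  table <- tibble::as_tibble(table)
  channels <- channels %||% channel_cols[
    raw_col(channel_cols) %in% names(table) |
      corr_col(channel_cols) %in% names(table)]
  for (ch in channels) {
    src <- if (corr_col(ch) %in% names(table)) corr_col(ch) else raw_col(ch)
    table <- table |>
      dplyr::group_by(.data$litter_id) |>
      dplyr::mutate(!!ch := .data[[src]] / max(.data[[src]])) |>
      dplyr::ungroup()
  }
  table
}

# Name clusters from their centroids. Double positive means both channels
# sit near the largest cluster centroid for that channel; NANOG-lo means both
# channels are absolutely low (below `low`) with NANOG still dominant;
# otherwise the dominant channel decides between epiblast and PrE.
label_clusters <- function(centroids, low = 0.25) {
  n_cen <- centroids[, 1]
  g_cen <- centroids[, 2]
  n_rel <- n_cen / max(n_cen)
  g_rel <- g_cen / max(g_cen)
  ifelse(n_rel >= 0.5 & g_rel >= 0.5, "DP",
    ifelse(n_cen < low & g_cen < low & n_cen > g_cen, "NANOG-lo",
      ifelse(n_cen >= g_cen, "EPI", "PrE")))
}

#' Classify ICM cells by UPGMA clustering of marker levels
#'
#' Hierarchical agglomerative clustering with average linkage (UPGMA) on the
#' rescaled (NANOG, GATA6) plane, cut at `k` clusters; each cluster is named
#' by the identity prototype nearest to its centroid (epiblast: high NANOG /
#' low GATA6; PrE: the reverse; DP: both high; NANOG-lo: both low with NANOG
#' dominant). Cells with both markers below `dn_threshold` are set aside as
#' double-negative (DN) before clustering - these are rare and usually
#' mitotic or dying cells. Rows are sorted by `cell_id` before clustering so
#' the result is invariant to input row order.
#'
#' @param table A cell table with rescaled `nanog` and `gata6` columns (see
#'   [rescale_by_litter()]); only rows with `ti_flag == "ICM"` are
#'   classified when the column is present.
#' @param k Number of clusters to cut the tree into (default 4).
#' @param dn_threshold Both-channels-below threshold for the DN pre-filter.
#' @return The table with an `identity` column filled in (`"EPI"`, `"PrE"`,
#'   `"DP"`, `"NANOG-lo"`, `"DN"`; TE rows, if any, get `"unassigned"`).
#' @export
classify_icm <- function(table, k = 4, dn_threshold = 0.1) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("nanog", "gata6", "cell_id") %in% names(table)))
  icm <- if ("ti_flag" %in% names(table)) table$ti_flag == "ICM" else
    rep(TRUE, nrow(table))
  table$identity <- ifelse(icm, NA_character_, "unassigned")
  ord <- order(table$cell_id)
  table <- table[ord, ]
  icm <- icm[ord]
  dn <- icm & table$nanog < dn_threshold & table$gata6 < dn_threshold
  table$identity[dn] <- "DN"
  work <- which(icm & !dn)
  if (k > length(work)) {
    stop("`k` exceeds the number of classifiable ICM cells", call. = FALSE)
  }
  m <- as.matrix(table[work, c("nanog", "gata6")])
  hc <- stats::hclust(stats::dist(m), method = "average")
  cl <- stats::cutree(hc, k = k)
  centroids <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(m[cl == g, , drop = FALSE])
  }))
  table$identity[work] <- label_clusters(centroids)[cl]
  table
}

#' Stratify an ESC compartment in epiblast equivalents
#'
#' ESC loads are reported relative to the average wild-type epiblast size:
#' the control range (5-10 cells by default) is the 1x stratum and each
#' doubling of its upper bound opens the next (2x = (10, 20], 4x = (20, 40],
#' ...). Zero ESCs is `"control"`, a load below the control range `"<1x"`.
#'
#' @param n_esc Non-negative ESC count(s). Vectorised.
#' @param control_epi_range Length-2 numeric, the control epiblast size range.
#' @return Character stratum labels (`"control"`, `"<1x"`, `"1x"`, `"2x"`,
#'   `"4x"`, ...).
#' @export
epi_equivalents <- function(n_esc, control_epi_range = c(5, 10)) {
  stopifnot(all(n_esc >= 0), length(control_epi_range) == 2,
            control_epi_range[1] < control_epi_range[2])
  lo <- control_epi_range[1]
  hi <- control_epi_range[2]
  vapply(n_esc, function(n) {
    if (n == 0) return("control")
    if (n < lo) return("<1x")
    if (n <= hi) return("1x")
    mult <- 2
    upper <- hi * 2
    while (n > upper) {
      mult <- mult * 2
      upper <- upper * 2
    }
    paste0(mult, "x")
  }, character(1))
}
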