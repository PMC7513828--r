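# smoothed_gfp preset to the raw signal so the classifier rule tests control
# the thresholded signal exactly; smooth_gfp overwrites it where exercised
mk_track <- function(gfp, cell_id = 1, identity_start = "DP") {
  tibble::tibble(cell_id = cell_id, frame = seq_along(gfp), gfp = gfp,
                 smoothed_gfp = gfp, event = "none",
                 identity_start = identity_start)
}

test_that("moving average: identity, constancy and the step response", {
  const <- mk_track(rep(0.4, 12))
  expect_equal(smooth_gfp(const, window = 4)$smoothed_gfp, rep(0.4, 12))
  noisy <- mk_track(runif(12))
  expect_equal(smooth_gfp(noisy, window = 1)$smoothed_gfp, noisy$gfp)
  # a unit step smoothed with window 4 climbs as a 4-frame ramp
  step <- mk_track(c(rep(0, 8), rep(1, 8)))
  sm <- smooth_gfp(step, window = 4)$smoothed_gfp
  # centred window (1 back, 2 forward): ramp 0, 1/4, 2/4, 3/4 around the edge
  expect_equal(sm[6:10], c(0, 1 / 4, 2 / 4, 3 / 4, 1))
  expect_error(smooth_gfp(step, window = 0), "window")
})

test_that("persistence rule: eight qualifying frames switch, seven do not", {
  th_pre <- c(0.6, 0.6)
  th_epi <- c(0.2, 0.2)
  base <- rep(0.4, 30)
  run_of <- function(n_above) {
    g <- base
    g[10:(10 + n_above - 1)] <- 0.9
    classify_track(mk_track(g), th_pre, th_epi)
  }
  # 2 hr at 15-min frames = 8 frames: the boundary case
  out7 <- run_of(7)
  expect_true(all(out7$identity_at_frame == "DP"))
  out8 <- run_of(8)
  expect_equal(out8$identity_at_frame[out8$frame >= 10], rep("PrE", 21))
  expect_equal(out8$identity_at_frame[out8$frame < 10], rep("DP", 9))
  # nine frames, matching the looser example
  out9 <- run_of(9)
  expect_equal(out9$identity_at_frame[10], "PrE")
  # four frames (1 hr) is not enough
  expect_true(all(run_of(4)$identity_at_frame == "DP"))
  # epiblast direction works symmetrically
  g <- base; g[5:20] <- 0.1
  oute <- classify_track(mk_track(g), th_pre, th_epi)
  expect_equal(oute$identity_at_frame[5], "EPI")
})

test_that("permanence: identity never reverts once assigned", {
  th_pre <- c(0.6, 0.6); th_epi <- c(0.2, 0.2)
  # a PrE-classified cell that later dips below every threshold stays PrE
  g <- c(rep(0.9, 10), rep(0.05, 20))
  out <- classify_track(mk_track(g), th_pre, th_epi)
  expect_true(all(out$identity_at_frame == "PrE"))
  # a cell already committed at movie start keeps its label throughout
  out2 <- classify_track(mk_track(rep(0.05, 15), identity_start = "PrE"),
                         th_pre, th_epi)
  expect_true(all(out2$identity_at_frame == "PrE"))
  # property: across random DP tracks, no output ever leaves a committed
  # state once entered
  set.seed(9)
  for (i in 1:20) {
    g <- pmin(pmax(cumsum(rnorm(40, 0, 0.12)) + 0.4, 0), 1)
    out <- classify_track(mk_track(g), th_pre, th_epi)
    id <- out$identity_at_frame
    committed <- which(id != "DP")
    if (length(committed)) {
      expect_true(all(id[min(committed):length(id)] == id[min(committed)]))
    }
  }
})

test_that("threshold interpolation follows the configured slope", {
  # rising PrE threshold: a level crossing it early but not late only counts
  # while above the interpolated line
  g <- rep(0.5, 20)
  out_flat <- classify_track(mk_track(g), th_pre = c(0.45, 0.45),
                             th_epi = c(0.1, 0.1))
  expect_equal(out_flat$identity_at_frame[1], "PrE")
  out_rising <- classify_track(mk_track(g), th_pre = c(0.45, 0.95),
                               th_epi = c(0.1, 0.1))
  # above threshold only for the first ~2 frames of the ramp: no switch
  expect_true(all(out_rising$identity_at_frame == "DP"))
})

test_that("simultaneous qualification is flagged, not guessed", {
  # constant level both above the PrE threshold and below the EPI threshold
  # (inverted thresholds) qualifies for both on the same frame
  out <- classify_track(mk_track(rep(0.5, 20)), th_pre = c(0.4, 0.4),
                        th_epi = c(0.6, 0.6))
  expect_true(all(out$ambiguous))
  expect_true(all(out$identity_at_frame == "DP"))
})

test_that("Kaplan-Meier estimate matches the closed-form product limit", {
  # hand-built cohort of 5: two deaths at 2 h, one at 3 h, two censored at 4 h
  tr <- dplyr::bind_rows(
    mk_track(rep(0, 8), cell_id = 1),   # death at frame 8 = 2 h
    mk_track(rep(0, 8), cell_id = 2),
    mk_track(rep(0, 12), cell_id = 3),  # death at frame 12 = 3 h
    mk_track(rep(0, 16), cell_id = 4),  # censored
    mk_track(rep(0, 16), cell_id = 5)
  )
  tr$event[tr$cell_id %in% c(1, 2, 3) &
             tr$frame == ave(tr$frame, tr$cell_id, FUN = max)] <- "death"
  sv <- survival_curve(tr)
  curve <- tidy(sv)
  # product-limit by hand: S(2h) = 3/5, S(3h) = 3/5 * 2/3 = 2/5
  expect_equal(curve$surv[curve$time == 2], 3 / 5)
  expect_equal(curve$surv[curve$time == 3], 2 / 5)
  expect_equal(sv$half_life, 3)
  expect_true(all(diff(curve$surv) <= 1e-12))
  # no deaths: survival stays at 1, half-life undefined
  tr2 <- dplyr::bind_rows(mk_track(rep(0, 10), 1), mk_track(rep(0, 10), 2))
  sv2 <- survival_curve(tr2)
  expect_true(all(tidy(sv2)$surv == 1))
  expect_true(is.na(sv2$half_life))
  # all deaths at one time: half-life is that time
  tr3 <- dplyr::bind_rows(mk_track(rep(0, 20), 1), mk_track(rep(0, 20), 2))
  tr3$event[tr3$frame == 20] <- "death"
  expect_equal(survival_curve(tr3)$half_life, 5)
  expect_error(survival_curve(tr3[0, ]), "no cells")
})
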