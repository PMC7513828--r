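test_that("Z-decay correction recovers injected slopes and flattens them", {
  # single-identity table: intensity noise is unimodal so the per-embryo fit
  # isolates the depth trend
  cfg <- synth_embryo_config(n_icm = 200,
                             composition = c(EPI = 0, PrE = 0, DP = 1),
                             z_decay_slope = -0.02)
  tb <- synth_embryo_table(cfg, seed = 1)
  out <- zdecay_correct(tb, mode = "linear")
  sl <- attr(out, "z_slopes")
  expect_true(all(abs(sl$slope - (-0.02)) < 0.1 * 0.02))
  # corrected data regress flat on z
  for (ch in c("nanog_corr", "gata6_corr")) {
    refit <- coef(lm(log(out[[ch]]) ~ out$z))[2]
    expect_lt(abs(refit), 1e-3)
  }
  # idempotence: correcting corrected data changes nothing appreciable
  tb2 <- out
  tb2$nanog_raw <- out$nanog_corr
  tb2$gata6_raw <- out$gata6_corr
  tb2$gfp_raw <- out$gfp_corr
  sl2 <- attr(zdecay_correct(tb2, mode = "linear"), "z_slopes")
  expect_lt(max(abs(sl2$slope)), 1e-3)
  # a (noise-free) zero-slope table passes through unchanged
  cfg0 <- synth_embryo_config(n_icm = 100,
                              composition = c(EPI = 0, PrE = 0, DP = 1),
                              sdlog = 1e-9, z_decay_slope = 0)
  tb0 <- synth_embryo_table(cfg0, seed = 2)
  out0 <- zdecay_correct(tb0, mode = "linear")
  expect_lt(max(abs(log(out0$nanog_corr) - log(out0$nanog_raw))), 1e-6)
  # too few cells per embryo errors
  tiny <- synth_embryo_table(synth_embryo_config(n_icm = 4), seed = 3)
  expect_error(zdecay_correct(tiny), "at least 5")
})

test_that("empirical-Bayes slopes shrink towards the litter mean", {
  cfg <- synth_embryo_config(n_icm = 40, z_decay_slope = -0.015)
  tb <- synth_litter(cfg, n_embryos = 6, seed = 4)
  lin <- attr(zdecay_correct(tb, mode = "linear"), "z_slopes")
  eb <- attr(zdecay_correct(tb, mode = "eb"), "z_slopes")
  for (ch in unique(lin$channel)) {
    l <- lin$slope[lin$channel == ch]
    b <- eb$slope[eb$channel == ch]
    expect_lte(stats::sd(b), stats::sd(l))
    expect_lt(abs(mean(b) - mean(l)), 0.1 * abs(mean(l)))
    # each shrunk slope lies between its raw estimate and the litter mean
    mu <- mean(l)
    expect_true(all((b - l) * (mu - l) >= -1e-12))
  }
})

test_that("antibody harmonisation recovers and inverts the linear map", {
  set.seed(5)
  truth <- runif(120, 50, 500)
  alt <- (truth - 0.2) / 1.5 + rnorm(120, 0, 2)
  calib <- fit_calibration(truth, alt)
  expect_equal(calib$slope, 1.5, tolerance = 0.05 * 1.5)
  expect_equal(calib$intercept, 0.2, tolerance = 5)
  tb <- tibble::tibble(nanog_raw = alt)
  tb2 <- harmonize_antibody(tb, calib, "nanog_raw")
  expect_equal(tb2$nanog_raw, truth, tolerance = 0.05)
  back <- harmonize_antibody(tb2, calib, "nanog_raw", inverse = TRUE)
  expect_equal(back$nanog_raw, alt, tolerance = 1e-10)
  # identity map leaves the table untouched
  id_map <- structure(list(slope = 1, intercept = 0),
                      class = "calibration_map")
  expect_equal(harmonize_antibody(tb, id_map, "nanog_raw"), tb)
  expect_error(fit_calibration(1:10, 10:1), "positive")
})

test_that("per-litter rescaling hits 1 at each litter maximum", {
  tb <- synth_litter(synth_embryo_config(n_icm = 30), n_embryos = 2,
                     n_litters = 3, seed = 6)
  rs <- rescale_by_litter(tb)
  for (l in unique(rs$litter_id)) {
    expect_equal(max(rs$nanog[rs$litter_id == l]), 1)
    expect_equal(max(rs$gata6[rs$litter_id == l]), 1)
  }
  # a single litter equals a global rescale
  one <- tb[tb$litter_id == 1, ]
  rs1 <- rescale_by_litter(one)
  expect_equal(rs1$nanog, one$nanog_raw / max(one$nanog_raw))
  # two-litter hand fixture
  hand <- tibble::tibble(
    cell_id = 1:4, embryo_id = c(1, 1, 2, 2), litter_id = c(1, 1, 2, 2),
    nanog_raw = c(2, 4, 10, 5), gata6_raw = c(1, 2, 2, 8))
  h <- rescale_by_litter(hand)
  expect_equal(h$nanog, c(0.5, 1, 1, 0.5))
  expect_equal(h$gata6, c(0.5, 1, 0.25, 1))
})

test_that("UPGMA classification separates clean clusters and ignores row order", {
  # two well-separated synthetic clusters, k = 2: perfect split
  set.seed(8)
  tb <- tibble::tibble(
    cell_id = 1:40,
    nanog = c(rnorm(20, 0.8, 0.03), rnorm(20, 0.1, 0.03)),
    gata6 = c(rnorm(20, 0.1, 0.03), rnorm(20, 0.8, 0.03)))
  out <- classify_icm(tb, k = 2)
  expect_equal(out$identity[match(1:20, out$cell_id)], rep("EPI", 20))
  expect_equal(out$identity[match(21:40, out$cell_id)], rep("PrE", 20))
  # row order does not matter
  out2 <- classify_icm(tb[sample(40), ], k = 2)
  expect_equal(dplyr::arrange(out2, cell_id)$identity,
               dplyr::arrange(out, cell_id)$identity)
  # DN pre-filter catches both-low cells before clustering
  tb$nanog[1] <- 0.05; tb$gata6[1] <- 0.04
  out3 <- classify_icm(tb, k = 2)
  expect_equal(out3$identity[out3$cell_id == 1], "DN")
  expect_error(classify_icm(tb, k = 100), "exceeds")
})

test_that("full pipeline recovers generator truth at default noise", {
  tb <- synth_litter(synth_embryo_config(), n_embryos = 5, n_litters = 3,
                     seed = 21) |>
    zdecay_correct(mode = "eb") |>
    rescale_by_litter() |>
    classify_icm(k = 4)
  expect_gte(mean(tb$identity == tb$true_identity), 0.95)
  per <- tb |>
    dplyr::group_by(embryo_id) |>
    dplyr::summarise(pre = sum(identity == "PrE") /
                       sum(identity %in% c("PrE", "EPI")))
  expect_equal(mean(per$pre), 0.60, tolerance = 0.08)
})

test_that("ESC loads stratify into dyadic epiblast equivalents", {
  expect_equal(epi_equivalents(0), "control")
  expect_equal(epi_equivalents(3), "<1x")
  expect_equal(epi_equivalents(7), "1x")
  expect_equal(epi_equivalents(c(5, 10)), c("1x", "1x"))
  expect_equal(epi_equivalents(15), "2x")
  expect_equal(epi_equivalents(c(25, 50, 100)), c("4x", "8x", "16x"))
})
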