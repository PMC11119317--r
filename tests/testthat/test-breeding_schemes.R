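test_that("stage plans enforce the fixed plot budget for every switch stage", {
  for (sw in c("PYT", "AYT", "EYT")) {
    for (method in c("DH", "EPR")) {
      cfg <- scheme_config(method, sw)
      p <- cfg$stage_plans
      expect_equal(p$pyt$plots, 784)
      expect_equal(p$ayt$plots, 288)
      expect_equal(p$eyt$plots, 144)
      expect_equal(p$ayt$n_entries, 144)
      expect_equal(p$ayt$r, 2L)
      expect_equal(p$eyt$n_entries, 36)
      expect_equal(p$eyt$r, 4L)
      expect_equal(p$eyt$mode, "IC")
      expect_equal(p$eyt$lines_per_crop, 6L)
      if (sw == "PYT") {
        expect_equal(p$pyt$mode, "IC")
        expect_equal(p$pyt$lines_per_crop, 28L)
        expect_equal(p$pyt$n_entries, 784)  # 28 x 28 combinations
        expect_equal(cfg$lines_per_family, 2L)
      } else {
        expect_equal(p$pyt$mode, "MC")
        expect_equal(p$pyt$lines_per_crop, 392L)
        expect_equal(p$pyt$n_entries, 784)  # 392 lines per crop
        expect_equal(cfg$lines_per_family, 28L)
      }
      expect_equal(p$ayt$mode, if (sw == "EYT") "MC" else "IC")
      expect_equal(p$pyt$n_select_per_crop, if (sw == "EYT") 72L else 12L)
      expect_equal(p$ayt$n_select_per_crop, 6L)
    }
  }
})

test_that("DH production yields the scheduled number of fully homozygous lines", {
  st <- study_state()
  set.seed(31)
  dh392 <- dh_production(st$s0$fb, 28)
  expect_equal(n_lines(dh392), 392)
  expect_equal(as.integer(table(dh392$family)), rep(28L, 14))
  expect_true(all(heterozygosity(dh392) == 0))

  dh28 <- dh_production(st$s0$fb, 2)
  expect_equal(n_lines(dh28), 28)
  expect_true(all(heterozygosity(dh28) == 0))
})

test_that("EPR fixation advances 8 percent of the S4 nursery per scenario", {
  st <- study_state()
  set.seed(32)

  cfg_ic <- scheme_config("EPR", "PYT")
  adv_ic <- epr_fixation(st$s0$fb, cfg_ic, st$archs$fb)
  expect_equal(n_lines(adv_ic), 28)               # 8% of 350
  expect_equal(as.integer(table(adv_ic$family)), rep(2L, 14))
  expect_equal(adv_ic$generation, "S4")

  cfg_mc <- scheme_config("EPR", "AYT")
  adv_mc <- epr_fixation(st$s0$tr, cfg_mc, st$archs$tr)
  expect_equal(n_lines(adv_mc), 392)              # 8% of 14 x 350
  expect_equal(as.integer(table(adv_mc$family)), rep(28L, 14))

  # S4 residual heterozygosity is near (1/2)^4 of the S0 level
  h_s0 <- mean(heterozygosity(st$s0$tr))
  expect_lt(abs(mean(heterozygosity(adv_mc)) / h_s0 - 1 / 16), 0.03)

  # noiseless visual selection improves the advanced set over its source
  cfg_exact <- scheme_config("EPR", "PYT", visual_h2 = 1)
  set.seed(33)
  adv_exact <- epr_fixation(st$s0$fb, cfg_exact, st$archs$fb)
  expect_gt(mean(gv_lines(adv_exact, st$archs$fb, "MC")),
            mean(gv_lines(st$s0$fb, st$archs$fb, "MC")))
})

test_that("within-family truncation matches a per-family sort oracle", {
  set.seed(34)
  family <- rep(1:4, each = 10)
  score <- stats::rnorm(40)
  got <- icbreedsim:::select_within_family(family, score, 3)
  oracle <- unlist(lapply(1:4, function(f) {
    i <- which(family == f)
    i[order(score[i], decreasing = TRUE)][1:3]
  }))
  expect_identical(got, oracle)

  # ties broken by stable input order
  tied <- icbreedsim:::select_within_family(rep(1L, 6), rep(0, 6), 2)
  expect_identical(tied, 1:2)
  expect_error(icbreedsim:::select_within_family(rep(1L, 3), 1:3, 5),
               "exceeds family size")
})

test_that("IC combinations form the full factorial with exact mean values", {
  for (n in c(28, 12, 6)) {
    gv_fb <- stats::rnorm(n)
    gv_tr <- stats::rnorm(n)
    cmb <- form_ic_combinations(gv_fb, gv_tr)
    expect_equal(nrow(cmb), n^2)
    oracle <- outer(gv_fb, gv_tr, function(a, b) (a + b) / 2)
    expect_equal(cmb$gv_ic, as.vector(oracle))
  }
})

test_that("noiseless trial stages equal brute-force top-k selection", {
  st <- study_state()
  set.seed(35)
  fixed <- lapply(st$s0, dh_production, lines_per_family = 28)

  # MC PYT: top 72 per crop on true MC genetic value
  plan_mc <- stage_plans("EYT")$pyt
  res <- run_stage(fixed, st$archs, plan_mc, h2 = 1)
  for (crop in c("fb", "tr")) {
    gv <- gv_lines(fixed[[crop]], st$archs[[crop]], "MC")
    oracle <- order(-gv, seq_along(gv))[1:72]
    expect_equal(gv_lines(res$selected[[crop]], st$archs[[crop]], "MC"),
                 gv[oracle])
    expect_identical(res$selected[[crop]]$family,
                     fixed[[crop]]$family[oracle])
    # directionality: the advanced set beats its candidate set
    expect_gt(mean(gv[oracle]), mean(gv))
  }
  expect_equal(res$record$plots, 784)

  # IC AYT: top 6 per crop on the row/column mean of the 12 x 12 factorial
  lines12 <- lapply(res$selected, subset_lines, idx = 1:12)
  plan_ic <- stage_plans("PYT")$ayt
  res2 <- run_stage(lines12, st$archs, plan_ic, h2 = 1)
  gv_fb <- gv_lines(lines12$fb, st$archs$fb, "IC")
  gv_tr <- gv_lines(lines12$tr, st$archs$tr, "IC")
  combo <- outer(gv_fb, gv_tr, function(a, b) (a + b) / 2)
  or_fb <- order(-rowMeans(combo), 1:12)[1:6]
  or_tr <- order(-colMeans(combo), 1:12)[1:6]
  expect_equal(gv_lines(res2$selected$fb, st$archs$fb, "IC"), gv_fb[or_fb])
  expect_equal(gv_lines(res2$selected$tr, st$archs$tr, "IC"), gv_tr[or_tr])
  expect_equal(res2$record$plots, 288)

  # EYT records the 36 combinations without further selection
  plan_eyt <- stage_plans("PYT")$eyt
  res3 <- run_stage(res2$selected, st$archs, plan_eyt, h2 = 1)
  expect_identical(res3$selected, res2$selected)
  expect_equal(res3$record$n_entries, 36)
  expect_equal(res3$record$plots, 144)
  expect_equal(res3$record$mean_gv,
               mean(outer(gv_fb[or_fb], gv_tr[or_tr],
                          function(a, b) (a + b) / 2)))

  # entry-count contract
  expect_error(run_stage(lines12, st$archs, plan_mc, h2 = 1), "expected")
})

test_that("tied phenotypes are resolved by stable entry order", {
  st <- study_state()
  clones <- lapply(st$s0, function(p)
    subset_lines(p, rep(1L, 392)))  # 392 identical lines per crop
  plan <- stage_plans("EYT")$pyt
  res <- run_stage(clones, st$archs, plan, h2 = 1)
  expect_identical(res$selected$fb$h1, clones$fb$h1[, 1:72])
})

test_that("parent recycling draws valid, reproducible crossing pairs", {
  set.seed(36)
  pairs <- recycle_parents(72, 14)
  expect_equal(nrow(pairs), 14)
  expect_true(all(pairs$p1 != pairs$p2))
  expect_true(all(unlist(pairs) >= 1 & unlist(pairs) <= 72))

  set.seed(36)
  expect_identical(recycle_parents(72, 14), pairs)

  small <- recycle_parents(12, 14)   # repeats allowed across crosses
  expect_equal(nrow(small), 14)
  expect_true(all(small$p1 != small$p2))

  expect_error(recycle_parents(1), "at least 2")
})
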