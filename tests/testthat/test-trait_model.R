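test_that("correlated effect sampling fixes the MC-IC correlation", {
  # perfect-correlation limit duplicates the effect vector exactly
  e1 <- sample_correlated_effects(500, R = 1, seed = 1)
  expect_identical(e1$mc, e1$ic)

  # null correlation at n = 1000 stays inside the 99% interval
  e0 <- sample_correlated_effects(1000, R = 0, seed = 2)
  expect_lt(abs(stats::cor(e0$mc, e0$ic)), 0.09)

  # R = 0.9 at n = 1000: sample correlation in [0.88, 0.92] for >= 95% of seeds
  set.seed(3)
  inside <- vapply(1:50, function(i) {
    e <- sample_correlated_effects(1000, 0.9)
    r <- stats::cor(e$mc, e$ic)
    r >= 0.88 && r <= 0.92
  }, logical(1))
  expect_gte(mean(inside), 0.95)

  expect_error(sample_correlated_effects(10, 1.2), "strictly inside")
  expect_error(sample_correlated_effects(10, -1), "strictly inside")
})

test_that("architecture scaling fixes the founder GV scale without changing structure", {
  pop <- toy_founders(seed = 21, sites = 80, qtl = 40, n = 30)
  arch <- trait_architecture(pop, 0.5, seed = 7)
  dos <- dosage(founders_as_lines(pop))

  for (trait in c("MC", "IC")) {
    gv <- genetic_value(dos, arch, trait)
    expect_equal(mean(gv), 0, tolerance = 1e-9)
    expect_equal(stats::var(gv), 1, tolerance = 1e-9)
  }

  # correlation is affine-invariant: doubling all raw effects pre-scaling
  # yields bitwise-equal scaled GVs
  raw <- arch
  raw$scaled <- FALSE
  raw2 <- raw
  raw2$effects_mc <- 2 * raw$effects_mc
  raw2$effects_ic <- 2 * raw$effects_ic
  s1 <- scale_architecture(raw, pop)
  s2 <- scale_architecture(raw2, pop)
  expect_equal(genetic_value(dos, s1, "MC"), genetic_value(dos, s2, "MC"),
               tolerance = 1e-12)
  expect_equal(genetic_value(dos, s1, "IC"), genetic_value(dos, s2, "IC"),
               tolerance = 1e-12)
  expect_equal(stats::cor(genetic_value(dos, s1, "MC"),
                          genetic_value(dos, s1, "IC")),
               stats::cor(genetic_value(dos, raw, "MC"),
                          genetic_value(dos, raw, "IC")),
               tolerance = 1e-12)
})

test_that("realized founder GV correlation recovers the target R per crop", {
  for (R in c(0.3, 0.5, 0.9)) {
    for (crop in c("faba_bean", "triticale")) {
      pop <- study_founders(crop)
      set.seed(round(1000 * R) + nchar(crop))
      arch <- trait_architecture(pop, R)
      lines <- founders_as_lines(pop)
      r_hat <- stats::cor(gv_lines(lines, arch, "MC"),
                          gv_lines(lines, arch, "IC"))
      expect_lt(abs(r_hat - R), 0.1)
    }
  }
})

test_that("genetic values equal brute-force dosage-by-effect sums", {
  arch <- toy_arch()
  dos <- rbind(c(0, 1, 2, 0, 1),
               c(2, 2, 2, 2, 2),
               c(0, 0, 0, 0, 0),
               c(1, 0, 1, 2, 2))
  brute <- function(d, effects, intercept) {
    q <- c(1, 3, 5)
    s <- 0
    for (i in seq_along(q)) s <- s + d[q[i]] * effects[i]
    s - intercept
  }
  for (trait in c("MC", "IC")) {
    ef <- if (trait == "MC") arch$effects_mc else arch$effects_ic
    ic <- if (trait == "MC") arch$intercept_mc else arch$intercept_ic
    expect_equal(genetic_value(dos, arch, trait),
                 apply(dos, 1, brute, effects = ef, intercept = ic))
  }
  # additive-model extremes: all-alt minus all-ref difference is 2 * sum(effects)
  expect_equal(genetic_value(dos[2, ], arch, "MC") -
                 genetic_value(dos[3, ], arch, "MC"),
               2 * sum(arch$effects_mc))
  expect_error(genetic_value(c(0, 3, 1, 0, 0), arch, "MC"), "dosages")
  expect_error(genetic_value(c(0, 1, 0.5, 0, 0), arch, "MC"), "dosages")
})

test_that("gv_lines matches the dosage-matrix genetic_value path", {
  pop <- toy_founders(seed = 33, sites = 40, qtl = 15, n = 10)
  arch <- trait_architecture(pop, 0.3, seed = 9)
  lines <- founders_as_lines(pop)
  f1 <- cross_lines(lines, lines, c(1, 2, 3), c(4, 5, 6))
  for (trait in c("MC", "IC"))
    expect_equal(gv_lines(f1, arch, trait),
                 genetic_value(dosage(f1), arch, trait))
})

test_that("intercrop combination value is the exact component mean", {
  expect_identical(ic_combination_gv(2, 4), 3)
  expect_identical(ic_combination_gv(0, 0), 0)
  expect_identical(ic_combination_gv(-1, 1), 0)
  set.seed(14)
  a <- stats::rnorm(200)
  b <- stats::rnorm(200)
  expect_identical(ic_combination_gv(a, b), ic_combination_gv(b, a))
  expect_equal(ic_combination_gv(a, b), (a + b) / 2)
})

test_that("environmental variance follows the heritability identity", {
  cases <- list(c(0.5, 1), c(0.2, 4), c(0.9, 1 / 9), c(0.3, 7 / 3))
  for (cs in cases)
    expect_equal(env_variance(cs[1]), cs[2])
  expect_equal(env_variance(0.5, sigma_a2 = 3), 3)
  expect_error(env_variance(0), "strictly between")
  expect_error(env_variance(1), "strictly between")
})

test_that("phenotype noise matches the heritability and replication", {
  gv <- c(-1, 0, 2.5)
  expect_identical(sim_phenotype(gv, phenotype_settings(1, 1)), gv)

  set.seed(9)
  ph1 <- sim_phenotype(rep(2, 10000), phenotype_settings(0.5, r = 1))
  expect_lt(abs(stats::var(ph1) - 1), 0.05)  # sigma_e2 / r = 1

  ph4 <- sim_phenotype(rep(2, 10000), phenotype_settings(0.5, r = 4))
  expect_lt(abs(stats::var(ph4) / stats::var(ph1) - 0.25), 0.03)
})

test_that("single-plot phenotypes realize the intended heritability", {
  pop <- study_founders("faba_bean")
  set.seed(27)
  arch <- trait_architecture(pop, 0.5)
  gv <- gv_lines(founders_as_lines(pop), arch, "MC")
  settings <- phenotype_settings(0.5, r = 1)
  ph <- sim_phenotype(rep(gv, 100), settings)
  fit <- stats::lm(ph ~ rep(gv, 100))
  expect_lt(abs(stats::coef(fit)[2] - 1), 0.05)
  # total phenotypic variance = sigma_a2 / h2 = 2
  expect_lt(abs(stats::var(ph) - 2) / 2, 0.05)
})
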