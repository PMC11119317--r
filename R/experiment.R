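#' Run one full breeding cycle
#'
#' Executes crossing, line fixation (DH induction or EPR selfing), and the
#' PYT, AYT and EYT trial stages for both crops, under the modes implied by
#' the scheme's switch stage. Genetic progress is recorded at the EYT as the
#' mean and variance of the IC genetic values of the 36 combinations formed
#' from the 6 + 6 elite lines. The lines that entered the AYT (or, under the
#' alternative recycling rule, the EYT lines) become the next cycle's parent
#' pool.
#'
#' @param parents Named list of `line_pop`s (`fb`, `tr`): the cycle's parent
#'   pools.
#' @param archs Named list of `trait_arch`s (`fb`, `tr`).
#' @param config A [scheme_config()].
#' @param h2 Trial heritability for all phenotyped stages.
#' @return List with `parents` (next cycle's pools), `mean_ic_gv` and
#'   `var_ic_gv` (the EYT record), and `stage_records` (data frame with one
#'   row per stage: entries, replications, plots, entry-GV mean/variance).
#' @export
run_cycle <- function(parents, archs, config, h2) {
  stopifnot(inherits(config, "scheme_config"))
  plans <- config$stage_plans

  s0 <- lapply(parents, function(pool) {
    pr <- recycle_parents(n_lines(pool), config$n_crosses)
    cross_lines(pool, pool, pr$p1, pr$p2, family = seq_len(config$n_crosses))
  })

  fixed <- if (config$method == "DH") {
    lapply(s0, dh_production, lines_per_family = config$lines_per_family)
  } else {
    list(fb = epr_fixation(s0$fb, config, archs$fb),
         tr = epr_fixation(s0$tr, config, archs$tr))
  }

  pyt <- run_stage(fixed, archs, plans$pyt, h2)
  ayt <- run_stage(pyt$selected, archs, plans$ayt, h2)
  eyt <- run_stage(ayt$selected, archs, plans$eyt, h2)

  next_parents <- switch(config$recycle_from,
                         AYT = pyt$selected,   # the lines that entered the AYT
                         EYT = ayt$selected)   # the 6 + 6 EYT lines
  list(parents = next_parents,
       mean_ic_gv = eyt$record$mean_gv,
       var_ic_gv = eyt$record$var_gv,
       stage_records = rbind(pyt$record, ayt$record, eyt$record))
}

#' Simulate a breeding scheme over replicated multi-cycle runs
#'
#' The main entry point. Each replicate independently simulates founder
#' populations and correlated MC/IC trait architectures for the two crops,
#' samples 14 founder parents per crop, and runs `n_cycles` breeding cycles
#' of the configured scheme. Genetic progress is the mean IC genetic value
#' of the 36 EYT combinations per cycle; the IC genetic variance among those
#' combinations tracks the depletion of standing variation.
#'
#' Replicate seeds are derived deterministically as `base_seed + replicate`,
#' so results are reproducible and replicates are independent; for a fixed
#' `base_seed`, different scheme configurations see identical founder
#' realizations in matched replicates, which pairs scenario comparisons.
#'
#' @param method `"DH"` or `"EPR"`.
#' @param switch_stage `"PYT"`, `"AYT"` or `"EYT"`.
#' @param h2 Trait heritability (study grid: 0.3, 0.5, 0.9).
#' @param R MC-IC genetic correlation (study grid: 0.3, 0.5, 0.9).
#' @param n_cycles Breeding cycles per replicate (20 at full scale).
#' @param n_replicates Independent simulation replicates (100 at full
#'   scale).
#' @param base_seed Integer base seed.
#' @param genomes Named list of [genome_spec()]s (`faba_bean`,
#'   `triticale`); see [default_genomes()].
#' @param n_founders Founder lines per crop (100).
#' @param ... Further arguments passed to [scheme_config()].
#' @return An object of class `ic_sim`: the configuration plus
#'   `mean_ic_gv` and `var_ic_gv` (`n_replicates x n_cycles` matrices) and
#'   the per-cycle replicate means.
#' @export
simulate_scheme <- function(method = c("DH", "EPR"),
                            switch_stage = c("PYT", "AYT", "EYT"),
                            h2 = 0.5, R = 0.5,
                            n_cycles = 20, n_replicates = 100,
                            base_seed = 1,
                            genomes = default_genomes(),
                            n_founders = 100, ...) {
  method <- match.arg(method)
  switch_stage <- match.arg(switch_stage)
  stopifnot(n_cycles >= 1, n_replicates >= 1)
  config <- scheme_config(method, switch_stage, ...)

  mean_mat <- matrix(NA_real_, n_replicates, n_cycles)
  var_mat <- matrix(NA_real_, n_replicates, n_cycles)

  for (rep_i in seq_len(n_replicates)) {
    set.seed(base_seed + rep_i)
    founders <- list(fb = simulate_founders(genomes$faba_bean, n_founders),
                     tr = simulate_founders(genomes$triticale, n_founders))
    archs <- list(fb = trait_architecture(founders$fb, R),
                  tr = trait_architecture(founders$tr, R))
    parents <- lapply(founders, function(f)
      founders_as_lines(f, sample.int(f$n_founders,
                                      config$n_founder_parents)))
    for (cyc in seq_len(n_cycles)) {
      out <- run_cycle(parents, archs, config, h2)
      parents <- out$parents
      mean_mat[rep_i, cyc] <- out$mean_ic_gv
      var_mat[rep_i, cyc] <- out$var_ic_gv
    }
  }

  structure(
    list(method = method, switch_stage = switch_stage, h2 = h2, R = R,
         n_cycles = n_cycles, n_replicates = n_replicates,
         base_seed = base_seed, config = config,
         mean_ic_gv = mean_mat, var_ic_gv = var_mat,
         trajectory = colMeans(mean_mat),
         var_trajectory = colMeans(var_mat)),
    class = "ic_sim"
  )
}

#' Detect convergence of a genetic-progress trajectory
#'
#' Scans the replicate-averaged trajectory and reports the first cycle at
#' which the increment in mean IC genetic value over the previous cycle
#' drops below the threshold (first-hit rule; later re-divergence is not
#' considered).
#'
#' @param mean_trajectory Numeric vector of per-cycle replicate-mean IC
#'   genetic values (length >= 2).
#' @param threshold Convergence threshold on the cycle-to-cycle increment
#'   (0.005 on the founder genetic-standard-deviation scale).
#' @return An object of class `convergence_result`: `converged`, `cycle`
#'   (NA if not converged) and `threshold`.
#' @export
detect_convergence <- function(mean_trajectory, threshold = 0.005) {
  if (length(mean_trajectory) < 2)
    stop("trajectory must contain at least 2 cycles", call. = FALSE)
  inc <- abs(diff(mean_trajectory))
  hit <- which(inc < threshold)
  structure(
    list(converged = length(hit) > 0,
         cycle = if (length(hit) > 0) hit[1] + 1L else NA_integer_,
         threshold = threshold),
    class = "convergence_result"
  )
}

#' Simulate a grid of scenarios
#'
#' Runs [simulate_scheme()] over the cartesian product of methods,
#' heritabilities, genetic correlations and switch stages, with a shared
#' base seed so matched replicates see identical founder realizations.
#'
#' @param methods,h2s,Rs,switch_stages Vectors defining the grid (defaults:
#'   the full study grid, 2 x 3 x 3 x 3 = 54 scenarios).
#' @param n_cycles,n_replicates,base_seed,... Passed to
#'   [simulate_scheme()].
#' @return An object of class `ic_sim_grid`: a list of `ic_sim` results
#'   with the grid definition attached.
#' @export
simulate_grid <- function(methods = c("DH", "EPR"),
                          h2s = c(0.3, 0.5, 0.9),
                          Rs = c(0.3, 0.5, 0.9),
                          switch_stages = c("PYT", "AYT", "EYT"),
                          n_cycles = 20, n_replicates = 100,
                          base_seed = 1, ...) {
  grid <- expand.grid(method = methods, h2 = h2s, R = Rs,
                      switch_stage = switch_stages,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  runs <- lapply(seq_len(nrow(grid)), function(i) {
    simulate_scheme(method = grid$method[i],
                    switch_stage = grid$switch_stage[i],
                    h2 = grid$h2[i], R = grid$R[i],
                    n_cycles = n_cycles, n_replicates = n_replicates,
                    base_seed = base_seed, ...)
  })
  structure(list(runs = runs, grid = grid), class = "ic_sim_grid")
}

#' Summarize a scenario grid
#'
#' One row per scenario: the asymptotic mean IC genetic value (mean of the
#' final-cycle replicate means), the convergence cycle under the 0.005
#' increment rule, and the early-cycle gain rate (mean per-cycle gain over
#' the first three cycle transitions).
#'
#' @param grid An `ic_sim_grid` (or a list of `ic_sim` objects).
#' @param threshold Convergence threshold.
#' @return Data frame with columns `method`, `h2`, `R`, `switch_stage`,
#'   `asymptote`, `convergence_cycle`, `early_gain_rate`.
#' @export
summarize_grid <- function(grid, threshold = 0.005) {
  runs <- if (inherits(grid, "ic_sim_grid")) grid$runs else grid
  do.call(rbind, lapply(runs, function(x) {
    tr <- x$trajectory
    conv <- detect_convergence(tr, threshold)
    span <- min(4L, length(tr))
    data.frame(method = x$method, h2 = x$h2, R = x$R,
               switch_stage = x$switch_stage,
               asymptote = tr[length(tr)],
               convergence_cycle = conv$cycle,
               early_gain_rate = (tr[span] - tr[1]) / (span - 1))
  }))
}

#' Write trajectories to CSV
#'
#' Long-format export: one row per (scenario, replicate, cycle) with the
#' mean IC genetic value of the 36 EYT combinations and their genetic
#' variance.
#'
#' @param grid An `ic_sim_grid` or single `ic_sim`.
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_trajectories <- function(grid, file) {
  runs <- if (inherits(grid, "ic_sim_grid")) grid$runs else list(grid)
  rows <- do.call(rbind, lapply(runs, function(x) {
    scen <- paste(x$method, x$switch_stage, "h2", x$h2, "R", x$R, sep = "_")
    data.frame(scenario = scen,
               replicate = rep(seq_len(x$n_replicates), x$n_cycles),
               cycle = rep(seq_len(x$n_cycles), each = x$n_replicates),
               mean_ic_gv = as.vector(x$mean_ic_gv),
               genetic_variance = as.vector(x$var_ic_gv))
  }))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}

#' Read a scenario configuration file
#'
#' Reads a YAML (or JSON) scenario description with keys `method`,
#' `switch_stage`, `h2`, `R`, `n_cycles`, `n_replicates`, `base_seed` and
#' optional [scheme_config()] overrides, and runs it.
#'
#' @param file Path to the YAML/JSON configuration.
#' @return The `ic_sim` result of [simulate_scheme()].
#' @export
run_scenario_file <- function(file) {
  reader <- if (grepl("[.]json$", file)) "jsonlite" else "yaml"
  if (!requireNamespace(reader, quietly = TRUE))
    stop("package '", reader, "' is required to read this configuration",
         call. = FALSE)
  cfg <- if (reader == "jsonlite") jsonlite::fromJSON(file) else
    yaml::read_yaml(file)
  do.call(simulate_scheme, cfg)
}

#' @export
print.ic_sim <- function(x, ...) {
  cat("Intercrop breeding simulation:", x$method, "scheme, IC testing from",
      x$switch_stage, "\n")
  cat("  h2 =", x$h2, " R =", x$R, " ", x$n_replicates, "replicates x",
      x$n_cycles, "cycles\n")
  conv <- detect_convergence(x$trajectory)
  cat("  final mean IC GV:", round(x$trajectory[x$n_cycles], 3),
      " (cycle-1:", round(x$trajectory[1], 3), ")\n")
  cat("  converged:", if (conv$converged) paste("cycle", conv$cycle) else "no",
      "(threshold", conv$threshold, ")\n")
  invisible(x)
}

#' @export
summary.ic_sim <- function(object, threshold = 0.005, ...) {
  conv <- detect_convergence(object$trajectory, threshold)
  out <- list(
    scenario = data.frame(method = object$method,
                          switch_stage = object$switch_stage,
                          h2 = object$h2, R = object$R),
    trajectory = data.frame(
      cycle = seq_len(object$n_cycles),
      mean_ic_gv = object$trajectory,
      sd_across_replicates = apply(object$mean_ic_gv, 2, stats::sd),
      genetic_variance = object$var_trajectory),
    convergence = conv)
  class(out) <- "summary.ic_sim"
  out
}

#' @export
print.summary.ic_sim <- function(x, ...) {
  with(x$scenario,
       cat(sprintf("%s scheme, IC from %s, h2 = %s, R = %s\n",
                   method, switch_stage, h2, R)))
  print(x$trajectory, row.names = FALSE, digits = 4)
  cat("converged:",
      if (x$convergence$converged) paste("cycle", x$convergence$cycle) else "no",
      "\n")
  invisible(x)
}

#' @export
print.convergence_result <- function(x, ...) {
  if (x$converged)
    cat("converged at cycle", x$cycle, "(increment <", x$threshold, ")\n")
  else cat("not converged (threshold", x$threshold, ")\n")
  invisible(x)
}

#' Plot genetic-progress trajectories
#'
#' For a single simulation: the replicate-mean IC genetic value per cycle
#' with a band of +/- 1 standard deviation across replicates. For a grid:
#' one panel per (h2, R) combination with one line per switch stage,
#' faceting the scenario comparison the study design is built around.
#'
#' @param x An `ic_sim` or `ic_sim_grid`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.ic_sim <- function(x, ...) {
  cyc <- seq_len(x$n_cycles)
  s <- apply(x$mean_ic_gv, 2, stats::sd)
  graphics::plot(cyc, x$trajectory, type = "l", lwd = 2,
                 ylim = range(x$trajectory - s, x$trajectory + s),
                 xlab = "breeding cycle", ylab = "mean IC genetic value",
                 main = sprintf("%s, IC from %s (h2 = %s, R = %s)",
                                x$method, x$switch_stage, x$h2, x$R), ...)
  graphics::lines(cyc, x$trajectory - s, lty = 3)
  graphics::lines(cyc, x$trajectory + s, lty = 3)
  invisible(x)
}

#' @rdname plot.ic_sim
#' @export
plot.ic_sim_grid <- function(x, ...) {
  g <- x$grid
  cells <- unique(g[, c("method", "h2", "R")])
  stages <- unique(g$switch_stage)
  cols <- grDevices::hcl.colors(max(3, length(stages)), "Dark 3")
  old <- graphics::par(mfrow = grDevices::n2mfrow(nrow(cells)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(nrow(cells))) {
    sel <- which(g$method == cells$method[i] & g$h2 == cells$h2[i] &
                   g$R == cells$R[i])
    tr <- sapply(x$runs[sel], function(r) r$trajectory)
    graphics::matplot(tr, type = "l", lty = 1, lwd = 2,
                      col = cols[seq_along(sel)],
                      xlab = "cycle", ylab = "mean IC GV",
                      main = sprintf("%s h2=%s R=%s", cells$method[i],
                                     cells$h2[i], cells$R[i]), ...)
    graphics::legend("bottomright", legend = g$switch_stage[sel],
                     col = cols[seq_along(sel)], lty = 1, bty = "n",
                     cex = 0.8)
  }
  invisible(x)
}
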