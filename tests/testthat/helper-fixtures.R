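# Shared fixtures, all built in code. Expensive study-scale objects are
# memoized for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

toy_spec <- function(sites = 60, qtl = 20, label = "faba_bean") {
  genome_spec(label, n_segregating_sites = sites, n_qtl = qtl)
}

toy_founders <- function(seed = 42, sites = 60, qtl = 20, n = 20) {
  simulate_founders(toy_spec(sites, qtl), n_founders = n, seed = seed)
}

# fully heterozygous diploid: one haplotype all 1s, one all 0s
het_parent <- function(n_sites = 200, L = 1, map = NULL) {
  if (is.null(map)) map <- (seq_len(n_sites) - 0.5) / n_sites * L
  line_pop(matrix(1L, length(map), 1), matrix(0L, length(map), 1),
           map, L, "faba_bean")
}

# study-scale founder population for one crop (100 founders, 2000 sites)
study_founders <- function(crop = "faba_bean", seed = 101) {
  memo(paste0("founders_", crop, "_", seed), {
    spec <- default_genomes()[[crop]]
    simulate_founders(spec, 100, seed = seed)
  })
}

# study-scale two-crop state: founders, architectures, 14 S0 plants per crop
study_state <- function(R = 0.5, seed = 101) {
  memo(paste0("state_", R, "_", seed), {
    founders <- list(fb = study_founders("faba_bean", seed),
                     tr = study_founders("triticale", seed + 1))
    set.seed(seed)
    archs <- list(fb = trait_architecture(founders$fb, R),
                  tr = trait_architecture(founders$tr, R))
    parents <- lapply(founders, function(f)
      founders_as_lines(f, sample.int(f$n_founders, 14)))
    s0 <- lapply(parents, function(pool) {
      pr <- recycle_parents(n_lines(pool), 14)
      cross_lines(pool, pool, pr$p1, pr$p2, family = 1:14)
    })
    list(founders = founders, archs = archs, parents = parents, s0 = s0)
  })
}

# a hand-specified 5-site, 3-QTL toy architecture for oracle checks
toy_arch <- function(effects_mc = c(0.5, -1, 2),
                     effects_ic = c(1, 0.25, -0.5),
                     intercept_mc = 0.3, intercept_ic = -0.2) {
  structure(
    list(qtl_indices = c(1L, 3L, 5L),
         effects_mc = effects_mc, effects_ic = effects_ic,
         intercept_mc = intercept_mc, intercept_ic = intercept_ic,
         R = 0.5, sigma_a2 = 1, scaled = TRUE, crop_label = "faba_bean"),
    class = "trait_arch")
}

# the scaled scenario grid the qualitative-findings checks run on:
# 13 scenarios at h2 = 0.5, 20 replicates x 15 cycles, shared base seed
acceptance_grid <- function() {
  memo("acceptance_grid", {
    scen <- rbind(
      data.frame(method = "DH",  R = 0.3, sw = c("PYT", "EYT")),
      data.frame(method = "DH",  R = 0.9, sw = c("PYT", "AYT", "EYT")),
      data.frame(method = "EPR", R = 0.3, sw = c("PYT", "EYT")),
      data.frame(method = "EPR", R = 0.5, sw = c("PYT", "AYT", "EYT")),
      data.frame(method = "EPR", R = 0.9, sw = c("PYT", "AYT", "EYT")))
    runs <- lapply(seq_len(nrow(scen)), function(i)
      simulate_scheme(scen$method[i], scen$sw[i], h2 = 0.5, R = scen$R[i],
                      n_cycles = 15, n_replicates = 20, base_seed = 1))
    list(scen = scen, runs = runs, summary = summarize_grid(runs))
  })
}

grid_asymptote <- function(grid, method, R, sw) {
  s <- grid$summary
  s$asymptote[s$method == method & s$R == R & s$switch_stage == sw]
}
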