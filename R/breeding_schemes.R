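#' Configuration of one breeding scheme
#'
#' Fixes the structural design of a line-breeding program for the binary
#' intercropping system: the line-fixation method (doubled haploids or
#' ear/pod-to-row selfing with visual selection), and the selection stage at
#' which phenotyping switches from monocrop (MC) plots to intercrop (IC)
#' combinations. All schemes share an identical phenotyping budget:
#' 784 single-replicate plots at the preliminary yield trial (PYT),
#' 144 entries in 2 replicates at the advanced yield trial (AYT, 288 plots)
#' and 36 entries in 4 replicates at the elite yield trial (EYT, 144 plots).
#' Stages before the switch stage phenotype lines in monocrop; the switch
#' stage and later stages phenotype full-factorial line combinations; the
#' EYT is always an IC trial of 36 combinations from 6 + 6 lines.
#'
#' Per cycle, 14 crosses are made per crop. Under `"DH"` each S0 plant
#' yields `lines_per_family` homozygous DH0 lines without selection; under
#' `"EPR"` each S0 founds a nursery family that is selfed to S4 with visual
#' within-family selection (heritability `visual_h2`), and 8 percent of the
#' S4 nursery is advanced to the PYT. In MC-PYT scenarios 392 lines per crop
#' (28 per family) enter the PYT; when IC testing starts at the PYT, 28
#' lines per crop (2 per family) enter, giving 784 combinations.
#'
#' @param method `"DH"` or `"EPR"`.
#' @param switch_stage `"PYT"`, `"AYT"` or `"EYT"` - the first IC-tested
#'   stage.
#' @param n_crosses Crosses per crop per cycle (14).
#' @param n_founder_parents Founders sampled as cycle-1 parents (14).
#' @param epr_nursery_per_family Nursery plants per family per selfing
#'   generation (350; 8 percent of 350 x 14 = 392, of 350 = 28).
#' @param epr_select_per_generation Plants selfed onward per family at each
#'   intermediate nursery generation (default 35, i.e. the top 10 percent,
#'   each contributing `epr_nursery_per_family / epr_select_per_generation`
#'   selfed progeny).
#' @param visual_h2 Heritability of the visual selection trait during EPR
#'   fixation (0.1); visual selection acts on the MC trait.
#' @param recycle_from `"AYT"` (lines that enter the AYT are recycled as
#'   parents; default) or `"EYT"` (the 6 + 6 EYT lines are recycled).
#' @return An object of class `scheme_config`, including the derived
#'   `stage_plans` and `lines_per_family` (28 or 2).
#' @export
scheme_config <- function(method = c("DH", "EPR"),
                          switch_stage = c("PYT", "AYT", "EYT"),
                          n_crosses = 14,
                          n_founder_parents = 14,
                          epr_nursery_per_family = 350,
                          epr_select_per_generation = 35,
                          visual_h2 = 0.1,
                          recycle_from = c("AYT", "EYT")) {
  method <- match.arg(method)
  switch_stage <- match.arg(switch_stage)
  recycle_from <- match.arg(recycle_from)
  stopifnot(n_crosses >= 1, epr_nursery_per_family >= 1,
            epr_select_per_generation >= 1,
            epr_select_per_generation <= epr_nursery_per_family,
            visual_h2 > 0, visual_h2 <= 1)
  lines_per_family <- if (switch_stage == "PYT") 2L else 28L
  structure(
    list(method = method,
         switch_stage = switch_stage,
         n_crosses = as.integer(n_crosses),
         n_founder_parents = as.integer(n_founder_parents),
         epr_nursery_per_family = as.integer(epr_nursery_per_family),
         epr_select_per_generation = as.integer(epr_select_per_generation),
         epr_selfing_generations = 4L,
         visual_h2 = visual_h2,
         lines_per_family = lines_per_family,
         recycle_from = recycle_from,
         stage_plans = stage_plans(switch_stage, n_crosses * lines_per_family)),
    class = "scheme_config"
  )
}

#' Stage plans under the fixed plot budget
#'
#' Derives the per-stage design (testing mode, entries, replications,
#' selected lines per crop) implied by the switch stage. The plot budget is
#' invariant across schemes: PYT 784 x 1, AYT 144 x 2, EYT 36 x 4. In IC
#' mode the entry count is the full factorial (lines per crop squared); in
#' MC mode it is the lines per crop summed over both crops.
#'
#' @param switch_stage First IC-tested stage.
#' @param pyt_lines_per_crop Lines per crop entering the PYT (392 in MC
#'   scenarios, 28 when IC starts at the PYT).
#' @return Named list of `stage_plan` objects (`pyt`, `ayt`, `eyt`), each
#'   with fields `stage`, `mode`, `lines_per_crop`, `n_entries`, `r`,
#'   `n_select_per_crop` and `plots`.
#' @export
stage_plans <- function(switch_stage = c("PYT", "AYT", "EYT"),
                        pyt_lines_per_crop = NULL) {
  switch_stage <- match.arg(switch_stage)
  mode_of <- function(stage) {
    order <- c(PYT = 1L, AYT = 2L, EYT = 3L)
    if (order[[stage]] >= order[[switch_stage]]) "IC" else "MC"
  }
  pyt_mode <- mode_of("PYT")
  if (is.null(pyt_lines_per_crop))
    pyt_lines_per_crop <- if (pyt_mode == "IC") 28L else 392L
  plan <- function(stage, mode, lines_per_crop, r, n_select_per_crop) {
    n_entries <- if (mode == "IC") lines_per_crop^2 else 2L * lines_per_crop
    structure(list(stage = stage, mode = mode,
                   lines_per_crop = as.integer(lines_per_crop),
                   n_entries = as.integer(n_entries),
                   r = as.integer(r),
                   n_select_per_crop = as.integer(n_select_per_crop),
                   plots = as.integer(n_entries * r)),
              class = "stage_plan")
  }
  pyt_sel <- if (mode_of("AYT") == "IC") 12L else 72L
  list(
    pyt = plan("PYT", pyt_mode, pyt_lines_per_crop, 1L, pyt_sel),
    ayt = plan("AYT", mode_of("AYT"),
               lines_per_crop = pyt_sel, r = 2L, n_select_per_crop = 6L),
    eyt = plan("EYT", "IC", lines_per_crop = 6L, r = 4L,
               n_select_per_crop = 0L)
  )
}

#' Ear/pod-to-row line fixation with visual selection
#'
#' Selfs the 14 S0 plants of one crop to S4 through family nurseries. Each
#' S0 plant founds a family of `epr_nursery_per_family` S1 plants; at each
#' intermediate generation the family is ranked on a visual phenotype (MC
#' genetic value plus noise at heritability `visual_h2`, single plot) and
#' the top `epr_select_per_generation` plants are selfed onward, keeping the
#' nursery size constant. At S4 the top `lines_per_family` plants per family
#' are advanced to the PYT (8 percent of the nursery in total).
#'
#' @param s0 A `line_pop` of S0 plants, one family per plant.
#' @param config A [scheme_config()] with `method = "EPR"`.
#' @param arch The crop's `trait_arch` (visual selection uses the MC trait).
#' @return A `line_pop` of advanced S4 lines
#'   (`n_crosses * lines_per_family`).
#' @export
epr_fixation <- function(s0, config, arch) {
  stopifnot(inherits(s0, "line_pop"), inherits(config, "scheme_config"))
  n_fam <- n_lines(s0)
  nursery <- config$epr_nursery_per_family
  k_sel <- config$epr_select_per_generation
  per_parent <- nursery %/% k_sel
  if (per_parent * k_sel != nursery)
    stop("epr_nursery_per_family must be a multiple of ",
         "epr_select_per_generation", call. = FALSE)
  if (config$lines_per_family > nursery)
    stop("cannot advance more lines per family than the nursery holds",
         call. = FALSE)
  vis <- phenotype_settings(config$visual_h2, r = 1)

  # S0 -> S1: every S0 plant founds a full nursery family
  pop <- self_lines(s0, rep(seq_len(n_fam), each = nursery), "S1")

  # S1 -> S2 -> S3 -> S4 with within-family visual selection
  for (gen in c("S2", "S3", "S4")) {
    ph <- sim_phenotype(gv_lines(pop, arch, "MC"), vis)
    keep <- select_within_family(pop$family, ph, k_sel)
    pop <- self_lines(pop, rep(keep, each = per_parent), gen)
  }

  # S4 advancement: top `lines_per_family` per family on a final visual score
  ph <- sim_phenotype(gv_lines(pop, arch, "MC"), vis)
  adv <- select_within_family(pop$family, ph, config$lines_per_family)
  subset_lines(pop, adv)
}

# Top-k indices within each family, ranked on score; ties broken by stable
# input order.
select_within_family <- function(family, score, k) {
  idx <- split(seq_along(score), family)
  unlist(lapply(idx, function(i) {
    if (k > length(i))
      stop("within-family selection count exceeds family size", call. = FALSE)
    i[order(-score[i], i)][seq_len(k)]
  }), use.names = FALSE)
}

#' Doubled-haploid line production
#'
#' Each S0 plant yields `lines_per_family` fully homozygous DH0 lines (one
#' doubled gamete each), with no selection during induction.
#'
#' @param s0 A `line_pop` of S0 plants, one family per plant.
#' @param lines_per_family DH0 lines per S0 plant (28 in MC scenarios, 2
#'   when IC testing starts at the PYT).
#' @return A `line_pop` of DH0 lines.
#' @export
dh_production <- function(s0, lines_per_family) {
  stopifnot(inherits(s0, "line_pop"), lines_per_family >= 1)
  make_dh(s0, rep(seq_len(n_lines(s0)), each = lines_per_family))
}

#' Full factorial of intercrop combinations
#'
#' Pairs every faba bean line with every triticale line and attaches the
#' combination genetic value, the mean of the two components' IC genetic
#' values.
#'
#' @param gv_fb_ic,gv_tr_ic IC genetic values of the candidate lines of each
#'   crop.
#' @return Data frame with one row per combination: `fb`, `tr` (line
#'   indices) and `gv_ic`.
#' @export
form_ic_combinations <- function(gv_fb_ic, gv_tr_ic) {
  stopifnot(length(gv_fb_ic) >= 1, length(gv_tr_ic) >= 1)
  grid <- expand.grid(fb = seq_along(gv_fb_ic), tr = seq_along(gv_tr_ic),
                      KEEP.OUT.ATTRS = FALSE)
  grid$gv_ic <- ic_combination_gv(gv_fb_ic[grid$fb], gv_tr_ic[grid$tr])
  grid
}

#' Run one yield-trial stage
#'
#' Phenotypes the stage entries under the plan's replication and advances
#' the top lines per crop by truncation selection. In MC mode each line is
#' phenotyped on its own MC trait. In IC mode the full factorial of
#' combinations is phenotyped on the combination genetic value, and each
#' line is scored by the mean phenotype over all its tested partners (an
#' empirical general-mixing-ability score). The EYT records the 36
#' combinations without further within-cycle selection. Ties are broken by
#' stable entry order.
#'
#' @param lines Named list with `line_pop`s `fb` and `tr` holding the stage
#'   candidates of each crop.
#' @param archs Named list of `trait_arch`s (`fb`, `tr`).
#' @param plan A `stage_plan`.
#' @param h2 Trial heritability (1 = noiseless test mode).
#' @return List with `selected` (named list of advanced `line_pop`s; the
#'   candidates themselves for the EYT), `record` (one-row data frame:
#'   stage, mode, entries, replications, plots, mean and variance of the
#'   entry genetic values - combination IC values in IC mode, line MC
#'   values in MC mode) and `scores` (per-crop line scores used for
#'   selection).
#' @export
run_stage <- function(lines, archs, plan, h2) {
  stopifnot(inherits(plan, "stage_plan"),
            all(c("fb", "tr") %in% names(lines)))
  n_fb <- n_lines(lines$fb); n_tr <- n_lines(lines$tr)
  if (plan$mode == "IC") {
    if (n_fb != plan$lines_per_crop || n_tr != plan$lines_per_crop)
      stop(plan$stage, ": expected ", plan$lines_per_crop,
           " lines per crop, got ", n_fb, " + ", n_tr, call. = FALSE)
  } else {
    if (n_fb + n_tr != plan$n_entries)
      stop(plan$stage, ": expected ", plan$n_entries, " entries, got ",
           n_fb + n_tr, call. = FALSE)
  }
  settings <- phenotype_settings(h2, r = plan$r)

  if (plan$mode == "MC") {
    gv <- list(fb = gv_lines(lines$fb, archs$fb, "MC"),
               tr = gv_lines(lines$tr, archs$tr, "MC"))
    ph <- lapply(gv, sim_phenotype, settings = settings)
    scores <- ph
    entry_gv <- c(gv$fb, gv$tr)
  } else {
    gv_ic <- list(fb = gv_lines(lines$fb, archs$fb, "IC"),
                  tr = gv_lines(lines$tr, archs$tr, "IC"))
    combos <- form_ic_combinations(gv_ic$fb, gv_ic$tr)
    ph <- sim_phenotype(combos$gv_ic, settings)
    ph_mat <- matrix(ph, nrow = n_fb, ncol = n_tr)  # fb varies fastest
    scores <- list(fb = rowMeans(ph_mat), tr = colMeans(ph_mat))
    entry_gv <- combos$gv_ic
  }

  record <- data.frame(stage = plan$stage, mode = plan$mode,
                       n_entries = plan$n_entries, r = plan$r,
                       plots = plan$plots,
                       mean_gv = mean(entry_gv), var_gv = stats::var(entry_gv))

  if (plan$n_select_per_crop == 0L) {
    return(list(selected = lines, record = record, scores = scores))
  }
  top_k <- function(score) order(-score, seq_along(score))[seq_len(plan$n_select_per_crop)]
  selected <- list(fb = subset_lines(lines$fb, top_k(scores$fb)),
                   tr = subset_lines(lines$tr, top_k(scores$tr)))
  list(selected = selected, record = record, scores = scores)
}

#' Draw crossing pairs from a parent pool
#'
#' Samples `n_crosses` parent pairs at random from the pool, without
#' self-pairing; the same pair may recur across crosses. With a fixed RNG
#' state the pair list is reproducible.
#'
#' @param n_parents Size of the parent pool (>= 2).
#' @param n_crosses Number of pairs (14).
#' @return Data frame with columns `p1`, `p2` (pool indices, `p1 != p2`).
#' @export
recycle_parents <- function(n_parents, n_crosses = 14) {
  if (n_parents < 2)
    stop("need at least 2 distinct parents to make crosses", call. = FALSE)
  pairs <- t(vapply(seq_len(n_crosses),
                    function(i) sample.int(n_parents, 2L),
                    integer(2)))
  data.frame(p1 = pairs[, 1], p2 = pairs[, 2])
}

#' @export
print.scheme_config <- function(x, ...) {
  cat("Breeding scheme:", x$method, "- IC testing from the", x$switch_stage,
      "stage\n")
  cat("  ", x$n_crosses, " crosses/crop/cycle, ", x$lines_per_family,
      " lines per family to PYT\n", sep = "")
  for (p in x$stage_plans)
    cat(sprintf("  %s: %s mode, %d entries x %d rep(s) = %d plots, select %d/crop\n",
                p$stage, p$mode, p$n_entries, p$r, p$plots,
                p$n_select_per_crop))
  invisible(x)
}
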