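#' Sample correlated monocrop / intercrop QTL effects
#'
#' Draws per-QTL additive effect pairs from a bivariate standard normal
#' distribution with correlation `R`, so that the same loci govern both the
#' monocrop (MC) and intercrop (IC) trait but with distinct allele effects
#' whose correlation is fixed at `R`. Indirect selection of IC performance
#' through MC phenotypes requires `R > 0`.
#'
#' `R = 1` is accepted as a degenerate test mode in which the IC effects are
#' an exact copy of the MC effects; any other `|R| >= 1` is a configuration
#' error.
#'
#' @param n_qtl Number of QTL.
#' @param R Target genetic correlation, in (-1, 1) or exactly 1.
#' @param seed Optional integer seed.
#' @return List with numeric vectors `mc` and `ic` of length `n_qtl`.
#' @export
sample_correlated_effects <- function(n_qtl, R, seed = NULL) {
  stopifnot(n_qtl >= 1, is.numeric(R), length(R) == 1L)
  if (!is.null(seed)) set.seed(seed)
  if (R == 1) {
    e <- stats::rnorm(n_qtl)
    return(list(mc = e, ic = e))
  }
  if (abs(R) >= 1)
    stop("R must lie strictly inside (-1, 1); R = 1 only as exact duplication",
         call. = FALSE)
  z1 <- stats::rnorm(n_qtl)
  z2 <- stats::rnorm(n_qtl)
  list(mc = z1, ic = R * z1 + sqrt(1 - R^2) * z2)
}

#' Build the correlated-trait architecture for one crop
#'
#' Designates QTL among the founder population's segregating sites, samples
#' correlated MC/IC reference-allele effects, and rescales them so that the
#' founder genetic-value distribution has mean 0 and variance 1 for each
#' trait (see [scale_architecture()]). Each crop receives its own
#' independently sampled architecture with the same target correlation.
#'
#' @param pop A [simulate_founders()] population.
#' @param R Target MC-IC genetic correlation.
#' @param n_qtl Number of QTL; defaults to the genome spec value.
#' @param seed Optional integer seed.
#' @return An object of class `trait_arch`: `qtl_indices`, `effects_mc`,
#'   `effects_ic`, per-trait intercepts (so founder mean genetic value is 0),
#'   `R`, `sigma_a2 = 1`, and `crop_label`.
#' @export
trait_architecture <- function(pop, R, n_qtl = pop$genome_spec$n_qtl,
                               seed = NULL) {
  stopifnot(inherits(pop, "founder_pop"))
  if (!is.null(seed)) set.seed(seed)
  qtl <- designate_qtl(pop, n_qtl)
  eff <- sample_correlated_effects(n_qtl, R)
  arch <- structure(
    list(qtl_indices = qtl,
         effects_mc = eff$mc,
         effects_ic = eff$ic,
         intercept_mc = 0,
         intercept_ic = 0,
         R = R,
         sigma_a2 = 1,
         scaled = FALSE,
         crop_label = pop$genome_spec$crop_label),
    class = "trait_arch"
  )
  scale_architecture(arch, pop)
}

#' Rescale a trait architecture to the founder genetic-value scale
#'
#' Affinely rescales the MC and IC effect vectors (and intercepts) so that
#' the founder population's genetic values have mean 0 and variance 1 for
#' each trait. Correlations are affine-invariant, so the realized MC-IC
#' genetic correlation is unchanged. Fixing the founder additive variance at
#' 1 puts all downstream quantities (environmental variance via the
#' heritability identity, the 0.005 convergence threshold) on a common scale.
#'
#' @param arch A `trait_arch`.
#' @param pop The founder population the scale is anchored to.
#' @return The rescaled `trait_arch` (with `scaled = TRUE`).
#' @export
scale_architecture <- function(arch, pop) {
  stopifnot(inherits(arch, "trait_arch"), inherits(pop, "founder_pop"))
  dos <- 2L * pop$haplotypes[, arch$qtl_indices, drop = FALSE]
  for (trait in c("mc", "ic")) {
    ef <- arch[[paste0("effects_", trait)]]
    gv_raw <- as.numeric(dos %*% ef)
    s <- stats::sd(gv_raw)
    if (!is.finite(s) || s == 0)
      stop("zero founder genetic variance for the ", toupper(trait),
           " trait; degenerate architecture", call. = FALSE)
    arch[[paste0("effects_", trait)]] <- ef / s
    arch[[paste0("intercept_", trait)]] <- mean(gv_raw / s)
  }
  arch$scaled <- TRUE
  arch
}

#' Additive genetic values of diploid genotypes
#'
#' Computes the genetic value of each genotype as the sum of dosage-weighted
#' QTL effects, centred so that the founder population mean is 0 (on the
#' scaled architecture). Dosages must be 0, 1 or 2 copies of the reference
#' allele.
#'
#' @param dosage A dosage matrix (genotypes in rows) or a single dosage
#'   vector. Columns may cover all segregating sites (QTL columns are
#'   extracted via `arch$qtl_indices`) or exactly the QTL.
#' @param arch A `trait_arch`.
#' @param trait `"MC"` or `"IC"`.
#' @return Numeric vector of genetic values, one per genotype.
#' @export
genetic_value <- function(dosage, arch, trait = c("MC", "IC")) {
  trait <- tolower(match.arg(trait))
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1L)
  rng <- range(dosage)
  if (rng[1] < 0 || rng[2] > 2 || any(dosage != trunc(dosage)))
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  n_qtl <- length(arch$qtl_indices)
  if (ncol(dosage) != n_qtl) {
    if (ncol(dosage) < max(arch$qtl_indices))
      stop("dosage matrix does not cover all QTL sites", call. = FALSE)
    dosage <- dosage[, arch$qtl_indices, drop = FALSE]
  }
  ef <- arch[[paste0("effects_", trait)]]
  as.numeric(dosage %*% ef) - arch[[paste0("intercept_", trait)]]
}

#' Genetic value of an intercrop combination
#'
#' The genetic value of a legume x cereal line combination is the arithmetic
#' mean of the two components' IC genetic values.
#'
#' @param g_f IC genetic value(s) of the faba bean component.
#' @param g_t IC genetic value(s) of the triticale component.
#' @return `(g_f + g_t) / 2`, vectorized.
#' @export
ic_combination_gv <- function(g_f, g_t) {
  (g_f + g_t) / 2
}

#' Environmental variance implied by a heritability
#'
#' For narrow-sense heritability `h2` and founder additive variance
#' `sigma_a2`, the single-plot environmental variance is
#' `sigma_e2 = (1 - h2) * sigma_a2 / h2`.
#'
#' @param h2 Narrow-sense heritability, strictly between 0 and 1.
#' @param sigma_a2 Founder additive genetic variance (1 on the scaled
#'   architecture).
#' @return The environmental variance.
#' @export
env_variance <- function(h2, sigma_a2 = 1) {
  stopifnot(is.numeric(h2), length(h2) == 1L, sigma_a2 > 0)
  if (h2 <= 0 || h2 >= 1)
    stop("h2 must lie strictly between 0 and 1", call. = FALSE)
  (1 - h2) * sigma_a2 / h2
}

#' Phenotyping settings for one trial stage
#'
#' Bundles the heritability, plot replication and the resulting entry-mean
#' noise variance `sigma_e2 / r`. Replication is simulated as entry-mean
#' noise rather than `r` separate plot records; this is statistically
#' identical for selection on entry means. `h2 = 1` is accepted as the
#' noiseless limit (`sigma_e2 = 0`), used as a test mode.
#'
#' @param h2 Narrow-sense heritability in (0, 1], where 1 means noiseless.
#' @param r Number of plot replications at the stage (>= 1).
#' @param sigma_a2 Founder additive variance the heritability refers to.
#' @return An object of class `pheno_settings` with fields `h2`, `r`,
#'   `sigma_e2` and `noise_var = sigma_e2 / r`.
#' @export
phenotype_settings <- function(h2, r = 1, sigma_a2 = 1) {
  stopifnot(h2 > 0, h2 <= 1, r >= 1)
  sigma_e2 <- if (h2 == 1) 0 else env_variance(h2, sigma_a2)
  structure(list(h2 = h2, r = as.integer(r), sigma_e2 = sigma_e2,
                 noise_var = sigma_e2 / r),
            class = "pheno_settings")
}

#' Simulate entry-mean phenotypes
#'
#' Adds independent Gaussian environmental noise with variance
#' `sigma_e2 / r` to each genetic value. For an intercrop combination the
#' supplied genetic value is the combination mean ([ic_combination_gv()]);
#' the combination is phenotyped as a single entity with one noise draw.
#'
#' @param gv Numeric vector of genetic values.
#' @param settings A [phenotype_settings()].
#' @return Numeric vector of phenotypes.
#' @export
sim_phenotype <- function(gv, settings) {
  stopifnot(inherits(settings, "pheno_settings"))
  if (settings$noise_var == 0) return(gv)
  gv + stats::rnorm(length(gv), 0, sqrt(settings$noise_var))
}

#' Write a trait architecture as a table
#'
#' @param arch A `trait_arch`.
#' @param file CSV path; columns `qtl_site`, `effect_mc`, `effect_ic`.
#' @return `file`, invisibly.
#' @export
write_architecture <- function(arch, file) {
  utils::write.csv(
    data.frame(qtl_site = arch$qtl_indices,
               effect_mc = arch$effects_mc,
               effect_ic = arch$effects_ic),
    file, row.names = FALSE)
  invisible(file)
}

#' @export
print.trait_arch <- function(x, ...) {
  cat("Trait architecture (", x$crop_label, "): ",
      length(x$qtl_indices), " QTL, target MC-IC correlation ", x$R, "\n",
      sep = "")
  cat("  realized effect correlation:",
      round(stats::cor(x$effects_mc, x$effects_ic), 3), "\n")
  invisible(x)
}
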