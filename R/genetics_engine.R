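#' Populations of diploid lines
#'
#' Internal workhorse container: a population is a pair of haplotype
#' matrices (`h1`, `h2`) stored site-major - one segregating site per row,
#' one line per column, 0/1 alleles - as raw bytes, so that each line's
#' haplotype is a contiguous block for the meiosis engine. Alongside the
#' haplotypes the population carries the genetic map, crop label and
#' per-line family-of-origin ids. All Mendelian operations are vectorized
#' over lines.
#'
#' @param h1,h2 0/1 haplotype matrices of identical dimension (sites in
#'   rows, lines in columns); integer input is converted to the internal
#'   raw storage.
#' @param map Genetic map positions (Morgans), strictly increasing, one per
#'   site.
#' @param genetic_length Chromosome length in Morgans.
#' @param crop_label Crop identifier.
#' @param family Integer vector of family ids, one per line (recycled if
#'   length 1).
#' @param generation Generation tag (e.g. `"founder"`, `"S0"`, `"S4"`,
#'   `"DH0"`).
#' @return An object of class `line_pop`.
#' @export
line_pop <- function(h1, h2, map, genetic_length, crop_label,
                     family = rep(1L, ncol(h1)), generation = NA_character_) {
  stopifnot(is.matrix(h1), is.matrix(h2),
            all(dim(h1) == dim(h2)),
            length(map) == nrow(h1),
            !is.unsorted(map, strictly = TRUE),
            genetic_length > 0)
  h1 <- as_hap_matrix(h1)
  h2 <- as_hap_matrix(h2)
  if (length(family) == 1L) family <- rep(as.integer(family), ncol(h1))
  stopifnot(length(family) == ncol(h1))
  structure(
    list(h1 = h1, h2 = h2, map = as.numeric(map),
         genetic_length = genetic_length,
         crop_label = crop_label,
         family = as.integer(family),
         generation = generation),
    class = "line_pop"
  )
}

# raw site-major storage; accepts 0/1 integer/double/raw matrices
as_hap_matrix <- function(m) {
  if (is.raw(m)) return(m)
  r <- as.raw(m)
  dim(r) <- dim(m)
  r
}

# back to a plain 0/1 integer matrix
hap_int <- function(m) {
  i <- as.integer(m)
  dim(i) <- dim(m)
  i
}

#' Turn founders into a line population
#'
#' @param pop A [simulate_founders()] population.
#' @param idx Founder indices to include (default all).
#' @return A `line_pop` of fully homozygous founder lines.
#' @export
founders_as_lines <- function(pop, idx = seq_len(pop$n_founders)) {
  stopifnot(inherits(pop, "founder_pop"))
  hap <- t(pop$haplotypes[idx, , drop = FALSE])
  line_pop(hap, hap, pop$locus_positions, pop$genome_spec$genetic_length,
           pop$genome_spec$crop_label, family = seq_along(idx),
           generation = "founder")
}

#' Number of lines in a population
#' @param pop A `line_pop`.
#' @return Integer count.
#' @export
n_lines <- function(pop) ncol(pop$h1)

#' Allele dosage matrix
#' @param pop A `line_pop`.
#' @return Integer matrix of reference-allele dosages (0/1/2), one line per
#'   row, one site per column.
#' @export
dosage <- function(pop) t(hap_int(pop$h1) + hap_int(pop$h2))

#' Per-line heterozygosity
#' @param pop A `line_pop`.
#' @return Numeric vector: fraction of sites at which each line is
#'   heterozygous.
#' @export
heterozygosity <- function(pop) colMeans(pop$h1 != pop$h2)

#' Genetic values of a line population
#'
#' Fast path for whole populations: computes the additive genetic value of
#' every line directly from the site-major haplotype storage, without
#' forming the full dosage matrix. Equivalent to
#' `genetic_value(dosage(pop), arch, trait)`.
#'
#' @param pop A `line_pop`.
#' @param arch A `trait_arch`.
#' @param trait `"MC"` or `"IC"`.
#' @return Numeric vector of genetic values, one per line.
#' @export
gv_lines <- function(pop, arch, trait = c("MC", "IC")) {
  trait <- tolower(match.arg(trait))
  gv_lines_cpp(pop$h1, pop$h2, arch$qtl_indices,
               arch[[paste0("effects_", trait)]]) -
    arch[[paste0("intercept_", trait)]]
}

#' Sample gametes from lines
#'
#' Meiosis under the Haldane (no-interference) model: the crossover count is
#' Poisson(genetic length in Morgans), crossover positions are uniform on
#' the genetic map, the starting haplotype is chosen at random, and zero
#' crossovers are possible (no obligate chiasma).
#'
#' @param pop A `line_pop`.
#' @param parent_idx Integer vector of parent column indices; one gamete is
#'   produced per entry (repeat an index for several gametes from the same
#'   parent).
#' @return Integer 0/1 matrix, sites in rows, one gamete per column.
#' @export
make_gametes <- function(pop, parent_idx) {
  hap_int(gametes_raw(pop, parent_idx))
}

gametes_raw <- function(pop, parent_idx) {
  stopifnot(inherits(pop, "line_pop"), all(parent_idx >= 1),
            all(parent_idx <= n_lines(pop)))
  make_gametes_cpp(pop$h1, pop$h2, as.integer(parent_idx), pop$map,
                   pop$genetic_length)
}

#' Cross pairs of lines
#'
#' Each progeny is formed from one independent gamete of each parent.
#' Crossing is only defined within a crop; interspecific hybrids do not
#' exist in this system.
#'
#' @param pop1,pop2 `line_pop`s holding the two parents (may be the same
#'   object).
#' @param p1_idx,p2_idx Parallel vectors of parent column indices; progeny
#'   `i` has parents `p1_idx[i]` and `p2_idx[i]`.
#' @param family Family ids for the progeny (default: progeny index, i.e.
#'   one family per cross).
#' @return A `line_pop` of S0 progeny.
#' @export
cross_lines <- function(pop1, pop2, p1_idx, p2_idx,
                        family = seq_along(p1_idx)) {
  stopifnot(length(p1_idx) == length(p2_idx))
  if (!identical(pop1$crop_label, pop2$crop_label))
    stop("cannot cross lines of different crops", call. = FALSE)
  g1 <- gametes_raw(pop1, p1_idx)
  g2 <- gametes_raw(pop2, p2_idx)
  line_pop(g1, g2, pop1$map, pop1$genetic_length, pop1$crop_label,
           family = family, generation = "S0")
}

#' Self lines
#'
#' Each progeny is formed from two independent gametes of the same parent.
#'
#' @param pop A `line_pop`.
#' @param parent_idx Parent column index per progeny (repeat an index for a
#'   larger selfed family).
#' @param generation Generation tag for the progeny.
#' @return A `line_pop` of selfed progeny; family ids are inherited from
#'   the parents.
#' @export
self_lines <- function(pop, parent_idx, generation = NA_character_) {
  g1 <- gametes_raw(pop, parent_idx)
  g2 <- gametes_raw(pop, parent_idx)
  line_pop(g1, g2, pop$map, pop$genetic_length, pop$crop_label,
           family = pop$family[parent_idx], generation = generation)
}

#' Produce doubled-haploid lines
#'
#' Each DH line is a single independent gamete doubled into a fully
#' homozygous diploid; induction succeeds for every sampled gamete (no
#' selection during DH production).
#'
#' @param pop A `line_pop`.
#' @param parent_idx Parent column index per DH line (repeat an index for
#'   several DH lines from the same plant).
#' @return A `line_pop` of exactly homozygous DH0 lines; family ids are
#'   inherited.
#' @export
make_dh <- function(pop, parent_idx) {
  g <- gametes_raw(pop, parent_idx)
  line_pop(g, g, pop$map, pop$genetic_length, pop$crop_label,
           family = pop$family[parent_idx], generation = "DH0")
}

#' Subset a line population
#' @param pop A `line_pop`.
#' @param idx Line (column) indices to keep, in the given order.
#' @return The subset `line_pop`.
#' @export
subset_lines <- function(pop, idx) {
  line_pop(pop$h1[, idx, drop = FALSE], pop$h2[, idx, drop = FALSE],
           pop$map, pop$genetic_length, pop$crop_label,
           family = pop$family[idx], generation = pop$generation)
}

#' @export
print.line_pop <- function(x, ...) {
  cat("Line population:", n_lines(x), x$crop_label, "lines",
      if (!is.na(x$generation)) paste0("(", x$generation, ")"), "\n")
  cat("  families:", length(unique(x$family)),
      " mean heterozygosity:", signif(mean(heterozygosity(x)), 3), "\n")
  invisible(x)
}
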