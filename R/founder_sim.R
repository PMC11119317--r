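#' Genome specification for one component crop
#'
#' Describes the simulated genome of one crop: a single diploid chromosome
#' carrying a fixed number of biallelic segregating sites, of which a subset
#' will later be designated as QTL. Physical length is carried as metadata
#' only; all recombination operates on the genetic map (Morgans).
#'
#' @param crop_label Identifier for the crop (e.g. `"faba_bean"`,
#'   `"triticale"`).
#' @param physical_length Physical chromosome length in basepairs. Defaults
#'   follow a faba-bean-like genome collapsed to one chromosome; see
#'   [default_genomes()] for the paired cereal-legume defaults.
#' @param genetic_length Genetic map length in Morgans. Default 1.
#' @param n_segregating_sites Number of polymorphic biallelic sites to
#'   simulate. Default 2000, so that QTL designation samples a proper subset.
#' @param n_qtl Number of sites that act as QTL for the traits. Default 1000.
#'
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(crop_label,
                        physical_length = 1.1e9,
                        genetic_length = 1,
                        n_segregating_sites = 2000,
                        n_qtl = 1000) {
  stopifnot(is.character(crop_label), length(crop_label) == 1L,
            physical_length > 0, genetic_length > 0,
            n_segregating_sites >= 1, n_qtl >= 1)
  if (n_qtl > n_segregating_sites)
    stop("n_qtl must not exceed n_segregating_sites", call. = FALSE)
  structure(
    list(crop_label = crop_label,
         n_chromosomes = 1L,
         physical_length = physical_length,
         genetic_length = genetic_length,
         n_segregating_sites = as.integer(n_segregating_sites),
         n_qtl = as.integer(n_qtl)),
    class = "genome_spec"
  )
}

#' Default genome specifications for the cereal-legume pair
#'
#' The two hypothetical component crops: a faba-bean-like legume (single
#' diploid chromosome of 1.1e9 bp) and a triticale-like cereal (9.9e8 bp,
#' the average of the parental wheat and rye chromosome sizes). Each carries
#' 2000 segregating sites on a 1-Morgan map with 1000 QTL.
#'
#' @param n_segregating_sites,n_qtl,genetic_length Overrides applied to both
#'   crops.
#' @return Named list with elements `faba_bean` and `triticale`, each a
#'   [genome_spec()].
#' @export
default_genomes <- function(n_segregating_sites = 2000, n_qtl = 1000,
                            genetic_length = 1) {
  list(
    faba_bean = genome_spec("faba_bean", physical_length = 1.1e9,
                            genetic_length = genetic_length,
                            n_segregating_sites = n_segregating_sites,
                            n_qtl = n_qtl),
    triticale = genome_spec("triticale", physical_length = 9.9e8,
                            genetic_length = genetic_length,
                            n_segregating_sites = n_segregating_sites,
                            n_qtl = n_qtl)
  )
}

#' Simulate a founder population of homozygous lines
#'
#' Generates standing variation among fully homozygous (inbred) founders.
#' Per-site reference-allele frequencies are drawn from the U-shaped
#' Beta(1/2, 1/2) distribution, mimicking the allele-frequency spectrum of a
#' drift-dominated population history, and each founder is assigned a
#' homozygous genotype at every site (both haplotypes identical). Columns
#' that come out monomorphic are resampled so that every segregating site is
#' truly polymorphic among the founders. Genetic map positions are uniform
#' on `[0, genetic_length]`, strictly increasing.
#'
#' @param spec A [genome_spec()].
#' @param n_founders Number of founder lines. Default 100.
#' @param seed Optional integer seed; if supplied, `set.seed(seed)` is called
#'   so the population is reproducible.
#' @param max_sweeps Resampling budget for monomorphic columns; if any column
#'   is still monomorphic after this many sweeps the spec is considered
#'   degenerate and an error is thrown.
#'
#' @return An object of class `founder_pop`: a list with `haplotypes`
#'   (a `n_founders x n_segregating_sites` 0/1 matrix; founders are fully
#'   homozygous so a single haplotype row represents both chromosome copies),
#'   `locus_positions` (Morgans), `genome_spec`, and `n_founders`.
#' @export
simulate_founders <- function(spec, n_founders = 100, seed = NULL,
                              max_sweeps = 1000L) {
  stopifnot(inherits(spec, "genome_spec"), n_founders >= 2)
  if (!is.null(seed)) set.seed(seed)
  n_sites <- spec$n_segregating_sites

  draw_cols <- function(k) {
    p <- stats::rbeta(k, 0.5, 0.5)
    matrix(stats::rbinom(n_founders * k, 1L, rep(p, each = n_founders)),
           nrow = n_founders, ncol = k)
  }

  hap <- draw_cols(n_sites)
  for (sweep in seq_len(max_sweeps)) {
    cs <- colSums(hap)
    mono <- which(cs == 0L | cs == n_founders)
    if (length(mono) == 0L) break
    hap[, mono] <- draw_cols(length(mono))
  }
  cs <- colSums(hap)
  if (any(cs == 0L | cs == n_founders))
    stop("could not make all segregating sites polymorphic; ",
         "degenerate genome specification", call. = FALSE)

  pos <- sort(stats::runif(n_sites, 0, spec$genetic_length))
  # strictly increasing positions (ties have probability zero but guard anyway)
  while (anyDuplicated(pos)) pos <- sort(stats::runif(n_sites, 0, spec$genetic_length))

  structure(
    list(haplotypes = hap,
         locus_positions = pos,
         genome_spec = spec,
         n_founders = as.integer(n_founders)),
    class = "founder_pop"
  )
}

#' Designate QTL among the segregating sites
#'
#' Samples `n_qtl` distinct site indices uniformly without replacement from
#' the polymorphic sites of a founder population and returns them sorted.
#'
#' @param pop A [simulate_founders()] population.
#' @param n_qtl Number of QTL; defaults to the value in the genome spec.
#' @param seed Optional integer seed for reproducibility.
#' @return Sorted integer vector of site indices (1-based).
#' @export
designate_qtl <- function(pop, n_qtl = pop$genome_spec$n_qtl, seed = NULL) {
  stopifnot(inherits(pop, "founder_pop"))
  n_sites <- ncol(pop$haplotypes)
  if (n_qtl > n_sites)
    stop("n_qtl exceeds the number of polymorphic sites", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sort(sample.int(n_sites, n_qtl))
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Genome spec:", x$crop_label, "\n")
  cat("  1 diploid chromosome,", format(x$physical_length, big.mark = ","),
      "bp,", x$genetic_length, "Morgan\n")
  cat(" ", x$n_segregating_sites, "segregating sites,", x$n_qtl, "QTL\n")
  invisible(x)
}

#' @export
print.founder_pop <- function(x, ...) {
  cat("Founder population:", x$n_founders, "homozygous",
      x$genome_spec$crop_label, "lines,",
      ncol(x$haplotypes), "segregating sites\n")
  maf <- founder_allele_freq(x)
  maf <- pmin(maf, 1 - maf)
  cat("  mean minor-allele frequency:", round(mean(maf), 3), "\n")
  invisible(x)
}

#' Reference-allele frequencies among founders
#'
#' @param pop A founder population.
#' @return Numeric vector of per-site reference-allele (coded 1) frequencies.
#' @export
founder_allele_freq <- function(pop) {
  colMeans(pop$haplotypes)
}

#' Write / read a founder population as plain text
#'
#' Serializes the haplotype matrix (one row per founder haplotype, 0/1,
#' comma-separated; founders are homozygous so one row per founder is stored)
#' together with a locus-map sidecar (`<file>.map.csv`: site index, genetic
#' position in Morgans).
#'
#' @param pop A founder population.
#' @param file Path for the haplotype matrix CSV.
#' @return `write_founders()` returns `file` invisibly; `read_founders()`
#'   returns a `founder_pop` (the genome spec is reconstructed from the
#'   stored attributes header).
#' @export
write_founders <- function(pop, file) {
  map_file <- paste0(file, ".map.csv")
  spec <- pop$genome_spec
  header <- sprintf("# crop=%s physical_length=%.10g genetic_length=%.10g n_qtl=%d",
                    spec$crop_label, spec$physical_length, spec$genetic_length,
                    spec$n_qtl)
  con <- file(file, "w")
  writeLines(header, con)
  utils::write.table(pop$haplotypes, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  close(con)
  utils::write.csv(
    data.frame(site = seq_along(pop$locus_positions),
               position_morgan = pop$locus_positions),
    map_file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_founders
#' @export
read_founders <- function(file) {
  header <- readLines(file, n = 1L)
  kv <- regmatches(header, gregexpr("[a-z_]+=[^ ]+", header))[[1]]
  vals <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  hap <- as.matrix(utils::read.table(file, sep = ",", skip = 1L))
  dimnames(hap) <- NULL
  storage.mode(hap) <- "integer"
  map <- utils::read.csv(paste0(file, ".map.csv"))
  spec <- genome_spec(crop_label = unname(vals["crop"]),
                      physical_length = as.numeric(vals["physical_length"]),
                      genetic_length = as.numeric(vals["genetic_length"]),
                      n_segregating_sites = ncol(hap),
                      n_qtl = as.integer(vals["n_qtl"]))
  structure(
    list(haplotypes = hap,
         locus_positions = map$position_morgan,
         genome_spec = spec,
         n_founders = nrow(hap)),
    class = "founder_pop"
  )
}
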