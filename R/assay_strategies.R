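## The four observed-genotype datasets per replicate: re-sequencing,
## reference-panel genotyping, GWAS-chip genotyping (ascertainment-biased),
## and the error / missingness models applied to them.

#' Extract cohort allele calls
#'
#' Returns the two per-individual haplotype allele matrices (allele-1
#' calls) for the cohort, in cohort order.
#'
#' @param pop a [hap_population].
#' @param cohort a `cohort`.
#' @return List with matrices `a1`, `a2` (individuals x variants).
#' @export
cohort_alleles <- function(pop, cohort) {
  list(a1 = pop$haplotypes[cohort$hap_idx[, 1L], , drop = FALSE],
       a2 = pop$haplotypes[cohort$hap_idx[, 2L], , drop = FALSE])
}

#' Per-element base-call error mask
#'
#' @param dim dimensions of the call matrix.
#' @param epsilon per-allele flip probability.
#' @param seed random seed.
#' @return Logical matrix marking the calls to flip.
#' @export
error_mask <- function(dim, epsilon, seed = 1) {
  stopifnot(epsilon >= 0, epsilon < 0.5)
  set.seed(seed)
  matrix(runif(prod(dim)) < epsilon, dim[1L], dim[2L])
}

#' Flip allele calls where a mask is set
#'
#' The flip is element-wise, so it commutes with transposition:
#' `t(flip_calls(M, mask)) == flip_calls(t(M), t(mask))`.
#'
#' @param calls 0/1 allele-call matrix.
#' @param mask logical matrix of the same shape.
#' @return Perturbed call matrix.
#' @export
flip_calls <- function(calls, mask) {
  stopifnot(all(dim(calls) == dim(mask)))
  calls[mask] <- 1L - calls[mask]
  calls
}

#' Inject base-call errors
#'
#' Each allele call is swapped (ancestral <-> mutant) independently with
#' probability `epsilon`.
#'
#' @param calls 0/1 allele-call matrix (haplotypes x variants).
#' @param epsilon per-allele flip probability.
#' @param seed random seed.
#' @return Perturbed call matrix.
#' @export
inject_errors <- function(calls, epsilon, seed = 1) {
  if (epsilon == 0) return(calls)
  flip_calls(calls, error_mask(dim(calls), epsilon, seed))
}

#' Inject missing genotypes
#'
#' Each genotype is masked (set `NA`) independently with probability
#' `kappa`.
#'
#' @param geno genotype matrix (individuals x variants).
#' @param kappa per-genotype missingness probability.
#' @param seed random seed.
#' @return The matrix with masked entries `NA`; the logical mask is
#'   attached as attribute `"mask"`.
#' @export
inject_missing <- function(geno, kappa, seed = 1) {
  stopifnot(kappa >= 0, kappa < 1)
  if (kappa == 0) {
    attr(geno, "mask") <- matrix(FALSE, nrow(geno), ncol(geno))
    return(geno)
  }
  set.seed(seed)
  mask <- matrix(runif(length(geno)) < kappa, nrow(geno), ncol(geno))
  geno[mask] <- NA
  attr(geno, "mask") <- mask
  geno
}

#' Expected carrier indicators from hard genotype counts
#'
#' Orients each variant by the cohort's allele frequency (folded MAF) and
#' converts allele-1 counts to carrier indicators `E(G)` (1 if at least
#' one minor allele, 0 if common homozygote; `NA` propagates).
#'
#' @param g matrix of allele-1 counts (individuals x variants), `NA` for
#'   missing genotypes.
#' @return List with `eg`, `maf` (cohort folded MAF), `freq1`,
#'   `minor_is_1`.
#' @export
genotype_carriers <- function(g) {
  n_obs <- colSums(!is.na(g))
  f1 <- colSums(g, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  f1[n_obs == 0] <- NA_real_
  minor_is_1 <- !is.na(f1) & f1 <= 0.5
  eg <- matrix(NA_real_, nrow(g), ncol(g))
  if (any(minor_is_1))
    eg[, minor_is_1] <- (g[, minor_is_1, drop = FALSE] > 0) * 1
  if (any(!minor_is_1))
    eg[, !minor_is_1] <- (g[, !minor_is_1, drop = FALSE] < 2) * 1
  list(eg = eg, maf = pmin(f1, 1 - f1), freq1 = f1, minor_is_1 = minor_is_1)
}

# shared filter: polymorphic rare variants by cohort MAF (strict <)
.rare_in_cohort <- function(maf, maf_threshold) {
  !is.na(maf) & maf > 0 & maf < maf_threshold
}

#' Re-sequencing strategy
#'
#' Hard genotype calls at every gene variant with cohort MAF below the
#' threshold (strictly; the MAF is computed in the analysis cohort, not
#' the population).  Monomorphic variants carry no carrier information and
#' are excluded.
#'
#' @param g cohort allele-1 count matrix over *all* population variants
#'   (individuals x variants), possibly with errors injected.
#' @param pop the [hap_population] (for gene positions).
#' @param maf_threshold rare-variant MAF threshold (default 0.01).
#' @return List with `eg` (individuals x kept variants), `maf`, and `idx`
#'   (variant indices into `pop`).
#' @export
strategy_seq <- function(g, pop, maf_threshold = 0.01) {
  gi <- gene_sites(pop)
  gc <- genotype_carriers(g[, gi, drop = FALSE])
  keep <- .rare_in_cohort(gc$maf, maf_threshold)
  list(eg = gc$eg[, keep, drop = FALSE], maf = gc$maf[keep],
       idx = gi[keep])
}

#' Reference-panel genotyping strategy
#'
#' As [strategy_seq()], restricted to gene variants segregating
#' (polymorphic) among the reference panel's haplotypes.
#'
#' @param g cohort allele-1 count matrix over all population variants.
#' @param panel_alleles reference-panel allele matrix (2R haplotypes x all
#'   variants), possibly with errors injected.
#' @param pop the [hap_population].
#' @param maf_threshold rare-variant MAF threshold.
#' @return List with `eg`, `maf`, `idx`.
#' @export
strategy_gen <- function(g, panel_alleles, pop, maf_threshold = 0.01) {
  gi <- gene_sites(pop)
  pf <- colMeans(panel_alleles[, gi, drop = FALSE])
  in_panel <- pf > 0 & pf < 1
  gc <- genotype_carriers(g[, gi, drop = FALSE])
  keep <- .rare_in_cohort(gc$maf, maf_threshold) & in_panel
  list(eg = gc$eg[, keep, drop = FALSE], maf = gc$maf[keep],
       idx = gi[keep])
}

#' Ascertain a GWAS chip design
#'
#' Selects `n_gwas` variants across the whole simulated region at random
#' and without replacement (sequential weighted draws), with ascertainment
#' weight proportional to the population MAF `q_j` by default.  Under the
#' neutral site-frequency spectrum (density proportional to `1/q`) this
#' weighting reproduces the approximately uniform MAF distribution
#' characteristic of GWAS genotyping chips.
#'
#' @param pop a [hap_population].
#' @param n_gwas number of chip variants in the region (default 240,
#'   matching a 660k-chip genome-wide density of roughly 230 SNPs/Mb over
#'   1.05 Mb).
#' @param seed random seed.
#' @param ascertainment `"maf_weighted"` (weight proportional to `q_j`),
#'   `"uniform"`, or a numeric vector of per-variant weights.
#' @return An object of class `chip_design`: sorted variant indices `idx`
#'   and `n_gwas`.
#' @export
chip_ascertain <- function(pop, n_gwas = 240, seed = 1,
                           ascertainment = "maf_weighted") {
  V <- length(pop$positions)
  stopifnot(n_gwas >= 0, n_gwas <= V)
  w <- if (is.numeric(ascertainment)) {
    stopifnot(length(ascertainment) == V)
    ascertainment
  } else {
    switch(match.arg(ascertainment, c("maf_weighted", "uniform")),
           maf_weighted = pop$q,
           uniform = rep(1, V))
  }
  if (n_gwas == 0)
    return(structure(list(idx = integer(), n_gwas = 0L),
                     class = "chip_design"))
  set.seed(seed)
  idx <- sample.int(V, n_gwas, replace = FALSE, prob = w)
  structure(list(idx = sort(idx), n_gwas = as.integer(n_gwas)),
            class = "chip_design")
}

#' GWAS-chip strategy
#'
#' Hard genotype calls at the chip variants that fall inside the gene and
#' have cohort MAF below the threshold.  This set is typically near-empty;
#' downstream code treats a zero-variant unit as a skipped gene.
#'
#' @param g cohort allele-1 count matrix over all population variants.
#' @param chip a [chip_ascertain()] design.
#' @param pop the [hap_population].
#' @param maf_threshold rare-variant MAF threshold.
#' @return List with `eg`, `maf`, `idx`.
#' @export
strategy_gwas <- function(g, chip, pop, maf_threshold = 0.01) {
  gi <- intersect(gene_sites(pop), chip$idx)
  if (length(gi) == 0L)
    return(list(eg = matrix(NA_real_, nrow(g), 0L), maf = numeric(),
                idx = integer()))
  gc <- genotype_carriers(g[, gi, drop = FALSE])
  keep <- .rare_in_cohort(gc$maf, maf_threshold)
  list(eg = gc$eg[, keep, drop = FALSE], maf = gc$maf[keep],
       idx = gi[keep])
}
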