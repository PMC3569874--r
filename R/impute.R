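## Reference-panel imputation stand-in: haploid Li-Stephens HMM
## posteriors, diploid genotype posteriors, and the IMPUTE-style info
## score used to screen imputed variants.

#' Li-Stephens model parameters
#'
#' For a panel of `K` haplotypes: the switch probability between adjacent
#' typed sites at distance `d` bp is `1 - exp(-4 * Ne * rec * d / K)`, and
#' the per-site emission error is `lambda_ls = theta / (2 (theta + K))`
#' with `theta = 1 / sum_{k=1}^{K-1} 1/k` (Watterson-style mutation
#' parameter; for `K = 1` the harmonic sum is taken as 1).
#'
#' @param K panel haplotype count.
#' @param Ne effective population size.
#' @param rec per-base recombination rate.
#' @return List with `K`, `Ne`, `rec`, `theta`, `lambda_ls`.
#' @export
ls_params <- function(K, Ne = 10000, rec = 1e-8) {
  stopifnot(K >= 1, Ne > 0, rec >= 0)
  theta <- 1 / sum(1 / seq_len(max(K - 1L, 1L)))
  list(K = as.integer(K), Ne = Ne, rec = rec, theta = theta,
       lambda_ls = theta / (2 * (theta + K)))
}

#' Haploid Li-Stephens allele posteriors
#'
#' Runs the forward-backward algorithm for one target haplotype typed at a
#' scaffold of sites, copying from a phased reference panel, and returns
#' the posterior probability of allele 1 at the requested sites.  At
#' untyped sites the posterior is the state-weighted panel allele,
#' linearly interpolated in position between the flanking typed sites.
#'
#' @param target 0/1 allele calls of the target haplotype at the scaffold
#'   sites.
#' @param scaffold_idx indices (into the panel's site list) of the typed
#'   scaffold sites, increasing; must be a subset of the panel sites.
#' @param panel phased reference panel matrix (K haplotypes x V sites).
#' @param positions site positions (bp) for all V panel sites.
#' @param out_idx site indices at which posteriors are requested (default
#'   all sites).
#' @param params [ls_params()] for the panel.
#' @return Numeric vector of allele-1 posteriors at `out_idx`.
#' @export
ls_posteriors <- function(target, scaffold_idx, panel, positions,
                          out_idx = seq_along(positions),
                          params = ls_params(nrow(panel))) {
  panel <- as.matrix(panel)
  storage.mode(panel) <- "integer"
  if (nrow(panel) < 1L) stop("reference panel has no haplotypes")
  stopifnot(ncol(panel) == length(positions),
            length(target) == length(scaffold_idx))
  if (length(scaffold_idx) > 1 && any(diff(scaffold_idx) <= 0))
    stop("scaffold indices must be increasing")
  .ls_posteriors_cpp(panel, as.numeric(positions),
                     as.integer(scaffold_idx), as.integer(target),
                     as.integer(out_idx), params$Ne, params$rec,
                     params$lambda_ls)
}

#' Diploid genotype posteriors from two haploid allele posteriors
#'
#' Treats the two haplotypes of an individual as independently imputed:
#' for allele-1 posteriors `a` and `b`, the genotype posterior over
#' allele-1 counts is `p0 = (1-a)(1-b)`, `p1 = a(1-b) + b(1-a)`,
#' `p2 = a b`, which sums to 1 exactly.
#'
#' @param a,b numeric vectors of per-site allele-1 posteriors in `[0, 1]`.
#' @return Matrix with columns `p0`, `p1`, `p2`.
#' @export
genotype_posteriors <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0 & a <= 1),
            all(b >= 0 & b <= 1))
  cbind(p0 = (1 - a) * (1 - b), p1 = a * (1 - b) + b * (1 - a),
        p2 = a * b)
}

#' IMPUTE-style info score
#'
#' Ratio of observed to complete-data information about the allele
#' frequency.  With per-sample expected dosage `e_i = p1 + 2 p2` and
#' second moment `f_i = p1 + 4 p2`, and estimated frequency
#' `theta = sum(e_i) / (2N)`:
#' `info = 1 - sum(f_i - e_i^2) / (2 N theta (1 - theta))`,
#' clipped to `[0, 1]`.  Degenerate (hard-call) triples give info 1;
#' `theta` of exactly 0 or 1 gives info 0 by convention.
#'
#' @param p0,p1,p2 matrices (variants x samples) or vectors (one variant)
#'   of genotype posteriors; `NA` entries (missing triples) are excluded
#'   sample-wise.
#' @return Per-variant info scores.
#' @export
info_score <- function(p0, p1, p2) {
  if (is.null(dim(p0))) {
    p0 <- matrix(p0, nrow = 1L); p1 <- matrix(p1, nrow = 1L)
    p2 <- matrix(p2, nrow = 1L)
  }
  e <- p1 + 2 * p2
  f <- p1 + 4 * p2
  obs <- !is.na(e)
  n_obs <- rowSums(obs)
  if (any(n_obs == 0))
    stop("info_score: variant with no non-missing genotype triple")
  theta <- rowSums(e, na.rm = TRUE) / (2 * n_obs)
  num <- rowSums(f - e^2, na.rm = TRUE)
  denom <- 2 * n_obs * theta * (1 - theta)
  info <- ifelse(theta <= 0 | theta >= 1, 0, 1 - num / denom)
  pmin(pmax(info, 0), 1)
}

#' Filter imputed variants on MAF and info score
#'
#' Retains variants with expected cohort MAF strictly below
#' `maf_threshold`, expected MAF above zero (monomorphic imputations are
#' dropped), and info score of at least `info_threshold` (boundary
#' inclusive).
#'
#' @param maf per-variant expected minor allele frequencies.
#' @param info per-variant info scores.
#' @param maf_threshold rare-variant threshold (default 0.01, strict).
#' @param info_threshold info threshold (default 0.4, inclusive).
#' @return Logical vector of retained variants.
#' @export
filter_imputed <- function(maf, info, maf_threshold = 0.01,
                           info_threshold = 0.4) {
  stopifnot(length(maf) == length(info))
  !is.na(maf) & maf > 0 & maf < maf_threshold &
    !is.na(info) & info >= info_threshold
}

#' Impute a cohort from a GWAS scaffold up to a reference panel
#'
#' For each cohort haplotype (treated as pre-phased, as in the simulation
#' design), runs the haploid Li-Stephens model over the typed scaffold and
#' combines the two haplotype posteriors into diploid genotype posteriors
#' at every panel-polymorphic site in the gene.  Directly typed,
#' non-missing scaffold genotypes inside the gene are kept as hard-call
#' triples.  Genotype posteriors are then oriented to the minor allele
#' (by expected frequency), and per-variant expected MAF and info scores
#' computed.
#'
#' @param a1,a2 cohort haplotype allele matrices (individuals x all
#'   variants), possibly with errors injected.
#' @param panel_alleles reference panel matrix (2R haplotypes x all
#'   variants), possibly with errors injected.
#' @param pop the [hap_population] (positions and gene interval).
#' @param scaffold_idx variant indices of the typed scaffold (the chip).
#' @param missing_mask optional logical matrix (individuals x all
#'   variants): scaffold genotypes masked as missing are excluded from
#'   that individual's scaffold.
#' @param Ne,rec Li-Stephens rate parameters.
#' @return List with `eg` (individuals x kept sites, `1 - h` where `h` is
#'   the major-homozygote posterior), `maf`, `info`, `idx` (variant
#'   indices), plus the unoriented triples `p0`, `p1`, `p2`.
#' @export
impute_cohort <- function(a1, a2, panel_alleles, pop, scaffold_idx,
                          missing_mask = NULL, Ne = 10000, rec = 1e-8) {
  n <- nrow(a1)
  gi <- gene_sites(pop)
  pf <- colMeans(panel_alleles[, gi, drop = FALSE])
  out_idx <- gi[pf > 0 & pf < 1]  # panel-polymorphic gene sites
  if (length(out_idx) == 0L)
    return(list(eg = matrix(NA_real_, n, 0L), maf = numeric(),
                info = numeric(), idx = integer(),
                p0 = NULL, p1 = NULL, p2 = NULL))
  params <- ls_params(nrow(panel_alleles), Ne, rec)
  positions <- as.numeric(pop$positions)
  U <- length(out_idx)
  pan <- panel_alleles
  storage.mode(pan) <- "integer"
  t1 <- a1[, scaffold_idx, drop = FALSE]
  t2 <- a2[, scaffold_idx, drop = FALSE]
  if (!is.null(missing_mask)) {
    mm <- missing_mask[, scaffold_idx, drop = FALSE]
    t1[mm] <- NA
    t2[mm] <- NA
  }
  storage.mode(t1) <- "integer"
  storage.mode(t2) <- "integer"
  P1 <- .ls_impute_cpp(pan, positions, as.integer(scaffold_idx), t1,
                       as.integer(out_idx), params$Ne, params$rec,
                       params$lambda_ls)
  P2 <- .ls_impute_cpp(pan, positions, as.integer(scaffold_idx), t2,
                       as.integer(out_idx), params$Ne, params$rec,
                       params$lambda_ls)
  p0 <- (1 - P1) * (1 - P2)
  p1 <- P1 * (1 - P2) + P2 * (1 - P1)
  p2 <- P1 * P2

  # directly typed scaffold sites in the gene keep their hard calls
  typed <- match(intersect(scaffold_idx, out_idx), out_idx)
  for (u in typed) {
    j <- out_idx[u]
    g <- a1[, j] + a2[, j]
    obs <- if (is.null(missing_mask)) rep(TRUE, n) else !missing_mask[, j]
    p0[obs, u] <- (g[obs] == 0) * 1
    p1[obs, u] <- (g[obs] == 1) * 1
    p2[obs, u] <- (g[obs] == 2) * 1
  }

  e <- p1 + 2 * p2
  theta <- colMeans(e) / 2  # expected allele-1 frequency
  minor_is_1 <- theta <= 0.5
  h <- matrix(NA_real_, n, U)
  h[, minor_is_1] <- p0[, minor_is_1, drop = FALSE]
  h[, !minor_is_1] <- p2[, !minor_is_1, drop = FALSE]
  info <- info_score(t(p0), t(p1), t(p2))
  list(eg = 1 - h, maf = pmin(theta, 1 - theta), info = info,
       idx = out_idx, p0 = p0, p1 = p1, p2 = p2)
}

#' Convert imputed genotype posteriors to a GEN data set
#'
#' Packages imputed triples as [gen_data] (alleles coded `A` = allele 0,
#' `B` = allele 1) so simulator output can be written with [write_gen()]
#' and analysed through the same file-based interface as real data.
#'
#' @param imp result of [impute_cohort()].
#' @param pop the [hap_population].
#' @param chromosome chromosome label for the variant table.
#' @return A [gen_data] object (variants x samples).
#' @export
imputed_to_gen <- function(imp, pop, chromosome = "1") {
  k <- length(imp$idx)
  variants <- data.frame(
    snp_id = paste0(chromosome, ":", pop$positions[imp$idx]),
    rs_id = paste0("var", imp$idx),
    position = as.integer(pop$positions[imp$idx]),
    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  gen_data(variants, t(imp$p0), t(imp$p1), t(imp$p2))
}

#' Write a per-variant info-score sidecar table
#'
#' @param gen a [gen_data] object.
#' @param info per-variant info scores.
#' @param path output path (tab-separated: snp_id, rs_id, position, info).
#' @export
write_info <- function(gen, info, path) {
  stopifnot(inherits(gen, "gen_data"), length(info) == nrow(gen$variants))
  write.table(data.frame(snp_id = gen$variants$snp_id,
                         rs_id = gen$variants$rs_id,
                         position = gen$variants$position,
                         info = info),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
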