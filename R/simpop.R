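## Coalescent haplotype populations, causal-variant selection and the
## quantitative-trait model used by the power study.

.python_bin <- function() {
  py <- getOption("rvburden.python", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no python interpreter found; set options(rvburden.python = ...)")
  py
}

# Run the msprime batch simulator, writing n_rep replicates under
# <dir>/<tag>_<i>.{pos,hap}.  Returns the file prefixes.
.sim_haplotype_batch <- function(n_rep, n_hap, length_bp, mu, rec, Ne, seed,
                                 dir = tempfile("haps"), tag = "rep") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  script <- system.file("python", "sim_haplotypes.py", package = "rvburden",
                        mustWork = TRUE)
  prefix <- file.path(dir, tag)
  out <- system2(.python_bin(),
                 c(script, "--n-hap", n_hap, "--length",
                   sprintf("%.10g", length_bp), "--mu", sprintf("%.10g", mu),
                   "--rec", sprintf("%.10g", rec), "--ne",
                   sprintf("%.10g", Ne), "--seed", seed, "--reps", n_rep,
                   "--out-prefix", prefix),
                 stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("haplotype simulation failed:\n", paste(out, collapse = "\n"))
  paste0(prefix, "_", seq_len(n_rep))
}

# Read one replicate written by the batch simulator and delete its files.
.read_hap_files <- function(prefix, n_hap, cleanup = TRUE) {
  pos_file <- paste0(prefix, ".pos")
  hap_file <- paste0(prefix, ".hap")
  positions <- scan(pos_file, what = numeric(), quiet = TRUE)
  V <- length(positions)
  haplotypes <- if (V > 0) {
    con <- file(hap_file, "rb")
    on.exit(close(con), add = TRUE)
    raw <- readBin(con, what = "integer", n = n_hap * V, size = 1L,
                   signed = FALSE)
    matrix(raw, nrow = n_hap, ncol = V)  # file is site-major
  } else matrix(0L, n_hap, 0L)
  if (cleanup) unlink(c(pos_file, hap_file))
  list(haplotypes = haplotypes, positions = positions)
}

#' Construct a haplotype population from a 0/1 matrix
#'
#' Builds the internal population representation from a phased binary
#' haplotype matrix: drops non-segregating sites, checks strictly
#' increasing positions, computes folded population minor allele
#' frequencies `q_j` and records the central gene interval.
#'
#' @param haplotypes haplotype x variant matrix of 0/1 allele calls.
#' @param positions 1-based bp positions, strictly increasing.
#' @param length_bp total simulated region length (default 1,050,000).
#' @param gene_bp length of the central gene (default 50,000); the gene
#'   interval is the centred window `[(L - g)/2 + 1, (L - g)/2 + g]`.
#' @return An object of class `hap_population`: list with `haplotypes`,
#'   `positions`, `q` (folded MAF), `freq1` (frequency of allele 1),
#'   `minor_allele` (0 or 1), `gene_interval`, `n_hap`, `length_bp`.
#' @export
hap_population <- function(haplotypes, positions, length_bp = 1050000,
                           gene_bp = 50000) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  positions <- as.numeric(positions)
  stopifnot(ncol(haplotypes) == length(positions),
            all(haplotypes %in% c(0L, 1L)),
            gene_bp <= length_bp)
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(positions < 1 | positions > length_bp))
    stop("positions must lie in [1, length_bp]")
  f1 <- colMeans(haplotypes)
  seg <- f1 > 0 & f1 < 1
  haplotypes <- haplotypes[, seg, drop = FALSE]
  positions <- positions[seg]
  f1 <- f1[seg]
  gstart <- floor((length_bp - gene_bp) / 2) + 1
  structure(list(haplotypes = haplotypes, positions = positions,
                 q = pmin(f1, 1 - f1), freq1 = f1,
                 minor_allele = ifelse(f1 <= 0.5, 1L, 0L),
                 gene_interval = c(gstart, gstart + gene_bp - 1),
                 n_hap = nrow(haplotypes), length_bp = length_bp),
            class = "hap_population")
}

#' @export
print.hap_population <- function(x, ...) {
  cat(sprintf(
    "<hap_population> %d haplotypes, %d segregating sites over %g bp (gene %g-%g, %d sites)\n",
    x$n_hap, length(x$positions), x$length_bp, x$gene_interval[1],
    x$gene_interval[2], length(gene_sites(x))))
  invisible(x)
}

#' Indices of sites inside the gene interval
#'
#' @param pop a `hap_population`.
#' @return Integer vector of variant indices with
#'   `start <= position <= stop`.
#' @export
gene_sites <- function(pop) {
  which(pop$positions >= pop$gene_interval[1] &
        pop$positions <= pop$gene_interval[2])
}

#' Generate a coalescent haplotype population
#'
#' Simulates a population of phased haplotypes under the neutral coalescent
#' with recombination (via msprime), with a mutation rate per base per
#' generation, a uniform recombination rate, and a given effective
#' population size.  The default region is 1,050 kb with a central 50 kb
#' gene, leaving 500 kb of imputation buffer either side.  Deterministic
#' under a fixed seed.  If the realisation leaves no segregating site
#' inside the gene, it is regenerated with an incremented seed (with a
#' warning), up to `max_tries` attempts.
#'
#' @param n_hap number of haplotypes (default 40,000).
#' @param length_bp region length in bp (default 1,050,000).
#' @param gene_bp central gene length in bp (default 50,000).
#' @param mu per-base per-generation mutation rate (default 1e-8).
#' @param rec per-base per-generation recombination rate (default 1e-8,
#'   i.e. 1 cM/Mb).
#' @param Ne effective population size (default 10,000).
#' @param seed random seed.
#' @param max_tries regeneration attempts before giving up.
#' @return A [hap_population].
#' @export
generate_population <- function(n_hap = 40000, length_bp = 1050000,
                                gene_bp = 50000, mu = 1e-8, rec = 1e-8,
                                Ne = 10000, seed = 1, max_tries = 5L) {
  stopifnot(n_hap >= 2, length_bp > 0, mu >= 0, rec >= 0, Ne > 0)
  for (try in seq_len(max_tries)) {
    prefix <- .sim_haplotype_batch(1L, n_hap, length_bp, mu, rec, Ne,
                                   seed + try - 1L)
    hp <- .read_hap_files(prefix, n_hap)
    pop <- hap_population(hp$haplotypes, hp$positions, length_bp, gene_bp)
    if (length(gene_sites(pop)) >= 1L) return(pop)
    warning(sprintf(
      "no segregating site in the gene (seed %d); regenerating with seed %d",
      seed + try - 1L, seed + try))
  }
  stop(sprintf(
    "no segregating site in the gene after %d attempts (last seed %d)",
    max_tries, seed + max_tries - 1L))
}

#' Read / write the plain-text haplotype format
#'
#' Header line `#positions p1 p2 ...`, then one row of 0/1 characters per
#' haplotype (optionally whitespace-separated).
#'
#' @param path file path.
#' @param length_bp,gene_bp region geometry passed to [hap_population()].
#' @return For `read_haplotypes`, a [hap_population].
#' @export
read_haplotypes <- function(path, length_bp = 1050000, gene_bp = 50000) {
  lines <- readLines(path)
  if (length(lines) == 0 || !startsWith(lines[1], "#positions"))
    stop("haplotype file must start with a '#positions' header line")
  positions <- as.numeric(strsplit(trimws(sub("^#positions", "", lines[1])),
                                   "\\s+")[[1L]])
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  rows <- lapply(body, function(l)
    as.integer(strsplit(gsub("\\s+", "", l), "")[[1L]]))
  if (length(unique(lengths(rows))) > 1 ||
      (length(rows) && lengths(rows)[1] != length(positions)))
    stop("haplotype rows must all match the number of positions")
  hap_population(do.call(rbind, rows), positions, length_bp, gene_bp)
}

#' @rdname read_haplotypes
#' @param pop a `hap_population` to serialise.
#' @export
write_haplotypes <- function(pop, path) {
  stopifnot(inherits(pop, "hap_population"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#positions", paste(pop$positions, collapse = " ")), con)
  writeLines(apply(pop$haplotypes, 1L, paste, collapse = ""), con)
  invisible(path)
}

#' Select causal variants in the gene
#'
#' Draws variants uniformly at random, without replacement, from the gene
#' variants with population MAF `q_j < delta`, until the cumulative MAF of
#' the selected set first reaches `Q`.  Because every eligible variant has
#' `q_j < delta`, the achieved total satisfies
#' `Q <= Q_achieved < Q + delta`.
#'
#' @param pop a [hap_population].
#' @param delta maximum MAF of any individual causal variant.
#' @param Q target total MAF of the causal set.
#' @param seed random seed.
#' @return An object of class `causal_set`: `idx` (variant indices into
#'   `pop`, sorted), `q`, `delta`, `Q_target`, `Q_achieved`, and
#'   `sel_order` (the indices in selection order, for auditing the
#'   stopping rule).
#' @export
select_causal <- function(pop, delta, Q, seed = 1) {
  stopifnot(inherits(pop, "hap_population"), delta > 0, Q >= 0)
  empty <- structure(list(idx = integer(), q = numeric(), delta = delta,
                          Q_target = Q, Q_achieved = 0),
                     class = "causal_set")
  if (Q == 0) return(empty)
  gi <- gene_sites(pop)
  elig <- gi[pop$q[gi] < delta]
  if (sum(pop$q[elig]) < Q)
    stop(sprintf(
      "gene cannot support total causal MAF Q = %g (eligible MAF sums to %g)",
      Q, sum(pop$q[elig])))
  set.seed(seed)
  ord <- if (length(elig) == 1L) elig else sample(elig)
  cs <- cumsum(pop$q[ord])
  k <- which(cs >= Q)[1L]
  idx <- sort(ord[seq_len(k)])
  structure(list(idx = idx, q = pop$q[idx], delta = delta, Q_target = Q,
                 Q_achieved = cs[k], sel_order = ord[seq_len(k)]),
            class = "causal_set")
}

# Per-haplotype indicator of carrying a minor allele at any causal variant.
.hap_carrier <- function(pop, causal_idx) {
  if (length(causal_idx) == 0L) return(rep(FALSE, pop$n_hap))
  M <- pop$haplotypes[, causal_idx, drop = FALSE]
  minor <- pop$minor_allele[causal_idx]
  hits <- sweep(M, 2L, minor, FUN = "==")
  rowSums(hits) > 0
}

#' Empirical population carrier probability
#'
#' The probability that an individual carries at least one minor allele
#' across the causal variants, estimated empirically from the haplotype
#' matrix by pairing the population's haplotypes into `H/2` disjoint
#' individuals.  Computing it from the realised haplotypes (rather than
#' the linkage-free product formula `1 - prod(1 - q_j)^2`) respects LD
#' among the causal variants.
#'
#' @param pop a [hap_population].
#' @param causal a `causal_set` (or integer variant indices).
#' @return Carrier probability in `[0, 1]`.
#' @export
carrier_probability <- function(pop, causal) {
  idx <- if (inherits(causal, "causal_set")) causal$idx else causal
  if (length(idx) == 0L) return(0)
  hc <- .hap_carrier(pop, idx)
  H2 <- floor(pop$n_hap / 2)
  pair <- matrix(hc[seq_len(2 * H2)], nrow = 2L)
  mean(colSums(pair) > 0)
}

#' Residual trait variance for a target variance-explained fraction
#'
#' The trait model gives carriers (of at least one causal minor allele) a
#' unit shift in expected phenotype, so the genetic variance contributed by
#' carrier status is `p (1 - p)` for carrier probability `p`.  Setting the
#' fraction of total variance explained to `lambda` requires
#' `lambda = p(1-p) / (p(1-p) + sigma2)`, i.e.
#' `sigma2 = p (1 - p) (1 - lambda) / lambda`.
#'
#' @param p_carrier population carrier probability, in `(0, 1)`.
#' @param lambda causal contribution to trait variance, in `(0, 1]`.
#' @return Residual variance `sigma2`.
#' @export
residual_variance <- function(p_carrier, lambda) {
  stopifnot(p_carrier > 0, p_carrier < 1)
  if (lambda <= 0 || lambda > 1)
    stop("lambda must lie in (0, 1]")
  p_carrier * (1 - p_carrier) * (1 - lambda) / lambda
}

#' Sample an analysis cohort of diploid individuals
#'
#' Draws `2 * n_individuals` haplotypes from the population (without
#' replacement by default) and pairs them into individuals.
#'
#' @param pop a [hap_population].
#' @param n_individuals cohort size (default 2,000).
#' @param seed random seed.
#' @param replace sample haplotypes with replacement (used only for very
#'   large synthetic cohorts that exceed the population size).
#' @return An object of class `cohort`: `hap_idx` (n x 2 matrix of
#'   haplotype indices) and `n`.
#' @export
sample_cohort <- function(pop, n_individuals = 2000, seed = 1,
                          replace = FALSE) {
  stopifnot(inherits(pop, "hap_population"))
  if (!replace && 2 * n_individuals > pop$n_hap)
    stop("population too small for the requested cohort")
  set.seed(seed)
  idx <- sample(pop$n_hap, 2 * n_individuals, replace = replace)
  structure(list(hap_idx = matrix(idx, ncol = 2L), n = n_individuals),
            class = "cohort")
}

#' Sample a reference panel disjoint from the cohort
#'
#' Draws `2R` haplotypes from the remainder of the population (those not
#' used by the analysis cohort).
#'
#' @param pop a [hap_population].
#' @param cohort the analysis [sample_cohort()] whose haplotypes are
#'   excluded.
#' @param R number of reference individuals (`2R` haplotypes).
#' @param seed random seed.
#' @return Integer vector of `2R` haplotype indices with attribute `R`.
#' @export
sample_reference <- function(pop, cohort, R, seed = 1) {
  stopifnot(inherits(pop, "hap_population"), inherits(cohort, "cohort"),
            R >= 0)
  if (R == 0) return(structure(integer(), R = 0L))
  remainder <- setdiff(seq_len(pop$n_hap), as.vector(cohort$hap_idx))
  if (2 * R > length(remainder))
    stop("population remainder too small for the requested reference panel")
  set.seed(seed)
  structure(sample(remainder, 2 * R), R = as.integer(R))
}

#' Minor-allele counts over the causal set
#'
#' @param pop a [hap_population].
#' @param cohort a `cohort`.
#' @param causal a `causal_set`.
#' @return Integer vector `m_i`, the number of causal minor alleles carried
#'   by each individual.
#' @export
causal_allele_count <- function(pop, cohort, causal) {
  idx <- causal$idx
  if (length(idx) == 0L) return(rep(0L, cohort$n))
  M <- pop$haplotypes[, idx, drop = FALSE]
  minor <- pop$minor_allele[idx]
  hits <- sweep(M, 2L, minor, FUN = "==")
  cnt <- rowSums(hits)
  as.integer(cnt[cohort$hap_idx[, 1L]] + cnt[cohort$hap_idx[, 2L]])
}

#' Simulate quantitative phenotypes under the carrier-shift model
#'
#' `y_i ~ N(mu_i, sigma)` with `mu_i = 1` if the individual carries at
#' least one minor allele across the causal variants (`m_i > 0`) and 0
#' otherwise.  With an empty causal set all individuals are non-carriers
#' and the phenotype is pure noise.
#'
#' @param cohort a `cohort`.
#' @param pop the [hap_population] the cohort was drawn from.
#' @param causal a `causal_set` (may be empty).
#' @param sigma2 residual variance (`>= 0`; see [residual_variance()]).
#' @param seed random seed.
#' @return Numeric phenotype vector with attribute `m` (causal
#'   minor-allele counts).
#' @export
simulate_phenotype <- function(cohort, pop, causal, sigma2, seed = 1) {
  stopifnot(sigma2 >= 0)
  m <- causal_allele_count(pop, cohort, causal)
  set.seed(seed)
  y <- as.numeric(m > 0) + sqrt(sigma2) * rnorm(cohort$n)
  attr(y, "m") <- m
  y
}
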