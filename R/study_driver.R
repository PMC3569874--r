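## Orchestration: the four-strategy power study over replicated coalescent
## populations, and the genome-wide scan pipeline (genomic control,
## Bonferroni threshold, conditional analysis, plot-data export).

#' Define a simulation scenario
#'
#' Bundles the parameters of one power-study scenario.  Defaults are the
#' study conditions of the simulation design: a population of 40,000
#' haplotypes over 1,050 kb (central 50 kb gene), an analysis cohort of
#' 2,000 individuals, reference panels of 120/500/4,000 individuals,
#' causal variants with individual MAF below `delta` totalling MAF `Q`,
#' jointly explaining `lambda` of the trait variance, 500 replicates, and
#' a 240-variant GWAS chip across the region.
#'
#' @param delta maximum MAF of an individual causal variant (default 0.01).
#' @param Q total causal MAF target (default 0.05); `Q = 0` gives a null
#'   scenario with genotype-independent phenotypes.
#' @param lambda causal fraction of trait variance (default 0.05).
#' @param R reference-panel sizes, individuals (default `c(120, 500,
#'   4000)`).
#' @param epsilon per-allele base-call error probability (default 0).
#' @param kappa per-genotype missingness probability, applied to the
#'   panel-genotyping, chip and imputation strategies (default 0).
#' @param n_gwas chip variants in the region (default 240).
#' @param ascertainment chip ascertainment weighting (see
#'   [chip_ascertain()]).
#' @param n_hap,length_bp,gene_bp,mu,rec,Ne population parameters (see
#'   [generate_population()]).
#' @param n_individuals analysis-cohort size (default 2,000).
#' @param replicates number of replicates (default 500).
#' @param maf_threshold,info_threshold rare-variant and info filters.
#' @param alpha nominal significance level (default 0.05).
#' @param seed master seed; all per-replicate randomness derives from it.
#' @return An object of class `scenario`.
#' @export
scenario <- function(delta = 0.01, Q = 0.05, lambda = 0.05,
                     R = c(120, 500, 4000), epsilon = 0, kappa = 0,
                     n_gwas = 240, ascertainment = "maf_weighted",
                     n_hap = 40000, length_bp = 1050000, gene_bp = 50000,
                     mu = 1e-8, rec = 1e-8, Ne = 10000,
                     n_individuals = 2000, replicates = 500,
                     maf_threshold = 0.01, info_threshold = 0.4,
                     alpha = 0.05, seed = 1) {
  stopifnot(delta > 0, Q >= 0, lambda > 0, lambda <= 1,
            all(R >= 0), epsilon >= 0, epsilon < 0.5,
            kappa >= 0, kappa < 1, n_gwas >= 0, n_individuals >= 2,
            replicates >= 1, alpha > 0, alpha < 1, seed == floor(seed))
  structure(as.list(environment()), class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> delta=%g Q=%g lambda=%g R={%s} eps=%g kappa=%g n=%d reps=%d seed=%d\n",
    x$delta, x$Q, x$lambda, paste(x$R, collapse = ","), x$epsilon,
    x$kappa, x$n_individuals, x$replicates, x$seed))
  invisible(x)
}

#' Deterministic seed derivation
#'
#' Counter-scheme mapping of a master seed, replicate index and stream
#' number to a sub-seed below 2^31, so that every strategy within a
#' replicate shares the same population, cohort and phenotypes while the
#' streams for causal selection, sampling, errors, missingness and chip
#' ascertainment stay distinct.  Exact in double arithmetic.
#'
#' @param master master seed (integer).
#' @param rep replicate index.
#' @param stream stream number (0-1023).
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(master, rep, stream) {
  as.integer(((master %% 2147483647) * 100003 + rep * 1024 + stream) %%
               2147483646 + 1)
}

#' Read a key-value scenario configuration file
#'
#' Lines of `key = value` (or `key value`); `#` starts a comment; the `R`
#' key takes a comma-separated list.  Keys match the arguments of
#' [scenario()].
#'
#' @param path configuration file path.
#' @return A `scenario` object.
#' @export
read_scenario_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (l in lines) {
    parts <- strsplit(l, "\\s*=\\s*|\\s+")[[1L]]
    if (length(parts) < 2) stop("malformed config line: ", l)
    key <- parts[1L]
    val <- paste(parts[-1L], collapse = " ")
    if (key %in% c("R"))
      kv[[key]] <- as.numeric(strsplit(val, ",\\s*|\\s+")[[1L]])
    else if (key %in% c("ascertainment"))
      kv[[key]] <- val
    else
      kv[[key]] <- as.numeric(val)
  }
  unknown <- setdiff(names(kv), names(formals(scenario)))
  if (length(unknown))
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "))
  do.call(scenario, kv)
}

# burden-test p-value for one strategy's genotype set (gaussian trait)
.strategy_p <- function(strat, y) {
  if (length(strat$idx) == 0L)
    return(list(p = NA_real_, n = 0L))
  res <- burden_test(strat$eg, y, maf = strat$maf, family = "gaussian")
  list(p = res$p_value, n = res$n_variants)
}

#' Run one replicate of the power study
#'
#' Executes the replicate pipeline: generate (or accept) a population;
#' select causal variants and simulate phenotypes; sample the cohort and
#' reference panels; inject base-call errors (panel first, then cohort)
#' and genotype missingness (panel-genotyping, chip and imputation
#' strategies only); build the four observed-genotype datasets; and run
#' the quantitative-trait burden test on each.  A strategy with zero
#' qualifying rare variants yields a missing p-value.
#'
#' @param scen a [scenario()].
#' @param rep replicate index (drives seed derivation).
#' @param pop optional pre-generated [hap_population] for this replicate;
#'   generated from the derived seed when `NULL`.
#' @return Long-format data frame: one row per strategy (`SEQ`, `GWAS`,
#'   and `GEN`/`IMP` per panel size `R`), with columns `rep`, `strategy`,
#'   `R`, `p`, `n_variants`, `n_pop_rare`.
#' @export
run_replicate <- function(scen, rep = 1L, pop = NULL) {
  stopifnot(inherits(scen, "scenario"))
  s <- function(stream) derive_seed(scen$seed, rep, stream)
  if (is.null(pop))
    pop <- generate_population(scen$n_hap, scen$length_bp, scen$gene_bp,
                               scen$mu, scen$rec, scen$Ne, seed = s(0L))

  causal <- if (scen$Q > 0)
    select_causal(pop, scen$delta, scen$Q, seed = s(1L))
  else
    structure(list(idx = integer(), q = numeric(), delta = scen$delta,
                   Q_target = 0, Q_achieved = 0), class = "causal_set")
  cohort <- sample_cohort(pop, scen$n_individuals, seed = s(2L))
  sigma2 <- if (length(causal$idx)) {
    p_carr <- carrier_probability(pop, causal)
    residual_variance(p_carr, scen$lambda)
  } else 1
  y <- simulate_phenotype(cohort, pop, causal, sigma2, seed = s(3L))

  al <- cohort_alleles(pop, cohort)
  if (scen$epsilon > 0) {
    al$a1 <- inject_errors(al$a1, scen$epsilon, seed = s(4L))
    al$a2 <- inject_errors(al$a2, scen$epsilon, seed = s(5L))
  }
  g <- al$a1 + al$a2
  mask <- if (scen$kappa > 0) error_mask(dim(g), scen$kappa, seed = s(6L))
          else NULL
  g_miss <- g
  if (!is.null(mask)) g_miss[mask] <- NA
  chip <- chip_ascertain(pop, scen$n_gwas, seed = s(7L),
                         ascertainment = scen$ascertainment)

  gi <- gene_sites(pop)
  n_pop_rare <- sum(pop$q[gi] < scen$maf_threshold)

  row <- function(strategy, R, pr)
    data.frame(rep = rep, strategy = strategy, R = R, p = pr$p,
               n_variants = pr$n, n_pop_rare = n_pop_rare,
               stringsAsFactors = FALSE)

  out <- list(
    row("SEQ", NA_real_,
        .strategy_p(strategy_seq(g, pop, scen$maf_threshold), y)),
    row("GWAS", NA_real_,
        .strategy_p(strategy_gwas(g_miss, chip, pop, scen$maf_threshold),
                    y)))

  for (k in seq_along(scen$R)) {
    R <- scen$R[k]
    panel_idx <- sample_reference(pop, cohort, R, seed = s(8L + 3L * k))
    pan <- pop$haplotypes[panel_idx, , drop = FALSE]
    if (scen$epsilon > 0)
      pan <- inject_errors(pan, scen$epsilon, seed = s(9L + 3L * k))
    out[[length(out) + 1L]] <- row(
      "GEN", R,
      .strategy_p(strategy_gen(g_miss, pan, pop, scen$maf_threshold), y))

    imp <- impute_cohort(al$a1, al$a2, pan, pop, chip$idx,
                         missing_mask = mask, Ne = scen$Ne, rec = scen$rec)
    keep <- filter_imputed(imp$maf, imp$info, scen$maf_threshold,
                           scen$info_threshold)
    pr <- if (any(keep))
      .strategy_p(list(eg = imp$eg[, keep, drop = FALSE],
                       maf = imp$maf[keep], idx = imp$idx[keep]), y)
    else list(p = NA_real_, n = 0L)
    out[[length(out) + 1L]] <- row("IMP", R, pr)
  }
  do.call(rbind, out)
}

#' Run the full power study for a scenario
#'
#' Loops [run_replicate()] over the scenario's replicates.  Populations
#' are generated in batches (one simulator call per `chunk_size`
#' replicates) for speed; the batch seed derives deterministically from
#' the master seed and the chunk's first replicate, so output is
#' reproducible for a given `(seed, replicates, chunk_size)`.
#'
#' @param scen a [scenario()].
#' @param chunk_size replicates per population-simulation batch.
#' @param progress print per-chunk progress.
#' @return Data frame of per-replicate results (see [run_replicate()]).
#' @export
run_power_study <- function(scen, chunk_size = 25L, progress = FALSE) {
  stopifnot(inherits(scen, "scenario"))
  res <- vector("list", scen$replicates)
  reps <- seq_len(scen$replicates)
  for (start in seq(1L, scen$replicates, by = chunk_size)) {
    chunk <- reps[start:min(start + chunk_size - 1L, scen$replicates)]
    dir <- tempfile("popchunk")
    prefixes <- .sim_haplotype_batch(
      length(chunk), scen$n_hap, scen$length_bp, scen$mu, scen$rec,
      scen$Ne, seed = derive_seed(scen$seed, chunk[1L], 999L), dir = dir)
    for (j in seq_along(chunk)) {
      hp <- .read_hap_files(prefixes[j], scen$n_hap)
      pop <- hap_population(hp$haplotypes, hp$positions, scen$length_bp,
                            scen$gene_bp)
      res[[chunk[j]]] <- tryCatch(
        run_replicate(scen, rep = chunk[j], pop = pop),
        error = function(e) {
          warning(sprintf("replicate %d skipped: %s", chunk[j],
                          conditionMessage(e)))
          NULL
        })
    }
    unlink(dir, recursive = TRUE)
    if (progress)
      message(sprintf("replicates %d-%d done", chunk[1L],
                      chunk[length(chunk)]))
  }
  do.call(rbind, res)
}

#' Estimate power from replicate results
#'
#' Power is the fraction of replicates with `p < alpha`; replicates where
#' a strategy had no qualifying rare variants (missing p) count as
#' non-rejections.  The Monte-Carlo standard error
#' `sqrt(power (1 - power) / B)` is attached, together with mean
#' rare-variant counts.
#'
#' @param results data frame from [run_power_study()] /
#'   [run_replicate()].
#' @param alpha nominal significance level (default 0.05).
#' @return Data frame with one row per `(strategy, R)`: `power`,
#'   `replicates`, `mc_se`, `mean_n_variants`, `mean_n_pop_rare`.
#' @export
estimate_power <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) >= 1)
  key <- paste(results$strategy, ifelse(is.na(results$R), "", results$R))
  split_idx <- split(seq_len(nrow(results)), key)
  rows <- lapply(split_idx, function(ii) {
    rej <- !is.na(results$p[ii]) & results$p[ii] < alpha
    B <- length(ii)
    pw <- mean(rej)
    data.frame(strategy = results$strategy[ii[1L]], R = results$R[ii[1L]],
               power = pw, replicates = B,
               mc_se = sqrt(pw * (1 - pw) / B),
               mean_n_variants = mean(results$n_variants[ii]),
               mean_n_pop_rare = mean(results$n_pop_rare[ii]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$strategy, out$R), ]
  rownames(out) <- NULL
  class(out) <- c("power_table", "data.frame")
  out
}

#' Genomic-control inflation factor
#'
#' Median of the one-degree-of-freedom test statistics divided by the
#' median of the chi-square(1) distribution (0.4549); values near 1
#' indicate no inflation from population structure.
#'
#' @param stats vector of LRT statistics (non-finite entries dropped).
#' @return `lambda_gc`.
#' @export
genomic_control <- function(stats) {
  stats <- stats[is.finite(stats)]
  if (length(stats) == 0) stop("no finite statistics")
  median(stats) / qchisq(0.5, df = 1)
}

#' Genome-wide gene-based burden scan
#'
#' Runs the burden likelihood-ratio test for every gene in a boundary
#' file against a GEN/SAMPLE dataset: variants are assigned to genes by
#' position (1-based inclusive), filtered to polymorphic rare variants
#' (cohort expected MAF below `maf_threshold`) and, when info scores are
#' supplied, to well-imputed variants (`info >= info_threshold`).  The
#' scan reports the genomic-control inflation factor of the resulting
#' statistics and a Bonferroni significance threshold.  All genes in the
#' boundary file are assumed to lie on the chromosome of the GEN file.
#'
#' @param gen_file,sample_file,genes_file input paths (see [read_gen()],
#'   [read_sample()], [read_genes()]).
#' @param trait `"quantitative"` or `"binary"`.
#' @param phenotype_col phenotype column name; defaults to the first
#'   column typed `P` (quantitative) or `B` (binary) in the SAMPLE file.
#' @param covar_cols names of covariate columns (e.g. principal
#'   components) in the SAMPLE file.
#' @param maf_threshold rare-variant MAF threshold (default 0.01).
#' @param info optional per-variant info scores: a numeric vector aligned
#'   with the GEN file, or the path of a sidecar table with `snp_id` and
#'   `info` columns (see [write_info()]).
#' @param info_threshold info filter, boundary inclusive (default 0.4).
#' @param condition_snp optional `rs_id`/`snp_id` of a lead SNP whose
#'   expected minor-allele dosage is added as a covariate to both models.
#' @param bonferroni `"auto"` (number of genes actually tested) or a
#'   number of tests (e.g. 30000).
#' @param alpha family-wise significance level (default 0.05).
#' @return An object of class `scan_result`: `results` (per-gene rows,
#'   ordered by position), `lambda_gc`, `bonferroni_threshold`,
#'   `n_genes_tested`, `significant` (gene ids), `alpha`.
#' @export
run_scan <- function(gen_file, sample_file, genes_file,
                     trait = c("quantitative", "binary"),
                     phenotype_col = NULL, covar_cols = NULL,
                     maf_threshold = 0.01, info = NULL,
                     info_threshold = 0.4, condition_snp = NULL,
                     bonferroni = "auto", alpha = 0.05) {
  trait <- match.arg(trait)
  family <- if (trait == "quantitative") "gaussian" else "binomial"
  gd <- read_gen(gen_file)
  st <- read_sample(sample_file)
  genes <- read_genes(genes_file)
  if (nrow(genes) == 0) stop("no genes to test")
  if (gd$n_samples != nrow(st))
    stop("GEN and SAMPLE files disagree on sample count")

  types <- attr(st, "types")
  want <- if (trait == "quantitative") "P" else "B"
  if (is.null(phenotype_col)) {
    k <- which(types == want)[1L]
    if (is.na(k)) stop("no SAMPLE column of type ", want)
    phenotype_col <- names(st)[k]
  }
  y <- st[[phenotype_col]]
  covars <- if (!is.null(covar_cols)) as.matrix(st[, covar_cols,
                                                  drop = FALSE])
            else NULL

  cp <- carrier_posterior(gd)
  info_vec <- NULL
  if (!is.null(info)) {
    if (is.character(info) && length(info) == 1L) {
      si <- read.table(info, header = TRUE, stringsAsFactors = FALSE)
      info_vec <- si$info[match(gd$variants$snp_id, si$snp_id)]
    } else {
      stopifnot(length(info) == nrow(gd$variants))
      info_vec <- as.numeric(info)
    }
  }

  dosage <- NULL
  if (!is.null(condition_snp)) {
    j <- which(gd$variants$rs_id == condition_snp |
               gd$variants$snp_id == condition_snp)[1L]
    if (is.na(j)) stop("conditioning SNP not found: ", condition_snp)
    # expected minor-allele count from the posterior triple
    dosage <- if (cp$minor_is_b[j])
      gd$pab[j, ] + 2 * gd$pbb[j, ]
    else
      gd$pab[j, ] + 2 * gd$paa[j, ]
    dosage[!cp$observed[j, ]] <- NA_real_
  }

  genes <- genes[order(genes$chromosome, genes$start, genes$gene_id), ,
                 drop = FALSE]
  qualifies <- cp$polymorphic & !is.na(cp$maf) & cp$maf < maf_threshold
  if (!is.null(info_vec))
    qualifies <- qualifies & !is.na(info_vec) & info_vec >= info_threshold

  rows <- lapply(seq_len(nrow(genes)), function(gidx) {
    gr <- genes[gidx, ]
    j <- which(gd$variants$position >= gr$start &
               gd$variants$position <= gr$stop & qualifies)
    burden_test(eg = t(cp$eg[j, , drop = FALSE]), y = y,
                maf = cp$maf[j], covariates = covars, family = family,
                gene = gr, condition_dosage = dosage)
  })
  results <- do.call(rbind, rows)

  ok <- results$status == "ok" & is.finite(results$lrt_stat)
  lambda_gc <- if (any(ok)) genomic_control(results$lrt_stat[ok])
               else NA_real_
  n_tested <- sum(results$status %in% c("ok", "separation"))
  n_bonf <- if (identical(bonferroni, "auto")) max(n_tested, 1L)
            else as.numeric(bonferroni)
  threshold <- alpha / n_bonf
  sig <- results$gene[!is.na(results$p_value) &
                        results$p_value < threshold]
  structure(list(results = results, lambda_gc = lambda_gc,
                 bonferroni_threshold = threshold,
                 n_genes_tested = n_tested, significant = sig,
                 alpha = alpha),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf(
    "<scan_result> %d genes tested, lambda_GC = %.3f, threshold = %.3g, %d significant\n",
    x$n_genes_tested, x$lambda_gc, x$bonferroni_threshold,
    length(x$significant)))
  invisible(x)
}

#' Export Manhattan and QQ plot tables
#'
#' The Manhattan table places each gene at the midpoint of its transcript,
#' `floor((start + stop) / 2)`, with its observed `-log10` p-value and a
#' genome-wide-significance flag.  The QQ table pairs the ranked observed
#' `-log10` p-values with expected quantiles `-log10((i - 0.5) / n)`.
#'
#' @param scan a [run_scan()] result.
#' @return List with data frames `manhattan` and `qq`.
#' @export
export_plots_data <- function(scan) {
  stopifnot(inherits(scan, "scan_result"))
  r <- scan$results
  manhattan <- data.frame(
    gene = r$gene, chr = r$chr,
    midpoint = floor((r$start + r$stop) / 2),
    neg_log10_p = -log10(r$p_value),
    significant = !is.na(r$p_value) &
      r$p_value < scan$bonferroni_threshold,
    stringsAsFactors = FALSE)
  p <- sort(r$p_value[!is.na(r$p_value)])
  n <- length(p)
  qq <- data.frame(expected = -log10((seq_len(n) - 0.5) / n),
                   observed = -log10(p))
  list(manhattan = manhattan, qq = qq)
}
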