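test_that("power estimation counts missing p-values as non-rejections", {
  res <- data.frame(rep = 1:6, strategy = "SEQ", R = NA_real_,
                    p = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.001),
                    n_variants = 5L, n_pop_rare = 10L)
  pt <- estimate_power(res)
  expect_equal(pt$power, 1)
  expect_equal(pt$mc_se, 0)

  res$p <- NA_real_
  expect_equal(estimate_power(res)$power, 0)

  res$p <- c(0.01, 0.2, NA, 0.03, 0.9, NA)
  pt <- estimate_power(res)
  expect_equal(pt$power, 2 / 6)
  expect_equal(pt$mc_se, sqrt((2 / 6) * (4 / 6) / 6))
  expect_equal(pt$replicates, 6L)
})

test_that("genomic control rescales by the chi-square(1) median", {
  expect_equal(genomic_control(rep(qchisq(0.5, 1), 5)), 1)
  set.seed(77)
  s <- rchisq(1e5, df = 1)
  expect_equal(genomic_control(s), 1, tolerance = 0.01)
  expect_equal(genomic_control(2 * s), 2 * genomic_control(s))
  expect_error(genomic_control(rep(NA_real_, 3)), "no finite")
})

test_that("replicate runs are reproducible under the master-seed scheme", {
  scen <- scenario(n_hap = 500, n_individuals = 80, R = c(20),
                   n_gwas = 60, replicates = 2, lambda = 0.2,
                   Q = 0.04, delta = 0.02, seed = 99)
  r1 <- run_replicate(scen, rep = 1)
  r2 <- run_replicate(scen, rep = 1)
  expect_identical(r1, r2)
  expect_setequal(r1$strategy, c("SEQ", "GWAS", "GEN", "IMP"))
  # seed streams are distinct and in range
  s <- sapply(0:20, function(k) derive_seed(99, 1, k))
  expect_equal(length(unique(s)), 21L)
  expect_true(all(s >= 1 & s < 2^31))
  expect_false(derive_seed(99, 1, 0) == derive_seed(99, 2, 0))
})

test_that("scenario configuration files round-trip", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c("delta = 0.005", "Q = 0.02", "lambda = 0.05",
               "R = 120, 500, 4000", "epsilon = 0.001", "kappa = 0.01",
               "n_gwas = 240", "n_individuals = 2000",
               "replicates = 500", "seed = 7",
               "# a comment", ""), f)
  scen <- read_scenario_config(f)
  expect_s3_class(scen, "scenario")
  expect_equal(scen$delta, 0.005)
  expect_equal(scen$R, c(120, 500, 4000))
  expect_equal(scen$kappa, 0.01)
  expect_equal(scen$seed, 7)
  writeLines("not_a_key = 3", f)
  expect_error(read_scenario_config(f), "unknown scenario key")
})

# Build a file-based scan fixture: `n_genes` genes of hard-called rare
# variants; gene `assoc` (if any) drives the quantitative phenotype.
make_scan_fixture <- function(n_genes, n_samples, vars_per_gene = 5L,
                              assoc = NULL, beta = 1, seed = 1,
                              dir = tempfile("scan")) {
  dir.create(dir)
  set.seed(seed)
  counts <- list(); positions <- integer(); gene_rows <- character()
  x_assoc <- rep(0, n_samples)
  for (g in seq_len(n_genes)) {
    base <- (g - 1L) * 10000L
    pos <- base + sort(sample.int(9000, vars_per_gene))
    cm <- matrix(rbinom(vars_per_gene * n_samples, 2,
                        runif(vars_per_gene, 0.002, 0.008)),
                 vars_per_gene, n_samples)
    if (!is.null(assoc) && g == assoc)
      x_assoc <- colMeans(cm > 0)
    counts[[g]] <- cm
    positions <- c(positions, pos)
    gene_rows <- c(gene_rows,
                   sprintf("1 %d %d GENE%03d", base + 1L, base + 9500L, g))
  }
  y <- beta * x_assoc + rnorm(n_samples)
  gen_path <- file.path(dir, "data.gen")
  write_gen_fixture(do.call(rbind, counts), positions, gen_path)
  sample_path <- file.path(dir, "data.sample")
  write_sample(data.frame(ID_1 = paste0("i", seq_len(n_samples)),
                          ID_2 = paste0("i", seq_len(n_samples)),
                          missing = 0, pheno = y),
               sample_path, types = c("0", "0", "0", "P"))
  genes_path <- file.path(dir, "genes.txt")
  writeLines(gene_rows, genes_path)
  list(gen = gen_path, sample = sample_path, genes = genes_path,
       dir = dir)
}

test_that("a planted associated gene attains the scan minimum p-value", {
  fx <- make_scan_fixture(n_genes = 15, n_samples = 400, assoc = 7,
                          beta = 6, seed = 5)
  scan <- run_scan(fx$gen, fx$sample, fx$genes, trait = "quantitative",
                   maf_threshold = 0.05)
  res <- scan$results
  expect_equal(nrow(res), 15L)
  expect_equal(res$gene[which.min(res$p_value)], "GENE007")
  expect_lt(res$p_value[res$gene == "GENE007"], 0.001)

  # scan output is invariant to gene-file ordering
  shuffled <- file.path(fx$dir, "genes_shuffled.txt")
  set.seed(2)
  writeLines(sample(readLines(fx$genes)), shuffled)
  scan2 <- run_scan(fx$gen, fx$sample, fx$genes, trait = "quantitative",
                    maf_threshold = 0.05)
  scan3 <- run_scan(fx$gen, fx$sample, shuffled, trait = "quantitative",
                    maf_threshold = 0.05)
  expect_equal(scan3$results, scan2$results)
  unlink(fx$dir, recursive = TRUE)
})

test_that("a null scan shows no genomic inflation and a calibrated QQ", {
  fx <- make_scan_fixture(n_genes = 800, n_samples = 250, assoc = NULL,
                          seed = 11)
  scan <- run_scan(fx$gen, fx$sample, fx$genes, trait = "quantitative",
                   maf_threshold = 0.05)
  expect_true(scan$lambda_gc > 0.8 && scan$lambda_gc < 1.2)
  expect_equal(scan$bonferroni_threshold, 0.05 / scan$n_genes_tested)

  # Bonferroni override for a genome-wide 30,000-gene family
  scan30 <- run_scan(fx$gen, fx$sample, fx$genes, trait = "quantitative",
                     maf_threshold = 0.05, bonferroni = 30000)
  expect_equal(signif(scan30$bonferroni_threshold, 2), 1.7e-6)

  # QQ points stay within a Kolmogorov-Smirnov band at level 0.01
  pd <- export_plots_data(scan)
  pv <- sort(scan$results$p_value[!is.na(scan$results$p_value)])
  n <- length(pv)
  ks_band <- sqrt(log(2 / 0.01) / (2 * n))
  ecdf_dev <- max(abs(seq_len(n) / n - pv))
  expect_lt(ecdf_dev, ks_band + 1 / n)
  expect_equal(pd$qq$expected, -log10((seq_len(n) - 0.5) / n))
  expect_equal(pd$qq$observed, -log10(pv))
  unlink(fx$dir, recursive = TRUE)
})

test_that("plot-data export places genes at transcript midpoints", {
  res <- data.frame(gene = c("A", "B"), chr = "1", start = c(1L, 100L),
                    stop = c(11L, 200L), n_variants = 2L, mean_maf = 0.1,
                    beta = 0, se = 1, or_per_allele = NA, or_lower = NA,
                    or_upper = NA, lrt_stat = c(0.45, 0.45),
                    p_value = c(0.5, 0.5), status = "ok")
  scan <- structure(list(results = res, lambda_gc = 1,
                         bonferroni_threshold = 0.025,
                         n_genes_tested = 2L, significant = character(),
                         alpha = 0.05),
                    class = "scan_result")
  pd <- export_plots_data(scan)
  expect_equal(pd$manhattan$midpoint, c(6, 150))
  expect_equal(pd$qq$expected[1], -log10(0.25))
  expect_false(any(pd$manhattan$significant))
})

test_that("binary-trait scans report odds ratios per minor allele", {
  set.seed(8)
  n <- 500L
  cm <- matrix(rbinom(6 * n, 2, 0.006), 6, n)
  x <- colMeans(cm > 0)
  y <- rbinom(n, 1, plogis(-0.4 + 8 * x))
  dir <- tempfile("bin"); dir.create(dir)
  gen <- write_gen_fixture(cm, seq(100, 600, by = 100),
                           file.path(dir, "d.gen"))
  smp <- file.path(dir, "d.sample")
  write_sample(data.frame(ID_1 = paste0("i", 1:n), ID_2 = paste0("i", 1:n),
                          missing = 0, pc1 = rnorm(n), disease = y),
               smp, types = c("0", "0", "0", "C", "B"))
  gf <- file.path(dir, "genes.txt")
  writeLines("1 1 1000 CANDIDATE", gf)
  scan <- run_scan(gen, smp, gf, trait = "binary", covar_cols = "pc1",
                   maf_threshold = 0.05)
  r <- scan$results
  expect_equal(r$status, "ok")
  expect_gt(r$or_per_allele, 1)
  expect_true(r$or_lower < r$or_per_allele &
                r$or_per_allele < r$or_upper)
  expect_equal(r$or_per_allele, exp(r$beta / r$n_variants))
  unlink(dir, recursive = TRUE)
})
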