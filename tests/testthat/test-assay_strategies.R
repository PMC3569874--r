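# SFS-like population: allele frequencies with density proportional to 1/q
# (log-uniform draws), realised as exact allele counts so the spectrum is
# not blurred by binomial sampling noise.
make_sfs_pop <- function(n_hap = 1000, n_var = 800, seed = 1,
                         qmin = 0.005, qmax = 0.5,
                         length_bp = 1.05e6, gene_bp = 5e4) {
  set.seed(seed)
  freq <- qmin * (qmax / qmin)^runif(n_var)
  H <- matrix(0L, n_hap, n_var)
  for (j in seq_len(n_var)) {
    k <- max(1L, min(n_hap - 1L, round(freq[j] * n_hap)))
    H[sample.int(n_hap, k), j] <- 1L
  }
  positions <- sort(sample.int(length_bp, n_var))
  hap_population(H, positions, length_bp = length_bp, gene_bp = gene_bp)
}

test_that("re-sequencing records gene variants below the cohort MAF threshold", {
  pop <- make_pop(n_hap = 600, n_var = 200, seed = 2, length_bp = 1e5,
                  gene_bp = 2e4, freq = runif(200, 0.001, 0.05))
  co <- sample_cohort(pop, 150, seed = 3)
  al <- cohort_alleles(pop, co)
  g <- al$a1 + al$a2
  st <- strategy_seq(g, pop)

  # brute-force recount oracle: cohort (not population) MAF, strict cutoff
  gi <- gene_sites(pop)
  f <- colMeans(g[, gi, drop = FALSE]) / 2
  maf <- pmin(f, 1 - f)
  expect_setequal(st$idx, gi[maf > 0 & maf < 0.01])
  expect_equal(ncol(st$eg), length(st$idx))
  # E(G) from hard calls is the carrier indicator
  for (k in seq_along(st$idx)) {
    gk <- g[, st$idx[k]]
    expected <- if (mean(gk) / 2 <= 0.5) (gk > 0) * 1 else (gk < 2) * 1
    expect_equal(st$eg[, k], expected)
  }
})

test_that("a variant at cohort MAF exactly 1% is excluded (strict cutoff)", {
  # 100 individuals: 2 carrier alleles / 200 = exactly 0.01
  H <- matrix(0L, 200, 3)
  H[1:2, 1] <- 1L       # exactly 1%
  H[1:40, 2] <- 1L      # common
  H[3, 3] <- 1L         # 0.5%
  pop <- hap_population(H, c(100, 200, 300), length_bp = 1000,
                        gene_bp = 1000)
  co <- structure(list(hap_idx = cbind(1:100, 101:200), n = 100L),
                  class = "cohort")
  g <- with(cohort_alleles(pop, co), a1 + a2)
  st <- strategy_seq(g, pop)
  expect_equal(st$idx, 3L)
})

test_that("panel genotyping intersects the re-sequencing set with panel variation", {
  pop <- make_pop(n_hap = 800, n_var = 300, seed = 6, length_bp = 1e5,
                  gene_bp = 3e4, freq = runif(300, 0.001, 0.03))
  co <- sample_cohort(pop, 150, seed = 1)
  al <- cohort_alleles(pop, co)
  g <- al$a1 + al$a2
  panel <- pop$haplotypes[sample_reference(pop, co, R = 60, seed = 2), ]

  st_seq <- strategy_seq(g, pop)
  st_gen <- strategy_gen(g, panel, pop)
  # set-intersection oracle
  pf <- colMeans(panel)
  expect_setequal(st_gen$idx,
                  intersect(st_seq$idx, which(pf > 0 & pf < 1)))
  expect_true(all(st_gen$idx %in% st_seq$idx))

  # panel covering every cohort haplotype reproduces re-sequencing
  full_panel <- pop$haplotypes
  st_full <- strategy_gen(g, full_panel, pop)
  expect_setequal(st_full$idx, st_seq$idx)

  # a variant private to the cohort is excluded
  priv <- matrix(0L, 100, 2)
  priv[1, 1] <- 1L; priv[1:30, 2] <- 1L
  ppop <- hap_population(priv, c(10, 20), length_bp = 100, gene_bp = 100)
  pco <- structure(list(hap_idx = cbind(1:2, 3:4), n = 2L),
                   class = "cohort")
  pg <- with(cohort_alleles(ppop, pco), a1 + a2)
  pg[1, 1] <- 1  # carrier inside cohort
  ppanel <- ppop$haplotypes[50:90, ]  # does not segregate at variant 1
  expect_false(1L %in% strategy_gen(pg, ppanel, ppop)$idx)
})

test_that("chip ascertainment weighted by MAF yields a near-uniform MAF spectrum", {
  # low sampling fraction, where inclusion probabilities stay proportional
  # to the ascertainment weight
  draws <- unlist(lapply(1:12, function(r) {
    pop <- make_sfs_pop(n_var = 10000, seed = 100 + r)
    chip <- chip_ascertain(pop, n_gwas = 100, seed = r)
    pop$q[chip$idx]
  }))
  expect_gte(length(draws), 1000)
  # chi-square goodness of fit against uniform on (0, 0.5]
  bins <- cut(draws, breaks = seq(0, 0.5, length.out = 6))
  gof <- suppressWarnings(chisq.test(table(bins)))
  expect_gt(gof$p.value, 0.01)

  # symmetric weights reduce to uniform sampling over variants
  pop <- make_pop(n_hap = 100, n_var = 50, seed = 5,
                  freq = rep(0.3, 50))
  c0 <- chip_ascertain(pop, n_gwas = 0, seed = 1)
  expect_length(c0$idx, 0L)
  c1 <- chip_ascertain(pop, n_gwas = 50, seed = 1)
  expect_setequal(c1$idx, seq_along(pop$positions))
})

test_that("the chip assays far fewer rare gene variants than re-sequencing", {
  counts <- t(sapply(1:15, function(r) {
    pop <- make_sfs_pop(n_hap = 600, n_var = 600, seed = 300 + r)
    co <- sample_cohort(pop, 150, seed = r)
    g <- with(cohort_alleles(pop, co), a1 + a2)
    chip <- chip_ascertain(pop, n_gwas = 240, seed = r)
    c(seq = length(strategy_seq(g, pop)$idx),
      gwas = length(strategy_gwas(g, chip, pop)$idx))
  }))
  expect_lt(mean(counts[, "gwas"]), 0.2 * mean(counts[, "seq"]))
})

test_that("error injection hits the documented genotype discordance rates", {
  # per-allele flip eps gives hom-ref genotype discordance 1 - (1-eps)^2
  n <- 1000; v <- 500
  zeros <- matrix(0L, n, v)
  for (eps in c(0.001, 0.002)) {
    a1 <- inject_errors(zeros, eps, seed = 17)
    a2 <- inject_errors(zeros, eps, seed = 18)
    disc <- mean((a1 + a2) != 0)
    expected <- 1 - (1 - eps)^2   # ~0.2% and ~0.4%
    se <- sqrt(expected * (1 - expected) / (n * v))
    expect_lt(abs(disc - expected), 4 * se)
  }
  # eps = 0 is the identity
  expect_identical(inject_errors(zeros, 0, seed = 1), zeros)
})

test_that("error injection is seed-reproducible and flips commute with transposition", {
  set.seed(4)
  m <- matrix(rbinom(600, 1, 0.5), 20)
  expect_identical(inject_errors(m, 0.05, seed = 9),
                   inject_errors(m, 0.05, seed = 9))
  mask <- error_mask(dim(m), 0.05, seed = 9)
  expect_identical(t(flip_calls(m, mask)), flip_calls(t(m), t(mask)))
})

test_that("missingness masks the documented fraction of genotypes", {
  g <- matrix(1L, 1000, 1000)
  gm <- inject_missing(g, 0.01, seed = 23)
  frac <- mean(is.na(gm))
  se <- sqrt(0.01 * 0.99 / 1e6)
  expect_lt(abs(frac - 0.01), 3 * se)
  expect_identical(attr(gm, "mask"), is.na(unname(gm)))
  # kappa = 0 leaves no mask
  g0 <- inject_missing(g, 0, seed = 1)
  expect_false(any(is.na(g0)))
  # masked entries are excluded from n_i downstream
  eg <- matrix(1, 4, 3)
  eg[1, 2] <- NA
  expect_equal(collapse_burden(eg)$n, c(2, 3, 3, 3))
})

test_that("strategy variant sets nest: SEQ contains GEN and the chip's gene variants", {
  for (r in 1:4) {
    pop <- make_sfs_pop(n_hap = 500, n_var = 400, seed = 40 + r)
    co <- sample_cohort(pop, 120, seed = r)
    g <- with(cohort_alleles(pop, co), a1 + a2)
    panel <- pop$haplotypes[sample_reference(pop, co, R = 40, seed = r), ]
    chip <- chip_ascertain(pop, 240, seed = r)
    s <- strategy_seq(g, pop)
    expect_true(all(strategy_gen(g, panel, pop)$idx %in% s$idx))
    expect_true(all(strategy_gwas(g, chip, pop)$idx %in% s$idx))
  }
})
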