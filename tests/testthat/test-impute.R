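test_that("Li-Stephens parameters follow the standard convention", {
  p <- ls_params(100)
  expect_equal(p$theta, 1 / sum(1 / (1:99)))
  expect_equal(p$lambda_ls, p$theta / (2 * (p$theta + 100)))
  expect_gt(p$lambda_ls, 0)
  expect_lt(p$lambda_ls, 0.5)
  # K = 1 still yields a valid emission error
  p1 <- ls_params(1)
  expect_gt(p1$lambda_ls, 0)
  expect_lt(p1$lambda_ls, 0.5)
})

test_that("forward-backward matches an independently coded oracle", {
  set.seed(33)
  for (case in 1:6) {
    K <- sample(2:6, 1)
    V <- sample(6:12, 1)
    panel <- matrix(rbinom(K * V, 1, 0.5), K, V)
    positions <- sort(sample.int(50000, V))
    S <- sample(2:(V - 1), 1)
    scaffold <- sort(sample.int(V, S))
    target <- rbinom(S, 1, 0.5)
    prm <- ls_params(K, Ne = 10000, rec = 1e-8)
    got <- ls_posteriors(target, scaffold, panel, positions,
                         out_idx = seq_len(V), params = prm)
    want <- ls_oracle(target, scaffold, panel, positions, seq_len(V),
                      Ne = 10000, rec = 1e-8, lambda = prm$lambda_ls)
    expect_equal(got, unname(want), tolerance = 1e-9)
  }
})

test_that("a target present in the panel is recovered at untyped sites", {
  # 5-haplotype panel over 10 tightly linked sites; the target equals panel
  # haplotype 1, and every other haplotype disagrees with it at >= 3 of the
  # typed sites
  panel <- rbind(
    c(1, 0, 1, 0, 1, 1, 0, 0, 1, 0),
    c(0, 1, 0, 1, 1, 0, 1, 0, 0, 1),
    c(0, 1, 1, 1, 0, 0, 1, 1, 0, 0),
    c(1, 1, 0, 0, 0, 0, 1, 1, 1, 1),
    c(0, 0, 0, 1, 0, 1, 1, 1, 0, 1))
  positions <- seq(100, 1000, length.out = 10)  # tight linkage
  scaffold <- c(1, 2, 4, 5, 7, 10)
  untyped <- setdiff(1:10, scaffold)
  target <- panel[1, scaffold]
  post <- ls_posteriors(target, scaffold, panel, positions,
                        out_idx = untyped)
  truth <- panel[1, untyped]
  expect_true(all(abs(post - truth) < 0.01))
})

test_that("single-haplotype panels and symmetric panels behave as limits", {
  positions <- c(100, 200, 300, 400)
  # K = 1: the posterior is the panel haplotype itself
  panel1 <- rbind(c(1, 0, 1, 0))
  post <- ls_posteriors(target = c(1, 0), scaffold_idx = c(1, 4),
                        panel = panel1, positions = positions,
                        out_idx = 2:3)
  expect_equal(post, c(0, 1))

  # two panel haplotypes equally consistent with the target, discordant at
  # an untyped site: posterior 0.5
  panel2 <- rbind(c(1, 0, 1, 0), c(1, 1, 1, 0))
  post2 <- ls_posteriors(target = c(1, 1, 0), scaffold_idx = c(1, 3, 4),
                         panel = panel2, positions = positions,
                         out_idx = 2L)
  expect_equal(post2, 0.5, tolerance = 1e-12)

  # empty panel errors
  expect_error(ls_posteriors(integer(), integer(),
                             matrix(0L, 0, 4), positions, 1L),
               "no haplotypes")
})

test_that("diploid genotype posteriors combine haploid posteriors exactly", {
  expect_equal(genotype_posteriors(0, 0), cbind(p0 = 1, p1 = 0, p2 = 0))
  expect_equal(genotype_posteriors(0.5, 0.5),
               cbind(p0 = 0.25, p1 = 0.5, p2 = 0.25))
  set.seed(2)
  a <- runif(50); b <- runif(50)
  gp <- genotype_posteriors(a, b)
  expect_equal(unname(rowSums(gp)), rep(1, 50), tolerance = 1e-15)
})

test_that("info score matches hand-evaluated and independently coded cases", {
  # polymorphic hard calls carry complete information
  p2 <- c(1, 1, 0, 0, 0, 0)
  p1 <- c(0, 0, 1, 0, 0, 1)
  p0 <- 1 - p1 - p2
  expect_equal(info_score(p0, p1, p2), 1)

  # flat triples: raw value 1 - (2/3)/(1/2) = -1/3, clipped to zero
  n <- 8
  flat <- rep(1 / 3, n)
  expect_equal(info_score(flat, flat, flat), 0)

  # mixed certain/uncertain samples against a direct formula evaluation
  set.seed(6)
  raw <- matrix(runif(30), 3)
  raw <- sweep(raw, 2, colSums(raw), "/")
  p0m <- c(rep(1, 5), rep(0, 5), raw[1, ])
  p1m <- c(rep(0, 5), rep(1, 5), raw[2, ])
  p2m <- c(rep(0, 10), raw[3, ])
  e <- p1m + 2 * p2m
  f <- p1m + 4 * p2m
  th <- sum(e) / (2 * length(e))
  manual <- 1 - sum(f - e^2) / (2 * length(e) * th * (1 - th))
  expect_equal(info_score(p0m, p1m, p2m), manual, tolerance = 1e-12)

  # monomorphic expectation gives info 0 by convention
  expect_equal(info_score(rep(1, 4), rep(0, 4), rep(0, 4)), 0)
  expect_error(info_score(rep(NA_real_, 3), rep(NA_real_, 3),
                          rep(NA_real_, 3)),
               "no non-missing")
})

test_that("imputed-variant filter applies inclusive info and strict MAF bounds", {
  maf <- c(0.005, 0.01, 0.005, 0, 0.009)
  info <- c(0.4, 0.9, 0.39, 0.8, 1)
  keep <- filter_imputed(maf, info)
  expect_equal(keep, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_length(filter_imputed(numeric(), numeric()), 0L)
})

test_that("hard-called cohorts reduce the filter to the MAF criterion", {
  pop <- make_pop(n_hap = 300, n_var = 60, seed = 44, length_bp = 1e5,
                  gene_bp = 1e5, freq = runif(60, 0.005, 0.2))
  co <- sample_cohort(pop, 60, seed = 1)
  al <- cohort_alleles(pop, co)
  # typed everywhere: scaffold covers every site
  imp <- impute_cohort(al$a1, al$a2, pop$haplotypes, pop,
                       scaffold_idx = seq_along(pop$positions))
  polym <- imp$maf > 0
  expect_true(all(imp$info[polym] == 1))
  expect_equal(filter_imputed(imp$maf, imp$info, 0.05, 0.4),
               !is.na(imp$maf) & imp$maf > 0 & imp$maf < 0.05)
  # triples are the hard calls themselves
  g <- al$a1 + al$a2
  j <- match(imp$idx[1], seq_along(pop$positions))
  expect_equal(imp$p1[, 1], as.numeric(g[, j] == 1))
})

test_that("imputation recovers held-out genotypes from a coalescent panel", {
  pop <- generate_population(n_hap = 800, seed = 19)
  co <- sample_cohort(pop, 80, seed = 2)
  al <- cohort_alleles(pop, co)
  panel <- pop$haplotypes[sample_reference(pop, co, R = 150, seed = 3), ]
  chip <- chip_ascertain(pop, 240, seed = 4)
  imp <- impute_cohort(al$a1, al$a2, panel, pop, chip$idx)
  g_true <- pop$haplotypes[co$hap_idx[, 1], imp$idx] +
    pop$haplotypes[co$hap_idx[, 2], imp$idx]
  dos <- imp$p1 + 2 * imp$p2
  expect_gt(cor(as.vector(dos), as.vector(g_true)), 0.8)
  expect_true(all(abs(imp$p0 + imp$p1 + imp$p2 - 1) < 1e-6))
  expect_true(all(imp$maf >= 0 & imp$maf <= 0.5))
  expect_true(all(imp$info >= 0 & imp$info <= 1))
})
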