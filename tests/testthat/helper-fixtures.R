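# Shared fixture builders: all test data are generated in code.

# Random binary haplotype population (no LD) with roughly the given
# allele-frequency range; positions spread uniformly over the region.
make_pop <- function(n_hap = 200, n_var = 60, seed = 1,
                     length_bp = 100000, gene_bp = 20000,
                     freq = NULL) {
  set.seed(seed)
  if (is.null(freq))
    freq <- runif(n_var, 0.5 / n_hap, 0.5)
  H <- sapply(freq, function(f) rbinom(n_hap, 1L, f))
  # ensure segregation
  H[1L, colSums(H) == 0] <- 1L
  H[1L, colSums(H) == n_hap] <- 0L
  positions <- sort(sample.int(length_bp, n_var))
  hap_population(H, positions, length_bp = length_bp, gene_bp = gene_bp)
}

# Minimal GEN file contents for a set of hard-called genotype counts
# (variants x samples matrix of 0/1/2 allele-B counts; NA = missing).
write_gen_fixture <- function(counts, positions, path) {
  v <- nrow(counts)
  lines <- vapply(seq_len(v), function(j) {
    triple <- vapply(counts[j, ], function(g) {
      if (is.na(g)) "0 0 0"
      else c("1 0 0", "0 1 0", "0 0 1")[g + 1L]
    }, character(1))
    paste("snp", paste0("rs", j), positions[j], "A", "G",
          paste(triple, collapse = " "))
  }, character(1))
  writeLines(lines, path)
  path
}

write_sample_fixture <- function(df, types, path) {
  write_sample(df, path, types = types)
}

# Independent R-language forward-backward oracle for the haploid
# Li-Stephens model (mirrors the model definition directly; no shared
# code with the package's C++ implementation).
ls_oracle <- function(target, scaffold_idx, panel, positions, out_idx,
                      Ne, rec, lambda) {
  K <- nrow(panel)
  S <- length(scaffold_idx)
  if (S == 0) return(colMeans(panel[, out_idx, drop = FALSE]))
  emis <- function(j) ifelse(panel[, scaffold_idx[j]] == target[j],
                             1 - lambda, lambda)
  rho <- sapply(seq_len(max(S - 1, 0)), function(j) {
    d <- positions[scaffold_idx[j + 1]] - positions[scaffold_idx[j]]
    1 - exp(-4 * Ne * rec * d / K)
  })
  A <- matrix(0, K, S)
  A[, 1] <- emis(1) / K
  A[, 1] <- A[, 1] / sum(A[, 1])
  if (S > 1) for (j in 2:S) {
    a <- (1 - rho[j - 1]) * A[, j - 1] + rho[j - 1] * sum(A[, j - 1]) / K
    A[, j] <- a * emis(j)
    A[, j] <- A[, j] / sum(A[, j])
  }
  B <- matrix(1, K, S)
  if (S > 1) for (j in (S - 1):1) {
    eb <- emis(j + 1) * B[, j + 1]
    B[, j] <- (1 - rho[j]) * eb + rho[j] * mean(eb)
    B[, j] <- B[, j] / mean(B[, j])
  }
  G <- A * B
  G <- sweep(G, 2, colSums(G), "/")
  spos <- positions[scaffold_idx]
  sapply(out_idx, function(u) {
    pu <- positions[u]
    rt <- which(spos >= pu)[1]  # first scaffold site at/after pu
    if (is.na(rt)) return(sum(G[, S] * panel[, u]))
    if (rt == 1) return(sum(G[, 1] * panel[, u]))
    w <- (pu - spos[rt - 1]) / (spos[rt] - spos[rt - 1])
    (1 - w) * sum(G[, rt - 1] * panel[, u]) + w * sum(G[, rt] * panel[, u])
  })
}

# Brute-force grid maximiser of the weighted binomial log-likelihood over
# (alpha, beta) for a burden-only logistic model.
grid_logistic <- function(x, y, w, alpha_grid, beta_grid) {
  best <- c(NA, NA, -Inf)
  for (a in alpha_grid) for (b in beta_grid) {
    eta <- a + b * x
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
    if (ll > best[3]) best <- c(a, b, ll)
  }
  best
}
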