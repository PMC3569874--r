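## Gene-based rare-variant burden test: collapse expected carrier
## indicators to a per-individual carrier proportion and test it in a
## call-rate-weighted GLM by likelihood-ratio analysis of deviance.

#' Collapse rare-variant carriers into a burden design
#'
#' Given per-individual expected carrier indicators `E(G_ij)` for the `N`
#' rare variants of a functional unit (rows = individuals, `NA` = variant
#' not successfully assayed in that individual), computes the carrier
#' proportion `x_i = sum_j E(G_ij) / n_i` over the `n_i` observed variants,
#' and the likelihood weight `w_i = n_i / N`.  Individuals with `n_i = 0`
#' get `x_i = 0` and weight 0, which removes them from the likelihood.
#'
#' @param eg numeric matrix (individuals x variants) of `E(G_ij)` values in
#'   `[0, 1]`, `NA` where unobserved.  Variants are assumed pre-filtered to
#'   the rare set (cohort MAF below threshold; info score above threshold
#'   for imputed variants).
#' @return An object of class `burden_design`: list with `x`, `n`, `N`, `w`.
#' @export
collapse_burden <- function(eg) {
  eg <- as.matrix(eg)
  N <- ncol(eg)
  if (N == 0L)
    stop(structure(class = c("no_rare_variants", "error", "condition"),
                   list(message = "no qualifying rare variants in unit",
                        call = sys.call())))
  if (any(eg < -1e-9 | eg > 1 + 1e-9, na.rm = TRUE))
    stop("E(G) values must lie in [0, 1]")
  n_i <- rowSums(!is.na(eg))
  s <- rowSums(eg, na.rm = TRUE)
  x <- ifelse(n_i > 0L, s / pmax(n_i, 1L), 0)
  structure(list(x = x, n = n_i, N = N, w = n_i / N),
            class = "burden_design")
}

.family_obj <- function(family) {
  family <- match.arg(family, c("gaussian", "binomial"))
  if (family == "gaussian") gaussian() else binomial()
}

#' Fit a weighted generalised linear model
#'
#' Maximises the weighted log-likelihood `sum_i w_i log L_i` by iteratively
#' reweighted least squares (via [stats::glm.fit()] with prior weights).
#' For the gaussian family the residual variance is profiled out at its
#' weighted maximum-likelihood value; for the binomial family the weights
#' scale the Bernoulli log-likelihood contributions.  Individuals with
#' weight 0, missing response or any missing covariate are excluded
#' listwise.
#'
#' @param x per-individual burden (carrier proportion), ignored when
#'   `include_burden = FALSE`.
#' @param y response vector (quantitative, or 0/1 for binomial).
#' @param covariates optional numeric matrix/data frame of covariates,
#'   included in the model whether or not the burden term is.
#' @param weights per-individual likelihood weights in `[0, 1]`
#'   (default all 1).
#' @param family `"gaussian"` (identity link) or `"binomial"` (logit link).
#' @param include_burden if `FALSE`, fits the null model with the burden
#'   effect constrained to zero.
#' @param max_iter,tol IRLS iteration cap and relative convergence
#'   tolerance.
#' @return An object of class `wglm_fit`: coefficients (`(Intercept)`,
#'   `burden` if included, covariates), `se` for the burden term,
#'   `log_likelihood`, `converged`, `separation`, `iterations`, `n_used`,
#'   `sum_w`.
#' @export
fit_weighted_glm <- function(x, y, covariates = NULL, weights = NULL,
                             family = "gaussian", include_burden = TRUE,
                             max_iter = 100L, tol = 1e-8) {
  fam <- .family_obj(family)
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0 & weights <= 1 + 1e-9,
                                      na.rm = TRUE))
  cv <- NULL
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    stopifnot(nrow(cv) == n)
    if (is.null(colnames(cv)))
      colnames(cv) <- paste0("covar", seq_len(ncol(cv)))
  }
  keep <- !is.na(y) & !is.na(weights) & weights > 0
  if (include_burden) keep <- keep & !is.na(x)
  if (!is.null(cv)) keep <- keep & complete.cases(cv)

  X <- cbind(`(Intercept)` = rep(1, sum(keep)))
  if (include_burden) X <- cbind(X, burden = x[keep])
  if (!is.null(cv)) X <- cbind(X, cv[keep, , drop = FALSE])
  yk <- y[keep]
  wk <- weights[keep]
  if (length(yk) <= ncol(X))
    return(structure(list(coefficients = setNames(rep(NA_real_, ncol(X)),
                                                  colnames(X)),
                          se = NA_real_, log_likelihood = NA_real_,
                          converged = FALSE, separation = FALSE,
                          iterations = 0L, n_used = length(yk),
                          sum_w = sum(wk), family = family),
                     class = "wglm_fit"))

  fit <- suppressWarnings(
    glm.fit(X, yk, weights = wk, family = fam,
            control = glm.control(epsilon = tol, maxit = max_iter)))
  mu <- fit$fitted.values
  W <- sum(wk)
  if (family == "gaussian") {
    rss <- sum(wk * (yk - mu)^2)
    sig2 <- max(rss / W, .Machine$double.xmin)
    ll <- -W / 2 * (log(2 * pi * sig2) + 1)
    p_eff <- sum(!is.na(fit$coefficients))
    dispersion <- rss / max(length(yk) - p_eff, 1L)
    separation <- FALSE
  } else {
    mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- sum(wk * (yk * log(mu_c) + (1 - yk) * log(1 - mu_c)))
    dispersion <- 1
    separation <- any(mu < 1e-8 | mu > 1 - 1e-8)
  }

  se <- NA_real_
  if (include_burden && !is.na(fit$coefficients["burden"])) {
    # covariance of the estimates from the final IRLS weighted least squares
    Rm <- fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE]
    Rm[lower.tri(Rm)] <- 0
    cov_u <- chol2inv(Rm) * dispersion
    kept_cols <- colnames(X)[fit$qr$pivot[seq_len(fit$rank)]]
    bpos <- match("burden", kept_cols)
    if (!is.na(bpos)) se <- sqrt(cov_u[bpos, bpos])
  }

  structure(list(coefficients = fit$coefficients, se = se,
                 log_likelihood = ll, converged = fit$converged,
                 separation = separation, iterations = fit$iter,
                 n_used = length(yk), sum_w = W, family = family),
            class = "wglm_fit")
}

#' @export
print.wglm_fit <- function(x, ...) {
  cat(sprintf("<wglm_fit> %s, logLik %.4f, converged: %s\n",
              x$family, x$log_likelihood, x$converged))
  print(x$coefficients)
  invisible(x)
}

#' Likelihood-ratio test between nested weighted GLM fits
#'
#' The statistic is `2 * (logLik_alt - logLik_null)`, clipped at zero, and
#' referred to a chi-square distribution with one degree of freedom (upper
#' tail).  Both fits must be on identical data, weights and covariates.
#'
#' @param null_fit,alt_fit `wglm_fit` objects for the constrained
#'   (`beta = 0`) and unconstrained models.
#' @return List with `statistic` and `p_value`; both `NA` if either fit
#'   failed to converge.
#' @export
lrt <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "wglm_fit"), inherits(alt_fit, "wglm_fit"))
  if (!isTRUE(null_fit$converged) || !isTRUE(alt_fit$converged))
    return(list(statistic = NA_real_, p_value = NA_real_))
  stat <- max(0, 2 * (alt_fit$log_likelihood - null_fit$log_likelihood))
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Odds ratio per minor allele
#'
#' On a binary trait, the burden coefficient `beta` measures the log-odds
#' increase for a full complement of minor alleles at the `N` rare variants
#' of the unit, so `beta / N` is the log-odds increase per minor allele.
#'
#' @param beta burden coefficient.
#' @param se its standard error.
#' @param N number of rare variants in the unit (`>= 1`).
#' @return List with `or`, `lower`, `upper` (95\% CI).
#' @export
or_per_minor_allele <- function(beta, se, N) {
  if (is.null(N) || is.na(N) || N < 1) stop("N must be >= 1")
  list(or = exp(beta / N),
       lower = exp((beta - 1.96 * se) / N),
       upper = exp((beta + 1.96 * se) / N))
}

#' Append a lead-SNP dosage to a covariate matrix
#'
#' For conditional analysis, the lead SNP's expected minor-allele count
#' (dosage in `[0, 2]`) is added as a covariate to both the null and
#' alternative models.  A constant dosage is dropped with a warning (the
#' result then equals the unadjusted analysis); samples with missing
#' dosage are flagged for weight-zero exclusion.
#'
#' @param covariates covariate matrix or `NULL`.
#' @param dosage per-sample lead-SNP dosage.
#' @param name column name for the new covariate.
#' @return List with `covariates` (possibly augmented), `zero_weight`
#'   (logical: samples whose dosage is missing) and `dropped`.
#' @export
conditional_adjust <- function(covariates, dosage, name = "lead_snp") {
  ok <- !is.na(dosage)
  if (any(dosage[ok] < -1e-9 | dosage[ok] > 2 + 1e-9))
    stop("lead-SNP dosages must lie in [0, 2]")
  if (sum(ok) == 0L || length(unique(dosage[ok])) == 1L) {
    warning("lead-SNP dosage is constant; conditional covariate dropped")
    return(list(covariates = covariates, zero_weight = rep(FALSE,
                                                           length(dosage)),
                dropped = TRUE))
  }
  cv <- if (is.null(covariates)) matrix(dosage, ncol = 1L,
                                        dimnames = list(NULL, name))
        else cbind(covariates, setNames(data.frame(dosage), name))
  list(covariates = cv, zero_weight = !ok, dropped = FALSE)
}

#' Burden likelihood-ratio test for one functional unit
#'
#' Runs the full per-gene analysis: collapse `E(G)` values to the burden
#' design, fit null and alternative weighted GLMs (covariates in both), and
#' perform the one-degree-of-freedom likelihood-ratio test.  For binary
#' traits the odds ratio per minor allele `exp(beta / N)` and its 95\% CI
#' are reported.
#'
#' @param eg matrix of `E(G_ij)` for the unit's qualifying rare variants
#'   (individuals x variants; `NA` = unobserved).
#' @param y phenotype vector.
#' @param maf per-variant cohort minor allele frequencies (fractions), used
#'   for the `mean_maf` summary (reported in %).
#' @param covariates optional covariate matrix.
#' @param family `"gaussian"` or `"binomial"`.
#' @param gene optional one-row data frame with `gene_id`, `chromosome`,
#'   `start`, `stop` used to label the result.
#' @param condition_dosage optional lead-SNP dosage for conditional
#'   adjustment; samples with missing dosage get weight 0.
#' @return One-row data frame (`gene, chr, start, stop, n_variants,
#'   mean_maf, beta, se, or_per_allele, or_lower, or_upper, lrt_stat,
#'   p_value, status`).
#' @export
burden_test <- function(eg, y, maf = NULL, covariates = NULL,
                        family = "gaussian", gene = NULL,
                        condition_dosage = NULL) {
  lab <- if (is.null(gene))
    data.frame(gene = NA_character_, chr = NA_character_,
               start = NA_integer_, stop = NA_integer_)
  else
    data.frame(gene = gene$gene_id, chr = gene$chromosome,
               start = gene$start, stop = gene$stop)

  empty <- cbind(lab, data.frame(
    n_variants = 0L, mean_maf = NA_real_, beta = NA_real_, se = NA_real_,
    or_per_allele = NA_real_, or_lower = NA_real_, or_upper = NA_real_,
    lrt_stat = NA_real_, p_value = NA_real_, status = "no_rare_variants",
    stringsAsFactors = FALSE))
  if (is.null(eg) || ncol(as.matrix(eg)) == 0L) return(empty)

  design <- tryCatch(collapse_burden(eg),
                     no_rare_variants = function(e) NULL)
  if (is.null(design)) return(empty)

  w <- design$w
  if (!is.null(condition_dosage)) {
    adj <- conditional_adjust(covariates, condition_dosage)
    covariates <- adj$covariates
    w[adj$zero_weight] <- 0
  }

  null_fit <- fit_weighted_glm(design$x, y, covariates, w, family,
                               include_burden = FALSE)
  alt_fit <- fit_weighted_glm(design$x, y, covariates, w, family,
                              include_burden = TRUE)
  lr <- lrt(null_fit, alt_fit)

  beta <- unname(alt_fit$coefficients["burden"])
  status <- if (!alt_fit$converged || !null_fit$converged) "not_converged"
            else if (isTRUE(alt_fit$separation)) "separation"
            else "ok"
  or <- list(or = NA_real_, lower = NA_real_, upper = NA_real_)
  if (family == "binomial" && !is.na(beta) && !is.na(alt_fit$se))
    or <- or_per_minor_allele(beta, alt_fit$se, design$N)

  cbind(lab, data.frame(
    n_variants = design$N,
    mean_maf = if (is.null(maf)) NA_real_ else 100 * mean(maf),
    beta = beta, se = alt_fit$se,
    or_per_allele = or$or, or_lower = or$lower, or_upper = or$upper,
    lrt_stat = lr$statistic, p_value = lr$p_value, status = status,
    stringsAsFactors = FALSE))
}
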