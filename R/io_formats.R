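## SNPTEST/IMPUTE-dialect file formats and conversion of genotype
## posterior-probability triples to the internal carrier representation.

#' Construct a genotype-probability data set
#'
#' Container for a set of variants with per-sample genotype posterior
#' probability triples, as carried by SNPTEST/IMPUTE GEN files.  The triple
#' for sample `i` at variant `j` is `(pAA, pAB, pBB)`, the posterior
#' probabilities of the three genotypes on the A/B allele coding of the
#' file.  An all-zero triple encodes a missing genotype.
#'
#' @param variants data frame with columns `snp_id`, `rs_id`, `position`
#'   (1-based bp), `allele_a`, `allele_b`.
#' @param paa,pab,pbb numeric matrices (variants x samples) of genotype
#'   posterior probabilities.
#' @return An object of class `gen_data`: a list with elements `variants`,
#'   `paa`, `pab`, `pbb` and `n_samples`.
#' @export
gen_data <- function(variants, paa, pab, pbb) {
  stopifnot(is.data.frame(variants),
            all(c("snp_id", "rs_id", "position", "allele_a", "allele_b")
                %in% names(variants)))
  paa <- as.matrix(paa); pab <- as.matrix(pab); pbb <- as.matrix(pbb)
  if (!all(dim(paa) == dim(pab)) || !all(dim(paa) == dim(pbb)))
    stop("probability matrices must share dimensions")
  if (nrow(paa) != nrow(variants))
    stop("probability matrices must have one row per variant")
  if (any(variants$position < 1))
    stop("variant positions must be >= 1")
  .check_triples(paa, pab, pbb)
  structure(list(variants = variants, paa = paa, pab = pab, pbb = pbb,
                 n_samples = ncol(paa)),
            class = "gen_data")
}

#' @export
print.gen_data <- function(x, ...) {
  cat(sprintf("<gen_data> %d variants x %d samples\n",
              nrow(x$variants), x$n_samples))
  invisible(x)
}

# triples must sum to 1 within 1e-3, or be exactly all-zero (missing)
.check_triples <- function(paa, pab, pbb, where = "gen_data") {
  s <- paa + pab + pbb
  missing <- paa == 0 & pab == 0 & pbb == 0
  bad <- !missing & abs(s - 1) > 1e-3
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "%s: probability triple at variant %d, sample %d sums to %.4f (not 1 within 1e-3)",
      where, ij[1L], ij[2L], s[ij[1L], ij[2L]]))
  }
  if (any(paa < -1e-9 | pab < -1e-9 | pbb < -1e-9, na.rm = TRUE))
    stop(sprintf("%s: negative genotype probability", where))
  invisible(!missing)
}

#' Read a GEN genotype file
#'
#' Parses a whitespace-delimited SNPTEST/IMPUTE GEN file: five leading
#' columns (`snp_id`, `rs_id`, `position`, `allele_a`, `allele_b`) followed
#' by three genotype-probability columns per sample.  An all-zero triple is
#' the missing-genotype sentinel; any other triple must sum to 1 within
#' 1e-3.
#'
#' @param path path to the GEN file.
#' @return A [gen_data] object, variants in file order.
#' @export
read_gen <- function(path) {
  if (!file.exists(path)) stop("GEN file not found: ", path)
  nf <- count.fields(path, comment.char = "")
  if (length(nf) == 0)
    return(gen_data(data.frame(snp_id = character(), rs_id = character(),
                               position = integer(), allele_a = character(),
                               allele_b = character()),
                    matrix(0, 0, 0), matrix(0, 0, 0), matrix(0, 0, 0)))
  bad <- which(nf < 8 | (nf - 5) %% 3 != 0 | nf != nf[1L])
  if (length(bad))
    stop(sprintf(
      "malformed GEN row at line %d: %d fields (expected 5 + 3 per sample, consistent across rows)",
      bad[1L], nf[bad[1L]]))
  dt <- data.table::fread(path, header = FALSE, colClasses = list(
    character = c(1L, 2L, 4L, 5L)))
  variants <- data.frame(snp_id = dt[[1L]], rs_id = dt[[2L]],
                         position = as.integer(dt[[3L]]),
                         allele_a = dt[[4L]], allele_b = dt[[5L]],
                         stringsAsFactors = FALSE)
  probs <- unname(as.matrix(dt[, -(1:5)]))
  n <- (nf[1L] - 5L) %/% 3L
  idx <- seq_len(n)
  gen_data(variants,
           paa = probs[, 3L * idx - 2L, drop = FALSE],
           pab = probs[, 3L * idx - 1L, drop = FALSE],
           pbb = probs[, 3L * idx, drop = FALSE])
}

#' Write a GEN genotype file
#'
#' Probabilities are written with six decimal places, so a
#' write-then-read round trip reproduces them to 6 decimals.
#'
#' @param gen a [gen_data] object.
#' @param path output path.
#' @export
write_gen <- function(gen, path) {
  stopifnot(inherits(gen, "gen_data"))
  v <- nrow(gen$variants)
  n <- gen$n_samples
  probs <- matrix("", v, 3L * n)
  probs[, 3L * seq_len(n) - 2L] <- sprintf("%.6f", gen$paa)
  probs[, 3L * seq_len(n) - 1L] <- sprintf("%.6f", gen$pab)
  probs[, 3L * seq_len(n)] <- sprintf("%.6f", gen$pbb)
  lines <- paste(gen$variants$snp_id, gen$variants$rs_id,
                 gen$variants$position, gen$variants$allele_a,
                 gen$variants$allele_b,
                 apply(probs, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Posterior carrier probabilities from genotype triples
#'
#' Orients each variant so that `h_ij` is the posterior probability that
#' sample `i` is homozygous for the *major* allele, and returns the
#' expected carrier indicator `E(G_ij) = 1 - h_ij`.  The minor allele is
#' determined from the expected allele frequency across non-missing
#' samples: the allele with expected frequency at most 0.5 is minor (ties
#' resolve to allele B).  Variants with expected frequency exactly 0 or 1
#' are flagged non-polymorphic.
#'
#' @param gen a [gen_data] object.
#' @param j optional variant indices (default all).
#' @return A list with matrices `h`, `eg` (variants x samples), logical
#'   `observed` mask, and per-variant vectors `maf` (expected cohort minor
#'   allele frequency), `minor_is_b` and `polymorphic`.
#' @export
carrier_posterior <- function(gen, j = NULL) {
  stopifnot(inherits(gen, "gen_data"))
  if (is.null(j)) j <- seq_len(nrow(gen$variants))
  paa <- gen$paa[j, , drop = FALSE]
  pab <- gen$pab[j, , drop = FALSE]
  pbb <- gen$pbb[j, , drop = FALSE]
  observed <- !(paa == 0 & pab == 0 & pbb == 0)
  eb <- pab + 2 * pbb                      # expected count of allele B
  eb[!observed] <- NA_real_
  n_obs <- rowSums(observed)
  fb <- rowSums(eb, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  fb[n_obs == 0] <- NA_real_
  minor_is_b <- !is.na(fb) & fb <= 0.5
  h <- ifelse(matrix(minor_is_b, nrow(paa), ncol(paa)), paa, pbb)
  h[!observed] <- NA_real_
  maf <- pmin(fb, 1 - fb)
  list(h = h, eg = 1 - h, observed = observed, maf = maf,
       minor_is_b = minor_is_b,
       polymorphic = !is.na(fb) & fb > 0 & fb < 1)
}

#' Read a SAMPLE file
#'
#' Parses the SNPTEST SAMPLE dialect: a header row of column names, a
#' second header row of type codes (`0` identifier/structural, `D` discrete
#' covariate, `C` continuous covariate, `B` binary phenotype, `P`
#' quantitative phenotype), then one row per sample.  `NA` and `-9` in
#' phenotype columns are treated as missing.
#'
#' @param path path to the SAMPLE file.
#' @return A data frame, one row per sample, with attribute `"types"`
#'   giving the per-column type codes.
#' @export
read_sample <- function(path) {
  if (!file.exists(path)) stop("SAMPLE file not found: ", path)
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L) stop("SAMPLE file needs two header rows")
  nms <- strsplit(trimws(hdr[1L]), "\\s+")[[1L]]
  types <- strsplit(trimws(hdr[2L]), "\\s+")[[1L]]
  if (length(nms) != length(types))
    stop("SAMPLE header rows have different lengths")
  unknown <- setdiff(unique(types), c("0", "D", "C", "B", "P"))
  if (length(unknown))
    stop("unknown SAMPLE type code(s): ", paste(unknown, collapse = ", "))
  df <- read.table(path, skip = 2L, header = FALSE, col.names = nms,
                   stringsAsFactors = FALSE, na.strings = c("NA"))
  for (k in which(types %in% c("B", "P", "C"))) {
    df[[k]] <- suppressWarnings(as.numeric(df[[k]]))
    df[[k]][df[[k]] == -9] <- NA_real_
  }
  for (k in which(types == "B")) {
    v <- df[[k]]
    if (any(!is.na(v) & !(v %in% c(0, 1))))
      stop(sprintf("binary phenotype column '%s' has values outside {0,1}",
                   nms[k]))
  }
  if (anyDuplicated(df[[1L]]))
    stop("duplicate sample identifiers in SAMPLE file")
  attr(df, "types") <- setNames(types, nms)
  df
}

#' Write a SAMPLE file
#'
#' @param df data frame as returned by [read_sample()]; the `"types"`
#'   attribute (or `types`) supplies the second header row.
#' @param path output path.
#' @param types per-column type codes, defaulting to `attr(df, "types")`.
#' @export
write_sample <- function(df, path, types = attr(df, "types")) {
  if (is.null(types)) stop("column type codes required")
  stopifnot(length(types) == ncol(df))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = " "), con)
  writeLines(paste(types, collapse = " "), con)
  body <- do.call(paste, c(lapply(df, function(v) {
    v <- as.character(v); v[is.na(v)] <- "NA"; v
  }), sep = " "))
  writeLines(body, con)
  invisible(path)
}

#' Read a gene-boundary file
#'
#' Whitespace-delimited rows of `chromosome start stop name`; coordinates
#' are 1-based and inclusive, and a variant belongs to a gene iff
#' `start <= position <= stop`.
#'
#' @param path path to the gene file.
#' @return Data frame with columns `gene_id`, `chromosome`, `start`, `stop`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("gene file not found: ", path)
  empty <- data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), stop = integer(),
                      stringsAsFactors = FALSE)
  nf <- tryCatch(count.fields(path), error = function(e) integer())
  if (length(nf) == 0 || all(is.na(nf))) {
    warning("gene file is empty: ", path)
    return(empty)
  }
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("gene file needs 4 columns: chr start stop name")
  out <- data.frame(gene_id = as.character(df[[4L]]),
                    chromosome = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    stop = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(out$start > out$stop))
    stop("gene with start > stop in ", path)
  out
}

#' Write a burden-test results table
#'
#' Tab-separated with header columns `gene, chr, start, stop, n_variants,
#' mean_maf, beta, se, or_per_allele, lrt_stat, p_value`.
#'
#' @param results data frame of per-gene results (see [burden_test()]).
#' @param path output path.
#' @export
write_results <- function(results, path) {
  cols <- c("gene", "chr", "start", "stop", "n_variants", "mean_maf",
            "beta", "se", "or_per_allele", "lrt_stat", "p_value")
  missing_cols <- setdiff(cols, names(results))
  for (m in missing_cols) results[[m]] <- NA
  write.table(results[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
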