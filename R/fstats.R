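## f2/f3/f4/D admixture statistics with weighted block jackknife, f4-ratio
## ancestry proportions, supervised two-way ML admixture, f3-profile
## correlation.

#' Population allele-frequency table
#'
#' @param p matrix of derived/alt-allele frequency estimates, variants x
#'   populations (column names are population names).
#' @param n matrix (or vector, recycled) of chromosome counts (non-missing
#'   alleles) backing each estimate.
#' @param variants optional data.frame of variant annotation (`chrom`, `pos`,
#'   `cm`) aligned with the rows; used for block assignment.
#' @return An object of class `freq_table`.
#' @export
freq_table <- function(p, n, variants = NULL) {
  p <- as.matrix(p)
  if (is.null(colnames(p))) stop("p must have population column names")
  if (!is.matrix(n)) n <- matrix(n, nrow(p), ncol(p), dimnames = dimnames(p))
  stopifnot(all(dim(n) == dim(p)))
  bad <- p[!is.na(p)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 1))
    stop("frequencies must lie in [0, 1]")
  structure(list(p = p, n = n, pops = colnames(p), variants = variants),
            class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat("freq_table:", nrow(x$p), "variants x", length(x$pops),
      "populations (", paste(x$pops, collapse = ", "), ")\n")
  invisible(x)
}

#' Per-population allele frequencies from a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param pops population grouping: `NULL` uses the panel's population
#'   labels; a character vector restricts to those populations; a named list
#'   maps group names to sample ids (e.g. one group per individual).
#' @return A [freq_table()] carrying the panel's variant annotation.
#' @export
allele_freqs <- function(panel, pops = NULL) {
  if (is.null(pops)) pops <- unique(panel$samples$pop)
  if (!is.list(pops)) {
    pops <- stats::setNames(lapply(pops, function(pp)
      panel$samples$id[panel$samples$pop == pp]), pops)
  }
  p <- matrix(NA_real_, nrow(panel$variants), length(pops),
              dimnames = list(NULL, names(pops)))
  n <- matrix(0L, nrow(panel$variants), length(pops),
              dimnames = list(NULL, names(pops)))
  for (j in seq_along(pops)) {
    g <- panel$geno[, sample_index(panel, pops[[j]]), drop = FALSE]
    nn <- 2L * rowSums(!is.na(g))
    alt <- rowSums(g, na.rm = TRUE)
    p[, j] <- ifelse(nn > 0, alt / nn, NA_real_)
    n[, j] <- nn
  }
  freq_table(p, n, variants = panel$variants)
}

#' Assign contiguous genomic blocks for the jackknife
#'
#' Contiguous blocks of `block_cm` centimorgans within each chromosome when
#' genetic-map coordinates are available, otherwise chunks of `block_snps`
#' consecutive variants.
#'
#' @param freqs a [freq_table()] (or a [genotype_panel()]).
#' @param block_cm block size in cM (default 5).
#' @param block_snps fallback block size in SNPs (default 500).
#' @return Integer vector of block ids, one per variant.
#' @export
make_blocks <- function(freqs, block_cm = 5, block_snps = 500) {
  v <- if (inherits(freqs, "genotype_panel")) freqs$variants else freqs$variants
  nv <- if (inherits(freqs, "genotype_panel")) nrow(freqs$variants)
        else nrow(freqs$p)
  if (!is.null(v) && !is.null(v$cm) && !anyNA(v$cm)) {
    key <- paste(v$chrom, floor((v$cm - ave(v$cm, v$chrom, FUN = min)) /
                                  block_cm))
    return(match(key, unique(key)))
  }
  (seq_len(nv) - 1L) %/% block_snps + 1L
}

#' Weighted block jackknife for ratio statistics
#'
#' Delete-one-block jackknife with block weights (typically the SNP count per
#' block), for estimates of the form `sum(num) / sum(den)`. Uses the weighted
#' jackknife variance of Busing et al., the standard companion of genome-wide
#' f-statistics.
#'
#' @param num_blocks,den_blocks per-block sums of the numerator/denominator.
#' @param weights per-block weights; defaults to equal weights.
#' @return list(estimate, se, z, n_blocks).
#' @export
block_jackknife <- function(num_blocks, den_blocks, weights = NULL) {
  m <- length(num_blocks)
  if (m < 2) stop("need at least 2 blocks")
  if (is.null(weights)) weights <- rep(1, m)
  stopifnot(length(den_blocks) == m, length(weights) == m, all(weights > 0))
  ntot <- sum(weights)
  est <- sum(num_blocks) / sum(den_blocks)
  loo <- (sum(num_blocks) - num_blocks) / (sum(den_blocks) - den_blocks)
  h <- ntot / weights
  theta_j <- m * est - sum((1 - weights / ntot) * loo)
  tau <- h * est - (h - 1) * loo
  var_j <- sum((tau - theta_j)^2 / (h - 1)) / m
  se <- sqrt(max(var_j, 0))
  list(estimate = est, se = se,
       z = if (se > 0) est / se else ifelse(est == 0, 0, Inf * sign(est)),
       n_blocks = m)
}

fstat_result <- function(stat, pops, jk, n_snps) {
  structure(list(stat = stat, pops = pops, estimate = jk$estimate,
                 se = jk$se, z = jk$z, n_blocks = jk$n_blocks,
                 n_snps = n_snps),
            class = "fstat_result")
}

#' @export
print.fstat_result <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE = %.3g  Z = %.2f  (%d SNPs, %d blocks)\n",
              x$stat, paste(x$pops, collapse = ", "), x$estimate, x$se,
              x$z, x$n_snps, x$n_blocks))
  invisible(x)
}

## listwise-complete SNP mask across argument populations
complete_snps <- function(freqs, pops, min_n = 1L) {
  ok <- rep(TRUE, nrow(freqs$p))
  for (pp in pops) {
    if (!pp %in% freqs$pops) stop("unknown population: ", pp)
    ok <- ok & !is.na(freqs$p[, pp]) & freqs$n[, pp] >= min_n
  }
  ok
}

jackknife_snps <- function(num, den, blocks) {
  nb <- rowsum(num, blocks)
  db <- rowsum(den, blocks)
  wb <- rowsum(rep(1, length(num)), blocks)
  block_jackknife(as.vector(nb), as.vector(db), as.vector(wb))
}

#' Three-population admixture test f3(target; ref1, ref2)
#'
#' Per-SNP term `(c - a)(c - b) - c(1-c)/(n_c - 1)`, where the subtraction
#' unbiases the target's sampling heterozygosity. A significantly negative
#' genome-wide value (conventionally Z < -4) indicates that the target is a
#' mixture of populations related to the two references.
#'
#' @param freqs a [freq_table()].
#' @param target,ref1,ref2 population names.
#' @param blocks optional per-variant block ids (default [make_blocks()]).
#' @return An `fstat_result`.
#' @export
f3 <- function(freqs, target, ref1, ref2, blocks = NULL) {
  ok <- complete_snps(freqs, c(target, ref1, ref2)) &
    freqs$n[, target] >= 2L
  if (!any(ok))
    stop("f3 target correction undefined: fewer than 2 chromosomes at all SNPs")
  if (is.null(blocks)) blocks <- make_blocks(freqs)
  cc <- freqs$p[ok, target]; a <- freqs$p[ok, ref1]; b <- freqs$p[ok, ref2]
  nc <- freqs$n[ok, target]
  num <- (cc - a) * (cc - b) - cc * (1 - cc) / (nc - 1)
  jk <- jackknife_snps(num, rep(1, sum(ok)), blocks[ok])
  fstat_result("f3", c(target, ref1, ref2), jk, sum(ok))
}

#' Four-population statistics f4 and D
#'
#' `f4(A, B, C, D)` is the genome-wide mean of `(a - b)(c - d)`. The D
#' statistic normalizes the same numerator by the total heterozygosity term
#' `(w + x - 2wx)(y + z - 2yz)` so that `D(W, chimp; Y, Z) > 0` iff W shares
#' more derived alleles with Y than with Z.
#'
#' @param freqs a [freq_table()].
#' @param A,B,C,D population names (first pair vs second pair).
#' @param blocks optional per-variant block ids.
#' @return An `fstat_result`.
#' @export
f4 <- function(freqs, A, B, C, D, blocks = NULL) {
  ok <- complete_snps(freqs, c(A, B, C, D))
  if (!any(ok)) stop("no complete SNPs for f4")
  if (is.null(blocks)) blocks <- make_blocks(freqs)
  num <- (freqs$p[ok, A] - freqs$p[ok, B]) *
    (freqs$p[ok, C] - freqs$p[ok, D])
  jk <- jackknife_snps(num, rep(1, sum(ok)), blocks[ok])
  fstat_result("f4", c(A, B, C, D), jk, sum(ok))
}

#' @rdname f4
#' @param W,X,Y,Z population names for the D orientation
#'   `D(W, X; Y, Z)`.
#' @export
d_stat <- function(freqs, W, X, Y, Z, blocks = NULL) {
  ok <- complete_snps(freqs, c(W, X, Y, Z))
  if (!any(ok)) stop("no complete SNPs for D")
  if (is.null(blocks)) blocks <- make_blocks(freqs)
  w <- freqs$p[ok, W]; x <- freqs$p[ok, X]
  y <- freqs$p[ok, Y]; z <- freqs$p[ok, Z]
  num <- (w - x) * (y - z)
  den <- (w + x - 2 * w * x) * (y + z - 2 * y * z)
  if (sum(den) == 0) stop("D undefined: zero denominator")
  jk <- jackknife_snps(num, den, blocks[ok])
  fstat_result("D", c(W, X, Y, Z), jk, sum(ok))
}

#' Admixture proportion by the f4 ratio
#'
#' `alpha = f4(A, O; X, B) / f4(A, O; Src, B)`, computed as a ratio of
#' genome-wide sums with the standard error from a delete-one-block jackknife
#' of the ratio. The estimate is deliberately not clamped to `[0, 1]`:
#' sampling noise can push it outside.
#'
#' @param freqs a [freq_table()].
#' @param num character vector `c(A, O, X, B)` naming the numerator f4.
#' @param den character vector `c(A, O, Src, B)` naming the denominator f4.
#' @param blocks optional per-variant block ids.
#' @param z_min_den warn when the denominator f4 has |Z| below this
#'   (default 4): the ratio is then poorly determined.
#' @return list of class `admixture_estimate`: alpha, se, z, method,
#'   n_snps, n_blocks.
#' @export
f4_ratio <- function(freqs, num, den, blocks = NULL, z_min_den = 4) {
  stopifnot(length(num) == 4, length(den) == 4)
  ok <- complete_snps(freqs, unique(c(num, den)))
  if (!any(ok)) stop("no complete SNPs for f4 ratio")
  if (is.null(blocks)) blocks <- make_blocks(freqs)
  term <- function(v)
    (freqs$p[ok, v[1]] - freqs$p[ok, v[2]]) *
    (freqs$p[ok, v[3]] - freqs$p[ok, v[4]])
  fn <- term(num); fd <- term(den)
  dz <- jackknife_snps(fd, rep(1, sum(ok)), blocks[ok])
  if (is.finite(dz$z) && abs(dz$z) < z_min_den)
    warning("denominator f4 is not significantly nonzero (|Z| = ",
            round(abs(dz$z), 2), "); alpha is poorly determined")
  jk <- jackknife_snps(fn, fd, blocks[ok])
  structure(list(alpha = jk$estimate, se = jk$se, z = jk$z,
                 method = "f4_ratio", n_snps = sum(ok),
                 n_blocks = jk$n_blocks),
            class = "admixture_estimate")
}

#' @export
print.admixture_estimate <- function(x, ...) {
  cat(sprintf("alpha = %.4f  SE = %.4f  (%s, %d SNPs)\n",
              x$alpha, x$se, x$method, x$n_snps))
  invisible(x)
}

#' Supervised two-way admixture proportions by maximum likelihood
#'
#' For each individual, maximizes
#' `sum_i log Binom(g_i | 2, alpha p_A_i + (1 - alpha) p_B_i)` over
#' `alpha` in `[0, 1]` (bounded 1-D optimization, tolerance 1e-8), the
#' supervised K = 2 model with fixed reference allele frequencies. Standard
#' errors come from the observed Fisher information at the optimum.
#'
#' @param panel a [genotype_panel()].
#' @param refA_freqs,refB_freqs reference allele-frequency vectors aligned
#'   with the panel's variants (clamped to `[eps, 1 - eps]`).
#' @param samples sample ids to estimate (default: all).
#' @param eps clamping constant (default 1e-6).
#' @param tol optimizer tolerance.
#' @return data.frame: sample, alpha, se, n_snps; `method` attribute
#'   `"supervised_ml"`.
#' @export
supervised_admixture <- function(panel, refA_freqs, refB_freqs,
                                 samples = NULL, eps = 1e-6, tol = 1e-8) {
  pA <- pmin(pmax(refA_freqs, eps), 1 - eps)
  pB <- pmin(pmax(refB_freqs, eps), 1 - eps)
  stopifnot(length(pA) == nrow(panel$variants),
            length(pB) == nrow(panel$variants))
  if (all(abs(pA - pB) < 1e-12))
    stop("no informative SNPs: reference frequencies are identical")
  if (is.null(samples)) samples <- panel$samples$id
  res <- lapply(samples, function(sid) {
    g <- panel$geno[, sample_index(panel, sid)]
    use <- !is.na(g)
    gg <- as.numeric(g[use]); qa <- pA[use]; qb <- pB[use]
    nll <- function(alpha) {
      pm <- alpha * qa + (1 - alpha) * qb
      -sum(gg * log(pm) + (2 - gg) * log1p(-pm))
    }
    opt <- stats::optimize(nll, c(0, 1), tol = tol)
    ah <- opt$minimum
    pm <- ah * qa + (1 - ah) * qb
    info <- sum((qa - qb)^2 * (gg / pm^2 + (2 - gg) / (1 - pm)^2))
    data.frame(sample = sid, alpha = ah,
               se = if (info > 0) 1 / sqrt(info) else NA_real_,
               n_snps = sum(use), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "method") <- "supervised_ml"
  out
}

#' Correlation of two f3 profiles over a shared reference list
#'
#' Pearson correlation of two vectors of f3 estimates computed against the
#' same ordered list of reference populations, with a Fisher-z 95% CI, used
#' to ask whether two admixed populations drew their ancestry from
#' correlated sources.
#'
#' @param profile_x,profile_y numeric vectors of f3 estimates (same
#'   references, same order), length >= 3.
#' @param conf_level confidence level for the CI (default 0.95).
#' @return list(r, ci, p_value, n).
#' @export
f3_profile_correlation <- function(profile_x, profile_y, conf_level = 0.95) {
  stopifnot(length(profile_x) == length(profile_y), length(profile_x) >= 3)
  ct <- stats::cor.test(profile_x, profile_y, method = "pearson",
                        conf.level = conf_level)
  list(r = unname(ct$estimate),
       ci = if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA, NA),
       p_value = ct$p.value, n = length(profile_x))
}
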