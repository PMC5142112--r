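## Admixture dating from weighted LD decay: curve computation, exponential
## fitting with chromosome-jackknife errors, multiple-pulse scan, and
## generations-to-years conversion.

#' Weighted LD decay curve
#'
#' For every pair of SNPs (s, t) on the same chromosome with genetic distance
#' `d(s, t)` between `d_min_cm` and `d_max_cm`, accumulates
#' `cov(s, t) * w(s) * w(t)` into the distance bin of `d`, where the
#' covariance is the sample covariance of alt-allele dosages in the target
#' population (pairwise-complete observations) and
#' `w(u) = p_ref1(u) - p_ref2(u)` is the reference allele-frequency
#' contrast. In an admixed target this curve decays as `exp(-n d)` with `n`
#' the number of generations since admixture and `d` in Morgans.
#' Cross-chromosome pairs are not used; per-chromosome accumulators are kept
#' so leave-one-chromosome-out curves are available for the jackknife.
#'
#' @param panel a [genotype_panel()] with genetic-map coordinates (attach
#'   with [attach_map()] or pass `map`).
#' @param target target (admixed) population name; needs >= 4 diploids.
#' @param ref1,ref2 reference population names.
#' @param map optional [genetic_map()] to attach first.
#' @param bin_cm bin width in cM (default 0.1).
#' @param d_min_cm,d_max_cm distance range in cM (defaults 0.5 and 30; the
#'   lower cutoff suppresses background LD).
#' @return An object of class `weighted_ld_curve` with a `bins` data.frame
#'   (`bin_cm` centers, `value`, `n_pairs`) and per-chromosome accumulators.
#' @export
weighted_ld_curve <- function(panel, target, ref1, ref2, map = NULL,
                              bin_cm = 0.1, d_min_cm = 0.5, d_max_cm = 30) {
  if (!is.null(map)) panel <- attach_map(panel, map)
  if (anyNA(panel$variants$cm))
    stop("missing genetic map: attach a map before computing the curve")
  tgt <- panel$samples$id[panel$samples$pop == target]
  if (length(tgt) < 4) stop("target population needs >= 4 diploids")
  fr <- allele_freqs(panel, c(ref1, ref2))
  w_all <- fr$p[, ref1] - fr$p[, ref2]
  chroms <- unique(panel$variants$chrom)
  nb <- ceiling((d_max_cm - d_min_cm) / bin_cm)
  sums <- matrix(0, nb, length(chroms), dimnames = list(NULL, chroms))
  cnts <- matrix(0, nb, length(chroms), dimnames = list(NULL, chroms))
  gmat <- panel$geno[, sample_index(panel, tgt), drop = FALSE]
  storage.mode(gmat) <- "double"
  for (ci in seq_along(chroms)) {
    rows <- which(panel$variants$chrom == chroms[ci] & !is.na(w_all))
    if (length(rows) < 2) next
    X <- gmat[rows, , drop = FALSE]
    C <- if (anyNA(X)) {
      stats::cov(t(X), use = "pairwise.complete.obs")
    } else {
      tcrossprod(X - rowMeans(X)) / (ncol(X) - 1)
    }
    w <- w_all[rows]
    M <- C * tcrossprod(w)
    cm <- panel$variants$cm[rows]
    Dm <- abs(outer(cm, cm, "-"))
    ut <- upper.tri(Dm)
    sel <- ut & Dm >= d_min_cm & Dm <= d_max_cm & !is.na(M)
    if (!any(sel)) next
    bi <- pmin(floor((Dm[sel] - d_min_cm) / bin_cm) + 1L, nb)
    acc <- rowsum(M[sel], bi)
    tmp <- numeric(nb)
    tmp[as.integer(rownames(acc))] <- acc[, 1]
    sums[, ci] <- sums[, ci] + tmp
    cnts[, ci] <- cnts[, ci] + tabulate(bi, nbins = nb)
  }
  if (sum(cnts) == 0) stop("no SNP pairs in distance range")
  value <- ifelse(rowSums(cnts) > 0, rowSums(sums) / rowSums(cnts), NA_real_)
  centers <- d_min_cm + (seq_len(nb) - 0.5) * bin_cm
  structure(list(bins = data.frame(bin_cm = centers, value = value,
                                   n_pairs = rowSums(cnts)),
                 chrom_sums = sums, chrom_counts = cnts,
                 bin_width_cm = bin_cm, d_min_cm = d_min_cm,
                 d_max_cm = d_max_cm, target = target,
                 refs = c(ref1, ref2), chroms = chroms),
            class = "weighted_ld_curve")
}

#' @export
print.weighted_ld_curve <- function(x, ...) {
  cat(sprintf("weighted_ld_curve: %s with refs (%s, %s); %d bins of %.2f cM in [%.2f, %.2f] cM\n",
              x$target, x$refs[1], x$refs[2], nrow(x$bins), x$bin_width_cm,
              x$d_min_cm, x$d_max_cm))
  invisible(x)
}

## leave-one-chromosome-out curve values
loo_curve <- function(curve, drop_chrom) {
  keep <- setdiff(colnames(curve$chrom_sums), drop_chrom)
  s <- rowSums(curve$chrom_sums[, keep, drop = FALSE])
  n <- rowSums(curve$chrom_counts[, keep, drop = FALSE])
  ifelse(n > 0, s / n, NA_real_)
}

exp_model_formula <- function(k) {
  terms <- paste0("A", seq_len(k), " * exp(-n", seq_len(k), " * d)")
  stats::as.formula(paste("y ~", paste(c(terms, "c0"), collapse = " + ")))
}

fit_exp_once <- function(d, y, k, n_start, A_start, c_start, w = NULL) {
  start <- c(stats::setNames(as.list(A_start), paste0("A", seq_len(k))),
             stats::setNames(as.list(n_start), paste0("n", seq_len(k))),
             list(c0 = c_start))
  lower <- c(rep(0, k), rep(1e-3, k), -Inf)
  if (is.null(w)) w <- rep(1, length(d))
  fo <- exp_model_formula(k)
  environment(fo) <- environment()   # so nls finds the local weight vector
  tryCatch(
    minpack.lm::nlsLM(fo, data = data.frame(d = d, y = y),
                      start = start, lower = lower, weights = w,
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
}

## multi-start k-exponential + offset weighted least squares (weights:
## pair counts per bin, approximately inverse-variance); returns the best
## fit or NULL
fit_exp_multistart <- function(d, y, k, n_grid, w = NULL) {
  combos <- if (k == 1) lapply(n_grid, function(x) x) else
    utils::combn(n_grid, k, simplify = FALSE)
  amp0 <- max(diff(range(y)), max(abs(y)), 1e-12)
  best <- NULL; best_rss <- Inf
  for (ns in combos) {
    fit <- fit_exp_once(d, y, k, sort(unlist(ns), decreasing = TRUE),
                        rep(amp0 / k, k), min(y), w)
    if (is.null(fit)) next
    rss <- sum(stats::weights(fit) * stats::residuals(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  best
}

sorted_components <- function(co, k) {
  A <- co[paste0("A", seq_len(k))]
  n <- co[paste0("n", seq_len(k))]
  o <- order(-n)
  list(A = unname(A[o]), n = unname(n[o]), c0 = unname(co["c0"]))
}

#' Fit an exponential-decay admixture-date model to a weighted LD curve
#'
#' Nonlinear least squares of `sum_j A_j exp(-n_j d) + c` to the binned
#' curve, with `d` in Morgans, so `n_j` is directly the age of pulse `j` in
#' generations. Initialization is multi-start over a grid of decay rates;
#' standard errors of rates and amplitudes come from delete-one-chromosome
#' jackknife refits. Components are reported oldest (largest `n`) first.
#'
#' @param curve a [weighted_ld_curve()].
#' @param k number of exponential components (>= 1).
#' @param gen_time years per generation used for the years conversion
#'   (default 30).
#' @param n_grid multi-start grid of decay rates in generations.
#'   Bins are weighted by their pair counts (approximately inverse
#'   variance) during fitting.
#' @param jackknife logical; compute leave-one-chromosome-out errors.
#' @return An object of class `admixture_date_fit`: `k`, `components`
#'   (data.frame: A, se_A, z_amp, n_gen, se_n, years, se_years), `c0`,
#'   `rss`, `n_bins`.
#' @export
fit_decay <- function(curve, k = 1, gen_time = 30,
                      n_grid = c(5, 15, 45, 135, 400, 1200), jackknife = TRUE) {
  stopifnot(k >= 1)
  use <- !is.na(curve$bins$value)
  d <- curve$bins$bin_cm[use] / 100
  y <- curve$bins$value[use]
  if (length(y) < 2 * k + 1)
    stop("need at least ", 2 * k + 1, " informative bins for k = ", k)
  wts <- curve$bins$n_pairs[use]
  fit <- fit_exp_multistart(d, y, k, n_grid, wts)
  if (is.null(fit))
    stop("decay fit did not converge for k = ", k,
         " after all multi-start initializations (", length(y), " bins, ",
         "value range [", min(y), ", ", max(y), "])")
  full <- sorted_components(stats::coef(fit), k)
  jk_n <- jk_A <- NULL
  if (jackknife && length(curve$chroms) >= 2) {
    reps <- lapply(curve$chroms, function(ch) {
      yv <- loo_curve(curve, ch)[use]
      okb <- !is.na(yv)
      if (sum(okb) < 2 * k + 1) return(NULL)
      wv <- rowSums(curve$chrom_counts[, setdiff(curve$chroms, ch),
                                       drop = FALSE])[use][okb]
      f1 <- fit_exp_once(d[okb], yv[okb], k, full$n, full$A, full$c0, wv)
      if (is.null(f1)) f1 <- fit_exp_multistart(d[okb], yv[okb], k, n_grid, wv)
      if (is.null(f1)) return(NULL)
      sorted_components(stats::coef(f1), k)
    })
    reps <- Filter(Negate(is.null), reps)
    if (length(reps) >= 2) {
      jk_n <- do.call(rbind, lapply(reps, `[[`, "n"))
      jk_A <- do.call(rbind, lapply(reps, `[[`, "A"))
    }
  }
  jack_se <- function(mat) {
    if (is.null(mat)) return(rep(NA_real_, k))
    m <- nrow(mat)
    sqrt((m - 1) / m * colSums(sweep(mat, 2, colMeans(mat))^2))
  }
  se_n <- jack_se(jk_n); se_A <- jack_se(jk_A)
  comp <- data.frame(A = full$A, se_A = se_A,
                     z_amp = ifelse(is.na(se_A) | se_A == 0, NA_real_,
                                    abs(full$A) / se_A),
                     n_gen = full$n, se_n = se_n,
                     years = full$n * gen_time,
                     se_years = se_n * gen_time)
  structure(list(k = k, components = comp, c0 = full$c0,
                 rss = sum(stats::residuals(fit)^2),
                 n_bins = length(y), gen_time = gen_time,
                 target = curve$target, refs = curve$refs),
            class = "admixture_date_fit")
}

#' @export
print.admixture_date_fit <- function(x, ...) {
  cat("admixture_date_fit: k =", x$k, "\n")
  if (x$k > 0)
    for (i in seq_len(nrow(x$components))) {
      cc <- x$components[i, ]
      cat(sprintf("  pulse %d: %.1f generations (SE %.1f) = %.0f years; amplitude Z = %.2f\n",
                  i, cc$n_gen, cc$se_n, cc$years,
                  ifelse(is.na(cc$z_amp), 0, cc$z_amp)))
    }
  cat(sprintf("  offset = %.3g, rss = %.3g over %d bins\n",
              x$c0, x$rss, x$n_bins))
  invisible(x)
}

#' Scan over the number of admixture pulses (MALDER-style)
#'
#' Fits k = 1..k_max exponentials and selects the largest k for which every
#' amplitude is significant by the chromosome jackknife (|Z| >= `z_min`;
#' 2.58 corresponds to a two-sided p < 0.01). k = 0 (no significant
#' admixture LD) is a valid outcome and is returned as a constant-only fit.
#'
#' @param curve a [weighted_ld_curve()].
#' @param k_max maximum number of pulses to try (default 3).
#' @param z_min amplitude significance threshold (default 2.58).
#' @param gen_time years per generation.
#' @return An `admixture_date_fit` with `k` set to the selected number of
#'   pulses (0 when none is significant) and a `scan` element recording all
#'   attempted fits.
#' @export
malder_scan <- function(curve, k_max = 3, z_min = 2.58, gen_time = 30) {
  fits <- list()
  best <- NULL
  for (k in seq_len(k_max)) {
    f <- tryCatch(fit_decay(curve, k, gen_time = gen_time),
                  error = function(e) NULL)
    fits[[k]] <- f
    if (is.null(f)) next
    zs <- f$components$z_amp
    ok <- all(!is.na(zs)) && all(zs >= z_min) && all(f$components$n_gen > 0)
    if (ok) best <- f
  }
  if (is.null(best)) {
    use <- !is.na(curve$bins$value)
    y <- curve$bins$value[use]
    best <- structure(list(k = 0, components = data.frame(
      A = numeric(0), se_A = numeric(0), z_amp = numeric(0),
      n_gen = numeric(0), se_n = numeric(0), years = numeric(0),
      se_years = numeric(0)),
      c0 = mean(y), rss = sum((y - mean(y))^2), n_bins = length(y),
      gen_time = gen_time, target = curve$target, refs = curve$refs),
      class = "admixture_date_fit")
  }
  best$scan <- fits
  best
}

#' Convert an admixture age from generations to years
#' @param n age in generations.
#' @param gen_time years per generation (default 30).
#' @return `n * gen_time` years.
#' @export
generations_to_years <- function(n, gen_time = 30) {
  stopifnot(all(n >= 0))
  n * gen_time
}
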