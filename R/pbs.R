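## Population branch statistic selection scan with Hudson FST, plus the
## neutral post-admixture allele-frequency expectation used to interpret
## candidate hits in admixed populations.

#' Hudson's FST estimator
#'
#' Per-SNP numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' denominator `p1(1-p2) + p2(1-p1)`; the set-level FST is the ratio of
#' averages (sums), which is robust to unequal sample sizes. Negative
#' per-SNP numerators are retained in the sums.
#'
#' @param p1,p2 allele-frequency vectors.
#' @param n1,n2 chromosome counts (vectors or scalars); must be >= 2.
#' @return list(num, den, fst) with per-SNP terms and the ratio-of-sums FST.
#' @export
hudson_fst <- function(p1, n1, p2, n2) {
  n1 <- rep_len(n1, length(p1)); n2 <- rep_len(n2, length(p2))
  stopifnot(length(p1) == length(p2))
  if (any(n1 < 2 | n2 < 2, na.rm = TRUE))
    stop("Hudson FST needs >= 2 chromosomes per population")
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (sum(den, na.rm = TRUE) == 0) stop("FST undefined: zero denominator")
  list(num = num, den = den,
       fst = sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE))
}

#' Branch-length transform of FST
#'
#' `T = -log(1 - FST)`, with FST clamped into `[0, 0.999999]` so the
#' transform stays finite; the population branch statistic is built from
#' these per-pair branch lengths.
#'
#' @param fst FST values.
#' @return Branch lengths `T >= 0`.
#' @export
fst_to_T <- function(fst) {
  -log(1 - pmin(pmax(fst, 0), 0.999999))
}

#' Population branch statistic scan
#'
#' For each variant (or window of variants), computes Hudson FST for the
#' three population pairs, transforms them to branch lengths
#' `T = -log(1 - FST)` and reports the focal branch length
#' `PBS = (T_fs + T_fo - T_so) / 2`, the allele-frequency change specific to
#' the focal population since its divergence from the sister. Candidates are
#' variants above the given quantile of the PBS distribution.
#'
#' @param x a [freq_table()] or a [genotype_panel()] (frequencies are then
#'   computed from the panel's population labels).
#' @param focal,sister,outgroup population names (must be distinct).
#' @param window_snps optional window size in SNPs; `NULL` (default) scans
#'   per SNP. Windowed FST uses the ratio of averages within each window.
#' @param percentile candidate threshold quantile (default 0.95).
#' @param normalize divide each pairwise `T` by its genome-wide median
#'   before forming PBS (a long-term-size normalization; off by default and
#'   reported as this package's own interpretation).
#' @return data.frame of class `pbs_result`: chrom, pos (or window index),
#'   fst and T per pair, pbs, pct_rank, candidate flag.
#' @export
pbs_scan <- function(x, focal, sister, outgroup, window_snps = NULL,
                     percentile = 0.95, normalize = FALSE) {
  if (length(unique(c(focal, sister, outgroup))) != 3)
    stop("focal, sister and outgroup must be three distinct populations")
  freqs <- if (inherits(x, "genotype_panel"))
    allele_freqs(x, c(focal, sister, outgroup)) else x
  ok <- complete_snps(freqs, c(focal, sister, outgroup), min_n = 2L)
  if (!any(ok)) stop("no SNPs with >= 2 chromosomes in all three populations")
  p <- freqs$p[ok, , drop = FALSE]; n <- freqs$n[ok, , drop = FALSE]
  v <- freqs$variants
  chrom <- if (!is.null(v)) v$chrom[ok] else rep("chr1", sum(ok))
  pos <- if (!is.null(v)) v$pos[ok] else seq_len(sum(ok))
  pair <- function(a, b) hudson_fst(p[, a], n[, a], p[, b], n[, b])
  fs <- pair(focal, sister); fo <- pair(focal, outgroup)
  so <- pair(sister, outgroup)
  ## per-SNP/window ratio of averages; a zero denominator (all populations
  ## of the pair monomorphic) carries no differentiation and scores FST = 0
  ratio <- function(h, idx) {
    vapply(idx, function(i) {
      dn <- sum(h$den[i])
      if (dn == 0) 0 else sum(h$num[i]) / dn
    }, numeric(1))
  }
  if (is.null(window_snps)) {
    idx <- as.list(seq_len(sum(ok)))
    out <- data.frame(chrom = chrom, pos = pos)
  } else {
    if (any(table(chrom) < window_snps))
      stop("window larger than a chromosome's SNP count")
    grp <- stats::ave(seq_along(chrom), chrom,
                      FUN = function(i) (seq_along(i) - 1) %/% window_snps)
    key <- paste(chrom, grp)
    idx <- split(seq_along(key), factor(key, levels = unique(key)))
    out <- data.frame(
      chrom = vapply(idx, function(i) chrom[i[1]], ""),
      pos = vapply(idx, function(i) pos[i[1]], numeric(1)),
      end = vapply(idx, function(i) pos[i[length(i)]], numeric(1)),
      n_snps = lengths(idx))
  }
  out$fst_fs <- ratio(fs, idx); out$fst_fo <- ratio(fo, idx)
  out$fst_so <- ratio(so, idx)
  t_fs <- fst_to_T(out$fst_fs); t_fo <- fst_to_T(out$fst_fo)
  t_so <- fst_to_T(out$fst_so)
  if (normalize) {
    t_fs <- t_fs / stats::median(t_fs, na.rm = TRUE)
    t_fo <- t_fo / stats::median(t_fo, na.rm = TRUE)
    t_so <- t_so / stats::median(t_so, na.rm = TRUE)
  }
  out$T_fs <- t_fs; out$T_fo <- t_fo; out$T_so <- t_so
  out$pbs <- (t_fs + t_fo - t_so) / 2
  r <- rank(out$pbs, na.last = "keep")
  out$pct_rank <- r / sum(!is.na(out$pbs))
  thr <- stats::quantile(out$pbs, percentile, na.rm = TRUE, names = FALSE)
  out$candidate <- !is.na(out$pbs) & out$pbs > thr
  attr(out, "config") <- list(focal = focal, sister = sister,
                              outgroup = outgroup, window_snps = window_snps,
                              percentile = percentile,
                              threshold = thr, normalize = normalize)
  class(out) <- c("pbs_result", "data.frame")
  out
}

#' Expected derived-allele frequency after admixture under neutrality
#'
#' If an admixed population draws a fraction `alpha` of its ancestry from a
#' source with derived-allele frequency `p_source` and the rest from a
#' background with frequency `p_background`, the neutral expectation for its
#' frequency is simply `alpha * p_source + (1 - alpha) * p_background`.
#' With `alpha = 0.30`, `p_source = 0.13`, `p_background = 0`, this gives
#' 0.039: an apparently selected allele at ~4% may need no selection at all.
#'
#' @param alpha admixture fraction in `[0, 1]`.
#' @param p_source,p_background derived-allele frequencies in `[0, 1]`.
#' @return Expected frequency in `[0, 1]`.
#' @export
neutral_daf_after_admixture <- function(alpha, p_source, p_background) {
  stopifnot(alpha >= 0, alpha <= 1, p_source >= 0, p_source <= 1,
            p_background >= 0, p_background <= 1)
  alpha * p_source + (1 - alpha) * p_background
}

#' Is an observed frequency compatible with neutral drift from an expectation?
#'
#' Simulates Wright-Fisher drift of the expected frequency for the given
#' number of generations at effective size `N_e`, followed by binomial
#' sampling of `n_chrom` chromosomes, and reports the central interval of
#' the simulated sample frequencies together with whether the observation
#' falls inside it.
#'
#' @param observed_freq observed sample frequency.
#' @param expected_freq neutral post-admixture expectation (e.g. from
#'   [neutral_daf_after_admixture()]).
#' @param n_chrom sampled chromosome count behind the observation.
#' @param generations generations of drift since admixture.
#' @param N_e diploid effective population size during drift.
#' @param reps Monte-Carlo replicates (default 10000).
#' @param level interval coverage (default 0.95).
#' @return list(compatible, interval, observed, expected).
#' @export
drift_compatible <- function(observed_freq, expected_freq, n_chrom,
                             generations, N_e, reps = 10000, level = 0.95) {
  stopifnot(n_chrom >= 1, generations >= 0, N_e >= 1)
  p <- rep(expected_freq, reps)
  n2 <- 2L * as.integer(N_e)
  if (generations > 0)
    for (g in seq_len(generations)) p <- stats::rbinom(reps, n2, p) / n2
  x <- stats::rbinom(reps, n_chrom, p) / n_chrom
  a <- (1 - level) / 2
  ci <- stats::quantile(x, c(a, 1 - a), names = FALSE)
  list(compatible = observed_freq >= ci[1] && observed_freq <= ci[2],
       interval = ci, observed = observed_freq, expected = expected_freq)
}
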