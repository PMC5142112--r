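## Heterozygosity metrics: per-individual rates over a mappable length,
## runs-of-homozygosity detection and exclusion, ancestry-segment
## heterozygosity, and the post-admixture heterozygosity experiment.

#' Heterozygosity configuration
#'
#' @param mappable_bp denominator length in bp. The default (2.17e9) is the
#'   uniquely mappable human autosomal length used for real-data runs; for
#'   simulated panels pass the simulated genome length.
#' @param roh_min_bp minimum run-of-homozygosity span (default 2 Mb).
#' @param roh_max_het heterozygous calls tolerated inside a run (default 0).
#' @export
het_config <- function(mappable_bp = 2.17e9, roh_min_bp = 2e6,
                       roh_max_het = 0L) {
  stopifnot(mappable_bp > 0, roh_min_bp > 0, roh_max_het >= 0)
  structure(list(mappable_bp = mappable_bp, roh_min_bp = roh_min_bp,
                 roh_max_het = as.integer(roh_max_het)),
            class = "het_config")
}

#' Per-individual heterozygosity in hets per kb
#'
#' @param panel a [genotype_panel()].
#' @param sample sample id.
#' @param cfg a [het_config()].
#' @return Heterozygous-call count divided by `mappable_bp / 1000`.
#' @export
het_per_kb <- function(panel, sample, cfg = het_config()) {
  g <- panel$geno[, sample_index(panel, sample)]
  sum(g == 1L, na.rm = TRUE) / (cfg$mappable_bp / 1000)
}

#' Detect runs of homozygosity
#'
#' Maximal stretches of consecutive genotyped variants containing at most
#' `roh_max_het` heterozygous calls whose bp span (first to last variant,
#' half-open) exceeds `roh_min_bp`. Missing genotypes are ignored.
#'
#' @inheritParams het_per_kb
#' @return data.frame: sample, chrom, start, end (0-based half-open),
#'   n_sites.
#' @export
detect_roh <- function(panel, sample, cfg = het_config()) {
  si <- sample_index(panel, sample)
  out <- list()
  for (ch in unique(panel$variants$chrom)) {
    rows <- which(panel$variants$chrom == ch & !is.na(panel$geno[, si]))
    if (!length(rows)) next
    g <- panel$geno[rows, si]
    pos <- panel$variants$pos[rows]
    hets <- which(g == 1L)
    ## maximal runs holding hets i+1 .. i+k lie strictly between het i and
    ## het i+k+1 (sentinels 0 and length+1 close the chromosome ends)
    k <- cfg$roh_max_het
    m <- length(hets)
    bounds <- c(0L, hets, rep(length(g) + 1L, k + 1L))
    starts <- integer(0); ends <- integer(0)
    for (i in 0:max(0L, m - k)) {
      s <- bounds[i + 1L] + 1L
      e <- bounds[i + k + 2L] - 1L
      if (e >= s) { starts <- c(starts, s); ends <- c(ends, e) }
    }
    keep <- !duplicated(paste(starts, ends))
    starts <- starts[keep]; ends <- ends[keep]
    span <- pos[ends] - pos[starts] + 1L
    sel <- span > cfg$roh_min_bp
    if (any(sel))
      out[[ch]] <- data.frame(sample = sample, chrom = ch,
                              start = pos[starts[sel]] - 1L,
                              end = pos[ends[sel]],
                              n_sites = ends[sel] - starts[sel] + 1L,
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_sites = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Heterozygosity excluding runs of homozygosity
#'
#' Corrects the per-individual rate for recent inbreeding: heterozygous
#' calls outside ROH divided by the mappable length minus the total ROH
#' span.
#'
#' @inheritParams het_per_kb
#' @return Rate in hets per kb.
#' @export
het_excluding_roh <- function(panel, sample, cfg = het_config()) {
  roh <- detect_roh(panel, sample, cfg)
  denom_bp <- cfg$mappable_bp - sum(roh$end - roh$start)
  if (denom_bp <= 0) stop("entire mappable genome lies in ROH")
  si <- sample_index(panel, sample)
  in_roh <- rep(FALSE, nrow(panel$variants))
  for (i in seq_len(nrow(roh))) {
    in_roh <- in_roh | (panel$variants$chrom == roh$chrom[i] &
                          (panel$variants$pos - 1L) >= roh$start[i] &
                          (panel$variants$pos - 1L) < roh$end[i])
  }
  hets <- sum(panel$geno[!in_roh, si] == 1L, na.rm = TRUE)
  hets / (denom_bp / 1000)
}

#' Heterozygosity of diploid ancestry-segment classes
#'
#' Pools heterozygous calls and segment lengths over samples per diploid
#' class (e.g. AA / AE / EE) and reports the length-weighted rate for each;
#' `unassigned` segments are excluded. Classes with no assigned length get
#' `NA`.
#'
#' @param panel a [genotype_panel()].
#' @param mask an `ancestry_mask` (from [build_masks()] or
#'   [truth_to_mask()]).
#' @param classes classes to report (default the classes present, minus
#'   `unassigned`).
#' @return data.frame: class, n_hets, length_bp, het_per_kb.
#' @export
segment_het_by_ancestry <- function(panel, mask,
                                    classes = setdiff(unique(mask$class),
                                                      "unassigned")) {
  res <- lapply(classes, function(cl) {
    mm <- mask[mask$class == cl, , drop = FALSE]
    hets <- 0; len <- 0
    for (i in seq_len(nrow(mm))) {
      si <- match(mm$sample[i], panel$samples$id)
      if (is.na(si)) next
      hit <- panel$variants$chrom == mm$chrom[i] &
        (panel$variants$pos - 1L) >= mm$start[i] &
        (panel$variants$pos - 1L) < mm$end[i]
      hets <- hets + sum(panel$geno[hit, si] == 1L, na.rm = TRUE)
      len <- len + (mm$end[i] - mm$start[i])
    }
    data.frame(class = cl, n_hets = hets, length_bp = len,
               het_per_kb = if (len > 0) hets / (len / 1000) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Post-admixture heterozygosity experiment
#'
#' Simulates gene flow at each admixture fraction in `alpha_grid` from the
#' scenario's donor population into its recipient, lets the admixed
#' population mate randomly for `mate_generations`, and reports the mean and
#' SD of per-individual heterozygosity. When the donor has lower diversity
#' than the recipient (e.g. after an out-of-Africa-style bottleneck), the
#' mixed population's heterozygosity declines at high `alpha` even though
#' admixture initially adds between-population variation.
#'
#' @param scenario a preset name for [canned_scenarios()] or a
#'   [demography_config()] containing populations `African` (recipient) and
#'   `Eurasian` (donor).
#' @param alpha_grid admixture fractions to evaluate (0 = recipient
#'   baseline, 1 = donor baseline).
#' @param replicates simulation replicates per alpha (default 2).
#' @param mate_generations random-mating generations after the pulse
#'   (default 10).
#' @param n_sample diploids sampled per replicate (default 20).
#' @param seed base seed; replicate r at alpha index a uses
#'   `seed + 97 * a + r`.
#' @param genome optional [genome_config()] override.
#' @return data.frame: alpha, mean_het (hets/kb), sd_het, n_ind.
#' @export
het_admixture_experiment <- function(scenario = "ooa_bottleneck",
                                     alpha_grid = c(0, 0.25, 0.5, 1),
                                     replicates = 2, mate_generations = 10,
                                     n_sample = 20, seed = 1L,
                                     genome = NULL) {
  base <- if (is.character(scenario)) canned_scenarios(scenario, genome)
          else scenario
  if (!all(c("African", "Eurasian") %in% names(base$populations)))
    stop("scenario must contain African (recipient) and Eurasian (donor)")
  samp_gen <- max(vapply(base$events,
                         function(e) if (e$type == "sampling") e$gen else 0,
                         numeric(1)))
  gl <- base$genome$n_chrom * base$genome$chrom_bp
  cfg_for <- function(alpha, sd) {
    ev <- Filter(function(e) e$type != "sampling", base$events)
    ## keep the brief random-mating stage small: het loss over
    ## mate_generations at N = 500 is ~1%, negligible against the effect
    ev <- c(ev, list(ev_bottleneck("African",
                                   samp_gen - mate_generations,
                                   samp_gen + 1, 500)))
    if (alpha > 0 && alpha < 1)
      ev <- c(ev, list(ev_pulse("African", "Eurasian", alpha,
                                samp_gen - mate_generations)))
    target_pop <- if (alpha >= 1) "Eurasian" else "African"
    ev <- c(ev, list(ev_sampling(target_pop, n_sample, samp_gen)))
    demography_config(base$populations, ev, base$genome,
                      base$generation_time, seed = sd,
                      outgroup = FALSE)
  }
  cfgh <- het_config(mappable_bp = gl)
  rows <- lapply(seq_along(alpha_grid), function(a) {
    hets <- unlist(lapply(seq_len(replicates), function(r) {
      sim <- simulate_panel(cfg_for(alpha_grid[a],
                                    seed + 97L * a + r))
      vapply(sim$panel$samples$id, function(sid)
        het_per_kb(sim$panel, sid, cfgh), numeric(1))
    }))
    data.frame(alpha = alpha_grid[a], mean_het = mean(hets),
               sd_het = stats::sd(hets), n_ind = length(hets))
  })
  do.call(rbind, rows)
}
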