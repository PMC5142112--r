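## Shared fixtures: all built in code, no files on disk.

## Small handcrafted panel: 5 variants x 4 samples across two populations,
## with one missing call and known dosages.
toy_panel <- function() {
  variants <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 250L, 900L, 50L, 700L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "C"),
    aa = c("A", "C", "A", "T", "C"),
    stringsAsFactors = FALSE)
  samples <- data.frame(id = c("s1", "s2", "s3", "s4"),
                        pop = c("P1", "P1", "P2", "P2"),
                        stringsAsFactors = FALSE)
  geno <- matrix(c(0L, 1L, 2L, 1L,
                   1L, 1L, 0L, 2L,
                   2L, 0L, NA, 1L,
                   0L, 0L, 1L, 1L,
                   1L, 2L, 2L, 0L), nrow = 5, byrow = TRUE)
  genotype_panel(variants, samples, geno)
}

## Phased version used by haplotype-level code.
toy_phased_panel <- function() {
  p <- toy_panel()
  g <- p$geno
  g[is.na(g)] <- 0L
  hap <- matrix(0L, nrow(g), 2L * ncol(g))
  for (j in seq_len(ncol(g))) {
    hap[, 2L * j - 1L] <- as.integer(g[, j] >= 1L)
    hap[, 2L * j] <- as.integer(g[, j] == 2L)
  }
  genotype_panel(p$variants, p$samples, g, hap)
}

## Two populations drifting apart with no gene flow; sampling n diploids.
two_pop_cfg <- function(t_gen = 100, N = 500, n = 25, seed = 1L) {
  demography_config(
    populations = c(A = N, B = N),
    events = list(
      ev_split("A", "B", 0),
      ev_sampling("A", n, t_gen), ev_sampling("B", n, t_gen)),
    seed = seed)
}

## Frequency-level admixture scenario: X receives a pulse from Src1; Src2 is
## the other ancestry source; SisterSrc shares the Src1 stem for f4 ratios.
pulse_freq_cfg <- function(alpha, seed = 1L, n_samp = 25,
                           post_gens = 10) {
  demography_config(
    populations = c(Anc = 5000, Src1 = 1000, Src2 = 1000, X = 1000,
                    SisterSrc = 1000),
    events = list(
      ev_split("Anc", "Src1", 0), ev_split("Anc", "Src2", 0),
      ev_split("Src1", "SisterSrc", 150),
      ev_split("Src2", "X", 290 - post_gens),
      ev_pulse("X", "Src1", alpha, 300 - post_gens),
      ev_sampling("Src1", n_samp, 300), ev_sampling("Src2", n_samp, 300),
      ev_sampling("X", n_samp, 300), ev_sampling("SisterSrc", n_samp, 300)),
    seed = seed)
}

## No-admixture version of the same topology.
null_freq_cfg <- function(seed = 1L, n_samp = 25) {
  demography_config(
    populations = c(Anc = 5000, Src1 = 1000, Src2 = 1000, X = 1000,
                    SisterSrc = 1000),
    events = list(
      ev_split("Anc", "Src1", 0), ev_split("Anc", "Src2", 0),
      ev_split("Src1", "SisterSrc", 150),
      ev_split("Src2", "X", 280),
      ev_sampling("Src1", n_samp, 300), ev_sampling("Src2", n_samp, 300),
      ev_sampling("X", n_samp, 300), ev_sampling("SisterSrc", n_samp, 300)),
    seed = seed)
}

## Haplotype-level admixture scenario with well-diverged sources; the pulse
## happens `gens_ago` generations before sampling.
pulse_panel_cfg <- function(alpha = 0.3, gens_ago = 100, N_rec = 1000,
                            n_chrom = 10, chrom_bp = 2e7, n_snps = 20000,
                            n_rec = 50, seed = 42L) {
  end <- 500 + gens_ago
  demography_config(
    populations = c(African = 10000, Eurasian = 1000, Recipient = N_rec),
    events = list(
      ev_split("African", "Eurasian", 0),
      ev_bottleneck("Eurasian", 0, 200, 500),
      ev_split("African", "Recipient", 450),
      ev_pulse("Recipient", "Eurasian", alpha, 500),
      ev_sampling("Recipient", n_rec, end),
      ev_sampling("African", 30, end),
      ev_sampling("Eurasian", 30, end)),
    genome = genome_config(n_chrom = n_chrom, chrom_bp = chrom_bp,
                           n_snps = n_snps),
    seed = seed)
}

## A small admixed panel reused by local-ancestry and heterozygosity tests
## (computed once per test run).
small_admixed_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- demography_config(
        populations = c(African = 2000, Eurasian = 800, Recipient = 800),
        events = list(
          ev_split("African", "Eurasian", 0),
          ev_bottleneck("Eurasian", 0, 150, 300),
          ev_split("African", "Recipient", 280),
          ev_pulse("Recipient", "Eurasian", 0.3, 300),
          ev_sampling("Recipient", 20, 310),
          ev_sampling("African", 20, 310),
          ev_sampling("Eurasian", 20, 310)),
        genome = genome_config(n_chrom = 4, chrom_bp = 2e7, n_snps = 8000),
        seed = 7L)
      cache <<- simulate_panel(cfg)
    }
    cache
  }
})
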