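## construct a synthetic curve object with known bin values spread over a
## given number of identical "chromosomes" (so the jackknife has units)
synthetic_curve <- function(values, centers, n_chrom = 4, n_pairs = 1000) {
  sums <- matrix(rep(values * n_pairs, n_chrom), ncol = n_chrom,
                 dimnames = list(NULL, paste0("chr", seq_len(n_chrom))))
  cnts <- matrix(n_pairs, length(values), n_chrom,
                 dimnames = list(NULL, paste0("chr", seq_len(n_chrom))))
  structure(list(
    bins = data.frame(bin_cm = centers, value = values,
                      n_pairs = n_pairs * n_chrom),
    chrom_sums = sums, chrom_counts = cnts,
    bin_width_cm = diff(centers[1:2]), d_min_cm = min(centers),
    d_max_cm = max(centers), target = "X", refs = c("R1", "R2"),
    chroms = colnames(sums)), class = "weighted_ld_curve")
}

test_that("noiseless single-exponential inversion recovers the rate", {
  centers <- seq(0.55, 30, by = 0.75)
  d <- centers / 100
  y <- 0.01 * exp(-100 * d) + 0.001
  fit <- fit_decay(synthetic_curve(y, centers), k = 1)
  expect_equal(fit$components$n_gen, 100, tolerance = 1e-3)
  expect_equal(fit$components$A, 0.01, tolerance = 1e-3)
  expect_equal(fit$c0, 0.001, tolerance = 1e-3)
  expect_equal(fit$components$years, fit$components$n_gen * 30)
})

test_that("two well-separated exponentials are both recovered", {
  centers <- seq(0.55, 40, by = 0.25)
  d <- centers / 100
  y <- 0.01 * exp(-300 * d) + 0.001 * exp(-30 * d) + 2e-4
  fit <- fit_decay(synthetic_curve(y, centers), k = 2)
  expect_equal(fit$components$n_gen[1], 300, tolerance = 0.3)
  expect_equal(fit$components$n_gen[2], 30, tolerance = 0.3)
})

test_that("the fitted rate is invariant to scaling the curve", {
  centers <- seq(0.55, 25, by = 0.5)
  y <- 0.005 * exp(-80 * centers / 100) + 5e-4
  f1 <- fit_decay(synthetic_curve(y, centers), 1, jackknife = FALSE)
  f2 <- fit_decay(synthetic_curve(7.3 * y, centers), 1, jackknife = FALSE)
  expect_equal(f1$components$n_gen, f2$components$n_gen, tolerance = 1e-6)
  expect_equal(f2$components$A / f1$components$A, 7.3, tolerance = 1e-6)
})

test_that("curve weights are bilinear: swapping references flips nothing", {
  sim <- small_admixed_sim()
  c12 <- weighted_ld_curve(sim$panel, "Recipient", "Eurasian", "African")
  c21 <- weighted_ld_curve(sim$panel, "Recipient", "African", "Eurasian")
  ## w -> -w multiplies the curve by (-1)^2 = 1
  expect_equal(c12$bins$value, c21$bins$value)
  ## identical references make every weight zero
  c11 <- weighted_ld_curve(sim$panel, "Recipient", "African", "African")
  expect_true(all(c11$bins$value[!is.na(c11$bins$value)] == 0))
})

test_that("a two-SNP toy curve matches a longhand computation", {
  ## 6 target diploids, 2 SNPs 1.05 cM apart; references fixed by hand
  geno <- matrix(c(0L, 1L, 2L, 1L, 0L, 2L,
                   1L, 1L, 2L, 0L, 0L, 2L), nrow = 2, byrow = TRUE)
  panel <- genotype_panel(
    data.frame(chrom = "chr1", pos = c(1000000L, 2050000L), ref = "A",
               alt = "G"),
    data.frame(id = sprintf("t%d", 1:6), pop = "T"), geno)
  refg <- matrix(c(2L, 2L, 0L, 0L,
                   2L, 0L, 0L, 0L), nrow = 2, byrow = TRUE)
  refp <- genotype_panel(
    panel$variants,
    data.frame(id = sprintf("r%d", 1:4), pop = c("R1", "R1", "R2", "R2")),
    refg)
  both <- merge_panels(panel, refp)
  both <- attach_map(both, uniform_map("chr1", 3e6))
  cv <- weighted_ld_curve(both, "T", "R1", "R2", bin_cm = 0.5,
                          d_min_cm = 0.5, d_max_cm = 2)
  ## hand values: cov of the target dosage rows, weights from ref freqs
  x <- geno[1, ]; y <- geno[2, ]
  covxy <- sum((x - mean(x)) * (y - mean(y))) / 5
  w1 <- 1 - 0; w2 <- 0.5 - 0
  hand <- covxy * w1 * w2
  filled <- which(cv$bins$n_pairs > 0)
  expect_length(filled, 1L)
  expect_equal(cv$bins$value[filled], hand)
  ## the pair sits in the bin covering 1.05 cM
  expect_equal(cv$bins$bin_cm[filled], 1.25)
})

test_that("curve computation requires a map and enough target diploids", {
  p <- toy_phased_panel()
  expect_error(weighted_ld_curve(p, "P1", "P2", "P2"), "missing genetic map")
  p <- attach_map(p, uniform_map(c("chr1", "chr2"), 1e6))
  expect_error(weighted_ld_curve(p, "P1", "P2", "P2"), "4 diploids")
})

test_that("generations convert to years at 30 years per generation", {
  expect_equal(generations_to_years(100), 3000)
  expect_equal(generations_to_years(0), 0)
  expect_equal(generations_to_years(c(95, 117)), c(2850, 3510))
  expect_equal(generations_to_years(100, gen_time = 25), 2500)
  expect_error(generations_to_years(-1))
})
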