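test_that("window partition tiles the map in genetic distance", {
  map <- uniform_map("chr1", 1e7)   # 10 cM
  w <- window_partition(map, size_cm = 1)
  expect_equal(nrow(w), 10L)
  expect_equal(w$start_cm, 0:9)
  expect_equal(w$end_cm, 1:10)
  ## bp spans are contiguous, half-open, and cover the mapped range
  expect_equal(w$start_bp[-1], w$end_bp[-nrow(w)])
  ## absent chromosome gives zero windows
  expect_equal(nrow(window_partition(map, "chrX")), 0L)
  ## a short trailing window is kept
  w2 <- window_partition(uniform_map("chr1", 1.25e7), size_cm = 1)
  expect_equal(nrow(w2), 13L)
  expect_lt(w2$end_cm[13] - w2$start_cm[13], 1)
})

## a panel with two perfectly separated reference populations and one
## admixed-looking query: ancestry A carries ref allele, E carries alt
separated_panel <- function(nv = 60, n_ref = 6, seed = 1) {
  set.seed(seed)
  n_all <- 2 * n_ref + 2
  hapA <- matrix(rbinom(nv * n_ref * 2, 1, 0.1), nv)
  hapE <- matrix(rbinom(nv * n_ref * 2, 1, 0.9), nv)
  ## query: haplotype 1 pure A, haplotype 2 pure E
  hapQ <- cbind(rbinom(nv, 1, 0.1), rbinom(nv, 1, 0.9))
  hap <- cbind(hapA, hapE, hapQ)
  geno <- hap[, seq(1, ncol(hap), 2)] + hap[, seq(2, ncol(hap), 2)]
  panel <- genotype_panel(
    data.frame(chrom = "chr1", pos = seq_len(nv) * 1e5, ref = "A",
               alt = "G"),
    data.frame(id = c(sprintf("a%d", seq_len(n_ref)),
                      sprintf("e%d", seq_len(n_ref)), "q1"),
               pop = c(rep("PA", n_ref), rep("PE", n_ref), "Q")),
    geno, hap)
  attach_map(panel, uniform_map("chr1", nv * 1e5))
}

test_that("separated references give confident, correct haplotype calls", {
  panel <- separated_panel()
  wins <- window_partition(uniform_map("chr1", 6e6), size_cm = 1)
  model <- fit_reference_pca(panel, wins, c(A = "PA", E = "PE"))
  calls <- call_ancestry(model, panel, "q1")
  expect_equal(calls$post_A + calls$post_E, rep(1, nrow(calls)))
  h1 <- calls[calls$haplotype == 1, ]
  h2 <- calls[calls$haplotype == 2, ]
  expect_true(all(h1$label[h1$assigned] == "A"))
  expect_true(all(h2$label[h2$assigned] == "E"))
  expect_gt(mean(calls$assigned), 0.9)
  ## swapping the reference panels swaps labels but not assignment
  model_sw <- fit_reference_pca(panel, wins, c(A = "PE", E = "PA"))
  calls_sw <- call_ancestry(model_sw, panel, "q1")
  expect_equal(calls_sw$assigned, calls$assigned)
  expect_true(all(calls_sw$label[calls_sw$assigned] !=
                    calls$label[calls$assigned]))
})

test_that("indistinguishable references leave windows unassigned", {
  panel <- separated_panel()
  ## both "ancestries" point at the same reference population
  wins <- window_partition(uniform_map("chr1", 6e6), size_cm = 1)
  samples <- panel$samples
  samples$pop[samples$pop == "PE"] <- "PA2"
  ## rebuild with PE haplotypes replaced by more PA-like draws
  set.seed(2)
  nv <- nrow(panel$variants)
  hap <- panel$hap
  hap[, 13:24] <- rbinom(nv * 12, 1, 0.1)
  geno <- hap[, seq(1, ncol(hap), 2)] + hap[, seq(2, ncol(hap), 2)]
  p2 <- genotype_panel(panel$variants, samples, geno, hap)
  model <- fit_reference_pca(p2, wins, c(A = "PA", E = "PA2"))
  calls <- call_ancestry(model, p2, "q1")
  expect_lt(mean(calls$assigned), 0.3)
})

test_that("masks merge windows into diploid segments correctly", {
  calls <- data.frame(
    sample = "s", haplotype = rep(1:2, each = 4), chrom = "chr1",
    window = rep(1:4, 2),
    start_bp = rep(c(0, 10, 20, 30), 2), end_bp = rep(c(10, 20, 30, 40), 2),
    post_A = 0.99, post_E = 0.01,
    label = c("A", "A", "E", "E",  "A", "E", "E", "A"),
    posterior = 0.99,
    assigned = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  m <- build_masks(calls)
  expect_equal(m$class, c("AA", "AE", "EE", "unassigned"))
  expect_equal(m$start, c(0, 10, 20, 30))
  expect_equal(m$end, c(10, 20, 30, 40))
  ## all-A haplotypes collapse to one segment
  calls$label <- "A"; calls$assigned <- TRUE
  m2 <- build_masks(calls)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$class, "AA")
  expect_equal(m2$n_windows, 4L)
})

test_that("negative masking blanks exactly the masked half-open span", {
  panel <- separated_panel()
  mask <- data.frame(sample = "q1", chrom = "chr1",
                     start = 2e5, end = 4e5, class = "EE",
                     n_windows = 1, mean_posterior = 1)
  class(mask) <- c("ancestry_mask", "data.frame")
  out <- apply_negative_mask(panel, mask, "EE")
  qi <- match("q1", panel$samples$id)
  ## pos 3e5 and 4e5 are 0-based 299999. and 399999: both inside [2e5, 4e5)
  expect_true(all(is.na(out$geno[panel$variants$pos %in% c(3e5, 4e5), qi])))
  ## boundary: pos 2e5 is 0-based 199999 < start, keeps its call
  expect_false(is.na(out$geno[panel$variants$pos == 2e5, qi]))
  expect_false(is.na(out$geno[panel$variants$pos == 5e5, qi]))
  ## dropping a class the sample does not carry changes nothing
  out2 <- apply_negative_mask(panel, mask, "AA")
  expect_equal(out2$geno, panel$geno)
})

test_that("calls on simulated admixture recover tracts and alpha", {
  sim <- small_admixed_sim()
  wins <- window_partition(sim$map, size_cm = 1)
  model <- fit_reference_pca(sim$panel, wins, c(A = "African", E = "Eurasian"))
  rec <- sim$panel$samples$id[sim$panel$samples$pop == "Recipient"]
  calls <- call_ancestry(model, sim$panel, rec)
  ## accuracy of assigned windows against the true tract at the window center
  tr <- sim$truth$tracts
  lut <- c(Recipient = "A", Eurasian = "E")
  hit <- vapply(which(calls$assigned), function(i) {
    tt <- tr[tr$sample == calls$sample[i] &
               tr$haplotype == calls$haplotype[i] &
               tr$chrom == calls$chrom[i], ]
    mid <- (calls$start_bp[i] + calls$end_bp[i]) / 2
    calls$label[i] == lut[[tt$ancestry[findInterval(mid, tt$start)]]]
  }, logical(1))
  expect_gt(mean(hit), 0.9)
  ## mask-implied Eurasian fraction tracks the truth within 0.05
  mask <- build_masks(calls)
  len <- tapply(mask$end - mask$start, mask$class, sum)
  eur <- (2 * len[["EE"]] + len[["AE"]]) /
    (2 * (len[["AA"]] + len[["AE"]] + len[["EE"]]))
  truth <- ancestry_fraction(sim$truth, rec)[["Eurasian"]]
  expect_lt(abs(eur - truth), 0.05)
})
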