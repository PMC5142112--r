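test_that("VCF round-trip preserves dosages, positions and AA tags", {
  p <- toy_panel()
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(p, f)
  q <- read_vcf(f, pops = p$samples)
  expect_equal(unname(q$geno), unname(p$geno))
  expect_equal(q$variants$pos, p$variants$pos)
  expect_equal(q$variants$aa, p$variants$aa)
  expect_equal(q$samples$pop, p$samples$pop)

  ph <- toy_phased_panel()
  write_vcf(ph, f)
  q2 <- read_vcf(f)
  expect_false(is.null(q2$hap))
  expect_equal(unname(q2$hap), unname(ph$hap))
})

test_that("multiallelic VCF records are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1",
    "chr1\t200\t.\tC\tT,G\t.\tPASS\t.\tGT\t0/1\t0/2",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/0\t./."), f)
  expect_warning(p <- read_vcf(f), "1 multiallelic")
  expect_equal(nrow(p$variants), 2L)
  expect_equal(p$variants$pos, c(100L, 300L))
  expect_true(is.na(p$geno[2, 2]))
})

## independent enumeration oracle: conditional probability of each
## heterozygote count given the allele counts, by direct factorial arithmetic
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa; na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1)
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  pr <- vapply(hs, function(h) {
    exp(lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
          lgamma((na - h) / 2 + 1) + h * log(2) +
          lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  obs <- pr[hs == nAa]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

test_that("Hardy-Weinberg exact test agrees with enumeration", {
  expect_equal(hwe_exact_test(10, 0, 0), 1)      # monomorphic
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  expect_equal(hwe_exact_test(0, 50, 0), hwe_oracle(0, 50, 0))
  ## maximal-heterozygosity table is a deep tail
  expect_lt(hwe_exact_test(0, 50, 0), 1e-10)
  set.seed(4)
  for (i in 1:25) {
    cnt <- as.vector(stats::rmultinom(1, sample(5:80, 1), c(.4, .3, .3)))
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-10)
  }
})

test_that("qc_filter applies each rule and is idempotent", {
  p <- toy_panel()
  res <- qc_filter(p, qc_config(call_rate = 1, maf = 0.05, hwe_p = 1e-6))
  ## variant 3 has a missing call and fails the 100% call-rate rule
  expect_equal(res$report$n_removed[res$report$criterion == "call_rate"], 1L)
  expect_false(900L %in% res$panel$variants$pos)
  ## filtering again changes nothing
  res2 <- qc_filter(res$panel, qc_config(call_rate = 1, maf = 0.05,
                                         hwe_p = 1e-6))
  expect_equal(res2$panel$variants, res$panel$variants)
  expect_true(all(res2$report$n_removed == 0L))
  ## empty panel passes through
  emp <- subset_panel(p, variants = rep(FALSE, 5))
  rese <- qc_filter(emp)
  expect_equal(nrow(rese$panel$variants), 0L)
  expect_true(all(rese$report$n_removed == 0L))
})

test_that("merge_panels intersects, recodes flipped alleles, drops ambiguous", {
  a <- toy_panel()
  ## second panel: same variants but chr1:250 has ref/alt swapped, and an
  ## extra A/T site that must be dropped as strand-ambiguous
  v <- a$variants
  v$ref[2] <- "T"; v$alt[2] <- "C"
  v <- rbind(v, data.frame(chrom = "chr3", pos = 10L, ref = "A", alt = "T",
                           aa = NA, cm = NA))
  g <- rbind(a$geno, c(0L, 1L, 2L, 1L))
  g[2, ] <- 2L - a$geno[2, ]
  colnames(g) <- NULL
  b <- genotype_panel(v, data.frame(id = c("t1", "t2", "t3", "t4"),
                                    pop = "P3"), g)
  expect_warning(m <- merge_panels(a, b), "strand-ambiguous")
  expect_equal(nrow(m$variants), 5L)
  expect_equal(nrow(m$samples), 8L)
  ## flipped site recoded back: dosages of b's samples match a's originals
  expect_equal(unname(m$geno[m$variants$pos == 250L, 5:8]),
               unname(a$geno[2, ]))
  expect_error(merge_panels(a, a), "duplicate sample id")
})

test_that("genetic map interpolation is linear, exact at anchors, clamped", {
  map <- genetic_map(data.frame(chrom = "chr1",
                                pos = c(0, 1e6, 3e6),
                                cm = c(0, 1, 1.5)))
  expect_equal(interpolate_cm(map, "chr1", 1e6), 1)
  expect_equal(interpolate_cm(map, "chr1", 5e5), 0.5)
  expect_equal(interpolate_cm(map, "chr1", 2e6), 1.25)
  expect_equal(interpolate_cm(map, "chr1", 9e6), 1.5)  # beyond last anchor
  expect_error(interpolate_cm(map, "chr9", 1), "not in map")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_genetic_map(map, f)
  m2 <- read_genetic_map(f)
  expect_equal(m2$chrom[["chr1"]]$cm, map$chrom[["chr1"]]$cm)
  p <- attach_map(toy_panel(), uniform_map(c("chr1", "chr2"), 1e6))
  expect_equal(p$variants$cm, (p$variants$pos - 1) / (1e6 - 1))
})
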