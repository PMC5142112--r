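test_that("invalid demographic configurations are rejected by name", {
  expect_error(
    demography_config(c(A = 100), list(ev_sampling("B", 5, 10))),
    "unknown population B")
  expect_error(
    demography_config(c(A = 100, B = 100),
                      list(ev_split("A", "B", 0),
                           ev_pulse("B", "A", 1.2, 5),
                           ev_sampling("B", 5, 10))),
    "alpha must be in")
  expect_error(
    demography_config(c(A = 100, B = 100),
                      list(ev_sampling("A", 5, 10),
                           ev_split("A", "B", 20),
                           ev_sampling("B", 5, 30))),
    "after sampling")
})

test_that("same seed gives byte-identical VCF output", {
  cfg <- demography_config(
    populations = c(P = 200, Q = 200),
    events = list(ev_split("P", "Q", 0),
                  ev_pulse("Q", "P", 0.2, 20),
                  ev_sampling("P", 10, 30), ev_sampling("Q", 10, 30)),
    genome = genome_config(n_chrom = 2, chrom_bp = 5e6, n_snps = 800),
    seed = 5L)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(simulate_panel(cfg)$panel, f1)
  write_vcf(simulate_panel(cfg)$panel, f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  fs1 <- simulate_freqs(cfg, 500)
  fs2 <- simulate_freqs(cfg, 500)
  expect_identical(fs1$freqs$p, fs2$freqs$p)
})

test_that("truth tracts tile every haplotype and respect labels", {
  sim <- small_admixed_sim()
  tr <- sim$truth$tracts
  ## conservation: tract lengths sum to the chromosome length everywhere
  tot <- tapply(tr$end - tr$start,
                paste(tr$sample, tr$haplotype, tr$chrom), sum)
  expect_true(all(tot == 2e7))
  ## no overlaps: starts equal previous ends within each haplotype
  sp <- split(tr, paste(tr$sample, tr$haplotype, tr$chrom))
  ok <- vapply(sp, function(d) {
    d <- d[order(d$start), ]
    all(d$start[-1] == d$end[-nrow(d)]) && d$start[1] == 0
  }, logical(1))
  expect_true(all(ok))
  ## unadmixed populations carry only their own label
  afr <- sim$panel$samples$id[sim$panel$samples$pop == "African"]
  expect_true(all(tr$ancestry[tr$sample %in% afr] == "African"))
})

test_that("an alpha = 0 pulse is a no-flow event", {
  cfg <- demography_config(
    populations = c(P = 200, Q = 200),
    events = list(ev_split("P", "Q", 0),
                  ev_pulse("Q", "P", 0, 20),
                  ev_sampling("P", 8, 30), ev_sampling("Q", 8, 30)),
    genome = genome_config(n_chrom = 2, chrom_bp = 2e6, n_snps = 400),
    seed = 9L)
  sim <- simulate_panel(cfg)
  tr <- sim$truth$tracts
  for (pp in c("P", "Q")) {
    ids <- sim$panel$samples$id[sim$panel$samples$pop == pp]
    expect_true(all(tr$ancestry[tr$sample %in% ids] == pp))
  }
})

test_that("tract-weighted donor ancestry recovers alpha within 3 SE", {
  cfg <- demography_config(
    populations = c(A = 1000, B = 1000),
    events = list(ev_split("A", "B", 0),
                  ev_pulse("B", "A", 0.3, 50),
                  ev_sampling("B", 50, 60), ev_sampling("A", 20, 60)),
    genome = genome_config(n_chrom = 5, chrom_bp = 1e7, n_snps = 5000),
    seed = 13L)
  sim <- simulate_panel(cfg)
  ids <- sim$panel$samples$id[sim$panel$samples$pop == "B"]
  frac <- ancestry_fraction(sim$truth, ids)[["A"]]
  se <- sqrt(0.3 * 0.7 / (2 * 50))   # binomial over 2n sampled gametes
  expect_lt(abs(frac - 0.3), 3 * se)
})

test_that("frequency mixing identity and zero-drift identity are exact", {
  ## zero drift generations anywhere: every population sits exactly on the
  ## ancestral frequencies
  cfg0 <- demography_config(
    populations = c(A = 1000, B = 1000),
    events = list(ev_split("A", "B", 0),
                  ev_sampling("A", 10, 0), ev_sampling("B", 10, 0)),
    seed = 3L)
  fs0 <- simulate_freqs(cfg0, 500)
  expect_identical(fs0$true_p[, "A"], fs0$truth$ancestral)
  expect_identical(fs0$true_p[, "B"], fs0$truth$ancestral)
  ## alpha = 0.5 pulse into a recipient with no drift after the pulse:
  ## exactly (p_A + p_B) / 2 even though both sources have drifted
  cfg <- demography_config(
    populations = c(A = 1000, B = 1000, X = 1000),
    events = list(ev_split("A", "B", 0), ev_split("A", "X", 50),
                  ev_pulse("X", "B", 0.5, 50),
                  ev_sampling("A", 10, 50), ev_sampling("B", 10, 50),
                  ev_sampling("X", 10, 50)),
    seed = 3L)
  fs <- simulate_freqs(cfg, 500)
  expect_false(identical(fs$true_p[, "A"], fs$true_p[, "B"]))
  expect_identical(fs$true_p[, "X"],
                   0.5 * fs$true_p[, "B"] + 0.5 * fs$true_p[, "A"])
  ## the outgroup carries the ancestral allele
  expect_true(all(fs$freqs$p[, "Chimp"] == 0))
})

test_that("drift calibration: Hudson FST matches 1 - exp(-t/2N)", {
  fs <- simulate_freqs(two_pop_cfg(t_gen = 100, N = 500, n = 50, seed = 17L),
                       10000)
  h <- hudson_fst(fs$freqs$p[, "A"], fs$freqs$n[, "A"],
                  fs$freqs$p[, "B"], fs$freqs$n[, "B"])
  expected <- 1 - exp(-100 / (2 * 500))
  ## Monte-Carlo error of the ratio-of-sums via block jackknife
  blocks <- (seq_len(10000) - 1) %/% 500 + 1
  jk <- block_jackknife(as.vector(rowsum(h$num, blocks)),
                        as.vector(rowsum(h$den, blocks)))
  expect_lt(abs(h$fst - expected), 3 * jk$se)
})

test_that("Y simulator: zero rate, Poisson calibration, perfect phylogeny", {
  tr <- y_star_tree(10, 5000)
  zero <- simulate_y(y_sim_config(tr, mu = 0, L = 1e7, seed = 1))
  expect_equal(ncol(zero$matrix), 0L)
  ## tip mutation counts are Poisson(mu * L * T): pool tips over replicates
  lam <- 0.76e-9 * 1e7 * 5000   # = 38 expected mutations per tip
  counts <- unlist(lapply(1:20, function(i) {
    s <- simulate_y(y_sim_config(y_star_tree(50, 5000), mu = 0.76e-9,
                                 L = 1e7, seed = 100L + i))
    rowSums(s$matrix)
  }))
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / length(counts)))
  ## nested-clade matrices build a perfect phylogeny without error
  nest <- ape::read.tree(text = "((a:2e3,b:2e3):2e3,(c:3e3,d:3e3):1e3);")
  s <- simulate_y(y_sim_config(nest, mu = 0.76e-9, L = 1e7, seed = 2))
  expect_s3_class(build_perfect_phylogeny(s$matrix), "y_tree")
})

test_that("canned scenarios validate; the bottlenecked donor has lower het", {
  expect_true(all(c("ooa_bottleneck", "chad_double_pulse") %in%
                    canned_scenarios()))
  expect_error(canned_scenarios("atlantis"), "unknown scenario")
  cfg <- canned_scenarios("ooa_bottleneck",
                          genome = genome_config(n_chrom = 2, chrom_bp = 1e7,
                                                 n_snps = 3000))
  sim <- simulate_panel(cfg)
  hc <- het_config(mappable_bp = 2e7)
  het <- vapply(sim$panel$samples$id, function(s)
    het_per_kb(sim$panel, s, hc), numeric(1))
  pop <- sim$panel$samples$pop
  expect_lt(mean(het[pop == "Eurasian"]), mean(het[pop == "African"]))
})
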