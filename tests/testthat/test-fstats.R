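test_that("weighted block jackknife matches hand arithmetic", {
  ## two equal-weight blocks: estimate and SE computed longhand here
  num <- c(2, 4); den <- c(10, 10); w <- c(5, 5)
  jk <- block_jackknife(num, den, w)
  est <- 6 / 20
  loo <- c(4 / 10, 2 / 10)
  h <- 10 / 5
  theta_j <- 2 * est - sum((1 - 0.5) * loo)
  tau <- h * est - (h - 1) * loo
  expect_equal(jk$estimate, est)
  expect_equal(jk$se, sqrt(sum((tau - theta_j)^2 / (h - 1)) / 2))
  ## proportional blocks leave nothing to resample
  jk0 <- block_jackknife(c(3, 6), c(1, 2), c(1, 2))
  expect_equal(jk0$se, 0)
  expect_error(block_jackknife(1, 1), "2 blocks")
})

test_that("jackknife SE shrinks like 1/sqrt(m) for iid blocks", {
  set.seed(11)
  se_for <- function(m) {
    num <- rnorm(m, 1, 0.3); den <- rep(1, m)
    block_jackknife(num, den, rep(10, m))$se
  }
  r <- mean(replicate(30, se_for(25) / se_for(100)))
  expect_gt(r, 1.4); expect_lt(r, 2.9)
})

test_that("f3 reproduces the known-frequency term and is symmetric", {
  nv <- 1000
  p <- cbind(C = rep(0.5, nv), A = rep(1, nv), B = rep(0, nv))
  ft <- freq_table(p, matrix(2e6, nv, 3, dimnames = list(NULL, colnames(p))))
  r <- f3(ft, "C", "A", "B")
  expect_equal(r$estimate, -0.25, tolerance = 1e-5)
  set.seed(2)
  p2 <- cbind(C = runif(1200), A = runif(1200), B = runif(1200))
  ft2 <- freq_table(p2, matrix(50, 1200, 3,
                               dimnames = list(NULL, colnames(p2))))
  expect_equal(f3(ft2, "C", "A", "B")$estimate,
               f3(ft2, "C", "B", "A")$estimate)
  ## correction needs 2 chromosomes in the target
  ft1 <- freq_table(p2, matrix(1, 1200, 3,
                               dimnames = list(NULL, colnames(p2))))
  expect_error(f3(ft1, "C", "A", "B"), "fewer than 2 chromosomes")
})

test_that("f4 antisymmetry is exact and D handles the textbook cases", {
  set.seed(3)
  nv <- 600
  p <- cbind(A = runif(nv), B = runif(nv), C = runif(nv), D = runif(nv))
  ft <- freq_table(p, matrix(40, nv, 4, dimnames = list(NULL, colnames(p))))
  f <- f4(ft, "A", "B", "C", "D")
  expect_equal(f4(ft, "B", "A", "C", "D")$estimate, -f$estimate)
  expect_equal(f4(ft, "A", "B", "D", "C")$estimate, -f$estimate)
  ## W = X identical frequencies: D is exactly zero
  pD <- cbind(W = p[, 1], X = p[, 1], Y = p[, 3], Z = p[, 4])
  ftD <- freq_table(pD, matrix(40, nv, 4, dimnames = list(NULL, colnames(pD))))
  expect_equal(d_stat(ftD, "W", "X", "Y", "Z")$estimate, 0)
  ## fully informative configuration w=1, x=0, y=1, z=0: D = 1
  p1 <- cbind(W = c(1, 1), X = c(0, 0), Y = c(1, 1), Z = c(0, 0))
  ft1 <- freq_table(p1, matrix(10, 2, 4, dimnames = list(NULL, colnames(p1))))
  expect_equal(d_stat(ft1, "W", "X", "Y", "Z",
                      blocks = c(1, 2))$estimate, 1)
  ## degenerate denominator errors
  p0 <- cbind(W = c(0, 0), X = c(0, 0), Y = c(0, 0), Z = c(0, 0))
  ft0 <- freq_table(p0, matrix(10, 2, 4, dimnames = list(NULL, colnames(p0))))
  expect_error(d_stat(ft0, "W", "X", "Y", "Z", blocks = c(1, 2)),
               "zero denominator")
})

test_that("f4 ratio is exact under the frequency mixing identity", {
  set.seed(4)
  nv <- 1200
  a <- runif(nv); o <- rep(0, nv); src <- runif(nv); b <- runif(nv)
  x <- 0.5 * src + 0.5 * b
  p <- cbind(A = a, O = o, Src = src, B = b, X = x, Xs = src)
  ft <- freq_table(p, matrix(1e6, nv, 6, dimnames = list(NULL, colnames(p))))
  expect_equal(
    suppressWarnings(
      f4_ratio(ft, c("A", "O", "X", "B"), c("A", "O", "Src", "B"))$alpha),
    0.5)
  expect_equal(
    suppressWarnings(
      f4_ratio(ft, c("A", "O", "Xs", "B"), c("A", "O", "Src", "B"))$alpha),
    1)
})

test_that("supervised admixture matches a likelihood grid search", {
  set.seed(5)
  nv <- 20000
  pA <- runif(nv, 0.1, 0.9)
  pB <- pmin(pmax(pA + runif(nv, -0.5, 0.5), 0.02), 0.98)
  geno <- cbind(rbinom(nv, 2, pA),                     # pure A individual
                rbinom(nv, 2, 0.3 * pA + 0.7 * pB))   # alpha = 0.3
  panel <- genotype_panel(
    data.frame(chrom = "chr1", pos = seq_len(nv), ref = "A", alt = "G"),
    data.frame(id = c("pure", "mixed"), pop = "X"), geno)
  est <- supervised_admixture(panel, pA, pB)
  expect_gte(est$alpha[est$sample == "pure"], 0.99)
  ## independent oracle: dense grid over alpha
  grid <- seq(0, 1, by = 5e-4)
  for (j in 1:2) {
    g <- geno[, j]
    ll <- vapply(grid, function(a) {
      pm <- pmin(pmax(a * pA + (1 - a) * pB, 1e-6), 1 - 1e-6)
      sum(g * log(pm) + (2 - g) * log(1 - pm))
    }, numeric(1))
    expect_lt(abs(est$alpha[j] - grid[which.max(ll)]), 1e-3)
  }
  expect_error(supervised_admixture(panel, pA, pA), "no informative SNPs")
})

test_that("f3 profile correlation covers exact and hand-computed cases", {
  x <- c(-0.01, -0.02, -0.03, -0.05)
  expect_equal(f3_profile_correlation(x, x)$r, 1)
  expect_equal(f3_profile_correlation(x, -x)$r, -1)
  y <- c(-0.012, -0.019, -0.035, -0.041)
  ## longhand Pearson r
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- f3_profile_correlation(x, y)
  expect_equal(res$r, r_hand)
  expect_true(res$ci[1] <= res$r && res$r <= res$ci[2])
  expect_error(f3_profile_correlation(x[1:2], y[1:2]), ">= 3")
})
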