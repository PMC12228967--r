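test_that("accumulated score reproduces the published worked examples", {
  expect_equal(round(accumulatedScore(0.494, 0.653, -7.018), 3), 1.849)
  expect_equal(round(accumulatedScore(0.488, 0.640, -7.532), 3), 1.881)
  expect_equal(round(accumulatedScore(0.497, 0.653, -7.197), 3), 1.870)
  expect_equal(round(accumulatedScore(0.502, 0.646, -7.024), 3), 1.850)
  expect_equal(accumulatedScore(0, 0, 0), 0)
  # linear in each argument
  expect_equal(accumulatedScore(0.5 + 0.1, 0.6, -7) -
                 accumulatedScore(0.5, 0.6, -7), 0.1)
  expect_equal(accumulatedScore(0.5, 0.6, -8) -
                 accumulatedScore(0.5, 0.6, -7), 0.1)
})

test_that("metric summaries: means, medians, success rate", {
  single <- data.frame(qed = 0.4, saNorm = 0.7, vina = -6.5)
  s1 <- summarizeMetrics(single)
  expect_equal(s1$mean[["qed"]], 0.4)
  expect_equal(s1$median[["qed"]], 0.4)
  expect_equal(s1$nMolecules, 1L)
  two <- data.frame(qed = c(0.5, 0.1), saNorm = c(0.7, 0.1),
                    vina = c(-9, -3))
  expect_equal(summarizeMetrics(two)$successRate, 0.5)
  expect_error(summarizeMetrics(data.frame()), "zero records")
  # medians match a sort-based oracle on random sets
  set.seed(14)
  for (rep in 1:20) {
    df <- data.frame(qed = runif(100), saNorm = runif(100),
                     vina = rnorm(100, -7))
    s <- summarizeMetrics(df)
    sortMedian <- function(x) {
      xs <- sort(x); (xs[50] + xs[51]) / 2
    }
    for (m in c("qed", "saNorm", "vina"))
      expect_equal(s$median[[m]], sortMedian(df[[m]]), tolerance = 1e-12)
    # success rate equals the mean of per-record flags exactly
    flags <- mapply(successFlag, df$qed, df$saNorm, df$vina)
    expect_equal(s$successRate, mean(flags))
  }
})

test_that("bond-distance JSD: identity, disjoint supports, symmetry", {
  world <- toyWorldConfig(seed = 51)
  mols <- lapply(1:15, function(i) makeToyLigand(world, i))
  q <- c("C", "C", "single")
  expect_equal(bondDistanceJSD(mols, mols, q), 0)
  # two degenerate non-overlapping distributions hit the base-2 bound
  mkPair <- function(d) list(Molecule3D(c("C", "C"),
                                        rbind(c(0, 0, 0), c(d, 0, 0)),
                                        bonds = cbind(1, 2, 1)))
  expect_equal(bondDistanceJSD(mkPair(1.0), mkPair(3.0), q), 1)
  # symmetric and bounded on distinct generated sets
  other <- lapply(21:35, function(i) makeToyLigand(world, i))
  j1 <- bondDistanceJSD(mols, other, q)
  j2 <- bondDistanceJSD(other, mols, q)
  expect_equal(j1, j2, tolerance = 1e-12)
  expect_gte(j1, 0); expect_lte(j1, 1)
  # element pairs match unordered
  qn <- bondDistanceJSD(mols, mols, c("C", "N", "single"))
  nq <- bondDistanceJSD(mols, mols, c("N", "C", "single"))
  expect_equal(qn, nq)
  expect_error(bondDistanceJSD(mols, mols, c("C", "C", "quintuple")),
               "unknown bond category")
  expect_error(bondDistanceJSD(mkPair(1), mols, c("C", "O", "triple")),
               "generated")
})

test_that("JSD of binned Gaussians matches an independent computation", {
  set.seed(8)
  a <- rnorm(1e4, 1.5, 0.1)
  b <- rnorm(1e4, 1.6, 0.1)
  wrap <- function(x) list(Molecule3D(
    rep("C", 2 * length(x)),
    do.call(rbind, lapply(x, function(d)
      rbind(c(0, 0, 0), c(d, 0, 0)))) +
      rep(seq(0, by = 100, length.out = length(x)), each = 2),
    bonds = cbind(seq(1, 2 * length(x), by = 2),
                  seq(2, 2 * length(x), by = 2), 1L)))
  got <- bondDistanceJSD(wrap(a), wrap(b), c("C", "C", "single"))
  # independent oracle: histogram + direct JSD formula
  breaks <- seq(0.8, 3.0, by = 0.02)
  clip <- function(x) pmin(pmax(x, 0.8 + 1e-12), 3.0 - 1e-12)
  p <- hist(clip(a), breaks = breaks, plot = FALSE)$counts / length(a)
  q <- hist(clip(b), breaks = breaks, plot = FALSE)$counts / length(b)
  m <- (p + q) / 2
  kl <- function(u, v) sum(ifelse(u > 0, u * (log2(u) - log2(v)), 0))
  expect_equal(got, (kl(p, m) + kl(q, m)) / 2, tolerance = 1e-9)
})

test_that("the JSD table reports finite values for shared bond types", {
  world <- toyWorldConfig(seed = 61)
  gen <- lapply(1:12, function(i) makeToyLigand(world, i))
  ref <- lapply(31:42, function(i) makeToyLigand(world, i))
  tab <- bondJSDTable(gen, ref)
  expect_true(all(c("bond", "jsd") %in% names(tab)))
  ccRow <- tab$jsd[tab$bond == "C:C"]
  expect_true(is.finite(ccRow))
  expect_true(all(tab$jsd >= 0 & tab$jsd <= 1, na.rm = TRUE))
})
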