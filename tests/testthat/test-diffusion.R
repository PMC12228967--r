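test_that("forward categorical: fixed point, single steps, terminal limit", {
  sch <- noiseSchedule(100)
  K <- 4
  u <- rep(1 / K, K)
  for (t in c(1, 37, 100))
    expect_equal(forwardCategorical(u, t, sch, K), u, tolerance = 1e-12)
  # composing t single steps equals the closed-form marginal
  p0 <- c(0.62, 0.2, 0.1, 0.08)
  p <- p0
  for (t in 1:80) {
    p <- forwardCategorical(p, t, sch, K, from = t - 1L)
    expect_lt(max(abs(p - forwardCategorical(p0, t, sch, K))), 1e-12)
  }
  # alphaBar -> 0 drives the marginal to uniform
  hot <- noiseSchedule(400, lambdaMin = 0.01, lambdaMax = 0.08)
  expect_lt(tail(alphaBar(hot), 1), 1e-6)
  pT <- forwardCategorical(c(1, 0, 0, 0), 400, hot, K)
  expect_lt(max(abs(pT - 1 / K)), 1e-6)
})

test_that("categorical posterior equals exhaustive Bayes for K in 2..5", {
  sch <- noiseSchedule(60, lambdaMin = 0.005, lambdaMax = 0.15)
  set.seed(101)
  for (K in 2:5) {
    for (rep in 1:25) {
      t <- sample(2:60, 1)
      p0 <- as.vector(randomSimplex(1, K))
      obs <- sample.int(K, 1)
      pT <- replace(numeric(K), obs, 1)
      bayes <- vapply(seq_len(K), function(k) {
        prior <- alphaBar(sch, t - 1L) * p0[k] +
          (1 - alphaBar(sch, t - 1L)) / K
        lik <- (1 - sch@lambda[t]) * pT[k] + sch@lambda[t] / K
        prior * lik
      }, numeric(1))
      expect_equal(categoricalPosterior(pT, p0, t, sch, K),
                   bayes / sum(bayes), tolerance = 1e-12)
    }
  }
})

test_that("categorical posterior symmetry and concentration cases", {
  sch <- noiseSchedule(50)
  K <- 5
  oneHot <- replace(numeric(K), 3, 1)
  post <- categoricalPosterior(oneHot, oneHot, 1L, sch, K)
  expect_gt(post[3], 0.999)
  u <- rep(1 / K, K)
  expect_equal(categoricalPosterior(u, u, 20L, sch, K), u,
               tolerance = 1e-12)
})

test_that("forward position: no-noise limit and analytic marginals", {
  tiny <- noiseSchedule(lambda = rep(1e-12, 5))
  world <- toyWorldConfig(seed = 2)
  db <- makeToyLigand(world, 3, plantedPartition = TRUE)
  pr <- estimatePriors(db$decomposed)
  x0 <- priorShift(atomCoords(db$mol), pr)
  for (mode in c("ddpm", "as-printed")) {
    fp <- forwardPosition(x0, 3L, tiny, pr, mode = mode, seed = 4)
    expect_lt(max(abs(fp$sample - x0)), 1e-4)
  }
  # ddpm terminal limit: mean ~ 0, covariance ~ Sigma_frag
  hot <- noiseSchedule(400, lambdaMin = 0.01, lambdaMax = 0.1)
  fpT <- forwardPosition(x0, 400L, hot, pr, mode = "ddpm", seed = 4)
  expect_lt(max(abs(fpT$mean)), 1e-4)
  expect_equal(fpT$covScale, 1 - tail(alphaBar(hot), 1),
               tolerance = 1e-12)
})

test_that("Monte-Carlo forward-position moments match the closed form", {
  # one atom in one fragment, replicated 20000 times in a single call
  n <- 20000
  sigma <- matrix(c(0.8, 0.2, 0, 0.2, 0.5, 0.1, 0, 0.1, 0.3), 3, 3)
  pr <- new("DecompPriors", mu = list(c(0, 0, 0)), sigma = list(sigma),
            assignment = rep(1L, n))
  x0 <- matrix(rep(c(1.2, -0.7, 0.4), each = n), n, 3)
  sch <- noiseSchedule(100)
  t <- 60L
  for (mode in c("ddpm", "as-printed")) {
    fp <- forwardPosition(x0, t, sch, pr, mode = mode, seed = 10)
    se <- sqrt(diag(sigma) * fp$covScale / n)
    expect_lt(max(abs(colMeans(fp$sample) - fp$mean[1, ]) / se), 4)
    empCov <- cov(fp$sample)
    expect_lt(max(abs(empCov - fp$covScale * sigma)),
              6 * max(diag(sigma)) * fp$covScale / sqrt(n))
  }
})

test_that("loss terms: identity zero, unit offsets, non-negativity", {
  world <- toyWorldConfig(seed = 6)
  db <- makeToyLigand(world, 1, plantedPartition = TRUE)
  pr <- estimatePriors(db$decomposed)
  vocab <- c("C", "N", "O", "S")
  truth <- DecompAlign:::moleculeToTruth(db$mol, pr, vocab)
  sch <- noiseSchedule(100)
  n <- nrow(truth$x0)
  state <- diffusionState(truth$x0, truth$v0, truth$b0,
                          truth$pairIndex, t = 30L)
  perfect <- lossTerms(state, truth, truth, sch)
  expect_equal(perfect$Lx, 0)
  expect_equal(perfect$Lv, 0)
  expect_equal(perfect$Lb, 0)
  expect_equal(perfect$Ltotal, 0)
  # positions offset by a unit vector on n atoms: Lx = n
  off <- truth
  off$x0 <- truth$x0 + matrix(rep(c(1, 0, 0), each = n), n, 3)
  expect_equal(lossTerms(state, truth, off, sch)$Lx, n)
  # KL terms are non-negative, zero iff the distributions are equal
  set.seed(55)
  for (rep in 1:200) {
    pred <- truth
    pred$v0 <- randomSimplex(n, 4)
    pred$b0 <- randomSimplex(nrow(truth$b0), 5)
    l <- lossTerms(state, truth, pred, sch)
    expect_gte(l$Lv, 0); expect_gte(l$Lb, 0)
    expect_gt(l$Lv + l$Lb, 0)
  }
  # gamma weighting enters the total linearly
  pred <- truth; pred$v0 <- randomSimplex(n, 4)
  l1 <- lossTerms(state, truth, pred, sch, lossWeights(1, 1))
  l2 <- lossTerms(state, truth, pred, sch, lossWeights(7, 3))
  expect_equal(l2$Ltotal - l1$Ltotal, 6 * l1$Lv + 2 * l1$Lb,
               tolerance = 1e-9)
})
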