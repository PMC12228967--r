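test_that("denoiser predictions have valid shapes and simplices", {
  world <- toyWorldFixture()
  model <- newDenoiser()
  sch <- noiseSchedule(100)
  batch <- dumbbellBatchFixture()
  prep <- DecompAlign:::.prepRecord(batch@records[[1]],
                                    model@atomVocab)
  state <- DecompAlign:::.noisyState(prep, 45L, sch, seed = 3L)
  pred <- predictDenoiser(model, state, batch@records[[1]]$pocket,
                          batch@records[[1]]$priors, sch)
  n <- nrow(state@positions)
  expect_equal(dim(pred$x0), c(n, 3))
  expect_equal(dim(pred$v0), c(n, 4))
  expect_equal(dim(pred$b0), c(nrow(state@bondProbs), 5))
  expect_lt(max(abs(rowSums(pred$v0) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(pred$b0) - 1)), 1e-9)
})

test_that("analytic gradients match finite differences", {
  # the geometric features of the categorical heads are computed from
  # the denoised positions with gradients stopped, so the analytic
  # position-head gradients are checked against the position loss and
  # the categorical-head gradients against the total loss
  model <- newDenoiser()
  sch <- noiseSchedule(100)
  batch <- dumbbellBatchFixture()
  prep <- DecompAlign:::.prepRecord(batch@records[[1]], model@atomVocab)
  lw <- lossWeights(100, 100)
  posIdx <- 1:4  # wx0 wx1 wx2 hx
  for (t in c(5L, 40L, 95L)) {
    state <- DecompAlign:::.noisyState(prep, t, sch, seed = 7L + t)
    lg <- DecompAlign:::.lossAndGrad(model, prep, state, sch, lw)
    fd <- function(i, component) {
      h <- 1e-6
      up <- model; up@params[i] <- up@params[i] + h
      dn <- model; dn@params[i] <- dn@params[i] - h
      (DecompAlign:::.lossAndGrad(up, prep, state, sch,
                                  lw)$loss[[component]] -
       DecompAlign:::.lossAndGrad(dn, prep, state, sch,
                                  lw)$loss[[component]]) / (2 * h)
    }
    numPos <- vapply(posIdx, fd, numeric(1), component = "Lx")
    expect_lt(max(abs(numPos - lg$grad[posIdx]) /
                    pmax(1, abs(numPos))), 1e-5)
    catIdx <- setdiff(seq_along(model@params), posIdx)
    numCat <- vapply(catIdx, fd, numeric(1), component = "Ltotal")
    expect_lt(max(abs(numCat - lg$grad[catIdx]) /
                    pmax(1, abs(numCat))), 1e-5)
  }
})

test_that("sampling is deterministic, respects n_atoms, stays near priors", {
  world <- toyWorldFixture()
  model <- newDenoiser()
  sch <- noiseSchedule(100)
  pr <- world$priors[[1]]
  m1 <- sampleLigand(model, world$pockets[[1]], pr, 12L, sch, seed = 7)
  m2 <- sampleLigand(model, world$pockets[[1]], pr, 12L, sch, seed = 7)
  expect_identical(m1@elements, m2@elements)
  expect_identical(m1@bonds, m2@bonds)
  expect_equal(m1@coords, m2@coords)
  expect_equal(nAtoms(m1), 12L)
  for (n in c(5L, 9L, 17L))
    expect_equal(nAtoms(sampleLigand(model, world$pockets[[1]], pr, n,
                                     sch, seed = 1)), n)
  # untrained model: sample clouds centre on the fragment priors
  samples <- lapply(1:60, function(k)
    sampleLigand(model, world$pockets[[1]], pr,
                 length(pr@assignment), sch, seed = k))
  muAll <- do.call(rbind, pr@mu)[pr@assignment, , drop = FALSE]
  offsets <- sapply(seq_along(pr@mu), function(f) {
    idx <- which(pr@assignment == f)
    centre <- Reduce(`+`, lapply(samples, function(s)
      colMeans(s@coords[idx, , drop = FALSE]))) / length(samples)
    sqrt(sum((centre - pr@mu[[f]])^2))
  })
  sigmas <- vapply(pr@sigma, function(S) sqrt(mean(diag(S))), numeric(1))
  expect_true(all(offsets < 3 * sigmas))
})

test_that("both forward modes produce sane samples", {
  world <- toyWorldFixture()
  model <- newDenoiser()
  sch <- noiseSchedule(100)
  for (mode in c("ddpm", "as-printed")) {
    m <- sampleLigand(model, world$pockets[[2]], world$priors[[2]], 10L,
                      sch, seed = 5, mode = mode)
    expect_true(all(is.finite(m@coords)))
    expect_true(all(m@elements %in% model@atomVocab))
  }
})

test_that("model save/load round-trips through the JSON artifact", {
  model <- newDenoiser()
  model@params[["bv1"]] <- 0.123456789
  sch <- noiseSchedule(50)
  path <- tempfile(fileext = ".json")
  saveDenoiser(model, path, schedule = sch)
  back <- loadDenoiser(path)
  expect_equal(back$model@params, model@params, tolerance = 1e-12)
  expect_identical(back$model@atomVocab, model@atomVocab)
  expect_equal(back$schedule@lambda, sch@lambda, tolerance = 1e-12)
})

test_that("finetune: zero iterations is the identity, training converges", {
  model <- newDenoiser()
  # denoising-regime schedule: mild corruption keeps the conditional-mean
  # floor low so convergence is visible
  sch <- noiseSchedule(100, lambdaMin = 1e-4, lambdaMax = 0.02)
  batch <- dumbbellBatchFixture()
  same <- finetuneDenoiser(model, batch, sch, lr = 1e-3, iters = 0L)
  expect_identical(same@params, model@params)
  expect_error(finetuneDenoiser(model,
                                new("CurationBatch", records = list(),
                                    batchSizeB = 1L, subsetSizeB = 0L),
                                sch), "non-empty")
  # toy overfit on one record from an uninformed (all-zero) model: the
  # deterministic evaluation loss drops several-fold toward the
  # conditional-mean floor of this small denoiser
  cold <- newDenoiser()
  cold@params[] <- 0
  before <- evalDenoiserLoss(cold, batch, sch)
  trained <- finetuneDenoiser(cold, batch, sch, lr = 1e-3, iters = 2000L,
                              seed = 3L)
  after <- evalDenoiserLoss(trained, batch, sch)
  expect_lt(after, before / 3)
  expect_equal(nrow(trained@trainLog), 2000L)
  expect_true(all(c("Lx", "Lv", "Lb", "Ltotal") %in%
                  names(trained@trainLog)))
  # frozen architectural constant is untouched by training
  expect_identical(trained@params[["hx"]], cold@params[["hx"]])
})
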