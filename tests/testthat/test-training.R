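test_that("logLoss matches the naive formula and its limits", {
  expect_equal(logLoss(c(0, 0), 1), log(2), tolerance = 1e-12)
  # answer score -> large with others fixed: loss -> 0
  expect_lt(logLoss(c(50, 0, 0), 1), 1e-20)

  set.seed(9)
  for (rep in 1:20) {
    s <- rnorm(6, sd = 3)
    a <- sample.int(6, 1)
    naive <- -s[a] + log(sum(exp(s)))
    expect_equal(logLoss(s, a), naive, tolerance = 1e-9)
  }
  expect_error(logLoss(c(1, Inf), 1), "finite")
})

test_that("totalLoss decomposes into mean log-loss plus gamma times the mean penalty", {
  kg <- randomKG(10, 2, 25, seed = 91)
  m <- tinyModel(kg, D = 4, nLayers = 2, K = 5, gamma = 0.2)
  qs <- tripleSplit(kg, "train")[1:3, , drop = FALSE]
  got <- totalLoss(qs, m, kg)

  parts <- vapply(seq_len(nrow(qs)), function(i) {
    sq <- kgfusion:::.scoreQuery(m, kg, list(qe = qs[i, 1L], qr = qs[i, 2L]))
    c(logLoss(sq$scores, qs[i, 3L]),
      n3Penalty(sq$eQe, sq$eQr, m@params$Et[qs[i, 3L], ]))
  }, c(0, 0))
  expect_equal(got, mean(parts[1, ]) + 0.2 * mean(parts[2, ]),
               tolerance = 1e-12)

  # gamma = 0 leaves the pure mean log-loss
  m0 <- m; m0@config$gamma <- 0
  expect_equal(totalLoss(qs, m0, kg), mean(parts[1, ]), tolerance = 1e-12)

  # zero CP embeddings make the N3 term vanish
  mz <- m
  mz@params$Eh[] <- 0; mz@params$Er[] <- 0; mz@params$Et[] <- 0
  qz <- qs[1, , drop = FALSE]
  sqz <- kgfusion:::.scoreQuery(mz, kg, list(qe = qz[1], qr = qz[2]))
  expect_equal(n3Penalty(sqz$eQe, sqz$eQr, mz@params$Et[qz[3], ]), 0)
})

test_that("batched training engine reproduces the modular forward loss exactly", {
  kg <- randomKG(12, 2, 30, seed = 101)
  for (variant in list(character(0), "no_gsp", "no_crr", "no_phi",
                       "random_query")) {
    cfg <- kgConfig(D = 4, nLayers = 2, K = 4, seed = 3, initScale = 0.4,
                    gamma = 0.05, ablation = variant)
    m <- newKGModel(kg, cfg)
    qs <- tripleSplit(kg, "train")[1:5, , drop = FALSE]
    modular <- totalLoss(qs, m, kg, mode = "infer")
    fw <- kgfusion:::.tapeForward(kg, qs, m@params, cfg, mode = "infer")
    expect_equal(as.numeric(kgfusion:::.tpVal(fw$tape, fw$lossId)), modular,
                 tolerance = 1e-10)
  }
})

test_that("analytic gradients agree with central finite differences of the modular loss", {
  kg <- randomKG(6, 2, 12, seed = 111)
  cfg <- kgConfig(D = 3, nLayers = 2, K = 50, seed = 5, initScale = 0.4,
                  gamma = 0.05, lambda = 0.7)
  m <- newKGModel(kg, cfg)
  qs <- tripleSplit(kg, "train")[1:3, , drop = FALSE]
  lg <- kgfusion:::.lossAndGrad(kg, qs, m@params, cfg, mode = "infer")
  expect_equal(lg$loss, totalLoss(qs, m, kg, mode = "infer"),
               tolerance = 1e-10)
  eps <- 1e-5
  for (nm in names(lg$grads)) {
    p <- m@params[[nm]]
    ga <- lg$grads[[nm]]
    idx <- seq_along(p)
    if (length(idx) > 12) {
      set.seed(7)
      idx <- sort(sample(idx, 12))  # spot-check large blocks
    }
    for (i in idx) {
      mp <- m; mp@params[[nm]][i] <- p[i] + eps
      mm <- m; mm@params[[nm]][i] <- p[i] - eps
      gf <- (totalLoss(qs, mp, kg, mode = "infer") -
             totalLoss(qs, mm, kg, mode = "infer")) / (2 * eps)
      denom <- max(abs(ga[i]), abs(gf), 1e-6)
      expect_lt(abs(ga[i] - gf) / denom, 1e-4)
    }
  }
})

test_that("filteredRank matches a sort-based oracle and ranks ties pessimistically", {
  expect_equal(filteredRank(c(0.9, 0.1, 0.2), 1, 1L), 1L)
  # all-equal scores, no other known answers: pessimistic rank = |V|
  expect_equal(filteredRank(rep(0.5, 4), 2, 2L), 4L)
  expect_error(filteredRank(c(1, 2), 1, 2L), "known answers")

  set.seed(13)
  for (rep in 1:100) {
    n <- sample(3:10, 1)
    s <- sample(round(rnorm(n), 1))  # ties likely
    ans <- sample.int(n, 1)
    known <- sort(unique(c(ans, sample.int(n, sample(0:3, 1)))))
    got <- filteredRank(s, ans, known)
    s2 <- s; s2[setdiff(known, ans)] <- -Inf
    oracle <- sum(s2 > s2[ans]) + sum(s2 == s2[ans])
    expect_equal(got, oracle)
  }
})

test_that("ranking metrics match brute-force aggregation on exhaustive small cases", {
  rr <- kgfusion:::.rankingResult(c(1L, 2L, 4L))
  expect_equal(rr@mrr, (1 + 0.5 + 0.25) / 3)
  rr1 <- kgfusion:::.rankingResult(c(1L, 1L, 1L))
  expect_equal(c(rr1@mrr, rr1@hit1, rr1@hit10), c(1, 1, 1))

  # exhaustive: every permutation of a 5-entity score vector, rank of each
  # answer against a brute-force sort
  base <- c(0.1, 0.2, 0.3, 0.4, 0.4)
  perms <- unique(combinat_perms(base))
  for (i in seq_len(min(nrow(perms), 60))) {
    s <- perms[i, ]
    for (ans in 1:5) {
      got <- filteredRank(s, ans, ans)
      oracle <- sum(s > s[ans]) + sum(s == s[ans])
      expect_equal(got, oracle)
    }
  }
  expect_true(rr@hit1 <= rr@hit10)
})

test_that("one-epoch training runs, is finite, and is reproducible given the seed", {
  kg <- randomKG(10, 2, 20, seed = 121)
  # tiny KG smoke test
  cfg <- kgConfig(D = 4, nLayers = 1, K = 4, epochs = 1, batchSize = 8,
                  seed = 11, evalEvery = 1, lr = 1e-2)
  m1 <- suppressMessages(trainKGModel(kg, cfg))
  expect_true(all(is.finite(trainingLog(m1)$loss)))

  m2 <- suppressMessages(trainKGModel(kg, cfg))
  expect_identical(trainingLog(m1), trainingLog(m2))
  e1 <- evaluateModel(m1, kg, queries = tripleSplit(kg, "train"))
  e2 <- evaluateModel(m2, kg, queries = tripleSplit(kg, "train"))
  expect_identical(e1@ranks, e2@ranks)
})

test_that("training loss decreases on a small synthetic KG across seeds", {
  spec <- syntheticSpec(nEntities = 25, density = 5, noiseRate = 0,
                        seed = 17)
  gen <- generateRuleKG(spec)
  d <- withr::local_tempdir()
  writeSplits(gen, d)
  kg <- loadKnowledgeGraph(d)
  for (seed in 1:3) {
    cfg <- kgConfig(D = 6, nLayers = 2, K = 8, epochs = 8, seed = seed,
                    evalEvery = 10, lr = 2e-2, gamma = 1e-3, clipNorm = Inf)
    m <- suppressMessages(trainKGModel(kg, cfg))
    lg <- trainingLog(m)$loss
    first2 <- mean(lg[1:2]); last2 <- mean(lg[(length(lg) - 1):length(lg)])
    expect_lt(last2, first2)  # smoothed monotone trend
  }
})

test_that("evaluateModel aggregates per-query filtered ranks", {
  kg <- randomKG(8, 2, 18, seed = 131)
  m <- tinyModel(kg, D = 4, nLayers = 1, K = 4)
  qs <- tripleSplit(kg, "train")[1:4, , drop = FALSE]
  res <- evaluateModel(m, kg, queries = qs)
  manual <- vapply(seq_len(nrow(qs)), function(i) {
    sc <- scoreAllEntities(m, kg, list(qe = qs[i, 1L], qr = qs[i, 2L]))
    filteredRank(sc, qs[i, 3L], knownAnswers(kg, qs[i, 1L], qs[i, 2L]))
  }, 0L)
  expect_equal(res@ranks, manual)
  expect_equal(res@mrr, mean(1 / manual))
})

test_that("apply_ablation validates variants and adjusts the configuration", {
  cfg <- kgConfig(lambda = 0.7)
  expect_error(applyAblation(cfg, "bogus"))
  expect_equal(applyAblation(cfg, "no_phi")$lambda, 1.0)
  expect_true("no_crr" %in% applyAblation(cfg, "no_crr")$ablation)
})

test_that("the no_gsp variant behaves as a standalone CP-only model", {
  spec <- syntheticSpec(nEntities = 15, density = 4, seed = 19)
  gen <- generateCpKG(spec)
  d <- withr::local_tempdir()
  writeSplits(gen, d)
  kg <- loadKnowledgeGraph(d)
  cfg <- applyAblation(kgConfig(D = 6, nLayers = 2, K = 8, epochs = 3,
                                seed = 2, evalEvery = 5, lr = 1e-2),
                       "no_gsp")
  m <- suppressMessages(trainKGModel(kg, cfg))
  # the trained model scores every query exactly as raw CP
  qs <- tripleSplit(kg, "test")[1:5, , drop = FALSE]
  f <- cpFactors(m)
  for (i in seq_len(nrow(qs))) {
    sc <- scoreAllEntities(m, kg, list(qe = qs[i, 1L], qr = qs[i, 2L]))
    expect_equal(sc, cpScoreAll(f, qs[i, 1L], f@Er[qs[i, 2L], ]),
                 tolerance = 1e-12)
  }
})
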