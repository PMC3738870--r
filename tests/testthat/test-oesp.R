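test_that("protein-like input is returned unchanged with zero score, all strategies", {
  chains <- list(zigzagChain(8), generateChain(12, seed = 3))
  for (ch in chains)
    for (s in c("basic", "simplified", "advanced")) {
      res <- proteinize(ch, strategy = s, edgeLength = 1, density = 6)
      expect_true(isFeasible(res))
      expect_equal(totalScore(res), 0)
      expect_equal(res@points, caCoords(ch))
    }
})

test_that("an overstretched line is pulled back into the distance window", {
  p <- cbind(c(0, 4, 8), 0, 0)
  res <- proteinizeBasic(p, edgeLength = 1, density = 6)
  expect_true(isFeasible(res))
  d <- sqrt(rowSums(diff(res@points)^2))
  expect_true(all(d >= 3.7 & d <= 3.9))
  # exhaustive cross-check at a coarser, enumerable density
  res2 <- proteinizeBasic(p, edgeLength = 1, density = 2)
  oracle <- bruteForceOesp(p, edgeLength = 1, density = 2,
                           includeAngles = FALSE)
  expect_equal(totalScore(res2), totalScore(oracle), tolerance = 1e-12)
  # its only equidistant corrections are collinear: angle window kills them
  adv <- proteinizeAdvanced(p, edgeLength = 1, density = 6)
  expect_false(isFeasible(adv))
  expect_false(isFeasible(proteinizeSimplified(p, edgeLength = 1,
                                               density = 6)))
})

test_that("points far beyond lattice reach are infeasible", {
  p <- rbind(c(0, 0, 0), c(50, 0, 0))
  res <- proteinize(p, strategy = "basic", edgeLength = 2, density = 6)
  expect_false(isFeasible(res))
  expect_equal(totalScore(res), Inf)
})

test_that("dynamic programs match the exhaustive oracle on random tiny instances", {
  set.seed(101)
  shared <- 0
  for (rep in 1:40) {
    inst <- randomTinyInstance(sample(2:4, 1))
    adv <- proteinizeAdvanced(inst$points, inst$brokenEdge, inst$brokenAngle,
                              edgeLength = 1, density = 2)
    bf <- bruteForceOesp(inst$points, inst$brokenEdge, inst$brokenAngle,
                         edgeLength = 1, density = 2)
    expect_equal(isFeasible(adv), isFeasible(bf))
    if (isFeasible(adv))
      expect_equal(totalScore(adv), totalScore(bf), tolerance = 1e-9)

    bas <- proteinizeBasic(inst$points, inst$brokenEdge, inst$brokenAngle,
                           edgeLength = 1, density = 2)
    bfb <- bruteForceOesp(inst$points, inst$brokenEdge, inst$brokenAngle,
                          edgeLength = 1, density = 2,
                          includeAngles = FALSE)
    expect_equal(isFeasible(bas), isFeasible(bfb))
    if (isFeasible(bas))
      expect_equal(totalScore(bas), totalScore(bfb), tolerance = 1e-9)

    sim <- proteinizeSimplified(inst$points, inst$brokenEdge,
                                inst$brokenAngle, edgeLength = 1,
                                density = 2)
    if (isFeasible(sim)) {
      # greedy history can only cost extra
      expect_gte(totalScore(sim), totalScore(adv) - 1e-9)
      expect_true(isFeasible(adv))
    }
    if (isFeasible(adv) && isFeasible(bas)) {
      shared <- shared + 1
      expect_lte(totalScore(bas), totalScore(adv) + 1e-9)
    }
  }
  expect_gt(shared, 5)  # the comparison actually exercised both outcomes
})

test_that("feasible outputs respect their strategy's constraints", {
  set.seed(202)
  for (rep in 1:10) {
    inst <- randomTinyInstance(4)
    for (s in c("basic", "simplified", "advanced")) {
      res <- proteinize(inst$points, inst$brokenEdge, inst$brokenAngle,
                        strategy = s, edgeLength = 1, density = 2)
      if (!isFeasible(res)) next
      expect_gte(totalScore(res), 0)
      d <- sqrt(rowSums(diff(res@points)^2))
      expect_true(all(d[!inst$brokenEdge] >= 3.7 - 1e-9 &
                        d[!inst$brokenEdge] <= 3.9 + 1e-9))
      if (s != "basic") {
        for (j in 2:3) {
          if (inst$brokenAngle[j]) next
          ang <- angDeg(res@points[j - 1, ], res@points[j, ],
                        res@points[j + 1, ])
          expect_true(ang >= 70 - 1e-9 && ang <= 120 + 1e-9)
        }
      }
    }
  }
})

test_that("proteinization is idempotent", {
  set.seed(7)
  ch <- generateChain(15, seed = 15)
  pe <- perturbChain(ch, 0.2, seed = 16)
  first <- proteinizeRetry(caCoords(pe))
  expect_true(isFeasible(first))
  again <- proteinizeSimplified(first@points)
  expect_true(isFeasible(again))
  expect_equal(totalScore(again), 0)
  expect_equal(again@points, first@points)
})

test_that("advanced at n = 2 reduces to the basic recurrence", {
  p <- rbind(c(0, 0, 0), c(4.05, 0, 0))
  adv <- proteinizeAdvanced(p, edgeLength = 1, density = 6)
  bas <- proteinizeBasic(p, edgeLength = 1, density = 6)
  expect_equal(isFeasible(adv), isFeasible(bas))
  expect_equal(totalScore(adv), totalScore(bas))
  expect_equal(adv@points, bas@points)
})

test_that("the oracle refuses instances beyond its enumeration budget", {
  p <- zigzagChain(8)
  expect_error(bruteForceOesp(p, edgeLength = 1, density = 6), "too large")
})
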