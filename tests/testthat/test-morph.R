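test_that("alpha-intermediates are pointwise convex combinations", {
  P <- zigzagChain(5)
  Q <- setCoords(P, caCoords(P) + 2)
  expect_equal(alphaIntermediate(P, Q, 0), caCoords(P))
  expect_equal(alphaIntermediate(P, Q, 1), caCoords(Q))
  expect_equal(alphaIntermediate(rbind(c(0, 0, 0)), rbind(c(2, 0, 0)), 0.5),
               rbind(c(1, 0, 0)))
  expect_error(alphaIntermediate(P, Q, 1.2), "\\[0, 1\\]")
})

test_that("maximum displacement is the largest per-residue distance", {
  ch <- zigzagChain(6)
  expect_equal(maxDisplacement(ch, ch), 0)
  moved <- caCoords(ch)
  moved[4, ] <- moved[4, ] + c(0, 0, 5)
  expect_equal(maxDisplacement(ch, CaTrace(moved)), 5.0)
  expect_error(maxDisplacement(ch, zigzagChain(5)), "equal dimensions")
})

test_that("K follows the rounded-largest-displacement rule", {
  ch <- zigzagChain(10)
  shift <- function(d) {
    m <- caCoords(ch)
    m[5, ] <- m[5, ] + c(0, 0, d)
    CaTrace(m)
  }
  expect_equal(chooseNumIntermediates(ch, shift(15.2)), 15L)
  expect_equal(chooseNumIntermediates(ch, ch), 1L)            # floor at 1
  expect_equal(chooseNumIntermediates(ch, shift(0.2)), 1L)
  expect_equal(chooseNumIntermediates(ch, shift(34.8)), 35L)
  expect_equal(chooseNumIntermediates(ch, shift(34.8), "truncate"), 34L)
})

test_that("a degenerate morph between identical structures stays put", {
  ch <- generateChain(10, seed = 9)
  m <- runMorph(ch, ch, morphConfig(K = 3))
  expect_length(morphFrames(m), 5L)
  for (f in morphFrames(m))
    expect_equal(caCoords(f), caCoords(ch))
  expect_equal(diagnostics(m)$totalScore, rep(0, 3))
})

test_that("a rigid-translation morph produces protein-like frames that approach the end", {
  ch <- generateChain(10, seed = 4)
  end <- setCoords(ch, caCoords(ch) + rep(c(4, 0, 0), each = 10))
  m <- runMorph(ch, end, morphConfig(K = 4))
  rep <- morphReport(m)
  expect_true(all(rep$proteinLike[2:5]))
  dg <- diagnostics(m)
  # interpolation targets strictly approach the end conformation
  distBefore <- c(rmsd(ch, end), dg$frameDistToEnd[-4])
  expect_true(all(dg$targetDistToEnd < distBefore))
  expect_true(all(diff(dg$targetDistToEnd) < 0))
})

test_that("morphs are byte-reproducible under a fixed configuration", {
  pair <- makeMorphPair(n = 14, hingeAngle = 20, seed = 8)
  run <- function() {
    f <- tempfile(fileext = ".pdb")
    writeMorphPdb(runMorph(pair$start, pair$end, morphConfig(K = 2)), f)
    readLines(f)
  }
  expect_identical(run(), run())
})

test_that("morphing either direction yields the configured frame count", {
  pair <- makeMorphPair(n = 12, hingeAngle = 25, seed = 10)
  cfg <- morphConfig(K = 3)
  m1 <- runMorph(pair$start, pair$end, cfg)
  m2 <- runMorph(pair$end, pair$start, cfg)
  expect_length(morphFrames(m1), 5L)
  expect_length(morphFrames(m2), 5L)
})

test_that("the lattice edge escalates when the default grid cannot reach", {
  # two points 5.0 A apart: max reach 2 * 0.5 A at edge 1.0 leaves the gap
  # outside [3.7, 3.9]; the 1.5 A lattice reaches it
  p <- rbind(c(0, 0, 0), c(5, 0, 0))
  res <- proteinizeRetry(p)
  expect_true(isFeasible(res))
  expect_equal(res@edgeLength, 1.5)
  d <- sqrt(sum(diff(res@points)^2))
  expect_true(d >= 3.7 && d <= 3.9)
})

test_that("an unreachable frame aborts the morph with a diagnostic", {
  start <- CaTrace(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  end <- CaTrace(rbind(c(0, 0, 0), c(50, 0, 0)))
  err <- tryCatch(runMorph(start, end, morphConfig(K = 2)),
                  camorphInfeasible = function(e) e)
  expect_s3_class(err, "camorphInfeasible")
  expect_match(conditionMessage(err), "frame 1")
  expect_match(conditionMessage(err), "2 A")
})

test_that("the fixed interpolation schedule uses the original endpoints", {
  ch <- generateChain(10, seed = 12)
  end <- setCoords(ch, caCoords(ch) + rep(c(3, 0, 0), each = 10))
  m <- runMorph(ch, end, morphConfig(K = 3, schedule = "fixed"))
  dg <- diagnostics(m)
  d0 <- rmsd(ch, end)
  expect_equal(dg$targetDistToEnd, d0 * (1 - (1:3) / 4), tolerance = 1e-9)
})

test_that("automatic K resolves from the displacement inside runMorph", {
  pair <- makeMorphPair(n = 12, hingeAngle = 35, seed = 2)
  K <- chooseNumIntermediates(pair$start, pair$end)
  m <- runMorph(pair$start, pair$end, morphConfig())
  expect_length(morphFrames(m), K + 2L)
})
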