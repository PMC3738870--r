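test_that("an ideal chain passes all three criteria", {
  rep <- checkProteinLike(zigzagChain(20, spacing = 3.8, angle = 100))
  expect_true(rep@passEquidistant)
  expect_true(rep@passAngles)
  expect_true(rep@passClash)
  expect_true(isProteinLike(rep))
  expect_equal(rep@distances, rep(3.8, 19), tolerance = 1e-9)
  expect_equal(rep@angles[2:19], rep(100, 18), tolerance = 1e-9)
  expect_true(is.na(rep@angles[1]) && is.na(rep@angles[20]))
})

test_that("a stretched bond fails equidistance at the offending edge", {
  xyz <- caCoords(zigzagChain(8))
  xyz[5:8, ] <- xyz[5:8, ] + rep(c(0.7, 0, 0), each = 4)  # edge 4-5 -> ~4.5
  rep <- checkProteinLike(xyz)
  expect_false(rep@passEquidistant)
  bad <- which(rep@distances < 3.7 | rep@distances > 3.9)
  expect_equal(bad, 4L)
})

test_that("close non-consecutive residues are reported as clash pairs", {
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0), c(7.6, 3.8, 0),
               c(1.5, 0, 0), c(-2.3, 0, 0))
  rep <- checkProteinLike(xyz)
  expect_false(rep@passClash)
  expect_true(any(rep@clashes$i == 1 & rep@clashes$j == 5))
  expect_equal(rep@clashes$dist[rep@clashes$i == 1 & rep@clashes$j == 5],
               1.5)
})

test_that("broken positions are exempt from distance and angle criteria", {
  xyz <- caCoords(zigzagChain(6))
  xyz[4:6, ] <- xyz[4:6, ] + rep(c(5, 0, 0), each = 3)  # chain break at 3-4
  be <- c(FALSE, FALSE, TRUE, FALSE, FALSE)
  ba <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  expect_false(isProteinLike(checkProteinLike(xyz)))
  expect_true(isProteinLike(checkProteinLike(xyz, be, ba)))
})

test_that("the RMSD profile is zero exactly at a frame's own reference", {
  pair <- makeMorphPair(n = 12, hingeAngle = 25, seed = 6)
  m <- runMorph(pair$start, pair$end, morphConfig(K = 3))
  prof <- trajectoryRmsdProfile(m, list(start = pair$start,
                                        end = pair$end))
  expect_equal(names(prof), c("frame", "start", "end"))
  expect_equal(prof$start[1], 0, tolerance = 1e-9)
  expect_equal(prof$end[nrow(prof)], 0, tolerance = 1e-9)
  expect_true(all(prof$start[-1] > 0))
})

test_that("a monotone translation morph approaches its end reference monotonically", {
  ch <- generateChain(10, seed = 4)
  end <- setCoords(ch, caCoords(ch) + rep(c(4, 0, 0), each = 10))
  m <- runMorph(ch, end, morphConfig(K = 4))
  # unsuperposed distance to the end structure decreases frame by frame
  expect_true(all(diff(diagnostics(m)$frameDistToEnd) < 0))
  # after superposition a rigid translation is invisible, so the profile
  # column is flat at zero -- trivially non-increasing within tolerance
  prof <- trajectoryRmsdProfile(m, list(end = end))
  expect_true(all(prof$end < 1e-6))
  expect_true(all(diff(prof$end) < 1e-9))
})

test_that("every frame emitted by runMorph validates as protein-like", {
  for (seed in c(1, 2)) {
    pair <- makeMorphPair(n = 15, hingeAngle = 30, seed = seed)
    m <- runMorph(pair$start, pair$end, morphConfig())
    rep <- morphReport(m)
    interior <- 2:(nrow(rep) - 1)
    expect_true(all(rep$passEquidistant[interior]))
    expect_true(all(rep$passAngles[interior]))
  }
})

test_that("length mismatches in references are rejected by name", {
  pair <- makeMorphPair(n = 10, hingeAngle = 20, seed = 3)
  m <- runMorph(pair$start, pair$end, morphConfig(K = 2))
  expect_error(trajectoryRmsdProfile(m, list(short = zigzagChain(5))),
               "short")
})
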