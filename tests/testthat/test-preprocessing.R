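test_that("identical sequences align without gaps", {
  al <- globalAlign("ACD", "ACD")
  expect_equal(nrow(al), 3L)
  expect_equal(al$a, 1:3)
  expect_equal(al$b, 1:3)
})

test_that("a deletion aligns the unmatched residue to a gap", {
  al <- globalAlign("ACD", "AD")
  expect_equal(sum(is.na(al$b)), 1L)
  expect_true(is.na(al$b[al$a == 2]))  # the C has no partner
  expect_equal(al$b[al$a == 3], 2L)
  expect_error(globalAlign("", "ACD"), "non-empty")
})

test_that("alignment score is symmetric", {
  s1 <- attr(globalAlign("ACDEFGHIKL", "ACDEGHKL"), "score")
  s2 <- attr(globalAlign("ACDEGHKL", "ACDEFGHIKL"), "score")
  expect_equal(s1, s2)
})

test_that("restriction records gap adjacency from the start structure", {
  ch <- zigzagChain(4)
  idAl <- data.frame(a = 1:4, b = 1:4)
  pair <- restrictToAligned(ch, ch, idAl)
  expect_false(any(pair@brokenEdge))
  expect_equal(pair@brokenAngle, c(TRUE, FALSE, FALSE, TRUE))

  # alignment skipping a middle residue of trace_a
  skipAl <- data.frame(a = c(1, 2, 4), b = c(1, 2, 3))
  ch3 <- zigzagChain(3)
  pair2 <- restrictToAligned(ch, ch3, skipAl)
  expect_equal(pair2@brokenEdge, c(FALSE, TRUE))

  # residue numbering 1,2,10,11: gap sits between positions 2 and 3
  chNum <- CaTrace(caCoords(ch), resno = c(1, 2, 10, 11))
  pair3 <- restrictToAligned(chNum, ch, idAl)
  expect_equal(pair3@brokenEdge, c(FALSE, TRUE, FALSE))
  expect_equal(pair3@brokenAngle, c(TRUE, TRUE, TRUE, TRUE))

  expect_error(restrictToAligned(ch, ch, data.frame(a = 1, b = 1)),
               "fewer than 2")
})

test_that("rmsd is the plain pointwise formula", {
  a <- zigzagChain(5)
  expect_equal(rmsd(a, a), 0)
  p <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE)
  expect_equal(rmsd(p, p + rep(c(1, 0, 0), each = 2)), 1.0)
  set.seed(11)
  x <- matrix(rnorm(30), 10, 3)
  y <- matrix(rnorm(30), 10, 3)
  expect_equal(rmsd(x, y), sqrt(sum((x - y)^2) / 10))
  expect_error(rmsd(x, y[1:5, ]), "equal dimensions")
})

test_that("Kabsch superposition recovers known rigid transforms", {
  set.seed(21)
  x <- matrix(rnorm(60), 20, 3)
  id <- kabschSuperpose(x, x)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$transform@rotation, diag(3), tolerance = 1e-9)
  expect_equal(id$transform@translation, c(0, 0, 0), tolerance = 1e-9)

  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)  # 90 degrees about z
  moved <- sweep(x %*% t(R90), 2, c(5, -3, 2), `+`)
  fit <- kabschSuperpose(moved, x)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$transform@rotation %*% R90, diag(3), tolerance = 1e-9)

  expect_error(kabschSuperpose(x, x[1:5, ]), "equal dimensions")
})

test_that("superposition never increases RMSD and ignores rigid pre-transforms", {
  set.seed(22)
  for (rep in 1:10) {
    x <- matrix(rnorm(45), 15, 3)
    y <- matrix(rnorm(45), 15, 3)
    fit <- kabschSuperpose(x, y)
    expect_lte(fit$rmsd, rmsd(x, y) + 1e-12)
    pre <- randomRotation()
    x2 <- sweep(x %*% t(pre), 2, rnorm(3), `+`)
    expect_equal(kabschSuperpose(x2, y)$rmsd, fit$rmsd, tolerance = 1e-9)
  }
})

test_that("preprocessPair aligns, restricts and superposes end onto start", {
  pair0 <- makeMorphPair(n = 15, hingeAngle = 20, seed = 5)
  start <- pair0$start
  # give the end structure an arbitrary rigid offset and an extra residue gap
  endXyz <- caCoords(pair0$end)
  endXyz <- sweep(endXyz %*% t(randomRotation()), 2, c(10, 0, -4), `+`)
  end <- CaTrace(endXyz, sequence = caSequence(pair0$end))
  prep <- preprocessPair(start, end)
  expect_s4_class(prep$pair, "AlignedPair")
  expect_equal(nResidues(prep$pair@start), 15L)
  # superposition must undo the arbitrary offset
  expect_equal(prep$rmsd, kabschSuperpose(pair0$end, start)$rmsd,
               tolerance = 1e-6)
  expect_equal(prep$maxDisplacement,
               maxDisplacement(start, kabschSuperpose(pair0$end,
                                                      start)$coords),
               tolerance = 1e-6)
})
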