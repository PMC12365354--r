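fix <- reference_fixtures()

test_that("densify interpolates through the knots on a shared parameter", {
  # collinear knots stay collinear (cubic reproduces linear data)
  dn <- densify(fix$line$knots)
  expect_equal(nrow(dn$points), 100)
  expect_lt(max(abs(dn$points[, 2])), 1e-9)

  # all 11 knots reproduced among the outputs
  set.seed(1)
  kn <- random_contour_knots()
  dn <- densify(kn)
  expect_false(is.null(dn$knot_index))
  expect_equal(dn$points[dn$knot_index, ], unname(kn),
               ignore_attr = TRUE, tolerance = 1e-9)

  # knots on a unit semicircle: dense curve hugs the circle
  dn <- densify(fix$semicircle$knots)
  r <- sqrt(rowSums(dn$points^2))
  expect_lt(max(abs(r - 1)), 0.01)

  # degenerate input: coincident consecutive knots
  bad <- fix$line$knots
  bad[5, ] <- bad[4, ]
  expect_error(densify(bad), "coincident")
})

test_that("highest point is the y-argmax with posterior tie-breaking", {
  # unit semicircle apex
  hp <- highest_point(densify(fix$semicircle$knots))
  expect_equal(unname(hp["x"]), 0, tolerance = 0.02)
  expect_equal(unname(hp["y"]), 1, tolerance = 0.02)

  # strictly rising contour: last (most anterior) point
  rising <- cbind(0:10, seq(0, 5, length.out = 11))
  dn <- densify(rising)
  hp <- highest_point(dn)
  expect_equal(attr(hp, "index"), nrow(dn$points))

  # two-bump contour: the taller (anterior) bump wins, matching an
  # exhaustive scan over the dense points
  dn <- densify(fix$two_bump$knots)
  hp <- highest_point(dn)
  brute <- dn$points[which.max(dn$points[, 2]), ]
  expect_equal(as.numeric(hp), as.numeric(brute))
  expect_equal(unname(hp["x"]), fix$two_bump$expected$apex_near_x,
               tolerance = 1.5)

  # exact ties break to the most posterior point
  flat <- as_dense_contour(cbind(seq(0, 10, length.out = 50), rep(1, 50)))
  expect_identical(attr(highest_point(flat), "index"), 1L)
})

test_that("highest vertex reproduces planar triangle geometry", {
  tri <- highest_vertex(as_dense_contour(fix$triangle$points))
  ex <- fix$triangle$expected
  expect_equal(unname(tri$HV), unname(ex$hv))
  expect_equal(unname(tri$D), unname(ex$d), tolerance = 1e-12)
  expect_equal(tri$AB, ex$ab)
  expect_equal(tri$AD, ex$ad, tolerance = 1e-12)
  expect_equal(tri$DB, ex$db, tolerance = 1e-12)
  expect_equal(tri$HVD, ex$hvd, tolerance = 1e-12)

  # chord-relative lengths survive a rigid rotation
  set.seed(2)
  rot <- random_similarity(fix$triangle$points, angle = pi / 6, s = 1,
                           tr = c(0, 0))
  tri2 <- highest_vertex(as_dense_contour(rot))
  expect_equal(tri2$HVD, tri$HVD, tolerance = 1e-9)
  expect_equal(tri2$AB, tri$AB, tolerance = 1e-9)
  expect_equal(tri2$AD, tri$AD, tolerance = 1e-9)

  # random smooth bump: HV equals exhaustive point-wise maximisation
  kn <- random_contour_knots()
  dn <- densify(kn)
  tri3 <- highest_vertex(dn)
  A <- dn$points[1, ]; B <- dn$points[nrow(dn$points), ]
  u <- (B - A) / sqrt(sum((B - A)^2))
  rel <- sweep(dn$points, 2, A)
  perp <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])
  expect_equal(unname(tri3$HV), unname(dn$points[which.max(perp), ]))

  # degenerate chord
  loop <- rbind(fix$triangle$points, fix$triangle$points[1, ] + 1e-9)
  expect_error(highest_vertex(as_dense_contour(loop)), "degenerate")
})

test_that("curvature ratios follow the triangle definitions", {
  tri <- highest_vertex(as_dense_contour(fix$triangle$points))
  cr <- curvature_ratios(tri)
  expect_identical(cr$tcp, 0.3)
  expect_identical(cr$tc, 2 / 3)
  expect_false(cr$degenerate)

  # symmetric arch: apex projects to the chord midpoint, TC = 1
  arch <- highest_vertex(densify(fix$semicircle$knots))
  cra <- curvature_ratios(arch)
  expect_equal(cra$tc, 1, tolerance = 1e-6)

  # flat contour: TCP 0, TC NaN, flagged
  flat <- highest_vertex(as_dense_contour(cbind(0:20, rep(0, 21))))
  crf <- curvature_ratios(flat)
  expect_identical(crf$tcp, 0)
  expect_true(is.nan(crf$tc))
  expect_true(crf$degenerate)
})

test_that("MCI recovers total turning of analytic shapes", {
  expect_lt(mci(densify(fix$line$knots)), 1e-6)

  # circular arcs: MCI equals the subtended angle, any radius
  for (nm in c("arc_pi_6", "arc_pi_2", "arc_pi")) {
    got <- mci(densify(fix[[nm]]$knots))
    expect_equal(got, fix[[nm]]$expected$mci,
                 tolerance = 0.02 * fix[[nm]]$expected$mci)
  }
  # radius invariance of the arc result
  th <- seq(pi * 0.75, pi * 0.25, length.out = 11)
  big <- cbind(250 * cos(th), 250 * sin(th))
  expect_equal(mci(densify(big)), pi / 2, tolerance = 0.02 * pi / 2)

  # quarter circle + straight segment, against the 10k-point turning oracle
  expected <- oracle_turning(fix$quarter_segment$points)
  expect_equal(expected, pi / 2, tolerance = 1e-4)
  got <- mci(densify(fix$quarter_segment$knots))
  expect_equal(got, expected, tolerance = 0.02 * expected)

  expect_error(mci(as_dense_contour(cbind(0:3, 0:3))), "at least 5")
})

test_that("shape measures are similarity-invariant, coordinates are not", {
  set.seed(7)
  for (i in 1:25) {
    kn <- random_contour_knots()
    dn <- densify(kn)
    cr <- curvature_ratios(highest_vertex(dn))
    m0 <- mci(dn)
    kn2 <- random_similarity(kn)
    dn2 <- densify(kn2)
    cr2 <- curvature_ratios(highest_vertex(dn2))
    expect_equal(cr2$tcp, cr$tcp, tolerance = 1e-6)
    expect_equal(cr2$tc, cr$tc, tolerance = 1e-6)
    expect_equal(mci(dn2), m0, tolerance = 1e-3)
  }

  # a 15-degree rotation moves HP but not the chord-relative HVD
  set.seed(8)
  kn <- random_contour_knots(bump = 6, center = 1.1)  # asymmetric bump
  rot <- random_similarity(kn, angle = 15 * pi / 180, s = 1, tr = c(0, 0))
  tri0 <- highest_vertex(densify(kn))
  tri1 <- highest_vertex(densify(rot))
  expect_lt(abs(tri1$HVD - tri0$HVD), 1e-6)
  hp0 <- highest_point(densify(kn))
  hp1 <- highest_point(densify(rot))
  expect_gt(abs(hp1["x"] - hp0["x"]), 0.5)  # HP is rotation-sensitive
})

test_that("the measure battery has the 8 x 8 structure and exact knot identities", {
  nm <- measure_names()
  expect_length(nm$position, 8)
  expect_length(nm$height_shape, 8)
  expect_equal(nrow(measure_combos()), 64)
  # alias swap renames without touching the math
  al <- measure_combos(alias = c(TCP = "TC", TC = "TCP"))
  expect_equal(sort(unique(al$height_shape)),
               sort(unique(measure_combos()$height_shape)))

  set.seed(9)
  kn <- random_contour_knots()
  kn[5, ] <- c(42.0, 31.5)
  k <- knot_contour("S1", "t1", "bad", 2, kn)
  rec <- extract_measures(k)
  expect_identical(rec$K5_X, 42.0)
  expect_identical(rec$K5_Y, 31.5)
  expect_identical(rec$K2_X, unname(kn[2, 1]))
  expect_identical(rec$K7_Y, unname(kn[7, 2]))
  expect_named(rec, c("speaker", "token", "vowel", "repetition",
                      measure_names()$all, "degenerate"))

  # unrotated contours are refused
  raw <- knot_contour("S1", "t2", "bad", 1, kn, rotated = FALSE)
  expect_error(extract_measures(raw), "rotated")

  # horizontal-chord arch: HP and HV coincide
  rec2 <- extract_measures(knot_contour("S", "t", "bid", 1,
                                        fix$semicircle$knots))
  expect_equal(rec2$HP_Y, rec2$HV_Y, tolerance = 0.01)

  # batch over synthetic tokens: no NaN except flagged degenerates
  cohort <- generate_cohort(small_cohort_config(n_speakers = 2))
  m <- measure_table(cohort$dataset)
  for (v in measure_names()$all)
    expect_true(all(is.finite(m[[v]]) | m$degenerate))
})

test_that("the dorsum-restricted highest-point window is honoured", {
  dn <- densify(fix$two_bump$knots)
  hp_all <- highest_point(dn)
  # restricting the search to the posterior half finds the smaller bump
  hp_win <- highest_point(dn, window = c(1, 6))
  expect_lt(hp_win["x"], hp_all["x"])
  expect_lt(hp_win["y"], hp_all["y"])
  expect_error(highest_point(as_dense_contour(dn$points), window = c(1, 6)),
               "spline-densified")
})
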