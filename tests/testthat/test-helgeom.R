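std_base_model_atoms <- function(code) {
  std <- std_base_coords(code)
  data.frame(name = std$name, resname = code, x = std$x, y = std$y, z = std$z,
             stringsAsFactors = FALSE)
}

test_that("base frames reproduce identity, rotations and noisy geometry", {
  atoms <- std_base_model_atoms("G")
  f <- base_frame(atoms)
  expect_equal(f$triad, diag(3), tolerance = 1e-8)
  expect_equal(f$origin, c(0, 0, 0), tolerance = 1e-8)

  set.seed(5)
  R <- random_rotation()
  t0 <- c(3, -2, 7)
  rotated <- atoms
  rotated[, c("x", "y", "z")] <-
    sweep(as.matrix(atoms[, c("x", "y", "z")]) %*% t(R), 2, t0, "+")
  f2 <- base_frame(rotated)
  expect_equal(f2$triad, R, tolerance = 1e-8)
  expect_equal(f2$origin, as.numeric(t0), tolerance = 1e-8)

  noisy <- rotated
  noisy[, c("x", "y", "z")] <- noisy[, c("x", "y", "z")] +
    matrix(rnorm(nrow(noisy) * 3, 0, 0.05), ncol = 3)
  f3 <- base_frame(noisy)
  ang <- acos((sum(diag(t(f3$triad) %*% R)) - 1) / 2) * 180 / pi
  expect_lt(ang, 1)
})

test_that("missing base atoms are reported by name", {
  atoms <- std_base_model_atoms("G")
  atoms <- atoms[!atoms$name %in% c("N1", "C2", "N2", "N3", "C4", "C5", "C6"), ]
  expect_error(base_frame(atoms), "missing base atoms")
  expect_error(base_frame(atoms), "N1")
})

test_that("pair frames average the flipped complementary frame", {
  f <- helixion:::new_frame(c(1, 2, 3), diag(3))
  flipped <- helixion:::new_frame(c(1, 2, 3), diag(c(1, -1, -1)))
  pf <- pair_frame(f, flipped)
  expect_equal(pf$triad, diag(3), tolerance = 1e-12)
  expect_equal(pf$origin, c(1, 2, 3))

  # frames mirror-symmetric about the xz plane: mid-frame lies on the mirror
  Ry <- helixion:::rot_axis(c(1, 0, 0), 0.3)
  fa <- helixion:::new_frame(c(0, 1, 0), Ry)
  fb <- helixion:::new_frame(c(0, -1, 0), t(Ry) %*% diag(c(1, -1, -1)))
  pm <- pair_frame(fa, fb)
  expect_equal(pm$origin, c(0, 0, 0))
  expect_equal(pm$triad, diag(3), tolerance = 1e-12)

  anti <- helixion:::new_frame(c(0, 0, 0),
                               helixion:::rot_axis(c(1, 0, 0), pi) %*% diag(c(1, -1, -1)))
  expect_error(pair_frame(f, anti), "anti-aligned")
})

test_that("pair origins of a generator duplex sit near the helix axis", {
  m <- cg5_duplex()
  pf <- duplex_pair_frames(m)
  ax <- screw_axis(pf)
  origins <- helixion:::pair_origins(pf)
  rel <- sweep(origins, 2, ax$point)
  radial <- sqrt(rowSums((rel - outer(as.numeric(rel %*% ax$direction),
                                      ax$direction))^2))
  expect_lt(max(radial) - min(radial), 0.2)
})

test_that("helix axis line fit recovers direction and orientation", {
  z <- cbind(0, 0, seq(0, 25, length.out = 8))
  ax <- helix_axis(z)
  expect_equal(ax$direction, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(helix_axis(z[nrow(z):1, ])$direction, c(0, 0, -1),
               tolerance = 1e-12)

  # long ideal helix (the straight-line fit needs several full turns)
  th <- (0:99) * (20 * pi / 100)
  helix <- cbind(4 * cos(th), 4 * sin(th), 2.8 * th / (2 * pi / 10))
  axh <- helix_axis(helix)
  ang <- acos(abs(sum(axh$direction * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 0.5)
  expect_error(helix_axis(z[1:3, ]), "at least 4")
})

test_that("built inclination is recovered across the A-form range", {
  for (target in c(0, 5, 10, 18.75, 25)) {
    m <- build_duplex(helix_spec("CGCGCGCGCG", inclination = target),
                      box_padding = NULL)
    inc <- inclination(duplex_pair_frames(m))
    expect_lt(abs(inc$mean - target), if (target == 0) 0.2 else 0.5)
  }
})

test_that("measured vs built inclination has unit slope", {
  built <- seq(5, 25, 5)
  measured <- vapply(built, function(t) {
    m <- build_duplex(helix_spec("CGCGCGCGCG", inclination = t),
                      box_padding = NULL)
    inclination(duplex_pair_frames(m))$mean
  }, numeric(1))
  slope <- coef(lm(measured ~ built))[2]
  expect_lt(abs(slope - 1), 0.02)
})

test_that("step parameters invert apply_step exactly", {
  f1 <- helixion:::new_frame(c(0, 0, 0), diag(3))
  f2 <- apply_step(f1, twist = 32.7, rise = 2.8)
  s <- helixion:::step_between(f1, f2)
  expect_equal(unname(s["twist"]), 32.7, tolerance = 1e-10)
  expect_equal(unname(s["roll"]), 0, tolerance = 1e-10)
  expect_equal(unname(s["rise"]), 2.8, tolerance = 1e-10)

  set.seed(8)
  for (i in 1:20) {
    fa <- helixion:::new_frame(rnorm(3, sd = 5), random_rotation())
    tw <- runif(1, 10, 50)
    ro <- runif(1, -15, 15)
    ti <- runif(1, -8, 8)
    sh <- rnorm(1)
    sl <- rnorm(1)
    ri <- runif(1, 2, 4)
    fb <- apply_step(fa, tw, ro, ti, sh, sl, ri)
    s <- helixion:::step_between(fa, fb)
    expect_equal(unname(s), c(tw, ro, ti, sh, sl, ri), tolerance = 1e-8)
  }

  same <- helixion:::step_between(f1, f1)
  expect_equal(unname(same), rep(0, 6), tolerance = 1e-12)
})

test_that("roll-twist construction matches the measured inclination", {
  for (rho in c(0, 5, 10)) {
    nominal <- regular_helix_axis(32.7, rho)$inclination
    spec <- helix_spec("GCGCGCGCGC", roll = rho, twist = 32.7)
    m <- build_duplex(spec, box_padding = NULL)
    inc <- inclination(duplex_pair_frames(m))
    expect_lt(abs(inc$mean - nominal), 0.2)
  }
})

test_that("helical parameters are invariant under rigid motion", {
  m <- cg5_duplex()
  pf <- duplex_pair_frames(m)
  inc0 <- inclination(pf)
  st0 <- step_params(pf)
  set.seed(13)
  R <- random_rotation()
  t0 <- rnorm(3, sd = 20)
  m2 <- m
  xyz <- sweep(coords(m) %*% t(R), 2, t0, "+")
  m2 <- helixion:::set_coords(m2, xyz)
  pf2 <- duplex_pair_frames(m2)
  inc2 <- inclination(pf2)
  expect_equal(inc2$mean, inc0$mean, tolerance = 1e-6)
  expect_equal(step_params(pf2)$twist, st0$twist, tolerance = 1e-6)
  expect_equal(step_params(pf2)$rise, st0$rise, tolerance = 1e-6)
})

test_that("terminal pairs do not influence the reported inclination", {
  m <- cg5_duplex()
  pf <- duplex_pair_frames(m)
  inc0 <- inclination(pf, exclude_terminal = 2)
  # distort the two outermost pairs at both ends
  for (k in c(1, 2, 9, 10)) {
    pf[[k]]$origin <- pf[[k]]$origin + c(3, -2, 1)
    pf[[k]]$triad <- helixion:::rot_axis(c(1, 1, 0), 0.4) %*% pf[[k]]$triad
  }
  inc1 <- inclination(pf, exclude_terminal = 2)
  expect_equal(inc1$mean, inc0$mean, tolerance = 1e-12)
  expect_error(inclination(pf, exclude_terminal = 5), "leaves no pairs")
})

test_that("fraying changes end-to-end distance but not inclination", {
  m <- cg5_duplex()
  closed <- make_trajectory(m, noise = noise_spec(n_frames = 6, seed = 41))
  frayed <- make_trajectory(m, noise = noise_spec(p_open = 1, n_frames = 6,
                                                  seed = 41))
  h0 <- helical_series(closed)
  h1 <- helical_series(frayed)
  expect_gt(abs(mean(h1$end_to_end) - mean(h0$end_to_end)), 0.5)
  expect_lt(abs(mean(h1$inclination) - mean(h0$inclination)), 0.3)
})

test_that("end-to-end distance follows the construction", {
  m <- build_duplex(helix_spec("AUAUAUAUAU", inclination = 0, rise = 2.8),
                    box_padding = NULL)
  pf <- duplex_pair_frames(m)
  expect_equal(end_to_end(pf), 9 * 2.8, tolerance = 0.1)
  expect_equal(end_to_end(pf[1]), 0)
})

test_that("dihedral matches the rotation-matrix oracle", {
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_equal(dihedral(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0)), 180)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")

  oracle <- function(p1, p2, p3, p4) {
    # rotate so the central bond is +z, then read the angle in the xy plane
    b <- p3 - p2
    b <- b / sqrt(sum(b * b))
    ref <- if (abs(b[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- ref - sum(ref * b) * b
    e1 <- e1 / sqrt(sum(e1 * e1))
    e2 <- helixion:::cross3(b, e1)
    v1 <- p1 - p2
    v2 <- p4 - p3
    a1 <- atan2(sum(v1 * e2), sum(v1 * e1))
    a2 <- atan2(sum(v2 * e2), sum(v2 * e1))
    ang <- (a1 - a2) * 180 / pi  # clockwise viewed along the central bond
    ang <- ((ang + 180) %% 360) - 180
    if (ang <= -180) ang + 360 else ang
  }
  set.seed(17)
  for (i in 1:200) {
    pts <- matrix(rnorm(12, sd = 3), ncol = 3)
    got <- tryCatch(dihedral(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                    error = function(e) NA)
    if (is.na(got)) next
    want <- oracle(pts[1, ], pts[2, ], pts[3, ], pts[4, ])
    delta <- abs(got - want)
    expect_lt(min(delta, 360 - delta), 1e-6)
  }
})

test_that("sugar pucker analysis inverts the pseudorotation construction", {
  ps <- sugar_pucker(pucker_torsions(18, 38))
  expect_equal(ps$phase, 18, tolerance = 0.5)
  expect_equal(ps$amplitude, 38, tolerance = 0.5)
  expect_equal(ps$class, "C3'-endo")
  expect_equal(sugar_pucker(pucker_torsions(162, 38))$class, "C2'-endo")
  # round trip across the full pseudorotation wheel
  for (p in seq(0, 350, 25)) {
    st <- sugar_pucker(pucker_torsions(p, 40))
    expect_equal(st$phase, p, tolerance = 1e-6)
    expect_equal(st$amplitude, 40, tolerance = 1e-6)
  }
})

test_that("a planar ring reports indeterminate phase and the pucker needs all atoms", {
  th <- seq(90, 90 + 360, length.out = 6)[1:5] * pi / 180
  ring <- data.frame(name = c("C1'", "C2'", "C3'", "C4'", "O4'"),
                     x = 1.25 * cos(th), y = 1.25 * sin(th), z = 0)
  st <- sugar_pucker(ring)
  expect_true(st$indeterminate)
  expect_equal(st$amplitude, 0)
  expect_true(is.na(st$phase))
  expect_error(sugar_pucker(ring[-2, ]), "missing ring atom")

  # geometric ring built from a puckered conformation classifies C3'-endo
  m <- cg3_duplex()
  st2 <- sugar_pucker(m, "A", 2)
  expect_false(st2$indeterminate)
  expect_gt(st2$amplitude, 10)
})
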