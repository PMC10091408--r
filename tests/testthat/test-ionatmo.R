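make_profile <- function(r, y) {
  structure(list(bin_edges = c(r - 0.05, r[length(r)] + 0.05), counts = y,
                 bin_width = 0.1, n_frames = 1, n_obs = sum(y),
                 concentration = NULL),
            class = "rdf_profile")
}

test_that("min_surface_distance matches simple geometry and brute force", {
  expect_equal(min_surface_distance(c(1, 2, 3),
                                    matrix(c(1, 2, 3), ncol = 3)), 0)
  rna <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(min_surface_distance(c(5, 0, 0), rna), 5)
  set.seed(42)
  for (rep in 1:10) {
    atoms <- matrix(rnorm(150, sd = 8), ncol = 3)
    ions <- matrix(rnorm(60, sd = 12), ncol = 3)
    brute <- apply(ions, 1, function(p)
      min(sqrt(colSums((t(atoms) - p)^2))))
    expect_equal(min_surface_distance(ions, atoms), brute, tolerance = 1e-10)
  }
})

test_that("rdf histogram bins per-frame minimal distances at 0.1 A", {
  rna <- rbind(c(0, 0, 0), c(10, 0, 0))
  ions <- rbind(c(-1.05, 0, 0), c(0, 1.07, 0), c(13.33, 0, 0))
  m <- point_model(rna, ions)
  tr <- trajectory(m, list(coords(m)))
  p <- rdf_histogram(tr, "ions", "nucleic", max_range = 10)
  r <- helixion:::bin_centers(p)
  expect_equal(p$counts[r > 1.0 & r < 1.1], 2)
  expect_equal(p$counts[r > 3.3 & r < 3.4], 1)
  expect_equal(sum(p$counts), 3)
})

test_that("histogram total times frames equals in-range observations", {
  m <- cg3_duplex()
  tr <- make_trajectory(m, atmosphere_spec(n_ions = 8, seed = 3),
                        noise_spec(n_frames = 25, seed = 4))
  p <- rdf_histogram(tr, max_range = 30)
  expect_equal(sum(p$counts) * p$n_frames, p$n_obs)
  expect_equal(p$n_obs, 8 * 25)  # box smaller than 30 A range: all in range
})

test_that("overlapping or empty selections are rejected", {
  m <- cg3_duplex()
  tr <- trajectory(m, list(coords(m)))
  expect_error(rdf_histogram(tr, "nucleic", "nucleic"), "overlap")
  expect_error(rdf_histogram(tr, "ions", "nucleic"), "no atoms")
})

test_that("histogram modes recover the generator shell centres", {
  s <- shell_sample()
  m <- add_ions(s$model, s$pos, "K+")
  tr <- trajectory(m, list(coords(m)))
  p <- rdf_histogram(tr, max_range = 12)
  b <- detect_shells(p, search_limit = 9)
  expect_lt(abs(b$r_peak1 - 3.4), 0.1 + 1e-9)
  expect_lt(abs(b$r_peak2 - 6.2), 0.1 + 1e-9)
})

test_that("probe volumes match analytic spherical shells for a point solute", {
  atoms <- data.frame(serial = 1L, name = "C1", element = "C", chain = "A",
                      resid = 1L, resname = "G", icode = "",
                      x = 7, y = 7, z = 7)
  pm <- rna_model(atoms, box = c(14, 14, 14))
  edges <- seq(0, 6.5, 0.1)
  vols <- mc_shell_volumes(pm, "all", edges, n_probe = 1e6, seed = 1)
  analytic <- 4 * pi / 3 * (edges[-1]^3 - edges[-length(edges)]^3)
  shellbins <- which(edges[-length(edges)] >= 3)  # solvation-shell regime
  rel <- abs(vols[shellbins] - analytic[shellbins]) / analytic[shellbins]
  expect_lt(max(rel), 0.02)
})

test_that("concentration is zero without ions and flat for a bulk-only gas", {
  m <- cg5_duplex()
  # zero ions anywhere: all-zero counts
  p0 <- make_profile(seq(0.05, 10, 0.1), rep(0, 100))
  p0 <- concentration_profile(p0, m, n_probe = 2e4, seed = 1)
  expect_true(all(p0$concentration[!is.na(p0$concentration)] == 0))

  spec <- atmosphere_spec(shell_weights = c(0, 0), bulk_fraction = 1,
                          n_ions = 4000, exclusion = 2.5, seed = 8)
  pos <- sample_atmosphere(m, spec, n_ions = 4000)
  mi <- add_ions(m, pos, "K+")
  tr <- trajectory(mi, list(coords(mi)))
  p <- rdf_histogram(tr, max_range = 16)
  p <- concentration_profile(p, m, n_probe = 2e5, seed = 2)
  # aggregate concentration beyond 10 A against the bulk expectation
  sel <- helixion:::bin_centers(p) > 10 & p$shell_volume > 0
  v_far <- sum(p$shell_volume[sel])
  counts_far <- sum(p$counts[sel])
  v_excl <- sum(p$shell_volume[helixion:::bin_centers(p) <= spec$exclusion])
  v_allowed <- prod(m$box) - v_excl
  expected <- 4000 * v_far / v_allowed
  expect_lt(abs(counts_far - expected), 3 * sqrt(expected))
})

test_that("shell boundaries are found where they were constructed", {
  r <- seq(0.05, 9.95, 0.1)
  # piecewise-linear bimodal profile with minima built at 3.45 and 6.25
  y <- approx(x = c(0.05, 2.65, 3.45, 5.15, 6.25, 7.95, 9.95),
              y = c(0.10, 2.00, 0.20, 1.20, 0.40, 0.80, 0.80),
              xout = r)$y
  b <- detect_shells(make_profile(r, y), search_limit = 9)
  expect_lt(abs(b$r_min1 - 3.5), 0.1 + 1e-9)
  expect_lt(abs(b$r_min2 - 6.3), 0.1 + 1e-9)
  expect_lt(abs(b$r_peak1 - 2.65), 0.1 + 1e-9)

  # single shell + flat tail: no second minimum, fallback applies
  bump <- function(x, c, w) pmax(0, 1 - ((x - c) / w)^2)
  y1 <- 2 * bump(r, 3.0, 1.0) + 0.1
  b1 <- detect_shells(make_profile(r, y1))
  expect_true(is.na(b1$r_min2))
  expect_equal(b1$fallback_radius, 6.3)
  expect_gt(b1$r_min1, 3.0)

  # monotone profile: no shell structure
  expect_error(detect_shells(make_profile(r, r)), "no shell structure")
})

test_that("detected first minimum tracks the constructed one over 3.3-3.5 A", {
  r <- seq(0.05, 9.95, 0.1)
  for (c1 in c(3.3, 3.4, 3.5)) {
    y <- dnorm(r, c1 - 1.2, 0.45) + 0.55 * dnorm(r, 6.2, 0.5) + 0.02
    truth <- optimize(function(x)
      dnorm(x, c1 - 1.2, 0.45) + 0.55 * dnorm(x, 6.2, 0.5) + 0.02,
      c(c1 - 1.2, 6.2))$minimum
    b <- detect_shells(make_profile(r, y), search_limit = 9)
    expect_lt(abs(b$r_min1 - truth), 0.1 + 1e-9)
  }
})

test_that("shell occupancy counts cumulative ions per convention", {
  rna <- rbind(c(0, 0, 0), c(10, 0, 0))
  ions <- rbind(c(-2, 0, 0), c(0, 4, 0), c(10, 0, 7))
  m <- point_model(rna, ions)
  tr <- trajectory(m, list(coords(m)))
  b <- structure(list(r_peak1 = 2, r_min1 = 3.5, r_peak2 = 5, r_min2 = 6.3,
                      fallback_radius = 6.3), class = "shell_boundaries")
  occ <- shell_occupancy(tr, boundaries = b)
  expect_equal(occ$n_first, 1)
  expect_equal(occ$n_second, 2)
  expect_equal(occ$n_fallback, 2)
  # per-shell (non-cumulative) counts on request
  occ2 <- shell_occupancy(tr, boundaries = b, cumulative = FALSE)
  expect_equal(occ2$n_second, 1)

  far <- point_model(rna, rbind(c(0, 0, 20), c(20, 20, 0)))
  occ3 <- shell_occupancy(trajectory(far, list(coords(far))), boundaries = b)
  expect_equal(c(occ3$n_first, occ3$n_second, occ3$n_fallback), c(0, 0, 0))
})

test_that("cumulative occupancy is monotone in radius", {
  m <- cg3_duplex()
  tr <- make_trajectory(m, atmosphere_spec(n_ions = 10, seed = 5),
                        noise_spec(n_frames = 20, seed = 6))
  idx <- helixion:::resolve_ion_rna(tr, "ions", "nucleic")
  radii <- seq(1, 12, 0.5)
  nr <- vapply(radii, function(r) {
    mean(vapply(tr$frames, function(xyz)
      sum(min_surface_distance(xyz[idx$ions, , drop = FALSE],
                               xyz[idx$rna, , drop = FALSE]) <= r),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(nr) >= 0))
  expect_true(all(nr <= 10))
})

test_that("shell occupancies match the generator expectation", {
  m <- cg5_duplex()
  spec <- atmosphere_spec(shell_centers = c(3.4, 5.5),
                          shell_widths = c(0.2, 0.2),
                          shell_weights = c(8 / 13, 5 / 13),
                          bulk_fraction = 0, n_ions = 13, seed = 21)
  tr <- make_trajectory(m, spec, noise_spec(n_frames = 500, seed = 22))
  b <- structure(list(r_peak1 = 3.4, r_min1 = 4.5, r_peak2 = 5.5,
                      r_min2 = NA_real_, fallback_radius = 6.3),
                 class = "shell_boundaries")
  occ <- shell_occupancy(tr, boundaries = b)
  p1 <- 8 / 13
  se1 <- sqrt(13 * p1 * (1 - p1) / 500)
  expect_lt(abs(occ$n_first - 8), 3 * se1)
  expect_lt(abs(occ$n_fallback - 13), max(3 * occ$sd_fallback / sqrt(500), 0.01))
})

test_that("residue occupancy counts ions near a nucleotide centre", {
  m <- cg3_duplex()
  xyz <- coords(m)
  idx3 <- helixion:::residue_atom_idx(m, "A", 3)
  c3 <- colMeans(xyz[idx3, , drop = FALSE])
  all_res <- helixion:::residue_table(m)
  centroids <- t(vapply(seq_len(nrow(all_res)), function(i) {
    ai <- helixion:::residue_atom_idx(m, all_res$chain[i], all_res$resid[i])
    colMeans(xyz[ai, , drop = FALSE])
  }, numeric(3)))
  # place the ion 1 A from the A3 centre, clear of every other residue centre
  set.seed(99)
  cand <- matrix(rnorm(300), ncol = 3)
  cand <- cand / sqrt(rowSums(cand^2))
  clearance <- apply(cand, 1, function(u)
    min(sqrt(rowSums(sweep(centroids[-3, , drop = FALSE], 2, c3 + u)^2))))
  ion <- c3 + cand[which.max(clearance), ]
  expect_gt(max(clearance), 3.5)
  mi <- add_ions(m, matrix(ion, ncol = 3), "K+")
  tr <- trajectory(mi, rep(list(coords(mi)), 4))
  occ <- residue_occupancy(tr, cutoff = 3.5)
  hit <- occ$chain == "A" & occ$resid == 3
  expect_equal(occ$mean[hit], 1)
  expect_true(all(occ$mean[!hit] == 0))
  expect_true(all(residue_occupancy(tr, cutoff = 0)$mean == 0))
})

test_that("palindromic duplex yields a symmetric occupancy profile", {
  m <- cg5_duplex()
  tr <- make_trajectory(m, atmosphere_spec(n_ions = 18, seed = 31),
                        noise_spec(n_frames = 150, seed = 32))
  occ <- residue_occupancy(tr, site_class = "major_groove", cutoff = 3.5)
  a <- occ[occ$chain == "A", ]
  b <- occ[occ$chain == "B", ]
  a <- a[order(a$resid), ]
  b <- b[order(b$resid), ]
  tol <- 3 * sqrt(a$sd^2 + b$sd^2) / sqrt(150) + 0.02
  expect_true(all(abs(a$mean - b$mean) < tol))
})
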