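# Build a sheared G.A pair: G contacts through its Sugar edge (N3, N2), A
# through its Hoogsteen edge (N7, N6); the adenine is then rotated about the
# fixed contact axis into the clash-free trans rotamer.
build_sheared_ga <- function(theta = 80) {
  g <- std_base_coords("G")
  a <- std_base_coords("A")
  gx <- as.matrix(g[, c("x", "y", "z")])
  rownames(gx) <- g$name
  ax <- as.matrix(a[, c("x", "y", "z")])
  rownames(ax) <- a$name
  N3g <- gx["N3", ]
  N2g <- gx["N2", ]
  dA <- sqrt(sum((ax["N6", ] - ax["N7", ])^2))
  u <- c(-cos(-0.2), sin(-0.2), 0)
  N6t <- N3g + 2.9 * u
  d12 <- N6t - N2g
  L <- sqrt(sum(d12^2))
  aa <- (2.9^2 - dA^2 + L^2) / (2 * L)
  h <- sqrt(max(2.9^2 - aa^2, 0))
  e <- d12 / L
  p <- c(-e[2], e[1], 0)
  N7t <- N2g + aa * e + h * p
  mid <- (N6t + N7t) / 2
  away <- mid - (N3g + N2g) / 2
  away <- away / sqrt(sum(away^2))
  relC5 <- ax["C5", ] - (ax["N6", ] + ax["N7", ]) / 2
  fit <- kabsch(ax[c("N6", "N7", "C5"), ],
                rbind(N6t, N7t, mid + sqrt(sum(relC5^2)) * away))
  axT <- sweep(ax %*% t(fit$R), 2, fit$t, "+")
  R <- helixion:::rot_axis(N7t - N6t, theta * pi / 180)
  axT <- sweep(sweep(axT, 2, N6t) %*% t(R), 2, N6t, "+")
  atoms <- rbind(
    data.frame(name = g$name, element = substr(g$name, 1, 1), chain = "A",
               resid = 1L, resname = "G", x = gx[, 1], y = gx[, 2], z = gx[, 3]),
    data.frame(name = a$name, element = substr(a$name, 1, 1), chain = "B",
               resid = 1L, resname = "A", x = axT[, 1], y = axT[, 2], z = axT[, 3]))
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms, icode = "")
  rna_model(atoms)
}

test_that("hydrogen bonds are found by distance and matched to brute force", {
  m <- cg3_duplex()
  hb <- find_hbonds(m)
  expect_gt(nrow(hb), 0)
  expect_true(all(hb$distance <= 3.4))

  # brute-force oracle: all donor-acceptor pairs across residues within cutoff
  atlas <- donor_acceptor_atlas()
  a <- m$atoms
  code <- normalize_resname(a$resname)
  don <- which(mapply(function(c, n) !is.na(c) && n %in% atlas[[c]]$donors,
                      code, a$name))
  acc <- which(mapply(function(c, n) !is.na(c) && n %in% atlas[[c]]$acceptors,
                      code, a$name))
  xyz <- coords(m)
  brute <- 0
  for (d in don) for (ac in acc) {
    if (a$chain[d] == a$chain[ac] && a$resid[d] == a$resid[ac]) next
    dd <- sqrt(sum((xyz[d, ] - xyz[ac, ])^2))
    if (dd <= 3.4 && dd > 1e-3) brute <- brute + 1
  }
  expect_equal(nrow(hb), brute)
})

test_that("the distance cutoff separates paired from unpaired bases", {
  m <- cg3_duplex()
  i <- helixion:::residue_atom_idx(m, "A", 2)
  j <- helixion:::residue_atom_idx(m, "B", 5)
  n1 <- i[m$atoms$name[i] == "N1"]   # G N1 donor (A2 is G)
  n3 <- j[m$atoms$name[j] == "N3"]   # C N3 acceptor
  d0 <- sqrt(sum((coords(m)[n1, ] - coords(m)[n3, ])^2))
  expect_lt(d0, 3.1)
  expect_true(any(find_hbonds(m, n1, n3)$distance < 3.4))
  # pull the strands apart: same atoms beyond the cutoff
  far <- m
  bsel <- far$atoms$chain == "B"
  far$atoms$x[bsel] <- far$atoms$x[bsel] + 4
  expect_equal(nrow(find_hbonds(far, n1, n3)), 0)
})

test_that("canonical pairs classify as cis Watson-Crick with expected H-bonds", {
  m <- build_duplex(helix_spec("GACG", inclination = 18.75))
  gc <- classify_pair(m, "A", 1, "B", 4)
  expect_equal(c(gc$edge_i, gc$edge_j), rep("Watson-Crick", 2))
  expect_equal(gc$orientation, "cis")
  expect_equal(gc$n_hbonds, 3)
  expect_true(gc$is_canonical)

  au <- classify_pair(m, "A", 2, "B", 3)
  expect_equal(c(au$edge_i, au$edge_j), rep("Watson-Crick", 2))
  expect_equal(au$orientation, "cis")
  expect_equal(au$n_hbonds, 2)
  expect_true(au$is_canonical)
})

test_that("a sheared G.A pair classifies as trans Sugar/Hoogsteen", {
  m <- build_sheared_ga()
  ann <- classify_pair(m, "A", 1, "B", 1)
  expect_equal(ann$edge_i, "Sugar")
  expect_equal(ann$edge_j, "Hoogsteen")
  expect_equal(ann$orientation, "trans")
  expect_equal(ann$n_hbonds, 2)
  expect_false(ann$is_canonical)

  # atom-membership oracle: the H-bonded atoms belong to the assigned edges
  atlas <- edge_atlas()
  hb_names_i <- m$atoms$name[unique(c(ann$hbonds$donor, ann$hbonds$acceptor))]
  g_atoms <- intersect(hb_names_i, atlas$atom[atlas$base == "G"])
  expect_true(all(g_atoms %in% atlas$atom[atlas$base == "G" & atlas$edge == "S"] |
                    !g_atoms %in% c("N3", "N2")))
})

test_that("classification is symmetric in its arguments", {
  m <- build_sheared_ga()
  ab <- classify_pair(m, "A", 1, "B", 1)
  ba <- classify_pair(m, "B", 1, "A", 1)
  expect_equal(ab$edge_i, ba$edge_j)
  expect_equal(ab$edge_j, ba$edge_i)
  expect_equal(ab$orientation, ba$orientation)
  expect_equal(ab$n_hbonds, ba$n_hbonds)

  m2 <- cg3_duplex()
  ab2 <- classify_pair(m2, "A", 1, "B", 6)
  ba2 <- classify_pair(m2, "B", 6, "A", 1)
  expect_equal(ab2$edge_i, ba2$edge_j)
  expect_equal(ab2$orientation, ba2$orientation)
})

test_that("ideal duplexes give full sensitivity and decoys zero pairs", {
  m <- cg5_duplex()
  found <- find_pairs(m)
  canon <- found[found$is_canonical, ]
  expect_equal(nrow(canon), 10)
  expect_setequal(paste(canon$chain_i, canon$resid_i, canon$chain_j, canon$resid_j),
                  paste("A", 1:10, "B", 10:1))

  apart <- m
  bsel <- apart$atoms$chain == "B"
  apart$atoms$x[bsel] <- apart$atoms$x[bsel] + 50
  expect_equal(nrow(find_pairs(apart)), 0)
})

test_that("stacked neighbours are not misread as pairs", {
  m <- cg5_duplex()
  expect_null(classify_pair(m, "A", 4, "A", 5))
  expect_null(classify_pair(m, "B", 2, "B", 3))
})

test_that("fraying statistics count open frames exactly", {
  m <- cg3_duplex()
  base <- coords(m)
  frames <- rep(list(base), 100)
  bsel <- which(m$atoms$chain == "B" & m$atoms$resid == 6)  # pairs A1
  for (k in 1:30) {
    xyz <- base
    xyz[bsel, 1] <- xyz[bsel, 1] + 15
    frames[[k]] <- xyz
  }
  tr <- trajectory(m, frames)
  fr <- fraying_series(tr)
  expect_equal(unname(fr$open_fraction), c(0.30, 0))

  closed <- trajectory(m, rep(list(base), 20))
  expect_equal(unname(fraying_series(closed)$open_fraction), c(0, 0))
})

test_that("the fraying estimator is unbiased across opening rates", {
  m <- cg3_duplex()
  for (p in c(0.05, 0.2, 0.5)) {
    n <- 300
    tr <- make_trajectory(m, noise = noise_spec(p_open = p, n_frames = n,
                                                seed = round(1000 * p)))
    fr <- fraying_series(tr)
    tol <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(max(abs(fr$open_fraction - p)), tol)
  }
})
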