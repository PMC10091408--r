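# Base-pair reference frames, global helix axis, inclination and local step
# parameters, end-to-end distance, dihedrals and sugar pucker.
#
# Frames follow the standard-reference-frame convention: the observed base
# heavy atoms are least-squares fitted with the embedded standard base
# geometry; the transformed standard frame is the base frame (x toward the
# major groove, y along the pair long axis, z the base normal). A pair frame
# averages the two base frames after flipping the complementary strand's frame
# (y and z negated). Step parameters use the mid-step-frame (CEHS-style)
# construction, so build -> measure is an exact round trip.

#' Base reference frame of a residue
#'
#' Rigidly superposes the standard base geometry onto the observed base heavy
#' atoms; the transformed standard frame is returned.
#'
#' @param x an [rna_model()] (with `chain`/`resid`) or a residue atom
#'   data.frame with `name`, `x`, `y`, `z` and a recognisable `resname`.
#' @param chain,resid residue address when `x` is a model.
#' @param code optional one-letter base code override.
#' @return object of class `base_frame`: `origin` (length 3), `triad`
#'   (3x3, columns x/y/z), `code`, `rmsd` of the fit.
#' @export
base_frame <- function(x, chain = NULL, resid = NULL, code = NULL) {
  if (inherits(x, "rna_model")) {
    idx <- residue_atom_idx(x, chain, resid)
    if (length(idx) == 0) stop("no atoms for residue ", chain, ":", resid)
    atoms <- x$atoms[idx, , drop = FALSE]
  } else atoms <- x
  if (is.null(code)) {
    code <- normalize_resname(atoms$resname[1])
    if (is.na(code)) stop("unknown residue name: ", atoms$resname[1])
  }
  std <- std_base_coords(code)
  std <- std[std$name != "C1'", , drop = FALSE]
  hit <- match(std$name, atoms$name)
  present <- !is.na(hit)
  if (sum(present) < 6)
    stop("cannot build base frame: missing base atoms ",
         paste(std$name[!present], collapse = ", "))
  P <- as.matrix(std[present, c("x", "y", "z")])
  Q <- as.matrix(atoms[hit[present], c("x", "y", "z")])
  fit <- kabsch(P, Q)
  structure(list(origin = as.numeric(fit$t), triad = fit$R, code = code,
                 rmsd = fit$rmsd),
            class = "base_frame")
}

new_frame <- function(origin, triad, code = NA_character_) {
  structure(list(origin = as.numeric(origin), triad = triad, code = code,
                 rmsd = 0), class = "base_frame")
}

FLIP_YZ <- diag(c(1, -1, -1))

#' Mid-frame of a base pair
#'
#' Averages the two base frames after flipping the second (complementary
#' strand) frame's y and z axes, then re-orthonormalises.
#'
#' @param frame_a,frame_b `base_frame`s of the paired residues (strand A, B).
#' @param strict error on anti-aligned normals (default); with `strict =
#'   FALSE` a broken pair degrades to strand A's frame at the mid-origin,
#'   so trajectory summaries survive transiently open pairs.
#' @return a `base_frame` for the pair.
#' @export
pair_frame <- function(frame_a, frame_b, strict = TRUE) {
  Tb <- frame_b$triad %*% FLIP_YZ
  if (sum(frame_a$triad[, 3] * Tb[, 3]) < 0) {
    if (strict)
      stop("pairing geometry error: base normals anti-aligned beyond 90 degrees")
    return(new_frame((frame_a$origin + frame_b$origin) / 2, frame_a$triad,
                     paste0(frame_a$code, frame_b$code)))
  }
  triad <- orthonormalize((frame_a$triad + Tb) / 2)
  new_frame((frame_a$origin + frame_b$origin) / 2, triad,
            paste0(frame_a$code, frame_b$code))
}

#' Base-pair frames of a duplex model
#'
#' Pairs residue k of the first chain with residue n+1-k of the second chain
#' (antiparallel register) unless an explicit pair table is given.
#'
#' @param model an [rna_model()].
#' @param pairs optional data.frame with `chain_i`, `resid_i`, `chain_j`,
#'   `resid_j`.
#' @param strict passed to [pair_frame()].
#' @return list of `base_frame`s, ordered 5'->3' along the first chain.
#' @export
duplex_pair_frames <- function(model, pairs = NULL, strict = TRUE) {
  if (is.null(pairs)) pairs <- duplex_pair_table(model)
  lapply(seq_len(nrow(pairs)), function(k) {
    fa <- base_frame(model, pairs$chain_i[k], pairs$resid_i[k])
    fb <- base_frame(model, pairs$chain_j[k], pairs$resid_j[k])
    pair_frame(fa, fb, strict = strict)
  })
}

duplex_pair_table <- function(model) {
  res <- residue_table(model)
  chains <- unique(res$chain)
  if (length(chains) != 2)
    stop("automatic pairing expects exactly two nucleic chains; give `pairs`")
  a <- res[res$chain == chains[1], ]
  b <- res[res$chain == chains[2], ]
  if (nrow(a) != nrow(b)) stop("strands differ in length; give `pairs`")
  data.frame(chain_i = a$chain, resid_i = a$resid,
             chain_j = b$chain, resid_j = rev(b$resid),
             stringsAsFactors = FALSE)
}

pair_origins <- function(frames) {
  do.call(rbind, lapply(frames, function(f) f$origin))
}

#' Global helix axis through pair origins
#'
#' Straight least-squares line fit (principal axis) through the pair origins,
#' oriented 5'->3' along the first strand.
#'
#' @param origins m x 3 matrix of pair origins (ordered along the strand).
#' @return list with `point` (centroid) and unit `direction`.
#' @export
helix_axis <- function(origins) {
  if (nrow(origins) < 4)
    stop("helix axis fit needs at least 4 pair origins")
  centred <- sweep(origins, 2, colMeans(origins))
  sv <- svd(centred)
  if (sv$d[1] < 1e-9) stop("degenerate pair origins: axis fit failed")
  dir <- sv$v[, 1]
  span <- origins[nrow(origins), ] - origins[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  list(point = colMeans(origins), direction = as.numeric(dir))
}

#' Helix screw axis from consecutive pair frames
#'
#' Direction of the common screw axis, estimated as the (least-squares) mean
#' of the per-step rotation axes; exact for a regular helix and robust for
#' short duplexes where a line fit through the origins of an incomplete turn
#' is biased. Oriented 5'->3' along the first strand.
#'
#' @param pair_frames list of pair `base_frame`s (>= 2).
#' @return list with `point` (origin centroid) and unit `direction`.
#' @export
screw_axis <- function(pair_frames) {
  n <- length(pair_frames)
  if (n < 2) stop("screw axis needs at least 2 pair frames")
  axes <- matrix(0, nrow = 0, ncol = 3)
  for (k in seq_len(n - 1)) {
    R <- pair_frames[[k + 1]]$triad %*% t(pair_frames[[k]]$triad)
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (vnorm(v) > 1e-8) axes <- rbind(axes, unitv(v))
  }
  origins <- pair_origins(pair_frames)
  if (nrow(axes) == 0)  # untwisted: fall back to the line fit
    return(helix_axis(origins))
  dir <- unitv(colMeans(axes))
  span <- origins[n, ] - origins[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  list(point = colMeans(origins), direction = dir)
}

#' Base-pair inclination against the helix axis
#'
#' Per-pair signed angle between the pair long axis (y) and the plane
#' perpendicular to the helix axis; positive for the A-form-like backward
#' tilt of the base pairs. Two terminal pairs at each end are excluded by
#' default. Unless an axis is supplied, the straight global axis is the
#' screw axis estimated from the included pair frames (see [screw_axis()]).
#'
#' @param pair_frames list of pair `base_frame`s, 5'->3' along strand A.
#' @param axis optional axis (a list with unit `direction`), e.g. from
#'   [helix_axis()] or [screw_axis()].
#' @param exclude_terminal pairs dropped at each end before averaging.
#' @return list with `mean`, `sd`, `per_pair` (degrees) and the `axis` used.
#' @export
inclination <- function(pair_frames, axis = NULL, exclude_terminal = 2) {
  n <- length(pair_frames)
  idx <- seq_len(n)
  if (exclude_terminal > 0)
    idx <- idx[idx > exclude_terminal & idx <= n - exclude_terminal]
  if (length(idx) == 0)
    stop("terminal exclusion leaves no pairs")
  if (is.null(axis)) axis <- screw_axis(pair_frames[idx])
  per <- vapply(idx, function(k) {
    y <- pair_frames[[k]]$triad[, 2]
    rad2deg(asin(clamp1(sum(y * axis$direction))))
  }, numeric(1))
  list(mean = mean(per), sd = stats::sd(per),
       per_pair = stats::setNames(per, idx), axis = axis)
}

# --- step parameters (mid-step-frame construction) -------------------------

#' Local step parameters between consecutive base-pair frames
#'
#' Twist, roll and tilt are rotations about the mid-step frame axes; shift,
#' slide and rise are the origin displacement expressed in the mid-step frame.
#'
#' @param pair_frames list of pair `base_frame`s (>= 2).
#' @return data.frame with one row per step: `twist`, `roll`, `tilt`
#'   (degrees), `shift`, `slide`, `rise` (Angstrom).
#' @export
step_params <- function(pair_frames) {
  if (length(pair_frames) < 2) stop("need at least two pair frames")
  out <- lapply(seq_len(length(pair_frames) - 1), function(k) {
    s <- step_between(pair_frames[[k]], pair_frames[[k + 1]])
    data.frame(step = k, twist = s["twist"], roll = s["roll"],
               tilt = s["tilt"], shift = s["shift"], slide = s["slide"],
               rise = s["rise"])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

step_between <- function(f1, f2) {
  T1 <- f1$triad
  T2 <- f2$triad
  z1 <- T1[, 3]
  z2 <- T2[, 3]
  cg <- clamp1(sum(z1 * z2))
  gamma <- acos(cg)
  if (abs(gamma) < 1e-10) {
    hinge <- T1[, 1]  # arbitrary: no bend
    T1p <- T1
    T2p <- T2
  } else {
    hinge <- unitv(cross3(z1, z2))
    T1p <- rot_axis(hinge, gamma / 2) %*% T1
    T2p <- rot_axis(hinge, -gamma / 2) %*% T2
  }
  Tm <- orthonormalize((T1p + T2p) / 2)
  zm <- Tm[, 3]
  x1 <- T1p[, 1]
  x2 <- T2p[, 1]
  twist <- atan2(sum(cross3(x1, x2) * zm), sum(x1 * x2))
  phi <- atan2(sum(cross3(hinge, Tm[, 2]) * zm), sum(hinge * Tm[, 2]))
  roll <- gamma * cos(phi)
  tilt <- gamma * sin(phi)
  disp <- as.numeric(t(Tm) %*% (f2$origin - f1$origin))
  c(twist = rad2deg(twist), roll = rad2deg(roll), tilt = rad2deg(tilt),
    shift = disp[1], slide = disp[2], rise = disp[3])
}

#' Apply a helical step to a frame
#'
#' Exact inverse of [step_params()]: constructs the next pair frame from
#' twist/roll/tilt (degrees) and shift/slide/rise (Angstrom).
#'
#' @param frame a `base_frame`.
#' @param twist,roll,tilt step rotations (degrees).
#' @param shift,slide,rise step displacement in the mid-step frame (Angstrom).
#' @return the stepped `base_frame`.
#' @export
apply_step <- function(frame, twist, roll = 0, tilt = 0,
                       shift = 0, slide = 0, rise = 2.81) {
  om <- deg2rad(twist)
  gamma <- deg2rad(sqrt(roll^2 + tilt^2))
  phi <- atan2(tilt, roll)
  hinge <- c(sin(phi), cos(phi), 0)  # mid-frame coordinates
  T1p <- rot_z(-om / 2)
  T2p <- rot_z(om / 2)
  if (abs(gamma) < 1e-12) {
    T1l <- T1p
    T2l <- T2p
  } else {
    T1l <- rot_axis(hinge, -gamma / 2) %*% T1p
    T2l <- rot_axis(hinge, gamma / 2) %*% T2p
  }
  M <- frame$triad %*% t(T1l)  # mid-frame -> global
  new_frame(frame$origin + as.numeric(M %*% c(shift, slide, rise)),
            M %*% T2l, frame$code)
}

#' Screw axis and nominal inclination of a regular helix
#'
#' For a regular helix generated by a constant (twist, roll, tilt, rise) step,
#' returns the global screw-axis direction (in the coordinates of the first
#' frame = identity) and the constant per-pair inclination it implies.
#'
#' @param twist,roll,tilt step rotations (degrees).
#' @param rise step rise (Angstrom).
#' @return list with `axis` (unit vector) and `inclination` (degrees).
#' @export
regular_helix_axis <- function(twist, roll = 0, tilt = 0, rise = 2.81) {
  f1 <- new_frame(c(0, 0, 0), diag(3))
  f2 <- apply_step(f1, twist, roll, tilt, rise = rise)
  R <- f2$triad  # rotation taking frame k to k+1 (global, since T1 = I)
  e <- eigen(R)
  k <- which.min(abs(e$values - 1))
  axis <- Re(e$vectors[, k])
  axis <- axis / vnorm(axis)
  if (sum(axis * (f2$origin - f1$origin)) < 0) axis <- -axis
  inc <- rad2deg(asin(clamp1(sum(c(0, 1, 0) * axis))))
  list(axis = axis, inclination = inc)
}

#' Roll realising a target inclination
#'
#' Solves (by root finding on the regular-helix construction) for the roll
#' angle that, combined with the given twist and rise, yields the requested
#' global inclination. This is the roll-twist-inclination coupling of regular
#' helices.
#'
#' @param inclination target inclination (degrees).
#' @param twist helical twist (degrees).
#' @param rise helical rise (Angstrom).
#' @return roll in degrees.
#' @export
roll_for_inclination <- function(inclination, twist = 32.7, rise = 2.81) {
  f <- function(r) regular_helix_axis(twist, r, rise = rise)$inclination - inclination
  stats::uniroot(f, interval = c(-75, 75), tol = 1e-10)$root
}

#' End-to-end distance of a duplex
#'
#' Distance between the first and last base-pair origins (no terminal
#' exclusion): a compactness measure that, unlike inclination, is sensitive
#' to terminal fraying.
#'
#' @param pair_frames list of pair `base_frame`s, or an origin matrix.
#' @return distance in Angstrom (0 for a single pair).
#' @export
end_to_end <- function(pair_frames) {
  origins <- if (is.matrix(pair_frames)) pair_frames else pair_origins(pair_frames)
  if (nrow(origins) < 1) stop("no pair origins")
  if (nrow(origins) == 1) return(0)
  vnorm(origins[nrow(origins), ] - origins[1, ])
}

#' Torsion angle of four points
#'
#' IUPAC sign convention; result in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric length-3 points.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined dihedral: three consecutive points are collinear")
  m1 <- cross3(n1, unitv(b2))
  ang <- rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
  if (ang <= -180) ang <- ang + 360
  ang
}

# --- sugar pucker ----------------------------------------------------------

PUCKER_CLASSES <- c("C3'-endo", "C4'-exo", "O4'-endo", "C1'-exo", "C2'-endo",
                    "C3'-exo", "C4'-endo", "O4'-exo", "C1'-endo", "C2'-exo")

#' Endocyclic ribose torsions from Altona-Sundaralingam parameters
#'
#' Forward model `nu_j = tau_m * cos(P + 144 deg * (j - 2))`, j = 0..4.
#'
#' @param phase pseudorotation phase P (degrees).
#' @param amplitude puckering amplitude tau_m (degrees).
#' @return numeric length-5 vector `nu0..nu4` (degrees).
#' @export
pucker_torsions <- function(phase, amplitude) {
  j <- 0:4
  amplitude * cos(deg2rad(phase + 144 * (j - 2)))
}

#' Sugar pucker (pseudorotation phase and amplitude)
#'
#' Altona-Sundaralingam analysis from the five endocyclic torsions
#' nu0 = C4'-O4'-C1'-C2' ... nu4 = C3'-C4'-O4'-C1'. A planar ring reports
#' amplitude 0 with an indeterminate phase.
#'
#' @param x an [rna_model()], a residue atom data.frame (columns `name`,
#'   `x`, `y`, `z`), or a numeric length-5 torsion vector.
#' @param chain,resid residue address when `x` is a model.
#' @return list of class `pucker_state`: `phase` (degrees in \[0, 360) or NA),
#'   `amplitude` (degrees), `class` (A-S conformer name or NA),
#'   `indeterminate`, `nu`.
#' @export
sugar_pucker <- function(x, chain = NULL, resid = NULL) {
  if (is.numeric(x) && length(x) == 5) {
    nu <- as.numeric(x)
  } else {
    if (inherits(x, "rna_model")) {
      idx <- residue_atom_idx(x, chain, resid)
      atoms <- x$atoms[idx, , drop = FALSE]
    } else atoms <- x
    ring <- c("C1'", "C2'", "C3'", "C4'", "O4'")
    hit <- match(ring, atoms$name)
    if (any(is.na(hit)))
      stop("missing ring atom(s): ", paste(ring[is.na(hit)], collapse = ", "))
    p <- as.matrix(atoms[hit, c("x", "y", "z")])
    rownames(p) <- ring
    nu <- c(dihedral(p["C4'", ], p["O4'", ], p["C1'", ], p["C2'", ]),
            dihedral(p["O4'", ], p["C1'", ], p["C2'", ], p["C3'", ]),
            dihedral(p["C1'", ], p["C2'", ], p["C3'", ], p["C4'", ]),
            dihedral(p["C2'", ], p["C3'", ], p["C4'", ], p["O4'", ]),
            dihedral(p["C3'", ], p["C4'", ], p["O4'", ], p["C1'", ]))
  }
  if (max(abs(nu)) < 1e-6) {
    return(structure(list(phase = NA_real_, amplitude = 0,
                          class = NA_character_, indeterminate = TRUE,
                          nu = nu), class = "pucker_state"))
  }
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (sin(deg2rad(36)) + sin(deg2rad(72)))
  P <- atan2(num, den)
  tau <- nu[3] / cos(P)
  Pdeg <- rad2deg(P) %% 360
  structure(list(phase = Pdeg, amplitude = abs(tau),
                 class = PUCKER_CLASSES[floor(Pdeg / 36) %% 10 + 1],
                 indeterminate = FALSE, nu = nu),
            class = "pucker_state")
}

#' @export
print.pucker_state <- function(x, ...) {
  if (x$indeterminate) cat("<pucker_state> planar ring (amplitude 0, phase indeterminate)\n")
  else cat(sprintf("<pucker_state> P = %.1f deg, amplitude = %.1f deg (%s)\n",
                   x$phase, x$amplitude, x$class))
  invisible(x)
}

# --- trajectory-level helical summaries ------------------------------------

#' Helical summary of a trajectory
#'
#' Per-frame mean inclination (two terminal pairs excluded by default),
#' end-to-end distance, and mean step twist/roll/rise.
#'
#' @param traj an `rna_traj` of a duplex.
#' @param pairs optional explicit pair table (see [duplex_pair_frames()]).
#' @param exclude_terminal pairs dropped at each end for inclination and step
#'   means.
#' @return data.frame with one row per frame: `frame`, `inclination`,
#'   `incl_sd`, `end_to_end`, `twist`, `roll`, `rise`.
#' @export
helical_series <- function(traj, pairs = NULL, exclude_terminal = 2) {
  if (is.null(pairs)) pairs <- duplex_pair_table(traj$topology)
  rows <- lapply(seq_along(traj$frames), function(k) {
    m <- frame_model(traj, k)
    pf <- duplex_pair_frames(m, pairs, strict = FALSE)
    inc <- inclination(pf, exclude_terminal = exclude_terminal)
    n <- length(pf)
    keep <- (1 + exclude_terminal):(n - exclude_terminal)
    st <- step_params(pf[keep])
    data.frame(frame = k, inclination = inc$mean, incl_sd = inc$sd,
               end_to_end = end_to_end(pf),
               twist = mean(st$twist), roll = mean(st$roll),
               rise = mean(st$rise))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
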