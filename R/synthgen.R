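# Synthetic A-RNA duplexes and two-shell ion atmospheres: the deterministic
# test bed for every analysis module. Duplexes are built from rigid idealized
# nucleotide templates placed by accumulated helical step transforms; the
# requested global inclination is realised through the roll-twist coupling of
# regular helices (the base-pair internal geometry stays rigid). Ion positions
# are drawn so that their surface-minimal distances follow a Gaussian
# two-shell + uniform-bulk mixture. Everything is reproducible bit-for-bit
# from the seeds.

#' Specification of a synthetic A-RNA helix
#'
#' @param sequence strand-A sequence, 5'->3' (A/C/G/U).
#' @param sequence_b optional strand-B sequence, 5'->3'; defaults to the
#'   reverse complement and must equal it when given.
#' @param twist helical twist per step (degrees), in (0, 60).
#' @param rise helical rise per step (Angstrom).
#' @param inclination target global inclination (degrees); realised by
#'   solving for the roll. Ignored when `roll` is given directly.
#' @param roll explicit roll per step (degrees), overrides `inclination`.
#' @param seed RNG seed recorded with the spec.
#' @return list of class `helix_spec` (with the solved `roll` and the nominal
#'   inclination implied by the construction).
#' @export
helix_spec <- function(sequence, sequence_b = NULL, twist = 32.7, rise = 2.81,
                       inclination = 18.75, roll = NULL, seed = 1) {
  sequence <- toupper(sequence)
  if (nchar(gsub("[ACGU]", "", sequence)) > 0)
    stop("sequence letters must be A/C/G/U")
  if (twist <= 0 || twist >= 60) stop("twist must be in (0, 60) degrees")
  if (rise <= 0) stop("rise must be positive")
  comp <- rev_complement(sequence)
  if (is.null(sequence_b)) sequence_b <- comp
  if (toupper(sequence_b) != comp)
    stop("strands are not complementary: expected strand B ", comp)
  if (is.null(roll)) roll <- roll_for_inclination(inclination, twist, rise)
  nominal <- regular_helix_axis(twist, roll, rise = rise)$inclination
  structure(list(sequence = sequence, sequence_b = sequence_b, twist = twist,
                 rise = rise, roll = roll, inclination = nominal, seed = seed),
            class = "helix_spec")
}

rev_complement <- function(sequence) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", sequence), "")[[1]]),
        collapse = "")
}

#' Build an ideal A-RNA duplex from a helix specification
#'
#' All-heavy-atom duplex from rigid nucleotide templates placed by accumulated
#' step transforms. Termini are 5'-OH (number of phosphorus atoms =
#' nucleotides - strands). The duplex is centred in an orthorhombic box with
#' the given padding.
#'
#' @param spec a [helix_spec()].
#' @param box_padding clearance between the duplex and each box face
#'   (Angstrom); `NULL` for no box.
#' @return an [rna_model()] (chains A and B, residues numbered 5'->3').
#' @export
build_duplex <- function(spec, box_padding = 12) {
  n <- nchar(spec$sequence)
  sa <- strsplit(spec$sequence, "")[[1]]
  sb_rev <- strsplit(chartr("ACGU", "UGCA", spec$sequence), "")[[1]]
  # pair k couples strand A residue k with strand B residue n + 1 - k
  frames <- vector("list", n)
  frames[[1]] <- new_frame(c(0, 0, 0), diag(3))
  for (k in seq_len(n - 1))
    frames[[k + 1]] <- apply_step(frames[[k]], spec$twist, spec$roll,
                                  rise = spec$rise)
  place <- function(tpl, triad, origin, flip = FALSE) {
    xyz <- as.matrix(tpl[, c("x", "y", "z")])
    if (flip) xyz <- xyz %*% t(FLIP_YZ)
    sweep(xyz %*% t(triad), 2, origin, "+")
  }
  rows_a <- vector("list", n)
  rows_b <- vector("list", n)
  for (k in seq_len(n)) {
    f <- frames[[k]]
    tpl_a <- nucleotide_template(sa[k])
    if (k == 1) tpl_a <- tpl_a[!tpl_a$name %in% c("P", "OP1", "OP2"), ]
    xa <- place(tpl_a, f$triad, f$origin)
    rows_a[[k]] <- data.frame(name = tpl_a$name, element = tpl_a$element,
                              chain = "A", resid = k, resname = sa[k],
                              x = xa[, 1], y = xa[, 2], z = xa[, 3],
                              stringsAsFactors = FALSE)
    code_b <- sb_rev[k]          # strand B residue paired with pair k
    resid_b <- n + 1 - k         # strand B numbering 5'->3'
    tpl_b <- nucleotide_template(code_b)
    if (resid_b == 1) tpl_b <- tpl_b[!tpl_b$name %in% c("P", "OP1", "OP2"), ]
    xb <- place(tpl_b, f$triad, f$origin, flip = TRUE)
    rows_b[[k]] <- data.frame(name = tpl_b$name, element = tpl_b$element,
                              chain = "B", resid = resid_b, resname = code_b,
                              x = xb[, 1], y = xb[, 2], z = xb[, 3],
                              stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, c(rows_a, rows_b[order(n + 1 - seq_len(n))]))
  atoms <- cbind(serial = seq_len(nrow(atoms)), atoms, icode = "")
  box <- NULL
  if (!is.null(box_padding)) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    lo <- apply(xyz, 2, min)
    hi <- apply(xyz, 2, max)
    box <- (hi - lo) + 2 * box_padding
    shift <- box_padding - lo
    atoms$x <- atoms$x + shift[1]
    atoms$y <- atoms$y + shift[2]
    atoms$z <- atoms$z + shift[3]
  }
  rna_model(atoms, box = box, metadata = list(helix_spec = unclass(spec)))
}

#' Specification of a synthetic two-shell ion atmosphere
#'
#' The surface-minimal-distance distribution is a mixture of Gaussian shells
#' plus a spatially uniform bulk term. Defaults place the two shells at the
#' positions typical for monovalent cations around A-RNA (first shell around
#' 3.4 A, second around 6.2 A from the surface).
#'
#' @param shell_centers shell centres (surface distance, Angstrom).
#' @param shell_widths Gaussian shell sigmas (Angstrom).
#' @param shell_weights mixture weights of the shells.
#' @param bulk_fraction weight of the uniform bulk component; weights and
#'   bulk fraction must sum to 1.
#' @param n_ions ions to place.
#' @param exclusion minimal surface distance allowed anywhere (Angstrom).
#' @param seed RNG seed.
#' @return list of class `atmosphere_spec`.
#' @export
atmosphere_spec <- function(shell_centers = c(3.4, 6.2),
                            shell_widths = c(0.3, 0.4),
                            shell_weights = c(0.35, 0.30),
                            bulk_fraction = 0.35,
                            n_ions = 18, exclusion = 2.5, seed = 1) {
  if (length(shell_centers) != length(shell_widths) ||
      length(shell_centers) != length(shell_weights))
    stop("shell centers, widths and weights must have equal length")
  if (abs(sum(shell_weights) + bulk_fraction - 1) > 1e-9)
    stop("shell weights + bulk fraction must sum to 1")
  if (n_ions < 0) stop("n_ions must be non-negative")
  structure(list(shell_centers = shell_centers, shell_widths = shell_widths,
                 shell_weights = shell_weights, bulk_fraction = bulk_fraction,
                 n_ions = as.integer(n_ions), exclusion = exclusion,
                 seed = seed),
            class = "atmosphere_spec")
}

# Shared machinery: draw positions whose surface distance follows a Gaussian
# shell, correcting for the available shell volume at each distance
# (estimated once by Monte-Carlo probes).
sample_shell_positions <- function(n, center, width, rna_xyz, box, vol_lookup) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  bw <- vol_lookup$bin_width
  dens <- function(d) stats::dnorm(d, center, width)
  # acceptance weight on the distance grid: target density / volume density
  vd <- vol_lookup$volumes / bw
  grid <- vol_lookup$centers
  w <- ifelse(vd > 0, dens(grid) / vd, 0)
  wmax <- max(w)
  if (wmax <= 0) stop("infeasible atmosphere: shell outside the box")
  out <- matrix(numeric(0), ncol = 3)
  guard <- 0
  while (nrow(out) < n) {
    guard <- guard + 1
    if (guard > 2000) stop("shell sampling failed to converge")
    m <- max(2000L, 4L * (n - nrow(out)))
    pos <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
                 stats::runif(m, 0, box[3]))
    d <- min_surface_distance(pos, rna_xyz)
    b <- pmin(pmax(floor(d / bw) + 1L, 1L), length(grid))
    acc <- stats::runif(m) * wmax < ifelse(vd[b] > 0, dens(d) / vd[b], 0)
    out <- rbind(out, pos[acc, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

sample_bulk_positions <- function(n, rna_xyz, box, exclusion) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  out <- matrix(numeric(0), ncol = 3)
  guard <- 0
  while (nrow(out) < n) {
    guard <- guard + 1
    if (guard > 2000) stop("bulk sampling failed to converge")
    m <- max(2000L, 2L * (n - nrow(out)))
    pos <- cbind(stats::runif(m, 0, box[1]), stats::runif(m, 0, box[2]),
                 stats::runif(m, 0, box[3]))
    d <- min_surface_distance(pos, rna_xyz)
    out <- rbind(out, pos[d > exclusion, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Sample an ion atmosphere around a model
#'
#' Draws `n_ions` positions inside the model's box so that their
#' surface-minimal distances follow the requested shell/bulk mixture
#' (rejection sampling with Monte-Carlo shell-volume correction).
#' Deterministic under the spec seed.
#'
#' @param model an [rna_model()] with a box.
#' @param spec an [atmosphere_spec()].
#' @param rna surface selection.
#' @param n_ions override of the spec ion count (e.g. frames x ions pooled).
#' @param vol_probes probes for the shell-volume lookup.
#' @return n x 3 matrix of ion positions (Angstrom).
#' @export
sample_atmosphere <- function(model, spec, rna = "nucleic", n_ions = NULL,
                              vol_probes = 2e5) {
  if (is.null(model$box)) stop("atmosphere sampling needs a box")
  n_ions <- as.integer(n_ions %||% spec$n_ions)
  if (n_ions == 0) return(matrix(numeric(0), ncol = 3))
  if (any(spec$shell_centers + 3 * spec$shell_widths > min(model$box) / 2))
    stop("infeasible atmosphere: shells extend beyond the box")
  rna_idx <- select_atoms(model, rna)
  rna_idx <- rna_idx[model$atoms$element[rna_idx] != "H"]
  rna_xyz <- coords(model)[rna_idx, , drop = FALSE]
  rmax <- max(spec$shell_centers) + 8 * max(spec$shell_widths)
  edges <- seq(0, rmax, by = 0.1)
  with_seed(spec$seed, {
    vols <- mc_shell_volumes(model, rna_idx, edges,
                             n_probe = vol_probes,
                             seed = spec$seed + 1303L)
    lookup <- list(centers = edges[-length(edges)] + 0.05,
                   volumes = vols, bin_width = 0.1)
    counts <- stats::rmultinom(1, n_ions,
                               c(spec$shell_weights, spec$bulk_fraction))[, 1]
    k <- length(spec$shell_centers)
    parts <- vector("list", k + 1)
    for (s in seq_len(k)) {
      parts[[s]] <- sample_shell_positions(counts[s], spec$shell_centers[s],
                                           spec$shell_widths[s], rna_xyz,
                                           model$box, lookup)
    }
    parts[[k + 1]] <- sample_bulk_positions(counts[k + 1], rna_xyz,
                                            model$box, spec$exclusion)
    pos <- do.call(rbind, parts)
    pos[sample.int(nrow(pos)), , drop = FALSE]
  })
}

#' Noise/fraying specification for synthetic trajectories
#'
#' @param sigma i.i.d. Gaussian coordinate noise (Angstrom).
#' @param p_open per-frame opening probability of each terminal pair.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(sigma = 0, p_open = 0, n_frames = 100, seed = 1) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (p_open < 0 || p_open > 1) stop("p_open must be in [0, 1]")
  if (n_frames < 1) stop("need at least one frame")
  structure(list(sigma = sigma, p_open = p_open,
                 n_frames = as.integer(n_frames), seed = seed),
            class = "noise_spec")
}

# Swing a terminal pair open: the strand-B residue of the pair is rotated
# about its glycosidic bond and displaced away from the helix, breaking all
# pair hydrogen bonds.
open_residue_coords <- function(xyz, model, chain, resid) {
  idx <- residue_atom_idx(model, chain, resid)
  sub <- xyz[idx, , drop = FALSE]
  nm <- model$atoms$name[idx]
  code <- normalize_resname(model$atoms$resname[idx[1]])
  c1 <- sub[match("C1'", nm), ]
  ng <- sub[match(glycosidic_atom(code), nm), ]
  R <- rot_axis(ng - c1, deg2rad(80))
  centroid <- colMeans(sub)
  helix_center <- colMeans(xyz[model$atoms$element != "H", , drop = FALSE])
  away <- unitv(centroid - helix_center)
  moved <- sweep(sweep(sub, 2, c1) %*% t(R), 2, c1 + 8 * away, "+")
  xyz[idx, ] <- moved
  xyz
}

#' Generate a synthetic trajectory
#'
#' Frames are copies of the model with i.i.d. Gaussian coordinate noise; ions
#' (when an atmosphere is given) are resampled independently every frame from
#' the same distribution; terminal pairs swing open in frames drawn with the
#' stated probability. Fully reproducible from the seeds.
#'
#' @param model duplex [rna_model()] (RNA only; ions are added here).
#' @param atmosphere optional [atmosphere_spec()].
#' @param noise a [noise_spec()].
#' @param species ion species name for added ions.
#' @return an `rna_traj` whose topology carries the RNA plus frame-1 ions and
#'   whose metadata records all generator parameters (ground truth).
#' @export
make_trajectory <- function(model, atmosphere = NULL,
                            noise = noise_spec(), species = "K+") {
  nf <- noise$n_frames
  rna_xyz <- coords(model)
  n_rna <- nrow(rna_xyz)
  n_ions <- if (is.null(atmosphere)) 0L else atmosphere$n_ions
  ion_pool <- NULL
  if (n_ions > 0)
    ion_pool <- sample_atmosphere(model, atmosphere, n_ions = n_ions * nf)
  term <- tryCatch(terminal_pair_table(model), error = function(e) NULL)
  frames <- vector("list", nf)
  with_seed(noise$seed, {
    open_draw <- if (!is.null(term) && noise$p_open > 0)
      matrix(stats::runif(nf * nrow(term)) < noise$p_open, nrow = nf)
    else matrix(FALSE, nrow = nf, ncol = max(1, nrow(term %||% data.frame(x = 1))))
    for (k in seq_len(nf)) {
      xyz <- rna_xyz
      if (noise$sigma > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, noise$sigma),
                            ncol = 3)
      if (!is.null(term)) {
        for (p in seq_len(nrow(term))) {
          if (open_draw[k, p])
            xyz <- open_residue_coords(xyz, model, term$chain_j[p],
                                       term$resid_j[p])
        }
      }
      if (n_ions > 0) {
        ions_k <- ion_pool[((k - 1) * n_ions + 1):(k * n_ions), , drop = FALSE]
        xyz <- rbind(xyz, ions_k)
      }
      frames[[k]] <- xyz
    }
  })
  topo <- model
  if (n_ions > 0)
    topo <- add_ions(model, ion_pool[seq_len(n_ions), , drop = FALSE], species)
  topo$metadata$atmosphere_spec <- if (is.null(atmosphere)) NULL else unclass(atmosphere)
  topo$metadata$noise_spec <- unclass(noise)
  trajectory(topo, frames)
}

#' Write a synthetic bundle (trajectory + ground-truth sidecar)
#'
#' Multi-model PDB plus a JSON sidecar recording every generator parameter.
#'
#' @param traj an `rna_traj` from [make_trajectory()].
#' @param prefix output path prefix (writes `<prefix>.pdb`, `<prefix>.json`).
#' @return the two paths, invisibly.
#' @export
write_synth_bundle <- function(traj, prefix) {
  pdb <- paste0(prefix, ".pdb")
  sidecar <- paste0(prefix, ".json")
  write_trajectory(traj, pdb)
  jsonlite::write_json(traj$topology$metadata, sidecar, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(pdb, sidecar))
}
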