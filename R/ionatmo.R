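# Ion-atmosphere quantification: surface-minimal-distance RDFs at 0.1 A
# binning, Monte-Carlo concentration normalisation, solvation-shell detection
# with the 6.3 A fallback convention, shell occupancies and per-residue /
# groove occupancies. Distances are always measured to the nearest RNA heavy
# atom ("surface-minimal distance") on non-imaged coordinates.

#' Minimal surface distance from point(s) to an atom set
#'
#' The distance from each probe/ion position to its nearest atom of the
#' reference coordinate set (the RNA "surface" = all heavy atoms).
#'
#' @param ion_xyz numeric length-3 vector or m x 3 matrix of positions.
#' @param rna_xyz n x 3 matrix of reference (heavy-atom) coordinates.
#' @return numeric vector of length m (Angstrom).
#' @export
min_surface_distance <- function(ion_xyz, rna_xyz) {
  if (is.null(dim(ion_xyz))) ion_xyz <- matrix(ion_xyz, ncol = 3)
  if (is.null(dim(rna_xyz)) || nrow(rna_xyz) < 1)
    stop("empty reference atom set")
  d2r <- rowSums(rna_xyz^2)
  out <- numeric(nrow(ion_xyz))
  # Chunk the ion dimension to bound the n_rna x n_ion distance block.
  chunk <- max(1L, floor(4e6 / nrow(rna_xyz)))
  for (s in seq(1L, nrow(ion_xyz), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(ion_xyz))
    blk <- ion_xyz[s:e, , drop = FALSE]
    d2 <- outer(d2r, rowSums(blk^2), "+") - 2 * (rna_xyz %*% t(blk))
    out[s:e] <- sqrt(pmax(apply(d2, 2, min), 0))
  }
  out
}

resolve_ion_rna <- function(traj, ions, rna) {
  top <- traj$topology
  ion_idx <- select_atoms(top, ions)
  rna_idx <- select_atoms(top, rna)
  rna_idx <- rna_idx[top$atoms$element[rna_idx] != "H"]  # surface = heavy atoms
  if (length(ion_idx) == 0) stop("ion selection resolves to no atoms")
  if (length(rna_idx) == 0) stop("rna selection resolves to no heavy atoms")
  if (length(intersect(ion_idx, rna_idx)) > 0)
    stop("ion and rna selections overlap")
  list(ions = ion_idx, rna = rna_idx)
}

#' Surface-distance histogram of ions around the RNA
#'
#' Per-frame minimal RNA-ion surface distances binned at a fixed pitch
#' (0.1 A default) and averaged over frames.
#'
#' @param traj an `rna_traj`.
#' @param ions,rna selection expressions (or index vectors) on the topology.
#' @param max_range histogram range (Angstrom).
#' @param bin_width bin pitch (Angstrom), default 0.1.
#' @return object of class `rdf_profile` with `bin_edges`, `counts` (mean ion
#'   count per bin per frame), `n_frames`, `n_obs` (total in-range ion-frame
#'   observations) and empty `concentration`.
#' @export
rdf_histogram <- function(traj, ions = "ions", rna = "nucleic",
                          max_range = 20, bin_width = 0.1) {
  idx <- resolve_ion_rna(traj, ions, rna)
  edges <- seq(0, max_range, by = bin_width)
  nbin <- length(edges) - 1L
  total <- numeric(nbin)
  for (k in seq_along(traj$frames)) {
    xyz <- traj$frames[[k]]
    d <- min_surface_distance(xyz[idx$ions, , drop = FALSE],
                              xyz[idx$rna, , drop = FALSE])
    b <- floor(d / bin_width) + 1L
    b <- b[b >= 1L & b <= nbin]
    if (length(b) > 0) total <- total + tabulate(b, nbins = nbin)
  }
  structure(list(bin_edges = edges, counts = total / length(traj$frames),
                 bin_width = bin_width, n_frames = length(traj$frames),
                 n_obs = sum(total), concentration = NULL,
                 shell_volume = NULL),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf("<rdf_profile> %d bins x %.2g A, %d frames, %.0f observations%s\n",
              length(x$counts), x$bin_width, x$n_frames, x$n_obs,
              if (is.null(x$concentration)) "" else ", concentration filled"))
  invisible(x)
}

bin_centers <- function(profile) {
  profile$bin_edges[-length(profile$bin_edges)] + profile$bin_width / 2
}

#' Shell volumes around an irregular solute by volume probing
#'
#' Estimates the volume of each surface-distance bin by classifying uniform
#' probe points in the box by their own minimal surface distance. The shell
#' around an irregular solute has no closed form. Probes are quasi-random
#' (Halton) points: at equal probe count their per-bin error is far below
#' pseudo-random sampling, and the estimate is exactly reproducible from the
#' probe count and seed (the seed offsets the sequence).
#'
#' @param model an [rna_model()] with a box.
#' @param rna selection defining the surface atoms.
#' @param bin_edges bin edges (Angstrom).
#' @param n_probe number of probes (>= 1e4 recommended).
#' @param seed deterministic offset into the probe sequence.
#' @return numeric vector of per-bin volumes (Angstrom^3).
#' @export
mc_shell_volumes <- function(model, rna = "nucleic", bin_edges,
                             n_probe = 1e5, seed = 1) {
  if (is.null(model$box)) stop("shell-volume estimation needs a box")
  if (n_probe < 1e4)
    warning("fewer than 1e4 probes: shell volumes will be noisy")
  rna_idx <- select_atoms(model, rna)
  rna_idx <- rna_idx[model$atoms$element[rna_idx] != "H"]
  if (length(rna_idx) == 0) stop("rna selection resolves to no heavy atoms")
  rna_xyz <- coords(model)[rna_idx, , drop = FALSE]
  nbin <- length(bin_edges) - 1L
  bw <- diff(bin_edges[1:2])
  counts <- numeric(nbin)
  skip <- (abs(as.integer(seed)) %% 8191L) * 64L
  done <- 0L
  while (done < n_probe) {
    m <- min(as.integer(n_probe) - done, 200000L)
    probes <- sweep(halton3(m, skip = skip + done), 2, model$box, "*")
    d <- min_surface_distance(probes, rna_xyz)
    b <- floor(d / bw) + 1L
    b <- b[b >= 1L & b <= nbin]
    if (length(b) > 0) counts <- counts + tabulate(b, nbins = nbin)
    done <- done + m
  }
  prod(model$box) * counts / n_probe
}

#' Convert a surface-distance histogram to a concentration profile
#'
#' Fills the `concentration` field (mol/L per bin) using Monte-Carlo shell
#' volumes: `c(r) = counts(r) / (N_A * V_shell(r))`.
#'
#' @param profile an `rdf_profile` from [rdf_histogram()].
#' @param model the topology (must carry a box).
#' @param rna surface selection, as used for the histogram.
#' @param n_probe,seed Monte-Carlo probe count and seed.
#' @return the profile with `concentration` and `shell_volume` filled.
#' @export
concentration_profile <- function(profile, model, rna = "nucleic",
                                  n_probe = 1e5, seed = 1) {
  vols <- mc_shell_volumes(model, rna, profile$bin_edges, n_probe, seed)
  conc <- rep(NA_real_, length(vols))
  pos <- vols > 0
  conc[pos] <- profile$counts[pos] / (AVOGADRO * vols[pos] * 1e-27)
  conc[!pos & profile$counts == 0] <- 0
  profile$concentration <- conc
  profile$shell_volume <- vols
  profile
}

smooth_ma3 <- function(y) {
  n <- length(y)
  if (n < 3) return(y)
  s <- as.numeric(stats::filter(y, rep(1 / 3, 3), sides = 2))
  s[1] <- mean(y[1:2])
  s[n] <- mean(y[(n - 1):n])
  s
}

#' Detect solvation-shell boundaries in an RDF profile
#'
#' Works on the concentration profile when available (counts otherwise) after
#' a centred 3-bin moving average. The first-shell boundary is the first local
#' minimum after the global peak; the second-shell boundary is the first local
#' minimum after the second peak. When no second minimum exists before
#' `search_limit` the boundary is reported absent and the fixed fallback
#' radius (6.3 A) is used downstream. Flat minima break ties toward the
#' smallest radius.
#'
#' @param profile an `rdf_profile`.
#' @param search_limit search range (Angstrom).
#' @param fallback_radius cumulative-count fallback radius (Angstrom).
#' @param prominence minimal peak-to-valley contrast, as a fraction of the
#'   first-peak height, for an extremum to count (suppresses sampling noise).
#' @return object of class `shell_boundaries` with `r_peak1`, `r_min1`,
#'   `r_peak2`, `r_min2` (NA when absent) and `fallback_radius`.
#' @export
detect_shells <- function(profile, search_limit = 8, fallback_radius = 6.3,
                          prominence = 0.05) {
  y <- profile$concentration %||% profile$counts
  r <- bin_centers(profile)
  keep <- r <= search_limit & !is.na(y)
  y <- smooth_ma3(y[keep])
  r <- r[keep]
  n <- length(y)
  if (n < 5) stop("profile too short for shell detection")
  # alternating local extrema (flat runs: smallest radius wins)
  ext_idx <- integer(0)
  ext_type <- character(0)
  add_ext <- function(i, type) {
    ext_idx <<- c(ext_idx, i)
    ext_type <<- c(ext_type, type)
  }
  d <- diff(y)
  trend <- 0
  last_nz <- 0L
  for (i in seq_len(n - 1)) {
    s <- sign(d[i])
    if (s == 0) next  # flat run: the extremum stays at its first point
    if (trend == 0) {
      if (s < 0) add_ext(1L, "max")
    } else if (s != trend) {
      add_ext(last_nz + 1L, if (s < 0) "max" else "min")
    }
    trend <- s
    last_nz <- i
  }
  if (trend > 0) add_ext(n, "max")
  if (!any(ext_type == "max"))
    stop("no shell structure: profile is monotone over the search range")
  # persistence pruning: drop adjacent extrema pairs with low contrast
  thr <- prominence * max(y)
  dedupe <- function() {
    # enforce alternation: of adjacent same-type extrema keep the stronger
    # (ties: smallest radius)
    i <- 2L
    while (i <= length(ext_idx)) {
      if (ext_type[i] == ext_type[i - 1]) {
        better_prev <- if (ext_type[i] == "max") y[ext_idx[i - 1]] >= y[ext_idx[i]]
                       else y[ext_idx[i - 1]] <= y[ext_idx[i]]
        drop <- if (better_prev) i else i - 1L
        ext_idx <<- ext_idx[-drop]
        ext_type <<- ext_type[-drop]
      } else i <- i + 1L
    }
  }
  repeat {
    if (length(ext_idx) < 2) break
    amp <- abs(diff(y[ext_idx]))
    k <- which.min(amp)
    if (amp[k] >= thr) break
    drop <- c(k, k + 1)
    # never drop the global maximum itself
    gm <- which(ext_idx == which.max(y))
    if (length(gm) == 1 && gm %in% drop) drop <- drop[drop != gm]
    ext_idx <- ext_idx[-drop]
    ext_type <- ext_type[-drop]
    dedupe()
  }
  maxima <- ext_idx[ext_type == "max"]
  if (length(maxima) == 0)
    stop("no shell structure: no significant peak in the search range")
  p1 <- maxima[1]  # first significant peak = first solvation shell
  after <- which(ext_idx > p1)
  mins_after <- ext_idx[after][ext_type[after] == "min"]
  if (length(mins_after) > 0) {
    m1 <- mins_after[1]
  } else {
    # peak decaying into a flat tail: the boundary is where the significant
    # descent ends (first point with no further drop beyond the noise floor)
    if (p1 >= n) stop("no shell structure: no descent after the peak")
    suffix_min <- rev(cummin(rev(y)))
    cand <- which(seq_len(n) > p1 & (y - suffix_min) <= thr)
    if (length(cand) == 0 || y[p1] - y[cand[1]] < thr)
      stop("no shell structure: no minimum after the first peak")
    m1 <- cand[1]
  }
  maxs_after <- ext_idx[ext_idx > m1 & ext_type == "max"]
  p2 <- if (length(maxs_after) > 0) maxs_after[1] else NA_integer_
  m2 <- NA_integer_
  if (!is.na(p2)) {
    mins2 <- ext_idx[ext_idx > p2 & ext_type == "min"]
    if (length(mins2) > 0) m2 <- mins2[1]
  }
  structure(list(r_peak1 = r[p1], r_min1 = r[m1],
                 r_peak2 = if (is.na(p2)) NA_real_ else r[p2],
                 r_min2 = if (is.na(m2)) NA_real_ else r[m2],
                 fallback_radius = fallback_radius),
            class = "shell_boundaries")
}

#' @export
print.shell_boundaries <- function(x, ...) {
  cat(sprintf("<shell_boundaries> peak1 %.2f A, min1 %.2f A; peak2 %s, min2 %s (fallback %.1f A)\n",
              x$r_peak1, x$r_min1,
              if (is.na(x$r_peak2)) "-" else sprintf("%.2f A", x$r_peak2),
              if (is.na(x$r_min2)) "-" else sprintf("%.2f A", x$r_min2),
              x$fallback_radius))
  invisible(x)
}

#' Time-averaged solvation-shell ion counts
#'
#' Cumulative occupancies: ions within the first-shell boundary, within the
#' second-shell boundary (first + second shell; the fallback radius stands in
#' when the profile has no second minimum), and within the fixed fallback
#' radius (parenthetical convention).
#'
#' @param traj an `rna_traj`.
#' @param ions,rna selections on the topology.
#' @param boundaries a `shell_boundaries` (from [detect_shells()] or built by
#'   hand).
#' @param cumulative if `FALSE`, `n_second` is reported as the second shell
#'   only (between the two boundaries).
#' @return list with means `n_first`, `n_second`, `n_fallback`, standard
#'   deviations `sd_*`, and the per-frame count matrix.
#' @export
shell_occupancy <- function(traj, ions = "ions", rna = "nucleic", boundaries,
                            cumulative = TRUE) {
  idx <- resolve_ion_rna(traj, ions, rna)
  r1 <- boundaries$r_min1
  r2 <- if (is.na(boundaries$r_min2)) boundaries$fallback_radius else boundaries$r_min2
  rf <- boundaries$fallback_radius
  per <- matrix(0, nrow = length(traj$frames), ncol = 3,
                dimnames = list(NULL, c("first", "second", "fallback")))
  for (k in seq_along(traj$frames)) {
    xyz <- traj$frames[[k]]
    d <- min_surface_distance(xyz[idx$ions, , drop = FALSE],
                              xyz[idx$rna, , drop = FALSE])
    per[k, ] <- c(sum(d <= r1), sum(d <= r2), sum(d <= rf))
  }
  if (!cumulative) per[, "second"] <- per[, "second"] - per[, "first"]
  list(n_first = mean(per[, 1]), n_second = mean(per[, 2]),
       n_fallback = mean(per[, 3]),
       sd_first = stats::sd(per[, 1]), sd_second = stats::sd(per[, 2]),
       sd_fallback = stats::sd(per[, 3]),
       boundaries = c(first = r1, second = r2, fallback = rf),
       per_frame = per)
}

#' Per-residue ion occupancy
#'
#' Mean (and sd over frames) number of ions within `cutoff` of each residue's
#' binding site: the geometric centre of the nucleotide heavy atoms, or any
#' atom of the major-groove / minor-groove / phosphate atom set.
#'
#' @param traj an `rna_traj`.
#' @param ions ion selection.
#' @param site_class `"nucleotide"`, `"major_groove"`, `"minor_groove"` or
#'   `"phosphate"`.
#' @param cutoff distance cutoff (Angstrom), default 3.5.
#' @param atlas optional override of the groove atom sets (see
#'   [groove_atlas()]).
#' @return data.frame with `chain`, `resid`, `resname`, `site`, `mean`, `sd`.
#' @export
residue_occupancy <- function(traj, ions = "ions",
                              site_class = c("nucleotide", "major_groove",
                                             "minor_groove", "phosphate"),
                              cutoff = 3.5, atlas = NULL) {
  site_class <- match.arg(site_class)
  top <- traj$topology
  ion_idx <- select_atoms(top, ions)
  if (length(ion_idx) == 0) stop("ion selection resolves to no atoms")
  res <- residue_table(top)
  if (nrow(res) == 0) stop("no nucleic residues in topology")
  if (site_class != "nucleotide" && is.null(atlas))
    atlas <- groove_atlas(site_class)
  site_idx <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    ai <- residue_atom_idx(top, res$chain[i], res$resid[i])
    ai <- ai[top$atoms$element[ai] != "H"]
    if (site_class != "nucleotide") {
      wanted <- atlas[[res$code[i]]]
      if (is.null(wanted))
        stop("no atlas entry for residue ", res$resname[i])
      ai <- ai[top$atoms$name[ai] %in% wanted]
    }
    site_idx[[i]] <- ai
  }
  counts <- matrix(0, nrow = length(traj$frames), ncol = nrow(res))
  for (k in seq_along(traj$frames)) {
    xyz <- traj$frames[[k]]
    ion_xyz <- xyz[ion_idx, , drop = FALSE]
    for (i in seq_len(nrow(res))) {
      ai <- site_idx[[i]]
      if (length(ai) == 0) next
      if (cutoff <= 0) next
      if (site_class == "nucleotide") {
        ref <- matrix(colMeans(xyz[ai, , drop = FALSE]), ncol = 3)
      } else {
        ref <- xyz[ai, , drop = FALSE]
      }
      counts[k, i] <- sum(min_surface_distance(ion_xyz, ref) <= cutoff)
    }
  }
  data.frame(chain = res$chain, resid = res$resid, resname = res$resname,
             site = site_class,
             mean = colMeans(counts),
             sd = apply(counts, 2, stats::sd),
             stringsAsFactors = FALSE)
}
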