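# Hydrogen-bond detection, base-pair identification and edge classification
# (Watson-Crick / Hoogsteen / Sugar with cis/trans glycosidic orientation),
# and terminal-fraying statistics. Default detection is distance-only on heavy
# atoms (MD-derived PDBs are often hydrogen-free); when hydrogens are present
# a donor-angle criterion is applied on top.

#' Detect hydrogen bonds between atom sets
#'
#' Heavy-atom donor-acceptor contacts within `d_cut`; when hydrogens are
#' present (and `use_hydrogens` is not `"never"`), a donor-H...acceptor angle
#' of at least `ang_cut` is additionally required.
#'
#' @param model an [rna_model()].
#' @param donors,acceptors atom index vectors (e.g. from [select_atoms()]);
#'   `NULL` selects all nucleic donor/acceptor atoms from the atlas.
#' @param d_cut heavy donor-acceptor distance cutoff (Angstrom).
#' @param ang_cut donor angle cutoff (degrees), used only with hydrogens.
#' @param use_hydrogens `"auto"` (use if present) or `"never"`.
#' @return data.frame with `donor`, `acceptor` (atom indices), `distance`,
#'   `angle` (NA in distance-only mode).
#' @export
find_hbonds <- function(model, donors = NULL, acceptors = NULL,
                        d_cut = 3.4, ang_cut = 120,
                        use_hydrogens = c("auto", "never")) {
  use_hydrogens <- match.arg(use_hydrogens)
  atlas <- donor_acceptor_atlas()
  a <- model$atoms
  if (is.null(donors) || is.null(acceptors)) {
    code <- normalize_resname(a$resname)
    role <- function(which) {
      hits <- logical(nrow(a))
      for (b in names(atlas)) {
        hits <- hits | (!is.na(code) & code == b & a$name %in% atlas[[b]][[which]])
      }
      which(hits)
    }
    if (is.null(donors)) donors <- role("donors")
    if (is.null(acceptors)) acceptors <- role("acceptors")
  }
  if (length(donors) == 0 || length(acceptors) == 0)
    return(data.frame(donor = integer(0), acceptor = integer(0),
                      distance = numeric(0), angle = numeric(0)))
  xyz <- coords(model)
  D <- xyz[donors, , drop = FALSE]
  A <- xyz[acceptors, , drop = FALSE]
  d2 <- outer(rowSums(D^2), rowSums(A^2), "+") - 2 * (D %*% t(A))
  hit <- which(d2 <= d_cut^2 & d2 > 1e-6, arr.ind = TRUE)
  out <- data.frame(donor = donors[hit[, 1]], acceptor = acceptors[hit[, 2]],
                    distance = sqrt(pmax(d2[hit], 0)),
                    angle = rep(NA_real_, nrow(hit)))
  # drop intra-residue contacts
  same <- a$chain[out$donor] == a$chain[out$acceptor] &
    a$resid[out$donor] == a$resid[out$acceptor]
  out <- out[!same, , drop = FALSE]
  has_h <- any(a$element == "H")
  if (use_hydrogens == "auto" && has_h && nrow(out) > 0) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      di <- out$donor[i]
      hs <- which(a$element == "H" & a$chain == a$chain[di] &
                    a$resid == a$resid[di])
      if (length(hs) == 0) return(TRUE)
      hd <- sqrt(rowSums(sweep(xyz[hs, , drop = FALSE], 2, xyz[di, ])^2))
      hs <- hs[hd < 1.25]
      if (length(hs) == 0) return(TRUE)
      ang <- vapply(hs, function(h) {
        v1 <- xyz[di, ] - xyz[h, ]
        v2 <- xyz[out$acceptor[i], ] - xyz[h, ]
        rad2deg(acos(clamp1(sum(v1 * v2) / (vnorm(v1) * vnorm(v2)))))
      }, numeric(1))
      best <- max(ang)
      out$angle[i] <<- best
      best >= ang_cut
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

CANONICAL_PAIRS <- c("GC", "CG", "AU", "UA", "GU", "UG")

#' Classify a base pair by edges and glycosidic orientation
#'
#' Finds inter-residue hydrogen bonds among the two residues' base atoms and
#' 2'-OH, assigns each base's interacting edge as the majority edge of its
#' H-bonded atoms (edge atlas; ties resolved WC > Hoogsteen > Sugar), and the
#' cis/trans orientation from the sign of the C1'(i)-N(i)-N(j)-C1'(j)
#' pseudo-torsion (|torsion| <= 90 deg is cis).
#'
#' @param model an [rna_model()].
#' @param chain_i,resid_i,chain_j,resid_j residue addresses.
#' @param d_cut H-bond distance cutoff (Angstrom).
#' @param max_centroid base-centroid separation beyond which no pair is
#'   considered (Angstrom).
#' @param max_stack_offset coplanarity gate: centroid offset along the mean
#'   base normal beyond which residues are considered stacked, not paired
#'   (Angstrom).
#' @param atlas edge atlas override (see [edge_atlas()]).
#' @return a `bp_annotation` list (`edge_i`, `edge_j`, `orientation`,
#'   `n_hbonds`, `is_canonical`, `hbonds`, residues), or `NULL` when the
#'   residues are not paired.
#' @export
classify_pair <- function(model, chain_i, resid_i, chain_j, resid_j,
                          d_cut = 3.4, max_centroid = 12,
                          max_stack_offset = 2.5, atlas = NULL) {
  atlas <- atlas %||% edge_atlas()
  a <- model$atoms
  idx_i <- residue_atom_idx(model, chain_i, resid_i)
  idx_j <- residue_atom_idx(model, chain_j, resid_j)
  if (length(idx_i) == 0 || length(idx_j) == 0)
    stop("unresolvable residue address")
  code_i <- normalize_resname(a$resname[idx_i[1]])
  code_j <- normalize_resname(a$resname[idx_j[1]])
  if (is.na(code_i) || is.na(code_j))
    stop("no atlas entry for residue ", a$resname[idx_i[1]], "/", a$resname[idx_j[1]])
  xyz <- coords(model)
  base_i <- idx_i[a$name[idx_i] %in% base_heavy_atoms(code_i)]
  base_j <- idx_j[a$name[idx_j] %in% base_heavy_atoms(code_j)]
  ci <- colMeans(xyz[base_i, , drop = FALSE])
  cj <- colMeans(xyz[base_j, , drop = FALSE])
  if (vnorm(ci - cj) > max_centroid) return(NULL)
  # Coplanarity gate: stacked bases sit displaced along the base normal.
  normal_of <- function(idx) {
    sv <- svd(sweep(xyz[idx, , drop = FALSE], 2, colMeans(xyz[idx, , drop = FALSE])))
    sv$v[, 3]
  }
  ni <- normal_of(base_i)
  nj <- normal_of(base_j)
  if (sum(ni * nj) < 0) nj <- -nj
  nm_axis <- unitv(ni + nj)
  if (abs(sum((cj - ci) * nm_axis)) > max_stack_offset) return(NULL)
  da <- donor_acceptor_atlas()
  edge_set <- function(code, idx) idx[a$name[idx] %in%
                                        c(base_heavy_atoms(code), "O2'")]
  cand_i <- edge_set(code_i, idx_i)
  cand_j <- edge_set(code_j, idx_j)
  don_i <- cand_i[a$name[cand_i] %in% da[[code_i]]$donors]
  acc_i <- cand_i[a$name[cand_i] %in% da[[code_i]]$acceptors]
  don_j <- cand_j[a$name[cand_j] %in% da[[code_j]]$donors]
  acc_j <- cand_j[a$name[cand_j] %in% da[[code_j]]$acceptors]
  hb <- rbind(find_hbonds(model, don_i, acc_j, d_cut = d_cut),
              find_hbonds(model, don_j, acc_i, d_cut = d_cut))
  # a donor/acceptor pair of atoms can match in both directions; keep one
  key <- paste(pmin(hb$donor, hb$acceptor), pmax(hb$donor, hb$acceptor))
  hb <- hb[!duplicated(key), , drop = FALSE]
  if (nrow(hb) == 0) return(NULL)
  majority_edge <- function(code, atoms_in_res) {
    votes <- c(WC = 0, H = 0, S = 0)
    sub <- atlas[atlas$base == code, ]
    for (nm in a$name[atoms_in_res]) {
      for (e in sub$edge[sub$atom == nm]) votes[e] <- votes[e] + 1
    }
    if (sum(votes) == 0) return(NA_character_)
    names(votes)[which.max(votes)]  # ties: WC > H > S by order
  }
  part_i <- unique(c(hb$donor[hb$donor %in% cand_i], hb$acceptor[hb$acceptor %in% cand_i]))
  part_j <- unique(c(hb$donor[hb$donor %in% cand_j], hb$acceptor[hb$acceptor %in% cand_j]))
  edge_i <- majority_edge(code_i, part_i)
  edge_j <- majority_edge(code_j, part_j)
  gi <- idx_i[a$name[idx_i] == glycosidic_atom(code_i)]
  gj <- idx_j[a$name[idx_j] == glycosidic_atom(code_j)]
  c1i <- idx_i[a$name[idx_i] == "C1'"]
  c1j <- idx_j[a$name[idx_j] == "C1'"]
  orientation <- NA_character_
  if (length(gi) == 1 && length(gj) == 1 && length(c1i) == 1 && length(c1j) == 1) {
    tors <- dihedral(xyz[c1i, ], xyz[gi, ], xyz[gj, ], xyz[c1j, ])
    orientation <- if (abs(tors) <= 90) "cis" else "trans"
  }
  edge_names <- c(WC = "Watson-Crick", H = "Hoogsteen", S = "Sugar")
  n_hb <- nrow(hb)
  canonical <- identical(edge_i, "WC") && identical(edge_j, "WC") &&
    identical(orientation, "cis") && n_hb >= 2 &&
    paste0(code_i, code_j) %in% CANONICAL_PAIRS
  structure(list(chain_i = chain_i, resid_i = resid_i, code_i = code_i,
                 chain_j = chain_j, resid_j = resid_j, code_j = code_j,
                 edge_i = unname(edge_names[edge_i]),
                 edge_j = unname(edge_names[edge_j]),
                 orientation = orientation, n_hbonds = n_hb,
                 is_canonical = canonical, hbonds = hb),
            class = "bp_annotation")
}

#' @export
print.bp_annotation <- function(x, ...) {
  cat(sprintf("<bp_annotation> %s%d(%s)-%s%d(%s): %s/%s %s, %d H-bond(s)%s\n",
              x$chain_i, x$resid_i, x$code_i, x$chain_j, x$resid_j, x$code_j,
              x$edge_i, x$edge_j, x$orientation, x$n_hbonds,
              if (x$is_canonical) ", canonical" else ""))
  invisible(x)
}

#' Find and classify all base pairs in a model
#'
#' Classifies every nucleic residue pair whose base centroids are within the
#' centroid cutoff.
#'
#' @inheritParams classify_pair
#' @return data.frame of annotations (one row per detected pair).
#' @export
find_pairs <- function(model, d_cut = 3.4, max_centroid = 12) {
  res <- residue_table(model)
  rows <- list()
  if (nrow(res) >= 2) {
    for (i in seq_len(nrow(res) - 1)) {
      for (j in (i + 1):nrow(res)) {
        ann <- classify_pair(model, res$chain[i], res$resid[i],
                             res$chain[j], res$resid[j],
                             d_cut = d_cut, max_centroid = max_centroid)
        if (!is.null(ann))
          rows[[length(rows) + 1]] <- data.frame(
            chain_i = ann$chain_i, resid_i = ann$resid_i, code_i = ann$code_i,
            chain_j = ann$chain_j, resid_j = ann$resid_j, code_j = ann$code_j,
            edge_i = ann$edge_i, edge_j = ann$edge_j,
            orientation = ann$orientation, n_hbonds = ann$n_hbonds,
            is_canonical = ann$is_canonical, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(chain_i = character(0), resid_i = integer(0),
                      code_i = character(0), chain_j = character(0),
                      resid_j = integer(0), code_j = character(0),
                      edge_i = character(0), edge_j = character(0),
                      orientation = character(0), n_hbonds = integer(0),
                      is_canonical = logical(0)))
  do.call(rbind, rows)
}

terminal_pair_table <- function(model) {
  tab <- duplex_pair_table(model)
  tab[c(1, nrow(tab)), , drop = FALSE]
}

#' Terminal base-pair fraying statistics
#'
#' A terminal pair is open in a frame when [classify_pair()] finds no pair or
#' a non-canonical one (loss of the cis Watson-Crick/Watson-Crick geometry
#' with at least two hydrogen bonds).
#'
#' @param traj an `rna_traj` of a duplex.
#' @param pairs optional pair table (`chain_i`, `resid_i`, `chain_j`,
#'   `resid_j`); defaults to the two terminal pairs of the duplex.
#' @param d_cut H-bond distance cutoff (Angstrom).
#' @return object of class `fraying_series`: logical `open` matrix
#'   (frames x pairs), `open_fraction` per pair, and the pair table.
#' @export
fraying_series <- function(traj, pairs = NULL, d_cut = 3.4) {
  if (is.null(pairs)) pairs <- terminal_pair_table(traj$topology)
  open <- matrix(FALSE, nrow = length(traj$frames), ncol = nrow(pairs))
  colnames(open) <- paste0(pairs$chain_i, pairs$resid_i, ":",
                           pairs$chain_j, pairs$resid_j)
  for (k in seq_along(traj$frames)) {
    m <- frame_model(traj, k)
    for (p in seq_len(nrow(pairs))) {
      ann <- classify_pair(m, pairs$chain_i[p], pairs$resid_i[p],
                           pairs$chain_j[p], pairs$resid_j[p], d_cut = d_cut)
      open[k, p] <- is.null(ann) || !ann$is_canonical
    }
  }
  structure(list(open = open, open_fraction = colMeans(open), pairs = pairs),
            class = "fraying_series")
}

#' @export
print.fraying_series <- function(x, ...) {
  cat("<fraying_series>", nrow(x$open), "frames\n")
  for (p in seq_along(x$open_fraction))
    cat(sprintf("  %s: open fraction %.3f\n",
                names(x$open_fraction)[p], x$open_fraction[p]))
  invisible(x)
}
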