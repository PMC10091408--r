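# Base atlases: standard reference-frame base coordinates, nucleotide template
# fixtures, hydrogen-bonding edge membership (Watson-Crick / Hoogsteen / Sugar),
# donor/acceptor lists and groove atom sets. Atlases are data, not code, and
# every classifier accepts an override.

RESNAME_MAP <- c(A = "A", G = "G", C = "C", U = "U",
                 RA = "A", RG = "G", RC = "C", RU = "U",
                 ADE = "A", GUA = "G", CYT = "C", URA = "U",
                 A5 = "A", G5 = "G", C5 = "C", U5 = "U",
                 A3 = "A", G3 = "G", C3 = "C", U3 = "U")

#' Normalise a nucleotide residue name to A/G/C/U
#' @param resname residue name(s) as found in PDB files (e.g. `RG`, `G5`, `GUA`).
#' @return one-letter code(s); `NA` for non-nucleotide names.
#' @export
normalize_resname <- function(resname) {
  unname(RESNAME_MAP[toupper(resname)])
}

# Standard reference-frame coordinates of the base heavy atoms plus C1'
# (x toward the major groove, y along the pair long axis, z the base normal,
# origin midway between the paired bases). Units: Angstrom.
STD_BASE <- list(
  A = data.frame(
    name = c("C1'", "N9", "C8", "N7", "C5", "C6", "N6", "N1", "C2", "N3", "C4"),
    x = c(-2.479, -1.291, 0.024, 0.877, 0.071, 0.369, 1.611, -0.668, -1.912, -2.320, -1.267),
    y = c(5.346, 4.498, 4.897, 3.902, 2.771, 1.398, 0.909, 0.532, 1.023, 2.290, 3.124),
    z = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0), stringsAsFactors = FALSE),
  G = data.frame(
    name = c("C1'", "N9", "C8", "N7", "C5", "C6", "O6", "N1", "C2", "N2", "N3", "C4"),
    x = c(-2.477, -1.289, 0.023, 0.870, 0.071, 0.424, 1.554, -0.700, -1.999, -2.949, -2.342, -1.265),
    y = c(5.399, 4.551, 4.962, 3.969, 2.833, 1.460, 0.955, 0.641, 1.087, 0.139, 2.364, 3.177),
    z = c(0, 0, 0, 0, 0, 0, 0, 0, 0, -0.001, 0.001, 0), stringsAsFactors = FALSE),
  C = data.frame(
    name = c("C1'", "N1", "C2", "O2", "N3", "C4", "N4", "C5", "C6"),
    x = c(-2.477, -1.285, -1.472, -2.628, -0.391, 0.837, 1.875, 1.056, -0.023),
    y = c(5.402, 4.542, 3.158, 2.709, 2.344, 2.868, 2.027, 4.275, 5.068),
    z = c(0, 0, 0, 0.001, 0, 0, 0.001, 0, 0), stringsAsFactors = FALSE),
  U = data.frame(
    name = c("C1'", "N1", "C2", "O2", "N3", "C4", "O4", "C5", "C6"),
    x = c(-2.481, -1.284, -1.462, -2.563, -0.302, 0.989, 1.935, 1.089, -0.024),
    y = c(5.354, 4.500, 3.131, 2.608, 2.397, 2.884, 2.094, 4.311, 5.053),
    z = c(0, 0, 0, 0, 0, 0, -0.001, 0, 0), stringsAsFactors = FALSE)
)

#' Standard-reference-frame base coordinates
#' @param code one-letter base code (`A`, `G`, `C`, `U`).
#' @return data.frame with `name`, `x`, `y`, `z` (base heavy atoms plus C1').
#' @export
std_base_coords <- function(code) {
  code <- toupper(code)
  if (!code %in% names(STD_BASE)) stop("unknown base code: ", code)
  STD_BASE[[code]]
}

is_purine <- function(code) toupper(code) %in% c("A", "G")

glycosidic_atom <- function(code) if (is_purine(code)) "N9" else "N1"

base_heavy_atoms <- function(code) setdiff(std_base_coords(code)$name, "C1'")

.template_cache <- new.env(parent = emptyenv())

#' Idealized all-heavy-atom nucleotide template
#'
#' Fixture geometry (base, ribose, 5'-phosphate; no hydrogens) expressed in the
#' standard base reference frame, shipped as plain-text fixtures under
#' `inst/extdata/nucleotide-templates/`.
#'
#' @param code one-letter base code.
#' @return data.frame with `name`, `element`, `x`, `y`, `z`.
#' @export
nucleotide_template <- function(code) {
  code <- toupper(code)
  if (!code %in% c("A", "G", "C", "U")) stop("unknown base code: ", code)
  if (!is.null(.template_cache[[code]])) return(.template_cache[[code]])
  path <- system.file("extdata", "nucleotide-templates",
                      paste0(code, ".tsv"), package = "helixion",
                      mustWork = TRUE)
  tpl <- utils::read.delim(path, stringsAsFactors = FALSE)
  .template_cache[[code]] <- tpl
  tpl
}

#' Hydrogen-bonding edge atlas
#'
#' Maps base atoms to the edge(s) they can hydrogen-bond through:
#' `WC` (Watson-Crick), `H` (Hoogsteen; the C-H edge for pyrimidines) and
#' `S` (Sugar). Atoms sitting between two edges (e.g. O6 of G, N2 of G) carry
#' both memberships. The ribose 2'-OH belongs to the Sugar edge of every base.
#'
#' @return data.frame with columns `base`, `atom`, `edge`.
#' @export
edge_atlas <- function() {
  rows <- list(
    c("A", "N1", "WC"), c("A", "C2", "WC"), c("A", "C6", "WC"),
    c("A", "N6", "WC"), c("A", "N6", "H"), c("A", "N7", "H"), c("A", "C8", "H"),
    c("A", "N3", "S"), c("A", "O2'", "S"),
    c("G", "N1", "WC"), c("G", "C2", "WC"), c("G", "C6", "WC"),
    c("G", "O6", "WC"), c("G", "O6", "H"), c("G", "N7", "H"), c("G", "C8", "H"),
    c("G", "N2", "WC"), c("G", "N2", "S"), c("G", "N3", "S"), c("G", "O2'", "S"),
    c("C", "N3", "WC"), c("C", "N4", "WC"), c("C", "N4", "H"),
    c("C", "C5", "H"), c("C", "C6", "H"),
    c("C", "O2", "WC"), c("C", "O2", "S"), c("C", "O2'", "S"),
    c("U", "N3", "WC"), c("U", "O4", "WC"), c("U", "O4", "H"),
    c("U", "C5", "H"), c("U", "C6", "H"),
    c("U", "O2", "WC"), c("U", "O2", "S"), c("U", "O2'", "S")
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(base = r[1], atom = r[2], edge = r[3], stringsAsFactors = FALSE)))
  out
}

#' Hydrogen-bond donor and acceptor heavy atoms per base
#'
#' Heavy-atom lists (amino/imino nitrogens as donors; keto oxygens and ring
#' nitrogens as acceptors). The 2'-OH oxygen acts as both.
#'
#' @return list with one entry per base, each holding `donors` and `acceptors`.
#' @export
donor_acceptor_atlas <- function() {
  list(
    A = list(donors = c("N6", "O2'"), acceptors = c("N1", "N3", "N7", "O2'")),
    G = list(donors = c("N1", "N2", "O2'"), acceptors = c("O6", "N3", "N7", "O2'")),
    C = list(donors = c("N4", "O2'"), acceptors = c("O2", "N3", "O2'")),
    U = list(donors = c("N3", "O2'"), acceptors = c("O2", "O4", "O2'"))
  )
}

#' Groove and phosphate atom sets
#'
#' Atom names defining the binding-site classes used by residue occupancy:
#' major groove (purine N7/O6 or N6/C8; pyrimidine O4 or N4/C5/C6), minor
#' groove (purine N3 and C2 or N2; pyrimidine O2) and phosphate oxygens.
#'
#' @param site one of `"major_groove"`, `"minor_groove"`, `"phosphate"`.
#' @return named list of atom-name vectors per base (or a single vector for
#'   `"phosphate"`).
#' @export
groove_atlas <- function(site = c("major_groove", "minor_groove", "phosphate")) {
  site <- match.arg(site)
  switch(site,
    major_groove = list(A = c("N7", "N6", "C8"), G = c("N7", "O6", "C8"),
                        C = c("N4", "C5", "C6"), U = c("O4", "C5", "C6")),
    minor_groove = list(A = c("N3", "C2"), G = c("N3", "N2"),
                        C = c("O2"), U = c("O2")),
    phosphate = list(A = c("OP1", "OP2"), G = c("OP1", "OP2"),
                     C = c("OP1", "OP2"), U = c("OP1", "OP2"))
  )
}

# Residue table of a model: one row per (chain, resid) nucleic residue,
# in chain/resid order, with normalised one-letter codes.
residue_table <- function(model, nucleic_only = TRUE) {
  a <- model$atoms
  key <- paste(a$chain, a$resid, sep = "\r")
  first <- !duplicated(key)
  res <- data.frame(chain = a$chain[first], resid = a$resid[first],
                    resname = a$resname[first], stringsAsFactors = FALSE)
  res$code <- normalize_resname(res$resname)
  if (nucleic_only) res <- res[!is.na(res$code), , drop = FALSE]
  res <- res[order(res$chain, res$resid), , drop = FALSE]
  rownames(res) <- NULL
  res
}

residue_atom_idx <- function(model, chain, resid) {
  which(model$atoms$chain == chain & model$atoms$resid == resid)
}
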