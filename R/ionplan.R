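# Charge and ion-count arithmetic for simulation-box setup.
#
# Each internal phosphodiester carries one negative formal charge, so a strand
# with 5'-OH termini contributes -(length - 1) e and a 5'-phosphorylated strand
# -length e. Termini default to 5'-OH, matching builder conventions for
# constructed duplexes.

#' Net formal charge of a nucleic acid from its sequence
#'
#' @param sequences character vector, one nucleotide string (A/C/G/U) per strand.
#' @param terminal_phosphates if `TRUE`, strands carry a 5'-terminal phosphate.
#' @return signed integer charge in elementary units (e).
#' @examples
#' net_charge(c("CGCGCGCGCG", "CGCGCGCGCG"))  # -18
#' @export
net_charge <- function(sequences, terminal_phosphates = FALSE) {
  if (length(sequences) == 0 || any(!nzchar(sequences)))
    stop("sequences must be non-empty")
  sequences <- toupper(sequences)
  bad <- gsub("[ACGU]", "", sequences)
  if (any(nzchar(bad)))
    stop("unknown nucleotide letter(s): ", paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]), collapse = ", "))
  n <- nchar(sequences)
  phosphates <- if (terminal_phosphates) sum(n) else sum(n - 1L)
  -as.integer(phosphates)
}

#' Net formal charge of a built structure model
#'
#' Counts phosphorus atoms in nucleic residues (one negative charge each).
#'
#' @param model an [rna_model()].
#' @return signed integer charge (e).
#' @export
model_net_charge <- function(model) {
  nucleic <- model$atoms$resname %in% names(RESNAME_MAP)
  -as.integer(sum(nucleic & model$atoms$name == "P"))
}

#' Anions required for overall electroneutrality
#'
#' With an RNA of charge `q` (negative) and `n_cations` monovalent cations in
#' the box, `n_cations + q` anions give a net-neutral system.
#'
#' @param rna_net_charge signed integer charge (e).
#' @param n_cations non-negative cation count.
#' @return non-negative anion count.
#' @examples
#' anions_for_neutrality(-18, 120)  # 102
#' @export
anions_for_neutrality <- function(rna_net_charge, n_cations) {
  if (n_cations < 0) stop("cation count must be non-negative")
  n <- n_cations + rna_net_charge
  if (n < 0)
    stop(sprintf("infeasible: %d cations cannot neutralise charge %d",
                 n_cations, rna_net_charge))
  as.integer(n)
}

#' Ion count for a nominal concentration in a box
#'
#' Nearest integer (half away from zero) to `concentration x volume x N_A`.
#'
#' @param concentration mol/L.
#' @param box_volume_nm3 box volume in nm^3.
#' @return non-negative integer ion count.
#' @examples
#' ions_for_concentration(0.15, 200)  # 18
#' @export
ions_for_concentration <- function(concentration, box_volume_nm3) {
  if (concentration < 0 || box_volume_nm3 <= 0)
    stop("concentration must be >= 0 and box volume > 0")
  as.integer(round_half_away(concentration * box_volume_nm3 * 1e-24 * AVOGADRO))
}

#' Cations compensating a fraction of the RNA charge
#'
#' @param rna_net_charge signed integer charge (e).
#' @param fraction fraction of the charge to compensate, in \[0, 1\].
#' @return integer cation count, `round(fraction * |charge|)`.
#' @examples
#' charge_fraction_cations(-18, 2 / 3)  # 12
#' @export
charge_fraction_cations <- function(rna_net_charge, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  as.integer(round_half_away(fraction * abs(rna_net_charge)))
}

#' Assemble a neutral salt plan
#'
#' Given a duplex sequence (or a precomputed charge) and either an explicit
#' cation count or a target concentration and box volume, returns the neutral
#' cation/anion bookkeeping for the box.
#'
#' @param sequences per-strand sequences (see [net_charge()]); ignored when
#'   `rna_net_charge` is given.
#' @param rna_net_charge signed integer charge (e).
#' @param n_cations explicit cation count; when `NULL` it is derived from
#'   `concentration` (excess-salt pairs on top of neutralisation).
#' @param concentration nominal salt concentration (mol/L), optional.
#' @param box_volume_nm3 box volume (nm^3), required with `concentration`.
#' @param terminal_phosphates passed to [net_charge()].
#' @return list of class `salt_plan` with fields `rna_net_charge`, `n_cations`,
#'   `n_anions`, `nominal_concentration`.
#' @export
salt_plan <- function(sequences = NULL, rna_net_charge = NULL, n_cations = NULL,
                      concentration = NULL, box_volume_nm3 = NULL,
                      terminal_phosphates = FALSE) {
  if (is.null(rna_net_charge)) {
    if (is.null(sequences)) stop("give either sequences or rna_net_charge")
    rna_net_charge <- net_charge(sequences, terminal_phosphates)
  }
  if (is.null(n_cations)) {
    if (is.null(concentration)) {
      n_cations <- abs(rna_net_charge)
    } else {
      if (is.null(box_volume_nm3)) stop("concentration needs box_volume_nm3")
      n_cations <- abs(rna_net_charge) +
        ions_for_concentration(concentration, box_volume_nm3)
    }
  }
  plan <- structure(list(
    rna_net_charge = as.integer(rna_net_charge),
    n_cations = as.integer(n_cations),
    n_anions = anions_for_neutrality(rna_net_charge, n_cations),
    nominal_concentration = concentration %||% NA_real_
  ), class = "salt_plan")
  stopifnot(plan$rna_net_charge + plan$n_cations - plan$n_anions == 0L)
  plan
}

#' @export
print.salt_plan <- function(x, ...) {
  cat(sprintf("<salt_plan> RNA charge %+d e: %d cations, %d anions%s\n",
              x$rna_net_charge, x$n_cations, x$n_anions,
              if (is.na(x$nominal_concentration)) ""
              else sprintf(" (nominal %.3g M)", x$nominal_concentration)))
  invisible(x)
}
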