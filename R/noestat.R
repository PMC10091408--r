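# NOE back-calculation and chi-square agreement scoring.
#
# Effective distances use the r^-6 ensemble-average convention,
# <r^-6>^(-1/6), the standard for NOE comparison against MD ensembles; a flag
# switches to the plain linear average. The chi-square uses asymmetric
# experimental errors: for each restraint the error is the LARGER of
# (max - exp) and (exp - min).

parse_atom_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("atom id must be 'chain:resid:name', got '", id, "'")
  list(chain = parts[1], resid = as.integer(parts[2]), name = parts[3])
}

atom_index <- function(model, id) {
  p <- parse_atom_id(id)
  idx <- which(model$atoms$chain == p$chain & model$atoms$resid == p$resid &
                 model$atoms$name == p$name)
  if (length(idx) != 1)
    stop("atom id '", id, "' resolves to ", length(idx), " atoms")
  idx
}

#' Read an NOE restraint table
#'
#' Tab-separated columns `atom1`, `atom2`, `exp`, `min`, `max` with a header
#' row; atom identifiers are `chain:resid:name`.
#'
#' @param file path or character vector of TSV lines.
#' @return data.frame with the restraints and the derived asymmetric error
#'   `err = max(max - exp, exp - min)`.
#' @export
read_noe_table <- function(file) {
  tab <- if (length(file) == 1 && file.exists(file))
    utils::read.delim(file, stringsAsFactors = FALSE)
  else utils::read.delim(textConnection(paste(file, collapse = "\n")),
                         stringsAsFactors = FALSE)
  need <- c("atom1", "atom2", "exp", "min", "max")
  if (!all(need %in% names(tab)))
    stop("NOE table needs columns: ", paste(need, collapse = ", "))
  if (any(tab$min > tab$exp | tab$exp > tab$max))
    stop("NOE bounds must satisfy min <= exp <= max")
  tab$err <- pmax(tab$max - tab$exp, tab$exp - tab$min)
  tab
}

#' Effective ensemble distance of an atom pair
#'
#' `<r^-6>^(-1/6)` over the trajectory frames (or the linear mean distance
#' with `method = "linear"`). Bounded by the per-frame minimum and maximum.
#'
#' @param traj an `rna_traj`.
#' @param atom1,atom2 atom ids (`chain:resid:name`) or atom indices.
#' @param method `"r6"` (default) or `"linear"`.
#' @return distance in Angstrom.
#' @export
effective_distance <- function(traj, atom1, atom2, method = c("r6", "linear")) {
  method <- match.arg(method)
  if (length(traj$frames) == 0) stop("no trajectory samples (M = 0)")
  i <- if (is.character(atom1)) atom_index(traj$topology, atom1) else atom1
  j <- if (is.character(atom2)) atom_index(traj$topology, atom2) else atom2
  r <- vapply(traj$frames, function(xyz) vnorm(xyz[i, ] - xyz[j, ]),
              numeric(1))
  if (any(r < 1e-9)) stop("coincident atoms in at least one frame")
  if (method == "r6") mean(r^(-6))^(-1 / 6) else mean(r)
}

#' Chi-square agreement between calculated and experimental NOEs
#'
#' `chi2 = (1/N) * sum_i ((calc_i - exp_i) / err_i)^2` with the asymmetric
#' error rule. Items with non-positive error are excluded with a warning
#' (never silently zero-weighted).
#'
#' @param items data.frame with `exp`, `min`, `max` (or a precomputed `err`).
#' @param calc numeric vector of calculated values, one per item.
#' @param n_samples optional ensemble size M, recorded in the report.
#' @return object of class `chi_square_report`: `chi2`, `n` (items used),
#'   `n_excluded`, `m_samples`, and per-item `items` (with `calc`, `err`,
#'   `contribution`).
#' @export
chi2_noe <- function(items, calc, n_samples = NA_integer_) {
  if (nrow(items) != length(calc))
    stop("need one calculated value per NOE item")
  if (is.null(items$err)) {
    if (any(items$min > items$exp | items$exp > items$max))
      stop("NOE bounds must satisfy min <= exp <= max")
    items$err <- pmax(items$max - items$exp, items$exp - items$min)
  }
  items$calc <- calc
  bad <- items$err <= 0
  if (any(bad))
    warning(sum(bad), " item(s) with non-positive experimental error excluded")
  use <- items[!bad, , drop = FALSE]
  if (nrow(use) == 0) stop("no NOE items with positive error")
  use$contribution <- ((use$calc - use$exp) / use$err)^2
  structure(list(chi2 = mean(use$contribution), n = nrow(use),
                 n_excluded = sum(bad), m_samples = n_samples,
                 items = use),
            class = "chi_square_report")
}

#' @export
print.chi_square_report <- function(x, ...) {
  cat(sprintf("<chi_square_report> chi2 = %.4f over %d NOEs%s%s\n",
              x$chi2, x$n,
              if (x$n_excluded > 0) sprintf(" (%d excluded)", x$n_excluded) else "",
              if (is.na(x$m_samples)) "" else sprintf(", M = %d samples", x$m_samples)))
  invisible(x)
}

#' Back-calculate and score a trajectory against an NOE table
#'
#' @param traj an `rna_traj`.
#' @param table NOE table (path or data.frame, see [read_noe_table()]).
#' @param method averaging convention for [effective_distance()].
#' @return a `chi_square_report`.
#' @export
noe_report <- function(traj, table, method = c("r6", "linear")) {
  method <- match.arg(method)
  if (!is.data.frame(table)) table <- read_noe_table(table)
  calc <- vapply(seq_len(nrow(table)), function(i)
    effective_distance(traj, table$atom1[i], table$atom2[i], method = method),
    numeric(1))
  chi2_noe(table, calc, n_samples = length(traj$frames))
}
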