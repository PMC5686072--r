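# Receptor-ensemble score aggregation and binding-pocket dynamics metrics.
#
# Cross-docking against an ensemble of receptor conformations averages out
# the sensitivity of single-structure docking to side-chain orientation;
# the per-compound ensemble mean is compared against the experimental
# affinity order by rank concordance. Pocket dynamics are summarised by
# "gate" side-chain distances (e.g. Tyr247 Cz to the Ca atoms of Leu221 and
# Leu246 across the binding site), per-atom RMSF after superposition on the
# stable helical regions, and open/closed/bound-like state classification.

#' Construct a coordinate ensemble
#'
#' @param atoms Data frame describing the shared atom table: columns
#'   `elety` (atom name), `resno`, `resid` (3-letter residue type), `chain`.
#' @param xyz Numeric matrix, one row per model, `3 * n_atoms` columns in
#'   bio3d order (x1, y1, z1, x2, ...), Angstrom.
#' @return Object of class `coord_ensemble`.
#' @export
coord_ensemble <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop_dynappi("xyz columns must equal 3 x atom count", "dynappi_ensemble_error")
  if (any(!is.finite(xyz)))
    stop_dynappi("non-finite coordinates in ensemble", "dynappi_ensemble_error")
  structure(list(atoms = atoms, xyz = xyz), class = "coord_ensemble")
}

#' @export
print.coord_ensemble <- function(x, ...) {
  cat(sprintf("Coordinate ensemble: %d models x %d atoms\n",
              nrow(x$xyz), nrow(x$atoms)))
  invisible(x)
}

n_models <- function(ens) nrow(ens$xyz)

# internal: n_atoms x 3 coordinates of model i
model_coords <- function(ens, i) {
  matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Aggregate a compound x receptor-conformation score matrix
#'
#' Per-compound mean, sd, min and max across receptor conformations, with
#' compounds ranked by ensemble-mean score (higher is better, ties broken
#' by id). `NA` cells are the explicit "failed docking" sentinel; they are
#' excluded from the aggregates and their count logged per compound.
#'
#' @param matrix Numeric matrix, rows = compounds (rownames), columns =
#'   receptor conformations; or a [score_matrix()].
#' @return Data frame `id`, `mean`, `sd`, `min`, `max`, `n_used`,
#'   `n_failed`, `rank`, ordered by rank.
#' @export
aggregate_ensemble_scores <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop_dynappi("empty score matrix", "dynappi_ensemble_error")
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  agg <- data.frame(
    id = ids,
    mean = apply(m, 1, mean, na.rm = TRUE),
    sd = apply(m, 1, function(r) if (sum(!is.na(r)) > 1) sd(r, na.rm = TRUE) else 0),
    min = apply(m, 1, min, na.rm = TRUE),
    max = apply(m, 1, max, na.rm = TRUE),
    n_used = rowSums(!is.na(m)),
    n_failed = rowSums(is.na(m)),
    stringsAsFactors = FALSE)
  agg <- agg[order(-agg$mean, agg$id), , drop = FALSE]
  agg$rank <- seq_len(nrow(agg))
  rownames(agg) <- NULL
  agg
}

#' Rank agreement between predicted scores and a reference order
#'
#' Kendall tau and Spearman rho between the ranking induced by the
#' predicted scores (higher = better) and a best-first reference order,
#' using the standard tie-corrected formulas.
#'
#' @param predicted Named numeric vector of scores.
#' @param reference_order Character vector of the same ids, best first.
#' @return List with `tau` and `rho`.
#' @export
rank_agreement <- function(predicted, reference_order) {
  if (!setequal(names(predicted), reference_order) ||
      length(predicted) != length(reference_order)) {
    extra <- setdiff(names(predicted), reference_order)
    miss <- setdiff(reference_order, names(predicted))
    stop_dynappi(sprintf("id mismatch (only in predicted: %s; only in reference: %s)",
                         paste(extra, collapse = ",") , paste(miss, collapse = ",")),
                 "dynappi_rank_error")
  }
  if (length(predicted) < 3L)
    stop_dynappi("need at least 3 ids", "dynappi_rank_error")
  ref_score <- setNames(rev(seq_along(reference_order)), reference_order)
  x <- predicted[reference_order]
  y <- ref_score[reference_order]
  list(tau = cor(x, y, method = "kendall"),
       rho = cor(x, y, method = "spearman"))
}

# internal: parse "A:247:CZ" or list(chain=, resno=, elety=)
parse_atom_spec <- function(spec) {
  if (is.character(spec) && length(spec) == 1L) {
    parts <- strsplit(spec, ":")[[1]]
    if (length(parts) != 3L)
      stop_dynappi(sprintf("atom spec '%s' is not chain:resno:name", spec),
                   "dynappi_atom_error")
    spec <- list(chain = parts[1], resno = as.integer(parts[2]), elety = parts[3])
  }
  spec
}

find_atom <- function(ens, spec) {
  spec <- parse_atom_spec(spec)
  i <- which(ens$atoms$chain == spec$chain &
             ens$atoms$resno == spec$resno &
             ens$atoms$elety == spec$elety)
  if (length(i) != 1L)
    stop_dynappi(sprintf("atom %s:%s:%s matched %d atoms in the ensemble table",
                         spec$chain, spec$resno, spec$elety, length(i)),
                 "dynappi_atom_error")
  i
}

#' Per-model distance between two named atoms
#'
#' @param ens A [coord_ensemble()].
#' @param atom_a,atom_b Atom specs, either `"chain:resno:name"` strings
#'   (e.g. `"A:247:CZ"`) or lists with `chain`, `resno`, `elety`.
#' @return List with `distances` (Angstrom, one per model) and `summary`
#'   (mean, sd, min, max).
#' @export
distance_series <- function(ens, atom_a, atom_b) {
  ia <- find_atom(ens, atom_a); ib <- find_atom(ens, atom_b)
  d <- vapply(seq_len(n_models(ens)), function(m) {
    co <- model_coords(ens, m)
    sqrt(sum((co[ia, ] - co[ib, ])^2))
  }, numeric(1))
  list(distances = d,
       summary = c(mean = mean(d), sd = if (length(d) > 1) sd(d) else 0,
                   min = min(d), max = max(d)))
}

# internal: resolve a selection spec (list(resno=, elety=), either may be
# NULL = all) to atom indices
resolve_selection <- function(ens, sel) {
  keep <- rep(TRUE, nrow(ens$atoms))
  if (!is.null(sel$resno)) keep <- keep & ens$atoms$resno %in% sel$resno
  if (!is.null(sel$elety)) keep <- keep & ens$atoms$elety %in% sel$elety
  which(keep)
}

#' Per-atom and per-residue RMSF after iterated superposition
#'
#' Each model is least-squares superposed onto the ensemble mean structure
#' using the fit selection (typically Ca atoms of the stable helical
#' regions); the mean structure is recomputed and the procedure iterated
#' (at least twice) until it changes by less than `tol`. RMSF of an atom is
#' the root-mean-square deviation of its position from the converged mean
#' across models; per-residue values average the residue's reported atoms.
#'
#' @param ens A [coord_ensemble()].
#' @param fit_sel Selection list `list(resno = ..., elety = ...)` for the
#'   superposition (e.g. `list(resno = c(218:232, 239:247), elety = "CA")`).
#' @param report_sel Selection for which RMSF is reported (default: all
#'   atoms).
#' @param tol Mean-structure convergence tolerance, Angstrom.
#' @return List with `atom` (data frame: atom table columns + `rmsf`) and
#'   `residue` (data frame `resno`, `rmsf`).
#' @export
superpose_rmsf <- function(ens, fit_sel, report_sel = NULL, tol = 1e-6) {
  fit_idx <- resolve_selection(ens, fit_sel)
  if (length(fit_idx) == 0L)
    stop_dynappi("empty fit selection", "dynappi_selection_error")
  rep_idx <- if (is.null(report_sel)) seq_len(nrow(ens$atoms))
             else resolve_selection(ens, report_sel)
  nm <- n_models(ens)
  coords <- lapply(seq_len(nm), function(m) model_coords(ens, m))
  mean_str <- Reduce(`+`, coords) / nm
  for (it in seq_len(50L)) {
    coords <- lapply(coords, function(co) {
      fit <- superpose_points(co[fit_idx, , drop = FALSE],
                              mean_str[fit_idx, , drop = FALSE])
      sweep(co %*% fit$rotation, 2, fit$translation, `+`)
    })
    new_mean <- Reduce(`+`, coords) / nm
    delta <- max(abs(new_mean - mean_str))
    mean_str <- new_mean
    if (it >= 2L && delta < tol) break
  }
  dev2 <- Reduce(`+`, lapply(coords, function(co) rowSums((co - mean_str)^2))) / nm
  rmsf <- sqrt(dev2)
  atom_df <- cbind(ens$atoms[rep_idx, , drop = FALSE], rmsf = rmsf[rep_idx])
  res_df <- aggregate(rmsf ~ resno, data = atom_df, FUN = mean)
  list(atom = atom_df, residue = res_df)
}

#' Gate-distance pocket metrics for an ensemble
#'
#' @param ens A [coord_ensemble()].
#' @param gate1,gate2 Each a length-2 list/vector of atom specs
#'   (`"chain:resno:name"`), e.g.
#'   `gate1 = c("A:247:CZ", "A:221:CA")`, `gate2 = c("A:247:CZ", "A:246:CA")`.
#' @return Data frame `model`, `d_gate1`, `d_gate2` (Angstrom).
#' @export
pocket_metrics <- function(ens,
                           gate1 = c("A:247:CZ", "A:221:CA"),
                           gate2 = c("A:247:CZ", "A:246:CA")) {
  d1 <- distance_series(ens, gate1[[1]], gate1[[2]])$distances
  d2 <- distance_series(ens, gate2[[1]], gate2[[2]])$distances
  data.frame(model = seq_along(d1), d_gate1 = d1, d_gate2 = d2)
}

#' Pocket-state classification thresholds
#'
#' The closed state has both gate distances at or below `closed_max`; the
#' open state both at or above `open_min`; a bound-like model has both
#' distances within `bound_tol` of the reference (e.g. lowest-energy
#' bound-form) distances. Regions must not overlap: the bound-like window,
#' when given, must lie strictly between the closed and open regions.
#'
#' @param closed_max Upper bound of the closed region, Angstrom.
#' @param open_min Lower bound of the open region, Angstrom.
#' @param bound_ref Optional reference gate distances `c(d_gate1, d_gate2)`.
#' @param bound_tol Half-width of the bound-like window, Angstrom.
#' @return Validated threshold list of class `pocket_thresholds`.
#' @export
pocket_thresholds <- function(closed_max, open_min, bound_ref = NULL,
                              bound_tol = 1.5) {
  if (closed_max >= open_min)
    stop_dynappi("closed and open regions overlap (closed_max >= open_min)",
                 "dynappi_threshold_error")
  if (!is.null(bound_ref)) {
    lo <- bound_ref - bound_tol; hi <- bound_ref + bound_tol
    if (any(lo <= closed_max) || any(hi >= open_min))
      stop_dynappi("bound-like window overlaps the closed or open region",
                   "dynappi_threshold_error")
  }
  structure(list(closed_max = closed_max, open_min = open_min,
                 bound_ref = bound_ref, bound_tol = bound_tol),
            class = "pocket_thresholds")
}

#' Classify pocket states from gate-distance metrics
#'
#' @param metrics Data frame from [pocket_metrics()] (`d_gate1`, `d_gate2`).
#' @param thresholds A [pocket_thresholds()] object.
#' @return List with `states` (factor per model over
#'   open/closed/bound_like/indeterminate) and `fractions` (named numeric).
#' @export
classify_pocket <- function(metrics, thresholds) {
  stopifnot(inherits(thresholds, "pocket_thresholds"))
  d1 <- metrics$d_gate1; d2 <- metrics$d_gate2
  if (any(c(d1, d2) <= 0))
    stop_dynappi("gate distances must be positive", "dynappi_threshold_error")
  lab <- rep("indeterminate", length(d1))
  if (!is.null(thresholds$bound_ref)) {
    ok <- abs(d1 - thresholds$bound_ref[1]) <= thresholds$bound_tol &
          abs(d2 - thresholds$bound_ref[2]) <= thresholds$bound_tol
    lab[ok] <- "bound_like"
  }
  lab[d1 <= thresholds$closed_max & d2 <= thresholds$closed_max] <- "closed"
  lab[d1 >= thresholds$open_min & d2 >= thresholds$open_min] <- "open"
  states <- factor(lab, levels = c("open", "closed", "bound_like", "indeterminate"))
  list(states = states, fractions = prop.table(table(states)))
}

#' Integer formal charge of a protein sequence at pH 7
#'
#' Simple integer ionisation model: Asp and Glu -1, Lys and Arg +1, His 0
#' (side-chain pKa ~6, predominantly neutral at pH 7), N-terminus +1 and
#' C-terminus -1 (net zero from the termini).
#'
#' @param sequence One-letter protein string over the 20 standard residues.
#' @param his_charge Histidine side-chain charge (default 0; set 1 to
#'   protonate).
#' @return Integer net charge.
#' @export
formal_charge <- function(sequence, his_charge = 0L) {
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- setdiff(aa, standard)
  if (length(bad) > 0L)
    stop_dynappi(sprintf("non-standard residue letter(s): %s",
                         paste(unique(bad), collapse = ", ")),
                 "dynappi_sequence_error")
  charges <- c(D = -1L, E = -1L, K = 1L, R = 1L, H = as.integer(his_charge))
  sum(charges[aa], na.rm = TRUE)  # termini contribute +1 - 1 = 0
}

#' Monovalent counterion count to neutralise a multimer
#'
#' @param charge_per_monomer Integer net charge of one monomer.
#' @param n_monomers Number of monomers in the simulated system.
#' @return List with `n_ions` (count of monovalent counterions) and `ion`
#'   (`"cation"` for a negative system, `"anion"` for positive, `"none"`).
#' @export
neutralizing_ions <- function(charge_per_monomer, n_monomers) {
  total <- charge_per_monomer * n_monomers
  list(n_ions = abs(total),
       ion = if (total < 0) "cation" else if (total > 0) "anion" else "none")
}

#' Deterministic toy docking backend
#'
#' A soft-sphere contact score for end-to-end pipeline tests, standing
#' behind the pluggable docking-backend contract
#' (`function(receptor_points, ligand_points) -> score`). Each ligand
#' feature point contributes a Gaussian contact term
#' `exp(-d^2 / (2 r^2))` to its nearest receptor pocket point; the score is
#' 100 times the mean contact. The score is deterministic and decreases
#' monotonically as ligand points leave the pocket spheres.
#'
#' @param radius Contact decay length, Angstrom.
#' @return A backend function taking two n x 3 coordinate matrices
#'   (receptor pocket points, ligand points) and returning a scalar score.
#' @export
toy_dock_backend <- function(radius = 2) {
  force(radius)
  function(receptor_points, ligand_points) {
    rp <- as.matrix(receptor_points); lp <- as.matrix(ligand_points)
    contact <- vapply(seq_len(nrow(lp)), function(i) {
      d2 <- rowSums(sweep(rp, 2, lp[i, ])^2)
      exp(-min(d2) / (2 * radius^2))
    }, numeric(1))
    100 * mean(contact)
  }
}

#' Import a compound x receptor-conformation score matrix from CSV
#'
#' First column `id`, remaining columns numeric scores (one per receptor
#' conformation or scoring function). Empty cells become the `NA`
#' "failed to score" sentinel; any other non-numeric cell is a parse error
#' reported with its line number.
#'
#' @param path CSV file path.
#' @param higher_is_better Per-column direction flags (default `TRUE`).
#' @return A [score_matrix()].
#' @export
import_scores <- function(path, higher_is_better = TRUE) {
  if (!file.exists(path))
    stop_dynappi(sprintf("score file not found: %s", path), "dynappi_io_error")
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  if (ncol(raw) < 2L)
    stop_dynappi(sprintf("%s: need an id column plus at least one score column", path),
                 "dynappi_io_error")
  ids <- raw[[1]]
  m <- matrix(NA_real_, nrow(raw), ncol(raw) - 1L,
              dimnames = list(ids, names(raw)[-1]))
  for (j in 2:ncol(raw)) {
    v <- raw[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & nzchar(trimws(v)))
    if (length(bad) > 0L)
      stop_dynappi(sprintf("%s line %d: cell '%s' in column '%s' is not numeric",
                           path, bad[1] + 1L, v[bad[1]], names(raw)[j]),
                   "dynappi_io_error")
    m[, j - 1L] <- num
  }
  score_matrix(m, higher_is_better)
}

#' @rdname import_scores
#' @export
read_matrix <- import_scores
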