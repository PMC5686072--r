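# Compound property calculation and multi-objective prioritisation:
# monoisotopic masses, ligand efficiency, Lipinski profiling, consensus
# scoring across scoring functions, Pareto non-dominated sorting, solubility
# and docking-pose consistency filters, and the staged selection funnel.

# principal-isotope (monoisotopic) masses, Da
ISOTOPE_MASSES <- c(
  C = 12.0, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
  S = 31.97207069, P = 30.97376151, F = 18.9984031627, Cl = 34.96885271,
  Br = 78.9183376, I = 126.904468, Na = 22.98976928, K = 38.9637064864,
  B = 11.0093054, Si = 27.9769265350
)

#' Parse a molecular formula string
#'
#' @param formula A Hill-style formula string, e.g. `"C16H23N3O2"`, or an
#'   already-named count vector (returned unchanged).
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    return(setNames(as.integer(formula), names(formula)))
  }
  stopifnot(is.character(formula), length(formula) == 1L)
  m <- gregexpr("([A-Z][a-z]?)(\\d*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L || sum(nchar(toks)) != nchar(formula))
    stop_dynappi(sprintf("cannot parse formula '%s'", formula), "dynappi_formula_error")
  elems <- sub("\\d+$", "", toks)
  counts <- as.integer(ifelse(grepl("\\d+$", toks), sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(counts, elems, sum)
  setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count times principal-isotope mass over the formula map. Values
#' are exact to the isotope-mass table; comparisons with printed masses are
#' conventionally made at two decimals.
#'
#' @param formula Formula string or named element-count vector.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")        # 18.0106
#' monoisotopic_mass("C16H23N3O2") # 289.179
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(ISOTOPE_MASSES))
  if (length(unknown) > 0L)
    stop_dynappi(sprintf("unknown element symbol(s): %s",
                         paste(unknown, collapse = ", ")),
                 "dynappi_formula_error")
  if (any(counts < 0))
    stop_dynappi("element counts must be non-negative", "dynappi_formula_error")
  sum(counts * ISOTOPE_MASSES[names(counts)])
}

#' Ligand efficiency
#'
#' Score normalised by the number of heavy atoms; applied column-wise to a
#' score matrix when `score` is a matrix and `heavy_atoms` a per-compound
#' vector.
#'
#' @param score Numeric score(s) or a compounds x functions score matrix.
#' @param heavy_atoms Heavy-atom count(s), >= 1.
#' @return Score / heavy-atom count, same shape as `score`.
#' @export
ligand_efficiency <- function(score, heavy_atoms) {
  if (any(!is.finite(heavy_atoms)) || any(heavy_atoms < 1))
    stop_dynappi("heavy_atoms must be >= 1", "dynappi_le_error")
  if (is.matrix(score)) {
    if (length(heavy_atoms) != nrow(score))
      stop_dynappi("need one heavy-atom count per score-matrix row", "dynappi_le_error")
    return(sweep(score, 1, heavy_atoms, `/`))
  }
  score / heavy_atoms
}

#' Lipinski rule-of-five profile
#'
#' Rules: molecular weight <= 500 g/mol, logP <= 5, hydrogen-bond donors
#' <= 5, hydrogen-bond acceptors <= 10. Boundary values pass (inclusive
#' thresholds).
#'
#' @param record List or one-row data frame with fields `mw`, `logp`, `hbd`,
#'   `hba`.
#' @return List with logical `rules` (named) and integer `violations`.
#' @export
lipinski_profile <- function(record) {
  needed <- c("mw", "logp", "hbd", "hba")
  missing <- needed[!vapply(needed, function(f)
    !is.null(record[[f]]) && is.finite(record[[f]]), logical(1))]
  if (length(missing) > 0L)
    stop_dynappi(sprintf("missing propert%s: %s",
                         if (length(missing) > 1) "ies" else "y",
                         paste(missing, collapse = ", ")),
                 "dynappi_property_error")
  rules <- c(mw = record$mw <= 500, logp = record$logp <= 5,
             hbd = record$hbd <= 5, hba = record$hba <= 10)
  list(rules = rules, violations = sum(!rules))
}

#' Construct a compound x scoring-function score matrix
#'
#' @param scores Numeric matrix, rows = compounds (rownames = ids),
#'   columns = scoring functions (colnames).
#' @param higher_is_better Logical per column (default all `TRUE`). Cells
#'   may be `NA` as an explicit "failed to score" sentinel.
#' @return A `score_matrix` (numeric matrix with attributes).
#' @export
score_matrix <- function(scores, higher_is_better = TRUE) {
  scores <- as.matrix(scores)
  if ((nrow(scores) > 0L && is.null(rownames(scores))) || is.null(colnames(scores)))
    stop_dynappi("score matrix needs compound rownames and function colnames",
                 "dynappi_matrix_error")
  if (anyDuplicated(rownames(scores)))
    stop_dynappi("duplicate compound ids in score matrix", "dynappi_matrix_error")
  hib <- rep_len(as.logical(higher_is_better), ncol(scores))
  structure(scores, higher_is_better = hib, class = c("score_matrix", "matrix", "array"))
}

#' Consensus top compounds across scoring functions
#'
#' Intersection, over every scoring column, of the top
#' `ceiling(fraction * n)` compounds of that column (direction per the
#' matrix's `higher_is_better` flags; ties broken deterministically by id).
#'
#' @param matrix A [score_matrix()].
#' @param fraction Top fraction per column, in (0, 1].
#' @return Character vector of ids in every column's top set (sorted).
#' @export
consensus_top <- function(matrix, fraction = 0.25) {
  if (!(fraction > 0 && fraction <= 1))
    stop_dynappi("fraction must be in (0, 1]", "dynappi_consensus_error")
  ids <- rownames(matrix)
  n <- length(ids)
  if (n == 0L) return(character(0))
  hib <- attr(matrix, "higher_is_better") %||% rep(TRUE, ncol(matrix))
  k <- ceiling(fraction * n)
  tops <- lapply(seq_len(ncol(matrix)), function(j) {
    s <- matrix[, j]
    if (anyNA(s))
      stop_dynappi(sprintf("column '%s' has unscored compounds; resolve sentinels first",
                           colnames(matrix)[j]), "dynappi_consensus_error")
    key <- if (hib[j]) -s else s
    ids[order(key, ids)][seq_len(k)]
  })
  sort(Reduce(intersect, tops))
}

#' Pareto non-dominated sorting of a compound objective matrix
#'
#' Compound A dominates B when A is no worse in every objective and strictly
#' better in at least one (after aligning directions). Front 1 holds the
#' non-dominated compounds; front k the compounds non-dominated once fronts
#' < k are removed. Within a front, compounds are ordered by a normalized
#' rank-sum tie key (mean of per-objective ranks scaled to \[0, 1\]; lower
#' is better), then id.
#'
#' @param objectives Numeric matrix, rows = compounds (rownames = ids),
#'   columns = objectives; no missing cells.
#' @param directions Character vector per objective, `"max"` or `"min"`.
#' @return Data frame `id`, `front`, `tie_key`, ordered by front then
#'   tie_key then id.
#' @export
pareto_rank <- function(objectives, directions) {
  objectives <- as.matrix(objectives)
  if (ncol(objectives) < 1L)
    stop_dynappi("need at least one objective", "dynappi_pareto_error")
  if (length(directions) != ncol(objectives))
    stop_dynappi(sprintf("got %d directions for %d objectives",
                         length(directions), ncol(objectives)),
                 "dynappi_pareto_error")
  if (!all(directions %in% c("max", "min")))
    stop_dynappi("directions must be 'max' or 'min'", "dynappi_pareto_error")
  if (anyNA(objectives))
    stop_dynappi("objective matrix has missing cells", "dynappi_pareto_error")
  ids <- rownames(objectives) %||% as.character(seq_len(nrow(objectives)))
  n <- nrow(objectives)
  # align so larger is always better
  z <- objectives
  z[, directions == "min"] <- -z[, directions == "min", drop = FALSE]
  front <- integer(n)
  remaining <- seq_len(n)
  f <- 0L
  while (length(remaining) > 0L) {
    f <- f + 1L
    zi <- z[remaining, , drop = FALSE]
    nondom <- vapply(seq_along(remaining), function(i) {
      ge_all <- rowSums(zi >= matrix(zi[i, ], length(remaining), ncol(z),
                                     byrow = TRUE)) == ncol(z)
      gt_any <- rowSums(zi > matrix(zi[i, ], length(remaining), ncol(z),
                                    byrow = TRUE)) > 0
      !any(ge_all & gt_any)
    }, logical(1))
    front[remaining[nondom]] <- f
    remaining <- remaining[!nondom]
  }
  # tie key: normalized rank-sum (rank 1 = best per objective)
  rks <- apply(-z, 2, rank, ties.method = "average")
  rks <- matrix(rks, nrow = n)
  tie_key <- rowMeans((rks - 1) / max(1L, n - 1L))
  out <- data.frame(id = ids, front = front, tie_key = tie_key,
                    stringsAsFactors = FALSE)
  out <- out[order(out$front, out$tie_key, out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Truncate a Pareto ranking to the best n compounds
#'
#' Whole fronts are taken in order; the boundary front is broken by tie key
#' then id.
#'
#' @param ranking Data frame from [pareto_rank()].
#' @param n Number of compounds to keep.
#' @return The first `n` rows under the front/tie_key/id ordering.
#' @export
pareto_top <- function(ranking, n) {
  ranking[seq_len(min(n, nrow(ranking))), , drop = FALSE]
}

#' Filter compounds by predicted aqueous solubility
#'
#' @param records Data frame with columns `id` and `solubility` (mol/L).
#' @param min_molar Cutoff, mol/L; records at or above it are kept
#'   (default 1e-4 M, the concentration scale of NMR screening).
#' @return The surviving rows.
#' @export
solubility_filter <- function(records, min_molar = 1e-4) {
  if (!"solubility" %in% names(records))
    stop_dynappi("records lack a solubility column", "dynappi_property_error")
  bad <- records$id[!is.finite(records$solubility)]
  if (length(bad) > 0L)
    stop_dynappi(sprintf("missing solubility for: %s", paste(bad, collapse = ", ")),
                 "dynappi_property_error")
  records[records$solubility >= min_molar, , drop = FALSE]
}

#' Docking-pose consistency (mean pairwise RMSD)
#'
#' Docked poses share the receptor frame, so RMSD is computed directly,
#' without superposition: a tight pose bundle indicates a consistent
#' predicted binding mode.
#'
#' @param poses List of >= 2 atom-coordinate matrices (n_atoms x 3),
#'   identical atom ordering.
#' @return List with `mean_rmsd` (Angstrom) and the symmetric `matrix` of
#'   pairwise RMSDs.
#' @export
pose_consistency <- function(poses) {
  k <- length(poses)
  if (k < 2L)
    stop_dynappi("need at least 2 poses", "dynappi_pose_error")
  nat <- vapply(poses, nrow, integer(1))
  if (length(unique(nat)) != 1L)
    stop_dynappi("poses have mismatched atom counts", "dynappi_pose_error")
  m <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    m[i, j] <- m[j, i] <- rmsd_points(poses[[i]], poses[[j]])
  }
  list(mean_rmsd = mean(m[upper.tri(m)]), matrix = m)
}

#' Staged compound-selection funnel
#'
#' Runs the screening-to-shortlist funnel on already-computed tables:
#' consensus scoring across functions, Pareto ranking of the configured
#' objectives, truncation to the top n, property filters (solubility,
#' optional Lipinski), and an optional pose-consistency cut. Each stage's
#' entering/leaving compound counts are recorded in an audit log.
#'
#' @param config List with elements:
#'   \describe{
#'     \item{scores}{[score_matrix()] of docking scores (required).}
#'     \item{properties}{data frame `id`, `heavy_atoms`, `mw`, `logp`,
#'       `hbd`, `hba`, `solubility` (required for property stages).}
#'     \item{consensus_fraction}{top fraction per column (default 0.25).}
#'     \item{top_n}{Pareto truncation (default all).}
#'     \item{min_solubility}{mol/L cutoff (default 1e-4; `NULL` skips).}
#'     \item{lipinski_max_violations}{default `NULL` (skip stage).}
#'     \item{poses}{named list of pose sets (optional).}
#'     \item{max_mean_pose_rmsd}{Angstrom (required if `poses` given).}
#'   }
#' @return List with `shortlist` (data frame `id`, `front`, `tie_key`, plus
#'   mean score and ligand efficiency) and `audit` (data frame `stage`,
#'   `n_in`, `n_out`).
#' @export
run_selection <- function(config) {
  audit <- data.frame(stage = character(0), n_in = integer(0), n_out = integer(0))
  log_stage <- function(stage, n_in, n_out) {
    audit <<- rbind(audit, data.frame(stage = stage, n_in = n_in, n_out = n_out))
  }
  scores <- config$scores
  if (is.null(scores))
    stop_dynappi("missing stage input: scores", "dynappi_stage_error")
  ids <- rownames(scores)
  empty <- data.frame(id = character(0), front = integer(0), tie_key = numeric(0),
                      mean_score = numeric(0), ligand_efficiency = numeric(0))
  if (length(ids) == 0L) {
    for (s in c("consensus", "pareto", "solubility", "pose_consistency"))
      log_stage(s, 0L, 0L)
    return(list(shortlist = empty, audit = audit))
  }

  # 1. consensus across scoring functions
  frac <- config$consensus_fraction %||% 0.25
  keep <- consensus_top(scores, frac)
  log_stage("consensus", length(ids), length(keep))
  ids <- keep

  props <- config$properties
  need_props <- !is.null(config$min_solubility %||% 1e-4) ||
    !is.null(config$lipinski_max_violations)
  if (is.null(props) && need_props)
    stop_dynappi("missing stage input: properties", "dynappi_stage_error")

  # 2. Pareto ranking on mean score, ligand efficiency and properties
  if (length(ids) > 0L) {
    ms <- rowMeans(scores[ids, , drop = FALSE])
    pr <- props[match(ids, props$id), , drop = FALSE]
    if (anyNA(pr$id))
      stop_dynappi("missing stage input: properties for screened compounds",
                   "dynappi_stage_error")
    le <- ms / pr$heavy_atoms
    obj <- cbind(mean_score = ms, ligand_efficiency = le, mw = pr$mw,
                 logp = pr$logp, hbd = pr$hbd, hba = pr$hba,
                 solubility = pr$solubility)
    rownames(obj) <- ids
    dirs <- c("max", "max", "min", "min", "min", "min", "max")
    ranking <- pareto_rank(obj, dirs)
    top_n <- config$top_n %||% length(ids)
    shortlist <- pareto_top(ranking, top_n)
    log_stage("pareto", length(ids), nrow(shortlist))
    ids <- shortlist$id
  } else {
    log_stage("pareto", 0L, 0L)
    shortlist <- empty
  }

  # 3. solubility filter
  min_sol <- config$min_solubility %||% 1e-4
  if (!is.null(min_sol) && length(ids) > 0L) {
    surv <- solubility_filter(props[match(ids, props$id), , drop = FALSE], min_sol)
    log_stage("solubility", length(ids), nrow(surv))
    ids <- surv$id
  } else log_stage("solubility", length(ids), length(ids))

  # 4. optional Lipinski stage
  if (!is.null(config$lipinski_max_violations) && length(ids) > 0L) {
    ok <- vapply(ids, function(i) {
      rec <- as.list(props[match(i, props$id), , drop = FALSE])
      lipinski_profile(rec)$violations <= config$lipinski_max_violations
    }, logical(1))
    log_stage("lipinski", length(ids), sum(ok))
    ids <- ids[ok]
  }

  # 5. optional pose-consistency stage
  if (!is.null(config$poses) && length(ids) > 0L) {
    cut <- config$max_mean_pose_rmsd
    if (is.null(cut))
      stop_dynappi("missing stage input: max_mean_pose_rmsd for pose stage",
                   "dynappi_stage_error")
    ok <- vapply(ids, function(i) {
      ps <- config$poses[[i]]
      is.null(ps) || pose_consistency(ps)$mean_rmsd <= cut
    }, logical(1))
    log_stage("pose_consistency", length(ids), sum(ok))
    ids <- ids[ok]
  } else log_stage("pose_consistency", length(ids), length(ids))

  shortlist <- shortlist[shortlist$id %in% ids, , drop = FALSE]
  if (nrow(shortlist) > 0L) {
    shortlist$mean_score <- rowMeans(scores[shortlist$id, , drop = FALSE])
    shortlist$ligand_efficiency <- shortlist$mean_score /
      props$heavy_atoms[match(shortlist$id, props$id)]
  } else shortlist <- empty
  rownames(shortlist) <- NULL
  list(shortlist = shortlist, audit = audit)
}
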