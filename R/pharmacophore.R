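# Pharmacophore models and conformer matching.
#
# A pharmacophore model is an ordered set of typed interaction points
# (hydrogen-bond acceptor / donor, hydrophobic centroid) extracted from a
# protein-peptide complex. Conformers are screened by enumerating
# kind-compatible injections of a feature-subset query into the conformer's
# ligand-side feature points and minimising the superposition RMSD.

FEATURE_KINDS <- c("acceptor", "donor", "hydrophobic")

#' Construct a pharmacophore feature table
#'
#' Features are held as a data frame with one row per typed interaction
#' point: `kind` (acceptor/donor/hydrophobic), Cartesian `x`, `y`, `z`
#' centres in Angstrom, a spherical match tolerance `radius`, an optional
#' unit `direction` vector (`dx`, `dy`, `dz`, `NA` when undirected) and a
#' provenance `label` (e.g. `"Ser5477:OG"`).
#'
#' @param kind Character vector over `acceptor`, `donor`, `hydrophobic`.
#' @param center Numeric matrix (n x 3) of feature centres, Angstrom.
#' @param radius Positive match tolerance per feature, Angstrom (default 1).
#' @param direction Optional n x 3 matrix of unit interaction directions;
#'   rows of all-`NA` mean "undirected".
#' @param label Unique provenance labels.
#' @return A validated `data.frame` of features.
#' @export
pharm_features <- function(kind, center, radius = 1, label,
                           direction = NULL) {
  center <- matrix(as.numeric(center), ncol = 3)
  n <- nrow(center)
  kind <- as.character(kind)
  radius <- rep_len(as.numeric(radius), n)
  if (is.null(direction)) direction <- matrix(NA_real_, n, 3)
  direction <- matrix(as.numeric(direction), ncol = 3)
  df <- data.frame(kind = kind, x = center[, 1], y = center[, 2],
                   z = center[, 3], radius = radius,
                   dx = direction[, 1], dy = direction[, 2],
                   dz = direction[, 3],
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  validate_features(df)
  df
}

validate_features <- function(df) {
  if (!all(df$kind %in% FEATURE_KINDS))
    stop_dynappi(sprintf("unknown feature kind(s): %s",
                         paste(setdiff(df$kind, FEATURE_KINDS), collapse = ", ")),
                 "dynappi_feature_error")
  if (any(!is.finite(df$radius)) || any(df$radius <= 0))
    stop_dynappi("feature radius must be > 0", "dynappi_feature_error")
  has_dir <- !is.na(df$dx)
  if (any(has_dir)) {
    nrm <- sqrt(df$dx[has_dir]^2 + df$dy[has_dir]^2 + df$dz[has_dir]^2)
    if (any(abs(nrm - 1) > 1e-6))
      stop_dynappi("feature direction vectors must be unit length", "dynappi_feature_error")
  }
  invisible(df)
}

#' Construct a pharmacophore model
#'
#' @param features A feature data frame as returned by [pharm_features()].
#' @param name Model name.
#' @param source Free-form provenance (structure id, chain, residues).
#' @return An object of class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(features, name = "model", source = "") {
  validate_features(features)
  if (nrow(features) < 1L)
    stop_dynappi("a pharmacophore model needs at least one feature", "dynappi_feature_error")
  if (anyDuplicated(features$label))
    stop_dynappi("feature labels must be unique", "dynappi_feature_error")
  structure(list(features = features, name = name, source = source),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat(sprintf("Pharmacophore model '%s' (%d features; source: %s)\n",
              x$name, nrow(x$features), x$source))
  tab <- table(factor(x$features$kind, levels = FEATURE_KINDS))
  cat("  kinds:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' The shipped SxIP pharmacophore preset
#'
#' Eight interaction points read off the SxIP peptide of an EB1-peptide
#' complex: two hydrogen-bond acceptors in the Ser5477 hydroxyl region
#' (which forms a water-mediated hydrogen-bond network with Arg222, Glu225,
#' Gln229 and Tyr247), three hydrophobic centroids over the Ile5479 side
#' chain and the Pro5480 ring (buried in the hydrophobic cavity), plus the
#' Ile5479 backbone amine as an acceptor and the Ile5479/Pro5480 carbonyl
#' oxygens as donors.
#'
#' The amine-as-acceptor / carbonyl-as-donor assignment follows the source
#' protocol as written; set `chemically_corrected = TRUE` to swap them to
#' the conventional donor/acceptor roles (the amide N-H donates, carbonyl
#' oxygens accept).
#'
#' @param radius Match tolerance applied to every feature, Angstrom.
#' @param chemically_corrected Swap the backbone amine/carbonyl roles.
#' @return A preset data frame consumed by [build_sxip_model()], columns
#'   `label`, `resno`, `atoms` (space-separated PDB atom names), `kind`,
#'   `radius`.
#' @export
sxip_preset <- function(radius = 1, chemically_corrected = FALSE) {
  p <- data.frame(
    label = c("Ser5477:OG:acc1", "Ser5477:OG:acc2", "Ile5479:N",
              "Ile5479:O", "Pro5480:O", "Ile5479:sc:hyd1",
              "Ile5479:sc:hyd2", "Pro5480:ring:hyd"),
    resno = c(5477, 5477, 5479, 5479, 5480, 5479, 5479, 5480),
    atoms = c("OG", "OG CB", "N", "O", "O",
              "CB CG1 CD1", "CG2", "CB CG CD"),
    kind = c("acceptor", "acceptor", "acceptor", "donor", "donor",
             "hydrophobic", "hydrophobic", "hydrophobic"),
    radius = radius,
    stringsAsFactors = FALSE
  )
  if (chemically_corrected) {
    p$kind[p$label == "Ile5479:N"] <- "donor"
    p$kind[p$label %in% c("Ile5479:O", "Pro5480:O")] <- "acceptor"
  }
  p
}

#' Build a pharmacophore model from a structure and a feature preset
#'
#' Each preset row names a residue, a set of atoms and a feature kind; the
#' feature centre is the centroid of the named atoms in the supplied
#' coordinates (first model of a multi-model file). Residue numbering is
#' taken as-is from the structure.
#'
#' @param structure Path to a PDB file, or a `bio3d` `pdb` object.
#' @param preset Preset table (see [sxip_preset()]).
#' @param name Model name.
#' @return A [pharmacophore_model()].
#' @export
build_sxip_model <- function(structure, preset = sxip_preset(),
                             name = "sxip") {
  if (is.character(structure))
    structure <- bio3d::read.pdb(structure, multi = FALSE, verbose = FALSE)
  atom <- structure$atom
  if (is.null(preset) || nrow(preset) == 0L)
    stop_dynappi("empty preset", "dynappi_preset_error")
  centers <- matrix(NA_real_, nrow(preset), 3)
  for (i in seq_len(nrow(preset))) {
    wanted <- strsplit(preset$atoms[i], "\\s+")[[1]]
    sel <- atom[atom$resno == preset$resno[i] & atom$elety %in% wanted, , drop = FALSE]
    missing <- setdiff(wanted, sel$elety)
    if (length(missing) > 0L)
      stop_dynappi(sprintf("atom(s) %s of residue %d not found in structure",
                           paste(missing, collapse = ","), preset$resno[i]),
                   "dynappi_missing_atom_error")
    centers[i, ] <- colMeans(as.matrix(sel[, c("x", "y", "z")]))
  }
  feats <- pharm_features(kind = preset$kind, center = centers,
                          radius = preset$radius, label = preset$label)
  pharmacophore_model(feats, name = name,
                      source = sprintf("residues %s",
                                       paste(unique(preset$resno), collapse = ",")))
}

#' Enumerate feature-subset queries of a pharmacophore model
#'
#' All index subsets of the model's features at each requested size, in
#' lexicographic order. Requesting a size larger than the model contributes
#' zero queries; sizes below 3 are rejected (a 3-D superposition needs at
#' least three points). An optional `constraint` predicate (taking the
#' integer index vector) filters the enumeration.
#'
#' @param model A [pharmacophore_model()].
#' @param sizes Integer vector of subset sizes, each >= 3.
#' @param constraint Optional `function(indices) -> logical` filter.
#' @return List of `subset_query` objects (fields `indices`, `size`,
#'   `features`).
#' @export
enumerate_subsets <- function(model, sizes, constraint = NULL) {
  stopifnot(inherits(model, "pharmacophore_model"))
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 3L))
    stop_dynappi("subset sizes below 3 are not meaningful for 3-D matching",
                 "dynappi_subset_error")
  n <- nrow(model$features)
  out <- list()
  for (s in sizes) {
    if (s > n) next
    idx <- combn(n, s)
    for (j in seq_len(ncol(idx))) {
      ind <- idx[, j]
      if (!is.null(constraint) && !isTRUE(constraint(ind))) next
      out[[length(out) + 1L]] <- structure(
        list(indices = ind, size = s,
             features = model$features[ind, , drop = FALSE]),
        class = "subset_query")
    }
  }
  out
}

#' Ligand-side conformer feature points
#'
#' @param molecule_id,conformer_id Non-empty identifiers.
#' @param points Feature data frame ([pharm_features()]); may have zero rows
#'   (an unmatchable conformer).
#' @return Object of class `conformer_features`.
#' @export
conformer_features <- function(molecule_id, conformer_id, points) {
  if (!nzchar(molecule_id) || !nzchar(conformer_id))
    stop_dynappi("molecule and conformer ids must be non-empty", "dynappi_feature_error")
  if (nrow(points) > 0L) validate_features(points)
  structure(list(molecule_id = molecule_id, conformer_id = conformer_id,
                 points = points),
            class = "conformer_features")
}

#' Default ligand feature-typing rules
#'
#' Deterministic element/connectivity rules standing in for the feature
#' perception of pharmacophore search engines: nitrogen and oxygen atoms are
#' hydrogen-bond acceptors; N or O carrying at least one explicit hydrogen
#' are donors (centred on the heavy atom); bonded clusters of carbon atoms
#' form hydrophobic centroids placed at the mean of the cluster's heavy
#' atoms.
#'
#' @return Rule list with entries `acceptor_elements`, `donor_elements`
#'   (heavy atoms that donate when protonated) and `hydrophobic_elements`.
#' @export
default_feature_rules <- function() {
  list(acceptor_elements = c("N", "O"),
       donor_elements = c("N", "O"),
       hydrophobic_elements = c("C"))
}

validate_feature_rules <- function(rules) {
  needed <- c("acceptor_elements", "donor_elements", "hydrophobic_elements")
  if (!all(needed %in% names(rules)))
    stop_dynappi(sprintf("feature rules missing entries: %s",
                         paste(setdiff(needed, names(rules)), collapse = ", ")),
                 "dynappi_rules_error")
  ok <- grepl("^[A-Z][a-z]?$", unlist(rules))
  if (!all(ok))
    stop_dynappi(sprintf("unparsable element pattern(s): %s",
                         paste(unlist(rules)[!ok], collapse = ", ")),
                 "dynappi_rules_error")
  invisible(rules)
}

#' Assign pharmacophore feature points to a 3-D conformer
#'
#' @param mol A molecule as returned by [read_sdf()]: list with `id`,
#'   `atoms` (data frame `elem`, `x`, `y`, `z`) and `bonds` (data frame
#'   `a1`, `a2`).
#' @param rules Rule list, see [default_feature_rules()].
#' @param conformer_id Conformer identifier (defaults to the molecule id).
#' @return A [conformer_features()] object.
#' @export
assign_ligand_features <- function(mol, rules = default_feature_rules(),
                                   conformer_id = NULL) {
  validate_feature_rules(rules)
  atoms <- mol$atoms
  if (is.null(atoms) || !all(c("x", "y", "z") %in% names(atoms)) ||
      any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_dynappi("molecule has no usable 3-D coordinates", "dynappi_coords_error")
  bonds <- mol$bonds
  n <- nrow(atoms)
  heavy <- which(atoms$elem != "H")
  # explicit-H adjacency for donor perception
  h_count <- integer(n)
  adj <- vector("list", n)
  if (!is.null(bonds) && nrow(bonds) > 0L) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds$a1[k]; b <- bonds$a2[k]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      if (atoms$elem[b] == "H") h_count[a] <- h_count[a] + 1L
      if (atoms$elem[a] == "H") h_count[b] <- h_count[b] + 1L
    }
  }
  kinds <- character(0); centers <- NULL; labels <- character(0)
  add <- function(kind, ctr, lab) {
    kinds <<- c(kinds, kind)
    centers <<- rbind(centers, ctr)
    labels <<- c(labels, lab)
  }
  for (i in heavy) {
    e <- atoms$elem[i]
    xyz <- as.numeric(atoms[i, c("x", "y", "z")])
    if (e %in% rules$acceptor_elements)
      add("acceptor", xyz, sprintf("atom%d:%s:acc", i, e))
    if (e %in% rules$donor_elements && h_count[i] > 0L)
      add("donor", xyz, sprintf("atom%d:%s:don", i, e))
  }
  # hydrophobic: connected components of the carbon subgraph
  carbons <- which(atoms$elem %in% rules$hydrophobic_elements)
  if (length(carbons) > 0L) {
    comp <- setNames(rep(NA_integer_, length(carbons)), carbons)
    cid <- 0L
    for (c0 in carbons) {
      if (!is.na(comp[as.character(c0)])) next
      cid <- cid + 1L
      stack <- c0
      while (length(stack) > 0L) {
        a <- stack[[1L]]; stack <- stack[-1L]
        if (!is.na(comp[as.character(a)])) next
        comp[as.character(a)] <- cid
        nb <- intersect(adj[[a]], carbons)
        stack <- c(stack, nb[is.na(comp[as.character(nb)])])
      }
    }
    for (g in seq_len(cid)) {
      members <- as.integer(names(comp)[comp == g])
      ctr <- colMeans(as.matrix(atoms[members, c("x", "y", "z"), drop = FALSE]))
      add("hydrophobic", as.numeric(ctr), sprintf("Cgroup%d:hyd", g))
    }
  }
  pts <- if (length(kinds) == 0L) {
    pharm_features(character(0), matrix(numeric(0), 0, 3), label = character(0))
  } else {
    pharm_features(kinds, centers, radius = 1, label = labels)
  }
  conformer_features(mol$id, conformer_id %||% mol$id, pts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: exact branch-and-bound over kind-compatible injections.
# Uses the inter-point distance-mismatch lower bound on the superposition
# RMSD: for any rigid motion, sum_{i<j} (d^P_ij - d^Q_ij)^2 <=
# 2 (n-1) n rmsd^2, so a partial assignment whose accumulated mismatch
# already exceeds the bound at the current threshold cannot beat it and the
# whole branch is skipped. Exactness is unaffected: only provably worse
# correspondences are pruned.
best_injection <- function(qxyz, qkinds, pxyz, pkinds, rmsd_max) {
  s <- nrow(qxyz)
  cand <- lapply(qkinds, function(k) which(pkinds == k))
  if (any(lengths(cand) == 0L)) return(NULL)
  qd <- as.matrix(stats::dist(qxyz))
  pd <- as.matrix(stats::dist(pxyz))
  denom <- 2 * s * (s - 1)
  best_rmsd <- Inf
  best <- NULL
  used <- logical(nrow(pxyz))
  assignment <- integer(s)
  rec <- function(i, psum) {
    if (best_rmsd == 0) return(invisible(NULL))
    for (p in cand[[i]]) {
      if (used[p]) next
      ds <- psum
      if (i > 1L) {
        prev <- assignment[seq_len(i - 1L)]
        dd <- pd[p, prev] - qd[i, seq_len(i - 1L)]
        ds <- ds + sum(dd * dd)
        if (s > 1L && ds / denom > min(best_rmsd, rmsd_max)^2 + 1e-9) next
      }
      assignment[i] <<- p
      if (i == s) {
        fit <- superpose_points(pxyz[assignment, , drop = FALSE], qxyz)
        if (fit$rmsd < best_rmsd) {
          best_rmsd <<- fit$rmsd
          best <<- list(assignment = assignment, fit = fit)
        }
      } else {
        used[p] <<- TRUE
        rec(i + 1L, ds)
        used[p] <<- FALSE
      }
    }
    invisible(NULL)
  }
  rec(1L, 0)
  best
}

#' Match a conformer against a feature-subset query
#'
#' Searches exhaustively over every kind-compatible injection of the query
#' features into the conformer's feature points; each candidate
#' correspondence is scored by the RMSD after optimal least-squares rigid
#' superposition of the matched conformer points onto the query points
#' ([superpose_points()]). The minimising correspondence is returned, or
#' `NULL` when no injection exists or the minimum RMSD exceeds `rmsd_max`.
#'
#' @param query A `subset_query` from [enumerate_subsets()].
#' @param conf A [conformer_features()] object.
#' @param rmsd_max Acceptance threshold, Angstrom (default 0.5).
#' @param max_query_size Cap on the exhaustive correspondence search
#'   (default 12); larger queries raise an error.
#' @return A `pharm_match` object (`molecule_id`, `conformer_id`,
#'   `query_indices`, `correspondence`, `rmsd`, `rotation`, `translation`)
#'   or `NULL`.
#' @export
match_conformer <- function(query, conf, rmsd_max = 0.5,
                            max_query_size = 12L) {
  stopifnot(inherits(query, "subset_query"), inherits(conf, "conformer_features"))
  if (rmsd_max <= 0)
    stop_dynappi("rmsd_max must be positive", "dynappi_match_error")
  if (query$size > max_query_size)
    stop_dynappi(sprintf(paste0("query size %d exceeds the exhaustive-search cap %d; ",
                                "lower the subset size or raise max_query_size"),
                         query$size, max_query_size),
                 "dynappi_match_error")
  qf <- query$features
  pts <- conf$points
  if (nrow(pts) == 0L) return(NULL)
  qxyz <- as.matrix(qf[, c("x", "y", "z")])
  pxyz <- as.matrix(pts[, c("x", "y", "z")])
  best <- best_injection(qxyz, qf$kind, pxyz, pts$kind, rmsd_max)
  if (is.null(best) || best$fit$rmsd > rmsd_max) return(NULL)
  best_rmsd <- best$fit$rmsd
  structure(list(molecule_id = conf$molecule_id,
                 conformer_id = conf$conformer_id,
                 query_indices = query$indices,
                 correspondence = best$assignment,
                 rmsd = best_rmsd,
                 rotation = best$fit$rotation,
                 translation = best$fit$translation),
            class = "pharm_match")
}

#' @export
print.pharm_match <- function(x, ...) {
  cat(sprintf("pharm_match: %s/%s query{%s} rmsd %.4f A\n",
              x$molecule_id, x$conformer_id,
              paste(x$query_indices, collapse = ","), x$rmsd))
  invisible(x)
}

#' Screen a conformer library against a pharmacophore model
#'
#' Every conformer is matched against all feature-subset queries of the
#' requested sizes; the best (lowest-RMSD) accepted match per conformer is
#' kept, then the table is deduplicated to one row per molecule, keeping the
#' lowest-RMSD conformer (multi-conformer libraries report each unique
#' compound once). Ties between queries are broken toward the larger query,
#' then lexicographic indices.
#'
#' @param library List of [conformer_features()] objects.
#' @param model A [pharmacophore_model()].
#' @param sizes Subset sizes to enumerate (default `c(5, 6, 7)`).
#' @param rmsd_max Acceptance threshold, Angstrom (default 0.5).
#' @param constraint Optional subset constraint, see [enumerate_subsets()].
#' @return Data frame with columns `molecule_id`, `conformer_id`,
#'   `query_size`, `query_indices`, `rmsd_A`, sorted by RMSD ascending (ties
#'   by molecule id); zero rows when nothing matches.
#' @export
screen_library <- function(library, model, sizes = c(5, 6, 7),
                           rmsd_max = 0.5, constraint = NULL) {
  queries <- enumerate_subsets(model, sizes, constraint = constraint)
  empty <- data.frame(molecule_id = character(0), conformer_id = character(0),
                      query_size = integer(0), query_indices = character(0),
                      rmsd_A = numeric(0), stringsAsFactors = FALSE)
  if (length(library) == 0L || length(queries) == 0L) return(empty)
  rows <- list()
  for (conf in library) {
    best <- NULL
    for (q in queries) {
      m <- match_conformer(q, conf, rmsd_max = rmsd_max)
      if (is.null(m)) next
      if (is.null(best) || m$rmsd < best$rmsd - 1e-12 ||
          (abs(m$rmsd - best$rmsd) <= 1e-12 &&
           length(m$query_indices) > length(best$query_indices))) {
        best <- m
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = best$molecule_id, conformer_id = best$conformer_id,
        query_size = length(best$query_indices),
        query_indices = paste(best$query_indices, collapse = ","),
        rmsd_A = best$rmsd, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  hits <- do.call(rbind, rows)
  # dedup: one row per molecule, lowest rmsd wins
  hits <- hits[order(hits$rmsd_A, hits$molecule_id, hits$conformer_id), , drop = FALSE]
  hits <- hits[!duplicated(hits$molecule_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
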