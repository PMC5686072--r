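# Seeded synthetic-data generators with machine-readable ground truth:
# planted conformer libraries, fast-exchange titration curves, toy gate
# ensembles and score matrices with a planted affinity order. One global
# seed expands into independent per-generator child seeds.

#' Derive a deterministic child seed from a global seed and a stream name
#'
#' Stage generators draw their own child seed so that stages are
#' independently reproducible under a single global seed. The stream name
#' is folded into the seed with a fixed polynomial character hash; results
#' stay within the 32-bit signed integer range.
#'
#' @param seed Global integer seed.
#' @param stream Stream name, e.g. `"library"`, `"titration"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Plant a conformer library with known hits and decoys
#'
#' Hits are copies of the model's feature points under a random rigid
#' motion plus isotropic Gaussian coordinate jitter (the screening stage
#' must undo the motion and recover them). Decoys alternate between two
#' constructions: *kind-scrambled* point sets (all points forced to one
#' kind, so no query mixing kinds admits any injection) and
#' *geometry-randomised* sets (the model's kind multiset with uniform
#' random coordinates, which should fail the RMSD filter).
#'
#' @param model A [pharmacophore_model()].
#' @param n_hits,n_decoys Non-negative counts.
#' @param jitter_sigma Coordinate jitter s.d., Angstrom.
#' @param seed Integer seed.
#' @param box Half-width of the decoy coordinate box, Angstrom.
#' @return List with `library` (list of [conformer_features()]) and `truth`
#'   (data frame `molecule_id`, `is_hit`, `type`).
#' @export
plant_conformer_library <- function(model, n_hits, n_decoys,
                                    jitter_sigma = 0.05, seed = 1,
                                    box = 8) {
  if (n_hits < 0 || n_decoys < 0)
    stop_dynappi("counts must be non-negative", "dynappi_generator_error")
  stopifnot(inherits(model, "pharmacophore_model"))
  set.seed(child_seed(seed, "library"))
  feats <- model$features
  xyz <- as.matrix(feats[, c("x", "y", "z")])
  lib <- list(); truth <- list()
  for (i in seq_len(n_hits)) {
    rot <- random_rotation()
    tr <- runif(3, -10, 10)
    pts <- sweep(xyz %*% rot, 2, tr, `+`) +
      matrix(rnorm(length(xyz), sd = jitter_sigma), ncol = 3)
    id <- sprintf("hit%03d", i)
    lib[[length(lib) + 1L]] <- conformer_features(
      id, paste0(id, "_c1"),
      pharm_features(feats$kind, pts, radius = feats$radius,
                     label = paste0("p", seq_len(nrow(pts)))))
    truth[[length(truth) + 1L]] <- data.frame(
      molecule_id = id, is_hit = TRUE, type = "planted")
  }
  kinds_cycle <- FEATURE_KINDS
  for (i in seq_len(n_decoys)) {
    id <- sprintf("decoy%03d", i)
    if (i %% 2L == 1L) {
      # kind-scrambled: single-kind point set, injections impossible for
      # any query that mixes kinds
      k <- kinds_cycle[(i %% length(kinds_cycle)) + 1L]
      pts <- matrix(runif(nrow(xyz) * 3, -box, box), ncol = 3)
      kinds <- rep(k, nrow(xyz))
      type <- "kind_scrambled"
    } else {
      pts <- matrix(runif(nrow(xyz) * 3, -box, box), ncol = 3)
      kinds <- feats$kind
      type <- "geometry_random"
    }
    lib[[length(lib) + 1L]] <- conformer_features(
      id, paste0(id, "_c1"),
      pharm_features(kinds, pts, radius = 1,
                     label = paste0("p", seq_len(nrow(pts)))))
    truth[[length(truth) + 1L]] <- data.frame(
      molecule_id = id, is_hit = FALSE, type = type)
  }
  list(library = lib, truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Simulate a fast-exchange titration series
#'
#' Forward model: `csp_r(L) = dmax_r * fraction_bound(pt, L, kd)` plus
#' Gaussian noise of s.d. `noise_fraction * dmax_r` at every point with
#' ligand present. The free-protein point (L = 0) is exactly zero — it is
#' the reference spectrum against which perturbations are measured.
#'
#' @param kd Dissociation constant, mM.
#' @param dmax Named (or unnamed) vector of per-residue saturation CSPs, ppm.
#' @param pt Total protein concentration, mM (default 0.05).
#' @param lt_grid Ascending ligand schedule from 0, mM (default 12 points,
#'   0 to 40 mM).
#' @param noise_fraction Noise s.d. as a fraction of each residue's `dmax`
#'   (default 0.02).
#' @param seed Integer seed.
#' @return A [titration_series()] with attribute `truth` (list `kd`,
#'   `dmax`).
#' @export
simulate_titration <- function(kd, dmax, pt = 0.05,
                               lt_grid = seq(0, 40, length.out = 12),
                               noise_fraction = 0.02, seed = 1) {
  if (is.unsorted(lt_grid) || lt_grid[1] != 0)
    stop_dynappi("lt_grid must ascend from 0", "dynappi_generator_error")
  if (kd <= 0 || pt <= 0)
    stop_dynappi("kd and pt must be positive", "dynappi_generator_error")
  set.seed(child_seed(seed, "titration"))
  if (is.null(names(dmax))) names(dmax) <- paste0("res", seq_along(dmax))
  fb <- fraction_bound(pt, lt_grid, kd)
  csp <- outer(dmax, fb)
  noisy <- lt_grid > 0
  for (r in seq_along(dmax)) {
    csp[r, noisy] <- csp[r, noisy] +
      rnorm(sum(noisy), sd = noise_fraction * abs(dmax[r]))
  }
  csp[, 1] <- 0
  s <- titration_series(pt, lt_grid, csp)
  attr(s, "truth") <- list(kd = kd, dmax = dmax,
                           noise_fraction = noise_fraction)
  s
}

#' Generate a toy gate ensemble with known open/closed fractions
#'
#' Builds a rigid scaffold (two short helix-like Ca strands, identical in
#' every model) plus a gate pseudo-side-chain atom (Tyr247 Cz analogue)
#' whose distances to the two anchor atoms (Leu221 Ca and Leu246 Ca
#' analogues) fall in the closed or open region per model. Each model is
#' closed with probability `closed_fraction` (independent Bernoulli
#' draws).
#'
#' @param n_models Number of models (> 0).
#' @param closed_fraction Probability of the closed state in `[0, 1]`.
#' @param gate_geometry List: `closed_mean`, `open_mean` (target gate
#'   distances, Angstrom), `sd` (distance spread), `anchor_sep` (distance
#'   between the two anchors).
#' @param seed Integer seed.
#' @return A [coord_ensemble()] with attribute `truth` (data frame `model`,
#'   `state`, `d_gate1`, `d_gate2`).
#' @export
make_toy_ensemble <- function(n_models, closed_fraction = 0.3,
                              gate_geometry = list(closed_mean = 6.5,
                                                   open_mean = 12,
                                                   sd = 0.4,
                                                   anchor_sep = 10),
                              seed = 1) {
  if (n_models < 1L)
    stop_dynappi("n_models must be positive", "dynappi_generator_error")
  if (closed_fraction < 0 || closed_fraction > 1)
    stop_dynappi("closed_fraction must be in [0, 1]", "dynappi_generator_error")
  set.seed(child_seed(seed, "ensemble"))
  g <- gate_geometry
  sep <- g$anchor_sep
  # scaffold: two 6-residue Ca strands flanking the gate region
  scaffold_res <- c(215:220, 240:245)
  scaffold <- cbind(c(seq(-9, 6, length.out = 6), seq(-9, 6, length.out = 6)),
                    rep(c(-3, -6), each = 6),
                    rep(c(0, 2), each = 6))
  atoms <- data.frame(
    elety = c(rep("CA", 12), "CA", "CA", "CZ"),
    resno = c(scaffold_res, 221, 246, 247),
    resid = c(rep("ALA", 12), "LEU", "LEU", "TYR"),
    chain = "A", stringsAsFactors = FALSE)
  anchor1 <- c(0, 0, 0)          # Leu221 Ca analogue
  anchor2 <- c(sep, 0, 0)        # Leu246 Ca analogue
  closed <- runif(n_models) < closed_fraction
  xyz <- matrix(NA_real_, n_models, 3 * nrow(atoms))
  truth <- data.frame(model = seq_len(n_models),
                      state = ifelse(closed, "closed", "open"),
                      d_gate1 = NA_real_, d_gate2 = NA_real_)
  for (m in seq_len(n_models)) {
    mu <- if (closed[m]) g$closed_mean else g$open_mean
    repeat {
      d1 <- rnorm(1, mu, g$sd); d2 <- rnorm(1, mu, g$sd)
      # gate position must satisfy the triangle with the anchors
      x <- (d1^2 - d2^2 + sep^2) / (2 * sep)
      y2 <- d1^2 - x^2
      if (d1 > 0 && d2 > 0 && y2 > 0.01) break
    }
    gate <- c(x, sqrt(y2), 0)
    co <- rbind(scaffold, anchor1, anchor2, gate)
    xyz[m, ] <- as.numeric(t(co))
    truth$d_gate1[m] <- d1; truth$d_gate2[m] <- d2
  }
  ens <- coord_ensemble(atoms, xyz)
  attr(ens, "truth") <- truth
  ens
}

#' Generate a score matrix with a planted affinity order
#'
#' Base scores decrease strictly along the supplied true order; independent
#' Gaussian noise is added per receptor conformation.
#'
#' @param true_order Character ids, best first (>= 2, unique).
#' @param n_conformations Number of receptor-conformation columns.
#' @param noise_sd Per-cell noise s.d. (score units).
#' @param seed Integer seed.
#' @param base_top,base_step Base score of the best compound and the
#'   decrement between consecutive compounds.
#' @return A [score_matrix()] with attribute `truth` (the true order).
#' @export
make_score_matrix <- function(true_order, n_conformations = 20,
                              noise_sd = 2, seed = 1,
                              base_top = 70, base_step = 6) {
  if (anyDuplicated(true_order))
    stop_dynappi("duplicate ids in true_order", "dynappi_generator_error")
  if (length(true_order) < 2L)
    stop_dynappi("need at least 2 ids", "dynappi_generator_error")
  set.seed(child_seed(seed, "scores"))
  base <- base_top - base_step * (seq_along(true_order) - 1L)
  m <- matrix(rep(base, n_conformations), ncol = n_conformations) +
    matrix(rnorm(length(true_order) * n_conformations, sd = noise_sd),
           ncol = n_conformations)
  dimnames(m) <- list(true_order, paste0("conf", seq_len(n_conformations)))
  sm <- score_matrix(m, higher_is_better = TRUE)
  attr(sm, "truth") <- true_order
  sm
}
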