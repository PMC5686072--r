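test_that("ensemble score aggregation matches brute-force row statistics", {
  const <- matrix(5, 3, 4, dimnames = list(c("a", "b", "c"), paste0("r", 1:4)))
  agg <- aggregate_ensemble_scores(const)
  expect_true(all(agg$mean == 5) && all(agg$sd == 0))

  set.seed(10)
  m <- matrix(rnorm(80, 50, 8), 4, 20,
              dimnames = list(paste0("cpd", 1:4), paste0("conf", 1:20)))
  agg <- aggregate_ensemble_scores(m)
  for (id in rownames(m)) {
    row <- m[id, ]
    i <- which(agg$id == id)
    expect_equal(agg$mean[i], sum(row) / length(row), tolerance = 1e-9)
    expect_equal(agg$sd[i], sqrt(sum((row - mean(row))^2) / (length(row) - 1)),
                 tolerance = 1e-9)
    expect_equal(agg$min[i], min(row))
    expect_equal(agg$max[i], max(row))
  }
  expect_true(all(diff(agg$mean) <= 0))  # ranked by mean, descending

  # NA sentinel cells are excluded and counted, never imputed
  m[2, 5] <- NA
  agg2 <- aggregate_ensemble_scores(m)
  i <- which(agg2$id == "cpd2")
  expect_equal(agg2$n_failed[i], 1L)
  expect_equal(agg2$mean[i], mean(m[2, ], na.rm = TRUE))
  expect_error(aggregate_ensemble_scores(matrix(numeric(0), 0, 0)), "empty")
})

test_that("ensemble-average ranking reproduces the printed score order", {
  # printed ensemble-average scores as a single-column input table
  printed <- matrix(c(64, 53, 48, 46), 4, 1,
                    dimnames = list(c("1d", "1a", "1c", "1b"), "ensemble_avg"))
  agg <- aggregate_ensemble_scores(printed)
  expect_equal(agg$id, c("1d", "1a", "1c", "1b"))
  ra <- rank_agreement(setNames(printed[, 1], rownames(printed)),
                       c("1d", "1a", "1c", "1b"))
  expect_equal(ra$tau, 1)
})

test_that("rank agreement equals explicit pair counting with ties", {
  x <- setNames(c(3, 2, 1), c("a", "b", "c"))
  expect_equal(rank_agreement(x, c("a", "b", "c"))$tau, 1)
  expect_equal(rank_agreement(x, c("c", "b", "a"))$tau, -1)
  set.seed(11)
  ids <- paste0("m", 1:8)
  for (rep in 1:10) {
    sc <- setNames(sample(1:6, 8, TRUE), ids)  # ties likely
    ref <- sample(ids)
    ra <- rank_agreement(sc, ref)
    ref_score <- setNames(rev(seq_along(ref)), ref)
    expect_equal(ra$tau, oracle_kendall_tau(sc[ref], ref_score[ref]))
    expect_equal(ra$rho, oracle_spearman(sc[ref], ref_score[ref]))
    expect_true(ra$tau >= -1 && ra$tau <= 1)
  }
  expect_error(rank_agreement(x, c("a", "b", "zz")), "mismatch")
  expect_error(rank_agreement(x[1:2], c("a", "b")), "3 ids")
})

make_two_atom_ensemble <- function(coords_list, names = c("CA", "CZ"),
                                   resno = c(221, 247)) {
  atoms <- data.frame(elety = names, resno = resno,
                      resid = "ALA", chain = "A")
  xyz <- do.call(rbind, lapply(coords_list, function(co) as.numeric(t(co))))
  coord_ensemble(atoms, xyz)
}

test_that("distance series are exact and rigid-motion invariant", {
  ens <- make_two_atom_ensemble(list(rbind(c(0, 0, 0), c(3, 4, 0))))
  d <- distance_series(ens, "A:221:CA", "A:247:CZ")
  expect_equal(d$distances, 5)

  same <- make_two_atom_ensemble(rep(list(rbind(c(0, 0, 0), c(1, 2, 2))), 4))
  ds <- distance_series(same, "A:221:CA", "A:247:CZ")
  expect_equal(unname(ds$summary["sd"]), 0)

  set.seed(12)
  coords <- lapply(1:6, function(i) matrix(rnorm(6), 2, 3))
  ens <- make_two_atom_ensemble(coords)
  d <- distance_series(ens, "A:221:CA", "A:247:CZ")
  oracle <- vapply(coords, function(co) sqrt(sum((co[1, ] - co[2, ])^2)),
                   numeric(1))
  expect_equal(d$distances, oracle)

  # global rigid transform of one model leaves its distance unchanged
  coords[[3]] <- apply_random_rigid(coords[[3]])
  d2 <- distance_series(make_two_atom_ensemble(coords), "A:221:CA", "A:247:CZ")
  expect_equal(d2$distances[3], oracle[3], tolerance = 1e-9)

  expect_error(distance_series(ens, "A:999:CA", "A:247:CZ"), "999")
})

test_that("RMSF is zero for identical models and matches the two-model
           closed form", {
  base <- matrix(rnorm(30), 10, 3)
  atoms <- data.frame(elety = "CA", resno = 1:10, resid = "ALA", chain = "A")
  same <- coord_ensemble(atoms, do.call(rbind, rep(list(as.numeric(t(base))), 5)))
  r <- superpose_rmsf(same, fit_sel = list(elety = "CA"))
  expect_true(all(r$atom$rmsf < 1e-9))

  # two models, one atom displaced +/- d about the mean, fit on the others
  d <- 0.8
  m1 <- base; m2 <- base
  m1[10, ] <- base[10, ] + c(d, 0, 0)
  m2[10, ] <- base[10, ] - c(d, 0, 0)
  ens2 <- coord_ensemble(atoms, rbind(as.numeric(t(m1)), as.numeric(t(m2))))
  r2 <- superpose_rmsf(ens2, fit_sel = list(resno = 1:9, elety = "CA"))
  expect_equal(r2$atom$rmsf[10], d, tolerance = 1e-6)
  expect_true(all(r2$atom$rmsf[1:9] < 1e-6))

  # rigid transform of a single model does not change RMSF
  set.seed(13)
  coords <- lapply(1:4, function(i) base + matrix(rnorm(30, sd = 0.1), 10, 3))
  ens <- coord_ensemble(atoms, do.call(rbind, lapply(coords, function(co)
    as.numeric(t(co)))))
  r3 <- superpose_rmsf(ens, fit_sel = list(elety = "CA"))
  coords[[2]] <- apply_random_rigid(coords[[2]])
  ens_m <- coord_ensemble(atoms, do.call(rbind, lapply(coords, function(co)
    as.numeric(t(co)))))
  r4 <- superpose_rmsf(ens_m, fit_sel = list(elety = "CA"))
  expect_equal(r4$atom$rmsf, r3$atom$rmsf, tolerance = 1e-6)

  expect_error(superpose_rmsf(ens, fit_sel = list(elety = "CB")), "empty")
})

test_that("pocket classification recovers planted state fractions", {
  thr <- pocket_thresholds(closed_max = 8, open_min = 10)
  m <- data.frame(d_gate1 = c(6, 12, 6, 12), d_gate2 = c(6.5, 13, 12, 6))
  cls <- classify_pocket(m, thr)
  expect_equal(as.character(cls$states),
               c("closed", "open", "indeterminate", "indeterminate"))

  # bound-like window takes models near the reference distances
  thrb <- pocket_thresholds(8, 12, bound_ref = c(9.5, 9.5), bound_tol = 0.5)
  mb <- data.frame(d_gate1 = 9.4, d_gate2 = 9.7)
  expect_equal(as.character(classify_pocket(mb, thrb)$states), "bound_like")
  expect_error(pocket_thresholds(10, 8), "overlap")
  expect_error(pocket_thresholds(8, 10, bound_ref = c(8.5, 8.5), bound_tol = 1),
               "overlap")

  # planted 30/70 closed/open ensemble, recovered within binomial error
  ens <- make_toy_ensemble(200, closed_fraction = 0.3, seed = 21)
  pm <- pocket_metrics(ens)
  cls <- classify_pocket(pm, thr)
  frac_closed <- unname(cls$fractions["closed"])
  expect_lt(abs(frac_closed - 0.3), 2 * sqrt(0.3 * 0.7 / 200) + 0.01)
  expect_equal(unname(cls$fractions["indeterminate"]), 0)
  truth <- attr(ens, "truth")
  expect_equal(as.character(cls$states), truth$state)
})

test_that("formal charge follows the integer ionisation model", {
  expect_equal(formal_charge("DDEEK"), -3)
  expect_equal(formal_charge("GGGG"), 0)
  expect_equal(formal_charge("HHH"), 0)            # His neutral at pH 7
  expect_equal(formal_charge("HHH", his_charge = 1), 3)
  expect_error(formal_charge("GAXG"), "X")

  # additivity over concatenation (termini cancel in this model)
  set.seed(14)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:5) {
    a <- paste(sample(aas, 12, TRUE), collapse = "")
    b <- paste(sample(aas, 9, TRUE), collapse = "")
    expect_equal(formal_charge(paste0(a, b)),
                 formal_charge(a) + formal_charge(b))
  }

  expect_equal(neutralizing_ions(-11, 2), list(n_ions = 22, ion = "cation"))
  expect_equal(neutralizing_ions(3, 2)$ion, "anion")
  expect_equal(neutralizing_ions(0, 2)$n_ions, 0)
})

test_that("the toy docking backend is deterministic and contact-monotone", {
  backend <- toy_dock_backend(radius = 2)
  pocket <- matrix(c(0, 0, 0, 3, 0, 0, 0, 3, 0), 3, 3, byrow = TRUE)
  lig <- matrix(c(0.5, 0.5, 0, 2.5, 0.2, 0), 2, 3, byrow = TRUE)
  s1 <- backend(pocket, lig)
  expect_identical(s1, backend(pocket, lig))  # identical receptor copies
  # moving a ligand point out of the pocket sphere lowers the score
  lig_out <- lig; lig_out[1, ] <- c(10, 10, 10)
  expect_lt(backend(pocket, lig_out), s1)
})

test_that("imported score matrices round-trip ids and dimensions", {
  set.seed(15)
  m <- matrix(round(rnorm(80, 50, 5), 3), 4, 20,
              dimnames = list(c("1a", "1b", "1c", "1d"), paste0("conf", 1:20)))
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = rownames(m), m, check.names = FALSE), path,
            row.names = FALSE)
  sm <- import_scores(path)
  expect_equal(dim(sm), dim(m))
  expect_equal(rownames(sm), rownames(m))
  expect_equal(unclass(sm)[, ], m[, ], tolerance = 1e-9, ignore_attr = TRUE)

  bad <- readLines(path)
  bad[3] <- sub(",[0-9.]+,", ",not_a_number,", bad[3])
  writeLines(bad, path)
  expect_error(import_scores(path), "line 3")
  unlink(path)
})
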