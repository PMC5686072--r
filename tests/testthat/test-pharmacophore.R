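test_that("SxIP preset extraction yields the expected feature set", {
  m <- sxip_model()
  expect_s3_class(m, "pharmacophore_model")
  expect_equal(nrow(m$features), 8L)
  kinds <- table(m$features$kind)
  expect_equal(as.integer(kinds[c("acceptor", "donor", "hydrophobic")]),
               c(3L, 2L, 3L))
  expect_false(anyDuplicated(m$features$label) > 0)

  # centres are centroids of the named atoms: spot-check the Pro ring centroid
  pdb <- bio3d::read.pdb(sxip_fixture_path(), verbose = FALSE)
  ring <- pdb$atom[pdb$atom$resno == 5480 & pdb$atom$elety %in% c("CB", "CG", "CD"), ]
  ctr <- colMeans(as.matrix(ring[, c("x", "y", "z")]))
  f <- m$features[m$features$label == "Pro5480:ring:hyd", ]
  expect_equal(unlist(f[, c("x", "y", "z")], use.names = FALSE),
               unname(ctr), tolerance = 1e-10)
})

test_that("chemically corrected preset swaps the backbone amine/carbonyl roles", {
  m <- build_sxip_model(sxip_fixture_path(),
                        preset = sxip_preset(chemically_corrected = TRUE))
  kinds <- table(m$features$kind)
  expect_equal(as.integer(kinds[c("acceptor", "donor", "hydrophobic")]),
               c(4L, 1L, 3L))
})

test_that("model building fails cleanly on bad presets and missing atoms", {
  expect_error(build_sxip_model(sxip_fixture_path(),
                                preset = sxip_preset()[0, ]),
               "empty preset")
  bad <- sxip_preset()
  bad$atoms[1] <- "OZ9"
  expect_error(build_sxip_model(sxip_fixture_path(), preset = bad),
               "OZ9.*5477")
})

test_that("subset enumeration matches the closed-form binomial count", {
  m <- sxip_model()
  expect_length(enumerate_subsets(m, c(5, 6, 7)), 92L)   # C(8,5)+C(8,6)+C(8,7)
  expect_length(enumerate_subsets(m, 8), 1L)
  expect_error(enumerate_subsets(m, 2), "below 3")

  # size exceeding the feature count contributes nothing
  small <- pharmacophore_model(m$features[1:4, ], "small")
  expect_length(enumerate_subsets(small, 5), 0L)

  # property: count equals the binomial sum for arbitrary (N, sizes)
  set.seed(42)
  for (n in c(4, 6, 9, 12)) {
    feats <- pharm_features(sample(c("acceptor", "donor", "hydrophobic"), n, TRUE),
                            matrix(rnorm(3 * n), ncol = 3),
                            label = paste0("f", 1:n))
    mod <- pharmacophore_model(feats, "rand")
    sizes <- 3:min(n + 1, 7)
    expected <- sum(choose(n, sizes[sizes <= n]))
    expect_length(enumerate_subsets(mod, sizes), expected)
  }

  # constraint hook filters the enumeration
  only_with_1 <- enumerate_subsets(m, 5, constraint = function(i) 1L %in% i)
  expect_length(only_with_1, choose(7, 4))
})

test_that("ligand feature assignment follows the element/connectivity rules", {
  methane <- list(id = "methane", atoms = data.frame(
    elem = c("C", "H", "H", "H", "H"),
    x = c(0, 1.09, -0.36, -0.36, -0.36),
    y = c(0, 0, 1.03, -0.51, -0.51),
    z = c(0, 0, 0, 0.89, -0.89)),
    bonds = data.frame(a1 = 1L, a2 = 2:5, order = 1L))
  cf <- assign_ligand_features(methane)
  expect_equal(sum(cf$points$kind == "hydrophobic"), 1L)
  expect_equal(sum(cf$points$kind == "donor"), 0L)
  expect_equal(sum(cf$points$kind == "acceptor"), 0L)

  water <- list(id = "water", atoms = data.frame(
    elem = c("O", "H", "H"), x = c(0, 0.96, -0.24), y = c(0, 0, 0.93),
    z = c(0, 0, 0)),
    bonds = data.frame(a1 = c(1L, 1L), a2 = c(2L, 3L), order = 1L))
  cf <- assign_ligand_features(water)
  expect_gte(sum(cf$points$kind == "donor"), 1L)
  expect_gte(sum(cf$points$kind == "acceptor"), 1L)
  o_pos <- c(0, 0, 0)
  acc <- cf$points[cf$points$kind == "acceptor", ]
  expect_equal(unlist(acc[1, c("x", "y", "z")], use.names = FALSE), o_pos)

  # centroid placement equals an independent coordinate-averaging oracle
  set.seed(7)
  nc <- 5
  frag <- list(id = "chain", atoms = data.frame(
    elem = rep("C", nc), x = rnorm(nc), y = rnorm(nc), z = rnorm(nc)),
    bonds = data.frame(a1 = 1:(nc - 1), a2 = 2:nc, order = 1L))
  cf <- assign_ligand_features(frag)
  hyd <- cf$points[cf$points$kind == "hydrophobic", ]
  expect_equal(nrow(hyd), 1L)
  manual <- c(sum(frag$atoms$x) / nc, sum(frag$atoms$y) / nc, sum(frag$atoms$z) / nc)
  expect_equal(unlist(hyd[1, c("x", "y", "z")], use.names = FALSE), manual)

  no_coords <- list(id = "bad", atoms = data.frame(elem = "C", x = NA_real_,
                                                   y = 0, z = 0),
                    bonds = data.frame(a1 = integer(0), a2 = integer(0),
                                       order = integer(0)))
  expect_error(assign_ligand_features(no_coords), "coordinates")
  expect_error(assign_ligand_features(water,
                                      rules = list(acceptor_elements = "xx",
                                                   donor_elements = "N",
                                                   hydrophobic_elements = "C")),
               "unparsable")
})

test_that("matching is exact on identity and invariant under rigid motions", {
  m <- sxip_model()
  q <- enumerate_subsets(m, 6)[[10]]
  pts <- m$features
  conf <- conformer_features("self", "c1", pts)
  res <- match_conformer(q, conf, rmsd_max = 0.5)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(res$rotation), 1, tolerance = 1e-9)

  set.seed(101)
  for (rep in 1:5) {
    moved <- pts
    moved[, c("x", "y", "z")] <- apply_random_rigid(as.matrix(pts[, c("x", "y", "z")]))
    res <- match_conformer(q, conformer_features("mv", "c1", moved), rmsd_max = 0.5)
    expect_lt(res$rmsd, 1e-6)
  }
})

test_that("match RMSD equals the exhaustive Horn-superposition oracle", {
  set.seed(202)
  kinds_pool <- c("acceptor", "donor", "hydrophobic")
  for (rep in 1:12) {
    s <- sample(3:6, 1)
    np <- sample(s:8, 1)
    qkinds <- sample(kinds_pool, s, replace = TRUE)
    pkinds <- c(qkinds, sample(kinds_pool, np - s, replace = TRUE))[sample(np)]
    qxyz <- matrix(runif(3 * s, -4, 4), ncol = 3)
    pxyz <- matrix(runif(3 * np, -4, 4), ncol = 3)
    oracle <- oracle_min_match_rmsd(qxyz, qkinds, pxyz, pkinds)

    feats <- pharm_features(qkinds, qxyz, label = paste0("f", 1:s))
    mod <- pharmacophore_model(feats, "r")
    q <- enumerate_subsets(mod, s)[[1]]
    conf <- conformer_features("r", "c1",
                               pharm_features(pkinds, pxyz, label = paste0("p", 1:np)))
    res <- match_conformer(q, conf, rmsd_max = Inf)
    if (is.finite(oracle)) {
      expect_equal(res$rmsd, oracle, tolerance = 1e-6)
    } else {
      expect_null(res)
    }
  }
})

test_that("jittered planted conformers match near the jitter scale and the
           0.5 A threshold is strict", {
  m <- sxip_model()
  q <- enumerate_subsets(m, 8)[[1]]
  set.seed(303)
  pts <- as.matrix(m$features[, c("x", "y", "z")])
  jit <- pts + matrix(rnorm(length(pts), sd = 0.05), ncol = 3)
  conf <- conformer_features("jit", "c1",
                             pharm_features(m$features$kind, apply_random_rigid(jit),
                                            label = paste0("p", 1:8)))
  res <- match_conformer(q, conf, rmsd_max = 0.5)
  expect_lt(res$rmsd, 0.2)
  oracle <- oracle_min_match_rmsd(
    pts[q$indices, , drop = FALSE], m$features$kind[q$indices],
    as.matrix(conf$points[, c("x", "y", "z")]), conf$points$kind)
  expect_equal(res$rmsd, oracle, tolerance = 1e-6)

  # a minimum just above the threshold is rejected: scale a planted conformer
  # so its best achievable rmsd lands slightly over 0.5
  res_any <- match_conformer(q, conf, rmsd_max = Inf)
  expect_null(match_conformer(q, conf, rmsd_max = res_any$rmsd * 0.99))
  expect_error(match_conformer(q, conf, rmsd_max = -1), "positive")

  big <- pharmacophore_model(
    pharm_features(rep("acceptor", 13), matrix(rnorm(39), ncol = 3),
                   label = paste0("f", 1:13)), "big")
  qbig <- enumerate_subsets(big, 13)[[1]]
  expect_error(match_conformer(qbig, conf), "cap")
})

test_that("library screening dedupes to unique molecules and honours rmsd_max", {
  m <- sxip_model()
  pts <- m$features
  set.seed(404)
  confs <- lapply(1:3, function(i) {
    moved <- pts
    xyz <- as.matrix(pts[, c("x", "y", "z")]) +
      matrix(rnorm(nrow(pts) * 3, sd = 0.02 * i), ncol = 3)
    moved[, c("x", "y", "z")] <- apply_random_rigid(xyz)
    conformer_features("molA", paste0("c", i), moved)
  })
  hits <- screen_library(confs, m, sizes = c(5, 6, 7))
  expect_equal(nrow(hits), 1L)           # duplicates removed
  expect_equal(hits$molecule_id, "molA")
  expect_true(all(hits$rmsd_A <= 0.5))

  # decoys with no kind-compatible injection produce no rows
  set.seed(405)
  decoys <- lapply(1:4, function(i) random_conformer(rep("hydrophobic", 8),
                                                     paste0("dec", i)))
  expect_equal(nrow(screen_library(decoys, m, sizes = c(5, 6, 7))), 0L)

  expect_equal(nrow(screen_library(list(), m, sizes = 5)), 0L)
})

test_that("planted libraries are recovered with full sensitivity and no
           decoy acceptance", {
  m <- sxip_model()
  planted <- plant_conformer_library(m, n_hits = 10, n_decoys = 50,
                                     jitter_sigma = 0.05, seed = 11)
  hits <- screen_library(planted$library, m, sizes = c(5, 6, 7))
  truth <- planted$truth
  expect_setequal(hits$molecule_id, truth$molecule_id[truth$is_hit])
  expect_false(anyDuplicated(hits$molecule_id) > 0)
  expect_true(all(hits$rmsd_A <= 0.5))
  expect_true(all(diff(hits$rmsd_A) >= 0))  # sorted ascending

  # sigma = 0: every hit at rmsd ~ 0
  exact <- plant_conformer_library(m, n_hits = 5, n_decoys = 10,
                                   jitter_sigma = 0, seed = 12)
  hits0 <- screen_library(exact$library, m, sizes = c(5, 6, 7))
  expect_equal(nrow(hits0), 5L)
  expect_true(all(hits0$rmsd_A < 1e-6))
})
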