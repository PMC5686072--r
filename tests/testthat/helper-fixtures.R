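# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately avoid the package's own code paths: superposition via
# Horn's quaternion method (eigen) instead of SVD, correspondences via plain
# permutation enumeration, rank statistics via explicit pair counting.

sxip_fixture_path <- function() {
  system.file("extdata", "sxip_peptide_synthetic.pdb", package = "dynappi")
}

eb1c_fasta_path <- function() {
  system.file("extdata", "EB1c_Q15691_191-260.fasta", package = "dynappi")
}

sxip_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_sxip_model(sxip_fixture_path())
    cache
  }
})

# a proper rigid transform of an n x 3 point matrix (seeded by caller)
apply_random_rigid <- function(pts) {
  th <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  r <- rx %*% ry %*% rz
  sweep(pts %*% r, 2, runif(3, -5, 5), `+`)
}

# --- oracle: optimal rigid superposition via Horn's quaternion method ------
horn_superpose_rmsd <- function(p, q) {
  pc <- sweep(p, 2, colMeans(p)); qc <- sweep(q, 2, colMeans(q))
  s <- crossprod(pc, qc)
  sxx <- s[1,1]; sxy <- s[1,2]; sxz <- s[1,3]
  syx <- s[2,1]; syy <- s[2,2]; syz <- s[2,3]
  szx <- s[3,1]; szy <- s[3,2]; szz <- s[3,3]
  n4 <- rbind(
    c(sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx),
    c(syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz),
    c(szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy),
    c(sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz))
  ev <- eigen(n4, symmetric = TRUE)
  qv <- ev$vectors[, 1]
  w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
  rot <- rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z),   2 * (x * z + w * y)),
    c(2 * (x * y + w * z),   w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y),   2 * (y * z + w * x),   w^2 - x^2 - y^2 + z^2))
  moved <- pc %*% t(rot)
  sqrt(mean(rowSums((moved - qc)^2)))
}

# --- oracle: exhaustive correspondence search ------------------------------
# enumerates every kind-compatible injection by plain recursion and scores
# each with the Horn superposition; returns the minimum RMSD (Inf if no
# injection exists)
oracle_min_match_rmsd <- function(qxyz, qkinds, pxyz, pkinds) {
  s <- length(qkinds)
  best <- Inf
  rec <- function(i, taken) {
    if (i > s) {
      r <- horn_superpose_rmsd(pxyz[taken, , drop = FALSE], qxyz)
      if (r < best) best <<- r
      return(NULL)
    }
    for (p in seq_along(pkinds)) {
      if (p %in% taken) next
      if (pkinds[p] != qkinds[i]) next
      rec(i + 1, c(taken, p))
    }
    NULL
  }
  rec(1, integer(0))
  best
}

# --- oracle: O(n^2) Pareto non-dominated sorting ---------------------------
oracle_pareto_fronts <- function(z) {
  # z: larger-is-better matrix
  n <- nrow(z)
  front <- rep(NA_integer_, n)
  left <- seq_len(n)
  f <- 0
  dominates <- function(a, b) all(z[a, ] >= z[b, ]) && any(z[a, ] > z[b, ])
  while (length(left) > 0) {
    f <- f + 1
    nd <- c()
    for (i in left) {
      dom <- FALSE
      for (j in left) if (j != i && dominates(j, i)) { dom <- TRUE; break }
      if (!dom) nd <- c(nd, i)
    }
    front[nd] <- f
    left <- setdiff(left, nd)
  }
  front
}

# --- oracle: tie-corrected Kendall tau-b by explicit pair counting ---------
oracle_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
    if (sx == 0 && sy == 0) next
    else if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# --- oracle: Spearman rho via ranks + explicit Pearson formula -------------
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random conformer-features object with given kinds
random_conformer <- function(kinds, id = "mol", spread = 5) {
  conformer_features(id, paste0(id, "_c1"),
                     pharm_features(kinds,
                                    matrix(runif(3 * length(kinds), -spread, spread), ncol = 3),
                                    label = paste0("p", seq_along(kinds))))
}
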