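test_that("superposition is exact for rigid motions and matches a
           multi-start minimisation oracle", {
  set.seed(7)
  a <- matrix(rnorm(12), 4, 3)
  # identical structures
  sp <- superpose(a, a)
  expect_equal(sp$rmsd, 0, tolerance = 1e-12)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  # rotated + translated copy
  th <- pi / 2
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_lt(superpose(a %*% rot + 3, a)$rmsd, 1e-12)
  expect_equal(det(superpose(a %*% rot + 3, a)$rotation), 1,
               tolerance = 1e-9)
  # fixed 4-point toy sets vs brute-force rotational minimisation
  for (i in 1:3) {
    b <- matrix(rnorm(12), 4, 3)
    expect_equal(superpose(a, b)$rmsd, oracle_min_rmsd(a, b),
                 tolerance = 1e-4)
  }
  expect_error(superpose(a[1:2, ], a[1:2, ]), ">= 3")
  line <- cbind(1:4, 2 * (1:4), -(1:4))
  expect_error(superpose(line, line), "collinear")
})

test_that("rmsd_matrix agrees with per-pair superposition and bio3d", {
  gen <- tiny_gen(n_frames = 6)
  ens <- gen$ensemble
  mat <- rmsd_matrix(ens)
  expect_equal(diag(mat), rep(0, 6))
  expect_equal(mat, t(mat), tolerance = 1e-9)
  expect_true(all(mat >= 0))
  ca <- ca_indices(ens$topology)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      sp <- superpose(frame_coords(ens, i), frame_coords(ens, j),
                      selection = ca)
      expect_equal(mat[i, j], sp$rmsd, tolerance = 1e-9)
      r_bio <- bio3d::rmsd(ens$xyz[j, 3 * rep(ca, each = 3) - c(2, 1, 0)],
                           ens$xyz[i, 3 * rep(ca, each = 3) - c(2, 1, 0)],
                           fit = TRUE)
      expect_lt(abs(mat[i, j] - r_bio), 6e-4)  # bio3d rounds to 3 decimals
    }
  }
  # identical frames -> zero matrix
  same <- conf_ensemble(ens$topology, ens$xyz[rep(1, 4), ])
  expect_equal(max(rmsd_matrix(same)), 0, tolerance = 1e-12)
})

test_that("dihedrals match the plane-normal oracle, bio3d, and are
           rigid-motion invariant", {
  set.seed(11)
  gen <- tiny_gen(n_frames = 3)
  ens <- gen$ensemble
  dih <- backbone_dihedrals(ens)
  # termini: no phi for first residue, no psi for last
  expect_true(all(is.na(dih$phi[, 1])))
  expect_true(all(is.na(dih$psi[, ncol(dih$psi)])))
  expect_true(all(abs(dih$phi[, -1]) <= pi))
  # oracle check on residue 5, frame 2
  at <- ens$topology$atoms
  pt <- function(res, nm, f) frame_coords(ens, f)[which(at$resid == res &
                                                          at$name == nm), ]
  ref <- oracle_dihedral(pt(4, "C", 2), pt(5, "N", 2), pt(5, "CA", 2),
                         pt(5, "C", 2))
  expect_equal(dih$phi[2, "5"], ref, tolerance = 1e-9,
               ignore_attr = TRUE)
  # bio3d as second, independent oracle
  ca_sel <- which(at$resid == 5 & at$name %in% c("N", "CA", "C"))
  quad <- c(which(at$resid == 4 & at$name == "C"), ca_sel)
  xyz_q <- as.vector(t(frame_coords(ens, 2)[quad, ]))
  t_bio <- bio3d::torsion.xyz(xyz_q, atm.inc = 4) * pi / 180
  expect_equal(dih$phi[2, "5"], t_bio[!is.na(t_bio)], tolerance = 1e-6,
               ignore_attr = TRUE)
  # rigid motion leaves all dihedrals unchanged
  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- t(apply(ens$xyz, 1, function(row) {
    as.vector(t(matrix(row, ncol = 3, byrow = TRUE) %*% rot + 2.5))
  }))
  dih2 <- backbone_dihedrals(conf_ensemble(ens$topology, moved))
  expect_equal(dih2$phi, dih$phi, tolerance = 1e-9)
  expect_equal(dih2$psi, dih$psi, tolerance = 1e-9)
})

test_that("planar four-atom chains give 0 (cis) and pi (trans)", {
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  d_cis <- cdrentropy:::.dihedral(cis[1, , drop = FALSE],
                                  cis[2, , drop = FALSE],
                                  cis[3, , drop = FALSE],
                                  cis[4, , drop = FALSE])
  d_trans <- cdrentropy:::.dihedral(trans[1, , drop = FALSE],
                                    trans[2, , drop = FALSE],
                                    trans[3, , drop = FALSE],
                                    trans[4, , drop = FALSE])
  expect_equal(d_cis, 0, tolerance = 1e-12)
  expect_equal(abs(d_trans), pi, tolerance = 1e-12)
})

test_that("contacts honour the strict cutoff and sequence separation", {
  # two-residue toy: nearest heavy atoms at a controlled distance
  make_pair <- function(gap_nm) {
    top <- topology(name = rep(c("N", "CA", "C"), 3),
                    element = rep(c("N", "C", "C"), 3),
                    resid = rep(1:3, each = 3),
                    resname = rep("GLY", 9))
    base <- as.vector(t(rbind(
      c(0, 0, 0), c(0.15, 0, 0), c(0.3, 0, 0),       # res 1
      c(10, 10, 10), c(10.15, 10, 10), c(10.3, 10, 10),  # res 2 (far)
      c(0.3 + gap_nm, 0, 0), c(0.45 + gap_nm, 0, 0),
      c(0.6 + gap_nm, 0, 0)                           # res 3
    )))
    conf_ensemble(top, matrix(base, nrow = 1))
  }
  # 0.44 nm between C(1) and N(3): contact ("below 0.45")
  expect_true(residue_contacts(make_pair(0.44), 1, 3)[1, 1])
  # 0.46 nm: no contact
  expect_false(residue_contacts(make_pair(0.46), 1, 3)[1, 1])
  # exactly at the cutoff: strict inequality -> no contact
  expect_false(residue_contacts(make_pair(0.45), 1, 3)[1, 1])
  # adjacent residues are excluded by min_seq_sep regardless of distance
  expect_false(residue_contacts(make_pair(0.1), 2, 3)[1, 1])
  expect_false(residue_contacts(make_pair(0.1), 3, 3,
                                min_seq_sep = 2)[1, 1])
})

test_that("contact sets are monotone in the cutoff", {
  gen <- tiny_gen(n_frames = 4)
  res <- 1:10
  for (f in 1:4) {
    tight <- residue_contacts(gen$ensemble, res, res, frame = f,
                              cutoff = 0.40)
    loose <- residue_contacts(gen$ensemble, res, res, frame = f,
                              cutoff = 0.45)
    expect_true(all(loose[tight]))
  }
})

test_that("rmsf recovers isotropic jitter and is weight-scale invariant", {
  set.seed(3)
  sigma <- 0.05
  tpl <- build_backbone(rep(-1.1, 8), rep(2.3, 8))
  n <- 4000
  xyz <- matrix(rep(as.vector(t(tpl$xyz)), n), n, byrow = TRUE)
  # jitter only the CA of residue 4
  ca4 <- which(tpl$topology$atoms$resid == 4 &
                 tpl$topology$atoms$name == "CA")
  cols <- (3 * (ca4 - 1) + 1):(3 * ca4)
  xyz[, cols] <- xyz[, cols] + rnorm(3 * n, 0, sigma)
  ens <- conf_ensemble(tpl$topology, xyz)
  # fit on the rigid residues so the jitter stays on residue 4
  r <- rmsf(ens, fit_residues = c(1:3, 5:8))
  expect_equal(unname(r["4"]), sigma * sqrt(3), tolerance = 0.05)
  expect_lt(max(r[-4]), 0.01)
  # scaling weights before normalisation changes nothing
  w <- rep(2 / n, n)
  expect_equal(rmsf(ens, weights = w / sum(w), fit_residues = c(1:3, 5:8)),
               r, tolerance = 1e-9)
  # identical frames -> zeros
  same <- conf_ensemble(tpl$topology, xyz[rep(1, 5), ])
  expect_equal(max(rmsf(same)), 0, tolerance = 1e-12)
})
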