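test_that("specs validate populations and basin resolvability", {
  expect_error(synthetic_spec(populations = c(0.5, 0.4)), "sum to 1")
  expect_error(synthetic_spec(populations = c(0.5, 0.5), sigma = 0.1,
                              min_separation = 0.5), "unresolvable")
  sp <- synthetic_spec(populations = c(0.7, 0.3), seed = 3)
  expect_equal(sp$n_basins, 2)
  expect_equal(sp$seed, 3)
})

test_that("a single zero-noise basin collapses the whole pipeline", {
  gen <- generate_multibasin_ensemble(synthetic_spec(
    n_residues = 8, populations = 1.0, sigma = 0, n_frames = 40,
    seed = 2, min_separation = 0.1))
  expect_equal(max(rmsd_matrix(gen$ensemble)), 0, tolerance = 1e-9)
  for (cutoff in c(0.05, 0.15, 0.3)) {
    cl <- gromos_cluster(rmsd_matrix(gen$ensemble), cutoff)
    expect_equal(cl$n_clusters, 1)
    expect_equal(cluster_entropy(cl), 0)
  }
})

test_that("basin templates respect the separation floor", {
  gen <- tiny_gen(populations = c(0.4, 0.3, 0.3), n_frames = 2)
  ca <- seq(2, 40, by = 4)
  for (i in 1:2) {
    for (j in (i + 1):3) {
      sep <- superpose(gen$templates[[i]]$xyz[ca, ],
                       gen$templates[[j]]$xyz[ca, ])$rmsd
      expect_gte(sep, 0.35)
    }
  }
})

test_that("clustering recovers ground-truth basins and populations", {
  set.seed(123)
  # small grid over noise, basin count and size
  grid <- expand.grid(sigma = c(0.01, 0.02), k = c(2, 3),
                      n = c(1000, 2000))
  for (g in seq_len(nrow(grid))) {
    p <- switch(grid$k[g], NULL, c(0.65, 0.35), c(0.5, 0.3, 0.2))
    gen <- generate_multibasin_ensemble(synthetic_spec(
      n_residues = 10, populations = p, sigma = grid$sigma[g],
      n_frames = grid$n[g], seed = 100 + g, min_separation = 0.35))
    cl <- gromos_cluster(rmsd_matrix(gen$ensemble), 0.15)
    expect_equal(cl$n_clusters, grid$k[g])
    se <- sqrt(p * (1 - p) / grid$n[g])
    expect_true(all(abs(cl$populations - p) <= 3 * se + 1e-9))
    # clusters coincide with the ground-truth basins
    agree <- table(cl$assignment, gen$assignment)
    expect_equal(sum(apply(agree, 1, max)), grid$n[g])
  }
})

test_that("bias mode reweights uniform sampling back to the targets", {
  p <- c(0.6, 0.3, 0.1)
  gen <- generate_multibasin_ensemble(synthetic_spec(
    n_residues = 10, populations = p, sigma = 0.02, n_frames = 3000,
    seed = 19, bias_mode = "reweight", min_separation = 0.35))
  # sampled basin fractions are uniform
  frac <- tabulate(gen$assignment, 3) / 3000
  expect_true(all(abs(frac - 1 / 3) < 3 * sqrt(2 / 9 / 3000) + 0.01))
  # weighted basin populations recover the targets
  wpop <- vapply(1:3, function(b)
    sum(gen$ensemble$weights[gen$assignment == b]), numeric(1))
  expect_equal(wpop, p, tolerance = 0.03)
  # and the ensemble invariant links bias to weights
  expect_equal(compute_weights(gen$ensemble$bias, 300)$w,
               gen$ensemble$weights, tolerance = 1e-12)
})

test_that("dihedral mixtures expose a trustworthy reference entropy", {
  # single near-point-mass component
  tight <- generate_dihedral_mixture(means = cbind(0.3, -0.4),
                                     concentrations = 1e6,
                                     n_samples = 2000, seed = 4,
                                     n_reference = 2000)
  expect_lt(dihedral_entropy(tight$phi, tight$psi), 0.1)
  # circular uniform approaches log(bins^2)
  unif <- generate_dihedral_mixture(means = cbind(0, 0),
                                    concentrations = 0,
                                    n_samples = 50000, seed = 4,
                                    n_reference = 1000)
  expect_equal(dihedral_entropy(unif$phi, unif$psi, bins_per_dim = 10),
               log(100), tolerance = 0.01)
  # pipeline entropy tracks the oracle reference on the same distribution
  mix <- generate_dihedral_mixture(means = rbind(c(-1, 1), c(2, -2)),
                                   concentrations = 10,
                                   n_samples = 100000, seed = 21,
                                   n_reference = 100000)
  expect_equal(dihedral_entropy(mix$phi, mix$psi), mix$reference_entropy,
               tolerance = 0.02)
  expect_error(generate_dihedral_mixture(means = matrix(0, 0, 2),
                                         concentrations = 1), "component")
})

test_that("entropy ladders are strictly ordered by construction and
           robust across seeds", {
  ladder <- build_entropy_ladder(seed = 10)
  expect_equal(ladder$true_entropies, c(0, 0.6109, 1.0889),
               tolerance = 1e-3)
  recovered <- vapply(ladder$ensembles, function(gen) {
    cluster_entropy(gromos_cluster(rmsd_matrix(gen$ensemble), 0.15))
  }, numeric(1))
  expect_true(all(diff(recovered) > 0))
  expect_warning(build_entropy_ladder(list(c(0.5, 0.5), c(0.5, 0.5)),
                                      seed = 1), "equal")
  expect_error(build_entropy_ladder(list(1.0), seed = 1), "at least 2")
})

test_that("fixtures are written in the pipeline's own input formats", {
  gen <- tiny_gen(populations = c(0.7, 0.3), n_frames = 8, seed = 91,
                  bias_mode = "reweight")
  dir <- tempfile()
  files <- write_synthetic_fixture(gen, dir)
  expect_named(files, c("pdb", "colvar", "regions"))
  top <- load_topology(files[["pdb"]])
  ens <- load_ensemble(top, files[["pdb"]])
  ens <- attach_bias(ens, load_bias_table(files[["colvar"]]))
  expect_equal(ens$weights, gen$ensemble$weights, tolerance = 1e-6)
})
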