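test_that("load_topology parses atoms, residues and heavy flags", {
  path <- write_toy_pdb()
  top <- load_topology(path)
  expect_s3_class(top, "topology")
  expect_equal(top$n_atoms, 12)
  expect_equal(top$n_residues, 3)
  # the single hydrogen (HA of residue 2) is excluded from the heavy set
  expect_equal(sum(top$atoms$heavy), 11)
  expect_false(top$atoms$heavy[top$atoms$name == "HA"])
})

test_that("a residue without CA triggers a warning, not an error", {
  lines <- toy_pdb_lines()
  lines <- lines[!grepl("CA  GLY", lines)]
  path <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), path)
  expect_warning(top <- load_topology(path), "without a CA")
  expect_equal(top$n_residues, 3)
})

test_that("multi-model ensembles load, convert to nm, and round-trip", {
  gen <- tiny_gen(n_frames = 5)
  path <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(gen$ensemble, path)
  top <- load_topology(path)
  ens <- load_ensemble(top, path)
  expect_equal(ens$n_frames, 5)
  # PDB stores 3 decimals in Angstrom -> 5e-5 nm quantisation
  expect_lt(max(abs(ens$xyz - gen$ensemble$xyz)), 1e-4)

  # single-model file: degenerate but valid
  one <- conf_ensemble(gen$ensemble$topology,
                       gen$ensemble$xyz[1, , drop = FALSE])
  p1 <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(one, p1)
  expect_equal(load_ensemble(top, p1)$n_frames, 1)
})

test_that("a model with a missing atom names the offending model", {
  gen <- tiny_gen(n_frames = 3)
  path <- tempfile(fileext = ".pdb")
  write_ensemble_pdb(gen$ensemble, path)
  lines <- readLines(path)
  atom_lines <- which(startsWith(lines, "ATOM"))
  n_at <- gen$ensemble$topology$n_atoms
  lines <- lines[-atom_lines[2 * n_at + 1]]   # drop first atom of model 3
  writeLines(lines, path)
  top <- topology(
    name = gen$ensemble$topology$atoms$name,
    element = gen$ensemble$topology$atoms$element,
    resid = gen$ensemble$topology$atoms$resid,
    resname = gen$ensemble$topology$atoms$resname
  )
  expect_error(load_ensemble(top, path), "model 3")
})

test_that("bias tables parse, deduplicate restarts, and validate", {
  path <- write_colvar(c(1.5, 2.5, 3.5, 4.5))
  bt <- load_bias_table(path)
  expect_equal(nrow(bt), 4)
  expect_equal(bt$pb.bias, c(1.5, 2.5, 3.5, 4.5))

  # duplicate time stamp: keep the last occurrence
  path <- write_colvar(c(1, 2, 99, 3), time = c(0, 10, 10, 20))
  bt <- load_bias_table(path)
  expect_equal(nrow(bt), 3)
  expect_equal(bt$pb.bias[bt$time == 10], 99)

  expect_error(load_bias_table(write_colvar(1:3, field = "other.bias")),
               "available fields")
  nohdr <- tempfile()
  writeLines(c("1 2", "3 4"), nohdr)
  expect_error(load_bias_table(nohdr), "FIELDS")
  badcell <- tempfile()
  writeLines(c("#! FIELDS time pb.bias", "0 1.0", "1 oops"), badcell)
  expect_error(load_bias_table(badcell), "row 2")
})

test_that("region sets validate ranges and derive the scaffold", {
  rs <- region_set(list(CDR1 = c(27, 36), CDR2 = c(51, 60),
                        CDR3 = c(101, 113), HV4 = c(75, 80)), 123)
  named <- unlist(rs$residues[c("CDR1", "CDR2", "CDR3", "HV4")],
                  use.names = FALSE)
  # scaffold is the exact complement: union is everything, overlap empty
  expect_setequal(c(named, rs$residues$scaffold), 1:123)
  expect_length(intersect(named, rs$residues$scaffold), 0)
  expect_equal(length(rs$residues$scaffold), 123 - length(named))

  expect_warning(region_set(list(all = c(1, 10)), 10), "empty")
  expect_error(region_set(list(CDR3 = c(99, 118)), 110), "outside")
  expect_error(region_set(list(a = c(1, 5), b = c(5, 9)), 10), "overlap")
})

test_that("region config files load against a topology", {
  gen <- tiny_gen(n_frames = 2)
  dir <- tempfile()
  files <- write_synthetic_fixture(gen, dir)
  top <- load_topology(files[["pdb"]])
  rs <- load_regions(files[["regions"]], top)
  expect_s3_class(rs, "region_set")
  expect_true("CDR3" %in% names(rs$ranges))
  expect_error(region_residues(rs, "CDR9"), "unknown region")
})

test_that("bias/frame alignment uses stride and rejects mismatches", {
  gen <- tiny_gen(n_frames = 10)
  bias <- rnorm(20)
  ens <- attach_bias(gen$ensemble, bias, stride = 2)
  expect_equal(ens$bias, bias[seq(1, 20, by = 2)])
  expect_equal(sum(ens$weights), 1, tolerance = 1e-12)
  expect_error(attach_bias(gen$ensemble, bias, stride = 3), "stride")
})

test_that("packaged sdAb sequences and regions are readable", {
  fa <- load_sequences(system.file("extdata", "sdab_sequences.fasta",
                                   package = "cdrentropy"))
  expect_named(fa, c("DesAbO", "DesAb-HSA-D3", "Nb10"))
  expect_true(all(nchar(fa) > 100))
  reg_file <- system.file("extdata", "regions_desabo.tsv",
                          package = "cdrentropy")
  raw <- read.table(reg_file, header = TRUE)
  rs <- region_set(setNames(lapply(seq_len(nrow(raw)), function(i)
    c(raw$start[i], raw$end[i])), raw$name), nchar(fa[["DesAbO"]]))
  expect_equal(rs$ranges$CDR3, c(101, 113))
})
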