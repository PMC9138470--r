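# Small fixtures built in code at test time.

# a tiny multi-basin ensemble shared across tests (cheap: 10 residues)
tiny_gen <- function(populations = c(0.6, 0.3, 0.1), n_frames = 400,
                     seed = 42, ...) {
  generate_multibasin_ensemble(synthetic_spec(
    n_residues = 10, populations = populations, sigma = 0.02,
    n_frames = n_frames, seed = seed, min_separation = 0.35, ...))
}

# hand-written 3-residue, 12-atom PDB (one hydrogen, one model)
toy_pdb_lines <- function() {
  fmt <- "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
  atoms <- list(
    list("N",  "ALA", 1, c(0.0, 0.0, 0.0), "N"),
    list("CA", "ALA", 1, c(1.5, 0.0, 0.0), "C"),
    list("C",  "ALA", 1, c(2.0, 1.4, 0.0), "C"),
    list("O",  "ALA", 1, c(1.3, 2.4, 0.0), "O"),
    list("N",  "GLY", 2, c(3.3, 1.5, 0.0), "N"),
    list("CA", "GLY", 2, c(4.0, 2.8, 0.1), "C"),
    list("C",  "GLY", 2, c(5.5, 2.6, 0.2), "C"),
    list("HA", "GLY", 2, c(3.8, 3.4, 1.0), "H"),
    list("N",  "SER", 3, c(6.1, 3.8, 0.2), "N"),
    list("CA", "SER", 3, c(7.5, 3.9, 0.4), "C"),
    list("C",  "SER", 3, c(8.2, 5.2, 0.1), "C"),
    list("O",  "SER", 3, c(7.6, 6.3, 0.2), "O")
  )
  vapply(seq_along(atoms), function(i) {
    a <- atoms[[i]]
    name <- if (nchar(a[[1]]) < 4) paste0(" ", a[[1]]) else a[[1]]
    sprintf(fmt, i, name, a[[2]], a[[3]], a[[4]][1], a[[4]][2], a[[4]][3],
            a[[5]])
  }, character(1))
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(toy_pdb_lines(), "END"), path)
  path
}

write_colvar <- function(bias, path = tempfile(fileext = ".dat"),
                         time = seq_along(bias) - 1,
                         field = "pb.bias") {
  writeLines(c(paste("#! FIELDS time", field),
               sprintf("%.4f %.8f", time, bias)), path)
  path
}
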