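#' Load a topology from a PDB file
#'
#' Reads ATOM records from the first model of a PDB file and builds the
#' atom table used by all downstream selections: atom names, heavy/hydrogen
#' flags, 1-based residue indices, residue names and chain ids. Heavy-atom
#' status is taken from the element column when present, otherwise derived
#' from the atom name (leading digits stripped; names starting with H are
#' hydrogens).
#'
#' @param path path to a PDB file containing ATOM records.
#' @return An object of class `topology`: a list with `atoms` (data.frame
#'   with columns `name`, `element`, `heavy`, `resid`, `resname`, `chain`),
#'   `n_atoms` and `n_residues`.
#' @export
load_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))
  if (length(bad) > 0) {
    stop("unparseable coordinates in ATOM record ", bad[1], " of ", path)
  }
  elem <- at$elesy
  guess <- toupper(substr(gsub("^[0-9]+", "", at$elety), 1, 1))
  elem[is.na(elem) | elem == ""] <- guess[is.na(elem) | elem == ""]
  topology(
    name = at$elety, element = elem,
    resid = at$resno, resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain)
  )
}

#' Construct a topology
#'
#' @param name atom names (e.g. "CA", "N").
#' @param element element symbols; anything equal to "H" is a hydrogen.
#' @param resid 1-based residue index per atom, non-decreasing.
#' @param resname residue name per atom.
#' @param chain chain identifier per atom.
#' @return A `topology` object.
#' @export
topology <- function(name, element, resid, resname, chain = "A") {
  n <- length(name)
  stopifnot(length(element) == n, length(resid) == n, length(resname) == n)
  if (any(diff(resid) < 0)) stop("residue indices must be non-decreasing")
  atoms <- data.frame(
    name = as.character(name), element = toupper(as.character(element)),
    heavy = toupper(as.character(element)) != "H",
    resid = as.integer(resid), resname = as.character(resname),
    chain = rep_len(as.character(chain), n),
    stringsAsFactors = FALSE
  )
  res_ids <- unique(atoms$resid)
  no_ca <- res_ids[!res_ids %in% atoms$resid[atoms$name == "CA"]]
  if (length(no_ca) > 0) {
    warning("residue(s) without a CA atom: ", paste(no_ca, collapse = ", "))
  }
  structure(
    list(atoms = atoms, n_atoms = n, n_residues = length(res_ids)),
    class = "topology"
  )
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", x$n_atoms, " atoms (",
      sum(x$atoms$heavy), " heavy), ", x$n_residues, " residues\n", sep = "")
  invisible(x)
}

#' Indices of CA atoms for a set of residues
#' @param top a `topology`.
#' @param residues residue ids (default all).
#' @return integer atom indices.
#' @export
ca_indices <- function(top, residues = NULL) {
  sel <- top$atoms$name == "CA"
  if (!is.null(residues)) sel <- sel & top$atoms$resid %in% residues
  which(sel)
}

#' Construct a conformational ensemble
#'
#' The central container: frames of coordinates in nm (bio3d xyz layout,
#' one frame per row), a topology, and optional per-frame metadynamics bias
#' (kJ/mol) and normalised statistical weights.
#'
#' @param topology a `topology`.
#' @param xyz numeric matrix `n_frames x (3 * n_atoms)`, coordinates in nm.
#' @param bias optional per-frame bias potential V_PB in kJ/mol.
#' @param weights optional normalised per-frame weights (sum to 1).
#' @param temperature simulation temperature in kelvin.
#' @return An object of class `conf_ensemble`.
#' @export
conf_ensemble <- function(topology, xyz, bias = NULL, weights = NULL,
                          temperature = 300) {
  stopifnot(inherits(topology, "topology"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * topology$n_atoms) {
    stop("xyz has ", ncol(xyz), " columns; topology implies ",
         3 * topology$n_atoms)
  }
  if (!is.null(bias)) {
    if (length(bias) != nrow(xyz)) stop("bias length != n_frames")
    if (any(!is.finite(bias))) {
      stop("non-finite bias at frame ", which(!is.finite(bias))[1])
    }
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(xyz)) stop("weights length != n_frames")
    if (any(weights < 0)) stop("negative weights")
    if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
    if (!is.null(bias)) {
      ref <- compute_weights(bias, temperature)
      if (max(abs(ref$w - weights)) > 1e-6) {
        stop("weights inconsistent with bias at this temperature")
      }
    }
  }
  structure(
    list(topology = topology, xyz = xyz, bias = bias, weights = weights,
         temperature = temperature, n_frames = nrow(xyz)),
    class = "conf_ensemble"
  )
}

#' @export
print.conf_ensemble <- function(x, ...) {
  cat("<conf_ensemble> ", x$n_frames, " frames, ",
      x$topology$n_atoms, " atoms, T = ", x$temperature, " K",
      if (!is.null(x$weights)) ", weighted" else "", "\n", sep = "")
  invisible(x)
}

#' Effective (possibly uniform) weights of an ensemble
#' @param ensemble a `conf_ensemble`.
#' @return normalised per-frame weights.
#' @export
ensemble_weights <- function(ensemble) {
  ensemble$weights %||% rep(1 / ensemble$n_frames, ensemble$n_frames)
}

# count ATOM/HETATM records per MODEL block without parsing coordinates;
# gives per-model error context before delegating to bio3d
.scan_models <- function(path) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  is_atom <- rec == "ATOM  "
  if (length(model_starts) == 0) {
    return(sum(is_atom))
  }
  ends <- which(rec == "ENDMDL")
  if (length(ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records in ", path)
  }
  vapply(seq_along(model_starts), function(k) {
    sum(is_atom[model_starts[k]:ends[k]])
  }, integer(1))
}

#' Load a multi-model PDB file as a conformational ensemble
#'
#' Models are stacked in file order; coordinates are converted from
#' Angstrom to nm. Every model must contain the same atoms, in the same
#' order, as the topology.
#'
#' @param topology a `topology` describing one model.
#' @param path multi-model PDB file (MODEL/ENDMDL delimited; a single
#'   model without MODEL records is also accepted).
#' @param temperature kelvin.
#' @return A `conf_ensemble` (no bias/weights attached).
#' @export
load_ensemble <- function(topology, path, temperature = 300) {
  counts <- .scan_models(path)
  bad <- which(counts != topology$n_atoms)
  if (length(bad) > 0) {
    stop("model ", bad[1], " has ", counts[bad[1]], " atoms; topology has ",
         topology$n_atoms)
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  conf_ensemble(topology, xyz / 10, temperature = temperature)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are converted from nm back to Angstrom. Inverse of
#' [load_ensemble()] up to output precision (3 decimals in Angstrom).
#'
#' @param ensemble a `conf_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  at <- ensemble$topology$atoms
  bio3d::write.pdb(
    file = path, xyz = ensemble$xyz * 10,
    resno = at$resid, resid = at$resname, elety = at$name,
    chain = at$chain, elesy = at$element
  )
  invisible(path)
}

#' Load a PLUMED COLVAR-style bias table
#'
#' Expects a `#! FIELDS <names...>` header line followed by
#' whitespace-separated numeric rows. Restart artifacts (repeated values in
#' the time column) are dropped keeping the last occurrence.
#'
#' @param path COLVAR file.
#' @param bias_col name of the bias column (default `"pb.bias"`).
#' @param time_col name of the time column used for deduplication
#'   (default the first field).
#' @return A data.frame of class `bias_table`, rows in file order, with
#'   attribute `bias_col`.
#' @export
load_bias_table <- function(path, bias_col = "pb.bias", time_col = NULL) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#! FIELDS")) {
    stop("missing '#! FIELDS' header in ", path)
  }
  fields <- strsplit(trimws(sub("^#! FIELDS", "", first)), "\\s+")[[1]]
  tab <- read.table(path, comment.char = "#", col.names = fields,
                    colClasses = "character")
  num <- suppressWarnings(
    as.data.frame(lapply(tab, as.numeric), col.names = fields)
  )
  for (j in seq_along(num)) {
    if (anyNA(num[[j]])) {
      stop("non-numeric value in column '", fields[j], "' at data row ",
           which(is.na(num[[j]]))[1])
    }
  }
  if (!bias_col %in% fields) {
    stop("bias column '", bias_col, "' not found; available fields: ",
         paste(fields, collapse = ", "))
  }
  time_col <- time_col %||% fields[1]
  # keep the last occurrence of each time stamp (restart artifacts)
  keep <- !duplicated(num[[time_col]], fromLast = TRUE)
  num <- num[keep, , drop = FALSE]
  rownames(num) <- NULL
  if (any(!is.finite(num[[bias_col]]))) stop("non-finite bias value")
  structure(num, class = c("bias_table", "data.frame"), bias_col = bias_col)
}

#' Write a COLVAR-style bias table
#' @param bias per-frame bias values (kJ/mol).
#' @param path output file.
#' @param time time stamps (default frame index starting at 0).
#' @param bias_col bias field name.
#' @return `path`, invisibly.
#' @export
write_bias_table <- function(bias, path, time = seq_along(bias) - 1,
                             bias_col = "pb.bias") {
  writeLines(c(paste("#! FIELDS time", bias_col),
               sprintf("%.6f %.10g", time, bias)), path)
  invisible(path)
}

#' Attach a bias table to an ensemble and compute weights
#'
#' If the table has more rows than the ensemble has frames, `stride` maps
#' rows to frames (row 1, 1 + stride, ...). A residual mismatch is an
#' error, never a silent truncation.
#'
#' @param ensemble a `conf_ensemble`.
#' @param bias_table a `bias_table` (or numeric vector of bias values).
#' @param stride integer stride from table rows to frames.
#' @return The ensemble with `bias` and `weights` populated.
#' @export
attach_bias <- function(ensemble, bias_table, stride = 1) {
  if (inherits(bias_table, "bias_table")) {
    v <- bias_table[[attr(bias_table, "bias_col")]]
  } else {
    v <- as.numeric(bias_table)
  }
  v <- v[seq(1, length(v), by = stride)]
  if (length(v) != ensemble$n_frames) {
    stop("bias table has ", length(v), " rows after stride ", stride,
         "; ensemble has ", ensemble$n_frames, " frames")
  }
  w <- compute_weights(v, ensemble$temperature)
  conf_ensemble(ensemble$topology, ensemble$xyz, bias = v, weights = w$w,
                temperature = ensemble$temperature)
}

#' Define named residue regions over a chain
#'
#' Regions are inclusive 1-based residue ranges (the CDR/HV loop
#' convention); the scaffold is derived as the complement of all named
#' ranges.
#'
#' @param ranges named list of `c(start, end)` integer pairs.
#' @param n_residues chain length.
#' @return An object of class `region_set` with elements `ranges`,
#'   `residues` (named list of residue id vectors, including `scaffold`)
#'   and `n_residues`.
#' @export
region_set <- function(ranges, n_residues) {
  stopifnot(length(ranges) > 0, !is.null(names(ranges)))
  covered <- integer(0)
  residues <- list()
  for (nm in names(ranges)) {
    r <- as.integer(ranges[[nm]])
    if (length(r) != 2 || r[1] > r[2]) stop("bad range for ", nm)
    if (r[1] < 1 || r[2] > n_residues) {
      stop("region ", nm, " (", r[1], "-", r[2],
           ") outside chain of ", n_residues, " residues")
    }
    ids <- r[1]:r[2]
    if (any(ids %in% covered)) stop("region ", nm, " overlaps another region")
    covered <- c(covered, ids)
    residues[[nm]] <- ids
  }
  scaffold <- setdiff(seq_len(n_residues), covered)
  if (length(scaffold) == 0) warning("scaffold region is empty")
  residues$scaffold <- scaffold
  structure(list(ranges = ranges, residues = residues,
                 n_residues = n_residues),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> over", x$n_residues, "residues\n")
  for (nm in names(x$ranges)) {
    r <- x$ranges[[nm]]
    cat(" ", nm, ": ", r[1], "-", r[2], "\n", sep = "")
  }
  cat("  scaffold: ", length(x$residues$scaffold), " residues\n", sep = "")
  invisible(x)
}

#' Residue ids of a named region (including the derived scaffold)
#' @param regions a `region_set`.
#' @param name region name, e.g. "CDR3" or "scaffold".
#' @return integer residue ids.
#' @export
region_residues <- function(regions, name) {
  if (!name %in% names(regions$residues)) {
    stop("unknown region '", name, "'; available: ",
         paste(names(regions$residues), collapse = ", "))
  }
  regions$residues[[name]]
}

#' Load region definitions from a config file
#'
#' The file is whitespace- or tab-separated text with columns
#' `name start end` (header optional), ranges 1-based inclusive. Ranges are
#' taken exactly as given.
#'
#' @param path config file.
#' @param topology a `topology` (provides the chain length).
#' @return A `region_set`.
#' @export
load_regions <- function(path, topology) {
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("name", "start", "end"))
  if (identical(tolower(raw$name[1]), "name")) raw <- raw[-1, , drop = FALSE]
  ranges <- lapply(seq_len(nrow(raw)), function(i) {
    as.integer(c(raw$start[i], raw$end[i]))
  })
  names(ranges) <- raw$name
  region_set(ranges, topology$n_residues)
}

#' Read amino-acid sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences (gaps removed).
#' @export
load_sequences <- function(path) {
  fa <- bio3d::read.fasta(path)
  vapply(seq_len(nrow(fa$ali)), function(i) {
    paste(fa$ali[i, fa$ali[i, ] != "-"], collapse = "")
  }, character(1), USE.NAMES = FALSE) |> setNames(fa$id)
}
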