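#' Pipeline configuration
#'
#' Collects all inputs and parameters for [run_pipeline()]. Defaults are
#' the analysis conditions used throughout this package: GROMOS cutoff
#' 0.15 nm, heavy-atom contact cutoff 0.45 nm, 100 histogram bins per
#' dihedral dimension, 20 bootstrap samples of 10,000 frames, 300 K, and
#' a 10% equilibration discard.
#'
#' @param topology_path PDB file providing the topology.
#' @param ensemble_path multi-model PDB file of frames (default: same as
#'   `topology_path`).
#' @param bias_path optional COLVAR-style bias table.
#' @param regions_path region config (`name start end` per line).
#' @param temperature kelvin.
#' @param cluster_algorithm `"gromos"` or `"hierarchical"`.
#' @param cluster_cutoff RMSD cutoff in nm.
#' @param contact_cutoff heavy-atom contact cutoff in nm.
#' @param dihedral_bins histogram bins per dimension.
#' @param fes_bins free-energy-surface bins per dimension.
#' @param n_bootstrap bootstrap samples.
#' @param frames_per_sample frames per bootstrap sample (default:
#'   ensemble size, capped at 10,000).
#' @param discard_fraction split-half equilibration discard.
#' @param bias_col bias column name in the COLVAR file.
#' @param loop name of the loop region analysed (default "CDR3").
#' @param seed integer seed.
#' @param output_dir run directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(topology_path, ensemble_path = topology_path,
                       bias_path = NULL, regions_path,
                       temperature = 300,
                       cluster_algorithm = c("gromos", "hierarchical"),
                       cluster_cutoff = 0.15, contact_cutoff = 0.45,
                       dihedral_bins = 100, fes_bins = 50,
                       n_bootstrap = 20, frames_per_sample = NULL,
                       discard_fraction = 0.10, bias_col = "pb.bias",
                       loop = "CDR3", seed = 1,
                       output_dir = "cdrentropy_run") {
  cluster_algorithm <- match.arg(cluster_algorithm)
  stopifnot(cluster_cutoff > 0, contact_cutoff > 0, dihedral_bins >= 1,
            fes_bins >= 1, temperature > 0,
            discard_fraction >= 0, discard_fraction < 1)
  structure(
    list(topology_path = topology_path, ensemble_path = ensemble_path,
         bias_path = bias_path, regions_path = regions_path,
         temperature = temperature,
         cluster_algorithm = cluster_algorithm,
         cluster_cutoff = cluster_cutoff,
         contact_cutoff = contact_cutoff,
         dihedral_bins = dihedral_bins, fes_bins = fes_bins,
         n_bootstrap = n_bootstrap,
         frames_per_sample = frames_per_sample,
         discard_fraction = discard_fraction, bias_col = bias_col,
         loop = loop, seed = seed, output_dir = output_dir),
    class = "run_config"
  )
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  message("[", name, "] ...")
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full conformational-entropy pipeline
#'
#' Stages: load inputs, reweight (if a bias table is given), build the
#' loop C-alpha RMSD matrix, cluster, bootstrap the cluster entropy,
#' per-residue dihedral entropies, contact CVs + free-energy surface,
#' contact probability map, and split-half convergence. All outputs are
#' plain text (TSV/JSON) in `config$output_dir`, plus a `manifest.json`
#' recording package version, parameters, seed and input checksums. A
#' rerun with the same config is bit-identical.
#'
#' @param config a `run_config`.
#' @return the manifest (invisibly a list), with `output_dir` attribute.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  outputs <- character(0)

  top <- .stage("load", load_topology(config$topology_path))
  ens <- .stage("frames", load_ensemble(top, config$ensemble_path,
                                        config$temperature))
  regions <- load_regions(config$regions_path, top)
  loop_res <- region_residues(regions, config$loop)
  scaf_res <- region_residues(regions, "scaffold")

  if (!is.null(config$bias_path)) {
    ens <- .stage("weights", {
      bt <- load_bias_table(config$bias_path, config$bias_col)
      stride <- nrow(bt) %/% ens$n_frames
      attach_bias(ens, bt, stride = max(stride, 1))
    })
  }
  w <- ensemble_weights(ens)
  write_weights(w, out("weights.tsv"))
  outputs <- c(outputs, "weights.tsv")

  mat <- .stage("rmsd", rmsd_matrix(ens, loop_res))

  cl <- .stage("cluster", {
    f <- if (config$cluster_algorithm == "gromos") gromos_cluster else
      hierarchical_cluster
    f(mat, config$cluster_cutoff, weights = w)
  })
  write_cluster_result(cl, out("clusters"))
  outputs <- c(outputs, "clusters.tsv", "clusters.json")

  fps <- config$frames_per_sample %||% min(ens$n_frames, 10000)
  est <- .stage("entropy", bootstrap_cluster_entropy(
    ens, loop_res, config$cluster_cutoff, w,
    n_samples = config$n_bootstrap, frames_per_sample = fps,
    seed = config$seed, mat = mat))
  write_entropy_estimate(est, out("entropy.json"))
  prof <- dihedral_entropy_profile(ens, loop_res, w,
                                   config$dihedral_bins)
  write.table(prof, out("dihedral_entropy.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  outputs <- c(outputs, "entropy.json", "dihedral_entropy.tsv")

  cvs <- .stage("contacts", contact_cvs(ens, regions,
                                        cutoff = config$contact_cutoff,
                                        loop = config$loop))
  write.table(cvs, out("contact_cvs.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  cmap <- contact_probability_map(ens, loop_res, scaf_res, w,
                                  cutoff = config$contact_cutoff)
  write_grid(cmap, out("contact_map.tsv"))
  outputs <- c(outputs, "contact_cvs.tsv", "contact_map.tsv")

  fes <- .stage("fes", free_energy_surface(cvs, w, config$fes_bins,
                                           config$temperature))
  write_grid(fes, out("fes.tsv"))
  outputs <- c(outputs, "fes.tsv")

  conv <- .stage("converge", split_half_convergence(
    ens, loop_res, config$cluster_cutoff, w,
    discard_fraction = config$discard_fraction, mat = mat,
    seed = config$seed))
  write_convergence_report(conv, out("convergence"))
  outputs <- c(outputs, "convergence.tsv", "convergence.json")

  inputs <- Filter(Negate(is.null),
                   config[c("topology_path", "ensemble_path", "bias_path",
                            "regions_path")])
  manifest <- list(
    package = "cdrentropy",
    version = as.character(packageVersion("cdrentropy")),
    parameters = config[setdiff(names(config),
                                c("topology_path", "ensemble_path",
                                  "bias_path", "regions_path"))],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    n_frames = ens$n_frames,
    outputs = outputs
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(structure(manifest, output_dir = config$output_dir))
}
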