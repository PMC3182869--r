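#' Analysis configuration
#'
#' Bundles the tunable parameters of the whole pipeline with the standard
#' defaults: 15 A spring cutoff and uniform force constant for the network,
#' 20 low-frequency modes, 4 A heavy-atom contact cutoff for the
#' communication model, 0.5 overlap threshold for correspondence-slope
#' fits, and inverse-frequency exponent 1/2 for distance-variation maps.
#'
#' @param cutoff Spring cutoff (A).
#' @param gamma Uniform force constant.
#' @param n_modes Number of low-frequency modes analysed.
#' @param atom_cutoff Heavy-atom contact cutoff (A).
#' @param zero_mode_tol Relative zero-eigenvalue threshold.
#' @param overlap_threshold Minimum overlap entering slope fits.
#' @param inverse_frequency_exponent Exponent q in `lambda^-q` scaling of
#'   distance-variation maps.
#' @param seed Seed for the synthetic generators (analysis stages are
#'   deterministic).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(cutoff = 15, gamma = 1, n_modes = 20,
                            atom_cutoff = 4, zero_mode_tol = 1e-8,
                            overlap_threshold = 0.5,
                            inverse_frequency_exponent = 0.5, seed = 1) {
  stopifnot(cutoff > 0, atom_cutoff > 0, n_modes >= 1, gamma > 0)
  structure(list(cutoff = cutoff, gamma = gamma, n_modes = n_modes,
                 atom_cutoff = atom_cutoff, zero_mode_tol = zero_mode_tol,
                 overlap_threshold = overlap_threshold,
                 inverse_frequency_exponent = inverse_frequency_exponent,
                 seed = seed),
            class = "analysis_config")
}

as_structure <- function(x, chains = NULL) {
  if (inherits(x, "coarse_structure")) {
    if (!is.null(chains)) x <- select_residues(x, chains = chains)
    return(x)
  }
  read_structure(x, chains = chains)
}

write_manifest <- function(out_dir, config, inputs, outputs) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) return(invisible(NULL))
  manifest <- list(
    config = unclass(config),
    inputs = lapply(inputs, function(p)
      if (is.character(p) && file.exists(p))
        list(path = p, md5 = unname(tools::md5sum(p))) else "in-memory"),
    outputs = outputs,
    package_version = as.character(utils::packageVersion("oligodyn")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' End-to-end normal-mode analysis of one structure
#'
#' Builds the elastic network, computes the requested low-frequency modes,
#' the all-mode mobility profile and its hinge sites, and (optionally)
#' writes NMD/TSV outputs plus a reproducibility manifest.
#'
#' @param structure A `coarse_structure` or PDB path.
#' @param config An [analysis_config()].
#' @param chains Optional chain selection.
#' @param out_dir Optional output directory for NMD/TSV files.
#' @return List with `structure`, `network`, `modes`, `profile`, `hinges`.
#' @export
run_mode_analysis <- function(structure, config = analysis_config(),
                              chains = NULL, out_dir = NULL) {
  s <- as_structure(structure, chains)
  net <- build_network(s, cutoff = config$cutoff, gamma = config$gamma)
  modes <- compute_modes(net, n_modes = "all",
                         zero_tol = config$zero_mode_tol)
  profile <- ms_fluctuations(modes)
  profile$res_id <- s$residues$res_id
  hinges <- find_hinges(profile, window = 5)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    low <- modes
    keep <- seq_len(min(config$n_modes, length(modes$values)))
    low$values <- modes$values[keep]
    low$vectors <- modes$vectors[, keep, drop = FALSE]
    write_nmd(low, s, file.path(out_dir, "modes.nmd"))
    write_modes_tsv(low, file.path(out_dir, "modes.tsv"))
    write_profile_tsv(profile[, c("res_id", "msf")],
                      file.path(out_dir, "fluctuations.tsv"))
    write_manifest(out_dir, config, list(structure = structure),
                   c("modes.nmd", "modes.tsv", "fluctuations.tsv"))
  }
  list(structure = s, network = net, modes = modes, profile = profile,
       hinges = hinges)
}

#' Mode-conservation analysis of a component within an assembly
#'
#' Compares the low-frequency modes of an isolated component (set of
#' chains) with (i) the assembly modes restricted to the component's
#' residues and (ii) the component-in-assembly modes from the effective
#' Hessian. Returns overlap matrices, subspace overlaps and weighted
#' correspondence-slope fits.
#'
#' @param assembly A `coarse_structure` or PDB path of the full oligomer.
#' @param component_chains Chain ids forming the component.
#' @param config An [analysis_config()].
#' @param out_dir Optional output directory for TSV files.
#' @return List with mode sets, `overlap_isolated_vs_assembly`,
#'   `overlap_isolated_vs_embedded`, `subspace_overlap`, `slope_fit`.
#' @export
run_conservation_analysis <- function(assembly, component_chains,
                                      config = analysis_config(),
                                      out_dir = NULL) {
  s <- as_structure(assembly)
  part <- chain_partition(s, component_chains)
  comp <- select_residues(s, indices = part$S)

  net_full <- build_network(s, cutoff = config$cutoff, gamma = config$gamma)
  H <- build_hessian(net_full)
  modes_assembly <- compute_modes(H, zero_tol = config$zero_mode_tol,
                                  expected_zero = 6)
  modes_isolated <- anm_modes(comp, cutoff = config$cutoff,
                              gamma = config$gamma,
                              zero_tol = config$zero_mode_tol)
  modes_embedded <- subsystem_modes(H, part, zero_tol = config$zero_mode_tol)

  m <- min(config$n_modes, length(modes_isolated$values))
  n_asm <- min(config$n_modes, length(modes_assembly$values))
  n_emb <- min(config$n_modes, length(modes_embedded$values))

  M_asm <- overlap_matrix(modes_assembly, modes_isolated,
                          m = n_asm, n = m, restrict = part$S)
  # component modes as rows, assembly modes as columns (heat-map layout)
  M_asm <- structure(t(unclass(M_asm)),
                     class = c("overlap_matrix", "matrix", "array"))
  dimnames(M_asm) <- list(seq_len(m), seq_len(n_asm))
  M_emb <- overlap_matrix(modes_isolated, modes_embedded, m = m, n = n_emb)

  sso <- subspace_overlap(modes_assembly, modes_isolated, m = n_asm, n = m,
                          restrict = part$S, reference = "second")
  slope <- tryCatch(
    correspondence_slope(M_asm, threshold = config$overlap_threshold),
    error = function(e) NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(unclass(M_asm),
                       file.path(out_dir, "overlap_component_assembly.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(unclass(M_emb),
                       file.path(out_dir, "overlap_isolated_embedded.tsv"),
                       sep = "\t", quote = FALSE)
    write_manifest(out_dir, config, list(assembly = assembly),
                   c("overlap_component_assembly.tsv",
                     "overlap_isolated_embedded.tsv"))
  }
  list(modes_assembly = modes_assembly, modes_isolated = modes_isolated,
       modes_embedded = modes_embedded,
       overlap_isolated_vs_assembly = M_asm,
       overlap_isolated_vs_embedded = M_emb,
       subspace_overlap = sso, slope_fit = slope, partition = part)
}

#' Conformational-transition analysis between two states
#'
#' Forms the superposed deformation vector between states A and B over the
#' correspondence map, computes the modes of state A (optionally as a
#' subsystem of a larger assembly restricted to mapped residues), and
#' reports per-mode overlaps with the cumulative-overlap curve.
#'
#' @param a,b `coarse_structure` objects or PDB paths of the two states.
#' @param map Optional `correspondence_map` (or path to one); default
#'   identity.
#' @param config An [analysis_config()].
#' @param subsystem If TRUE, modes of A are computed for the mapped
#'   residues embedded in the rest of A via the effective Hessian (the
#'   workflow for comparing homologous proteins over aligned residues).
#' @return List with `deformation`, `modes`, `curve` (a `co_curve`
#'   tibble), `best_mode`.
#' @export
run_transition_analysis <- function(a, b, map = NULL,
                                    config = analysis_config(),
                                    subsystem = FALSE) {
  a <- as_structure(a); b <- as_structure(b)
  if (is.character(map)) map <- read_correspondence(map)
  if (is.null(map)) map <- identity_map(a, b)
  d <- deformation_vector(a, b, map)
  net <- build_network(a, cutoff = config$cutoff, gamma = config$gamma)
  full_map <- length(d$a_indices) == a$n
  if (subsystem && !full_map) {
    part <- make_partition(a$n, d$a_indices)
    modes <- subsystem_modes(build_hessian(net), part,
                             zero_tol = config$zero_mode_tol)
    restrict <- NULL
  } else {
    modes <- compute_modes(net, zero_tol = config$zero_mode_tol)
    restrict <- if (full_map) NULL else d$a_indices
  }
  m_max <- min(config$n_modes, length(modes$values))
  curve <- overlap_curve(modes, d, m_max = m_max, restrict = restrict)
  list(deformation = d, modes = modes, curve = curve,
       best_mode = curve$mode[which.max(curve$overlap)])
}

#' Intersubunit communication analysis
#'
#' Builds the heavy-atom contact Markov model and the per-residue
#' occurrence profile over all ordered residue pairs between two chains
#' (or explicit endpoint lists), plus the top maximum-likelihood pathways.
#'
#' @param structure A `coarse_structure` or PDB path.
#' @param chain_a,chain_b Chain ids of the two subunits, or residue-id
#'   vectors used verbatim as endpoint sets.
#' @param config An [analysis_config()].
#' @param n_top Number of highest-likelihood pathways to return.
#' @return List with `network`, `profile` (occurrence tibble), `top_paths`.
#' @export
run_communication_analysis <- function(structure, chain_a, chain_b,
                                       config = analysis_config(),
                                       n_top = 10) {
  s <- as_structure(structure)
  net <- markov_model(affinity_matrix(s, atom_cutoff = config$atom_cutoff))
  pick <- function(sel) {
    if (all(sel %in% unique(s$residues$chain))) {
      ids <- s$residues$res_id[s$residues$chain %in% sel]
    } else ids <- sel
    intersect(ids, net$res_id)
  }
  ids_a <- pick(chain_a); ids_b <- pick(chain_b)
  prof <- occurrence_profile(net, ids_a, ids_b)
  # highest-likelihood pathways over a subsample of endpoint pairs
  pairs <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE)
  if (nrow(pairs) > 200) pairs <- pairs[seq(1, nrow(pairs), length.out = 200), ]
  paths <- lapply(seq_len(nrow(pairs)), function(i)
    tryCatch(max_likelihood_path(net, pairs$a[i], pairs$b[i]),
             error = function(e) NULL))
  paths <- Filter(Negate(is.null), paths)
  ord <- order(vapply(paths, function(p) p$length, 1))
  list(network = net, profile = prof,
       top_paths = paths[utils::head(ord, n_top)])
}
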