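#' @include AllClasses.R synthetic.R interface.R conformation.R thermo.R contacts.R
NULL

.configGet <- function(config, key, required = FALSE, default = NULL) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  v <- config
  for (p in parts) {
    v <- v[[p]]
    if (is.null(v)) break
  }
  if (is.null(v)) {
    if (required)
      stop("config key '", key, "' is required", call. = FALSE)
    return(default)
  }
  v
}

.loadConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  config
}

# Load inputs for the interface pipeline: either on-disk files or a
# synthetic slab described in the config.
.pipelineInputs <- function(config) {
  syn <- .configGet(config, "synthetic")
  if (!is.null(syn)) {
    seed <- .configGet(config, "seed", default = 1)
    spec <- slabSpec(
      box = .configGet(syn, "box", default = c(8, 4, 4)),
      axis = .configGet(config, "interface.axis", default = "x"),
      interfaces = .configGet(syn, "interfaces", default = 4),
      mixingWidth = .configGet(syn, "mixingWidth", default = 0.3),
      nFrames = .configGet(syn, "nFrames", default = 20),
      seed = seed)
    ref <- makeTestProtein(.configGet(syn, "proteinAtoms", default = 60))
    lib <- makeOrientationLibrary(ref)
    prot <- pseudoProteinSpec(
      ref, library = lib, comProgram = "drift",
      comStart = .configGet(syn, "comStart", default = c(2, 2, 2)),
      comEnd = .configGet(syn, "comEnd", default = c(3, 2, 2)),
      orientations = .configGet(syn, "orientations",
                                default = orientationLabels(lib)[3]),
      noiseSigma = .configGet(syn, "noiseSigma", default = 0))
    sim <- makeSlabTrajectory(spec, prot)
    list(trajectory = sim$trajectory, topology = sim$topology,
         library = lib, groundTruth = sim$groundTruth,
         source = "synthetic")
  } else {
    structurePath <- .configGet(config, "input.structure", required = TRUE)
    trajPath <- .configGet(config, "input.trajectory")
    massMap <- unlist(.configGet(config, "input.massMap"))
    st <- readStructure(structurePath, massMap = massMap)
    traj <- if (is.null(trajPath)) st$trajectory
            else readTrajectory(trajPath, st$topology)
    sel <- atomData(st$topology)$species == "protein"
    lib <- NULL
    if (any(sel))
      lib <- makeOrientationLibrary(frameCoords(traj, 1)[sel, , drop = FALSE])
    list(trajectory = traj, topology = st$topology, library = lib,
         groundTruth = NULL, source = structurePath)
  }
}

#' Run the interface analysis pipeline
#'
#' Orchestrates the per-frame analyses on a slab trajectory: interface
#' localization, signed COM distance, orientation classification, RMSD,
#' regime-resolved RMSF and residue-distance profiles, density profiles
#' and spreading widths. Emits TSV tables plus a JSON run manifest (config
#' hash, package version, seed) into the output directory. Deterministic
#' for a fixed config and seed.
#'
#' Required config keys: \code{regime.close_nm}, \code{regime.near_nm},
#' \code{output.dir}, and either a \code{synthetic} block or
#' \code{input.structure}.
#'
#' @param config list or YAML file path.
#' @return (invisibly) list with the per-frame series, profiles and the
#'   written file paths.
#' @export
runInterfaceAnalysis <- function(config) {
  config <- .loadConfig(config)
  closeNm <- .configGet(config, "regime.close_nm", required = TRUE)
  nearNm <- .configGet(config, "regime.near_nm", required = TRUE)
  outDir <- .configGet(config, "output.dir", required = TRUE)
  thresholds <- regimeThresholds(closeNm, nearNm)
  axis <- .configGet(config, "interface.axis", default = "x")
  cutoff <- .configGet(config, "interface.cutoff_nm", default = 0.5)
  binWidth <- .configGet(config, "interface.bin_nm", default = 0.1)
  superpose <- .configGet(config, "rmsd.superpose", default = FALSE)
  inputs <- .pipelineInputs(config)
  nIfaces <- if (!is.null(inputs$groundTruth))
    ncol(inputs$groundTruth$interface) else
      .configGet(config, "interface.count", default = 1)
  pbc <- .configGet(config, "interface.pbc", default = nIfaces == 2)

  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  iface <- locateInterfaceHistogram(inputs$trajectory, inputs$topology,
                                    axis = axis, cutoff = cutoff,
                                    binWidth = binWidth, pbc = pbc)
  series <- conformationSeries(inputs$trajectory, inputs$topology, iface,
                               inputs$library, superpose = superpose)
  series$regime <- as.character(classifyRegime(series$distance, thresholds))
  perframe <- file.path(outDir, "perframe.tsv")
  write.table(series, perframe, sep = "\t", quote = FALSE,
              row.names = FALSE)

  rmsf <- rmsfProfile(inputs$trajectory, inputs$topology,
                      selection = which(atomData(inputs$topology)$species ==
                                          "protein"))
  rmsfPath <- file.path(outDir, "rmsf.tsv")
  write.table(rmsf, rmsfPath, sep = "\t", quote = FALSE, row.names = FALSE)

  resDist <- do.call(rbind, lapply(c("close", "near", "far"), function(rg)
    residueDistanceProfile(inputs$trajectory, inputs$topology, iface,
                           regime = rg, thresholds = thresholds)))
  resPath <- file.path(outDir, "residue_distance.tsv")
  write.table(resDist, resPath, sep = "\t", quote = FALSE,
              row.names = FALSE)

  prof <- densityProfile(inputs$trajectory, inputs$topology, axis = axis)
  profPath <- file.path(outDir, "density_profile.tsv")
  write.table(data.frame(center = profileCenters(prof),
                         profileDensity(prof), check.names = FALSE),
              profPath, sep = "\t", quote = FALSE, row.names = FALSE)

  width <- densityWidth(inputs$trajectory, inputs$topology, axis = axis)
  widthPath <- file.path(outDir, "width.tsv")
  write.table(data.frame(frame = seq_along(width) - 1L, width = width),
              widthPath, sep = "\t", quote = FALSE, row.names = FALSE)

  ifacePath <- file.path(outDir, "interface.tsv")
  writeInterfaceTable(iface, inputs$trajectory, ifacePath)

  manifest <- list(configHash = rlang::hash(config),
                   package = as.character(utils::packageVersion("slabtraj")),
                   seed = .configGet(config, "seed", default = 1),
                   source = inputs$source,
                   nFrames = nFrames(inputs$trajectory),
                   outputs = c(perframe, rmsfPath, resPath, profPath,
                               widthPath, ifacePath))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE)

  invisible(list(series = series, rmsf = rmsf, residueDistance = resDist,
                 profile = prof, width = width, interface = iface,
                 files = c(manifest$outputs, manifestPath),
                 groundTruth = inputs$groundTruth))
}

#' Run the contact analysis pipeline
#'
#' Computes the per-residue contact-frequency map over a docked-complex
#' ensemble (read from PDB files or generated synthetically from the
#' config), writes it as TSV and paints it into a PDB copy.
#'
#' Required config keys: \code{output.dir} and either
#' \code{ensemble.dir} / \code{ensemble.paths} or an
#' \code{ensemble.synthetic} block.
#'
#' @param config list or YAML file path.
#' @return (invisibly) list with the [ContactFrequencyMap-class], ground
#'   truth (if synthetic) and written paths.
#' @export
runContactAnalysis <- function(config) {
  config <- .loadConfig(config)
  outDir <- .configGet(config, "output.dir", required = TRUE)
  cutoff <- .configGet(config, "contacts.cutoff_nm", default = 0.5)
  syn <- .configGet(config, "ensemble.synthetic")
  gt <- NULL
  if (!is.null(syn)) {
    ens <- makeComplexEnsemble(
      nModels = .configGet(syn, "nModels", default = 10),
      receptorSize = .configGet(syn, "receptorSize", default = 20),
      ligandSize = .configGet(syn, "ligandSize", default = 10),
      plantedResidues = .configGet(syn, "plantedResidues",
                                   default = c(3, 7, 11)),
      contactRate = .configGet(syn, "contactRate", default = 0.5),
      seed = .configGet(config, "seed", default = 1))
    models <- ens$models
    gt <- ens$groundTruth
    receptorChains <- "R"; ligandChains <- "L"
  } else {
    src <- .configGet(config, "ensemble.paths",
                      default = .configGet(config, "ensemble.dir"))
    if (is.null(src))
      stop("config key 'ensemble.dir' (or 'ensemble.paths' or ",
           "'ensemble.synthetic') is required", call. = FALSE)
    models <- readEnsemble(src)
    receptorChains <- .configGet(config, "contacts.receptorChains",
                                 required = TRUE)
    ligandChains <- .configGet(config, "contacts.ligandChains",
                               required = TRUE)
  }
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  map <- contactFrequency(models, receptorChains, ligandChains, cutoff)
  tabPath <- file.path(outDir, "contacts.tsv")
  tab <- frequencyTable(map)
  tab$n_models <- map@nModels
  write.table(tab, tabPath, sep = "\t", quote = FALSE, row.names = FALSE)
  pdbPath <- file.path(outDir, "contacts_painted.pdb")
  paintContactMap(models[[1]], map, pdbPath)
  manifest <- list(configHash = rlang::hash(config),
                   package = as.character(utils::packageVersion("slabtraj")),
                   nModels = length(models), cutoff = cutoff,
                   outputs = c(tabPath, pdbPath))
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE)
  invisible(list(map = map, groundTruth = gt,
                 files = c(tabPath, pdbPath, manifestPath)))
}
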