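#' @include AllClasses.R io.R
NULL

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specification of a synthetic biphasic slab
#'
#' Describes a rectangular box half-filled (or interior-filled) with water
#' at one bulk density and with an organic solvent at another, separated by
#' one or two planar interfaces along a normal axis with a diffuse mixing
#' zone. Solvents are single-site particles whose masses set the particle
#' counts needed to reach the target mass densities.
#'
#' With one interface the water phase occupies \code{[0, x1)}; with two
#' interfaces it occupies the interior \code{[x1, x2)} so that the slab is
#' consistent under periodic wrapping (half-open \code{[0, L)} convention).
#'
#' @param box length-3 box edge lengths (nm).
#' @param axis interface normal axis (\code{"x"}, \code{"y"} or \code{"z"}).
#' @param interfaces 1 or 2 interface positions along the normal (nm),
#'   strictly inside the box.
#' @param waterDensity,organicDensity bulk mass densities (kg/m^3);
#'   defaults 997 and 1322.
#' @param mixingWidth width of the diffuse mixing zone (nm, >= 0); the
#'   species fraction follows a tanh ramp of this width. Default 0.3 nm.
#' @param waterMass,organicMass single-site particle masses (u).
#' @param nFrames number of frames to generate.
#' @param seed RNG seed (integer).
#' @return validated list of class \code{"SlabSpec"}.
#' @export
slabSpec <- function(box = c(8, 4, 4), axis = "x", interfaces = 4,
                     waterDensity = 997, organicDensity = 1322,
                     mixingWidth = 0.3, waterMass = 18, organicMass = 85,
                     nFrames = 5, seed = 1) {
  ax <- .axisIndex(axis)
  interfaces <- sort(as.numeric(interfaces))
  if (!length(interfaces) %in% 1:2)
    stop("1 or 2 interface positions required")
  if (any(interfaces <= 0) || any(interfaces >= box[ax]))
    stop("interface positions must lie strictly inside the box")
  if (length(interfaces) == 2L && diff(interfaces) <= 0)
    stop("two interfaces must be distinct")
  if (waterDensity <= 0 || organicDensity <= 0) stop("densities must be > 0")
  if (mixingWidth < 0) stop("mixing width must be >= 0")
  structure(list(box = as.numeric(box), axis = ax,
                 interfaces = interfaces, waterDensity = waterDensity,
                 organicDensity = organicDensity, mixingWidth = mixingWidth,
                 waterMass = waterMass, organicMass = organicMass,
                 nFrames = as.integer(nFrames), seed = as.integer(seed)),
            class = "SlabSpec")
}

# Water volume fraction along the normal coordinate.
.waterFraction <- function(x, interfaces, width) {
  if (length(interfaces) == 1L) {
    if (width <= 0) return(as.numeric(x < interfaces))
    0.5 * (1 - tanh(2 * (x - interfaces) / width))
  } else {
    if (width <= 0)
      return(as.numeric(x >= interfaces[1] & x < interfaces[2]))
    0.5 * (tanh(2 * (x - interfaces[1]) / width) -
           tanh(2 * (x - interfaces[2]) / width))
  }
}

# Stratified inverse-CDF positions along the normal: particle i draws its
# quantile uniformly from stratum [(i-1)/n, i/n), so any interval holds its
# expected count to within +/- 2 particles every frame while the jitter
# still varies frame to frame. `centers`/`weights` describe the (relative)
# density profile on a fine uniform grid of width `binw`.
.stratifiedPositions <- function(n, centers, weights, binw) {
  if (n == 0L) return(numeric(0))
  w <- weights / sum(weights)
  cdf <- cumsum(w)
  u <- (seq_len(n) - runif(n)) / n
  bin <- findInterval(u, cdf, left.open = TRUE) + 1L
  bin <- pmin(bin, length(w))
  lower <- c(0, cdf)[bin]
  left <- centers[bin] - binw / 2
  # linear placement within the bin; zero-weight bins are never selected
  left + (u - lower) / w[bin] * binw
}

#' Specification of a rigid pseudo-protein in a slab
#'
#' A rigid reference body whose per-frame pose is a library orientation plus
#' a centre-of-mass (COM) program, with optional internal Gaussian noise.
#' Stands in for a real protein so that distance tracking, orientation
#' classification and fluctuation analyses can be validated against known
#' ground truth.
#'
#' @param refCoords \code{[nAtoms, 3]} rigid reference coordinates (nm);
#'   centred on its COM internally.
#' @param library an [OrientationLibrary-class] built from
#'   \code{refCoords} (see [makeOrientationLibrary()]); default built here.
#' @param comProgram \code{"fixed"}, \code{"drift"} (linear COM
#'   interpolation from \code{comStart} to \code{comEnd}) or \code{"walk"}
#'   (Gaussian random walk with per-step sd \code{walkSigma}).
#' @param comStart,comEnd length-3 COM positions (nm).
#' @param walkSigma random-walk step sd (nm).
#' @param orientations orientation label per frame (recycled), drawn from
#'   the library labels.
#' @param noiseSigma internal (per-atom, per-coordinate) Gaussian noise sd
#'   (nm, >= 0).
#' @param masses per-atom masses (u), default 110 (residue-scale beads).
#' @param chain chain id for the protein atoms.
#' @return list of class \code{"PseudoProteinSpec"}.
#' @export
pseudoProteinSpec <- function(refCoords, library = makeOrientationLibrary(refCoords),
                              comProgram = c("fixed", "drift", "walk"),
                              comStart, comEnd = comStart, walkSigma = 0.05,
                              orientations = orientationLabels(library)[1],
                              noiseSigma = 0, masses = 110, chain = "P") {
  comProgram <- match.arg(comProgram)
  refCoords <- as.matrix(refCoords)
  if (nrow(refCoords) < 2L) stop("reference needs >= 2 atoms")
  if (noiseSigma < 0) stop("noise sigma must be >= 0")
  if (!all(orientations %in% orientationLabels(library)))
    stop("orientation labels must index the library")
  refCoords <- sweep(refCoords, 2, colMeans(refCoords))
  structure(list(refCoords = refCoords, library = library,
                 comProgram = comProgram, comStart = as.numeric(comStart),
                 comEnd = as.numeric(comEnd), walkSigma = walkSigma,
                 orientations = as.character(orientations),
                 noiseSigma = noiseSigma,
                 masses = rep_len(masses, nrow(refCoords)), chain = chain),
            class = "PseudoProteinSpec")
}

#' Deterministic asymmetric rigid test body
#'
#' A chiral, elongated bead spiral used as a stand-in protein in synthetic
#' slabs (one bead per residue). Deterministic; no RNG involved.
#'
#' @param nAtoms number of beads.
#' @param size overall extent scale (nm).
#' @return \code{[nAtoms, 3]} COM-centred coordinate matrix (nm).
#' @export
makeTestProtein <- function(nAtoms = 60, size = 1.0) {
  t <- seq_len(nAtoms) / nAtoms
  xyz <- cbind(1.0 * t * cos(4 * pi * t),
               0.7 * t * sin(4 * pi * t),
               1.6 * (t - 0.5)) * size
  sweep(xyz, 2, colMeans(xyz))
}

# Per-frame protein COM path.
.comPath <- function(protein, nFrames) {
  switch(protein$comProgram,
         fixed = matrix(protein$comStart, nFrames, 3, byrow = TRUE),
         drift = {
           f <- if (nFrames == 1L) 0 else (seq_len(nFrames) - 1) / (nFrames - 1)
           outer(1 - f, protein$comStart) + outer(f, protein$comEnd)
         },
         walk = {
           steps <- matrix(rnorm(3 * nFrames, sd = protein$walkSigma),
                           nFrames, 3)
           steps[1, ] <- 0
           sweep(apply(steps, 2, cumsum), 2, protein$comStart, `+`)
         })
}

# Signed distance of a point to the nearest interface along the normal,
# positive on the water side. `waterInterior` describes the generator's
# phase layout (ground-truth computation only).
.plantedSignedDistance <- function(comX, interfaces, L) {
  if (length(interfaces) == 1L) {
    interfaces - comX               # water on [0, x1): positive below x1
  } else {
    d1 <- .minImageDiff(comX - interfaces[1], L)
    d2 <- .minImageDiff(interfaces[2] - comX, L)
    inside <- d1 >= 0 & d2 >= 0     # inside the interior water slab
    nearer <- pmin(abs(d1), abs(d2))
    ifelse(inside, nearer, -nearer)
  }
}

#' Generate a synthetic slab trajectory with ground truth
#'
#' Builds solvent particles whose number profile along the normal follows
#' the spec's bulk densities joined by a tanh mixing ramp, plus an optional
#' rigid pseudo-protein with a planted COM program and orientation schedule.
#' Particle counts per fine bin are deterministic (largest-remainder
#' quotas), so bulk densities are reproduced to well within 1\%; positions
#' within bins are uniform random under the spec seed. Deterministic for a
#' fixed (spec, protein) pair.
#'
#' @param spec a [slabSpec()].
#' @param protein optional [pseudoProteinSpec()].
#' @return list with \code{trajectory} ([Trajectory-class]),
#'   \code{topology} ([Topology-class]) and \code{groundTruth} (list with
#'   per-frame \code{interface} matrix, \code{comDistance},
#'   \code{orientation}, plus the generating densities).
#' @examples
#' sim <- makeSlabTrajectory(slabSpec(nFrames = 2, seed = 7))
#' sim$trajectory
#' @export
makeSlabTrajectory <- function(spec, protein = NULL) {
  stopifnot(inherits(spec, "SlabSpec"))
  ax <- spec$axis
  L <- spec$box[ax]
  area <- prod(spec$box[-ax])
  binw <- 0.02
  nb <- max(50L, as.integer(ceiling(L / binw)))
  binw <- L / nb
  centers <- (seq_len(nb) - 0.5) * binw
  fw <- .waterFraction(centers, spec$interfaces, spec$mixingWidth)
  fo <- 1 - fw
  numDens <- function(rho, mass) rho / (.MASS_U_TO_KG_M3 * mass)  # per nm^3
  nW <- as.integer(round(numDens(spec$waterDensity, spec$waterMass) *
                           area * binw * sum(fw)))
  nO <- as.integer(round(numDens(spec$organicDensity, spec$organicMass) *
                           area * binw * sum(fo)))
  if (nW + nO == 0L) stop("spec yields zero solvent particles")

  protCoordsRef <- NULL
  nP <- 0L
  if (!is.null(protein)) {
    stopifnot(inherits(protein, "PseudoProteinSpec"))
    nP <- nrow(protein$refCoords)
    r <- max(sqrt(rowSums(protein$refCoords^2)))
    com <- rbind(protein$comStart, protein$comEnd)
    for (k in 1:3) {
      if (any(com[, k] - r < 0) || any(com[, k] + r > spec$box[k]))
        stop("protein does not fit in the box with clearance along axis ", k)
    }
  }

  tangential <- setdiff(1:3, ax)
  nTot <- nW + nO + nP
  coords <- array(0, c(nTot, 3, spec$nFrames))
  gtDist <- numeric(spec$nFrames)
  gtOrient <- character(spec$nFrames)

  .withSeed(spec$seed, {
    for (f in seq_len(spec$nFrames)) {
      xs <- .stratifiedPositions(nW, centers, fw, binw)
      xo <- .stratifiedPositions(nO, centers, fo, binw)
      frame <- matrix(0, nTot, 3)
      frame[seq_len(nW), ax] <- xs
      frame[nW + seq_len(nO), ax] <- xo
      for (k in tangential) {
        frame[seq_len(nW + nO), k] <- runif(nW + nO) * spec$box[k]
      }
      coords[, , f] <- frame
    }
    if (nP > 0L) {
      comPath <- .comPath(protein, spec$nFrames)
      labels <- rep_len(protein$orientations, spec$nFrames)
      for (f in seq_len(spec$nFrames)) {
        li <- match(labels[f], orientationLabels(protein$library))
        pc <- referenceCoords(protein$library, li)
        if (protein$noiseSigma > 0)
          pc <- pc + matrix(rnorm(length(pc), sd = protein$noiseSigma),
                            nrow(pc), 3)
        coords[nW + nO + seq_len(nP), , f] <-
          sweep(pc, 2, comPath[f, ], `+`)
      }
      comX <- vapply(seq_len(spec$nFrames), function(f)
        .com(coords[nW + nO + seq_len(nP), , f, drop = TRUE],
             protein$masses)[ax], 0)
      gtDist <- .plantedSignedDistance(comX, spec$interfaces, L)
      gtOrient <- labels
    }
  })

  top <- Topology(
    name = c(rep("OW", nW), rep("C1", nO), rep("CA", nP)),
    species = c(rep("water", nW), rep("organic", nO), rep("protein", nP)),
    mass = c(rep(spec$waterMass, nW), rep(spec$organicMass, nO),
             if (nP) protein$masses else numeric(0)),
    chain = c(rep("W", nW), rep("O", nO),
              if (nP) rep(protein$chain, nP) else character(0)),
    resid = c(seq_len(nW), seq_len(nO), seq_len(nP)),
    resname = c(rep("SOL", nW), rep("DCM", nO), rep("PRT", nP)))

  gt <- list(
    interface = matrix(rep(spec$interfaces, each = spec$nFrames),
                       spec$nFrames, length(spec$interfaces)),
    comDistance = if (nP) gtDist else NULL,
    orientation = if (nP) gtOrient else NULL,
    waterDensity = spec$waterDensity, organicDensity = spec$organicDensity,
    mixingWidth = spec$mixingWidth, axis = ax,
    nWater = nW, nOrganic = nO)

  list(trajectory = Trajectory(coords, spec$box,
                               as.numeric(seq_len(spec$nFrames) - 1L)),
       topology = top, groundTruth = gt)
}

#' Generate a pressure-tensor series with a planted surface tension
#'
#' The inverse of [surfaceTension()]: constructs diagonal pressure
#' components whose anisotropy along the normal equals
#' \code{tension * nInterfaces / boxLength}, split isotropically about
#' \code{basePressure}, plus iid Gaussian noise on each component. With
#' zero noise the estimator recovers the planted tension exactly.
#'
#' @param tension planted tension (bar nm).
#' @param boxLength box edge along the interface normal (nm).
#' @param nInterfaces 1 or 2.
#' @param nFrames number of frames.
#' @param noiseSd per-component Gaussian noise sd (bar).
#' @param seed RNG seed.
#' @param axis interface normal axis.
#' @param basePressure isotropic baseline (bar).
#' @return a [PressureSeries-class].
#' @export
makePressureSeries <- function(tension, boxLength = 10, nInterfaces = 2,
                               nFrames = 1000, noiseSd = 0, seed = 1,
                               axis = "x", basePressure = 1) {
  if (!nInterfaces %in% 1:2) stop("nInterfaces must be 1 or 2")
  if (boxLength <= 0) stop("box length must be positive")
  ax <- .axisIndex(axis)
  A <- tension * nInterfaces / boxLength
  P <- matrix(basePressure - A / 3, nFrames, 3)
  P[, ax] <- basePressure + 2 * A / 3
  if (noiseSd > 0)
    P <- P + .withSeed(seed, matrix(rnorm(3 * nFrames, sd = noiseSd),
                                    nFrames, 3))
  PressureSeries(data.frame(time = as.numeric(seq_len(nFrames) - 1L),
                            Pxx = P[, 1], Pyy = P[, 2], Pzz = P[, 3],
                            Lx = boxLength, Ly = boxLength, Lz = boxLength))
}

#' Generate a docked-complex ensemble with planted contacts
#'
#' Builds \code{nModels} two-chain bead models: receptor residues spaced
#' 1.5 nm apart (so a ligand atom near one residue cannot touch its
#' neighbours at any cutoff <= 0.7 nm), and a ligand whose atoms sit
#' \code{contactDistance} from each planted receptor residue in a
#' \code{contactRate} fraction of models (the first
#' \code{round(contactRate * nModels)}), and far from every receptor atom
#' otherwise. Non-planted residues are beyond the cutoff in all models.
#'
#' @param nModels ensemble size.
#' @param receptorSize,ligandSize residue counts per chain.
#' @param plantedResidues receptor residue indices planted as contacts.
#' @param contactRate fraction of models in which planted residues touch
#'   the ligand (0-1).
#' @param seed RNG seed (tangential jitter of ligand atoms).
#' @param contactDistance planted atom-atom contact distance (nm).
#' @return list with \code{models} (each a list \code{topology},
#'   \code{coords}, \code{box}) and \code{groundTruth}.
#' @export
makeComplexEnsemble <- function(nModels, receptorSize = 20, ligandSize = 10,
                                plantedResidues = c(3, 7, 11),
                                contactRate = 0.5, seed = 1,
                                contactDistance = 0.3) {
  if (contactRate < 0 || contactRate > 1) stop("contactRate must be in [0, 1]")
  if (!all(plantedResidues >= 1 & plantedResidues <= receptorSize))
    stop("planted residues must lie within the receptor")
  if (ligandSize < length(plantedResidues))
    stop("geometric placement infeasible: ligand has fewer atoms (",
         ligandSize, ") than planted residues (", length(plantedResidues), ")")
  spacing <- 1.5
  nContact <- as.integer(round(contactRate * nModels))
  recX <- (seq_len(receptorSize) - 1L) * spacing + 2
  box <- c(receptorSize * spacing + 4, 30, 10)
  top <- Topology(
    name = rep("CA", receptorSize + ligandSize),
    species = "protein", mass = 110,
    chain = c(rep("R", receptorSize), rep("L", ligandSize)),
    resid = c(seq_len(receptorSize), seq_len(ligandSize)),
    resname = "ALA")
  models <- .withSeed(seed, lapply(seq_len(nModels), function(m) {
    coords <- matrix(0, receptorSize + ligandSize, 3)
    coords[seq_len(receptorSize), 1] <- recX
    coords[seq_len(receptorSize), 2] <- 5
    coords[seq_len(receptorSize), 3] <- 5
    lig <- matrix(0, ligandSize, 3)
    lig[, 1] <- (seq_len(ligandSize) - 1L) * spacing + 2
    lig[, 2] <- 20
    lig[, 3] <- 5
    if (m <= nContact) {
      k <- length(plantedResidues)
      lig[seq_len(k), 1] <- recX[plantedResidues]
      lig[seq_len(k), 2] <- 5 + contactDistance
      lig[seq_len(k), 3] <- 5
    }
    coords[receptorSize + seq_len(ligandSize), ] <- lig
    list(topology = top, coords = coords, box = box)
  }))
  list(models = models,
       groundTruth = list(contactResidues = sort(plantedResidues),
                          contactRate = contactRate,
                          nContactModels = nContact, nModels = nModels))
}

#' Write ground truth as a JSON sidecar
#'
#' @param groundTruth ground-truth list from a generator.
#' @param path output path.
#' @export
writeGroundTruth <- function(groundTruth, path) {
  jsonlite::write_json(groundTruth, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a ground-truth JSON sidecar
#'
#' @param path path written by [writeGroundTruth()].
#' @return ground-truth list.
#' @export
readGroundTruth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(gt$interface) && is.null(dim(gt$interface)))
    gt$interface <- matrix(gt$interface, ncol = 1)
  gt
}
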