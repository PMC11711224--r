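#' @include geometry-core.R
NULL

.SPECIES <- c("water", "organic", "protein")

#' Per-atom topology table
#'
#' Labels every atom of a system with its species (\code{"water"},
#' \code{"organic"} or \code{"protein"}), chain, 1-based residue index,
#' residue name and mass in u. The species tag is what lets the interface
#' locators select solvent particles and the protein analyses select chains.
#'
#' @slot atoms data.frame with columns \code{atomId} (unique integer),
#'   \code{name}, \code{species}, \code{chain}, \code{resid} (1-based
#'   integer), \code{resname}, \code{mass} (u, > 0).
#' @seealso [Topology()] for construction, [readStructure()]
#' @exportClass Topology
setClass("Topology", representation(atoms = "data.frame"))

setValidity("Topology", function(object) {
  a <- object@atoms
  need <- c("atomId", "name", "species", "chain", "resid", "resname", "mass")
  if (!all(need %in% names(a)))
    return(paste("missing columns:", paste(setdiff(need, names(a)), collapse = ", ")))
  if (anyDuplicated(a$atomId)) return("atomId values must be unique")
  if (!all(a$species %in% .SPECIES))
    return(paste("species must be one of:", paste(.SPECIES, collapse = ", ")))
  if (any(!is.finite(a$mass)) || any(a$mass <= 0)) return("masses must be positive")
  if (any(a$resid < 1)) return("residue indices are 1-based")
  TRUE
})

#' Construct a Topology
#'
#' @param atomId unique integer atom ids (default sequential).
#' @param name atom names (e.g. \code{"CA"}, \code{"OW"}).
#' @param species per-atom species tag: \code{"water"}, \code{"organic"} or
#'   \code{"protein"}.
#' @param chain chain identifiers.
#' @param resid 1-based residue indices.
#' @param resname residue names.
#' @param mass atomic/particle masses in u.
#' @return A [Topology-class] object.
#' @examples
#' top <- Topology(name = c("OW", "C1"), species = c("water", "organic"),
#'                 mass = c(18, 85))
#' nAtoms(top)
#' @export
Topology <- function(name, species, mass, chain = "X",
                     resid = seq_along(name), resname = toupper(species),
                     atomId = seq_along(name)) {
  n <- length(name)
  atoms <- data.frame(atomId = as.integer(atomId),
                      name = as.character(name),
                      species = as.character(rep_len(species, n)),
                      chain = as.character(rep_len(chain, n)),
                      resid = as.integer(rep_len(resid, n)),
                      resname = as.character(rep_len(resname, n)),
                      mass = as.numeric(rep_len(mass, n)),
                      stringsAsFactors = FALSE)
  new("Topology", atoms = atoms)
}

#' Particle trajectory bound to a box
#'
#' Ordered frames of coordinates (nm) with per-frame orthorhombic box edge
#' lengths (nm) and times (ps). The atom count is constant across frames and
#' must match the [Topology-class] the trajectory is analysed with.
#'
#' @slot coords numeric array \code{[nAtoms, 3, nFrames]} in nm.
#' @slot box numeric matrix \code{[nFrames, 3]} of box edge lengths (nm).
#' @slot time numeric vector of frame times (ps), nondecreasing.
#' @seealso [Trajectory()], [readTrajectory()]
#' @exportClass Trajectory
setClass("Trajectory",
         representation(coords = "array", box = "matrix", time = "numeric"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an [nAtoms, 3, nFrames] array")
  if (nrow(object@box) != d[3] || ncol(object@box) != 3L)
    return("box must be an [nFrames, 3] matrix")
  if (length(object@time) != d[3]) return("time length must equal nFrames")
  if (any(!is.finite(object@box)) || any(object@box <= 0))
    return("box lengths must be positive and finite")
  if (is.unsorted(object@time)) return("frame times must be nondecreasing")
  if (any(!is.finite(object@coords))) return("coordinates must be finite")
  TRUE
})

#' Construct a Trajectory
#'
#' @param coords \code{[nAtoms, 3, nFrames]} array, or a single
#'   \code{[nAtoms, 3]} matrix for a one-frame trajectory (nm).
#' @param box per-frame box edge lengths: \code{[nFrames, 3]} matrix or a
#'   length-3 vector recycled over frames (nm).
#' @param time frame times in ps (default \code{0, 1, 2, ...}).
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(coords, box, time = NULL) {
  if (length(dim(coords)) == 2L) dim(coords) <- c(dim(coords), 1L)
  nf <- dim(coords)[3]
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  if (is.null(time)) time <- as.numeric(seq_len(nf) - 1L)
  new("Trajectory", coords = coords, box = box, time = as.numeric(time))
}

#' Per-frame interface plane positions
#'
#' Holds 1 or 2 interface positions per frame along the interface normal,
#' together with the method that produced them.
#'
#' @slot positions numeric matrix \code{[nFrames, nInterfaces]} (nm).
#' @slot axis integer 1-3, the interface normal axis.
#' @slot method \code{"histogram"}, \code{"gibbs"} or \code{"planted"}.
#' @slot cutoff cross-solvent proximity cutoff used (nm; \code{NA} for
#'   methods that do not use one).
#' @slot binWidth histogram bin width used (nm).
#' @exportClass InterfaceModel
setClass("InterfaceModel",
         representation(positions = "matrix", axis = "integer",
                        method = "character", cutoff = "numeric",
                        binWidth = "numeric"))

setValidity("InterfaceModel", function(object) {
  p <- object@positions
  if (!ncol(p) %in% 1:2) return("1 or 2 interfaces per frame supported")
  if (any(!is.finite(p))) return("interface positions must be finite")
  if (ncol(p) == 2L && any(abs(p[, 1] - p[, 2]) < 1e-9))
    return("two interfaces must be distinct")
  if (!object@axis %in% 1:3) return("axis must be 1, 2 or 3")
  if (!object@method %in% c("histogram", "gibbs", "planted"))
    return("unknown method tag")
  TRUE
})

#' Construct an InterfaceModel
#'
#' @param positions per-frame interface positions: numeric vector (one
#'   interface) or \code{[nFrames, 1 or 2]} matrix (nm).
#' @param axis interface normal axis.
#' @param method \code{"histogram"}, \code{"gibbs"} or \code{"planted"}.
#' @param cutoff,binWidth method parameters (nm), recorded as metadata.
#' @return an [InterfaceModel-class].
#' @export
InterfaceModel <- function(positions, axis, method, cutoff = NA_real_,
                           binWidth = NA_real_) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 1)
  new("InterfaceModel", positions = positions, axis = .axisIndex(axis),
      method = method, cutoff = as.numeric(cutoff),
      binWidth = as.numeric(binWidth))
}

#' Mass-density profile along the interface normal
#'
#' Uniform bins along one axis with per-species mass density in kg/m^3.
#'
#' @slot centers bin centres (nm).
#' @slot density matrix \code{[nBins, nSpecies]}, columns named by species.
#' @slot binWidth bin width (nm).
#' @slot axis integer 1-3.
#' @slot area box cross-section perpendicular to the axis (nm^2).
#' @exportClass DensityProfile
setClass("DensityProfile",
         representation(centers = "numeric", density = "matrix",
                        binWidth = "numeric", axis = "integer",
                        area = "numeric"))

setValidity("DensityProfile", function(object) {
  if (length(object@centers) != nrow(object@density))
    return("centers/density length mismatch")
  if (any(object@density < 0)) return("densities must be nonnegative")
  if (length(object@centers) > 1) {
    dd <- diff(object@centers)
    if (max(abs(dd - object@binWidth)) > 1e-6 * object@binWidth)
      return("bins must be uniform with spacing binWidth")
  }
  TRUE
})

#' Diagonal pressure-tensor time series
#'
#' Per-frame diagonal pressure components (bar) and box edge lengths (nm),
#' the inputs of the mechanical surface-tension estimator.
#'
#' @slot data data.frame with columns \code{time} (ps), \code{Pxx},
#'   \code{Pyy}, \code{Pzz} (bar), \code{Lx}, \code{Ly}, \code{Lz} (nm).
#' @exportClass PressureSeries
setClass("PressureSeries", representation(data = "data.frame"))

setValidity("PressureSeries", function(object) {
  need <- c("time", "Pxx", "Pyy", "Pzz", "Lx", "Ly", "Lz")
  if (!all(need %in% names(object@data)))
    return(paste("missing columns:", paste(setdiff(need, names(object@data)),
                                           collapse = ", ")))
  if (!all(vapply(object@data[need], function(x) all(is.finite(x)), TRUE)))
    return("pressure series values must be finite")
  TRUE
})

#' Construct a PressureSeries
#'
#' @param data data.frame with columns \code{time}, \code{Pxx}, \code{Pyy},
#'   \code{Pzz} (bar) and \code{Lx}, \code{Ly}, \code{Lz} (nm).
#' @return a [PressureSeries-class].
#' @export
PressureSeries <- function(data) new("PressureSeries", data = data)

#' Six-pose orientation reference library
#'
#' Six labelled reference coordinate sets for one protein, generated by 90
#' degree rotations of a base pose about two axes. Orientation
#' classification assigns each trajectory frame to the reference with the
#' smallest per-atom deviation after centre-of-mass alignment.
#'
#' @slot coords list of six \code{[nAtoms, 3]} matrices (nm), COM-centred.
#' @slot labels character labels, by convention
#'   \code{c("red","orange","yellow","green","blue","purple")}.
#' @seealso [makeOrientationLibrary()], [classifyOrientation()]
#' @exportClass OrientationLibrary
setClass("OrientationLibrary",
         representation(coords = "list", labels = "character"))

setValidity("OrientationLibrary", function(object) {
  if (length(object@coords) != length(object@labels))
    return("one label per reference")
  if (anyDuplicated(object@labels)) return("labels must be unique")
  n <- vapply(object@coords, nrow, 1L)
  if (length(unique(n)) != 1L)
    return("all references must share the atom count")
  TRUE
})

#' Per-residue cross-protein contact frequencies
#'
#' For every receptor residue, the fraction of ensemble models in which at
#' least one of its atoms lies within the cutoff of any partner-protein
#' atom.
#'
#' @slot table data.frame with columns \code{resid}, \code{chain},
#'   \code{frequency}.
#' @slot nModels ensemble size.
#' @slot cutoff contact cutoff (nm).
#' @seealso [contactFrequency()]
#' @exportClass ContactFrequencyMap
setClass("ContactFrequencyMap",
         representation(table = "data.frame", nModels = "integer",
                        cutoff = "numeric"))

setValidity("ContactFrequencyMap", function(object) {
  f <- object@table$frequency
  if (is.null(f)) return("table needs a frequency column")
  if (any(f < 0 | f > 1)) return("frequencies must lie in [0, 1]")
  if (object@nModels < 1L) return("ensemble size must be >= 1")
  TRUE
})

#' Surface-tension estimate from a pressure series
#'
#' @slot mean mean tension over frames (bar nm).
#' @slot se standard error by block averaging (bar nm).
#' @slot gamma per-frame tension values (bar nm).
#' @slot axis interface normal axis (integer 1-3).
#' @slot nInterfaces number of interfaces the estimate was divided by.
#' @slot nBlocks blocks used for the SE.
#' @seealso [surfaceTension()]
#' @exportClass TensionEstimate
setClass("TensionEstimate",
         representation(mean = "numeric", se = "numeric", gamma = "numeric",
                        axis = "integer", nInterfaces = "integer",
                        nBlocks = "integer"))

setValidity("TensionEstimate", function(object) {
  if (length(object@se) && is.finite(object@se) && object@se < 0)
    return("SE must be nonnegative")
  if (!object@nInterfaces %in% 1:2) return("nInterfaces must be 1 or 2")
  TRUE
})
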