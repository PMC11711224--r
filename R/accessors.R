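#' @include AllClasses.R
NULL

#' Accessors for slabtraj objects
#'
#' Small generic accessors used throughout the package instead of direct
#' slot access.
#'
#' @param x a slabtraj object.
#' @param i frame index.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("boxLengths", function(x, i) standardGeneric("boxLengths"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))
#' @rdname accessors
#' @export
setGeneric("atomMasses", function(x) standardGeneric("atomMasses"))
#' @rdname accessors
#' @export
setGeneric("atomSpecies", function(x) standardGeneric("atomSpecies"))
#' @rdname accessors
#' @export
setGeneric("interfacePositions", function(x, i) standardGeneric("interfacePositions"))
#' @rdname accessors
#' @export
setGeneric("normalAxis", function(x) standardGeneric("normalAxis"))

#' @rdname accessors
#' @export
setMethod("nAtoms", "Topology", function(x) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1])
#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3])
#' @rdname accessors
#' @export
setMethod("nFrames", "InterfaceModel", function(x) nrow(x@positions))
#' @rdname accessors
#' @export
setMethod("nFrames", "PressureSeries", function(x) nrow(x@data))

#' @rdname accessors
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) x@coords[, , i, drop = TRUE])
#' @rdname accessors
#' @export
setMethod("boxLengths", "Trajectory", function(x, i) {
  if (missing(i)) i <- 1L
  x@box[i, ]
})
#' @rdname accessors
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@time)

#' @rdname accessors
#' @export
setMethod("atomData", "Topology", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atomMasses", "Topology", function(x) x@atoms$mass)
#' @rdname accessors
#' @export
setMethod("atomSpecies", "Topology", function(x) x@atoms$species)

#' @rdname accessors
#' @export
setMethod("interfacePositions", "InterfaceModel", function(x, i) {
  if (missing(i)) return(x@positions)
  x@positions[i, ]
})
#' @rdname accessors
#' @export
setMethod("normalAxis", "InterfaceModel", function(x) x@axis)

#' @rdname accessors
#' @export
setGeneric("tensionMean", function(x) standardGeneric("tensionMean"))
#' @rdname accessors
#' @export
setMethod("tensionMean", "TensionEstimate", function(x) x@mean)
#' @rdname accessors
#' @export
setGeneric("tensionSE", function(x) standardGeneric("tensionSE"))
#' @rdname accessors
#' @export
setMethod("tensionSE", "TensionEstimate", function(x) x@se)

#' @rdname accessors
#' @export
setGeneric("frequencyTable", function(x) standardGeneric("frequencyTable"))
#' @rdname accessors
#' @export
setMethod("frequencyTable", "ContactFrequencyMap", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("orientationLabels", function(x) standardGeneric("orientationLabels"))
#' @rdname accessors
#' @export
setMethod("orientationLabels", "OrientationLibrary", function(x) x@labels)
#' @rdname accessors
#' @export
setGeneric("referenceCoords", function(x, i) standardGeneric("referenceCoords"))
#' @rdname accessors
#' @export
setMethod("referenceCoords", "OrientationLibrary", function(x, i) {
  if (missing(i)) return(x@coords)
  x@coords[[i]]
})

#' @rdname accessors
#' @export
setGeneric("pressureData", function(x) standardGeneric("pressureData"))
#' @rdname accessors
#' @export
setMethod("pressureData", "PressureSeries", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("profileDensity", function(x) standardGeneric("profileDensity"))
#' @rdname accessors
#' @export
setMethod("profileDensity", "DensityProfile", function(x) x@density)
#' @rdname accessors
#' @export
setGeneric("profileCenters", function(x) standardGeneric("profileCenters"))
#' @rdname accessors
#' @export
setMethod("profileCenters", "DensityProfile", function(x) x@centers)

setMethod("show", "Topology", function(object) {
  a <- object@atoms
  cat("Topology:", nrow(a), "atoms;",
      sum(a$species == "water"), "water,",
      sum(a$species == "organic"), "organic,",
      sum(a$species == "protein"), "protein\n")
  pc <- a[a$species == "protein", ]
  if (nrow(pc))
    cat("  protein chains:", paste(unique(pc$chain), collapse = ", "),
        "(", length(unique(paste(pc$chain, pc$resid))), "residues )\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", dim(object@coords)[1], "atoms x",
      dim(object@coords)[3], "frames; box[1] =",
      paste(signif(object@box[1, ], 4), collapse = " x "), "nm\n")
})

setMethod("show", "InterfaceModel", function(object) {
  cat("InterfaceModel (", object@method, "): ", nrow(object@positions),
      " frames, ", ncol(object@positions), " interface(s) along ",
      names(.AXES)[object@axis], "\n", sep = "")
  cat("  mean position(s):",
      paste(signif(colMeans(object@positions), 4), collapse = ", "), "nm\n")
})

setMethod("show", "TensionEstimate", function(object) {
  cat("TensionEstimate: ", signif(object@mean, 5), " +/- ",
      signif(object@se, 3), " bar nm (", length(object@gamma),
      " frames, ", object@nInterfaces, " interface(s), ",
      object@nBlocks, "-block SE)\n", sep = "")
})

setMethod("show", "ContactFrequencyMap", function(object) {
  cat("ContactFrequencyMap:", nrow(object@table), "receptor residues,",
      object@nModels, "models, cutoff", object@cutoff, "nm\n")
  cat("  residues with frequency > 0:", sum(object@table$frequency > 0), "\n")
})

setMethod("show", "OrientationLibrary", function(object) {
  cat("OrientationLibrary:", length(object@labels), "references (",
      paste(object@labels, collapse = ", "), "),",
      nrow(object@coords[[1]]), "atoms each\n")
})

setMethod("show", "DensityProfile", function(object) {
  cat("DensityProfile:", length(object@centers), "bins of",
      signif(object@binWidth, 4), "nm along", names(.AXES)[object@axis],
      "; species:", paste(colnames(object@density), collapse = ", "), "\n")
})

setMethod("show", "PressureSeries", function(object) {
  cat("PressureSeries:", nrow(object@data), "frames\n")
})
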