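#' @name accessors
#' @title Accessors for crowdbd objects
#'
#' @description Read access to the core S4 containers. \code{positions}
#' returns unwrapped coordinates; \code{wrappedPositions} maps them into
#' \code{[0, L)} and \code{imageCounts} returns the integer image counters
#' such that \code{unwrapped = wrapped + counts * boxLength}.
#'
#' @param object a \code{CGProtein}, \code{SystemState} or
#'   \code{BDTrajectory}.
#' @return The requested component (matrix, vector or scalar).
NULL

#' @rdname accessors
#' @export
setGeneric("nSpheres", function(object) standardGeneric("nSpheres"))
#' @rdname accessors
#' @export
setGeneric("sphereRadii", function(object) standardGeneric("sphereRadii"))
#' @rdname accessors
#' @export
setGeneric("sphereCenters", function(object) standardGeneric("sphereCenters"))
#' @rdname accessors
#' @export
setGeneric("boxLength", function(object) standardGeneric("boxLength"))
#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("wrappedPositions", function(object) standardGeneric("wrappedPositions"))
#' @rdname accessors
#' @export
setGeneric("imageCounts", function(object) standardGeneric("imageCounts"))
#' @rdname accessors
#' @export
setGeneric("molecules", function(object) standardGeneric("molecules"))
#' @rdname accessors
#' @export
setGeneric("proteinIds", function(object) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("diluteD", function(object) standardGeneric("diluteD"))
#' @rdname accessors
#' @export
setGeneric("frozenSpheres", function(object) standardGeneric("frozenSpheres"))
#' @rdname accessors
#' @export
setGeneric("bondTable", function(object) standardGeneric("bondTable"))
#' @rdname accessors
#' @export
setGeneric("angleTable", function(object) standardGeneric("angleTable"))
#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

# ---- CGProtein ----

#' @rdname accessors
setMethod("nSpheres", "CGProtein", function(object) nrow(object@centers))
#' @rdname accessors
setMethod("sphereRadii", "CGProtein", function(object) object@radii)
#' @rdname accessors
setMethod("sphereCenters", "CGProtein", function(object) object@centers)
#' @rdname accessors
setMethod("bondTable", "CGProtein", function(object)
  data.frame(i = object@bonds[, 1], j = object@bonds[, 2],
             length = object@bondLengths))
#' @rdname accessors
setMethod("angleTable", "CGProtein", function(object)
  data.frame(i = object@angles[, 1], vertex = object@angles[, 2],
             k = object@angles[, 3], angle = object@angleValues))

setMethod("show", "CGProtein", function(object) {
  cat("CGProtein", object@proteinId, "\n")
  cat("  spheres:", nSpheres(object),
      " radii (A):", paste(sprintf("%.2f", object@radii), collapse = ", "), "\n")
  cat("  MW:", object@molecularWeight, "kDa  copies:", object@copyNumber,
      if (object@tracer) " [tracer]" else "", "\n")
  cat("  topology:", nrow(object@bonds), "bonds,", nrow(object@angles), "angles\n")
})

# ---- SystemState ----

#' @rdname accessors
setMethod("nSpheres", "SystemState", function(object) nrow(object@positions))
#' @rdname accessors
setMethod("sphereRadii", "SystemState", function(object) object@radii)
#' @rdname accessors
setMethod("boxLength", "SystemState", function(object) object@boxLength)
#' @rdname accessors
setMethod("positions", "SystemState", function(object) object@positions)
#' @rdname accessors
setMethod("wrappedPositions", "SystemState", function(object)
  object@positions - object@boxLength * floor(object@positions / object@boxLength))
#' @rdname accessors
setMethod("imageCounts", "SystemState", function(object)
  floor(object@positions / object@boxLength))
#' @rdname accessors
setMethod("molecules", "SystemState", function(object) object@molecule)
#' @rdname accessors
setMethod("proteinIds", "SystemState", function(object) object@proteinId)
#' @rdname accessors
setMethod("diluteD", "SystemState", function(object) object@D0)
#' @rdname accessors
setMethod("frozenSpheres", "SystemState", function(object) object@frozen)
#' @rdname accessors
setMethod("bondTable", "SystemState", function(object)
  data.frame(i = object@bonds[, 1], j = object@bonds[, 2],
             length = object@bondLengths))
#' @rdname accessors
setMethod("angleTable", "SystemState", function(object)
  data.frame(i = object@angles[, 1], vertex = object@angles[, 2],
             k = object@angles[, 3], angle = object@angleValues))

setMethod("show", "SystemState", function(object) {
  cat("SystemState:", nSpheres(object), "spheres,",
      length(unique(object@molecule)), "molecules, box",
      object@boxLength, "A\n")
  occ <- sum(4 / 3 * pi * object@radii^3) / object@boxLength^3
  cat(sprintf("  occupied volume (no-overlap estimate): %.1f%%\n", 100 * occ))
  if (any(object@frozen)) cat("  frozen spheres:", sum(object@frozen), "\n")
})

# ---- BDConfig ----

setMethod("show", "BDConfig", function(object) {
  cat("BDConfig: box", object@boxLength, "A, dt", object@dt, "ns,",
      format(object@nSteps, big.mark = ","), "steps, save every",
      object@saveInterval, "ns\n")
  cat("  T =", object@temperature, "K, eta =", object@viscosity, "mPa s, seed",
      object@seed, "\n")
  cat("  HI:", object@hydrodynamics, " repulsion:", object@repulsion, "\n")
  cat("  k_s =", object@kStretch, "k_b =", object@kBend, "k_r =",
      object@kRepulse, "(kcal/mol; E = k x^2 convention)\n")
})

# ---- BDTrajectory ----

#' @rdname accessors
setMethod("nSpheres", "BDTrajectory", function(object) dim(object@frames)[2])
#' @rdname accessors
setMethod("sphereRadii", "BDTrajectory", function(object) object@radii)
#' @rdname accessors
setMethod("frames", "BDTrajectory", function(object) object@frames)
#' @rdname accessors
setMethod("frameTimes", "BDTrajectory", function(object) object@times)
#' @rdname accessors
setMethod("molecules", "BDTrajectory", function(object) object@molecule)
#' @rdname accessors
setMethod("proteinIds", "BDTrajectory", function(object) object@proteinId)
#' @rdname accessors
setMethod("boxLength", "BDTrajectory", function(object) object@config$boxLength)

setMethod("show", "BDTrajectory", function(object) {
  d <- dim(object@frames)
  cat("BDTrajectory:", d[1], "frames x", d[2], "spheres;",
      "t =", object@times[1], "..", object@times[d[1]], "ns\n")
  cat("  save interval:", if (d[1] > 1) diff(object@times)[1] else NA, "ns;",
      "HI:", isTRUE(object@config$hydrodynamics),
      " repulsion:", isTRUE(object@config$repulsion), "\n")
})
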