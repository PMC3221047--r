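#' @include AllClasses.R
NULL

#' Accessors for pattern-component objects
#'
#' Small accessor generics: \code{patternMatrix} returns the N x P data
#' matrix, \code{trialInfo} the per-trial metadata, \code{voxelCoords} the
#' voxel coordinates (or NULL), \code{designMatrix} the N x Q design,
#' \code{basisMatrices} the basis catalogue, \code{componentBlocks} the named
#' block partition, \code{componentNames} the component labels,
#' \code{Gmatrix} the (estimated or assembled) component covariance,
#' \code{noiseVariance} the noise variance, \code{thetaHat} the estimated
#' basis weights, \code{loglikTrace} the EM log-likelihood trace, and
#' \code{blup} the fitted Q x P BLUP pattern matrix.
#'
#' @param x an object of the appropriate class.
#' @return The slot contents, see Details.
#' @name accessors
#' @aliases patternMatrix trialInfo voxelCoords designMatrix basisMatrices
#'   componentBlocks componentNames Gmatrix noiseVariance thetaHat
#'   loglikTrace blup nTrials nVoxels conditions
NULL

#' @rdname accessors
#' @export
setGeneric("patternMatrix", function(x) standardGeneric("patternMatrix"))
#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))
#' @rdname accessors
#' @export
setGeneric("voxelCoords", function(x) standardGeneric("voxelCoords"))
#' @rdname accessors
#' @export
setGeneric("designMatrix", function(x) standardGeneric("designMatrix"))
#' @rdname accessors
#' @export
setGeneric("basisMatrices", function(x) standardGeneric("basisMatrices"))
#' @rdname accessors
#' @export
setGeneric("componentBlocks", function(x) standardGeneric("componentBlocks"))
#' @rdname accessors
#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))
#' @rdname accessors
#' @export
setGeneric("Gmatrix", function(x) standardGeneric("Gmatrix"))
#' @rdname accessors
#' @export
setGeneric("noiseVariance", function(x) standardGeneric("noiseVariance"))
#' @rdname accessors
#' @export
setGeneric("thetaHat", function(x) standardGeneric("thetaHat"))
#' @rdname accessors
#' @export
setGeneric("loglikTrace", function(x) standardGeneric("loglikTrace"))
#' @rdname accessors
#' @export
setGeneric("blup", function(x) standardGeneric("blup"))
#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("conditions", function(x) standardGeneric("conditions"))

#' @rdname accessors
setMethod("patternMatrix", "PatternDataset", function(x) x@Y)
#' @rdname accessors
setMethod("trialInfo", "PatternDataset", function(x) x@trialInfo)
#' @rdname accessors
setMethod("voxelCoords", "PatternDataset", function(x) x@coords)
#' @rdname accessors
setMethod("nTrials", "PatternDataset", function(x) nrow(x@Y))
#' @rdname accessors
setMethod("nVoxels", "PatternDataset", function(x) ncol(x@Y))
#' @rdname accessors
setMethod("conditions", "PatternDataset", function(x) x@trialInfo$condition)

#' @rdname accessors
setMethod("designMatrix", "ComponentModel", function(x) x@Z)
#' @rdname accessors
setMethod("basisMatrices", "ComponentModel", function(x) x@basis)
#' @rdname accessors
setMethod("componentBlocks", "ComponentModel", function(x) x@blocks)
#' @rdname accessors
setMethod("componentNames", "ComponentModel", function(x) x@componentNames)

#' @rdname accessors
setMethod("designMatrix", "PatternFit", function(x) x@model@Z)
#' @rdname accessors
setMethod("Gmatrix", "PatternFit", function(x) x@G)
#' @rdname accessors
setMethod("noiseVariance", "PatternFit", function(x) x@noiseVar)
#' @rdname accessors
setMethod("thetaHat", "PatternFit", function(x) x@theta)
#' @rdname accessors
setMethod("loglikTrace", "PatternFit", function(x) x@loglikTrace)
#' @rdname accessors
setMethod("blup", "PatternFit", function(x) x@Uhat)

setMethod("show", "PatternDataset", function(object) {
  cat("PatternDataset:", nrow(object@Y), "trials x", ncol(object@Y), "voxels\n")
  tab <- table(object@trialInfo$condition)
  cat("  conditions:", paste0(names(tab), " (", tab, ")", collapse = ", "), "\n")
  if ("run" %in% names(object@trialInfo))
    cat("  runs:", length(unique(object@trialInfo$run)), "\n")
  cat("  coordinates:", if (is.null(object@coords)) "none" else
    paste0(ncol(object@coords), "-d"), "\n")
})

setMethod("show", "ComponentModel", function(object) {
  cat("ComponentModel:", nrow(object@Z), "trials,", ncol(object@Z),
      "components,", length(object@basis), "free parameters\n")
  cat("  components:", paste(object@componentNames, collapse = ", "), "\n")
  cat("  blocks:", paste(names(object@blocks), collapse = ", "), "\n")
})

setMethod("show", "PatternFit", function(object) {
  cat("PatternFit (", if (object@converged) "converged" else "NOT converged",
      " after ", object@nIter, " EM iterations)\n", sep = "")
  cat("  log-likelihood:", format(tail(object@loglikTrace, 1L)), "\n")
  cat("  noise variance:", format(object@noiseVar, digits = 4), "\n")
  cat("  component variances:\n")
  v <- diag(object@G)
  names(v) <- object@model@componentNames
  print(round(v, 4))
})

setMethod("show", "SimilarityResult", function(object) {
  cat("SimilarityResult (", length(object@variances), " components",
      if (any(object@unstable)) paste0(", ", sum(object@unstable), " unstable"),
      ")\n", sep = "")
  cat("  corrected correlations:\n")
  print(round(object@corrected, 3))
})

setMethod("show", "SpatialEstimate", function(object) {
  cat("SpatialEstimate [", object@block, "]: s = ",
      format(object@s, digits = 4), ", FWHM = ",
      format(object@fwhm, digits = 4),
      if (object@flag != "ok") paste0(" (", object@flag, ")"), "\n", sep = "")
})

setMethod("show", "ScenarioTruth", function(object) {
  cat("ScenarioTruth:", ncol(object@model@Z), "components,",
      nrow(object@trialInfo), "trials, P =", object@nVoxels, "\n")
  cat("  noise variance:", object@noiseVar, "\n")
  if (length(object@targetCorrelations))
    cat("  target correlations:",
        paste0(names(object@targetCorrelations), " = ",
               object@targetCorrelations, collapse = ", "), "\n")
  if (!is.null(object@spatial))
    cat("  spatial SDs:",
        paste0(names(object@spatial$sPerBlock), " = ",
               object@spatial$sPerBlock, collapse = ", "),
        "; noise:", object@spatial$noiseS, "\n")
})
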