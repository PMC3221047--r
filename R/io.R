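#' @include AllClasses.R scenarios.R estimation.R similarity.R spatial.R
NULL

# write a table atomically (no partial files on failure) with a provenance
# header: tool version, seed and config digest
.writeTSV <- function(df, path, provenance = NULL) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  ok <- FALSE
  tryCatch({
    if (!is.null(provenance))
      writeLines(paste0("# ", names(provenance), ": ", unlist(provenance)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    ok <- TRUE
  }, finally = {
    close(con)
    if (!ok) unlink(tmp)
  })
  file.rename(tmp, path)
  invisible(path)
}

#' Read a trial-by-voxel dataset from delimited text
#'
#' Reads the data matrix (TSV with a header row, one row per trial), the
#' trial metadata (TSV with at least a \code{condition} column) and,
#' optionally, voxel coordinates (TSV with columns voxel, x, y, z or just
#' x, y, z). Shapes are validated against each other before the object is
#' built.
#'
#' @param dataPath path to the N x P data TSV.
#' @param metaPath path to the N-row trial metadata TSV.
#' @param coordsPath optional path to the P-row coordinates TSV.
#' @return A [PatternDataset-class].
#' @export
readPatternDataset <- function(dataPath, metaPath, coordsPath = NULL) {
  Y <- as.matrix(utils::read.delim(dataPath, check.names = FALSE,
                                   comment.char = "#"))
  if (!is.numeric(Y)) stop("data file contains non-numeric cells")
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE,
                            comment.char = "#")
  if (!"condition" %in% names(meta))
    stop("metadata must contain a 'condition' column")
  if ("trial" %in% names(meta) && anyDuplicated(meta$trial))
    stop("duplicate trial ids in metadata")
  if (nrow(meta) != nrow(Y))
    stop("shape mismatch: ", nrow(Y), " data rows vs ", nrow(meta),
         " metadata rows")
  coords <- NULL
  if (!is.null(coordsPath)) {
    cdf <- utils::read.delim(coordsPath, comment.char = "#")
    cols <- intersect(c("x", "y", "z"), names(cdf))
    if (length(cols) < 2) stop("coordinates need x, y (and usually z) columns")
    coords <- as.matrix(cdf[, cols, drop = FALSE])
    if (!is.numeric(coords)) stop("coordinates contain non-numeric cells")
    if (nrow(coords) != ncol(Y))
      stop("shape mismatch: ", ncol(Y), " voxels vs ", nrow(coords),
           " coordinate rows")
  }
  PatternDataset(Y, trialInfo = meta, coords = coords)
}

#' Write a dataset to delimited text
#'
#' Inverse of [readPatternDataset()]; full double precision is preserved.
#'
#' @param data a [PatternDataset-class].
#' @param dataPath,metaPath,coordsPath output paths (coordinates only
#'   written when present and a path is given).
#' @param provenance optional named list written as '#' header lines.
#' @return invisibly, the data path.
#' @export
writePatternDataset <- function(data, dataPath, metaPath, coordsPath = NULL,
                                provenance = NULL) {
  Y <- as.data.frame(data@Y)
  names(Y) <- paste0("v", seq_len(ncol(Y)))
  .writeTSV(format(Y, digits = 17, trim = TRUE, scientific = FALSE),
            dataPath, provenance)
  .writeTSV(data@trialInfo, metaPath, provenance)
  if (!is.null(coordsPath) && !is.null(data@coords)) {
    cdf <- as.data.frame(data@coords)
    names(cdf) <- c("x", "y", "z")[seq_len(ncol(cdf))]
    .writeTSV(cbind(voxel = seq_len(nrow(cdf)), cdf), coordsPath, provenance)
  }
  invisible(dataPath)
}

#' Serialise a fitted model to JSON
#'
#' Writes theta, parameter names, the dense G matrix, the noise variance,
#' the mean coefficients, the log-likelihood trace and the convergence flag.
#'
#' @param fit a [PatternFit-class].
#' @param path output path.
#' @param uhatPath optional TSV path for the BLUP pattern matrix.
#' @return invisibly, \code{path}.
#' @export
writeFit <- function(fit, path, uhatPath = NULL) {
  obj <- list(theta = fit@theta, param_names = fit@model@paramNames,
              G = fit@G, noise_var = fit@noiseVar, mean_coef = fit@meanCoef,
              loglik_trace = fit@loglikTrace, n_iter = fit@nIter,
              converged = fit@converged,
              component_names = fit@model@componentNames)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  if (!is.null(uhatPath)) {
    U <- as.data.frame(fit@Uhat)
    names(U) <- paste0("v", seq_len(ncol(U)))
    .writeTSV(cbind(component = fit@model@componentNames, U), uhatPath)
  }
  invisible(path)
}

#' Build a ComponentModel from a JSON specification
#'
#' The specification either names a builder (\code{one_factorial},
#' \code{common_pattern}, \code{factorial}) with its arguments, or supplies
#' an explicit design matrix \code{Z} and list of dense Q x Q basis
#' matrices.
#'
#' @param path path to the JSON model specification.
#' @return A [ComponentModel-class].
#' @export
readComponentModel <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(spec$builder)) {
    a <- spec$args
    return(switch(spec$builder,
      one_factorial = buildOneFactorial(a$n_levels, a$trials_per_level),
      common_pattern = buildCommonPattern(a$n_levels, a$trials_per_level,
        controlTrials = if (is.null(a$control_trials)) 0L else a$control_trials,
        anchorPairs = if (is.null(a$anchor_pairs)) list() else
          lapply(seq_len(nrow(a$anchor_pairs)), function(i) a$anchor_pairs[i, ])),
      factorial = buildFactorial(a$n_conditions, a$n_levels,
        trialsPerCell = if (is.null(a$trials_per_cell)) 5L else a$trials_per_cell,
        nRuns = a$n_runs),
      stop("unknown builder '", spec$builder, "'")))
  }
  Z <- as.matrix(spec$Z)
  basis <- if (is.array(spec$basis) && length(dim(spec$basis)) == 3L) {
    lapply(seq_len(dim(spec$basis)[1]), function(h)
      matrix(spec$basis[h, , ], dim(spec$basis)[2]))
  } else {
    lapply(spec$basis, as.matrix)
  }
  Q <- ncol(Z)
  new("ComponentModel", Z = Z, basis = basis,
      paramNames = if (!is.null(spec$param_names)) spec$param_names else
        paste0("theta", seq_along(basis)),
      blocks = if (!is.null(spec$blocks))
        lapply(spec$blocks, as.integer) else list(all = seq_len(Q)),
      componentNames = if (!is.null(spec$component_names))
        spec$component_names else paste0("comp", seq_len(Q)))
}

# ---- scenario-grid driver ---------------------------------------------------

.scenarioFuns <- list(
  one_factorial = scenarioOneFactorial,
  common_activation = scenarioCommonActivation,
  two_factorial = scenarioTwoFactorial,
  voxel_selection = scenarioVoxelSelection,
  spatial = scenarioSpatial
)

# matched / non-matched means from a cell x cell correlation matrix with
# "cond:level" dimnames
.crossCondMeans <- function(R) {
  cond <- sub(":.*$", "", rownames(R))
  lev <- sub("^.*:", "", rownames(R))
  conds <- unique(cond)
  i1 <- which(cond == conds[1]); i2 <- which(cond == conds[2])
  matched <- mean(vapply(lev[i1], function(l)
    R[i1[lev[i1] == l], i2[lev[i2] == l]], numeric(1)))
  nm <- R[i1, i2, drop = FALSE]
  nonmatched <- mean(nm[outer(lev[i1], lev[i2], "!=")])
  c(matched = matched, nonmatched = nonmatched)
}

# per-replicate estimators for each scenario family
.oneFactorialEstimators <- function(sim, fit, control = FALSE) {
  idx <- if (control) 2:4 else 1:3
  cc <- correctedCorrelations(fit)@corrected
  out <- c(corrected_r12 = cc[idx[1], idx[2]],
           corrected_r13 = cc[idx[1], idx[3]],
           corrected_r23 = cc[idx[2], idx[3]])
  lbl <- paste0("s", 1:3)
  R <- sampleCorrMeanPatterns(sim$data)[lbl, lbl]
  out <- c(out, sample_r12 = R[1, 2], sample_r13 = R[1, 3],
           sample_r23 = R[2, 3])
  if (control) {
    Rc <- controlSubtractedCorr(sim$data, "control")[lbl, lbl]
    out <- c(out, ctrlsub_r12 = Rc[1, 2], ctrlsub_r13 = Rc[1, 3],
             ctrlsub_r23 = Rc[2, 3])
  }
  out
}

.factorialEstimators <- function(sim, fit) {
  G <- fit@G
  bl <- fit@model@blocks
  b1 <- bl$level[1]; b2 <- bl$level[5]   # beta[1,1] and beta[2,1]
  corrected <- G[b1, b2] / sqrt(G[b1, b1] * G[b2, b2])
  sm <- .crossCondMeans(sampleCorrMeanPatterns(sim$data))
  ms <- .crossCondMeans(conditionMeanSubtractedCorr(sim$data))
  c(corrected_matched = corrected,
    sample_matched = sm[["matched"]],
    sample_diff = sm[["matched"]] - sm[["nonmatched"]],
    meansub_matched = ms[["matched"]])
}

.spatialEstimators <- function(sim, fit) {
  G <- fit@G
  out <- .factorialEstimators(sim, fit)
  est <- estimateSmoothness(fit, sim$data,
                            blocks = c("condition", "level", "noise"))
  c(out,
    corrected_alpha = G[1, 2] / sqrt(G[1, 1] * G[2, 2]),
    var_alpha1 = G[1, 1], var_alpha2 = G[2, 2],
    var_beta1 = G[3, 3], var_beta2 = G[7, 7],
    noise_var = fit@noiseVar,
    s_alpha = est$condition@s, s_beta = est$level@s, s_eps = est$noise@s)
}

#' Run a simulation scenario over a parameter grid
#'
#' For every grid point and replicate: draw a dataset from the scenario's
#' generative truth, fit the scenario's component model by EM, and compute
#' the corrected and naive similarity estimators (plus spatial smoothness
#' estimates for the spatial scenario). Replicate seeds are derived
#' deterministically from \code{seed}, so two runs with the same arguments
#' produce identical tables. Non-converged fits are kept (flagged in the
#' \code{converged} column), and the summary reports the convergence rate.
#'
#' @param scenario one of "one_factorial", "common_activation",
#'   "two_factorial", "voxel_selection", "spatial".
#' @param grid data.frame of scenario arguments, one row per grid point
#'   (e.g. \code{data.frame(noiseVar = c(0.5, 2, 5, 10))}); NULL for one
#'   point at the scenario defaults.
#' @param nReps replicates per grid point.
#' @param seed integer base seed.
#' @param fitOpts list of [emFit()] options; the driver defaults to
#'   \code{tol = 1e-8, maxIter = 2000}.
#' @param outDir optional directory for \code{results.tsv} and
#'   \code{summary.tsv} (written atomically with provenance headers).
#' @return list with \code{results} (tidy per-replicate table) and
#'   \code{summary} (mean, SE and convergence rate per grid point and
#'   estimator).
#' @export
runScenarioGrid <- function(scenario, grid = NULL, nReps = 10L, seed = 1L,
                            fitOpts = list(), outDir = NULL) {
  if (!scenario %in% names(.scenarioFuns)) stop("unknown scenario '", scenario, "'")
  fun <- .scenarioFuns[[scenario]]
  if (is.null(grid)) grid <- data.frame(.point = 1)[, 0, drop = FALSE]
  nG <- max(nrow(grid), 1L)
  opts <- utils::modifyList(list(tol = 1e-8, maxIter = 2000L), fitOpts)
  seeds <- .withSeed(seed, matrix(sample.int(.Machine$integer.max - 1L,
                                             nG * max(nReps, 1L)), nG))
  rows <- list()
  for (g in seq_len(nG)) {
    args <- as.list(grid[g, , drop = FALSE])
    for (r in seq_len(nReps)) {
      sim <- do.call(fun, c(args, list(seed = seeds[g, r])))
      fit <- emFit(sim$data, sim$truth@model, tol = opts$tol,
                   maxIter = opts$maxIter)
      est <- switch(scenario,
        one_factorial = .oneFactorialEstimators(sim, fit, control = FALSE),
        common_activation = .oneFactorialEstimators(sim, fit, control = TRUE),
        spatial = .spatialEstimators(sim, fit),
        .factorialEstimators(sim, fit))
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scenario, grid[g, , drop = FALSE], replicate = r,
        converged = fit@converged, estimator = names(est), value = unname(est),
        row.names = NULL, check.names = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scenario = character(), replicate = integer(),
               converged = logical(), estimator = character(),
               value = numeric())
  gcols <- names(grid)
  summary <- if (nrow(results)) {
    key <- interaction(results[, c(gcols, "estimator"), drop = FALSE],
                       drop = TRUE)
    agg <- do.call(rbind, lapply(split(results, key), function(d) {
      cbind(d[1, c("scenario", gcols, "estimator"), drop = FALSE],
            data.frame(mean = mean(d$value, na.rm = TRUE),
                       se = stats::sd(d$value, na.rm = TRUE) /
                         sqrt(sum(is.finite(d$value))),
                       n = nrow(d),
                       convergence_rate = mean(d$converged)))
    }))
    rownames(agg) <- NULL
    agg
  } else results
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    prov <- list(tool = paste0("patternComp ",
                   as.character(utils::packageVersion("patternComp"))),
                 scenario = scenario, seed = seed,
                 config = paste(utils::capture.output(utils::str(grid)),
                                collapse = " "))
    .writeTSV(results, file.path(outDir, "results.tsv"), prov)
    .writeTSV(summary, file.path(outDir, "summary.tsv"), prov)
  }
  list(results = results, summary = summary)
}
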