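## End-to-end orchestration: phantom (or input data) -> tensor fit -> FACT
## and Gibbs tracking -> quantification -> clustering, with all
## intermediates written in standard formats and a machine-readable report.
## Configuration is one declarative YAML file (or the equivalent list)
## mirroring the function arguments; every stage seed derives from the
## single global seed so a run is reproducible end to end.

#' Assemble a pipeline configuration
#'
#' Exactly one of \code{phantom} (a [PhantomSpec-class] or list of
#' [phantomSpec()] arguments) and \code{inputs} (named paths dwi, bval,
#' bvec, mask) must be given.
#'
#' @param phantom phantom specification (synthetic-data branch).
#' @param inputs named list of input paths (real-data branch).
#' @param outDir output directory.
#' @param seed global RNG seed.
#' @param fact list of [factParams()] overrides.
#' @param gibbs list of [gibbsParams()] overrides.
#' @param quant list: \code{planes} (each a list with origin and normal),
#'   \code{cosineOrder}, \code{binWidth}.
#' @param cluster list: \code{k}, \code{sigma}.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(phantom = NULL, inputs = NULL, outDir = tempfile("myotract"),
                           seed = 1L, fact = list(), gibbs = list(),
                           quant = list(), cluster = list()) {
  if (is.null(phantom) == is.null(inputs))
    stop("exactly one of 'phantom' and 'inputs' must be given")
  list(phantom = phantom, inputs = inputs, outDir = outDir,
       seed = as.integer(seed), fact = fact, gibbs = gibbs, quant = quant,
       cluster = cluster)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring [pipelineConfig()] fields.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y[intersect(names(y),
    c("phantom", "inputs", "outDir", "seed", "fact", "gibbs", "quant",
      "cluster"))])
}

#' Run the full reconstruction and quantification pipeline
#'
#' Stages, in order: data acquisition (phantom generation or loading),
#' tensor fit (FA, color map), FACT tracking, Gibbs global tracking,
#' tract quantification (slicing, cosine fits, heading histograms,
#' symmetry), spectral clustering. A stage failure is recorded in the
#' report and halts downstream stages. Deterministic given the global
#' seed.
#'
#' @param config from [pipelineConfig()] or [readPipelineConfig()].
#' @return the report list (also written to \code{report.json}).
#' @export
runPipeline <- function(config) {
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  report <- list(package = "myotract",
                 version = as.character(utils::packageVersion("myotract")),
                 seed = seed, stages = list())
  truth <- NULL
  failed <- FALSE
  record <- function(name, value) {
    report$stages[[name]] <<- value
  }
  runStage <- function(name, expr) {
    if (failed) { record(name, list(status = "skipped")); return(NULL) }
    tryCatch(expr, error = function(e) {
      failed <<- TRUE
      record(name, list(status = "failed", error = conditionMessage(e)))
      NULL
    })
  }

  ## -- stage: data -----------------------------------------------------------
  dat <- runStage("data", {
    if (!is.null(config$phantom)) {
      spec <- if (is(config$phantom, "PhantomSpec")) config$phantom else {
        args <- config$phantom
        if (is.null(args$seed)) args$seed <- seed
        do.call(phantomSpec, args)
      }
      gtab <- makeGradientScheme()
      truth <- makeGeometry(spec)   # stage exprs evaluate in this frame
      dwi <- simulateDWI(truth, spec, gtab)
      saveDWI(dwi, file.path(outDir, "dwi.nii.gz"))
      saveGradientTable(gtab, file.path(outDir, "dwi.bval"),
                        file.path(outDir, "dwi.bvec"))
      mask <- phantomMask(truth)
      saveMask(mask, file.path(outDir, "mask.nii.gz"))
      saveTracts(truth@tracts, file.path(outDir, "truth.tck"))
      record("data", list(status = "ok", source = "phantom",
                          kind = spec@geometryKind,
                          nTruthTracts = length(truth@tracts@tracts)))
      list(dwi = dwi, mask = mask, spec = spec)
    } else {
      gtab <- loadGradientTable(config$inputs$bval, config$inputs$bvec)
      dwi <- loadDWI(config$inputs$dwi, gtab)
      mask <- loadMask(config$inputs$mask, dwi)
      record("data", list(status = "ok", source = "files"))
      list(dwi = dwi, mask = mask, spec = NULL)
    }
  })

  ## -- stage: tensor ---------------------------------------------------------
  tf <- runStage("tensor", {
    tf <- fitTensor(dat$dwi, dat$mask)
    saveMap(tf@fa, dat$dwi@affine, file.path(outDir, "fa.nii.gz"))
    saveMap(colorFAMap(tf), dat$dwi@affine, file.path(outDir, "color_fa.nii.gz"))
    record("tensor", list(status = "ok", nValid = sum(tf@valid),
                          meanFA = mean(tf@fa[tf@valid])))
    tf
  })

  ## -- stage: fact -----------------------------------------------------------
  factTs <- runStage("fact", {
    p <- do.call(factParams, config$fact)
    raw <- factTrack(tf, dat$mask, p, seed = seed)
    saveTracts(raw, file.path(outDir, "fact.tck"))
    record("fact", list(status = "ok", nTracts = length(raw@tracts)))
    raw
  })

  ## -- stage: gibbs ----------------------------------------------------------
  gibbsRes <- runStage("gibbs", {
    gargs <- config$gibbs
    if (is.null(gargs$rngSeed)) gargs$rngSeed <- seed
    p <- do.call(gibbsParams, gargs)
    res <- gibbsTrack(dat$dwi, dat$mask, p)
    saveTracts(res$tracts, file.path(outDir, "gibbs.tck"))
    utils::write.csv(data.frame(step = seq_along(res$trace),
                                energy = res$trace),
                     file.path(outDir, "energy_trace.csv"), row.names = FALSE)
    tr <- res$trace
    n10 <- max(1L, floor(length(tr) / 10))
    record("gibbs", list(
      status = "ok", nParticles = nrow(res$config@particles),
      nTracts = length(res$tracts@tracts),
      energyStart = mean(tr[seq_len(n10)]),
      energyEnd = mean(tr[seq(length(tr) - n10 + 1L, length(tr))]),
      acceptance = as.list(res$accepted / pmax(res$attempted, 1L))))
    res
  })

  ## -- stage: quant ----------------------------------------------------------
  quantRes <- runStage("quant", {
    q <- config$quant
    order <- if (is.null(q$cosineOrder)) 9L else as.integer(q$cosineOrder)
    binWidth <- if (is.null(q$binWidth)) 10 else q$binWidth
    ts <- canonicalizeHeading(gibbsRes$tracts)
    planes <- q$planes
    sliceCounts <- if (!is.null(planes))
      lapply(planes, function(pl)
        nrow(sliceTracts(ts, slicePlane(pl$origin, pl$normal)))) else NULL
    fits <- lapply(ts@tracts, function(p)
      if (nrow(p) > order + 1L) fitCosineSeries(p, order) else NULL)
    rmse <- unlist(lapply(fits, function(f) if (!is.null(f)) mean(f@rmse)))
    out <- list(status = "ok",
                meanCosineRMSE = if (length(rmse)) mean(rmse) else NA_real_,
                sliceCounts = sliceCounts)
    record("quant", out)
    list(ts = ts, binWidth = binWidth)
  })

  ## -- stage: cluster --------------------------------------------------------
  runStage("cluster", {
    k <- if (is.null(config$cluster$k)) 2L else as.integer(config$cluster$k)
    sg <- if (is.null(config$cluster$sigma)) NA_real_ else config$cluster$sigma
    ts <- quantRes$ts
    if (length(ts@tracts) < max(3L, k)) stop("too few tracts to cluster")
    ts <- clusterTractSet(ts, k = k, sigma = sg, seed = seed)
    jsonlite::write_json(list(labels = ts@labels),
                         file.path(outDir, "cluster_labels.json"))
    sym <- headingSymmetry(ts)
    entry <- list(status = "ok", k = k,
                  sizes = as.list(table(ts@labels)),
                  headingSymmetryDeviation = as.list(sym$deviation))
    ## recovery metrics when truth is available
    if (!is.null(truth)) {
      tl <- matchToTruth(ts, truth)
      entry$purityVsTruth <- clusterPurity(ts@labels, tl)
      if (dat$spec@geometryKind == "purse_string")
        entry$oppositeHalfRate <- oppositeHalfRate(ts)
      if (dat$spec@geometryKind %in% c("crossing", "purse_string")) {
        hw <- dat$spec@geometryParams$bundleRadius
        entry$gibbsCrossingRate <- throughCrossingRate(ts, hw)$rate
        entry$factCrossingRate <-
          if (!is.null(factTs)) throughCrossingRate(factTs, hw)$rate else NA
      }
    }
    record("cluster", entry)
    NULL
  })

  report$status <- if (failed) "failed" else "ok"
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)
  invisible(report)
}
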