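#' Run the full pipeline from a configuration
#'
#' Executes simulate (or load) -> preprocess -> fit -> evaluate ->
#' interpret, writing every artifact plus a manifest under `outDir`. One
#' global seed fans out to per-stage seeds (stage-name hashed) so stages
#' are individually reproducible; every numerical decision (eps, the
#' scaled rho and mu, k, tolerances) is logged. Rerunning the same
#' configuration reproduces the same report.
#'
#' @param config A named list or the path of a YAML file with (optional)
#'   sections `simulate` (arguments of [simulateMultiOmics()], plus
#'   `scenario` in `base`, `mixed_rna`, `mixed_both`, `sparse`, `rare`
#'   and its parameters), `input` (`container` path, used instead of
#'   `simulate`), `preprocess` (arguments of [preprocessDataset()]),
#'   `fit` (arguments of [modelConfig()], plus `method = "ot"` or
#'   `"nmf"`), `evaluate` (`kNeighbors`, `resolutions`), and a global
#'   `seed`.
#' @param outDir Output directory.
#' @return Invisibly, a list with the fitted model, the evaluation report
#'   and the manifest.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 0L
  stageSeed <- function(stage)
    (seed * 1009L + sum(utf8ToInt(stage))) %% 1000000L

  manifest <- list(seed = seed, stages = list())
  stage <- "simulate"
  ds <- tryCatch({
    if (!is.null(config$input$container)) {
      stage <- "input"
      d <- readDataset(config$input$container)
      manifest$stages$input <- list(
        container = config$input$container,
        hash = unname(tools::md5sum(file.path(config$input$container,
                                              "manifest.json"))))
      d
    } else {
      sim <- config$simulate
      if (is.null(sim)) sim <- list()
      scenario <- if (is.null(sim$scenario)) "base" else sim$scenario
      sim$scenario <- NULL
      sim$seed <- stageSeed("simulate")
      d <- do.call(simulateMultiOmics, sim)
      d <- switch(scenario,
                  base = d,
                  mixed_rna = mixInRNA(d, seed = stageSeed("mix")),
                  mixed_both = mixInBoth(d, seed = stageSeed("mix")),
                  sparse = addDropout(d, p = if (is.null(config$simulate$p))
                    0.5 else config$simulate$p, seed = stageSeed("dropout")),
                  rare = rarePopulation(d, seed = stageSeed("rare")),
                  stop("unknown scenario '", scenario, "'"))
      manifest$stages$simulate <- c(sim, list(scenario = scenario))
      d
    }
  }, error = function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE))

  stage <- "preprocess"
  res <- tryCatch({
    pp <- if (is.null(config$preprocess)) list() else config$preprocess
    dsP <- do.call(preprocessDataset, c(list(dataset = ds), pp))
    manifest$stages$preprocess <- pp
    dsP
  }, error = function(e) stop("stage 'preprocess' failed: ",
                              conditionMessage(e), call. = FALSE))

  stage <- "fit"
  model <- tryCatch({
    fit <- if (is.null(config$fit)) list() else config$fit
    method <- if (is.null(fit$method)) "ot" else fit$method
    fit$method <- NULL
    if (is.null(fit$seed)) fit$seed <- stageSeed("fit")
    if (method == "nmf") {
      k <- if (is.null(fit$k)) 30 else fit$k
      mdl <- integrativeNMF(res, k = k, seed = fit$seed)
    } else {
      cfg <- do.call(modelConfig, fit)
      sc <- scaleRegularization(cfg, res)
      message(sprintf(
        "fit: k=%d eps=%g mu=%.3g rho=[%s] innerTol=%g lossRTol=%g",
        cfg$k, cfg$eps, sc$mu,
        paste(sprintf("%s=%.3g", names(sc$rho), sc$rho), collapse = ", "),
        cfg$innerTol, cfg$lossRTol))
      mdl <- fitFactorModel(res, cfg)
    }
    manifest$stages$fit <- c(fit, list(method = method))
    writeFactorModel(mdl, file.path(outDir, "model"))
    mdl
  }, error = function(e) stop("stage 'fit' failed: ",
                              conditionMessage(e), call. = FALSE))

  report <- NULL
  if (length(cellLabels(res))) {
    report <- tryCatch({
      ev <- if (is.null(config$evaluate)) list() else config$evaluate
      ev$seed <- stageSeed("evaluate")
      rep <- do.call(evaluateModel,
                     c(list(model = model, labels = cellLabels(res)), ev))
      jsonlite::write_json(
        list(silhouette = rep$silhouette, maxARI = rep$maxARI,
             knnPurity = rep$knnPurity, ariCurve = rep$ariCurve,
             specificity = rep$specificity),
        file.path(outDir, "report.json"), auto_unbox = TRUE,
        pretty = TRUE, digits = NA, dataframe = "columns")
      manifest$stages$evaluate <- ev
      rep
    }, error = function(e) stop("stage 'evaluate' failed: ",
                                conditionMessage(e), call. = FALSE))
  }

  tryCatch({
    exportInterpretation(model, file.path(outDir, "interpretation"))
    manifest$stages$interpret <- list(dir = "interpretation")
  }, error = function(e) stop("stage 'interpret' failed: ",
                              conditionMessage(e), call. = FALSE))

  # embedding export for external plotting
  utils::write.csv(t(embedding(model)),
                   file.path(outDir, "embedding.csv"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(model = model, report = report, manifest = manifest))
}
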