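# Run configuration and the staged pipeline driver.

#' Default run configuration
#'
#' A complete, self-contained configuration that runs the whole pipeline on
#' the default synthetic phantom. Every block can be overridden from a
#' YAML/JSON file (see [readRunConfig()]): population parameters, osteotomy
#' geometry, materials, the spring table, solver schedule/tolerances, mesh
#' paths and the seed.
#'
#' @return nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    paths = list(mesh = NULL, landmarks = NULL, outDir = "cranio-out"),
    phantom = list(ofd = 125, bpd = 96, height = 80, skinThickness = 2.8,
                   skullThickness = 2.5, meshResolution = 3, jitter = 0),
    population = list(skinThickness = 2.8, skullThickness = 2.5,
                      alpha = 83, beta = 68, abFrac = 0.30, lpFrac = 0.25,
                      sutureWidth = 2, nSubjects = 8),
    osteotomy = list(lateralOffset = 25, kerf = 1, anteriorExtent = 0.34,
                     posteriorExtent = 0.76, notchFractions = c(0.25, 0.75)),
    materials = list(
      skull = list(youngsModulus = 421, poisson = 0.22, pronyG = 0.5,
                   pronyTau = 3e4),
      suture = list(youngsModulus = 8, poisson = 0.45, pronyG = 0.5,
                    pronyTau = 3e4)),
    springs = list(anterior = "S12", posterior = "S12"),
    springTable = defaultSpringTable(),
    schedule = list(tPostop = 1, tEnd = 432000, nRamp = 5, nLog = 40),
    solver = list(tol = 1e-6, maxIter = 40))
}

#' Read a run configuration (YAML or JSON)
#'
#' Values present in the file override [defaultRunConfig()]; everything
#' else keeps its default.
#'
#' @param path configuration file, `.yaml`/`.yml` or `.json`.
#' @return nested named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: missing config: %s", path))
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop(sprintf("I/O error: unsupported config format '%s'", ext)))
  cfg <- modifyList(defaultRunConfig(), user)
  for (p in c("mesh", "landmarks"))
    if (!is.null(cfg$paths[[p]]) && !file.exists(cfg$paths[[p]]))
      stop(sprintf("config error: referenced file missing: %s",
                   cfg$paths[[p]]))
  cfg
}

.cfgPop <- function(cfg) {
  p <- cfg$population
  populationParams(p$skinThickness, p$skullThickness,
                   sutureGeometry(p$alpha, p$beta, p$abFrac, p$lpFrac),
                   p$sutureWidth)
}

.cfgMaterials <- function(cfg) {
  lapply(cfg$materials, function(m)
    material(m$youngsModulus, m$poisson, as.numeric(m$pronyG %||% numeric(0)),
             as.numeric(m$pronyTau %||% numeric(0))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.cfgHash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = 12,
                              force = TRUE, null = "null"), tf)
  unname(tools::md5sum(tf))
}

#' Run the surgical-planning pipeline
#'
#' Stages (any ordered subset, with dependencies enforced):
#' \describe{
#'   \item{synth}{write the phantom head mesh and landmark JSON into the
#'     output directory (skipped when `paths$mesh` points at a real scan).}
#'   \item{measure}{generate a synthetic two-layer population, measure
#'     thickness and suture geometry per subject, average -> population
#'     parameter JSON.}
#'   \item{build}{build the S model from the head surface and population
#'     parameters -> labeled model mesh + sidecar.}
#'   \item{simulate}{attach springs, assemble and solve the quasi-static
#'     expansion -> opening history CSV.}
#'   \item{report}{openings and BPD/OFD/CI at PREOP/POSTOP/FU -> summary
#'     JSON (deterministic: reruns with the same config are byte-identical).}
#' }
#'
#' @param config nested list from [defaultRunConfig()] / [readRunConfig()].
#' @param stages character vector of stage names.
#' @param verbose print per-stage progress.
#' @return invisible list of in-memory stage products (model, solution,
#'   summary, paths of written artifacts).
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        stages = c("synth", "measure", "build", "simulate",
                                   "report"),
                        verbose = FALSE) {
  allStages <- c("synth", "measure", "build", "simulate", "report")
  stages <- match.arg(stages, allStages, several.ok = TRUE)
  outDir <- config$paths$outDir %||% "cranio-out"
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  state <- list(artifacts = character(0))
  logLines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    logLines <<- c(logLines, msg)
    if (verbose) message(msg)
  }
  tic <- function() proc.time()[["elapsed"]]

  phSpec <- do.call(phantomSpec, c(config$phantom[
    intersect(names(config$phantom),
              c("ofd", "bpd", "height", "skinThickness", "skullThickness",
                "meshResolution", "jitter"))],
    list(suture = sutureGeometry(config$population$alpha,
                                 config$population$beta,
                                 config$population$abFrac,
                                 config$population$lpFrac),
         seed = config$seed)))

  if ("synth" %in% stages) {
    t0 <- tic()
    ph <- generateHead(phSpec)
    state$head <- ph
    mp <- file.path(outDir, "phantom_head.stl")
    lp <- file.path(outDir, "phantom_landmarks.json")
    writeMesh(ph$mesh, mp)
    writeLandmarks(ph$landmarks, lp)
    state$artifacts <- c(state$artifacts, mp, lp)
    note("stage synth: %d faces [%.1fs]", nFaces(ph$mesh), tic() - t0)
  }

  if ("measure" %in% stages) {
    t0 <- tic()
    n <- config$population$nSubjects %||% 8
    specs <- generatePopulation(n, seed = config$seed)
    meas <- lapply(specs, function(sp) {
      tl <- generateTwoLayer(sp)
      basePlane <- fitBasePlane(tl$landmarks$nasion, tl$landmarks$tragion_left,
                                tl$landmarks$tragion_right)
      crop <- cropPlaneAtFraction(tl$skin, basePlane, 0.25)
      frame <- anatomicalFrame(tl$landmarks$nasion, tl$landmarks$tragion_left,
                               tl$landmarks$tragion_right, mesh = tl$skin,
                               bregma = tl$landmarks$bregma,
                               lambdaPt = tl$landmarks$lambda,
                               abFrac = sp@suture@abFrac,
                               lpFrac = sp@suture@lpFrac)
      list(skin = thicknessBetween(tl$skin, tl$skullOuter, crop),
           skull = thicknessBetween(tl$skullOuter, tl$skullInner, crop),
           suture = measureSutureGeometry(frame))
    })
    pop <- populationAverage(meas, config$population$sutureWidth)
    state$measuredPop <- pop
    pj <- file.path(outDir, "population.json")
    jsonlite::write_json(list(
      skinThickness = pop@skinThickness, skullThickness = pop@skullThickness,
      alpha = pop@suture@alpha, beta = pop@suture@beta,
      abFrac = pop@suture@abFrac, lpFrac = pop@suture@lpFrac,
      sds = as.list(pop@sds)), pj, auto_unbox = TRUE, digits = 10)
    pc <- file.path(outDir, "measurements.csv")
    write.csv(data.frame(
      subject = seq_along(meas),
      skin = vapply(meas, function(m) m$skin@mean, 1),
      skull = vapply(meas, function(m) m$skull@mean, 1),
      alpha = vapply(meas, function(m) m$suture@alpha, 1),
      beta = vapply(meas, function(m) m$suture@beta, 1)), pc,
      row.names = FALSE)
    state$artifacts <- c(state$artifacts, pj, pc)
    note("stage measure: %d subjects [%.1fs]", n, tic() - t0)
  }

  if ("build" %in% stages) {
    t0 <- tic()
    if (!is.null(config$paths$mesh)) {
      mesh <- readMesh(config$paths$mesh)
      lmk <- readLandmarks(config$paths$landmarks)
    } else {
      if (is.null(state$head)) state$head <- generateHead(phSpec)
      mesh <- state$head$mesh
      lmk <- state$head$landmarks
    }
    ost <- do.call(osteotomySpec, config$osteotomy)
    model <- buildSModel(mesh, lmk, .cfgPop(config), ost)
    state$model <- model
    mp <- file.path(outDir, "s_model.stl")
    writeMesh(model@shell, mp)
    jsonlite::write_json(list(
      thickness = model@thickness, provenance = model@provenance,
      sutureWidth = model@sutureWidth,
      notchSets = model@notchSets,
      springs = names(config$springs)), paste0(mp, ".model.json"),
      auto_unbox = TRUE, digits = 10)
    state$artifacts <- c(state$artifacts, mp, paste0(mp, ".model.json"))
    note("stage build: %d faces, 5 regions [%.1fs]", nFaces(model@shell),
         tic() - t0)
  }

  if ("simulate" %in% stages) {
    if (is.null(state$model))
      stop("stage error: 'simulate' requires the 'build' stage")
    t0 <- tic()
    model <- attachSprings(state$model,
                           c(config$springs$anterior, config$springs$posterior),
                           as.data.frame(config$springTable))
    sys <- femAssemble(model, .cfgMaterials(config))
    sched <- do.call(femSchedule, config$schedule)
    sol <- solveQuasistatic(sys, model@springs, sched,
                            control = config$solver)
    state$model <- model
    state$solution <- sol
    oc <- file.path(outDir, "openings.csv")
    df <- data.frame(time_s = sol@timePoints, sol@openings)
    names(df)[-1] <- paste0("opening_", names(model@springs), "_mm")
    write.csv(df, oc, row.names = FALSE)
    for (nm in names(sol@deformedMeshes)) {
      dp <- file.path(outDir, sprintf("deformed_%s.stl", nm))
      writeMesh(sol@deformedMeshes[[nm]], dp)
      state$artifacts <- c(state$artifacts, dp)
    }
    state$artifacts <- c(state$artifacts, oc)
    note("stage simulate: %d time points [%.1fs]", length(sol@timePoints),
         tic() - t0)
  }

  if ("report" %in% stages) {
    if (is.null(state$solution))
      stop("stage error: 'report' requires the 'simulate' stage")
    t0 <- tic()
    rep <- extractOutputs(state$solution, state$model@frame)
    summary <- list(
      provenance = list(package = "SpringCranio",
                        version = as.character(packageVersion("SpringCranio")),
                        seed = config$seed, configHash = .cfgHash(config)),
      openings = rep$openings,
      metrics = rep$metrics,
      forceBalance = max(rep$diagnostics$balance))
    sj <- file.path(outDir, "summary.json")
    jsonlite::write_json(summary, sj, auto_unbox = TRUE, digits = 10,
                         dataframe = "rows")
    state$summary <- summary
    state$artifacts <- c(state$artifacts, sj)
    note("stage report: CI PREOP %.3f -> FU %.3f [%.1fs]",
         rep$metrics$ci[rep$metrics$timepoint == "PREOP"],
         rep$metrics$ci[rep$metrics$timepoint == "FU"], tic() - t0)
  }

  writeLines(logLines, file.path(outDir, "pipeline.log"))
  invisible(state)
}
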