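# End-to-end pipeline: validate -> media -> FBA -> FVA -> deletions ->
# comparisons -> reports, with a reproducible run manifest.

#' Run the full analysis pipeline
#'
#' Wires the stages together for a model and a set of media: model
#' validation and element-balance check, FBA and FVA per medium,
#' single-gene deletion essentiality classification across the media,
#' amino-acid supply/demand accounting in the last (richest) medium,
#' dead-end/blocked-reaction detection, and a manifest with parameters and
#' file hashes sufficient to re-run the pipeline identically. All tabular
#' outputs are TSV with headers; reports are JSON.
#'
#' @param model a [MetabolicModel-class].
#' @param media list of [MediumSpec-class] objects (>= 1; the deletion scan
#'   classifies conditional essentiality when >= 2).
#' @param outDir output directory (created if needed).
#' @param ngam NGAM maintenance floor, mmol gDCW^-1 h^-1.
#' @param threshold essentiality growth-ratio cutoff.
#' @param fvaReactions reaction ids for the FVA stage (default: all).
#' @param verbose print per-stage progress.
#' @return invisibly, a list with the stage results and the manifest.
#' @export
runPipeline <- function(model, media, outDir, ngam = 0, threshold = 0.05,
                        fvaReactions = NULL, verbose = TRUE) {
  t0 <- Sys.time()
  if (is(media, "MediumSpec")) media <- list(media)
  if (is.null(names(media)) || any(!nzchar(names(media))))
    names(media) <- vapply(media, function(m) m@name, character(1))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[thermoflux] ", ...)
  timings <- list()
  stage <- function(name, expr) {
    t <- Sys.time()
    say(name, " ...")
    out <- expr
    timings[[name]] <<- round(as.numeric(difftime(Sys.time(), t, units = "secs")), 3)
    out
  }

  stage("validate", {
    methods::validObject(model)
    bal <- checkMassBalance(model)
    if (any(bal$status == "imbalanced"))
      stop("element-imbalanced reaction(s): ",
           paste(bal$id[bal$status == "imbalanced"], collapse = ", "))
    NULL
  })

  sols <- list(); fvas <- list()
  stage("fba_fva", {
    for (nm in names(media)) {
      constrained <- applyMedium(model, media[[nm]], ngam = ngam)
      sols[[nm]] <- solveFBA(constrained)
      if (sols[[nm]]@status != "optimal")
        stop("FBA not optimal in medium '", nm, "': ", sols[[nm]]@status)
      fvas[[nm]] <- runFVA(constrained, reactions = fvaReactions,
                           zObj = sols[[nm]]@objective)
    }
    NULL
  })
  fluxTab <- data.frame(id = model@rxns$id, name = model@rxns$name,
                        stringsAsFactors = FALSE)
  for (nm in names(media)) {
    fluxTab[[paste0("flux_", nm)]] <- sols[[nm]]@fluxes[model@rxns$id]
  }
  writeTsv(fluxTab, file.path(outDir, "fluxes.tsv"))
  fvaTab <- NULL
  for (nm in names(media)) {
    rg <- fvas[[nm]]@ranges
    names(rg)[2:3] <- paste0(c("min_", "max_"), nm)
    fvaTab <- if (is.null(fvaTab)) rg else merge(fvaTab, rg, by = "id", sort = FALSE)
  }
  writeTsv(fvaTab, file.path(outDir, "fva.tsv"))

  report <- stage("deletions", {
    rep <- scanSingleDeletions(model, media, ngam = ngam)
    classifyEssentiality(rep, model = model, threshold = threshold)
  })
  essTab <- report@ratios
  essTab$class <- report@classification[essTab$gene]
  essTab$subsystems <- vapply(essTab$gene, function(g) {
    hit <- vapply(model@gprs, function(t) g %in% gprLeaves(t), logical(1))
    paste(unique(model@rxns$subsystem[hit]), collapse = ";")
  }, character(1))
  writeTsv(essTab, file.path(outDir, "essentiality.tsv"))

  balance <- stage("aa_balance", {
    nm <- names(media)[length(media)]
    constrained <- applyMedium(model, media[[nm]], ngam = ngam)
    aminoAcidBalance(sols[[nm]], constrained)
  })
  writeTsv(balance, file.path(outDir, "balance.tsv"))

  gaps <- stage("gaps", {
    de <- findDeadEnds(model)
    list(no_production = de$no_production,
         no_consumption = de$no_consumption,
         blocked_reactions = findBlockedReactions(model))
  })
  jsonlite::write_json(gaps, file.path(outDir, "gaps.json"), auto_unbox = FALSE)

  outputs <- c("fluxes.tsv", "fva.tsv", "essentiality.tsv", "balance.tsv",
               "gaps.json")
  manifest <- list(
    tool = "thermoflux",
    version = as.character(utils::packageVersion("thermoflux")),
    parameters = list(ngam = ngam, threshold = threshold),
    media = names(media),
    growth = lapply(sols, function(s) s@objective),
    output_hashes = as.list(tools::md5sum(file.path(outDir, outputs))),
    timings_sec = timings,
    finished = format(t0, "%Y-%m-%dT%H:%M:%S")
  )
  names(manifest$output_hashes) <- outputs
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: ", outDir)
  invisible(list(solutions = sols, fva = fvas, deletions = report,
                 balance = balance, gaps = gaps, manifest = manifest))
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
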