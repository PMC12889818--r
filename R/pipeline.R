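#' Read and validate a pipeline configuration
#'
#' The YAML config is a flat list of stage parameters plus an input mode.
#' Unknown keys are rejected so that typos cannot silently fall back to
#' defaults; the config round-trips losslessly through YAML.
#'
#' @param path YAML file path, or \code{NULL} to get the defaults.
#' @param overrides named list merged over the file's values.
#' @return a validated named list of parameters.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
    defaults <- list(
        mode = "simulate",
        cell_table = NULL, image = NULL, truth_dir = NULL,
        sample_id = "sample_1", genotype = "control",
        seed = 1,
        radius_um = 200, dormancy_cutoff = 8, pseudocount = 0.5,
        alpha = 0.05, k = 5, min_support = 20,
        top_fraction = 1e-4, smooth_radius_px = 4, min_area_px = 20,
        pixel_size = 0.284, reference_type = "CD8_T",
        exclude_types = character(), arithmetic = list(),
        nagq = 15, log_size = FALSE, reml = FALSE,
        simulate = list())
    cfg <- defaults
    if (!is.null(path)) {
        file <- yaml::read_yaml(path)
        unknown <- setdiff(names(file), names(defaults))
        if (length(unknown))
            stop("unknown config key(s): ",
                 paste(unknown, collapse = ", "), call. = FALSE)
        cfg[names(file)] <- file
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "),
             call. = FALSE)
    cfg[names(overrides)] <- overrides
    if (!cfg$mode %in% c("simulate", "cell-table", "images"))
        stop("mode must be simulate, cell-table or images", call. = FALSE)
    cfg
}

#' Validate pipeline inputs before any stage runs
#'
#' Checks panel/marker consistency, coordinate presence, genotype levels
#' and sample counts. Fatal problems are collected and reported together;
#' recoverable issues become warnings in the report.
#'
#' @param config list from \code{\link{readPipelineConfig}}.
#' @param panel a \linkS4class{MarkerPanel}.
#' @return list with \code{errors} and \code{warnings} character vectors;
#'   invisibly throws if any error when \code{strict}.
#' @param strict if \code{TRUE} (default) stop when fatal issues exist.
#' @export
validateInputs <- function(config, panel = defaultPanel(), strict = TRUE) {
    errors <- character(); warnings <- character()
    if (config$mode == "cell-table") {
        if (is.null(config$cell_table) || !file.exists(config$cell_table))
            errors <- c(errors, "cell_table path missing or nonexistent")
        else {
            cells <- utils::read.csv(config$cell_table, nrows = 50)
            need <- c("cell_id", "sample_id", "genotype", "x_um", "y_um",
                      "area_px")
            miss <- setdiff(need, names(cells))
            if (length(miss))
                errors <- c(errors, paste("cell table missing column(s):",
                                          paste(miss, collapse = ", ")))
            missM <- setdiff(markerNames(panel), names(cells))
            if (length(missM))
                errors <- c(errors,
                            paste("cell table missing MFI column(s):",
                                  paste(missM, collapse = ", ")))
            full <- utils::read.csv(config$cell_table)
            if (anyDuplicated(full$cell_id))
                errors <- c(errors, "duplicate cell_ids")
            if ("genotype" %in% names(full)) {
                ng <- length(unique(full$genotype))
                if (ng != 2)
                    errors <- c(errors, paste0("expected 2 genotype ",
                                               "levels, found ", ng))
                else {
                    perG <- tapply(full$sample_id, full$genotype,
                                   function(s) length(unique(s)))
                    if (any(perG < 2))
                        warnings <- c(warnings,
                            "single sample in a genotype: random effect inestimable, fixed-only fallback")
                }
            }
        }
    }
    if (config$mode == "images") {
        if (is.null(config$image) || !all(file.exists(unlist(config$image))))
            errors <- c(errors, "image path(s) missing or nonexistent")
        if (is.null(config$pixel_size) || !is.numeric(config$pixel_size))
            errors <- c(errors, "pixel_size missing in image mode")
    }
    if (strict && length(errors))
        stop("invalid pipeline inputs:\n  ",
             paste(errors, collapse = "\n  "), call. = FALSE)
    list(errors = errors, warnings = warnings)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (simulation, a cell-table CSV, or
#' image normalization + segmentation + measurement), phenotyping, lesion
#' definition, compositional niche analysis, and the three mixed models;
#' every intermediate table, the model fits, a provenance record and a log
#' are written under \code{outDir}. A stage failure aborts with the
#' failing stage named; outputs written so far are retained alongside a
#' \code{FAILED_<stage>} marker.
#'
#' @param config list from \code{\link{readPipelineConfig}}.
#' @param outDir output directory (created).
#' @param panel a \linkS4class{MarkerPanel}.
#' @return invisibly, a list with the main results (cells, assignments,
#'   lesionSet, niche, fits, summary).
#' @export
runPipeline <- function(config = readPipelineConfig(), outDir,
                        panel = defaultPanel()) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logFile <- file.path(outDir, "run.log")
    logMsg <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                                "\n", file = logFile, append = TRUE)
    stageName <- "validate"
    runStage <- function(name, expr) {
        stageName <<- name
        logMsg("stage:", name)
        tryCatch(expr, error = function(e) {
            writeLines(conditionMessage(e),
                       file.path(outDir, paste0("FAILED_", name)))
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
    }
    seed <- as.integer(config$seed)
    if (length(config$exclude_types))
        panel@excludeTypes <- as.character(config$exclude_types)

    validateInputs(config, panel)
    truth <- NULL
    cells <- runStage("input", {
        if (config$mode == "simulate") {
            simArgs <- config$simulate
            simArgs$seed <- seed
            simArgs$panel <- panel
            sim <- do.call(simConfig, simArgs)
            out <- generateCellTable(sim)
            truth <- out$truth
            writeSimulation(out, sim, file.path(outDir, "simulation"))
            out$cells
        } else if (config$mode == "cell-table") {
            readCellTable(config$cell_table, markers = markerNames(panel))
        } else {
            stacks <- as.list(unlist(config$image))
            recs <- lapply(seq_along(stacks), function(i) {
                raw <- readChannelStack(stacks[[i]])
                prep <- prepareStack(raw, config$arithmetic,
                                     config$top_fraction)
                lab <- segmentNuclei(getChannel(prep, "Hoechst"),
                                     minAreaPx = config$min_area_px,
                                     pixelSize = config$pixel_size)
                sid <- if (length(config$sample_id) >= i)
                    config$sample_id[[i]] else paste0("sample_", i)
                gt <- if (length(config$genotype) >= i)
                    config$genotype[[i]] else "control"
                rec <- measureCells(lab, prep, panel,
                                    config$smooth_radius_px,
                                    sampleId = sid, genotype = gt)
                rec$cell_id <- paste0(sid, "_", rec$cell_id)
                rec
            })
            do.call(rbind, recs)
        }
    })
    writeCellTable(cells, file.path(outDir, "cells.csv"))

    pheno <- runStage("phenotype",
        phenotypeCells(cells, panel, alpha = config$alpha,
                       minSupport = config$min_support, k = config$k,
                       seed = deriveSeed(seed, 2)))
    utils::write.csv(pheno$assignments,
                     file.path(outDir, "assignments.csv"),
                     row.names = FALSE)

    lesionSet <- runStage("lesions",
        buildLesionSet(cells, pheno$assignments, panel,
                       radius = config$radius_um,
                       dormancyCutoff = config$dormancy_cutoff))
    writeLesionTables(lesionSet, pheno$panel, outDir)
    lesionSummary <- summarizeLesions(lesionSet, cells,
                                      pheno$assignments, panel)
    utils::write.csv(lesionSummary[, setdiff(names(lesionSummary),
                                             "sizes")],
                     file.path(outDir, "sample_summary.csv"),
                     row.names = FALSE)

    niche <- runStage("niches", {
        nn <- nicheAnalysis(lesionSet, pheno$panel,
                            pseudocount = config$pseudocount,
                            referenceType = config$reference_type)
        utils::write.csv(nn$correlation,
                         file.path(outDir, "correlation.csv"))
        utils::write.csv(nn$pca$loadings,
                         file.path(outDir, "pc_loadings.csv"))
        lt <- lesionTable(lesionSet)
        lt$pc1 <- nn$pca$pc1[as.character(lt$lesion_id)]
        lt$module_niche <- NA_integer_
        utils::write.csv(lt, file.path(outDir, "lesions_scored.csv"),
                         row.names = FALSE)
        nn
    })

    fits <- runStage("models", {
        a <- pheno$assignments
        keep <- a$stage %in% c("matched", "regression")
        cellDat <- data.frame(
            is_tumor = as.integer(a$type[keep] == tumorType(panel)),
            genotype = cells$genotype[match(a$cell_id[keep],
                                            cells$cell_id)],
            sample_id = cells$sample_id[match(a$cell_id[keep],
                                              cells$cell_id)])
        lt <- lesionTable(lesionSet)
        lt$pc1 <- niche$pca$pc1[as.character(lt$lesion_id)]
        list(binomial = fitBinomialMixed(cellDat, nAGQ = config$nagq,
                                         seed = deriveSeed(seed, 3)),
             ztnb = fitZTNBMixed(lt, nAGQ = config$nagq,
                                 seed = deriveSeed(seed, 4)),
             gaussian = fitGaussianMixed(lt, response = "pc1",
                                         logSize = config$log_size,
                                         REML = config$reml,
                                         seed = deriveSeed(seed, 5)))
    })
    jsonlite::write_json(lapply(fits, fitRecord),
                         file.path(outDir, "model_fits.json"),
                         auto_unbox = TRUE, digits = NA)
    for (f in names(fits)) {
        sink(file.path(outDir, paste0("fit_", f, ".txt")))
        show(fits[[f]])
        sink()
    }

    prov <- list(package = "tumorNiche",
                 version = as.character(utils::packageVersion("tumorNiche")),
                 r_version = paste(R.version$major, R.version$minor,
                                   sep = "."),
                 seed = seed, config = config[!vapply(config, is.null,
                                                      logical(1))],
                 config_hash = fnvHash(yaml::as.yaml(
                     config[!vapply(config, is.null, logical(1))])))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    logMsg("done")
    invisible(list(cells = cells, truth = truth,
                   assignments = pheno$assignments,
                   thresholds = pheno$thresholds, panel = pheno$panel,
                   summary = pheno$summary, lesionSet = lesionSet,
                   lesionSummary = lesionSummary, niche = niche,
                   fits = fits))
}

# Polynomial rolling hash, hex string; provenance fingerprint for configs.
fnvHash <- function(s) {
    h <- 0
    for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
    sprintf("%08x", as.integer(h))
}
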