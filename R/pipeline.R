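#' Read a pipeline configuration file
#'
#' The pipeline is driven by a flat, human-editable YAML file; any key may
#' be overridden programmatically (or by CLI flags in the shipped script).
#' Recognised keys, with defaults in parentheses: `seed` (1), `radius` (3),
#' `alpha` (0.05), `resels` (estimated from the mask when absent),
#' `n_perm` (1000), `tfce_E` (0.5), `tfce_H` (2), `tfce_connectivity`
#' (26), `out_dir` ("."), `volumes_dir`, `mask`, `traits`; and for
#' `simulate`: `n_subjects` (20), `grid_shape` (24 24 24), `noise_sd` (1),
#' `smooth_fwhm` (3), `signal_scale` (1), `subject_sd` (0.1), `roi_lo`,
#' `roi_hi`, `roi_contrast`, `roi_subscale`, `roi_slope`.
#'
#' @param path YAML file.
#' @param overrides named list of keys overriding the file.
#' @return named list of configuration values with defaults filled in.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
    cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
    cfg[names(overrides)] <- overrides
    defaults <- list(seed = 1L, radius = 3, alpha = 0.05, n_perm = 1000L,
                     tfce_E = 0.5, tfce_H = 2, tfce_connectivity = 26L,
                     out_dir = ".", n_subjects = 20L,
                     grid_shape = c(24L, 24L, 24L), noise_sd = 1,
                     smooth_fwhm = 3, signal_scale = 1, subject_sd = 0.1)
    for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    cfg
}

# config hash + seed sidecar for reproducibility audits
.configSidecar <- function(cfg, path, extra = list()) {
    tmp <- tempfile(fileext = ".json")
    jsonlite::write_json(cfg[order(names(cfg))], tmp, auto_unbox = TRUE,
                         digits = NA)
    hash <- unname(tools::md5sum(tmp))
    unlink(tmp)
    jsonlite::write_json(c(list(config = cfg, config_md5 = hash,
                                seed = cfg$seed), extra),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(hash)
}

.msg <- function(...) message("[SearchlightMVPA] ", sprintf(...))

# load volumes + mask + traits as declared in a config
.loadInputs <- function(cfg) {
    if (is.null(cfg$mask)) stop("config error: key 'mask' is required")
    if (is.null(cfg$volumes_dir))
        stop("config error: key 'volumes_dir' is required")
    grid <- readMask(cfg$mask)
    traits <- NULL
    if (!is.null(cfg$traits)) {
        traits <- read.csv(cfg$traits, stringsAsFactors = FALSE)
        subjects <- traits$subject_id
    } else {
        f <- list.files(cfg$volumes_dir, pattern = "_pain\\.nii(\\.gz)?$")
        subjects <- sub("_pain\\.nii(\\.gz)?$", "", f)
    }
    maps <- readConditionMaps(cfg$volumes_dir, subjects, grid)
    list(grid = grid, maps = maps, traits = traits, subjects = subjects)
}

#' Pipeline stages
#'
#' Config-driven orchestration of the full analysis, mirroring the order
#' decode -> threshold -> dissimilarity -> trait correlation. Each stage is
#' idempotent for a fixed config and seed, logs its substantive parameters,
#' and writes a JSON sidecar with the config hash and seed next to every
#' output.
#'
#' * `pipelineSimulate()` writes a synthetic cohort (volumes + traits.csv).
#' * `pipelineClassify()` runs the decoding searchlight and writes the
#'   accuracy map, the [ThresholdSpec-class] JSON and the thresholded mask.
#' * `pipelineDissim()` writes per-subject dissimilarity maps, group means
#'   and the peak table.
#' * `pipelineCorrelate()` runs the 24-test trait-correlation battery and
#'   writes stat/tfce/1-p volumes and a summary CSV.
#' * `pipelineReport()` writes a plain-text run summary.
#'
#' @param cfg configuration list from [readPipelineConfig()].
#' @return each stage invisibly returns its main in-memory result.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipelineSimulate <- function(cfg) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    shape <- as.integer(cfg$grid_shape)
    grid <- volumeGrid(shape, mask = ellipsoidMask(shape))
    rois <- list()
    if (!is.null(cfg$roi_lo)) {
        rois <- list(list(
            name = "roi1",
            voxels = roiBlock(grid, as.integer(cfg$roi_lo),
                              as.integer(cfg$roi_hi)),
            contrast = cfg$roi_contrast %||% "pain_vs_control",
            subscale = cfg$roi_subscale %||% NA_character_,
            slope = cfg$roi_slope %||% 0
        ))
    }
    sc <- syntheticConfig(
        nSubjects = cfg$n_subjects, grid = grid, rois = rois,
        noiseSD = cfg$noise_sd, smoothFWHM = cfg$smooth_fwhm,
        signalScale = cfg$signal_scale, subjectSD = cfg$subject_sd,
        seed = cfg$seed)
    .msg("simulate: %d subjects, grid %s, seed %d", cfg$n_subjects,
         paste(shape, collapse = "x"), cfg$seed)
    coh <- generateCohort(sc)
    vdir <- file.path(cfg$out_dir, "volumes")
    writeConditionMaps(coh$maps, vdir)
    writeVolume(array(as.numeric(brainMask(grid)), dim = shape),
                file.path(cfg$out_dir, "mask.nii.gz"), grid = grid)
    write.csv(coh$traits, file.path(cfg$out_dir, "traits.csv"),
              row.names = FALSE)
    .configSidecar(cfg, file.path(cfg$out_dir, "simulate.json"),
                   list(stage = "simulate"))
    invisible(coh)
}

#' @rdname pipeline
#' @export
pipelineClassify <- function(cfg) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    inp <- .loadInputs(cfg)
    sphere <- sphereOffsets(cfg$radius)
    resels <- if (!is.null(cfg$resels)) as.integer(cfg$resels)
              else reselCount(inp$grid, sphere)
    nclass <- length(inp$subjects) * 3L
    spec <- thresholdSpec(nclass, resels = resels,
                          alphaNominal = cfg$alpha)
    .msg("classify: radius %g, alpha %.3g / %d resels = %.4g, k >= %d (%.1f%%), n_class %d",
         cfg$radius, cfg$alpha, resels, spec@alphaCorrected,
         spec@kCritical, 100 * spec@accuracyCritical, nclass)
    acc <- classificationSearchlight(inp$maps, sphere = sphere)
    accPath <- file.path(cfg$out_dir, "accuracy.nii.gz")
    writeVolume(acc, accPath)
    .writeSidecar(accPath, inp$grid,
                  list(statistic = "loso_accuracy", radius = cfg$radius,
                       seed = cfg$seed))
    writeThresholdSpec(spec, file.path(cfg$out_dir, "threshold_spec.json"))
    thr <- thresholdAccuracyMap(acc, spec)
    writeVolume(array(as.numeric(thr), dim = dim(thr)),
                file.path(cfg$out_dir, "accuracy_significant.nii.gz"),
                grid = inp$grid)
    .configSidecar(cfg, file.path(cfg$out_dir, "classify.json"),
                   list(stage = "classify"))
    invisible(list(accuracy = acc, spec = spec, significant = thr))
}

#' @rdname pipeline
#' @export
pipelineDissim <- function(cfg) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    inp <- .loadInputs(cfg)
    sphere <- sphereOffsets(cfg$radius)
    .msg("dissim: radius %g, %d subjects", cfg$radius,
         length(inp$subjects))
    dm <- dissimilaritySearchlight(inp$maps, sphere = sphere)
    cd <- colData(dm)
    for (i in seq_len(ncol(dm))) {
        f <- file.path(cfg$out_dir, paste0(cd$subject[i], "_",
                                           cd$contrast[i],
                                           "_dissim.nii.gz"))
        writeVolume(assay(dm)[, i], f, grid = inp$grid)
    }
    peaks <- list()
    for (ct in .CONTRASTS) {
        gm <- groupMeanDissimilarity(dm, ct)
        writeVolume(gm, file.path(cfg$out_dir, paste0(ct, "_mean.nii.gz")))
        pk <- reportPeaks(gm, threshold = cfg$peak_threshold %||% 1.5)
        pk$contrast <- if (nrow(pk)) ct else character(0)
        peaks[[ct]] <- pk
    }
    peaks <- do.call(rbind, peaks)
    write.csv(peaks, file.path(cfg$out_dir, "dissim_peaks.csv"),
              row.names = FALSE)
    .configSidecar(cfg, file.path(cfg$out_dir, "dissim.json"),
                   list(stage = "dissim"))
    invisible(list(dissim = dm, peaks = peaks))
}

#' @rdname pipeline
#' @export
pipelineCorrelate <- function(cfg) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    inp <- .loadInputs(cfg)
    if (is.null(inp$traits))
        stop("config error: key 'traits' is required for correlate")
    sphere <- sphereOffsets(cfg$radius)
    dm <- dissimilaritySearchlight(inp$maps, sphere = sphere)
    params <- tfceParams(cfg$tfce_E, cfg$tfce_H,
                         connectivity = as.integer(cfg$tfce_connectivity))
    .msg("correlate: %d perms, TFCE E=%g H=%g conn=%d, seed %d",
         cfg$n_perm, params@E, params@H, params@connectivity, cfg$seed)
    res <- runEmpathyCorrelations(dm, inp$traits, params = params,
                                  nPerm = as.integer(cfg$n_perm),
                                  seed = cfg$seed)
    for (nm in names(res)) {
        r <- res[[nm]]
        base <- file.path(cfg$out_dir, nm)
        writeVolume(r@stat, paste0(base, "_stat.nii.gz"), grid = r@grid)
        writeVolume(r@tfce, paste0(base, "_tfce.nii.gz"), grid = r@grid)
        writeVolume(r@fweInvP, paste0(base, "_fwe1mp.nii.gz"),
                    grid = r@grid)
    }
    summ <- summarizeStatResults(res, alpha = cfg$alpha)
    write.csv(summ, file.path(cfg$out_dir, "correlation_summary.csv"),
              row.names = FALSE)
    .configSidecar(cfg, file.path(cfg$out_dir, "correlate.json"),
                   list(stage = "correlate", n_perm = cfg$n_perm))
    invisible(list(results = res, summary = summ))
}

#' @rdname pipeline
#' @export
pipelineReport <- function(cfg) {
    out <- file.path(cfg$out_dir, "report.txt")
    lines <- c("SearchlightMVPA run report", strrep("=", 26), "")
    specFile <- file.path(cfg$out_dir, "threshold_spec.json")
    if (file.exists(specFile)) {
        sp <- jsonlite::read_json(specFile)
        lines <- c(lines, sprintf(
            "Decoding threshold: alpha %s / %s resels -> k >= %s (%.1f%% of %s)",
            sp$alpha_nominal, sp$resel_count, sp$k_critical,
            100 * sp$accuracy_critical, sp$n_classifications))
    }
    pkFile <- file.path(cfg$out_dir, "dissim_peaks.csv")
    if (file.exists(pkFile)) {
        pk <- read.csv(pkFile)
        lines <- c(lines, sprintf("Dissimilarity peaks above threshold: %d",
                                  nrow(pk)))
    }
    smFile <- file.path(cfg$out_dir, "correlation_summary.csv")
    if (file.exists(smFile)) {
        sm <- read.csv(smFile)
        sig <- sm[sm$n_significant > 0, , drop = FALSE]
        lines <- c(lines, sprintf(
            "Trait-correlation tests with FWE-significant voxels: %d of %d",
            nrow(sig), nrow(sm)))
        if (nrow(sig))
            lines <- c(lines, paste0("  ", sig$test, " (peak 1-p = ",
                                     signif(sig$peak_inv_p, 3), ")"))
    }
    writeLines(lines, out)
    invisible(out)
}
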