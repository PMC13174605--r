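#' Read and validate a pipeline run configuration
#'
#' The YAML configuration mirrors the module surface: a \code{simulate}
#' block (arguments of \code{\link{SimConfig}}) or an \code{inputs} block
#' (paths to matrix/map/lift/phenotype files), plus \code{seed},
#' \code{split_fraction}, \code{tier_rules}, \code{model} hyperparameters,
#' \code{stages} toggles and an output directory. Validation happens
#' before any stage runs.
#'
#' @param path YAML file path.
#' @return A validated config list of class \code{"proteoBridgeConfig"}.
#' @export
readRunConfig <- function(path) {
    stopIfNot(file.exists(path), sprintf("config file not found: %s", path))
    cfg <- yaml::read_yaml(path)
    validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a config list (as parsed from YAML).
#' @export
validateRunConfig <- function(cfg) {
    defaults <- list(seed = 1L, split_fraction = 0.75, qc_threshold = 0.10,
                     knn_k = 10L,
                     tier_rules = list(t_high = 0.7, t_mid = 0.4,
                                       t_low = 0.1),
                     model = list(), targets = NULL,
                     directions = c("A2B", "B2A"),
                     stages = list(fidelity = TRUE, consensus = TRUE,
                                   replication = FALSE))
    for (nm in names(defaults))
        if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    stopIfNot(!is.null(cfg$out_dir), "config needs an 'out_dir'")
    stopIfNot(cfg$split_fraction > 0 && cfg$split_fraction < 1,
              "split_fraction must be in (0, 1)")
    stopIfNot(all(cfg$directions %in% c("A2B", "B2A")),
              "directions must be among A2B, B2A")
    has_sim <- !is.null(cfg$simulate)
    has_inputs <- !is.null(cfg$inputs)
    stopIfNot(has_sim || has_inputs,
              "config needs a 'simulate' block or an 'inputs' block")
    if (has_inputs) {
        for (f in c("matrix_A", "matrix_B", "assay_map")) {
            stopIfNot(!is.null(cfg$inputs[[f]]),
                      sprintf("inputs block needs '%s'", f))
            stopIfNot(file.exists(cfg$inputs[[f]]),
                      sprintf("input file not found: %s", cfg$inputs[[f]]))
        }
        for (f in c("lift", "phenotypes"))
            if (!is.null(cfg$inputs[[f]]))
                stopIfNot(file.exists(cfg$inputs[[f]]),
                          sprintf("input file not found: %s", cfg$inputs[[f]]))
    }
    rl <- cfg$tier_rules
    do.call(TierRules, rl)  # validity check
    class(cfg) <- "proteoBridgeConfig"
    cfg
}

stageLog <- function(stage, t0, ...) {
    message(sprintf("[proteoBridge] %-12s %6.1fs  %s", stage,
                    as.numeric(Sys.time() - t0, units = "secs"),
                    paste0(...)))
}

#' Run the end-to-end bridging pipeline
#'
#' Executes (per config toggles): simulate -> harmonize -> split ->
#' train(A2B, B2A) -> impute -> fidelity -> consensus -> replication, and
#' writes tier tables, the distribution summary, a serialized copy of the
#' config and its hash into the output directory. Fully deterministic
#' under a fixed config.
#'
#' @param cfg a config list from \code{\link{readRunConfig}} /
#'   \code{\link{validateRunConfig}}, or a YAML path.
#' @return Invisibly, a list with the run artifacts (fidelity records per
#'   direction, consensus, report paths, truth when simulated).
#' @export
runPipeline <- function(cfg) {
    if (is.character(cfg)) cfg <- readRunConfig(cfg)
    if (!inherits(cfg, "proteoBridgeConfig")) cfg <- validateRunConfig(cfg)
    t0 <- Sys.time()
    out_dir <- cfg$out_dir
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    cfg_copy <- unclass(cfg)
    yaml::write_yaml(cfg_copy, file.path(out_dir, "run_config.yaml"))
    cfg_hash <- hashString(paste(utils::capture.output(utils::str(cfg_copy)),
                                 collapse = "\n"))
    writeLines(as.character(cfg_hash), file.path(out_dir, "config_hash.txt"))

    truth <- NULL; phenotypes <- NULL
    if (!is.null(cfg$simulate)) {
        sim_args <- cfg$simulate
        if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
        sim_cfg <- do.call(SimConfig, sim_args)
        truth <- simulateLatent(sim_cfg)
        rawA <- measurePlatform(truth, "A_aptamer")
        rawB <- measurePlatform(truth, "B_pea")
        phenotypes <- simulatePhenotypes(truth)
        mapA <- simAssayMap(truth, "A_aptamer")
        mapB <- simAssayMap(truth, "B_pea")
        stageLog("simulate", t0, sprintf("%d samples x %d proteins",
                                         sim_cfg@n_samples,
                                         sim_cfg@n_proteins))
    } else {
        rawA <- readMatrix(cfg$inputs$matrix_A, platform = "A_aptamer",
                           scale = "raw")
        rawB <- readMatrix(cfg$inputs$matrix_B, platform = "B_pea",
                           scale = "log2")
        map <- utils::read.table(cfg$inputs$assay_map, header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
        mapA <- map[map$platform == "A_aptamer", , drop = FALSE]
        mapB <- map[map$platform == "B_pea", , drop = FALSE]
        if (!is.null(cfg$inputs$lift)) {
            lift <- utils::read.table(cfg$inputs$lift, header = TRUE,
                                      sep = "\t", stringsAsFactors = FALSE)
            rawA <- liftPanel(rawA, lift)
        }
        if (!is.null(cfg$inputs$phenotypes))
            phenotypes <- utils::read.table(cfg$inputs$phenotypes,
                                            header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE)
        stageLog("read", t0, sprintf("A: %d assays, B: %d assays",
                                     length(assayIDs(rawA)),
                                     length(assayIDs(rawB))))
    }

    # Harmonize platform B: QC, duplicate resolution, KNN imputation.
    qcB <- qcMissingness(rawB, threshold = cfg$qc_threshold)
    qcB <- resolveDuplicates(qcB, mapB)
    impB <- knnImpute(qcB, k = cfg$knn_k)

    shared <- intersect(sampleIDs(rawA), sampleIDs(impB))
    stopIfNot(length(shared) >= 4L, "fewer than 4 shared samples after QC")
    split <- splitSamples(shared, fraction = cfg$split_fraction,
                          seed = cfg$seed)

    stdA <- log2Standardize(rawA[shared, ], fit_subset = split@train_ids)
    stdB <- log2Standardize(impB[shared, ], fit_subset = split@train_ids)
    emA <- stdA$matrix; emB <- stdB$matrix
    stageLog("harmonize", t0, sprintf("%d shared samples (%d train / %d test)",
                                      length(shared),
                                      length(split@train_ids),
                                      length(split@test_ids)))

    mapA <- mapA[mapA$assay_id %in% assayIDs(emA), , drop = FALSE]
    mapB <- mapB[mapB$assay_id %in% assayIDs(emB), , drop = FALSE]
    overlap <- buildOverlap(mapA, mapB)

    rules <- do.call(TierRules, cfg$tier_rules)
    spec <- do.call(ModelSpec, cfg$model)
    artifacts <- list(config = cfg_copy, truth = truth, overlap = overlap,
                      split = split)
    records_by_dir <- list()
    for (direction in cfg$directions) {
        src <- if (direction == "A2B") emA else emB
        dst <- if (direction == "A2B") emB else emA
        targets <- cfg$targets
        models <- trainDirection(src, dst, split, spec, seed = cfg$seed,
                                 targets = targets)
        imputed <- imputeValues(models, src, samples = split@test_ids)
        stageLog("train", t0, sprintf("%s: %d models", direction,
                                      length(models@models)))
        ov <- overlap
        dest_assays <- if (direction == "A2B") ov$assay_id_B else
            ov$assay_id_A
        ov <- ov[dest_assays %in% names(models@models), , drop = FALSE]
        base <- baselineCorrelation(emA, emB, ov,
                                    samples = split@train_ids)
        post <- postImputationCorrelation(imputed, src, ov,
                                          samples = split@test_ids)
        perf <- modelPerformance(imputed, dst, samples = split@test_ids)
        rec <- fidelityRecords(base, post, perf, direction = direction,
                               rules = rules)
        records_by_dir[[direction]] <- rec
        stageLog("fidelity", t0, sprintf("%s: %d records", direction,
                                         nrow(rec)))
    }
    all_rec <- do.call(rbind, records_by_dir)
    report <- tierReport(all_rec,
                         tsv_path = file.path(out_dir, "tier_table.tsv"),
                         json_path = file.path(out_dir,
                                               "tier_distribution.json"))
    artifacts$records <- records_by_dir
    artifacts$report <- report
    if (length(records_by_dir) == 2L && isTRUE(cfg$stages$consensus)) {
        cons <- consensusTiers(rollupBestAptamer(records_by_dir[[1L]]),
                               rollupBestAptamer(records_by_dir[[2L]]))
        utils::write.table(cons$per_protein,
                           file.path(out_dir, "tier_consensus.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        artifacts$consensus <- cons
        stageLog("consensus", t0,
                 sprintf("%.0f%% agreement", cons$overall_pct_agree))
    }
    if (isTRUE(cfg$stages$replication) && !is.null(phenotypes)) {
        phenotypes <- phenotypes[phenotypes$sample_id %in% shared, ,
                                 drop = FALSE]
        covs <- phenotypes[, c("age", "sex", "group"), drop = FALSE]
        scan <- phScan(emA[phenotypes$sample_id, ], covs,
                       time = phenotypes$time, event = phenotypes$event)
        utils::write.table(scan, file.path(out_dir, "ph_scan.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        artifacts$ph_scan <- scan
        stageLog("replication", t0,
                 sprintf("%d proteins scanned", nrow(scan)))
    }
    stageLog("done", t0, out_dir)
    invisible(artifacts)
}
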