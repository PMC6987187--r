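#' @include CtExperiment.R io.R screen.R deltact.R genorm.R normfinder.R
#' @include bestkeeper.R consensus.R ddct.R
NULL

.KNOWN_METHODS <- c("delta_ct", "genorm", "normfinder", "bestkeeper")

#' Build a pipeline run configuration
#'
#' Collects inputs and thresholds for [runPipeline()]. Defaults are the
#' conventional values throughout: 5 TPM expression floor, CV cutoffs
#' 0.5/0.3, |log2FC| cutoffs 2/0.2, pairwise-variation cutoff 0.15,
#' BestKeeper SD cutoff 1 cycle, efficiency validity window 90--110%.
#'
#' @param experiment A [CtExperiment-class]; alternatively give the
#'   three CSV paths.
#' @param ctPath,samplesPath,efficienciesPath CSV paths for the Ct
#'   matrix, sample sheet and efficiency table (efficiencies optional).
#' @param tpm Expression matrix (genes x samples) for the candidate
#'   screen, or `tpmPath` to read one; optional.
#' @param tpmPath,tpmTissue Path / tissue labels for the screen matrix.
#' @param subsets Subset labels to analyze; default: every subset
#'   present plus `"total"`.
#' @param methods Stability methods to run. Default all four.
#' @param genes Optional candidate-gene restriction (default: rows with
#'   `rowData()$role == "candidate"` when present, else all genes).
#' @param minTpm,cvStage1,cvStage2,log2fcStage1,log2fcStage2 Screen
#'   thresholds.
#' @param vCutoff geNorm pairwise-variation cutoff.
#' @param bkSdCutoff BestKeeper SD exclusion cutoff.
#' @param efficiencyCorrection Use stored efficiencies in the relative-
#'   quantity transform (default FALSE = assume doubling).
#' @param target,referenceSets,controlGroup Optional 2^-ddCt validation:
#'   target gene, named list of normalizer sets (default: consensus
#'   top-1, the recommended set, and the consensus-worst gene), control
#'   group label.
#' @param outDir Optional output directory for CSV tables and a JSON
#'   summary.
#' @param seed Seed recorded in the summary (the analysis itself is
#'   deterministic).
#' @return A list of class `RunConfig`.
#' @export
runConfig <- function(experiment = NULL, ctPath = NULL,
                      samplesPath = NULL, efficienciesPath = NULL,
                      tpm = NULL, tpmPath = NULL, tpmTissue = NULL,
                      subsets = NULL, methods = .KNOWN_METHODS,
                      genes = NULL, minTpm = 5, cvStage1 = 0.5,
                      cvStage2 = 0.3, log2fcStage1 = 2,
                      log2fcStage2 = 0.2, vCutoff = 0.15,
                      bkSdCutoff = 1, efficiencyCorrection = FALSE,
                      target = NULL, referenceSets = NULL,
                      controlGroup = "ck", outDir = NULL, seed = 1L) {
    bad <- setdiff(methods, .KNOWN_METHODS)
    if (length(bad))
        stop("unknown method name(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
    if (is.null(experiment) && is.null(ctPath))
        stop("either an experiment or ctPath + samplesPath is required",
             call. = FALSE)
    structure(as.list(environment()), class = "RunConfig")
}

#' Read a pipeline configuration from a flat key=value file
#'
#' Lines of the form `key = value` (# comments allowed). Recognized
#' keys mirror the [runConfig()] arguments in snake_case, e.g.
#' `ct = ct.csv`, `samples = samples.csv`, `subsets = cold,drought`,
#' `v_cutoff = 0.15`, `methods = genorm,bestkeeper`, `target = TGT`,
#' `refs = g01,g02`, `control = ck`, `out = results/`.
#'
#' @param path Config file path.
#' @return A `RunConfig` list (see [runConfig()]).
#' @export
readRunConfig <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    kv <- strsplit(lines, "\\s*=\\s*")
    bad <- lengths(kv) != 2L
    if (any(bad))
        stop("malformed config line: ", lines[bad][1L], call. = FALSE)
    vals <- setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
    num <- function(k, d) if (k %in% names(vals)) as.numeric(vals[[k]])
                          else d
    chr <- function(k) if (k %in% names(vals)) vals[[k]] else NULL
    lst <- function(k) if (k %in% names(vals))
        trimws(strsplit(vals[[k]], ",")[[1L]]) else NULL
    runConfig(ctPath = chr("ct"), samplesPath = chr("samples"),
              efficienciesPath = chr("efficiencies"),
              tpmPath = chr("expr"),
              subsets = lst("subsets"),
              methods = if (is.null(lst("methods"))) .KNOWN_METHODS
                        else lst("methods"),
              genes = lst("genes"),
              minTpm = num("min_tpm", 5),
              cvStage1 = num("cv_stage1", 0.5),
              cvStage2 = num("cv_stage2", 0.3),
              log2fcStage1 = num("log2fc_stage1", 2),
              log2fcStage2 = num("log2fc_stage2", 0.2),
              vCutoff = num("v_cutoff", 0.15),
              bkSdCutoff = num("bk_sd_cutoff", 1),
              efficiencyCorrection =
                  isTRUE(as.logical(chr("efficiency_correction"))),
              target = chr("target"), referenceSets = NULL,
              controlGroup = if (is.null(chr("control"))) "ck"
                             else chr("control"),
              outDir = chr("out"), seed = as.integer(num("seed", 1)))
}

#' Run the full reference-gene selection pipeline
#'
#' Orchestrates: optional candidate screen (TPM matrix) -> the four
#' stability methods per sample subset -> geNorm pairwise variation and
#' optimal reference-gene count -> consensus ranking -> optional
#' 2^-ddCt validation of normalizer choices. Output tables (one CSV per
#' subset and method, a consensus CSV, and a machine-readable JSON
#' summary) are written when `outDir` is set. Results are a pure
#' function of the inputs and configuration.
#'
#' @param config A `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return (Invisibly) a list: `screen` ([ScreenReport-class] or NULL),
#'   `stability` (subset -> method -> [StabilityResult-class]),
#'   `consensus` (subset -> [ConsensusResult-class]), `validation`
#'   (subset -> comparison list or NULL), `summary` (the JSON payload).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    exp <- config$experiment
    if (is.null(exp)) {
        ct <- readCtMatrix(config$ctPath)
        sheet <- readSampleSheet(config$samplesPath)
        eff <- if (!is.null(config$efficienciesPath))
            readEfficiencies(config$efficienciesPath) else NULL
        exp <- CtExperiment(ct, sheet, efficiencies = eff)
    }
    genes <- config$genes
    if (is.null(genes)) {
        genes <- if ("role" %in% colnames(rowData(exp)))
            rownames(exp)[rowData(exp)$role == "candidate"]
        else rownames(exp)
    }
    screen <- NULL
    tpm <- config$tpm
    if (is.null(tpm) && !is.null(config$tpmPath))
        tpm <- readExpressionMatrix(config$tpmPath)
    if (!is.null(tpm)) {
        tissue <- config$tpmTissue
        if (is.null(tissue)) {
            si <- sampleInfo(exp)
            tissue <- si[colnames(tpm), "tissue"]
        }
        screen <- screenCandidates(
            screenStats(tpm, tissue),
            minTpm = config$minTpm, cvStage1 = config$cvStage1,
            cvStage2 = config$cvStage2,
            maxLog2fcStage1 = config$log2fcStage1,
            maxLog2fcStage2 = config$log2fcStage2)
    }
    subsets <- config$subsets
    if (is.null(subsets))
        subsets <- c(sort(unique(sampleInfo(exp)$subset)), "total")
    ec <- config$efficiencyCorrection
    stability <- list(); consensus <- list(); validation <- list()
    for (s in subsets) {
        res <- list()
        if ("delta_ct" %in% config$methods)
            res$delta_ct <- deltaCtStability(exp, s, genes = genes)
        if ("genorm" %in% config$methods)
            res$genorm <- geNorm(exp, s, genes = genes,
                                 efficiencyCorrection = ec,
                                 vCutoff = config$vCutoff)
        if ("normfinder" %in% config$methods)
            res$normfinder <- normFinder(exp, s, genes = genes,
                                         efficiencyCorrection = ec)
        if ("bestkeeper" %in% config$methods)
            res$bestkeeper <- bestKeeper(exp, s, genes = genes,
                                         sdCutoff = config$bkSdCutoff)
        stability[[s]] <- res
        if (length(res) == 4L)
            consensus[[s]] <- consensusRank(unname(res))
        if (!is.null(config$target) && !is.null(consensus[[s]])) {
            cons <- consensus[[s]]
            sets <- config$referenceSets
            if (is.null(sets)) {
                tab <- resultTable(cons)
                sets <- list(top1 = tab$gene[1L],
                             recommended = recommendedSet(cons),
                             worst = tab$gene[nrow(tab)])
            }
            validation[[s]] <- compareNormalizers(
                exp, config$target, sets, config$controlGroup,
                subset = s, efficiencyCorrection = ec)
        }
    }
    summary <- list(
        seed = config$seed,
        n_genes = length(genes),
        subsets = subsets,
        methods = config$methods,
        thresholds = list(min_tpm = config$minTpm,
                          cv = c(config$cvStage1, config$cvStage2),
                          log2fc = c(config$log2fcStage1,
                                     config$log2fcStage2),
                          v_cutoff = config$vCutoff,
                          bk_sd_cutoff = config$bkSdCutoff),
        optimal_n = lapply(stability, function(r)
            if (!is.null(r$genorm)) optimalN(r$genorm) else NA),
        recommended = lapply(consensus, recommendedSet),
        screen = if (!is.null(screen))
            list(stage1 = screen@stage1, stage2 = screen@stage2)
    )
    out <- list(experiment = exp, screen = screen, stability = stability,
                consensus = consensus, validation = validation,
                summary = summary)
    if (!is.null(config$outDir)) .writePipelineOutputs(out, config)
    invisible(out)
}

.writeDf <- function(df, path)
    write.csv(as.data.frame(df), path, row.names = FALSE, quote = FALSE)

.writePipelineOutputs <- function(out, config) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(config$outDir, paste0(...))
    if (!is.null(out$screen))
        .writeDf(cbind(gene = rownames(resultTable(out$screen)),
                       as.data.frame(resultTable(out$screen))),
                 p("screen.csv"))
    for (s in names(out$stability)) {
        for (m in names(out$stability[[s]]))
            .writeDf(resultTable(out$stability[[s]][[m]]),
                     p(s, "_", m, ".csv"))
        if (!is.null(out$stability[[s]]$genorm)) {
            v <- vSeries(out$stability[[s]]$genorm)
            .writeDf(data.frame(n = names(v), V = unname(v)),
                     p(s, "_genorm_V.csv"))
        }
        if (!is.null(out$consensus[[s]]))
            .writeDf(resultTable(out$consensus[[s]]),
                     p(s, "_consensus.csv"))
        if (!is.null(out$validation[[s]]))
            .writeDf(out$validation[[s]]$table, p(s, "_validation.csv"))
    }
    jsonlite::write_json(out$summary, p("summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(NULL)
}
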