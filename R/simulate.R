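#' @include CtExperiment.R
NULL

# run code under a seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(code)
}

.groupKeys <- function(design) {
    unlist(lapply(names(design), function(s)
        paste(s, design[[s]], sep = ":")), use.names = FALSE)
}

#' Configuration for the Ct-data simulator
#'
#' Describes a multi-tissue, multi-condition RT-qPCR study: per-gene
#' baseline Ct, gene-specific noise SDs, condition-specific Ct shifts
#' for unstable genes, a per-sample loading effect shared by all genes
#' (cDNA input variation a good normalizer must cancel), amplification
#' efficiencies, and an optional target gene with a planted fold-change
#' schedule. The default design mirrors a typical medicinal-plant
#' reference-gene study: 15 candidate genes, three tissues
#' (leaf/stem/root), a developmental series (ck/15d/30d), a cold
#' time course (ck/4h/8h/12h), a drought series (ck/5d/10d) and three
#' biological replicates per cell.
#'
#' The default gene panel plants known structure for recovery tests:
#' genes g01--g03 are highly stable (sigma 0.05 cycles, no shifts),
#' g04--g13 span intermediate noise (0.15--0.6 cycles), and g14/g15 are
#' deliberately unstable, carrying condition shifts up to +/-2 cycles
#' (the classic misbehaving-housekeeper pattern) on top of 0.5-cycle
#' noise.
#'
#' @param nGenes Number of candidate genes (default 15; the default
#'   panel structure above is built for 15, other counts get a scaled
#'   noise gradient and no planted shifts).
#' @param tissues Tissue labels. Default leaf/stem/root.
#' @param design Named list: subset -> group labels (first label = the
#'   control).
#' @param replicates Biological replicates per tissue x group. Default 3.
#' @param mu Named per-gene baseline Ct (defaults spread over 18--32
#'   cycles).
#' @param sigma Named per-gene noise SD in cycles.
#' @param delta Gene x group-key matrix of condition shifts in cycles
#'   (group keys `subset:group`); default as described above.
#' @param tau Loading-effect SD in cycles. Default 0.2.
#' @param efficiencies Named per-gene efficiency in percent (defaults
#'   spread over 91--109).
#' @param target `NULL` or a list with `id`, `mu`, `sigma`, and `fold`
#'   (named by group key, expression fold change vs control; unlisted
#'   groups mean fold 1). The default plants a 2/4/8-fold cold
#'   induction, 4/2-fold developmental induction and 2/4-fold drought
#'   repression on gene `TGT`.
#' @param missingRate Probability of a non-detect per candidate Ct
#'   entry. Default 0.
#' @return A validated list of class `SimCtConfig`.
#' @seealso [simulateCt()]
#' @export
simCtConfig <- function(nGenes = 15L,
                        tissues = c("leaf", "stem", "root"),
                        design = list(
                            developmental = c("ck", "15d", "30d"),
                            cold = c("ck", "4h", "8h", "12h"),
                            drought = c("ck", "5d", "10d")),
                        replicates = 3L,
                        mu = NULL, sigma = NULL, delta = NULL,
                        tau = 0.2, efficiencies = NULL, target = "default",
                        missingRate = 0) {
    nGenes <- as.integer(nGenes)
    stopifnot(nGenes >= 3L, replicates >= 1L, tau >= 0,
              missingRate >= 0, missingRate < 1)
    genes <- sprintf("g%02d", seq_len(nGenes))
    keys <- .groupKeys(design)
    if (is.null(mu))
        mu <- setNames(seq(18, 32, length.out = nGenes), genes)
    if (is.null(sigma)) {
        sigma <- if (nGenes == 15L)
            c(rep(0.05, 3), seq(0.15, 0.6, length.out = 10),
              0.5, 0.5)
        else seq(0.05, 0.6, length.out = nGenes)
        sigma <- setNames(sigma, genes)
    }
    if (is.null(delta)) {
        delta <- matrix(0, nGenes, length(keys),
                        dimnames = list(genes, keys))
        if (nGenes == 15L) {
            up <- c("developmental:15d" = 0.5, "developmental:30d" = 1,
                    "cold:4h" = 0.5, "cold:8h" = 1, "cold:12h" = 2,
                    "drought:5d" = 1, "drought:10d" = 2)
            up <- up[intersect(names(up), keys)]
            delta["g14", names(up)] <- up
            delta["g15", names(up)] <- -up
        }
    }
    if (is.null(efficiencies))
        efficiencies <- setNames(seq(91, 109, length.out = nGenes), genes)
    if (identical(target, "default"))
        target <- list(id = "TGT", mu = 24, sigma = 0.1,
                       fold = c("cold:4h" = 2, "cold:8h" = 4,
                                "cold:12h" = 8,
                                "developmental:15d" = 4,
                                "developmental:30d" = 2,
                                "drought:5d" = 0.5,
                                "drought:10d" = 0.25))
    stopifnot(identical(names(mu), genes), identical(names(sigma), genes),
              all(sigma >= 0), identical(rownames(delta), genes),
              identical(colnames(delta), keys))
    structure(list(genes = genes, tissues = tissues, design = design,
                   replicates = as.integer(replicates), mu = mu,
                   sigma = sigma, delta = delta, tau = tau,
                   efficiencies = efficiencies, target = target,
                   missingRate = missingRate),
              class = "SimCtConfig")
}

#' Simulate an RT-qPCR Ct data set with known ground truth
#'
#' Draws Ct values under the additive error model
#' `Ct = mu_gene + loading_sample + delta_gene,group + N(0, sigma_gene)`,
#' with `loading ~ N(0, tau)` shared by all genes of a sample (modeling
#' cDNA input differences). The optional target gene replaces its
#' `delta` by `-log2(fold)` so a planted f-fold induction lowers its Ct
#' by log2(f) cycles. Deterministic given the seed.
#'
#' @param config A [simCtConfig()] object.
#' @param seed Integer seed fixing all randomness.
#' @return List with:
#' \describe{
#'   \item{experiment}{A [CtExperiment-class] (candidate genes plus the
#'     target; `rowData()$role` distinguishes them).}
#'   \item{sheet}{The sample sheet `data.frame`.}
#'   \item{truth}{Planted parameters: `mu`, `sigma`, `delta`, `tau`,
#'     `loadings`, `efficiencies`, `targetFold`, the candidate gene ids,
#'     and `trueStability` -- the declared composite
#'     `sqrt(sigma^2 + Var(delta over samples))` whose ascending order
#'     (`trueOrder`) is the planted stability ranking.}
#' }
#' @examples
#' sim <- simulateCt(simCtConfig(), seed = 1)
#' sim$experiment
#' @export
simulateCt <- function(config = simCtConfig(), seed = 1L) {
    stopifnot(inherits(config, "SimCtConfig"))
    .withSeed(seed, {
        sheet <- do.call(rbind, lapply(names(config$design), function(s)
            expand.grid(subset = s, group = config$design[[s]],
                        tissue = config$tissues,
                        replicate = seq_len(config$replicates),
                        stringsAsFactors = FALSE)))
        sheet$sample_id <- paste(sheet$subset, sheet$group, sheet$tissue,
                                 paste0("r", sheet$replicate), sep = "_")
        sheet <- sheet[, c("sample_id", "tissue", "subset", "group",
                           "replicate")]
        rownames(sheet) <- sheet$sample_id
        nS <- nrow(sheet)
        keys <- paste(sheet$subset, sheet$group, sep = ":")
        loadings <- setNames(rnorm(nS, 0, config$tau), sheet$sample_id)

        ct <- matrix(NA_real_, length(config$genes), nS,
                     dimnames = list(config$genes, sheet$sample_id))
        for (g in config$genes)
            ct[g, ] <- config$mu[g] + loadings +
                config$delta[g, keys] +
                rnorm(nS, 0, config$sigma[g])
        if (config$missingRate > 0) {
            drop <- matrix(runif(length(ct)) < config$missingRate,
                           nrow(ct))
            ct[drop] <- NA_real_
        }
        eff <- config$efficiencies
        tgt <- config$target
        targetFold <- NULL
        if (!is.null(tgt)) {
            fold <- setNames(rep(1, length(unique(keys))), unique(keys))
            fold[names(tgt$fold)[names(tgt$fold) %in% names(fold)]] <-
                tgt$fold[names(tgt$fold) %in% names(fold)]
            tct <- tgt$mu + loadings - log2(fold[keys]) +
                rnorm(nS, 0, tgt$sigma)
            ct <- rbind(ct, matrix(tct, 1L,
                                   dimnames = list(tgt$id, NULL)))
            eff <- c(eff, setNames(100, tgt$id))
            targetFold <- fold
        }
        exp <- CtExperiment(ct, sheet, efficiencies = eff)
        rowData(exp)$role <- ifelse(rownames(exp) %in% config$genes,
                                    "candidate", "target")
        # declared planted stability: noise SD plus the spread of the
        # condition shifts over the realized samples
        dPerSample <- config$delta[, keys, drop = FALSE]
        dVar <- apply(dPerSample, 1L, function(v) mean((v - mean(v))^2))
        trueStab <- sqrt(config$sigma^2 + dVar)
        truth <- list(mu = config$mu, sigma = config$sigma,
                      delta = config$delta, tau = config$tau,
                      loadings = loadings,
                      efficiencies = config$efficiencies,
                      targetFold = targetFold,
                      candidates = config$genes,
                      trueStability = trueStab,
                      trueOrder = names(sort(trueStab)))
        list(experiment = exp, sheet = sheet, truth = truth)
    })
}

#' Configuration for the TPM-matrix simulator
#'
#' Describes a panel of genes with planted screening statistics. Each
#' row fixes a gene's overall mean TPM (`mv`), its between-tissue log2
#' fold change (`log2fc`, realized exactly through the tissue means) and
#' its overall coefficient of variation (`cv`, realized exactly by
#' standardizing the within-tissue residuals). Residuals are bounded
#' (standardized uniforms) so TPM stays positive. Because the realized
#' MV/CV/log2FC equal their targets by construction, the expected
#' screening-stage membership of every gene is known in advance at any
#' seed.
#'
#' The default panel plants genes on both sides of every screening
#' threshold (5 TPM; CV 0.5 and 0.3; |log2FC| 2 and 0.2).
#'
#' @param panel `data.frame` with columns `gene`, `mv`, `cv`, `log2fc`.
#' @param tissues Tissue labels. Default leaf/stem/root.
#' @param replicates Samples per tissue. Default 6.
#' @return A list of class `SimTpmConfig`.
#' @export
simTpmConfig <- function(panel = NULL,
                         tissues = c("leaf", "stem", "root"),
                         replicates = 6L) {
    if (is.null(panel))
        panel <- data.frame(
            gene = c("stable_hi", "stable_lo", "midcv", "midfc",
                     "low_tpm", "high_fc", "high_cv",
                     "fill1", "fill2", "fill3"),
            mv = c(100, 20, 100, 50, 4.9, 30, 100, 10, 60, 200),
            cv = c(0.10, 0.25, 0.40, 0.10, 0.10, NA, 0.60, 0.15, 0.12,
                   0.20),
            log2fc = c(0.05, 0.10, 0.10, 0.50, 0.05, log2(5), 1.5,
                       0.10, 0.05, 0.12))
    stopifnot(all(c("gene", "mv", "cv", "log2fc") %in% colnames(panel)),
              !anyDuplicated(panel$gene), all(panel$mv >= 0),
              length(tissues) >= 2L, replicates >= 2L)
    structure(list(panel = panel, tissues = tissues,
                   replicates = as.integer(replicates)),
              class = "SimTpmConfig")
}

#' Simulate a TPM matrix with exactly planted screening statistics
#'
#' See [simTpmConfig()] for the construction. A gene's `cv` entry may be
#' `NA`, meaning "whatever the planted fold change implies" (within-
#' tissue CV 0.05); its realized CV is still deterministic and reported
#' in the truth table.
#'
#' @param config A [simTpmConfig()] object.
#' @param seed Integer seed (affects only the residual draws, not the
#'   realized statistics).
#' @return List with `tpm` (matrix), `sheet` (sample sheet
#'   `data.frame`, tissues as groups), and `truth`: per gene the exact
#'   realized `mv`, `cv`, `log2fc` and the `expected_stage`
#'   (`"none"`, `"stage1"`, `"stage2"`) under the default thresholds.
#' @export
simulateTpm <- function(config = simTpmConfig(), seed = 1L) {
    stopifnot(inherits(config, "SimTpmConfig"))
    .withSeed(seed, {
        p <- config$panel
        tl <- config$tissues
        n <- config$replicates
        N <- n * length(tl)
        samples <- paste(rep(tl, each = n), rep(seq_len(n), length(tl)),
                         sep = "_r")
        tissue <- rep(tl, each = n)
        tpm <- matrix(0, nrow(p), N,
                      dimnames = list(p$gene, samples))
        realized <- data.frame(gene = p$gene, mv = p$mv,
                               cv = NA_real_, log2fc = p$log2fc)
        for (i in seq_len(nrow(p))) {
            m <- p$mv[i]; f <- p$log2fc[i]
            qf <- 2^(seq(-f / 2, f / 2, length.out = length(tl)))
            mt <- m * qf / mean(qf)
            between <- n * sum((mt - m)^2)
            sumMt2 <- sum(mt^2)
            cvw <- if (is.na(p$cv[i])) 0.05 else {
                need <- p$cv[i]^2 * m^2 * (N - 1) - between
                if (m == 0) 0 else sqrt(max(0, need) / ((n - 1) * sumMt2))
            }
            if (cvw > 0.45)
                stop("gene '", p$gene[i], "': requested CV needs a ",
                     "within-tissue CV above 0.45, which cannot ",
                     "guarantee positive TPM; raise log2fc or lower cv",
                     call. = FALSE)
            s2 <- ((n - 1) * cvw^2 * sumMt2 + between) / (N - 1)
            realized$cv[i] <- if (m > 0) sqrt(s2) / m else NA_real_
            for (t in seq_along(tl)) {
                z <- runif(n)
                z <- (z - mean(z)) / sd(z)   # exact mean 0, sd 1
                tpm[i, tissue == tl[t]] <- mt[t] * (1 + cvw * z)
            }
        }
        stage1 <- realized$mv >= 5 & realized$log2fc <= 2 &
            !is.na(realized$cv) & realized$cv <= 0.5
        stage2 <- stage1 & realized$cv < 0.3 & realized$log2fc < 0.2
        realized$expected_stage <- ifelse(stage2, "stage2",
                                          ifelse(stage1, "stage1",
                                                 "none"))
        sheet <- data.frame(sample_id = samples, tissue = tissue,
                            subset = "custom", group = tissue,
                            replicate = rep(seq_len(n), length(tl)),
                            row.names = samples)
        list(tpm = tpm, sheet = sheet, truth = realized)
    })
}
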