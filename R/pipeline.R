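## Multi-stage pipeline driver: a YAML config names the inputs, the stages
## to run and the seed; each stage writes machine-readable tables plus a
## log line with its parameters, and completed stages are skipped on
## rerun.

.stageNames <- c("simulate", "qc", "twisst", "sitestats", "netscore",
                 "calibrate", "asr")

#' Run the analysis pipeline
#'
#' Stages: \code{simulate} (coalescent simulation on a network),
#' \code{qc} (gene-tree filtering/normalization), \code{twisst}
#' (topology weighting + ILS chi-square test), \code{sitestats} (SNP
#' filtering, D/f4, similarity), \code{netscore} (candidate evaluation
#' and prevailing-network selection), \code{calibrate} (ultrametrization)
#' and \code{asr} (trait reconstruction).  Outputs are deterministic
#' given the config seed; a rerun resumes after stages whose
#' \code{.done} marker exists.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#'   Keys: \code{seed}, \code{stages} (subset of the stage names),
#'   \code{outdir}, plus per-stage blocks (see the package vignette).
#' @param outdir output directory (overrides the config).
#' @return invisibly, the run directory.
#' @export
runPipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) stop("config must set a seed")
  seed <- as.integer(cfg$seed)
  stages <- cfg$stages
  if (is.null(stages)) stages <- .stageNames
  bad <- setdiff(stages, .stageNames)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (is.null(outdir)) outdir <- cfg$outdir
  if (is.null(outdir)) stop("an output directory is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outdir, "pipeline.log")

  ## pre-flight: every referenced input must exist before any stage runs
  refFiles <- c(cfg$qc$trees, cfg$twisst$trees, cfg$twisst$grouping,
                cfg$sitestats$snps, cfg$sitestats$grouping,
                cfg$netscore$candidates, cfg$netscore$trees,
                cfg$calibrate$network, cfg$calibrate$trees,
                cfg$asr$network, cfg$asr$traits, cfg$simulate$network)
  refFiles <- unlist(refFiles)
  missing_ <- refFiles[!vapply(refFiles, file.exists, logical(1))]
  # files produced by earlier stages of this run are allowed
  missing_ <- missing_[!startsWith(normalizePath(missing_, mustWork = FALSE),
                                   normalizePath(outdir, mustWork = FALSE))]
  if (length(missing_)) {
    stop("missing input files (pre-flight): ", paste(missing_, collapse = ", "))
  }
  if ("asr" %in% stages && is.null(cfg$asr$traits)) {
    stop("asr stage enabled but no trait table configured (pre-flight)")
  }

  logLine <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = logFile, append = TRUE)
  }
  doneFile <- function(stage) file.path(outdir, paste0(".", stage, ".done"))
  stagePath <- function(...) file.path(outdir, ...)
  writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  num <- function(x, d = 10) formatC(x, digits = d, format = "g")

  for (stage in .stageNames) {
    if (!(stage %in% stages)) next
    if (file.exists(doneFile(stage))) {
      logLine(stage, "skipped (done marker present)")
      next
    }
    switch(stage,
      simulate = {
        sc <- cfg$simulate
        net <- if (is.character(sc$network)) readNetworks(sc$network, "coalescent")[[1]]
               else sc$networkObject
        simcfg <- simConfig(net, nLoci = sc$nLoci %||% 100L, seed = seed,
                            sigmaRate = sc$sigmaRate %||% 0,
                            meanlogRate = sc$meanlogRate %||% 0,
                            mTax = sc$mTax %||% 0, mGt = sc$mGt %||% 0,
                            locusLength = sc$locusLength %||% 300L)
        sim <- simulateGeneTrees(simcfg)
        sim <- scaleToSubstitutions(sim)
        snp <- simulateSnpMatrix(sim)
        writeGeneTrees(sim$coalTrees, stagePath("sim_genetrees_coal.nwk"))
        writeGeneTrees(sim$subsTrees, stagePath("sim_genetrees_subs.nwk"))
        writeSnpTsv(snp, stagePath("sim_snps.tsv"))
        jsonlite::write_json(list(seed = seed, nLoci = simcfg$nLoci,
                                  sigmaRate = simcfg$sigmaRate,
                                  mTax = simcfg$mTax, mGt = simcfg$mGt,
                                  network = writeExtendedNewick(net)),
                             stagePath("sim_truth.json"), auto_unbox = TRUE)
        logLine(stage, sprintf("nLoci=%d seed=%d sigmaRate=%s mTax=%s mGt=%s",
                               simcfg$nLoci, seed, num(simcfg$sigmaRate),
                               num(simcfg$mTax), num(simcfg$mGt)))
      },
      qc = {
        qs <- cfg$qc
        trees <- readGeneTrees(qs$trees %||% stagePath("sim_genetrees_subs.nwk"))
        res <- qcBatch(trees, ingroup = qs$ingroup, outgroup = qs$outgroup,
                       ratio = qs$ratio %||% 1.5,
                       minOutDist = qs$minOutDist %||% 1e-4)
        writeTsv(res$report, stagePath("qc_report.tsv"))
        writeGeneTrees(res$retained, stagePath("qc_retained.nwk"))
        logLine(stage, sprintf("ratio=%s minOutDist=%s pass=%d of %d",
                               num(qs$ratio %||% 1.5), num(qs$minOutDist %||% 1e-4),
                               res$counts[["pass"]], length(trees)))
      },
      twisst = {
        ts <- cfg$twisst
        trees <- readGeneTrees(ts$trees %||% stagePath("qc_retained.nwk"))
        grouping <- if (is.character(ts$grouping)) readGrouping(ts$grouping)
                    else ts$groupingObject
        desig <- as.integer(ts$designation %||% c(1L, 2L, 3L))
        tc <- twisstCounts(trees, grouping, designation = desig, seed = seed)
        test <- ilsChisqTest(tc$counts[["minor"]], tc$counts[["contra"]])
        writeTsv(tc$perTree, stagePath("twisst_pertree.tsv"))
        jsonlite::write_json(list(counts = as.list(tc$counts),
                                  nUsable = tc$nUsable,
                                  chisq = test$chisq, p = test$p,
                                  direction = test$direction,
                                  rounded = test$rounded),
                             stagePath("twisst_test.json"), auto_unbox = TRUE,
                             digits = NA)
        logLine(stage, sprintf("designation=%s chisq=%s p=%s",
                               paste(desig, collapse = ","),
                               num(test$chisq), num(test$p)))
      },
      sitestats = {
        ss <- cfg$sitestats
        snpPath <- ss$snps %||% stagePath("sim_snps.tsv")
        snp <- if (grepl("\\.vcf$", snpPath)) readSnpVcf(snpPath)
               else readSnpTsv(snpPath, ploidy = ss$ploidy %||% 1L)
        snp <- filterSnps(snp, maxMissing = ss$maxMissing %||% 0.2,
                          thinBp = ss$thinBp %||% 100L)
        writeSnpTsv(snp, stagePath("sitestats_filtered.tsv"))
        grouping <- if (is.character(ss$grouping)) readGrouping(ss$grouping)
                    else ss$groupingObject
        popMap <- c(grouping@groups,
                    list(outgroup = grouping@outgroup))
        fr <- popFreqs(snp, popMap)
        fq <- fr$freq[c("P1", "P2", "P3", "outgroup"), , drop = FALSE]
        d <- pattersonD(fq, nBlocks = ss$blocks %||% 20L)
        f <- f4Ratio(fq, nBlocks = ss$blocks %||% 20L)
        writeTsv(data.frame(stat = c("D", "f4ratio"),
                            value = c(d$D, f$f), se = c(d$se, f$se),
                            z = c(d$z, f$z), p = c(d$p, f$p),
                            nSites = c(d$nSites, f$nSites)),
                 stagePath("sitestats_df4.tsv"))
        sim <- simpleMatchingSimilarity(snp)
        writeTsv(data.frame(individual = rownames(sim),
                            as.data.frame(sim, check.names = FALSE)),
                 stagePath("sitestats_similarity.tsv"))
        logLine(stage, sprintf("maxMissing=%s thinBp=%d blocks=%d sites=%d",
                               num(ss$maxMissing %||% 0.2),
                               as.integer(ss$thinBp %||% 100L),
                               as.integer(ss$blocks %||% 20L), nSites(snp)))
      },
      netscore = {
        ns <- cfg$netscore
        trees <- readGeneTrees(ns$trees %||% stagePath("qc_retained.nwk"))
        cand <- ns$candidates
        candSets <- if (is.character(cand)) lapply(cand, readNetworks, lengthUnit = "coalescent")
                    else ns$candidateObjects
        cf <- observedQuartetCF(trees)
        evals <- list()
        for (r in seq_along(candSets)) {
          ev <- evaluateCandidates(candSets[[r]], cf, outgroup = ns$outgroup)
          ev$resampling <- r
          evals[[r]] <- ev
        }
        allEv <- do.call(rbind, evals)
        writeTsv(allEv, stagePath("netscore_evaluations.tsv"))
        sel <- selectPrevailing(allEv)
        writeTsv(sel, stagePath("netscore_selected.tsv"))
        logLine(stage, sprintf("resamplings=%d candidates=%d selected=%d",
                               length(candSets), nrow(allEv), nrow(sel)))
      },
      calibrate = {
        cs <- cfg$calibrate
        net <- readNetworks(cs$network, "coalescent")[[1]]
        trees <- readGeneTrees(cs$trees %||% stagePath("qc_retained.nwk"))
        mpd <- meanPairwiseDistances(trees, taxa = tipLabels(net))
        cal <- calibrateNetwork(net, mpd$D, pInit = cs$pInit %||% 1,
                                multistarts = cs$multistarts %||% 8L,
                                seed = seed)
        writeNetworks(cal$network, stagePath("calibrated.enwk"))
        chk <- ultrametricCheck(cal$network)
        jsonlite::write_json(list(p = cal$p, objective = cal$objective,
                                  distanceTerm = cal$terms[["distance"]],
                                  penaltyTerm = cal$terms[["penalty"]],
                                  w = cal$w, ultrametric = chk$pass,
                                  maxDeviation = chk$maxDeviation),
                             stagePath("calibrate_report.json"),
                             auto_unbox = TRUE, digits = NA)
        logLine(stage, sprintf("pInit=%s p=%s objective=%s",
                               num(cs$pInit %||% 1), num(cal$p), num(cal$objective)))
      },
      asr = {
        as_ <- cfg$asr
        netPath <- as_$network %||% stagePath("calibrated.enwk")
        net <- readNetworks(netPath, "coalescent")[[1]]
        traits <- readTraitTable(as_$traits)
        res <- reconstructAll(net, traits)
        writeTsv(res$table, stagePath("asr_posteriors.tsv"))
        jsonlite::write_json(as.list(res$alpha), stagePath("asr_alpha.json"),
                             auto_unbox = TRUE, digits = NA)
        logLine(stage, sprintf("traits=%s alpha=%s",
                               paste(names(res$alpha), collapse = ","),
                               paste(num(res$alpha), collapse = ",")))
      })
    file.create(doneFile(stage))
  }
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
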