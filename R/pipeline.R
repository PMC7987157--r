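# End-to-end orchestration: one declarative configuration drives the whole
# analysis graph (replicated reconstruction at the nodes of interest,
# threshold sweep, composition tables, simulation null and depletion test,
# feature report), writes every artifact under one run directory and
# records a manifest. Fixed config + seed reruns are byte-identical.

#' Pipeline configuration
#'
#' Inputs may be file paths (FASTA alignment, Newick tree, cluster file) or
#' in-memory objects, or a [simulationScenario()] from which alignment and
#' tree are generated. Flags override nothing silently: validation happens
#' in [runPipeline()].
#'
#' @param alignment path to a FASTA alignment or a
#'   [ProteinAlignment-class]; ignored when \code{scenario} is given.
#' @param tree path to a Newick tree or an [ape::phylo]; ignored when
#'   \code{scenario} is given.
#' @param clusters path to a cluster file, a [ClusterSet-class],
#'   \code{"auto"} (greedy identity clustering with \code{softMax}), or
#'   NULL for singleton clusters.
#' @param scenario optional [simulationScenario()] generating synthetic
#'   inputs.
#' @param nodes character vector of nodes of interest (\code{"root"} or
#'   internal node labels).
#' @param thresholds gap-inference thresholds in percent, all in [1, 99].
#' @param nReplicates replicate count for the resampling design (>= 1).
#' @param nSims simulation count for the null distribution (0 disables the
#'   null/depletion stage).
#' @param nullGapThreshold gap threshold for the simulation arm (default
#'   10).
#' @param softMax soft cluster size bound when \code{clusters = "auto"}.
#' @param lateResidues residues tested for depletion.
#' @param seed master integer seed for every random stage.
#' @param logLevel \code{"info"} or \code{"quiet"}.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(alignment = NULL, tree = NULL, clusters = NULL,
                           scenario = NULL, nodes = "root",
                           thresholds = c(10, 50, 90), nReplicates = 100L,
                           nSims = 100L, nullGapThreshold = 10,
                           softMax = 5L, lateResidues = LATE_RESIDUES,
                           seed = 1L, logLevel = c("info", "quiet")) {
  logLevel <- match.arg(logLevel)
  if (any(thresholds < 1 | thresholds > 99))
    .err("validationError", "thresholds must lie in [1, 99]")
  if (nReplicates < 1L)
    .err("validationError", "nReplicates must be >= 1")
  if (is.null(scenario)) {
    if (is.null(alignment) || is.null(tree))
      .err("validationError", "either scenario or alignment+tree must be given")
    for (p in c(alignment, tree, if (is.character(clusters) &&
                                     !identical(clusters, "auto")) clusters)) {
      if (is.character(p) && !file.exists(p))
        .err("validationError", sprintf("input path does not exist: %s", p))
    }
  }
  structure(list(alignment = alignment, tree = tree, clusters = clusters,
                 scenario = scenario, nodes = nodes, thresholds = thresholds,
                 nReplicates = as.integer(nReplicates),
                 nSims = as.integer(nSims),
                 nullGapThreshold = nullGapThreshold,
                 softMax = as.integer(softMax),
                 lateResidues = lateResidues, seed = as.integer(seed),
                 logLevel = logLevel),
            class = "PipelineConfig")
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: input loading (or synthetic generation), clustering, replicated
#' reconstruction with consensus at every node and threshold, the 1-99\%
#' threshold-occupancy sweep, composition tables, the simulation null and
#' depletion tests for the late residues, and a physicochemical feature
#' report. Every output file is declared in \code{manifest.yaml}; the log
#' contains one line per replicate with its seed substream. Any stage
#' failure aborts with the stage name attached to the error.
#'
#' @param config a [pipelineConfig()] or path to a YAML file with the same
#'   fields.
#' @param outDir output directory; default a timestamped \code{run-*}
#'   directory under the working directory. Created if missing.
#' @return invisibly, the run directory path.
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    y$scenario <- if (!is.null(y$scenario)) do.call(simulationScenario, y$scenario)
    config <- do.call(pipelineConfig, y[!vapply(y, is.null, logical(1))])
  }
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.null(outDir))
    outDir <- paste0("run-", format(Sys.time(), "%Y%m%d-%H%M%S"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "log.txt")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  logmsg <- function(...) {
    line <- paste0(...)
    writeLines(line, logCon)
    if (config$logLevel == "info") message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .err("pipelineError",
           sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           stage = name)
    })
  }
  files <- character(0)
  declare <- function(path) files <<- c(files, basename(path))

  model <- wagModel()

  ## inputs
  inputs <- stage("inputs", {
    if (!is.null(config$scenario)) {
      tree <- simulateTree(config$scenario)
      rf <- config$scenario$rootFreqs
      sim <- simulateAlignment(tree, model, config$scenario$length,
                               rootFreqs = rf, seed = config$scenario$seed)
      aln <- sim$alignment
      if (!is.null(config$scenario$gapTemplate))
        aln <- overlayGaps(aln, config$scenario$gapTemplate)
      writeFastaAlignment(aln, file.path(outDir, "input_alignment.fasta"))
      declare("input_alignment.fasta")
      ape::write.tree(tree, file.path(outDir, "input_tree.nwk"))
      declare("input_tree.nwk")
      writeFastaAlignment(c(trueRoot = sim$rootSequence),
                          file.path(outDir, "true_root.fasta"))
      declare("true_root.fasta")
      list(alignment = aln, tree = tree, trueRoot = sim$rootSequence)
    } else {
      aln <- if (is.character(config$alignment))
        readFastaAlignment(config$alignment) else config$alignment
      tree <- if (is.character(config$tree))
        readNewickTree(config$tree) else validateTree(config$tree)
      list(alignment = aln, tree = tree, trueRoot = NULL)
    }
  })
  aln <- inputs$alignment
  tree <- inputs$tree
  checkPairing(tree, aln)
  logmsg(sprintf("inputs: %d sequences x %d columns, %d tips",
                 nSequences(aln), nColumns(aln), length(tree$tip.label)))

  ## clusters
  clusters <- stage("clusters", {
    cl <- config$clusters
    if (is.null(cl)) new("ClusterSet",
                         clusters = as.list(sequenceNames(aln)),
                         provenance = "computed")
    else if (identical(cl, "auto"))
      clusterSequences(aln, softMax = config$softMax, seed = config$seed)
    else if (is.character(cl)) parseClusterFile(cl)
    else cl
  })
  checkClusterPairing(clusters, aln)
  logmsg(sprintf("clusters: %d (%s)", nClusters(clusters), clusters@provenance))

  ## replicated reconstruction per node
  thrNames <- as.character(config$thresholds)
  allCons <- list()
  for (node in config$nodes) {
    res <- stage(paste0("replicated-asr:", node), {
      replicatedASR(aln, tree, model, clusters, nodeId = node,
                    thresholds = config$thresholds,
                    n = config$nReplicates, seed = config$seed)
    })
    for (r in seq_len(config$nReplicates))
      logmsg(sprintf("replicate node=%s r=%d seed=%d", node, r, config$seed + r))
    for (tn in thrNames) {
      rs <- res$sets[[tn]]
      fn <- sprintf("replicates_%s_thr%s.fasta", node, tn)
      seqs <- setSequences(rs)
      names(seqs) <- sprintf("%s_thr%s_rep%03d", node, tn, seq_along(seqs))
      writeFastaAlignment(seqs, file.path(outDir, fn))
      declare(fn)
    }
    cons <- vapply(res$consensus, ancSequence, character(1))
    names(cons) <- sprintf("%s_consensus_thr%s", node, thrNames)
    fn <- sprintf("consensus_%s.fasta", node)
    writeFastaAlignment(cons, file.path(outDir, fn))
    declare(fn)
    allCons[[node]] <- res$consensus

    ## threshold sweep on the full-data profile
    sweep <- stage(paste0("sweep:", node), {
      prof <- reconstructionProfile(tree, aln, model, nodeId = node)
      data.frame(column = seq_len(nColumns(aln)),
                 occupancy = thresholdSweep(prof),
                 gapPosterior = gapPosterior(prof))
    })
    fn <- sprintf("sweep_%s.tsv", node)
    .writeTSV(sweep, file.path(outDir, fn))
    declare(fn)
  }

  ## composition tables (consensus sequences + extant sequences)
  stage("composition", {
    consSeqs <- unlist(lapply(names(allCons), function(node) {
      s <- vapply(allCons[[node]], ancSequence, character(1))
      names(s) <- sprintf("%s_thr%s", node, names(allCons[[node]]))
      s
    }))
    tbl <- rbind(
      cbind(set = "ancestral_consensus",
            compositionSummary(consSeqs, residues = config$lateResidues)),
      cbind(set = "extant",
            compositionSummary(alignmentStrings(aln),
                               residues = config$lateResidues)))
    .writeTSV(tbl, file.path(outDir, "composition.tsv"))
    declare("composition.tsv")
    .writeTSV(compositionStats(tbl), file.path(outDir, "composition_stats.tsv"))
    declare("composition_stats.tsv")
  })

  ## simulation null + depletion
  if (config$nSims > 0L) {
    for (node in config$nodes) {
      nd <- stage(paste0("null:", node), {
        nullReconstructionDistribution(
          tree, templateAlignment = aln, model = model, clusters = clusters,
          nodeId = node, aminoAcids = config$lateResidues,
          nSims = config$nSims, gapThreshold = config$nullGapThreshold,
          seed = config$seed)
      })
      fn <- sprintf("null_%s.tsv", node)
      .writeTSV(as.data.frame(nullCounts(nd)), file.path(outDir, fn))
      declare(fn)
      dep <- stage(paste0("depletion:", node), {
        prof <- reconstructionProfile(tree, aln, model, nodeId = node)
        obsSeq <- ancSequence(callSequence(prof, config$nullGapThreshold))
        do.call(rbind, lapply(config$lateResidues, function(a) {
          obs <- countResidues(obsSeq, a)
          dt <- depletionTest(obs, nd, residue = a)
          data.frame(node = node, residue = a, observed = obs,
                     nullMean = dt$nullMean, nullSD = dt$nullSD,
                     p = dt$p, z = if (is.na(dt$z)) NA else dt$z)
        }))
      })
      fn <- sprintf("depletion_%s.tsv", node)
      .writeTSV(dep, file.path(outDir, fn))
      declare(fn)
      logmsg(sprintf("depletion node=%s: min p = %g", node, min(dep$p)))
    }
  }

  ## feature report on consensus sequences
  stage("features", {
    rows <- list()
    for (node in names(allCons)) {
      for (tn in names(allCons[[node]])) {
        s <- gsub("-", "", ancSequence(allCons[[node]][[tn]]), fixed = TRUE)
        if (nchar(gsub("X", "", s, fixed = TRUE)) == 0L) next
        h <- meanHydropathy(s)
        rows[[length(rows) + 1L]] <- data.frame(
          node = node, threshold = tn, length = nchar(s),
          pI = isoelectricPoint(s)$pI, hydropathy = h,
          localization = classifyLocalization(h))
      }
    }
    if (length(rows)) {
      .writeTSV(do.call(rbind, rows), file.path(outDir, "features.tsv"))
      declare("features.tsv")
    }
  })

  ## manifest
  cfgPath <- file.path(outDir, "config.yaml")
  cfgOut <- config
  cfgOut$alignment <- if (is.character(config$alignment)) config$alignment else "in-memory"
  cfgOut$tree <- if (is.character(config$tree)) config$tree else "in-memory"
  cfgOut$clusters <- if (is.character(config$clusters)) config$clusters
                     else if (is.null(config$clusters)) "singletons" else "in-memory"
  cfgOut$scenario <- if (is.null(config$scenario)) NULL
                     else config$scenario[c("nTaxa", "treeShape", "branchScale",
                                            "duplicationAtRoot", "length", "seed")]
  yaml::write_yaml(unclass(cfgOut), cfgPath)
  declare("config.yaml")
  declare("log.txt")
  manifest <- list(package = "srpAncestry",
                   version = as.character(utils::packageVersion("srpAncestry")),
                   seed = config$seed,
                   configHash = unname(tools::md5sum(cfgPath)),
                   files = sort(unique(c(files, "manifest.yaml"))))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  logmsg(sprintf("run complete: %d artifacts", length(manifest$files)))
  invisible(outDir)
}
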