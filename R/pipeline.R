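.CONFIG_KEYS <- c("simulate", "loci", "alignment", "locus_order", "clades",
                  "calibration", "cgi", "indels", "outdir", "seed")

.CONFIG_DEFAULTS <- list(
  cgi = list(min_gc = 0.5, min_obs_exp = 0.6, min_len = 200L),
  indels = "mismatch",
  seed = 1L
)

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML file path or an R list. Exactly one of \code{simulate}
#' (erosion-simulator parameters, plus optional \code{rate}) or real input
#' (\code{alignment}: pre-aligned FASTA path, or \code{loci}: named map
#' locus -> FASTA path with \code{locus_order}) must be present. Optional
#' blocks: \code{clades} (\code{members_a}, \code{members_b}),
#' \code{calibration} (\code{pair}, \code{time_ma}), \code{cgi} thresholds,
#' \code{indels} scoring for the all-changes tree, \code{outdir},
#' \code{seed}. Unknown keys are rejected; every defaulted value is echoed
#' with \code{message()}.
#'
#' @param config A path to a YAML file or a list.
#' @return The validated, defaulted config list (class
#'   \code{PipelineConfig}).
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    .assert(file.exists(config), "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  .assert(is.list(config), "config must be a list or a YAML file path")
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  .assert(length(unknown) == 0L, "unknown config key: %s", unknown[1L])
  has_sim <- !is.null(config$simulate)
  has_real <- !is.null(config$loci) || !is.null(config$alignment)
  .assert(xor(has_sim, has_real),
          "config must have exactly one of 'simulate' or real input (loci/alignment)")
  for (key in names(.CONFIG_DEFAULTS)) {
    if (is.null(config[[key]])) {
      config[[key]] <- .CONFIG_DEFAULTS[[key]]
      message(sprintf("config: '%s' defaulted to %s", key,
                      paste(deparse(.CONFIG_DEFAULTS[[key]]), collapse = "")))
    } else if (is.list(.CONFIG_DEFAULTS[[key]])) {
      for (sub in names(.CONFIG_DEFAULTS[[key]])) {
        if (is.null(config[[key]][[sub]])) {
          config[[key]][[sub]] <- .CONFIG_DEFAULTS[[key]][[sub]]
          message(sprintf("config: '%s.%s' defaulted to %s", key, sub,
                          .CONFIG_DEFAULTS[[key]][[sub]]))
        }
      }
    }
  }
  .assert(config$indels %in% c("mismatch", "exclude"),
          "indels must be 'mismatch' or 'exclude'")
  if (has_sim) {
    sim <- config$simulate
    known <- c("mu", "lambda_cpg", "kappa", "root_length", "cpg_fraction",
               "rate")
    unknown <- setdiff(names(sim), known)
    .assert(length(unknown) == 0L, "unknown simulate key: %s", unknown[1L])
    config$simulate$params <- erosionParams(
      mu = sim$mu %||% 1, lambdaCpg = sim$lambda_cpg %||% 25,
      kappa = sim$kappa %||% 2, rootLength = sim$root_length %||% 5000L,
      cpgFraction = sim$cpg_fraction %||% 0.085, seed = config$seed)
  } else if (!is.null(config$loci)) {
    .assert(!is.null(config$locus_order),
            "locus_order is required with 'loci'")
    .assert(all(config$locus_order %in% names(config$loci)),
            "locus_order names a locus not present under 'loci'")
  }
  if (!is.null(config$clades)) {
    .assert(!is.null(config$clades$members_a) &&
              !is.null(config$clades$members_b),
            "clades needs members_a and members_b")
    config$clades$partition <- cladePartition(
      unlist(config$clades$members_a), unlist(config$clades$members_b))
  }
  if (!is.null(config$calibration)) {
    .assert(length(config$calibration$pair) == 2L,
            "calibration.pair must name two species")
    .assert(is.numeric(config$calibration$time_ma) &&
              config$calibration$time_ma > 0,
            "calibration.time_ma must be a positive number")
  }
  structure(config, class = "PipelineConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr, outdir) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full phylo-epigenetic pipeline
#'
#' Orchestrates: input (simulated or real), dinucleotide tiling and
#' classification, variability statistics, substitution spectrum, clade
#' markers, CpG recoding, percent identity, and two calibrated UPGMA trees
#' (all-changes and CpG-only) plus their Robinson-Foulds distance. All
#' artefacts are written under \code{config$outdir}; two runs with the same
#' config and seed produce byte-identical outputs (the manifest carries no
#' timestamps).
#'
#' @param config A [validateConfig()]-acceptable configuration.
#' @return Invisibly, a list with every intermediate object plus a
#'   \code{summary} list of headline numbers.
#' @export
runPipeline <- function(config) {
  config <- if (inherits(config, "PipelineConfig")) config
            else validateConfig(config)
  outdir <- config$outdir %||% tempfile("phylocpg_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  # fail before compute on calibration species not in input (simulate mode
  # checks against the study tree labels)
  sim <- NULL
  if (!is.null(config$simulate)) {
    tree <- studyTree(rate = config$simulate$rate %||% 1.6e-4)
    ids <- tree@phy$tip.label
  } else if (!is.null(config$alignment)) {
    ids <- names(readFasta(config$alignment, allowGaps = TRUE))
  } else {
    ids <- names(readFasta(config$loci[[config$locus_order[1L]]]))
  }
  if (!is.null(config$calibration)) {
    missing <- setdiff(config$calibration$pair, ids)
    .assert(length(missing) == 0L,
            "calibration species '%s' not among input ids", missing[1L])
  }
  if (!is.null(config$clades)) {
    missing <- setdiff(c(config$clades$partition$membersA,
                         config$clades$partition$membersB), ids)
    .assert(length(missing) == 0L,
            "clade species '%s' not among input ids", missing[1L])
  }

  if (!is.null(config$simulate)) {
    sim <- .stage("simulate", {
      s <- simulateStudyDataset(config$simulate$params, tree = tree)
      writeFasta(s@sequences, file.path(outdir, "leaves.fasta"))
      writeNewick(s@tree, file.path(outdir, "truth.nwk"))
      eventLogTsv(s, file.path(outdir, "events.tsv"))
      s
    }, outdir)
    msa <- simMsa(sim)
  } else if (!is.null(config$alignment)) {
    msa <- .stage("align", buildMsa(config$alignment, mode = "preloaded"),
                  outdir)
  } else {
    msa <- .stage("align", {
      loci <- lapply(config$loci, readFasta)
      cat_seqs <- concatenateLoci(loci, config$locus_order)
      writeFasta(cat_seqs, file.path(outdir, "concatenated.fasta"))
      buildMsa(cat_seqs, mode = "external")
    }, outdir)
  }
  writeFasta(msa@seqs, file.path(outdir, "alignment.fasta"))

  table <- .stage("annotate", {
    tb <- classifyPositions(tileDinucleotides(msa))
    positionTableTsv(tb, file.path(outdir, "positions.tsv"))
    tb
  }, outdir)
  stats <- .stage("stats", {
    st <- variabilityStats(table, msa)
    con <- file(file.path(outdir, "variability.txt"), "w")
    sink(con); show(st); sink(); close(con)
    st
  }, outdir)
  spectrum <- .stage("spectrum", {
    sp <- substitutionSpectrum(table)
    utils::write.table(
      data.frame(alt_state = names(sp), count = as.integer(sp)),
      file.path(outdir, "spectrum.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    sp
  }, outdir)
  markers <- NULL
  if (!is.null(config$clades)) {
    markers <- .stage("markers", {
      mk <- list(cpg = cladeMarkers(table, config$clades$partition, "cpg"),
                 snv = cladeMarkers(table, config$clades$partition, "snv"))
      writeLines(c("# cpg markers: dinucleotide position indices (1-based)",
                   paste(mk$cpg, collapse = "\t"),
                   "# snv markers: alignment column indices (1-based)",
                   paste(mk$snv, collapse = "\t")),
                 file.path(outdir, "clade_markers.txt"))
      mk
    }, outdir)
  }
  recoded <- .stage("recode", {
    rc <- recodeCpg(table)
    writeRecodedFasta(rc, file.path(outdir, "recoded.fasta"))
    recodedMatrixTsv(rc, table, file.path(outdir, "recoded.tsv"))
    rc
  }, outdir)
  pim <- .stage("pim", {
    p <- percentIdentity(msa)
    matrixTsv(round(p, 4), file.path(outdir, "percent_identity.tsv"))
    p
  }, outdir)
  trees <- .stage("trees", {
    t_all <- upgmaTree(pDistance(msa, indels = config$indels))
    t_cpg <- upgmaTree(pDistance(recoded))
    if (!is.null(config$calibration)) {
      t_all <- calibrateTree(t_all, config$calibration$pair,
                             config$calibration$time_ma)
      t_cpg <- calibrateTree(t_cpg, config$calibration$pair,
                             config$calibration$time_ma)
    }
    writeNewick(t_all, file.path(outdir, "tree_all_changes.nwk"))
    writeNewick(t_cpg, file.path(outdir, "tree_cpg_only.nwk"))
    list(all = t_all, cpg = t_cpg, rf = rfDistance(t_all, t_cpg))
  }, outdir)

  cfg_echo <- unclass(config)
  cfg_echo$outdir <- NULL  # keep the manifest location-independent
  cfg_txt <- yaml::as.yaml(lapply(cfg_echo, function(x) {
    if (inherits(x, "CladePartition") || inherits(x, "ErosionParams"))
      unclass(x) else x
  }))
  manifest <- c(
    sprintf("phyloCpG_version: %s",
            as.character(utils::packageVersion("phyloCpG"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("config_checksum: %s", .checksum(cfg_txt)),
    "config:",
    paste0("  ", strsplit(cfg_txt, "\n")[[1L]]))
  writeLines(manifest, file.path(outdir, "manifest.yaml"))

  summary <- list(
    n_dinuc_positions = stats@nDinucPositions,
    n_cpg_positions = stats@nCpgPositions,
    n_variable_cpg = stats@nVariableCpg,
    n_conserved_cpg = stats@nConservedCpg,
    n_noncpg_variable_nt = stats@nNonCpgVariableNt,
    rf_between_trees = trees$rf)
  invisible(list(outdir = outdir, sim = sim, msa = msa, table = table,
                 stats = stats, spectrum = spectrum, markers = markers,
                 recoded = recoded, pim = pim, treeAll = trees$all,
                 treeCpg = trees$cpg, rfBetweenTrees = trees$rf,
                 summary = summary))
}
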