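#' @importFrom jsonlite toJSON write_json read_json
#' @importFrom tools md5sum
NULL

.configKeys <- c(
  "seed", "n_woody", "n_nonwoody", "woody_k", "woody_c", "nonwoody_k",
  "nonwoody_c", "sr_mode_woody", "sr_mode_nonwoody", "sr_slope_woody",
  "sr_intercept_woody", "sigma_t", "sigma_sr", "sigma_rtd", "sigma_rn",
  "rho_stele", "rho_outer", "nu_stele", "nu_outer",
  "meanlog_woody", "sdlog_woody", "meanlog_nonwoody", "sdlog_nonwoody",
  "lambda", "sigma2", "anatomy_woody", "anatomy_nonwoody",
  "duplicate_fraction", "frac_correlated", "frac_uncorrelated",
  "rtd_threshold")

#' Read a flat key = value generator configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Unknown keys are an
#' error listing them; `seed` is mandatory. Keys not present fall back to the
#' [generatorConfig()] defaults.
#'
#' @param path configuration file path
#' @return list with `config` (a [GeneratorConfig-class]) and `extras`
#'   (class-assignment settings: frac_correlated, frac_uncorrelated,
#'   rtd_threshold)
#' @export
readGeneratorConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("bad config line: ", ln)
    kv[[m[2]]] <- trimws(m[3])
  }
  unknown <- setdiff(names(kv), .configKeys)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(kv$seed)) stop("seed is mandatory in the config")
  num <- function(key, default) if (is.null(kv[[key]])) default else as.numeric(kv[[key]])
  chr <- function(key, default) if (is.null(kv[[key]])) default else kv[[key]]
  cfg <- generatorConfig(
    seed = as.integer(kv$seed),
    nWoody = num("n_woody", 505), nNonWoody = num("n_nonwoody", 361),
    woodyParams = AllometryParams(num("woody_k", 0.43), num("woody_c", -0.016)),
    nonWoodyParams = AllometryParams(num("nonwoody_k", 0.32), num("nonwoody_c", 0.011)),
    srModeWoody = chr("sr_mode_woody", "independent"),
    srModeNonWoody = chr("sr_mode_nonwoody", "complement"),
    srSlopeWoody = num("sr_slope_woody", 0.068),
    srInterceptWoody = num("sr_intercept_woody", 0.016),
    sigmaT = num("sigma_t", 0.02), sigmaSR = num("sigma_sr", 0.004),
    sigmaRTD = num("sigma_rtd", 0.05), sigmaRN = num("sigma_rn", 2),
    mixture = TissueMixture(num("rho_stele", 0.45), num("rho_outer", 0.12),
                            num("nu_stele", 6), num("nu_outer", 14)),
    meanlogWoody = num("meanlog_woody", log(0.35)),
    sdlogWoody = num("sdlog_woody", 0.45),
    meanlogNonWoody = num("meanlog_nonwoody", log(0.25)),
    sdlogNonWoody = num("sdlog_nonwoody", 0.4),
    lambda = num("lambda", 0.83), sigma2 = num("sigma2", 1),
    anatomyWoody = num("anatomy_woody", 158),
    anatomyNonWoody = num("anatomy_nonwoody", 13),
    duplicateFraction = num("duplicate_fraction", 0))
  list(config = cfg,
       extras = list(frac_correlated = num("frac_correlated", 0.53),
                     frac_uncorrelated = num("frac_uncorrelated", 0.17),
                     rtd_threshold = num("rtd_threshold", 0.236)))
}

.manifestStage <- function(name, rowsIn, rowsOut, note = "") {
  list(stage = name, rows_in = rowsIn, rows_out = rowsOut, note = note)
}

.writeManifest <- function(outDir, seed, stages, files) {
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- basename(files)
  manifest <- list(
    package_version = as.character(utils::packageVersion("rootAllometry")),
    master_seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = stages,
    output_hashes = hashes)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a dataset to files
#'
#' Writes `traits.csv`, `tree.nwk`, `truth.json` and `manifest.json` into
#' `outDir`. Identical config and seed give byte-identical trait/tree/truth
#' files (the manifest carries a timestamp).
#'
#' @param config a [GeneratorConfig-class], or a path to a flat key = value
#'   config file
#' @param outDir writable output directory (created if needed)
#' @param classFracs optional c(correlated, uncorrelated) high-RTD fractions
#'   used to fill `data_source_class` (defaults 0.53 / 0.17); NULL leaves the
#'   column unassigned
#' @return (invisibly) the [RootTraitData-class] that was written
#' @export
simulateToFiles <- function(config, outDir, classFracs = c(0.53, 0.17)) {
  if (is.character(config)) config <- readGeneratorConfig(config)$config
  stopifnot(is(config, "GeneratorConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dat <- generateDataset(config)
  tab <- traits(dat)
  if (!is.null(classFracs)) {
    # the correlated/uncorrelated study split is a woody-root phenomenon:
    # realize the target high-RTD frequencies within the woody records and
    # split non-woody records evenly
    iW <- which(tab$growth_form == "woody")
    tab$thin_high_rtd <- NA
    if (length(iW) >= 4) {
      w <- makeDataSourceClasses(tab[iW, , drop = FALSE],
                                 classFracs[1], classFracs[2],
                                 seed = stageSeed(config@seed, "classes"))
      tab$data_source_class[iW] <- w$data_source_class
      tab$thin_high_rtd[iW] <- w$thin_high_rtd
    }
    iN <- which(tab$growth_form != "woody")
    if (length(iN)) {
      set.seed(stageSeed(config@seed, "classesNW"))
      tab$data_source_class[iN] <-
        sample(rep(c("correlated", "uncorrelated"), length.out = length(iN)))
    }
  }
  traitsPath <- file.path(outDir, "traits.csv")
  treePath <- file.path(outDir, "tree.nwk")
  truthPath <- file.path(outDir, "truth.json")
  utils::write.csv(tab, traitsPath, row.names = FALSE, na = "NA")
  writeNewick(phylogeny(dat), treePath)
  jsonlite::write_json(generatorTruth(dat), truthPath, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stages <- list(.manifestStage("simulate", 0L, nrow(tab)),
                 .manifestStage("classes", nrow(tab), nrow(tab),
                                if (is.null(classFracs)) "skipped" else "assigned"))
  .writeManifest(outDir, config@seed, stages, c(traitsPath, treePath, truthPath))
  dat@traits <- tab
  invisible(dat)
}

.requiredColumns <- c("species", "diameter", "RTD", "RN", "growth_form")

.readTraitTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.requiredColumns, names(tab))
  if (length(miss)) stop("trait CSV schema violation: missing columns ",
                         paste(miss, collapse = ", "))
  for (cn in c("diameter", "RTD", "RN")) {
    bad <- which(!is.na(tab[[cn]]) & !is.finite(suppressWarnings(as.numeric(tab[[cn]]))))
    if (length(bad)) stop(sprintf("trait CSV schema violation: column %s row %d not numeric",
                                  cn, bad[1]))
    tab[[cn]] <- as.numeric(tab[[cn]])
  }
  bad <- which(!is.na(tab$diameter) & tab$diameter <= 0)
  if (length(bad)) stop(sprintf("trait CSV schema violation: column diameter row %d not positive",
                                bad[1]))
  tab
}

#' Run the full analysis pipeline on a trait table (and optional tree)
#'
#' Orchestrates, in order: species-mean aggregation; the tToS/SR-diameter
#' allometry per growth form with SMA slope comparisons; the stele-proportion
#' stage (outlier exclusion, PRS-diameter nonlinear fits, PRS-RTD/RN linear
#' fits); nonlinear trait-diameter fits for all species and by growth form,
#' mycorrhizal type and root-order class, with ANCOVA interaction tests;
#' phylogenetic stages (PIC regressions, Blomberg's K, Pagel's lambda, PGLS)
#' when a tree with at least 4 matching species is given; and the
#' data-source split analysis when classes are assigned. Skipped stages are
#' recorded with the reason rather than failing the run.
#'
#' @param traitsPath path to the trait CSV
#' @param treePath optional Newick tree path (NULL skips phylogenetic stages)
#' @param outDir output directory for `report.json`, `exclusions.csv` and
#'   `manifest.json`
#' @param rtdThreshold RTD threshold for the high-RTD frequency comparison
#' @param signalPermutations permutations for Blomberg's K p-values
#' @return (invisibly) the report list
#' @export
analyzeFiles <- function(traitsPath, treePath = NULL, outDir,
                         rtdThreshold = 0.236, signalPermutations = 199L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  raw <- .readTraitTable(traitsPath)
  report <- list(substitution_note = paste(
    "interaction tests are OLS ANCOVA F-tests, substituting a REML mixed model",
    "with study structure"))
  stages <- list()
  tab <- aggregateSpeciesMeans(raw)
  stages[[length(stages) + 1]] <- .manifestStage("aggregate", nrow(raw), nrow(tab))

  # --- anatomy allometry + SMA slope comparisons ---
  anatomy <- list(); smaCmp <- list()
  anaGroups <- list()
  for (g in unique(tab$growth_form)) {
    i <- which(tab$growth_form == g & is.finite(tab$tToS) & is.finite(tab$diameter))
    if (length(i) >= 3) {
      fa <- fitAnatomyAllometry(tab$diameter[i], tab$tToS[i])
      entry <- list(tToS = fitReport(fa$fit),
                    k = paramK(fa$params), c = paramC(fa$params))
      j <- i[is.finite(tab$SR[i])]
      if (length(j) >= 3) {
        entry$SR <- fitReport(olsFit(tab$diameter[j], tab$SR[j]))
        anaGroups[[g]] <- list(x = tab$diameter[j], tToS = tab$tToS[j], SR = tab$SR[j])
      }
      anatomy[[g]] <- entry
    }
  }
  if (length(anaGroups) >= 2) {
    gs <- names(anaGroups)[1:2]
    smaCmp$tToS <- smaCommonSlopeTest(list(
      list(x = anaGroups[[gs[1]]]$x, y = anaGroups[[gs[1]]]$tToS),
      list(x = anaGroups[[gs[2]]]$x, y = anaGroups[[gs[2]]]$tToS)))
    smaCmp$SR <- smaCommonSlopeTest(list(
      list(x = anaGroups[[gs[1]]]$x, y = anaGroups[[gs[1]]]$SR),
      list(x = anaGroups[[gs[2]]]$x, y = anaGroups[[gs[2]]]$SR)))
    smaCmp$groups <- gs
  }
  report$anatomy_allometry <- anatomy
  report$sma_slope_comparison <- smaCmp
  stages[[length(stages) + 1]] <- .manifestStage("anatomy", nrow(tab), nrow(tab))

  # --- PRS stage: outlier exclusion, PRS-diameter and PRS-trait fits ---
  prsStage <- list()
  if ("PRS" %in% names(tab)) {
    excl <- excludeOutliers(tab)
    utils::write.csv(excl$log, file.path(outDir, "exclusions.csv"), row.names = FALSE)
    prsTab <- excl$table
    prsStage$excluded <- excl$log$species
    for (g in unique(prsTab$growth_form)) {
      i <- which(prsTab$growth_form == g & is.finite(prsTab$PRS))
      entry <- list()
      if (length(i) >= 10)
        entry$prs_vs_diameter <- fitReport(
          nlsAllometricFit(prsTab$diameter[i], prsTab$PRS[i]))
      if (length(i) >= 3) {
        entry$prs_vs_rtd <- fitReport(olsFit(prsTab$PRS[i], prsTab$RTD[i]))
        if (length(i) >= 14)   # small-sample PRS-RN relations are not tested
          entry$prs_vs_rn <- fitReport(olsFit(prsTab$PRS[i], prsTab$RN[i]))
      }
      if (length(entry)) prsStage[[g]] <- entry
    }
    stages[[length(stages) + 1]] <- .manifestStage("prs", nrow(tab), nrow(prsTab),
                                                   sprintf("%d excluded", nrow(excl$log)))
  } else {
    prsStage$skipped <- "no PRS column"
  }
  report$prs_stage <- prsStage

  # --- nonlinear trait fits across groupings ---
  nlf <- list()
  for (tr in c("RTD", "RN")) {
    i <- which(is.finite(tab$diameter) & is.finite(tab[[tr]]))
    nlf[[tr]] <- list(all = fitReport(nlsAllometricFit(tab$diameter[i], tab[[tr]][i])))
    byForm <- fitByGroup(tab, tr, "growth_form")
    nlf[[tr]]$by_growth_form <- lapply(byForm$fits, fitReport)
    woody <- tab[tab$growth_form == "woody", , drop = FALSE]
    if (nrow(woody) >= 10 && "mycorrhiza" %in% names(tab)) {
      byMyc <- fitByGroup(woody, tr, "mycorrhiza")
      nlf[[tr]]$by_mycorrhiza <- lapply(byMyc$fits, fitReport)
      nlf[[tr]]$by_mycorrhiza_skipped <- as.list(byMyc$skipped)
    }
    if (nrow(woody) >= 10 && "root_sampling" %in% names(tab)) {
      byOrd <- fitByGroup(woody, tr, "root_sampling")
      nlf[[tr]]$by_root_sampling <- lapply(byOrd$fits, fitReport)
    }
  }
  report$nonlinear_fits <- nlf
  interactions <- list()
  for (tr in c("RTD", "RN")) {
    if (length(unique(tab$growth_form)) >= 2)
      interactions[[paste0(tr, "_x_growth_form")]] <-
        interactionTest(tab, tr, "growth_form")
    woody <- tab[tab$growth_form == "woody", , drop = FALSE]
    main <- woody[woody$mycorrhiza %in% c("AM", "EM", "ERM"), , drop = FALSE]
    if (length(unique(main$mycorrhiza)) >= 2 && all(table(main$mycorrhiza) >= 3))
      interactions[[paste0(tr, "_x_mycorrhiza")]] <-
        interactionTest(main, tr, "mycorrhiza")
  }
  report$interaction_tests <- interactions
  stages[[length(stages) + 1]] <- .manifestStage("nonlinear", nrow(tab), nrow(tab))

  # --- phylogenetic stages ---
  phylo <- list()
  tree <- NULL
  if (!is.null(treePath)) tree <- readNewick(treePath)
  if (is.null(tree)) {
    phylo$skipped <- "no tree supplied"
  } else {
    common <- intersect(.normalizeSpecies(tree$tip.label),
                        .normalizeSpecies(tab$species))
    if (length(common) < 4) {
      phylo$skipped <- sprintf("only %d species shared between tree and table",
                               length(common))
    } else {
      keepTips <- tree$tip.label[.normalizeSpecies(tree$tip.label) %in% common]
      sub <- ape::keep.tip(tree, keepTips)
      if (!ape::is.binary(sub)) sub <- resolvePolytomies(sub, seed = 1L)
      ti <- match(.normalizeSpecies(sub$tip.label), .normalizeSpecies(tab$species))
      ptab <- tab[ti, , drop = FALSE]
      for (tr in c("diameter", "RTD", "RN")) {
        v <- stats::setNames(ptab[[tr]], sub$tip.label)
        if (any(!is.finite(v))) next
        phylo$signals[[tr]] <- list(
          K = {
            s <- blombergK(sub, v, nPerm = signalPermutations,
                           seed = stageSeed(1L, paste0("K", tr)))
            list(estimate = signalEstimate(s), p = signalP(s))
          },
          lambda = {
            s <- pagelLambdaML(sub, v)
            list(estimate = signalEstimate(s), p = signalP(s))
          })
      }
      for (tr in c("RTD", "RN")) {
        xv <- stats::setNames(ptab$diameter, sub$tip.label)
        yv <- stats::setNames(ptab[[tr]], sub$tip.label)
        if (any(!is.finite(xv)) || any(!is.finite(yv))) next
        phylo$pic[[tr]] <- picRegression(sub, xv, yv)
        if (length(unique(ptab$growth_form)) >= 2) {
          fml <- stats::as.formula(paste(tr, "~ diameter * growth_form"))
          pg <- pglsFit(sub, fml, ptab, correlation = "BM")
          phylo$pgls[[tr]] <- list(
            coefficients = cbind(term = rownames(pg$coefficients),
                                 pg$coefficients),
            sigma2 = pg$sigma2, n = pg$n)
        }
      }
      phylo$n_tips <- length(sub$tip.label)
    }
  }
  report$phylogenetic <- phylo
  stages[[length(stages) + 1]] <- .manifestStage(
    "phylo", nrow(tab), nrow(tab),
    if (!is.null(phylo$skipped)) paste("skipped:", phylo$skipped) else "ran")

  # --- data-source split ---
  ds <- list()
  if ("data_source_class" %in% names(tab) &&
      all(c("correlated", "uncorrelated") %in% tab$data_source_class)) {
    woody <- tab[tab$growth_form == "woody", , drop = FALSE]
    use <- if (all(c("correlated", "uncorrelated") %in% woody$data_source_class))
      woody else tab
    res <- dataSourceAnalysis(use, threshold = rtdThreshold)
    ds <- list(r2 = as.list(as.data.frame(res$r2)),
               high_rtd_freq = as.list(res$highRTDFreq),
               freq_gap_points = as.numeric(res$freqGap),
               correlated_fits_better = res$r2Ordering,
               threshold = res$threshold)
  } else {
    ds$skipped <- "data_source_class not assigned"
  }
  report$data_source <- ds
  stages[[length(stages) + 1]] <- .manifestStage(
    "data_source", nrow(tab), nrow(tab),
    if (!is.null(ds$skipped)) paste("skipped:", ds$skipped) else "ran")

  reportPath <- file.path(outDir, "report.json")
  jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  .writeManifest(outDir, NA, stages, reportPath)
  invisible(report)
}

#' Repeated simulate-and-recover summary
#'
#' Repeats the generator and the anatomy-allometry fits `nReps` times with
#' fresh seeds and summarizes, for every allometry truth parameter, the mean
#' estimate, bias, and empirical coverage of the 95% OLS confidence
#' intervals.
#'
#' @param config a [GeneratorConfig-class] (its seed seeds rep 1; later reps
#'   increment it)
#' @param nReps number of repetitions (>= 10)
#' @param nAnatomy roots simulated per rep for the anatomy recovery
#' @return data.frame with one row per parameter: truth, mean estimate, bias,
#'   coverage
#' @export
recoverySummary <- function(config, nReps = 50L, nAnatomy = 500L) {
  stopifnot(is(config, "GeneratorConfig"), nReps >= 10)
  pars <- list(
    woody_k = list(truth = config@woodyParams@k),
    woody_c = list(truth = config@woodyParams@c),
    nonwoody_k = list(truth = config@nonWoodyParams@k),
    nonwoody_c = list(truth = config@nonWoodyParams@c))
  est <- matrix(NA_real_, nReps, 4, dimnames = list(NULL, names(pars)))
  cover <- matrix(NA, nReps, 4, dimnames = list(NULL, names(pars)))
  for (r in seq_len(nReps)) {
    sW <- generateAnatomySample(nAnatomy, config@woodyParams,
                                seed = stageSeed(config@seed + r, "recW"),
                                sigmaT = config@sigmaT,
                                meanlog = config@meanlogWoody,
                                sdlog = config@sdlogWoody)
    sN <- generateAnatomySample(nAnatomy, config@nonWoodyParams,
                                seed = stageSeed(config@seed + r, "recN"),
                                sigmaT = config@sigmaT,
                                meanlog = config@meanlogNonWoody,
                                sdlog = config@sdlogNonWoody)
    fW <- olsFit(sW$diameter, sW$tToS)
    fN <- olsFit(sN$diameter, sN$tToS)
    tcrit <- stats::qt(0.975, nAnatomy - 2)
    est[r, ] <- c(fW@slope, fW@intercept, fN@slope, fN@intercept)
    cover[r, ] <- c(
      abs(fW@slope - pars$woody_k$truth) <= tcrit * fW@slopeSE,
      abs(fW@intercept - pars$woody_c$truth) <= tcrit * fW@interceptSE,
      abs(fN@slope - pars$nonwoody_k$truth) <= tcrit * fN@slopeSE,
      abs(fN@intercept - pars$nonwoody_c$truth) <= tcrit * fN@interceptSE)
  }
  data.frame(
    parameter = names(pars),
    truth = vapply(pars, `[[`, numeric(1), "truth"),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - vapply(pars, `[[`, numeric(1), "truth"),
    coverage95 = colMeans(cover),
    n_reps = nReps, row.names = NULL)
}

#' Validate an analysis report against the in-repo schema
#'
#' Lightweight structural check: the schema (inst/schema/report-schema.json)
#' lists required top-level keys and required sub-keys per section; missing
#' keys are an error.
#'
#' @param report the report list (or a path to report.json)
#' @param schemaPath schema path; default the installed copy
#' @return TRUE (invisibly) if valid
#' @export
validateReport <- function(report,
                           schemaPath = system.file("schema", "report-schema.json",
                                                    package = "rootAllometry")) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(schemaPath)
  miss <- setdiff(unlist(schema$required), names(report))
  if (length(miss)) stop("report invalid: missing sections ",
                         paste(miss, collapse = ", "))
  for (sec in names(schema$sections)) {
    if (!sec %in% names(report)) next
    node <- report[[sec]]
    if (!is.null(node$skipped)) next
    need <- unlist(schema$sections[[sec]]$required_unless_skipped)
    missSec <- setdiff(need, names(node))
    if (length(missSec))
      stop("report invalid: section ", sec, " missing ",
           paste(missSec, collapse = ", "))
  }
  invisible(TRUE)
}
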