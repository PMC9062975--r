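#' Pipeline configuration
#'
#' Collects everything a full run needs: discovery inputs (a matrix TSV +
#' group CSV, or a simulation spec), optional GMT annotation, validation
#' inputs (a cohort CSV or a simulation spec), selection thresholds, CV
#' settings, one global seed (expanded deterministically into per-stage
#' seeds) and the output directory.
#'
#' @param discovery list. Either `list(matrix = "m.tsv", groups =
#'   "meta.csv")` or a simulation spec: any arguments of
#'   [simulateDiscovery()] (its `seed` is derived from the global seed).
#' @param validation list, or `NULL` to skip the validation stage. Either
#'   `list(cohort = "c.csv")` or arguments of [simulateValidation()].
#' @param annotation optional path to a GMT file for enrichment.
#' @param biomarkers biomarker columns to validate; default: the selected
#'   discovery features present in the cohort, falling back to every
#'   cohort biomarker.
#' @param scale optional named numeric of per-unit multipliers for
#'   [rescaleHR()] reporting (e.g. `c(EPCR = 10, CETP = 100)`).
#' @param fcHi,fcLo,alpha DEP thresholds, see [depTable()].
#' @param kMax,folds feature-selection settings, see [ifsSelect()].
#' @param seed global integer seed.
#' @param outDir output directory (created if needed).
#' @return object of class `pipelineConfig`.
#' @seealso [runPipeline()], [readPipelineConfig()]
#' @export
pipelineConfig <- function(discovery = list(), validation = NULL,
                           annotation = NULL, biomarkers = NULL,
                           scale = NULL, fcHi = 1.2, fcLo = 0.8,
                           alpha = 0.05, kMax = 30, folds = 10, seed = 1,
                           outDir = tempfile("proteomace_run_")) {
  structure(list(discovery = discovery, validation = validation,
                 annotation = annotation, biomarkers = biomarkers,
                 scale = scale, fcHi = fcHi, fcLo = fcLo, alpha = alpha,
                 kMax = as.integer(kMax), folds = as.integer(folds),
                 seed = as.integer(seed), outDir = outDir),
            class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file with the fields above (snake_case accepted).
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  nm <- names(y)
  names(y)[nm == "fc_hi"] <- "fcHi"
  names(y)[nm == "fc_lo"] <- "fcLo"
  names(y)[nm == "k_max"] <- "kMax"
  names(y)[nm == "out_dir"] <- "outDir"
  if (!is.null(y$scale)) y$scale <- unlist(y$scale)
  do.call(pipelineConfig, y)
}

load_discovery <- function(config) {
  dc <- config$discovery
  if (!is.null(dc$matrix)) {
    if (is.null(dc$groups))
      stop("discovery$matrix given without discovery$groups", call. = FALSE)
    readAbundanceTsv(dc$matrix, dc$groups)
  } else {
    dc$seed <- derive_seed(config$seed, 101L)
    do.call(simulateDiscovery, dc)
  }
}

load_validation <- function(config) {
  vc <- config$validation
  if (is.null(vc)) return(NULL)
  if (!is.null(vc$cohort)) {
    readCohortCsv(vc$cohort)
  } else {
    vc$seed <- derive_seed(config$seed, 202L)
    do.call(simulateValidation, vc)
  }
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes differential-abundance selection, optional enrichment,
#' incremental feature selection over the soft-voting classifier, and
#' (when a validation cohort is configured) Cox survival validation with a
#' DeLong comparison of the Framingham baseline model against the
#' biomarker-augmented model. All stage tables are written to
#' `config$outDir` along with a machine-readable `report.json`; outputs are
#' pure functions of (inputs, config).
#'
#' Files written: `dep_table.tsv`, `volcano.tsv`, `enrichment.tsv` (if
#' annotated), `ranking.tsv`, `ifs_curve.tsv`, `selected_features.json`,
#' `cv_roc.tsv`, `cv_summary.json`, and with a cohort `cox_univariate.tsv`,
#' `cox_multivariate.tsv`, `roc_base.tsv`, `roc_combined.tsv`,
#' `model_comparison.json`; always `report.json`.
#'
#' @param config a [pipelineConfig()].
#' @return the report, invisibly (a named list mirroring `report.json`).
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(
#'   discovery = list(nPerGroup = 10, nProteins = 60, nDep = 6,
#'                    log2Effect = 1.5),
#'   validation = list(nSubjects = 250), kMax = 5, seed = 42)
#' rep <- runPipeline(cfg)
#' rep$dep$n_selected
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  # validate inputs before any computation
  for (p in c(config$discovery$matrix, config$discovery$groups,
              config$annotation, config$validation$cohort)) {
    if (!is.null(p) && !file.exists(p))
      stop("missing input file: ", p, call. = FALSE)
  }
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)

  ae <- load_discovery(config)

  ## stage 1: differential abundance
  dep <- depTable(ae, fcHi = config$fcHi, fcLo = config$fcLo,
                  alpha = config$alpha)
  write_tsv(dep, out("dep_table.tsv"))
  volcano <- data.frame(protein_id = dep$protein_id,
                        log2_fc = log2(dep$fold_change),
                        neg_log10_p = -log10(dep$p_value),
                        selected = dep$selected)
  write_tsv(volcano, out("volcano.tsv"))
  dep_ids <- dep$protein_id[dep$selected]
  if (!length(dep_ids))
    stop("pipeline aborted at stage dep_analysis: no differential proteins ",
         "passed the selection criterion", call. = FALSE)

  ## stage 2: enrichment (optional)
  enr <- NULL
  if (!is.null(config$annotation)) {
    ann <- readGmt(config$annotation)
    enr <- fisherEnrichment(dep_ids, dep$protein_id[dep$testable], ann)
    write_tsv(enr, out("enrichment.tsv"))
  }

  ## stage 3: feature selection
  ranking <- rankFeatures(ae, dep_ids)
  write_tsv(ranking, out("ranking.tsv"))
  cls <- classifierSpec(seed = derive_seed(config$seed, 303L))
  curve <- ifsSelect(ae, ranking, kMax = config$kMax, spec = cls,
                     folds = config$folds)
  write_tsv(ifsPoints(curve), out("ifs_curve.tsv"))
  sel <- selectedFeatures(curve)
  jsonlite::write_json(list(selected_k = selectedK(curve), features = sel),
                       out("selected_features.json"), auto_unbox = TRUE)
  roc <- cvRoc(ae, featureIds = sel, spec = cls, folds = config$folds)
  write_tsv(roc$roc, out("cv_roc.tsv"))
  jsonlite::write_json(
    list(auc = roc$auc, confusion = roc$counts, folds = config$folds,
         seed = cls$seed),
    out("cv_summary.json"), auto_unbox = TRUE, digits = NA)

  report <- list(
    config = unclass(config)[c("fcHi", "fcLo", "alpha", "kMax", "folds",
                               "seed")],
    versions = list(ProteoMACE = as.character(utils::packageVersion(
      "ProteoMACE")), R = paste(R.version$major, R.version$minor, sep = ".")),
    dep = list(n_proteins = nrow(dep),
               n_untestable = metadata(dep)$n_untestable,
               n_selected = length(dep_ids)),
    enrichment = if (!is.null(enr))
      list(n_terms = nrow(enr), n_significant = sum(enr$p_adjusted < 0.05)),
    selection = list(selected_k = selectedK(curve), features = sel,
                     max_mcc = max(ifsPoints(curve)$mcc), cv_auc = roc$auc)
  )

  ## stage 4: survival validation (optional)
  cohort <- load_validation(config)
  if (!is.null(cohort)) {
    writeCohortCsv(cohort, out("cohort.csv"))
    bms <- config$biomarkers
    if (is.null(bms)) {
      bms <- intersect(sel, biomarkerNames(cohort))
      if (!length(bms)) bms <- biomarkerNames(cohort)
    }
    uni <- do.call(rbind, lapply(bms, function(b) coxTable(fitCox(cohort, b))))
    multi_fit <- fitCox(cohort, c(framinghamCovariates(), bms))
    multi <- coxTable(multi_fit)
    if (!is.null(config$scale)) {
      for (b in intersect(names(config$scale), bms)) {
        k <- config$scale[[b]]
        for (tab in c("uni", "multi")) {
          t0 <- get(tab)
          i <- which(t0$term == b)
          r <- exp(k * (t0$beta[i] + c(0, -1, 1) * 1.959963984540054 *
                          t0$se[i]))
          t0$hr[i] <- r[1]; t0$ci_lower[i] <- r[2]; t0$ci_upper[i] <- r[3]
          t0$scale_k <- if (is.null(t0$scale_k)) 1 else t0$scale_k
          t0$scale_k[i] <- k
          assign(tab, t0)
        }
      }
    }
    write_tsv(uni, out("cox_univariate.tsv"))
    write_tsv(multi, out("cox_multivariate.tsv"))

    d <- cohortData(cohort)
    base_score <- buildRiskScore(cohort, framinghamCovariates())
    comb_score <- buildRiskScore(cohort, c(framinghamCovariates(), bms))
    write_tsv(rocAuc(base_score, d$event)$roc, out("roc_base.tsv"))
    write_tsv(rocAuc(comb_score, d$event)$roc, out("roc_combined.tsv"))
    dl <- delongTest(comb_score, base_score, d$event)
    comparison <- list(auc_base = dl$aucB, auc_combined = dl$aucA,
                       z = dl$z, p = dl$p, n = nrow(d))
    jsonlite::write_json(comparison, out("model_comparison.json"),
                         auto_unbox = TRUE, digits = NA)

    report$validation <- list(
      n_subjects = nrow(d), n_events = sum(d$event),
      event_fraction = mean(d$event), biomarkers = bms,
      cox_univariate = uni, cox_multivariate = multi,
      model_comparison = comparison)
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", null = "null")
  invisible(report)
}
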