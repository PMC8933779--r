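#' Published band-count distribution of a post-COVID cohort
#'
#' The observed three-category band counts (and the percentages as
#' printed) of the 33-score battery in a cohort of 63 outpatients assessed
#' for subjective cognitive complaints after SARS-CoV-2 infection.  Shipped
#' as a worked reference input for [distributionFromCounts()] and for
#' consistency checks; note that the recognition-memory row is internally
#' inconsistent in the source (its printed percentages imply a denominator
#' of 60 while its counts sum to 63) — see [checkDistributionConsistency()].
#'
#' @return A \code{data.frame} of counts and printed percentages.
#' @export
referenceBandCounts <- function() {
  read.csv(system.file("extdata", "postcovid_cohort_band_counts.csv",
                       package = "neurocog"),
           stringsAsFactors = FALSE, check.names = FALSE)
}

#' Check printed percentages against their own counts
#'
#' Recomputes the percentage columns of a distribution table from its
#' counts and flags rows whose printed percentages disagree (beyond the
#' 2-decimal rounding of the report).
#'
#' @param table A \code{data.frame} in the layout of
#'   [referenceBandCounts()]: counts plus printed \code{pct_*} columns.
#' @param tol Largest tolerated absolute difference; default 0.011 (one
#'   unit in the second decimal).
#' @return The table with a logical \code{consistent} column appended.
#' @examples
#' chk <- checkDistributionConsistency(referenceBandCounts())
#' chk$score_id[!chk$consistent]
#' @export
checkDistributionConsistency <- function(table, tol = 0.011) {
  comp <- distributionFromCounts(table[c("score_id", "n_impaired",
                                         "n_low_avg", "n_avg_plus",
                                         "n_total")])
  cols <- c("pct_impaired", "pct_low_avg", "pct_avg_plus", "pct_below_24")
  dev <- abs(as.matrix(table[cols]) - as.matrix(comp[cols]))
  table$consistent <- apply(dev, 1, max) <= tol
  table
}

#' Run the full analysis pipeline
#'
#' Executes score loading, domain mapping, distribution table, impairment
#' profiles, and clinical correlates, writing versioned CSV artifacts plus
#' a run log that records every option.  Stages fail with a stage-named
#' error; artifacts written before the failure are preserved.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{cohort}{path to a scores CSV, or a [ScoredCohort-class].}
#'     \item{format}{\code{"wide"} or \code{"long"} (CSV input).}
#'     \item{norms}{optional normative-table CSV for raw long input.}
#'     \item{map}{optional domain-map YAML; default the built-in map.}
#'     \item{covariates}{optional covariates CSV (\code{patient_id} column).}
#'     \item{min_coverage, thresholds}{classification options.}
#'     \item{group, ancova_outcome, ancova_covariate}{optional covariate
#'       names for the hospitalization-style comparisons.}
#'     \item{out_dir}{output directory (created).}
#'     \item{seed}{optional integer; set before any stochastic stage.}
#'   }
#' @return Invisibly, a list with the in-memory results (cohort, map,
#'   distribution, profiles, summary, composites, correlations).
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run_log.txt")
  logline <- function(...) cat(..., "\n", file = logf, append = TRUE)
  cat("pipeline run", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "\n",
      file = logf)
  if (!is.null(config$seed)) {
    set.seed(config$seed)
    logline("seed:", config$seed)
  }
  opts <- config[setdiff(names(config), c("cohort", "out_dir"))]
  for (nm in names(opts))
    logline(nm, ":", paste(unlist(opts[[nm]]), collapse = " "))

  cohort <- stage("score", {
    if (is(config$cohort, "ScoredCohort")) config$cohort
    else {
      norms <- if (!is.null(config$norms))
        readNormativeTable(config$norms) else NULL
      readCohortScores(config$cohort,
                       format = config$format %||% "wide", norms = norms)
    }
  })
  if (!is.null(config$covariates) && is.character(config$covariates)) {
    cv <- stage("covariates", read.csv(config$covariates,
                                       stringsAsFactors = FALSE))
    i <- match(colnames(cohort), as.character(cv$patient_id))
    if (anyNA(i)) stop("pipeline stage 'covariates' failed: ",
                       "covariates missing for some patients", call. = FALSE)
    SummarizedExperiment::colData(cohort) <-
      S4Vectors::DataFrame(cv[i, setdiff(names(cv), "patient_id"),
                              drop = FALSE],
                           row.names = colnames(cohort))
  }
  map <- stage("domains", {
    if (is.null(config$map)) defaultDomainMap()
    else if (is(config$map, "DomainMap")) config$map
    else readDomainMap(config$map)
  })
  cohort <- setDomainMap(cohort, map)

  thresholds <- unlist(config$thresholds %||%
                         c(majority = 0.5, combined_impaired = 0.3,
                           combined_low = 0.3))
  min_coverage <- config$min_coverage %||% 0.5
  logline("effective thresholds:", paste(names(thresholds), thresholds,
                                         sep = "=", collapse = " "))
  logline("effective min_coverage:", min_coverage)

  dist <- stage("distribution", scoreDistributionTable(cohort, map))
  write.csv(dist, file.path(out_dir, "distribution.csv"), row.names = FALSE)
  prof <- stage("classify",
                impairmentProfiles(cohort, map, min_coverage = min_coverage,
                                   thresholds = thresholds))
  write.csv(prof, file.path(out_dir, "profiles.csv"), row.names = FALSE)
  summ <- stage("summary", profileSummary(prof))
  write.csv(as.data.frame(summ$cooccurrence),
            file.path(out_dir, "cooccurrence.csv"))
  write.csv(summ$class_freq, file.path(out_dir, "profile_classes.csv"),
            row.names = FALSE)

  comp <- stage("composites", compositeScores(cohort, map))
  corr <- NULL
  cv <- covariates(cohort)
  if (ncol(cv)) {
    num <- names(cv)[vapply(cv, is.numeric, TRUE)]
    corr <- stage("correlates", {
      do.call(rbind, lapply(num, function(nm) {
        res <- suppressWarnings(
          correlateCovariate(comp, cv[[nm]]))
        cbind(covariate = nm, res)
      }))
    })
    write.csv(corr, file.path(out_dir, "covariate_correlations.csv"),
              row.names = FALSE)
  }
  logline("artifacts written to", normalizePath(out_dir))
  invisible(list(cohort = cohort, map = map, distribution = dist,
                 profiles = prof, summary = summ, composites = comp,
                 correlations = corr))
}
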