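#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames rowData
#'   "rowData<-" colData "colData<-"
#' @importFrom S4Vectors DataFrame metadata "metadata<-"
#' @importFrom stats pnorm qnorm rnorm rbinom runif rlnorm cor cor.test
#'   chisq.test lm anova coef complete.cases setNames p.adjust var sd
#' @importFrom utils read.csv write.csv
NULL

.DOMAINS <- c("L+LTM", "VVA", "ST/WM", "ProcessingSpeed", "Language",
              "Attention", "EF")

.PROVENANCE <- c("factor_loading", "manual_override", "unassigned")

#' Seven-band performance classification scheme
#'
#' Encodes the consensus performance labels of the American Academy of
#' Clinical Neuropsychology as a partition of the percentile range
#' \eqn{[0, 100]}, together with the deterministic collapse onto the three
#' analysis categories (\code{impaired}, \code{low_average},
#' \code{average_plus}).
#'
#' The printed integer ranges (e.g. "low average: Pc 9--24") leave gaps for
#' non-integer percentiles; the scheme closes every interval on the right
#' (upper boundary included), so that \code{impaired} is exactly
#' \eqn{Pc \le 8} and \code{low_average} is \eqn{8 < Pc \le 24}.
#'
#' @slot breaks Numeric vector of interior cut points (strictly increasing,
#'   within \eqn{(0, 100)}).
#' @slot labels Character vector of band labels, ordered worst to best;
#'   one more label than cut points.
#' @slot collapse Named character vector mapping each seven-band label to a
#'   three-category label.
#' @seealso [bandScheme()], [band7()], [band3()]
#' @export
setClass("BandScheme", representation(
  breaks = "numeric",
  labels = "character",
  collapse = "character"
))

setValidity("BandScheme", function(object) {
  msg <- NULL
  if (length(object@labels) != length(object@breaks) + 1L)
    msg <- c(msg, "need exactly one more label than break")
  if (is.unsorted(object@breaks, strictly = TRUE) ||
      any(object@breaks <= 0) || any(object@breaks >= 100))
    msg <- c(msg, "breaks must be strictly increasing and inside (0, 100)")
  if (!all(object@labels %in% names(object@collapse)))
    msg <- c(msg, "every band label needs a collapse entry")
  if (is.null(msg)) TRUE else msg
})

#' Normative reference table
#'
#' Per-score normative references used to convert raw test scores to the T
#' metric (mean 50, SD 10 in the reference population).  Each row gives the
#' reference mean and standard deviation of one score of one test, plus the
#' direction of the raw scale: \code{"higher_raw_is_better"} for accuracy-type
#' scores, \code{"higher_raw_is_worse"} for times and error counts.
#'
#' @slot table A \code{data.frame} with columns \code{test_id},
#'   \code{score_id}, \code{ref_mean}, \code{ref_sd}, \code{direction}.
#' @seealso [normativeTable()], [readNormativeTable()], [tFromRaw()]
#' @export
setClass("NormativeTable", representation(table = "data.frame"))

setValidity("NormativeTable", function(object) {
  tb <- object@table
  need <- c("test_id", "score_id", "ref_mean", "ref_sd", "direction")
  msg <- NULL
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste("missing columns:",
                        paste(setdiff(need, names(tb)), collapse = ", ")))
  else {
    if (any(!is.finite(tb$ref_sd)) || any(tb$ref_sd <= 0))
      msg <- c(msg, "ref_sd must be strictly positive")
    if (anyDuplicated(tb$score_id))
      msg <- c(msg, "duplicated (test_id, score_id): score_id must be unique")
    bad <- setdiff(unique(tb$direction),
                   c("higher_raw_is_better", "higher_raw_is_worse"))
    if (length(bad))
      msg <- c(msg, paste("unknown direction value(s):",
                          paste(bad, collapse = ", ")))
  }
  if (is.null(msg)) TRUE else msg
})

#' Battery-to-domain assignment map
#'
#' Maps every score of a neuropsychological battery to exactly one cognitive
#' domain.  Each assignment records its provenance: \code{"factor_loading"}
#' when it came from the rotated loading matrix, \code{"manual_override"}
#' when a reassignment rule placed it, \code{"unassigned"} while provisional.
#'
#' @slot assignments A \code{data.frame} with columns \code{score_id},
#'   \code{test_id}, \code{domain}, \code{provenance}.  \code{domain} may be
#'   \code{NA} only when \code{provenance} is \code{"unassigned"}.
#' @seealso [defaultDomainMap()], [assignByLoading()],
#'   [applyReassignmentRules()]
#' @export
setClass("DomainMap", representation(assignments = "data.frame"))

setValidity("DomainMap", function(object) {
  a <- object@assignments
  need <- c("score_id", "test_id", "domain", "provenance")
  msg <- NULL
  if (!all(need %in% names(a)))
    return(paste("missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (anyDuplicated(a$score_id))
    msg <- c(msg, "each score must be mapped at most once")
  bad <- setdiff(unique(a$domain[!is.na(a$domain)]), .DOMAINS)
  if (length(bad))
    msg <- c(msg, paste("unknown domain(s):", paste(bad, collapse = ", ")))
  if (!all(a$provenance %in% .PROVENANCE))
    msg <- c(msg, "unknown provenance value")
  if (any(is.na(a$domain) & a$provenance != "unassigned"))
    msg <- c(msg, "NA domain only allowed with provenance 'unassigned'")
  if (is.null(msg)) TRUE else msg
})

#' Scored cohort container
#'
#' A \linkS4class{SummarizedExperiment} holding one neuropsychological cohort:
#' rows are battery scores, columns are patients.  The \code{"tscore"} assay
#' is mandatory (T metric, higher = better performance); a \code{"percentile"}
#' assay is derived from it.  Patient covariates (age, hospitalization,
#' biomarkers, mood scores, ...) live in \code{colData}; per-score metadata
#' (test id, domain) in \code{rowData}.  Synthetic cohorts additionally carry
#' the planted ground truth in \code{metadata(x)$ground_truth}.
#'
#' @seealso [ScoredCohort()], [scoreCohort()], [simulateCohort()]
#' @export
setClass("ScoredCohort", contains = "SummarizedExperiment")

setValidity("ScoredCohort", function(object) {
  msg <- NULL
  if (!"tscore" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'tscore' assay is required")
  if ("percentile" %in% SummarizedExperiment::assayNames(object)) {
    p <- SummarizedExperiment::assay(object, "percentile")
    if (any(p < 0 | p > 100, na.rm = TRUE))
      msg <- c(msg, "percentiles must lie in [0, 100]")
  }
  if (is.null(msg)) TRUE else msg
})

#' Simulation configuration
#'
#' Parameters of the latent-factor cohort generator.  See
#' [simConfig()] for defaults and units, and the package vignette for the
#' generative model.
#'
#' @slot n_patients Number of simulated patients.
#' @slot loadings Named numeric vector: generating loading of each score on
#'   its own domain factor (correlation metric, in \eqn{(0, 1)}).
#' @slot domains Named character vector: generating domain of each score.
#' @slot factor_cor Common correlation between latent domain factors.
#' @slot prevalence Named numeric vector: per-domain probability of a planted
#'   impairment.
#' @slot severity_shift Planted deficit in T units (applied to every score of
#'   an affected domain).
#' @slot severity_mechanism Either \code{"capped"} (deficit is a floor:
#'   residual ability in the affected domain is capped at the population
#'   mean) or \code{"displacement"} (pure mean shift of the latent factor).
#' @slot residual_sd Residual score noise in T units; \code{NA} means the
#'   complement \eqn{\sqrt{100(1-\lambda^2)}} so unaffected scores are
#'   marginally \eqn{N(50, 10)}.
#' @slot missing_rate Named numeric vector, per-score missingness
#'   probability.
#' @slot hosp_rate,hosp_age_shift Covariate model: hospitalization
#'   probability and mean age increment (years) of hospitalized patients.
#' @slot biomarker_effect Correlation scale linking log-biomarkers to the
#'   patient's mean latent severity (0 = independent).
#' @export
setClass("SimConfig", representation(
  n_patients = "integer",
  loadings = "numeric",
  domains = "character",
  factor_cor = "numeric",
  prevalence = "numeric",
  severity_shift = "numeric",
  severity_mechanism = "character",
  residual_sd = "numeric",
  missing_rate = "numeric",
  hosp_rate = "numeric",
  hosp_age_shift = "numeric",
  biomarker_effect = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- NULL
  if (object@n_patients < 1L) msg <- c(msg, "n_patients must be >= 1")
  if (any(object@loadings <= 0 | object@loadings >= 1))
    msg <- c(msg, "loadings must lie in (0, 1)")
  if (!identical(names(object@loadings), names(object@domains)))
    msg <- c(msg, "loadings and domains must be named identically")
  if (!all(object@domains %in% .DOMAINS))
    msg <- c(msg, "unknown generating domain")
  if (object@factor_cor < 0 || object@factor_cor >= 1)
    msg <- c(msg, "factor_cor must lie in [0, 1)")
  if (any(object@prevalence < 0 | object@prevalence > 1))
    msg <- c(msg, "prevalence must lie in [0, 1]")
  if (!all(names(object@prevalence) %in% .DOMAINS))
    msg <- c(msg, "prevalence names must be domain labels")
  if (object@severity_shift < 0) msg <- c(msg, "severity_shift must be >= 0")
  if (!object@severity_mechanism %in% c("capped", "displacement"))
    msg <- c(msg, "severity_mechanism must be 'capped' or 'displacement'")
  if (!is.na(object@residual_sd) && object@residual_sd <= 0)
    msg <- c(msg, "residual_sd must be > 0 (or NA for complement)")
  if (any(object@missing_rate < 0 | object@missing_rate > 1))
    msg <- c(msg, "missing_rate must lie in [0, 1]")
  if (object@hosp_rate < 0 || object@hosp_rate > 1)
    msg <- c(msg, "hosp_rate must lie in [0, 1]")
  if (is.null(msg)) TRUE else msg
})
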