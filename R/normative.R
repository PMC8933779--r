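#' The seven-band percentile scheme and its three-category collapse
#'
#' Returns the [BandScheme-class] used throughout the package: the seven
#' consensus performance labels over percentile ranges (exceptionally low
#' below the 2nd percentile up to exceptionally high above the 98th) and
#' their collapse onto the three analysis categories.
#'
#' Intervals are closed on the right, so the three categories are
#' \code{impaired}: \eqn{Pc \le 8}; \code{low_average}: \eqn{8 < Pc \le 24};
#' \code{average_plus}: \eqn{Pc > 24}.
#'
#' @return A [BandScheme-class] object.
#' @examples
#' sch <- bandScheme()
#' band7(c(1.5, 15, 50, 99), sch)
#' @export
bandScheme <- function() {
  new("BandScheme",
      breaks = c(2, 8, 24, 74, 90, 98),
      labels = c("exceptionally_low", "below_average", "low_average",
                 "average", "high_average", "above_average",
                 "exceptionally_high"),
      collapse = c(exceptionally_low = "impaired",
                   below_average = "impaired",
                   low_average = "low_average",
                   average = "average_plus",
                   high_average = "average_plus",
                   above_average = "average_plus",
                   exceptionally_high = "average_plus"))
}

.BAND3 <- c("impaired", "low_average", "average_plus")

.checkPercentile <- function(percentile) {
  if (any(!is.na(percentile) & (percentile < 0 | percentile > 100)))
    stop("percentiles must lie in [0, 100]", call. = FALSE)
}

#' Convert a raw score to the T metric
#'
#' \eqn{T = 50 + 10 s (raw - \mu) / \sigma}, with \eqn{s = +1} when a higher
#' raw score means better performance and \eqn{s = -1} otherwise (completion
#' times, error counts).  On the T metric higher is always better.  No
#' clipping is applied; banding handles the tails.
#'
#' @param raw Numeric vector of raw scores.
#' @param ref_mean,ref_sd Reference mean and standard deviation (raw units);
#'   \code{ref_sd} must be strictly positive.
#' @param direction \code{"higher_raw_is_better"} (default) or
#'   \code{"higher_raw_is_worse"}.
#' @return Numeric vector of T scores.
#' @examples
#' tFromRaw(30, 25, 5)                            # one SD above the mean
#' tFromRaw(70, 50, 10, "higher_raw_is_worse")    # slow completion time
#' @export
tFromRaw <- function(raw, ref_mean, ref_sd,
                     direction = c("higher_raw_is_better",
                                   "higher_raw_is_worse")) {
  direction <- match.arg(direction)
  if (any(!is.finite(ref_sd)) || any(ref_sd <= 0))
    stop("ref_sd must be strictly positive", call. = FALSE)
  s <- if (direction == "higher_raw_is_better") 1 else -1
  50 + 10 * s * (raw - ref_mean) / ref_sd
}

#' Percentile of a T score
#'
#' Uses the normal-distribution convention
#' \eqn{Pc = 100\,\Phi((T - 50)/10)}, the standard mapping for the T metric.
#' Strictly increasing in \code{t}, so bands derived from percentiles are
#' monotone in T.
#'
#' @param t Numeric vector of T scores.
#' @return Percentiles in \eqn{(0, 100)}.
#' @examples
#' percentileFromT(c(36, 50, 63))
#' @export
percentileFromT <- function(t) 100 * pnorm((t - 50) / 10)

#' Inverse of [percentileFromT()]
#'
#' @param percentile Percentiles in \eqn{(0, 100)} (the boundary values map
#'   to infinite T).
#' @return T scores.
#' @export
tFromPercentile <- function(percentile) {
  .checkPercentile(percentile)
  50 + 10 * qnorm(percentile / 100)
}

#' Seven-band performance label of a percentile
#'
#' @param percentile Numeric vector of percentiles in \eqn{[0, 100]}.
#' @param scheme A [BandScheme-class]; default [bandScheme()].
#' @return Ordered factor (worst to best) with the seven band labels.
#' @examples
#' band7(c(1, 5, 15, 50, 80, 95, 99))
#' @export
band7 <- function(percentile, scheme = bandScheme()) {
  .checkPercentile(percentile)
  idx <- findInterval(percentile, scheme@breaks, left.open = TRUE) + 1L
  # the lowest band is right-open: its upper boundary belongs to the band
  # above (the published ranges put the 2nd percentile in "below average"
  # while "exceptionally low" is strictly below it); all other boundaries
  # are upper-inclusive
  idx[!is.na(percentile) & percentile == scheme@breaks[1]] <- 2L
  factor(scheme@labels[idx], levels = scheme@labels, ordered = TRUE)
}

#' Three-category label of a percentile
#'
#' Deterministic coarsening of [band7()]: the two lowest bands collapse to
#' \code{impaired} (\eqn{Pc \le 8}), \code{low_average} stays
#' (\eqn{8 < Pc \le 24}), everything above is \code{average_plus}.
#'
#' @inheritParams band7
#' @return Ordered factor with levels \code{impaired < low_average <
#'   average_plus}.
#' @examples
#' band3(c(5, 24, 50))
#' @export
band3 <- function(percentile, scheme = bandScheme()) {
  b7 <- band7(percentile, scheme)
  factor(unname(scheme@collapse[as.character(b7)]),
         levels = .BAND3, ordered = TRUE)
}

#' Construct a normative reference table
#'
#' @param table A \code{data.frame} with columns \code{test_id},
#'   \code{score_id}, \code{ref_mean}, \code{ref_sd}, \code{direction}.
#' @return A [NormativeTable-class].
#' @export
normativeTable <- function(table) {
  table <- as.data.frame(table)
  new("NormativeTable", table = table)
}

#' Read a normative table from CSV
#'
#' The file must have columns \code{test_id}, \code{score_id},
#' \code{ref_mean}, \code{ref_sd}, \code{direction}; it is validated on load.
#'
#' @param file Path to a delimited text file.
#' @return A [NormativeTable-class].
#' @export
readNormativeTable <- function(file) {
  normativeTable(read.csv(file, stringsAsFactors = FALSE))
}

#' @describeIn normativeTable Number of normative entries.
#' @param x A \code{NormativeTable}.
#' @export
setMethod("length", "NormativeTable", function(x) nrow(x@table))

setMethod("show", "NormativeTable", function(object) {
  cat("NormativeTable with", nrow(object@table), "entries for",
      length(unique(object@table$test_id)), "tests\n")
})

#' Apply normative references to long-format raw scores
#'
#' Converts a long table of scores (columns \code{patient_id},
#' \code{score_id}, \code{value}, and optionally \code{value_type} with
#' entries \code{"raw"} or \code{"t"}) to T scores.  Rows already on the T
#' metric pass through unchanged (their direction is assumed harmonized:
#' higher T = better).  A raw score whose \code{score_id} has no normative
#' entry is an error naming the score.
#'
#' @param scores Long-format \code{data.frame}.
#' @param norms A [NormativeTable-class] (may be \code{NULL} if all rows are
#'   T scores already).
#' @return The input with a \code{t_score} column appended.
#' @export
applyNorms <- function(scores, norms = NULL) {
  scores <- as.data.frame(scores)
  if (!all(c("patient_id", "score_id", "value") %in% names(scores)))
    stop("need columns patient_id, score_id, value", call. = FALSE)
  if (is.null(scores$value_type)) scores$value_type <- "raw"
  t_score <- rep(NA_real_, nrow(scores))
  is_t <- scores$value_type == "t"
  t_score[is_t] <- scores$value[is_t]
  if (any(!is_t)) {
    if (is.null(norms))
      stop("raw scores supplied but no normative table given", call. = FALSE)
    tb <- norms@table
    i <- match(scores$score_id[!is_t], tb$score_id)
    if (anyNA(i)) {
      missing_ids <- unique(scores$score_id[!is_t][is.na(i)])
      stop("no normative entry for score(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    s <- ifelse(tb$direction[i] == "higher_raw_is_better", 1, -1)
    t_score[!is_t] <-
      50 + 10 * s * (scores$value[!is_t] - tb$ref_mean[i]) / tb$ref_sd[i]
  }
  scores$t_score <- t_score
  scores
}

#' Build a ScoredCohort from a T-score matrix
#'
#' @param tscores Numeric matrix, scores in rows and patients in columns
#'   (both dimnames required).  Values on the T metric, higher = better.
#' @param covariates Optional \code{data.frame} of patient covariates, one
#'   row per patient (matched by \code{patient_id} column or row names).
#' @param domainMap Optional [DomainMap-class] recorded in \code{rowData}.
#' @return A [ScoredCohort-class] with assays \code{tscore} and
#'   \code{percentile}.
#' @examples
#' m <- matrix(rnorm(6, 50, 10), 3, 2,
#'             dimnames = list(c("a", "b", "c"), c("p1", "p2")))
#' ScoredCohort(m)
#' @export
ScoredCohort <- function(tscores, covariates = NULL, domainMap = NULL) {
  tscores <- as.matrix(tscores)
  if (is.null(rownames(tscores)) || is.null(colnames(tscores)))
    stop("tscores needs score row names and patient column names",
         call. = FALSE)
  cd <- S4Vectors::DataFrame(row.names = colnames(tscores))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    key <- if ("patient_id" %in% names(covariates))
      as.character(covariates$patient_id) else rownames(covariates)
    i <- match(colnames(tscores), key)
    if (anyNA(i)) stop("covariates missing for some patients", call. = FALSE)
    cd <- S4Vectors::DataFrame(covariates[i, setdiff(names(covariates),
                                                     "patient_id"),
                                          drop = FALSE],
                               row.names = colnames(tscores))
  }
  rd <- S4Vectors::DataFrame(score_id = rownames(tscores),
                             row.names = rownames(tscores))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(tscore = tscores,
                  percentile = percentileFromT(tscores)),
    rowData = rd, colData = cd)
  obj <- new("ScoredCohort", se)
  if (!is.null(domainMap)) obj <- setDomainMap(obj, domainMap)
  obj
}

#' Score a cohort from long-format values and normative references
#'
#' Convenience wrapper: [applyNorms()] then reshape to a
#' [ScoredCohort-class].
#'
#' @inheritParams applyNorms
#' @param covariates Optional covariate \code{data.frame} (see
#'   [ScoredCohort()]).
#' @return A [ScoredCohort-class].
#' @export
scoreCohort <- function(scores, norms = NULL, covariates = NULL) {
  long <- applyNorms(scores, norms)
  pats <- unique(as.character(long$patient_id))
  sids <- unique(as.character(long$score_id))
  m <- matrix(NA_real_, length(sids), length(pats),
              dimnames = list(sids, pats))
  m[cbind(match(long$score_id, sids), match(long$patient_id, pats))] <-
    long$t_score
  ScoredCohort(m, covariates = covariates)
}

#' Read cohort scores from CSV
#'
#' Two layouts are supported.  \emph{Wide}: one row per patient, first
#' column \code{patient_id}, remaining columns one per score (values are T
#' scores).  \emph{Long}: columns \code{patient_id}, \code{score_id},
#' \code{value} and optionally \code{value_type} (\code{"raw"}/\code{"t"});
#' raw values require \code{norms}.
#'
#' @param file CSV path.
#' @param format \code{"wide"} or \code{"long"}.
#' @param norms Optional [NormativeTable-class] for long-format raw values.
#' @return A [ScoredCohort-class].
#' @export
readCohortScores <- function(file, format = c("wide", "long"), norms = NULL) {
  format <- match.arg(format)
  df <- read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "wide") {
    if (!"patient_id" %in% names(df))
      stop("wide format needs a patient_id column", call. = FALSE)
    m <- t(as.matrix(df[setdiff(names(df), "patient_id")]))
    colnames(m) <- as.character(df$patient_id)
    ScoredCohort(m)
  } else {
    scoreCohort(df, norms)
  }
}

# ---- accessors ----

#' Assay and covariate accessors for ScoredCohort
#'
#' @param x A [ScoredCohort-class].
#' @return \code{tScores} and \code{percentiles} return score-by-patient
#'   matrices; \code{bandMatrix} a character matrix of band labels;
#'   \code{covariates} the colData as a \code{data.frame}.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
tScores <- function(x) SummarizedExperiment::assay(x, "tscore")

#' @rdname cohort-accessors
#' @export
percentiles <- function(x) SummarizedExperiment::assay(x, "percentile")

#' @rdname cohort-accessors
#' @param type 3 or 7: which band scheme granularity.
#' @export
bandMatrix <- function(x, type = 3) {
  p <- percentiles(x)
  f <- if (type == 3) band3 else band7
  matrix(as.character(f(as.vector(p))), nrow(p), ncol(p),
         dimnames = dimnames(p))
}

#' @rdname cohort-accessors
#' @export
covariates <- function(x)
  as.data.frame(SummarizedExperiment::colData(x))

setMethod("show", "ScoredCohort", function(object) {
  cat("ScoredCohort:", nrow(object), "scores x", ncol(object), "patients\n")
  cat(" assays:", paste(SummarizedExperiment::assayNames(object),
                        collapse = ", "), "\n")
  if ("domain" %in% names(SummarizedExperiment::rowData(object))) {
    d <- table(SummarizedExperiment::rowData(object)$domain)
    cat(" domains:", paste(names(d), d, sep = ":", collapse = " "), "\n")
  }
  if (ncol(SummarizedExperiment::colData(object)))
    cat(" covariates:",
        paste(names(SummarizedExperiment::colData(object)), collapse = ", "),
        "\n")
})
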