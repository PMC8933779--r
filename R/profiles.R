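#' Band-distribution table from per-score counts
#'
#' Computes the percentage columns of a score-distribution report from
#' integer band counts.  Percentages are \eqn{100 \cdot count / n_{total}}
#' rounded to two decimals (round-half-even); the below-24 column is
#' computed from the combined count \eqn{n_{imp} + n_{low}} and then
#' rounded, so it can differ from the sum of the two rounded percentages in
#' the last decimal.
#'
#' @param counts A \code{data.frame} with columns \code{score_id},
#'   \code{n_impaired}, \code{n_low_avg}, \code{n_avg_plus} and optionally
#'   \code{domain} and \code{n_total} (defaults to the row sum).
#' @return A \code{data.frame} with the counts plus \code{pct_impaired},
#'   \code{pct_low_avg}, \code{pct_avg_plus}, \code{pct_below_24}.
#' @examples
#' distributionFromCounts(data.frame(score_id = "ravlt_total",
#'   n_impaired = 16, n_low_avg = 17, n_avg_plus = 30))
#' @export
distributionFromCounts <- function(counts) {
  counts <- as.data.frame(counts)
  need <- c("score_id", "n_impaired", "n_low_avg", "n_avg_plus")
  if (!all(need %in% names(counts)))
    stop("need columns ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(counts$n_total))
    counts$n_total <- counts$n_impaired + counts$n_low_avg + counts$n_avg_plus
  pc <- function(k) round(100 * k / counts$n_total, 2)
  counts$pct_impaired <- pc(counts$n_impaired)
  counts$pct_low_avg <- pc(counts$n_low_avg)
  counts$pct_avg_plus <- pc(counts$n_avg_plus)
  counts$pct_below_24 <- pc(counts$n_impaired + counts$n_low_avg)
  counts
}

#' Score-distribution table of a cohort
#'
#' One row per battery score: counts and percentages of patients in each of
#' the three analysis categories, with per-score denominators equal to the
#' number of non-missing values.  Rows are grouped by cognitive domain in
#' the canonical order.
#'
#' @param x A [ScoredCohort-class].
#' @param map A [DomainMap-class]; every score present in the cohort must be
#'   mapped (unmapped score ids are an error naming them).
#' @return A \code{data.frame}, see [distributionFromCounts()], plus
#'   \code{domain} and (when known) a human-readable \code{label}.
#' @export
scoreDistributionTable <- function(x, map = defaultDomainMap()) {
  b <- bandMatrix(x, type = 3)
  dom <- domainOf(map, rownames(b))
  cnt <- function(lv) rowSums(b == lv, na.rm = TRUE)
  out <- data.frame(
    score_id = rownames(b),
    domain = dom,
    n_impaired = cnt("impaired"),
    n_low_avg = cnt("low_average"),
    n_avg_plus = cnt("average_plus"),
    n_total = rowSums(!is.na(b)),
    row.names = NULL, stringsAsFactors = FALSE)
  lab <- .DEFAULT_BATTERY$label[match(out$score_id,
                                      .DEFAULT_BATTERY$score_id)]
  if (!anyNA(lab)) out <- cbind(out[1], label = lab, out[-1])
  out <- out[order(match(out$domain, .DOMAINS),
                   match(out$score_id, map@assignments$score_id)), ]
  rownames(out) <- NULL
  distributionFromCounts(out)
}

#' Rule-based domain-impairment classification
#'
#' A cognitive domain is affected when, over its observed (non-missing)
#' scores, at least 50\% fall in the \code{impaired} category, or at least
#' 30\% are \code{impaired} \emph{and} at least 30\% are
#' \code{low_average}.  Thresholds are inclusive ("at least") and are
#' evaluated with exact integer arithmetic.
#'
#' An empty input (all scores missing) is unevaluable and returns \code{NA}
#' rather than "unaffected".
#'
#' @param bands Character vector or factor of three-category labels
#'   (\code{impaired}, \code{low_average}, \code{average_plus}); \code{NA}s
#'   are dropped.
#' @param thresholds Numeric vector with elements \code{majority} (default
#'   0.50), \code{combined_impaired} and \code{combined_low} (default 0.30
#'   each).
#' @return \code{TRUE}, \code{FALSE}, or \code{NA} if unevaluable.
#' @examples
#' classifyDomain(c("impaired", "impaired", "impaired",
#'                  "average_plus", "average_plus", "average_plus"))
#' classifyDomain(rep(c("impaired", "low_average", "average_plus"), 2))
#' @export
classifyDomain <- function(bands,
                           thresholds = c(majority = 0.5,
                                          combined_impaired = 0.3,
                                          combined_low = 0.3)) {
  bands <- as.character(bands)
  bands <- bands[!is.na(bands)]
  n <- length(bands)
  if (n == 0L) return(NA)
  bad <- setdiff(unique(bands), .BAND3)
  if (length(bad))
    stop("unknown band label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  ni <- sum(bands == "impaired")
  nl <- sum(bands == "low_average")
  # integer comparisons: 100*ni >= 100*thr*n avoids float edge cases at the
  # inclusive thresholds (thresholds are read as percentages)
  geq <- function(k, thr) 100 * k >= round(100 * thr) * n
  geq(ni, thresholds[["majority"]]) ||
    (geq(ni, thresholds[["combined_impaired"]]) &&
       geq(nl, thresholds[["combined_low"]]))
}

#' Per-patient impairment profiles
#'
#' Applies [classifyDomain()] to every patient and domain.  A domain is
#' evaluated for a patient only when the fraction of its scores observed
#' for that patient reaches \code{min_coverage} (guarding against
#' classification of, say, a 12-score domain from a single observed score);
#' otherwise it is \code{NA} (unevaluable).  Patients with no evaluable
#' domain are an error.
#'
#' @param x A [ScoredCohort-class].
#' @param map A [DomainMap-class].
#' @param min_coverage Minimal fraction of a domain's scores that must be
#'   observed; default 0.5.
#' @param thresholds Passed to [classifyDomain()].
#' @return A \code{data.frame} with one row per patient: a logical column
#'   per domain, \code{affected} (semicolon-joined labels),
#'   \code{n_affected}, and \code{profile_class} (\code{none},
#'   \code{single}, \code{multi}).
#' @examples
#' cohort <- simulateCohort(simConfig(n_patients = 40), seed = 7)
#' prof <- impairmentProfiles(cohort)
#' table(prof$profile_class)
#' @export
impairmentProfiles <- function(x, map = defaultDomainMap(),
                               min_coverage = 0.5,
                               thresholds = c(majority = 0.5,
                                              combined_impaired = 0.3,
                                              combined_low = 0.3)) {
  b <- bandMatrix(x, type = 3)
  dom <- domainOf(map, rownames(b))
  doms <- intersect(.DOMAINS, unique(dom))
  aff <- matrix(NA, ncol(b), length(doms),
                dimnames = list(colnames(b), doms))
  for (d in doms) {
    rows <- which(dom == d)
    size <- length(rows)
    for (p in seq_len(ncol(b))) {
      v <- b[rows, p]
      if (sum(!is.na(v)) >= max(1L, ceiling(min_coverage * size)))
        aff[p, d] <- classifyDomain(v, thresholds)
    }
  }
  if (any(rowSums(!is.na(aff)) == 0L))
    stop("patient(s) with no evaluable domain: ",
         paste(rownames(aff)[rowSums(!is.na(aff)) == 0L], collapse = ", "),
         call. = FALSE)
  n_aff <- rowSums(aff, na.rm = TRUE)
  out <- data.frame(patient_id = colnames(b), aff,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$affected <- apply(aff, 1, function(r)
    paste(colnames(aff)[which(r)], collapse = ";"))
  out$n_affected <- as.integer(n_aff)
  out$profile_class <- cut(n_aff, c(-1, 0, 1, Inf),
                           labels = c("none", "single", "multi"))
  rownames(out) <- NULL
  out
}

#' Cohort-level profile summary
#'
#' Frequencies of the impairment profile classes, per-domain impairment
#' frequencies (overall and within single-domain patients), the pairwise
#' domain co-occurrence matrix, and a 1-df goodness-of-fit chi-square of
#' single- versus multi-domain impairment against equal expected counts
#' among impaired patients (no continuity correction).
#'
#' @param profiles Output of [impairmentProfiles()].
#' @return A list with elements \code{class_freq}, \code{domain_freq},
#'   \code{single_domain_freq}, \code{cooccurrence}, \code{chisq}
#'   (statistic, df, p), and \code{n}.
#' @export
profileSummary <- function(profiles) {
  if (!nrow(profiles)) stop("empty cohort", call. = FALSE)
  doms <- intersect(.DOMAINS, names(profiles))
  A <- as.matrix(profiles[doms])
  A[is.na(A)] <- FALSE
  cls <- table(profiles$profile_class)
  class_freq <- data.frame(
    profile_class = names(cls),
    n = as.integer(cls),
    pct = round(100 * as.integer(cls) / nrow(profiles), 2))
  domain_freq <- data.frame(
    domain = doms,
    n = colSums(A),
    pct = round(100 * colSums(A) / nrow(profiles), 2),
    row.names = NULL)
  single <- profiles$profile_class == "single"
  single_domain_freq <- data.frame(
    domain = doms,
    n = colSums(A[single, , drop = FALSE]),
    pct = round(100 * colSums(A[single, , drop = FALSE]) /
                  nrow(profiles), 2),
    row.names = NULL)
  cooc <- crossprod(A)
  n_single <- sum(single)
  n_multi <- sum(profiles$profile_class == "multi")
  n_imp <- n_single + n_multi
  if (n_imp > 0) {
    expected <- n_imp / 2
    stat <- (n_single - expected)^2 / expected +
      (n_multi - expected)^2 / expected
    pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stat <- NA_real_; pval <- NA_real_
  }
  list(class_freq = class_freq, domain_freq = domain_freq,
       single_domain_freq = single_domain_freq,
       cooccurrence = cooc,
       chisq = c(statistic = stat, df = 1, p = pval),
       n = nrow(profiles))
}
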