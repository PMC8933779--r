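#' Per-domain composite T scores
#'
#' Arithmetic mean of a patient's observed T scores over the constituent
#' scores of each domain.  All T scores are direction-harmonized (higher =
#' better) at the normative stage, so composites are comparable across
#' domains.  Missing scores are dropped, not imputed; a composite is
#' \code{NA} when the patient's coverage of the domain falls below
#' \code{min_coverage}.
#'
#' @param x A [ScoredCohort-class].
#' @param map A [DomainMap-class].
#' @param min_coverage Minimal observed fraction of the domain's scores;
#'   default: any observed score counts.
#' @return Patients-by-domains numeric matrix of composite T scores.
#' @examples
#' cohort <- simulateCohort(simConfig(n_patients = 30), seed = 3)
#' head(compositeScores(cohort))
#' @export
compositeScores <- function(x, map = defaultDomainMap(), min_coverage = 0) {
  tt <- tScores(x)
  dom <- domainOf(map, rownames(tt))
  doms <- intersect(.DOMAINS, unique(dom))
  out <- matrix(NA_real_, ncol(tt), length(doms),
                dimnames = list(colnames(tt), doms))
  for (d in doms) {
    sub <- tt[dom == d, , drop = FALSE]
    k <- colSums(!is.na(sub))
    m <- colMeans(sub, na.rm = TRUE)
    m[k == 0 | k < min_coverage * nrow(sub)] <- NA_real_
    out[, d] <- m
  }
  out
}

.pearson <- function(u, v) {
  ok <- is.finite(u) & is.finite(v)
  u <- u[ok]; v <- v[ok]
  n <- length(u)
  if (n < 3) stop("fewer than 3 complete pairs", call. = FALSE)
  if (var(u) == 0 || var(v) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- cor.test(u, v, method = "pearson", alternative = "two.sided")
  c(n = n, r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation between two domain composites
#'
#' Pearson correlation with a two-tailed test from the t distribution on
#' \eqn{n - 2} degrees of freedom; pairwise deletion of missing composites.
#'
#' @param composites Matrix from [compositeScores()].
#' @param domain1,domain2 Domain labels (columns of \code{composites}).
#' @return Named vector \code{n}, \code{r}, \code{p}.
#' @examples
#' cohort <- simulateCohort(simConfig(n_patients = 63), seed = 9)
#' comp <- compositeScores(cohort)
#' correlateComposites(comp, "EF", "Attention")
#' @export
correlateComposites <- function(composites, domain1, domain2) {
  .pearson(composites[, domain1], composites[, domain2])
}

#' Correlate every domain composite with a covariate
#'
#' One Pearson correlation per domain, uncorrected for multiplicity (an
#' optional Holm-adjusted column is provided, off by default, since each
#' covariate spawns as many tests as there are domains).  A constant
#' covariate or insufficient pairs is flagged per domain with \code{NA}
#' and a warning rather than aborting the whole table.
#'
#' @param composites Matrix from [compositeScores()].
#' @param covariate Numeric vector aligned with the composite rows, or the
#'   name of a column of \code{data}.
#' @param data Optional covariate \code{data.frame} (e.g.
#'   [covariates()]) used when \code{covariate} is a name.
#' @param holm Add a Holm-adjusted p-value column.
#' @return \code{data.frame} with one row per domain: \code{domain},
#'   \code{n}, \code{r}, \code{p} (and \code{p_holm}).
#' @export
correlateCovariate <- function(composites, covariate, data = NULL,
                               holm = FALSE) {
  if (is.character(covariate) && length(covariate) == 1L) {
    if (is.null(data)) stop("covariate name given but no data", call. = FALSE)
    covariate <- data[[covariate]]
  }
  covariate <- as.numeric(covariate)
  if (length(covariate) != nrow(composites))
    stop("covariate length must match composite rows", call. = FALSE)
  res <- lapply(colnames(composites), function(d) {
    out <- tryCatch(.pearson(composites[, d], covariate),
                    error = function(e) {
                      warning("domain ", d, ": ", conditionMessage(e),
                              call. = FALSE)
                      c(n = NA_real_, r = NA_real_, p = NA_real_)
                    })
    data.frame(domain = d, n = out[["n"]], r = out[["r"]], p = out[["p"]])
  })
  res <- do.call(rbind, res)
  if (holm) res$p_holm <- p.adjust(res$p, method = "holm")
  rownames(res) <- NULL
  res
}

#' One-way ANCOVA group comparison
#'
#' Compares an outcome between two groups adjusting for a single numeric
#' covariate: a linear model \code{outcome ~ covariate + group} with the
#' group effect tested by the sequential F after the covariate.
#'
#' @param outcome Numeric outcome vector.
#' @param group Two-level factor or logical (e.g. hospitalized yes/no).
#' @param covariate Numeric covariate (e.g. age).
#' @return Named vector \code{F}, \code{df1}, \code{df2}, \code{p} for the
#'   group effect.
#' @examples
#' cohort <- simulateCohort(simConfig(), seed = 2)
#' cv <- covariates(cohort)
#' compareGroupsAncova(cv$MoCA, cv$hospitalized, cv$age)
#' @export
compareGroupsAncova <- function(outcome, group, covariate) {
  group <- factor(group)
  ok <- is.finite(outcome) & !is.na(group) & is.finite(covariate)
  outcome <- outcome[ok]; group <- droplevels(group[ok])
  covariate <- covariate[ok]
  if (nlevels(group) != 2L)
    stop("group must have exactly two non-empty levels", call. = FALSE)
  fit <- lm(outcome ~ covariate + group)
  if (any(is.na(coef(fit))))
    stop("singular design", call. = FALSE)
  av <- anova(fit)
  c(F = av["group", "F value"], df1 = av["group", "Df"],
    df2 = av["Residuals", "Df"], p = av["group", "Pr(>F)"])
}

#' Chi-square test of band membership between groups
#'
#' Dichotomizes one score's three-category labels and cross-tabulates the
#' resulting bin against a two-level group.  Bins: \code{"combined"}
#' (percentile at or below 24 versus above), \code{"impaired"}
#' (\code{impaired} versus not), \code{"low_average"} (\code{low_average}
#' versus not).
#'
#' @param x A [ScoredCohort-class].
#' @param score_id A score present in the cohort.
#' @param group Two-level factor/logical aligned with patients.
#' @param bins Binning rule, see above.
#' @param correct Yates continuity correction; off by default.
#' @return Named vector \code{statistic}, \code{df}, \code{p}.
#' @export
binnedGroupTest <- function(x, score_id,
                            group,
                            bins = c("combined", "impaired", "low_average"),
                            correct = FALSE) {
  bins <- match.arg(bins)
  b <- bandMatrix(x, type = 3)
  if (!score_id %in% rownames(b))
    stop("score not in cohort: ", score_id, call. = FALSE)
  v <- b[score_id, ]
  memb <- switch(bins,
                 combined = v %in% c("impaired", "low_average"),
                 impaired = v == "impaired",
                 low_average = v == "low_average")
  group <- factor(group)
  ok <- !is.na(v) & !is.na(group)
  tab <- table(memb[ok], droplevels(group[ok]))
  if (nrow(tab) < 2L || ncol(tab) < 2L || any(rowSums(tab) == 0) ||
      any(colSums(tab) == 0))
    stop("degenerate contingency table for ", score_id, call. = FALSE)
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  if (any(ct$expected < 5))
    warning("expected count below 5 for ", score_id, call. = FALSE)
  c(statistic = unname(ct$statistic), df = unname(ct$parameter),
    p = ct$p.value)
}
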