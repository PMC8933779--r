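#' @rdname simConfig
#' @format NULL
.DEFAULT_LOADINGS <- c(
  ravlt_trial_i = 0.47, ravlt_trial_v = 0.84, ravlt_total = 0.78,
  ravlt_delayed_recall = 0.88, ravlt_recognition = 0.79,
  rocft_delayed_recall = 0.60,
  objects_15 = 0.71, rocft_copy = 0.48, rocft_time = 0.60,
  block_design = 0.64,
  forward_span = 0.35, backward_span = 0.35,
  coding = 0.35, symbol_search = 0.35,
  boston_naming = 0.46, phonemic_fluency = 0.43, semantic_fluency = 0.77,
  cpt_omissions = 0.91, cpt_commissions = 0.87, cpt_hit_rt = 0.81,
  cpt_hit_se = 0.62, cpt_variability = 0.83, cpt_detectability = 0.81,
  cpt_response_style = 0.60, cpt_perseverations = 0.77,
  cpt_hit_rt_block_change = 0.60, cpt_hit_se_block_change = 0.60,
  cpt_hit_rt_isi_change = 0.46, cpt_hit_se_isi_change = 0.60,
  tmt_a = 0.65, tmt_b = 0.762, stroop_color = 0.80,
  stroop_inhibition = 0.79)

.DEFAULT_PREVALENCE <- c("L+LTM" = 0.20, "VVA" = 0.07, "ST/WM" = 0.10,
                         "ProcessingSpeed" = 0.07, "Language" = 0.10,
                         "Attention" = 0.47, "EF" = 0.30)

#' Simulation configuration for synthetic cohorts
#'
#' Builds a [SimConfig-class] describing the latent-factor generative model:
#' each battery score loads on the latent factor of its own cognitive
#' domain; factors are equicorrelated; planted domain impairments subtract
#' \code{severity_shift} T-units from every score of the affected domain
#' and (by default) cap the patient's residual latent ability in that
#' domain at the population mean, so the planted deficit is a severity
#' floor.  See the package vignette for the rationale and for the
#' calibration of every default.
#'
#' @param n_patients Cohort size; default 63.
#' @param loadings Named generating loadings; default: the reference
#'   battery's printed loadings, 0.60 for unprinted scores of the five main
#'   factors, 0.35 for the weakly loading span and speed scores.
#' @param domains Named generating domain per score; default: the built-in
#'   map.
#' @param factor_cor Equicorrelation of the latent domain factors;
#'   default 0.3.
#' @param prevalence Per-domain planted impairment probability; defaults
#'   approximate the reference cohort's per-domain frequencies.
#' @param severity_shift Planted deficit in T units; default 20 (2 SD).
#' @param severity_mechanism \code{"capped"} (default) or
#'   \code{"displacement"} (pure latent mean shift, no score-level deficit).
#' @param residual_sd Residual noise SD in T units; \code{NA} (default)
#'   uses the complement \eqn{\sqrt{100(1-\lambda^2)}} per score, making
#'   unaffected scores marginally \eqn{N(50, 10)}.  The value 3.4
#'   reproduces a five-component explained-variance share near 80\%.
#' @param missing_rate Per-score missingness; default 2/63 for the three
#'   scores typically incomplete in clinical batteries of this layout
#'   (TMT-B and the two Stroop scores), 0 elsewhere.
#' @param hosp_rate,hosp_age_shift Hospitalization probability (0.524) and
#'   mean age increment of hospitalized patients (+9.2 years).
#' @param biomarker_effect Slope linking log-biomarkers to mean planted
#'   severity; default 0 (independent).
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(n_patients = 100, severity_shift = 30)
#' cohort <- simulateCohort(cfg, seed = 1)
#' @export
simConfig <- function(n_patients = 63L,
                      loadings = .DEFAULT_LOADINGS,
                      domains = NULL,
                      factor_cor = 0.3,
                      prevalence = .DEFAULT_PREVALENCE,
                      severity_shift = 20,
                      severity_mechanism = c("capped", "displacement"),
                      residual_sd = NA_real_,
                      missing_rate = NULL,
                      hosp_rate = 0.524,
                      hosp_age_shift = 9.2,
                      biomarker_effect = 0) {
  severity_mechanism <- match.arg(severity_mechanism)
  if (is.null(domains)) {
    domains <- setNames(
      .DEFAULT_BATTERY$domain[match(names(loadings),
                                    .DEFAULT_BATTERY$score_id)],
      names(loadings))
    if (anyNA(domains))
      stop("domains must be given for non-default score ids", call. = FALSE)
  }
  if (is.null(missing_rate)) {
    missing_rate <- setNames(rep(0, length(loadings)), names(loadings))
    missing_rate[intersect(c("tmt_b", "stroop_color", "stroop_inhibition"),
                           names(missing_rate))] <- 2 / 63
  }
  new("SimConfig",
      n_patients = as.integer(n_patients), loadings = loadings,
      domains = domains, factor_cor = factor_cor, prevalence = prevalence,
      severity_shift = severity_shift,
      severity_mechanism = severity_mechanism,
      residual_sd = as.numeric(residual_sd), missing_rate = missing_rate,
      hosp_rate = hosp_rate, hosp_age_shift = hosp_age_shift,
      biomarker_effect = biomarker_effect)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@n_patients, "patients,",
      length(object@loadings), "scores,",
      length(unique(object@domains)), "domains\n",
      "severity", object@severity_shift, "T",
      paste0("(", object@severity_mechanism, "),"),
      "residual",
      if (is.na(object@residual_sd)) "complement" else object@residual_sd,
      ", factor cor", object@factor_cor, "\n")
})

.BIOMARKERS <- list(  # meanlog, sdlog of log-normal baselines
  CRP = c(log(10), 1.0), AST = c(log(30), 0.4), ALT = c(log(32), 0.5),
  LDH = c(log(250), 0.3), CK = c(log(90), 0.6), Hg = c(log(14), 0.1),
  platelets = c(log(250), 0.25), leukocytes = c(log(6.8), 0.3),
  lymphocytes = c(log(1.8), 0.4), D_dimer = c(log(500), 0.8),
  ferritin = c(log(300), 0.9), IL6 = c(log(10), 1.0))

#' Simulate a synthetic cohort
#'
#' Draws a cohort from the latent-factor model of a [SimConfig-class]:
#' correlated standard-normal domain factors, planted per-domain
#' impairments, T scores \eqn{T = 50 + 10\lambda f - s\,[affected] +
#' \epsilon}, per-score missingness, and clinical covariates
#' (hospitalization, age, education, days since diagnosis, a cognitive
#' screening total, anxiety/depression subscores, and twelve log-normal
#' biomarkers taken at diagnosis).  Fully reproducible under a fixed seed.
#'
#' @param config A [SimConfig-class].
#' @param seed Integer seed; if given, the RNG state is set.
#' @return A [ScoredCohort-class] whose \code{metadata} carries
#'   \code{ground_truth}: the planted affected-domain matrix, the latent
#'   factor scores, and the config.
#' @export
simulateCohort <- function(config = simConfig(), seed = NULL) {
  validObject(config)
  if (!is.null(seed)) set.seed(seed)
  n <- config@n_patients
  sc <- names(config@loadings)
  doms <- intersect(.DOMAINS, unique(config@domains))
  k <- length(doms)
  Phi <- matrix(config@factor_cor, k, k); diag(Phi) <- 1
  Z <- matrix(rnorm(n * k), n, k) %*% chol(Phi)
  colnames(Z) <- doms
  prev <- config@prevalence[doms]
  prev[is.na(prev)] <- 0
  Aff <- matrix(rbinom(n * k, 1, rep(prev, each = n)) == 1L, n, k,
                dimnames = list(NULL, doms))
  F <- Z
  if (config@severity_mechanism == "capped") {
    F[Aff] <- -abs(Z[Aff])
  } else {
    F[Aff] <- Z[Aff] - config@severity_shift / 10
  }
  di <- match(config@domains, doms)
  lam <- config@loadings
  resid <- if (is.na(config@residual_sd))
    sqrt(100 * (1 - lam^2)) else rep(config@residual_sd, length(lam))
  T <- 50 + 10 * sweep(F[, di, drop = FALSE], 2, lam, `*`) +
    sweep(matrix(rnorm(n * length(lam)), n), 2, resid, `*`)
  if (config@severity_mechanism == "capped")
    T <- T - config@severity_shift * Aff[, di, drop = FALSE]
  colnames(T) <- sc
  # missingness
  mr <- config@missing_rate[sc]
  mr[is.na(mr)] <- 0
  drop <- matrix(runif(n * length(sc)) < rep(mr, each = n), n)
  T[drop] <- NA_real_
  # covariates
  mean_sev <- rowMeans(Aff) * config@severity_shift
  hosp <- runif(n) < config@hosp_rate
  age <- round(rnorm(n, 46.7 + config@hosp_age_shift * hosp, 11.8))
  age <- pmin(pmax(age, 18), 90)
  edu <- pmin(pmax(round(rnorm(n, 14.4, 3.1)), 5), 22)
  days <- pmax(round(rnorm(n, ifelse(hosp, 198.6, 177.5),
                           ifelse(hosp, 92.3, 106.1))), 30)
  icu <- hosp & runif(n) < 15 / 33
  moca <- round(17.8 - 2.0 * hosp - 0.05 * (age - 46.7) -
                  0.05 * mean_sev + rnorm(n, 0, 2.8))
  moca <- pmin(pmax(moca, 0), 30)
  hads_anx <- pmin(pmax(round(rnorm(n, 8, 4)), 0), 21)
  hads_dep <- pmin(pmax(round(rnorm(n, 7, 4)), 0), 21)
  cov <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    age = age, education_years = edu,
                    hospitalized = hosp, icu = icu,
                    days_since_diagnosis = days, MoCA = moca,
                    HADS_anxiety = hads_anx, HADS_depression = hads_dep)
  sev_std <- if (sd(mean_sev) > 0) as.numeric(scale(mean_sev)) else
    rep(0, n)
  for (bm in names(.BIOMARKERS)) {
    p <- .BIOMARKERS[[bm]]
    cov[[bm]] <- round(rlnorm(n, p[1] + config@biomarker_effect *
                                sev_std * p[2], p[2]), 2)
  }
  tm <- t(T)
  colnames(tm) <- cov$patient_id
  cohort <- ScoredCohort(tm, covariates = cov)
  cohort <- setDomainMap(cohort, domainMap(data.frame(
    score_id = sc,
    test_id = .DEFAULT_BATTERY$test_id[match(sc, .DEFAULT_BATTERY$score_id)],
    domain = config@domains,
    provenance = "factor_loading", stringsAsFactors = FALSE)))
  rownames(Aff) <- rownames(F) <- cov$patient_id
  S4Vectors::metadata(cohort)$ground_truth <-
    list(affected = Aff, latent = F, config = config)
  cohort
}

#' Planted ground truth of a synthetic cohort
#'
#' @param x A [ScoredCohort-class] produced by [simulateCohort()].
#' @return List with \code{affected} (patients-by-domains logical),
#'   \code{latent} (factor scores) and \code{config}.
#' @export
groundTruth <- function(x) {
  gt <- S4Vectors::metadata(x)$ground_truth
  if (is.null(gt)) stop("cohort carries no ground truth", call. = FALSE)
  gt
}

#' Recovery experiment: classification against planted truth
#'
#' Runs simulate \eqn{\to} score \eqn{\to} classify for \code{n_replicates}
#' independent cohorts and tallies how often the rule-based classifier
#' recovers the planted affected domains: pooled and per-domain sensitivity
#' and specificity with normal-approximation Monte-Carlo confidence
#' intervals.
#'
#' @param config A [SimConfig-class].
#' @param n_replicates Number of replicate cohorts (>= 1).
#' @param seed Base seed; replicate \eqn{r} uses \code{seed + r - 1}.
#' @param min_coverage Passed to [impairmentProfiles()].
#' @return A list with \code{pooled} (sensitivity/specificity with 95\% CI
#'   and counts) and \code{per_domain} (a \code{data.frame}).
#' @examples
#' recoveryExperiment(simConfig(n_patients = 80), n_replicates = 2, seed = 1)
#' @export
recoveryExperiment <- function(config = simConfig(), n_replicates = 1L,
                               seed = 1L, min_coverage = 0.5) {
  stopifnot(n_replicates >= 1L)
  doms <- intersect(.DOMAINS, unique(config@domains))
  tp <- fp <- fn <- tn <- setNames(numeric(length(doms)), doms)
  for (r in seq_len(n_replicates)) {
    cohort <- simulateCohort(config, seed = seed + r - 1L)
    truth <- groundTruth(cohort)$affected
    prof <- impairmentProfiles(cohort, min_coverage = min_coverage)
    for (d in doms) {
      est <- prof[[d]]
      ok <- !is.na(est)
      tp[d] <- tp[d] + sum(est[ok] & truth[ok, d])
      fp[d] <- fp[d] + sum(est[ok] & !truth[ok, d])
      fn[d] <- fn[d] + sum(!est[ok] & truth[ok, d])
      tn[d] <- tn[d] + sum(!est[ok] & !truth[ok, d])
    }
  }
  ci <- function(p, n) {
    if (n == 0) return(c(NA_real_, NA_real_))
    se <- sqrt(p * (1 - p) / n)
    c(max(0, p - 1.96 * se), min(1, p + 1.96 * se))
  }
  sens <- sum(tp) / (sum(tp) + sum(fn))
  spec <- sum(tn) / (sum(tn) + sum(fp))
  list(
    pooled = list(
      sensitivity = sens, sensitivity_ci = ci(sens, sum(tp) + sum(fn)),
      specificity = spec, specificity_ci = ci(spec, sum(tn) + sum(fp)),
      counts = c(tp = sum(tp), fp = sum(fp), fn = sum(fn), tn = sum(tn))),
    per_domain = data.frame(
      domain = doms,
      sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_),
      specificity = ifelse(tn + fp > 0, tn / (tn + fp), NA_real_),
      n_affected = as.integer(tp + fn), row.names = NULL))
}
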