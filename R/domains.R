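#' Construct a DomainMap
#'
#' @param assignments \code{data.frame} with columns \code{score_id},
#'   \code{test_id}, \code{domain}, \code{provenance} (and optionally
#'   \code{label}).
#' @return A [DomainMap-class].
#' @export
domainMap <- function(assignments) {
  assignments <- as.data.frame(assignments)
  rownames(assignments) <- NULL
  new("DomainMap", assignments = assignments)
}

# the built-in 33-score battery: score id, owning test, domain, report label
.DEFAULT_BATTERY <- data.frame(
  score_id = c(
    "ravlt_trial_i", "ravlt_trial_v", "ravlt_total", "ravlt_delayed_recall",
    "ravlt_recognition", "rocft_delayed_recall",
    "objects_15", "rocft_copy", "rocft_time", "block_design",
    "forward_span", "backward_span",
    "coding", "symbol_search",
    "boston_naming", "phonemic_fluency", "semantic_fluency",
    "cpt_omissions", "cpt_commissions", "cpt_hit_rt", "cpt_hit_se",
    "cpt_variability", "cpt_detectability", "cpt_response_style",
    "cpt_perseverations", "cpt_hit_rt_block_change",
    "cpt_hit_se_block_change", "cpt_hit_rt_isi_change",
    "cpt_hit_se_isi_change",
    "tmt_a", "tmt_b", "stroop_color", "stroop_inhibition"),
  test_id = c(
    rep("ravlt", 5), "rocft",
    "objects_15", "rocft", "rocft", "wais_iv",
    "digit_span", "digit_span",
    "wais_iv", "wais_iv",
    "bnt", "verbal_fluency", "verbal_fluency",
    rep("cpt_ii", 12),
    "tmt", "tmt", "stroop", "stroop"),
  domain = c(
    rep("L+LTM", 6),
    rep("VVA", 4),
    rep("ST/WM", 2),
    rep("ProcessingSpeed", 2),
    rep("Language", 3),
    rep("Attention", 12),
    rep("EF", 4)),
  label = c(
    "RAVLT - Trial I", "RAVLT - Trial V", "RAVLT - Total",
    "RAVLT - Delayed recall", "RAVLT - Recognition",
    "ROCFT - Delayed recall",
    "15-Objects test", "ROCFT - Copy", "ROCFT - Time",
    "WAIS-IV - Block design",
    "Forward span", "Backward span",
    "WAIS-IV - Coding test", "WAIS-IV - Symbol search",
    "Boston naming", "Phonemic fluency", "Semantic fluency",
    "CPT-II - Omissions %", "CPT-II - Commissions %", "CPT-II - Hit RT",
    "CPT-II - Hit SE", "CPT-II - Variability", "CPT-II - Detectability (d')",
    "CPT-II - Response Style (B)", "CPT-II - Perseverations %",
    "CPT-II - Hit RT block change", "CPT-II - Hit SE block change",
    "CPT-II - Hit RT ISI change", "CPT-II - Hit SE ISI change",
    "TMT-A", "TMT-B", "Stroop - Color", "Stroop - Inhibition"),
  stringsAsFactors = FALSE)

#' The built-in battery-to-domain map
#'
#' The default 33-score battery grouped into seven cognitive domains:
#' 6 learning/long-term memory scores (all RAVLT scores plus the complex
#' figure delayed recall), 4 visuospatial/visuoconstructive, 2 short-term /
#' working memory (digit spans), 2 processing speed (Coding, Symbol Search),
#' 3 language, the 12 CPT-II sustained-attention subscores, and 4 executive
#' scores (trail making A/B, Stroop colour naming and inhibition).
#'
#' The cognitive screening total (MoCA) is deliberately \emph{not} part of
#' the map: it spans several domains and is analysed as a covariate instead.
#'
#' @return A [DomainMap-class] with provenance \code{"factor_loading"} for
#'   scores placed by the rotated factor solution and
#'   \code{"manual_override"} for the rule-based placements (digit spans,
#'   Coding/Symbol Search, the off-factor CPT-II subscores, and the complex
#'   figure delayed recall).
#' @examples
#' m <- defaultDomainMap()
#' domainCounts(m)
#' domainOf(m, "tmt_b")
#' @export
defaultDomainMap <- function() {
  a <- .DEFAULT_BATTERY
  manual <- c("forward_span", "backward_span", "coding", "symbol_search",
              "rocft_delayed_recall",
              "cpt_response_style", "cpt_hit_rt_block_change",
              "cpt_hit_se_block_change", "cpt_hit_se_isi_change")
  a$provenance <- ifelse(a$score_id %in% manual,
                         "manual_override", "factor_loading")
  domainMap(a)
}

#' @describeIn domainMap Assignment table of the map.
#' @param x A \code{DomainMap}.
#' @export
assignments <- function(x) x@assignments

#' Domain of given scores
#'
#' @param map A [DomainMap-class].
#' @param score_id Character vector of score identifiers.
#' @param strict Error (default) or \code{NA} for unmapped scores.
#' @return Character vector of domain labels.
#' @export
domainOf <- function(map, score_id, strict = TRUE) {
  i <- match(score_id, map@assignments$score_id)
  if (strict && anyNA(i))
    stop("score(s) not in domain map: ",
         paste(score_id[is.na(i)], collapse = ", "), call. = FALSE)
  map@assignments$domain[i]
}

#' Number of mapped scores per domain
#'
#' @param map A [DomainMap-class].
#' @return Named integer vector over the seven domain labels.
#' @export
domainCounts <- function(map) {
  a <- map@assignments[!is.na(map@assignments$domain), ]
  tab <- table(factor(a$domain, levels = .DOMAINS))
  setNames(as.integer(tab), names(tab))
}

#' Attach a domain map to a cohort
#'
#' Adds \code{domain} and \code{provenance} columns to the cohort's
#' \code{rowData}.
#'
#' @param x A [ScoredCohort-class].
#' @param map A [DomainMap-class].
#' @return The updated cohort.
#' @export
setDomainMap <- function(x, map) {
  rd <- SummarizedExperiment::rowData(x)
  i <- match(rownames(x), map@assignments$score_id)
  rd$domain <- map@assignments$domain[i]
  rd$provenance <- map@assignments$provenance[i]
  SummarizedExperiment::rowData(x) <- rd
  x
}

setMethod("show", "DomainMap", function(object) {
  cc <- domainCounts(object)
  un <- sum(is.na(object@assignments$domain))
  cat("DomainMap:", nrow(object@assignments), "scores\n ",
      paste(names(cc), cc, sep = ":", collapse = " "), "\n")
  if (un) cat(" unassigned:", un, "\n")
})

#' Write / read a domain map as a YAML config
#'
#' The on-disk format is a list of \code{score_id: \{test, domain,
#' provenance\}} entries, so other batteries can be described by hand.  The
#' loader validates uniqueness and domain labels.
#'
#' @param map A [DomainMap-class].
#' @param file Path to the YAML file.
#' @return \code{readDomainMap} returns a [DomainMap-class];
#'   \code{writeDomainMap} returns \code{file} invisibly.
#' @export
writeDomainMap <- function(map, file) {
  a <- map@assignments
  lst <- lapply(seq_len(nrow(a)), function(i)
    list(test = a$test_id[i],
         domain = if (is.na(a$domain[i])) NULL else a$domain[i],
         provenance = a$provenance[i]))
  names(lst) <- a$score_id
  yaml::write_yaml(lst, file)
  invisible(file)
}

#' @rdname writeDomainMap
#' @export
readDomainMap <- function(file) {
  lst <- yaml::read_yaml(file)
  domainMap(data.frame(
    score_id = names(lst),
    test_id = vapply(lst, function(e) e$test %||% NA_character_, ""),
    domain = vapply(lst, function(e) e$domain %||% NA_character_, ""),
    provenance = vapply(lst, function(e) e$provenance %||% "unassigned", ""),
    stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
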