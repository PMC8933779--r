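#' Rotated loading matrix
#'
#' Result of [extractFactors()]: obliquely rotated component loadings plus
#' the proportion of total variance explained by the retained components
#' (before rotation; rotation redistributes but does not change it).
#'
#' @slot loadings Scores-by-factors pattern matrix.
#' @slot Phi Factor correlation matrix implied by the oblique rotation.
#' @slot variance_explained Proportion of total variance in \eqn{[0, 1]}.
#' @slot n_factors Number of retained components.
#' @slot converged,iterations Rotation convergence diagnostics.
#' @export
setClass("LoadingMatrix", representation(
  loadings = "matrix", Phi = "matrix", variance_explained = "numeric",
  n_factors = "integer", converged = "logical", iterations = "integer"))

setValidity("LoadingMatrix", function(object) {
  if (object@variance_explained < 0 || object@variance_explained > 1)
    return("variance_explained must lie in [0, 1]")
  if (ncol(object@loadings) != object@n_factors)
    return("loadings must have n_factors columns")
  TRUE
})

setMethod("show", "LoadingMatrix", function(object) {
  cat("LoadingMatrix:", nrow(object@loadings), "scores x",
      object@n_factors, "factors;",
      sprintf("%.1f%% of variance;", 100 * object@variance_explained),
      if (object@converged) "rotation converged" else
        "rotation NOT converged", paste0("(", object@iterations, " it.)\n"))
})

#' @rdname LoadingMatrix-class
#' @param x A \code{LoadingMatrix}.
#' @export
loadings <- function(x) x@loadings

#' @rdname LoadingMatrix-class
#' @export
varianceExplained <- function(x) x@variance_explained

# quartimin criterion and gradient (direct oblimin with gamma = 0)
.vgQuartimin <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  list(f = sum(L2 * (L2 %*% N)) / 4, Gq = L * (L2 %*% N))
}

#' Direct-oblimin (quartimin) rotation
#'
#' Oblique gradient-projection rotation of an unrotated loading matrix,
#' minimising the quartimin criterion (the direct-oblimin family with
#' \eqn{\gamma = 0}).  Column signs are fixed so the largest-magnitude
#' loading of each factor is positive.
#'
#' @param A Unrotated loadings (scores by factors).
#' @param tol Convergence tolerance on the projected gradient norm.
#' @param maxit Maximum iterations.
#' @return List with \code{loadings} (pattern matrix), \code{Phi} (factor
#'   correlations), \code{criterion}, \code{converged}, \code{iterations}.
#' @references Jennrich, R. I. (2002). A simple general method for oblique
#'   rotation. \emph{Psychometrika} 67, 7--19.
#' @export
obliminRotate <- function(A, tol = 1e-6, maxit = 500L) {
  Tmat <- diag(ncol(A))
  al <- 1
  L <- A
  vg <- .vgQuartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% solve(Tmat))
  conv <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), ncol(A))
    s <- sqrt(sum(Gp^2))
    if (s < tol) { conv <- TRUE; break }
    al <- 2 * al
    for (i in 0:20) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), ncol(A))
      L <- A %*% t(solve(Tt))
      vgt <- .vgQuartimin(L)
      if (f - vgt$f > 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% solve(Tt))
  }
  Phi <- crossprod(Tmat)
  sg <- apply(L, 2, function(x) {
    s <- sign(x[which.max(abs(x))]); if (s == 0) 1 else s
  })
  L <- sweep(L, 2, sg, `*`)
  Phi <- diag(sg, ncol(A)) %*% Phi %*% diag(sg, ncol(A))
  dimnames(L) <- dimnames(A)
  list(loadings = L, Phi = Phi, criterion = f,
       converged = conv, iterations = iter)
}

#' Extract an oblique factor solution from cohort percentiles
#'
#' Principal component analysis of the score-by-score correlation matrix
#' followed by direct-oblimin rotation of the retained components.  The
#' default input is the percentile assay (scores enter the analysis on a
#' common, direction-harmonized scale); T scores can be selected instead.
#'
#' Missing cells are handled by complete-case deletion of patients
#' (default) or mean imputation per score.
#'
#' @param x A [ScoredCohort-class], or a patients-by-scores numeric matrix.
#' @param n_factors Number of components to retain (must be < number of
#'   scores).
#' @param input \code{"percentile"} (default) or \code{"tscore"}; ignored
#'   for matrix input.
#' @param missing \code{"complete"} or \code{"impute_mean"}.
#' @param tol,maxit Rotation controls, see [obliminRotate()].
#' @return A [LoadingMatrix-class].
#' @examples
#' cohort <- simulateCohort(simConfig(n_patients = 200), seed = 1)
#' extractFactors(cohort, n_factors = 5)
#' @export
extractFactors <- function(x, n_factors = 5L,
                           input = c("percentile", "tscore"),
                           missing = c("complete", "impute_mean"),
                           tol = 1e-6, maxit = 500L) {
  input <- match.arg(input)
  missing <- match.arg(missing)
  m <- if (is(x, "SummarizedExperiment"))
    t(SummarizedExperiment::assay(x, input)) else as.matrix(x)
  if (n_factors >= ncol(m))
    stop("n_factors must be smaller than the number of scores",
         call. = FALSE)
  if (anyNA(m)) {
    if (missing == "complete") {
      m <- m[complete.cases(m), , drop = FALSE]
    } else {
      for (j in seq_len(ncol(m))) {
        mj <- m[, j]
        mj[is.na(mj)] <- mean(mj, na.rm = TRUE)
        m[, j] <- mj
      }
    }
  }
  if (nrow(m) <= n_factors)
    stop("not enough complete patients for extraction", call. = FALSE)
  sds <- apply(m, 2, sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop("degenerate input: constant score column(s): ",
         paste(colnames(m)[sds == 0 | !is.finite(sds)], collapse = ", "),
         call. = FALSE)
  R <- cor(m)
  e <- eigen(R, symmetric = TRUE)
  if (e$values[n_factors] < sqrt(.Machine$double.eps))
    stop("degenerate correlation matrix: retained eigenvalue ~ 0",
         call. = FALSE)
  A <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(n_factors)]), n_factors)
  rownames(A) <- colnames(m)
  colnames(A) <- paste0("F", seq_len(n_factors))
  rot <- obliminRotate(A, tol = tol, maxit = maxit)
  new("LoadingMatrix", loadings = rot$loadings, Phi = rot$Phi,
      variance_explained = sum(e$values[seq_len(n_factors)]) / ncol(m),
      n_factors = as.integer(n_factors), converged = rot$converged,
      iterations = as.integer(rot$iterations))
}

# anchor scores used to name factors after domains: the highest printed
# loading of each factor in the reference battery
.FACTOR_ANCHORS <- c("L+LTM" = "ravlt_delayed_recall",
                     "VVA" = "objects_15",
                     "Language" = "semantic_fluency",
                     "Attention" = "cpt_omissions",
                     "EF" = "stroop_color")

#' Name factors after cognitive domains via anchor scores
#'
#' Each factor is labelled with the domain whose anchor score (the
#' strongest marker of that domain in the reference battery) loads on it
#' most strongly.
#'
#' @param lm A [LoadingMatrix-class].
#' @param anchors Named character vector, domain label -> anchor score id.
#' @return Character vector of domain labels, one per factor (\code{NA} for
#'   factors claimed by no anchor).
#' @export
labelFactors <- function(lm, anchors = .FACTOR_ANCHORS) {
  L <- lm@loadings
  anchors <- anchors[anchors %in% rownames(L)]
  lab <- rep(NA_character_, ncol(L))
  for (d in names(anchors)) {
    j <- which.max(abs(L[anchors[[d]], ]))
    if (!is.na(lab[j]))
      warning("anchors for ", lab[j], " and ", d,
              " claim the same factor", call. = FALSE)
    lab[j] <- d
  }
  lab
}

#' Provisional domain assignment by maximal loading
#'
#' Each score is assigned to the factor carrying its maximal absolute
#' pattern loading, provided that loading reaches \code{threshold};
#' otherwise the score is flagged unassigned.  Exact ties are broken
#' deterministically toward the lowest factor index, with a warning.
#'
#' @param lm A [LoadingMatrix-class].
#' @param threshold Minimal absolute loading in \eqn{(0, 1)}; default 0.40,
#'   a conventional cutoff below the smallest retained printed loading of
#'   the reference solution.
#' @param factorLabels Domain label per factor; default [labelFactors()].
#' @return A [DomainMap-class] with provenance \code{"factor_loading"} for
#'   assigned scores and \code{"unassigned"} otherwise.
#' @export
assignByLoading <- function(lm, threshold = 0.4, factorLabels = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)", call. = FALSE)
  L <- abs(lm@loadings)
  if (is.null(factorLabels)) factorLabels <- labelFactors(lm)
  best <- apply(L, 1, which.max)
  ties <- apply(L, 1, function(r) sum(r == max(r)) > 1L)
  if (any(ties))
    warning("loading tie(s) broken toward the lowest factor index for: ",
            paste(rownames(L)[ties], collapse = ", "), call. = FALSE)
  mx <- L[cbind(seq_len(nrow(L)), best)]
  dom <- ifelse(mx >= threshold, factorLabels[best], NA_character_)
  test <- .DEFAULT_BATTERY$test_id[match(rownames(L),
                                         .DEFAULT_BATTERY$score_id)]
  domainMap(data.frame(
    score_id = rownames(L),
    test_id = ifelse(is.na(test), rownames(L), test),
    domain = dom,
    provenance = ifelse(is.na(dom), "unassigned", "factor_loading"),
    stringsAsFactors = FALSE))
}

#' Apply the battery's reassignment rules to a provisional map
#'
#' Encodes the rule-based placements that complete the factor solution:
#' \itemize{
#'   \item digit spans (forward/backward) form the short-term / working
#'     memory domain;
#'   \item Coding and Symbol Search form the processing-speed domain;
#'   \item every CPT-II subscore belongs to Attention, including those whose
#'     loadings fell outside the main attention factor;
#'   \item the complex-figure delayed recall belongs to learning and
#'     long-term memory.
#' }
#' Scores whose provisional assignment already matches keep their
#' \code{"factor_loading"} provenance; every changed or previously
#' unassigned score is recorded as \code{"manual_override"}.  The operation
#' is idempotent.
#'
#' @param map A provisional [DomainMap-class].
#' @return The completed [DomainMap-class].
#' @export
applyReassignmentRules <- function(map) {
  a <- map@assignments
  target <- function(sel, dom) {
    chg <- sel & (is.na(a$domain) | a$domain != dom)
    a$domain[chg] <<- dom
    a$provenance[chg] <<- "manual_override"
  }
  target(a$test_id == "digit_span" |
           a$score_id %in% c("forward_span", "backward_span"), "ST/WM")
  target(a$score_id %in% c("coding", "symbol_search"), "ProcessingSpeed")
  target(a$test_id == "cpt_ii" | grepl("^cpt_", a$score_id), "Attention")
  target(a$score_id == "rocft_delayed_recall", "L+LTM")
  domainMap(a)
}
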