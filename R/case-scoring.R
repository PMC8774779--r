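# Quality scoring and triage of an initial case base.
#
# Score1 (audit) and Score2 (expert readability) are sigmoid-normalized
# linear combinations of index features, reported on a 0-100 scale so the
# thresholds sigma and gamma (both stated on [0, 100]) are directly
# comparable. Cases at or above sigma on Score1 are flagged high-quality;
# cases at or above gamma on Score2 are flagged well-known; cases whose
# disease relative frequency falls below omega are flagged rare.

#' Logistic sigmoid
#'
#' sigmoid(x) = 1 / (1 + exp(-x)); strictly increasing, values in (0, 1).
#' @param x numeric
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Audit / readability scoring configurations
#'
#' An audit configuration names the audit indices x1..xn (x1 = knowledge
#' richness, x2 = curative effect or treatment time, ...) and their weights
#' a1..an; a readability configuration names the classification indices
#' z1..zn (z1 = accuracy of wording, z2 = simplicity, ...) with weights
#' b1..bn. Both are plain `(names, weights)` pairs.
#'
#' @param index_names character vector of index names
#' @param weights numeric weights, same length, finite
#' @return list of class `scoring_config`
#' @export
scoring_config <- function(index_names, weights) {
  index_names <- as.character(index_names)
  weights <- as.numeric(weights)
  if (length(index_names) != length(weights))
    stop("index_names and weights must have the same length")
  if (any(!is.finite(weights))) stop("weights must be finite")
  structure(list(index_names = index_names, weights = weights),
            class = "scoring_config")
}

score_linear <- function(features, config) {
  if (is.null(features))
    stop("feature matrix absent; supply audit_features / class_features")
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(config$weights))
    stop(sprintf("feature length %d does not match config length %d",
                 ncol(features), length(config$weights)))
  100 * sigmoid(as.vector(features %*% config$weights))
}

#' Audit score (Score1) on the 0-100 scale
#'
#' Score1 = 100 * sigmoid(sum_i a_i x_i) over the case's audit features;
#' strictly inside (0, 100) for finite features.
#'
#' @param case a case list with `audit_features`, a numeric feature vector,
#'   or a `case_base` (scores all cases)
#' @param config an audit [scoring_config()]
#' @return numeric score(s) in (0, 100)
#' @export
score1 <- function(case, config) {
  feats <- if (inherits(case, "case_base")) case$audit_features
           else if (is.list(case)) case$audit_features else case
  score_linear(feats, config)
}

#' Expert-readability score (Score2) on the 0-100 scale
#'
#' Score2 = 100 * sigmoid(sum_i b_i z_i) over the case's readability
#' (classification-index) features.
#'
#' @param case a case list with `class_features`, a numeric feature vector,
#'   or a `case_base`
#' @param config a readability [scoring_config()]
#' @return numeric score(s) in (0, 100)
#' @export
score2 <- function(case, config) {
  feats <- if (inherits(case, "case_base")) case$class_features
           else if (is.list(case)) case$class_features else case
  score_linear(feats, config)
}

#' Compute and store both scores on a case base
#'
#' @param base a `case_base` with `audit_features` and/or `class_features`
#' @param audit_config,readability_config [scoring_config()] objects (either
#'   may be `NULL` to skip that score)
#' @return the base with its `scores` columns filled
#' @export
score_case_base <- function(base, audit_config = NULL, readability_config = NULL) {
  if (!is.null(audit_config)) base$scores$score1 <- score1(base, audit_config)
  if (!is.null(readability_config)) base$scores$score2 <- score2(base, readability_config)
  base
}

#' Flag cases at or above a score threshold
#'
#' Cases with Score1 >= sigma are flagged `high_quality`; cases with
#' Score2 >= gamma are flagged `well_known`. No case is removed; the flags
#' select the high-quality / well-known sub-bases.
#'
#' @param base a scored `case_base`
#' @param score_name `"score1"` or `"score2"`
#' @param threshold cut on the 0-100 scale
#' @return list with `base` (flagged) and `n_selected`
#' @export
select_cases <- function(base, score_name = c("score1", "score2"), threshold) {
  score_name <- match.arg(score_name)
  s <- base$scores[[score_name]]
  if (any(is.na(s))) stop(sprintf("%s has not been computed for all cases", score_name))
  flag <- if (score_name == "score1") "high_quality" else "well_known"
  sel <- s >= threshold
  base$flags[[flag]] <- base$flags[[flag]] | sel
  list(base = base, n_selected = sum(sel))
}

#' Relative frequency of each disease label
#'
#' @param base a non-empty labeled `case_base`
#' @return named numeric vector of relative frequencies over the observed
#'   class labels, summing to 1
#' @export
disease_frequency <- function(base) {
  if (!n_cases(base)) stop("empty case base")
  y <- base$y[!is.na(base$y)]
  if (!length(y)) stop("no class labels present")
  tab <- table(y)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Flag rare-disease cases
#'
#' Every case whose disease (class label) has relative frequency strictly
#' below `omega` is flagged `rare`.
#'
#' @param base a labeled `case_base`
#' @param omega rarity threshold, in (0, 1)
#' @return list with `base` (flagged), `rare_labels` (character vector) and
#'   `n_rare`
#' @export
classify_rare <- function(base, omega) {
  if (!(is.numeric(omega) && length(omega) == 1 && omega > 0 && omega < 1))
    stop("omega must lie strictly between 0 and 1")
  freq <- disease_frequency(base)
  rare_labels <- names(freq)[freq < omega]
  sel <- !is.na(base$y) & base$y %in% rare_labels
  base$flags$rare <- base$flags$rare | sel
  list(base = base, rare_labels = rare_labels, n_rare = sum(sel))
}

#' Triage thresholds
#'
#' sigma: high-quality cut on Score1 (0-100); gamma: well-known cut on
#' Score2 (0-100); omega: rare-disease frequency cut in (0, 1).
#' @param sigma,gamma,omega numeric thresholds
#' @export
thresholds <- function(sigma = 50, gamma = 50, omega = 0.01) {
  stopifnot(sigma >= 0, sigma <= 100, gamma >= 0, gamma <= 100,
            omega > 0, omega < 1)
  structure(list(sigma = sigma, gamma = gamma, omega = omega),
            class = "cbr_thresholds")
}

#' Default audit-feature extractor
#'
#' Reference implementation of the audit indices for cases built from text:
#' x1 (knowledge richness) = fraction of the seven entity categories with a
#' non-empty section; x2 (treatment time surrogate) = number of key-data
#' values scaled by 0.1. Users replace this with their own extractor.
#'
#' @param base a `case_base` with sections
#' @return numeric matrix, one row per case, columns `richness`, `key_data`
#' @export
default_audit_features <- function(base) {
  n <- n_cases(base)
  rich <- vapply(seq_len(n), function(i) {
    s <- if (is.null(base$sections)) character(0) else base$sections[[i]]
    sum(ENTITY_CATEGORIES %in% names(s)[nzchar(s)]) / length(ENTITY_CATEGORIES)
  }, numeric(1))
  nkd <- vapply(seq_len(n), function(i) {
    sum(!is.na(unlist(base$x[i, , drop = FALSE])))
  }, numeric(1))
  cbind(richness = rich, key_data = 0.1 * nkd)
}
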