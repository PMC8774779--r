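#' @title Case bases for case-based reasoning
#' @description
#' A `case_base` holds an attribute schema (discrete/continuous kinds and
#' their domains), a finite set of class values, and an ordered collection of
#' cases. Each case carries a case ID, a patient ID, an attribute vector
#' aligned to the schema, an optional class label, optional free-text
#' sections keyed by the seven clinical entity categories (CL1--CL7),
#' optional audit/readability feature vectors, and triage flags set by the
#' scoring operations. Case order is the stable tie-break ordering used by
#' all downstream retrieval.
#' @name case_base
NULL

#' The seven clinical entity categories
#'
#' CL1 patient information, CL2 time, CL3 disease, CL4 symptom,
#' CL5 examination test, CL6 treatment plan, CL7 other.
#' @export
ENTITY_CATEGORIES <- paste0("CL", 1:7)

#' BMES character segmentation labels
#'
#' B beginning, M middle, E end of a multi-character word, S single-character
#' word. Row order is also the deterministic argmax tie-break order.
#' @export
BMES_LABELS <- c("B", "M", "E", "S")

#' Construct a case base
#'
#' @param x data.frame of attribute columns. Numeric columns default to
#'   continuous attributes, everything else to discrete.
#' @param y class labels (length `nrow(x)`), or `NULL` for unlabeled cases.
#'   `NA` marks an individual unknown (target) label.
#' @param case_id,patient_id identifier vectors; defaults are generated.
#'   Case IDs must be unique.
#' @param kinds named character vector overriding inferred attribute kinds;
#'   values `"discrete"` or `"continuous"`.
#' @param class_values declared class set; the final set is the union of
#'   declared and observed labels.
#' @param sections list (one element per case) of named character vectors,
#'   names in `ENTITY_CATEGORIES`, or `NULL`.
#' @param audit_features,class_features numeric matrices (rows = cases) of
#'   audit / readability index values, or `NULL`.
#' @param missing_token sentinel string written for missing values on disk.
#' @return An object of class `case_base`.
#' @examples
#' cb <- case_base(data.frame(stage = c("I", "II"), age = c(40, 61)),
#'                 y = c("benign", "malignant"))
#' cb
#' @export
case_base <- function(x, y = NULL, case_id = NULL, patient_id = NULL,
                      kinds = NULL, class_values = NULL, sections = NULL,
                      audit_features = NULL, class_features = NULL,
                      missing_token = "") {
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  n <- nrow(x)
  if (is.null(kinds)) {
    kinds <- vapply(x, function(col) if (is.numeric(col)) "continuous" else "discrete",
                    character(1))
  } else {
    miss <- setdiff(names(x), names(kinds))
    if (length(miss)) stop("kinds missing for attribute(s): ", paste(miss, collapse = ", "))
    kinds <- kinds[names(x)]
  }
  if (!all(kinds %in% c("discrete", "continuous")))
    stop("unknown attribute kind: ", paste(setdiff(kinds, c("discrete", "continuous")), collapse = ", "))
  if (anyDuplicated(names(x))) stop("attribute names must be unique within a schema")
  for (nm in names(x)) {
    if (kinds[[nm]] == "continuous") {
      x[[nm]] <- as.numeric(x[[nm]])
    } else {
      x[[nm]] <- as.character(x[[nm]])
    }
  }
  if (is.null(case_id)) case_id <- if (n) paste0("case_", seq_len(n)) else character(0)
  case_id <- as.character(case_id)
  if (anyDuplicated(case_id)) {
    stop("duplicate case_id: ", paste(unique(case_id[duplicated(case_id)]), collapse = ", "))
  }
  if (is.null(patient_id)) patient_id <- case_id
  patient_id <- as.character(patient_id)
  stopifnot(length(case_id) == n, length(patient_id) == n)
  if (is.null(y)) y <- rep(NA_character_, n)
  y <- as.character(y)
  stopifnot(length(y) == n)
  class_values <- sort(unique(c(as.character(class_values), y[!is.na(y)])))
  if (!is.null(sections)) {
    stopifnot(is.list(sections), length(sections) == n)
  }
  for (m in list(audit_features, class_features)) {
    if (!is.null(m)) stopifnot(is.matrix(m), nrow(m) == n, is.numeric(m))
  }
  domains <- lapply(names(x), function(nm) {
    col <- x[[nm]]
    if (kinds[[nm]] == "continuous") {
      ok <- !is.na(col)
      if (any(ok)) range(col[ok]) else c(NA_real_, NA_real_)
    } else {
      sort(unique(col[!is.na(col)]))
    }
  })
  names(domains) <- names(x)
  structure(list(
    schema = data.frame(name = names(x), kind = unname(kinds),
                        stringsAsFactors = FALSE),
    domains = domains,
    class_values = class_values,
    case_id = case_id,
    patient_id = patient_id,
    x = x,
    y = y,
    sections = sections,
    audit_features = audit_features,
    class_features = class_features,
    scores = data.frame(score1 = rep(NA_real_, n), score2 = rep(NA_real_, n)),
    flags = data.frame(high_quality = rep(FALSE, n), well_known = rep(FALSE, n),
                       rare = rep(FALSE, n)),
    missing_token = missing_token
  ), class = "case_base")
}

#' Number of cases in a case base
#' @param base a `case_base`
#' @return integer count
#' @export
n_cases <- function(base) nrow(base$x)

#' @export
print.case_base <- function(x, ...) {
  cat(sprintf("<case_base> %d cases, %d attributes (%d discrete, %d continuous), %d classes\n",
              n_cases(x), nrow(x$schema),
              sum(x$schema$kind == "discrete"), sum(x$schema$kind == "continuous"),
              length(x$class_values)))
  if (length(x$class_values))
    cat("  classes:", paste(x$class_values, collapse = ", "), "\n")
  fl <- colSums(x$flags)
  if (any(fl > 0))
    cat("  flags:", paste(sprintf("%s=%d", names(fl), fl), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a case base by case index
#'
#' Keeps schema, domains and class set; subsets cases, sections, features,
#' scores and flags in step. Used for reference/test splits.
#' @param x a `case_base`
#' @param i integer or logical index over cases
#' @param ... ignored
#' @export
`[.case_base` <- function(x, i, ...) {
  i <- seq_len(n_cases(x))[i]
  out <- x
  out$case_id <- x$case_id[i]
  out$patient_id <- x$patient_id[i]
  out$x <- x$x[i, , drop = FALSE]
  rownames(out$x) <- NULL
  out$y <- x$y[i]
  if (!is.null(x$sections)) out$sections <- x$sections[i]
  if (!is.null(x$audit_features)) out$audit_features <- x$audit_features[i, , drop = FALSE]
  if (!is.null(x$class_features)) out$class_features <- x$class_features[i, , drop = FALSE]
  out$scores <- x$scores[i, , drop = FALSE]
  rownames(out$scores) <- NULL
  out$flags <- x$flags[i, , drop = FALSE]
  rownames(out$flags) <- NULL
  out
}

#' Extract one case as a standalone list
#'
#' @param base a `case_base`
#' @param i case index
#' @return list with `case_id`, `patient_id`, `x` (named list), `y`
#' @export
get_case <- function(base, i) {
  stopifnot(length(i) == 1, i >= 1, i <= n_cases(base))
  list(case_id = base$case_id[i], patient_id = base$patient_id[i],
       x = as.list(base$x[i, , drop = FALSE]), y = base$y[i])
}

#' Construct a target case
#'
#' A target case is a case whose class label is unknown and which is matched
#' against a stored case base.
#' @param ... named attribute values (must cover the schema of the base it is
#'   matched against)
#' @param y optional class label (e.g. for evaluation)
#' @export
new_case <- function(..., y = NA_character_) {
  list(case_id = NA_character_, patient_id = NA_character_,
       x = list(...), y = y)
}

#' Validate a case against a case base schema
#'
#' Report-style validation: returns a character vector of violations, empty
#' iff the case is valid. Checks vector length, discrete domain membership
#' and numeric type of continuous values.
#'
#' @param case a case list (see [get_case()] / [new_case()])
#' @param base the `case_base` whose schema to validate against
#' @return character vector of violation messages
#' @export
validate_case <- function(case, base) {
  report <- character(0)
  sch <- base$schema
  xs <- case$x
  if (length(xs) != nrow(sch)) {
    report <- c(report, sprintf("attribute vector has length %d, schema has %d",
                                length(xs), nrow(sch)))
    return(report)
  }
  if (!is.null(names(xs)) && !all(names(xs) == sch$name) &&
      setequal(names(xs), sch$name)) {
    xs <- xs[sch$name]
  }
  for (j in seq_len(nrow(sch))) {
    nm <- sch$name[j]; v <- xs[[j]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) next  # missing allowed
    if (sch$kind[j] == "continuous") {
      if (!is.numeric(v))
        report <- c(report, sprintf("attribute '%s': continuous value is not numeric", nm))
    } else {
      dom <- base$domains[[nm]]
      if (length(dom) && !(as.character(v) %in% dom))
        report <- c(report, sprintf("attribute '%s': value '%s' outside discrete domain", nm, v))
    }
  }
  if (!is.na(case$y) && length(base$class_values) &&
      !(case$y %in% base$class_values)) {
    report <- c(report, sprintf("class label '%s' not in class set", case$y))
  }
  report
}

#' Min-max normalize continuous attributes to [0, 1]
#'
#' Continuous attribute values are mapped by (v - min) / (max - min) using
#' statistics of the non-missing values in `base`; constant attributes map
#' to 0. The returned normalization map is applied to later target cases via
#' [apply_normalization()], clipping to [0, 1]. Required before distance
#' computation so that squared continuous differences are scale-comparable
#' with the value-difference terms of discrete attributes.
#'
#' @param base a `case_base`
#' @return list with `base` (normalized copy) and `map` (per-attribute
#'   `c(min, max)` list)
#' @export
normalize_continuous <- function(base) {
  cont <- base$schema$name[base$schema$kind == "continuous"]
  map <- list()
  out <- base
  for (nm in cont) {
    col <- base$x[[nm]]
    ok <- !is.na(col)
    if (!any(ok)) stop(sprintf("attribute '%s' has no non-missing values", nm))
    lo <- min(col[ok]); hi <- max(col[ok])
    map[[nm]] <- c(min = lo, max = hi)
    if (hi > lo) {
      out$x[[nm]] <- (col - lo) / (hi - lo)
    } else {
      out$x[[nm]] <- ifelse(ok, 0, NA_real_)
    }
    out$domains[[nm]] <- range(out$x[[nm]], na.rm = TRUE)
  }
  list(base = out, map = map)
}

#' Apply a stored normalization map to a case or case base
#'
#' Values outside the training range are clipped to [0, 1].
#' @param obj a case list or a `case_base`
#' @param map normalization map from [normalize_continuous()]
#' @return the object with continuous values normalized
#' @export
apply_normalization <- function(obj, map) {
  scale1 <- function(v, mm) {
    if (is.na(v)) return(NA_real_)
    if (mm[["max"]] > mm[["min"]]) {
      min(1, max(0, (v - mm[["min"]]) / (mm[["max"]] - mm[["min"]])))
    } else 0
  }
  if (inherits(obj, "case_base")) {
    for (nm in names(map)) {
      obj$x[[nm]] <- vapply(obj$x[[nm]], scale1, numeric(1), mm = map[[nm]])
      obj$domains[[nm]] <- range(obj$x[[nm]], na.rm = TRUE)
    }
  } else {
    for (nm in names(map)) {
      if (!is.null(obj$x[[nm]])) obj$x[[nm]] <- scale1(obj$x[[nm]], map[[nm]])
    }
  }
  obj
}

#' Irreversibly mask private fields of a case base
#'
#' Replaces the named metadata/text fields (e.g. `patient_id`, a text
#' section) by a fixed mask token to protect patient privacy. Attribute
#' vectors and class labels are never touched, so retrieval over a masked
#' base is identical to retrieval over the original.
#'
#' @param base a `case_base`
#' @param fields character vector of field names: `"patient_id"` and/or
#'   section names present in the base
#' @param mask_token replacement string
#' @return the masked `case_base`
#' @export
mask_private_fields <- function(base, fields, mask_token = "***MASKED***") {
  fields <- as.character(fields)
  known <- c("patient_id",
             if (!is.null(base$sections)) unique(unlist(lapply(base$sections, names))))
  bad <- setdiff(fields, known)
  if (length(bad)) stop("unknown field name(s): ", paste(bad, collapse = ", "))
  if ("patient_id" %in% fields) {
    base$patient_id <- rep(mask_token, n_cases(base))
  }
  sec_fields <- setdiff(fields, "patient_id")
  if (length(sec_fields) && !is.null(base$sections)) {
    base$sections <- lapply(base$sections, function(s) {
      hit <- intersect(names(s), sec_fields)
      s[hit] <- mask_token
      s
    })
  }
  base
}
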