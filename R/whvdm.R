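# Weighted heterogeneous value distance measure (WHVDM).
#
# The distance between a target case t and a stored case r is
#   WHVDM(t, r) = sum_i w_i * d_i^2(t, r),
# where d_i^2 is a value-difference term for discrete attributes and a
# squared difference for continuous attributes (which must be min-max
# normalized to [0,1] so the two component kinds are scale-comparable).
#
# For a discrete attribute the value difference metric (VDM) of Stanfill
# and Waltz compares the conditional class distributions of the two values:
#   classic:     sum_a (Pr(y=a|x_i=x_t,i) - Pr(y=a|x_i=x_r,i))^2
#   as_printed:  the same sum multiplied by sum_a Pr(y=a|x_i=x_t,i)^2
# The as_printed variant keeps the trailing squared-probability factor of
# the source formula; it is asymmetric in (t, r), so the classic symmetric
# form is available by configuration.

#' Attribute weight vector
#'
#' Validates the WHVDM weight constraints: 0 <= w_i <= 1 for all i and
#' sum_i w_i = 1 (within 1e-9).
#'
#' @param w numeric vector of attribute weights
#' @return the validated weight vector (class `weight_vector`)
#' @export
weight_vector <- function(w) {
  w <- as.numeric(w)
  if (any(w < -1e-12) || any(w > 1 + 1e-12))
    stop("weights must lie in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stop("weights must sum to 1")
  structure(pmin(pmax(w, 0), 1), class = "weight_vector")
}

#' Uniform attribute weights
#' @param n number of attributes
#' @export
uniform_weights <- function(n) weight_vector(rep(1 / n, n))

#' Distance configuration
#'
#' @param vdm_variant `"as_printed"` (default; keeps the trailing
#'   squared-probability factor) or `"classic"` (symmetric Stanfill-Waltz
#'   form)
#' @param alpha add-alpha smoothing for the conditional class probabilities
#'   (default 1)
#' @param missing_penalty component distance contributed when either value
#'   is missing (default 1, the maximum normalized continuous contribution)
#' @param metric `"whvdm"` (default) or `"euclidean"` (baseline: squared
#'   differences for continuous attributes, 0/1 mismatch for discrete)
#' @return list of class `distance_config`
#' @export
distance_config <- function(vdm_variant = c("as_printed", "classic"),
                            alpha = 1, missing_penalty = 1,
                            metric = c("whvdm", "euclidean")) {
  vdm_variant <- match.arg(vdm_variant)
  metric <- match.arg(metric)
  stopifnot(alpha >= 0, missing_penalty >= 0)
  structure(list(vdm_variant = vdm_variant, alpha = alpha,
                 missing_penalty = missing_penalty, metric = metric),
            class = "distance_config")
}

#' Estimate conditional class probabilities from a case base
#'
#' For each discrete attribute i and observed value v,
#'   Pr(y = a | x_i = v) = (count(x_i = v, y = a) + alpha) /
#'                         (count(x_i = v) + alpha * |Y|).
#' Values unseen in the base are handled at query time with the same
#' formula, which degenerates to the uniform distribution over Y.
#'
#' @param base a labeled `case_base`
#' @param alpha add-alpha smoothing parameter (>= 0)
#' @return object of class `cond_prob_table`: per discrete attribute a
#'   (values x classes) probability matrix, rows summing to 1
#' @export
estimate_cond_probs <- function(base, alpha = 1) {
  if (!n_cases(base)) stop("empty case base")
  Y <- base$class_values
  if (!length(Y)) stop("case base has no class labels")
  disc <- base$schema$name[base$schema$kind == "discrete"]
  tables <- lapply(disc, function(nm) {
    v <- base$x[[nm]]; y <- base$y
    ok <- !is.na(v) & !is.na(y)
    vals <- sort(unique(v[ok]))
    counts <- matrix(0, nrow = length(vals), ncol = length(Y),
                     dimnames = list(vals, Y))
    if (any(ok)) {
      tab <- table(factor(v[ok], levels = vals), factor(y[ok], levels = Y))
      counts <- counts + as.matrix(tab)
    }
    probs <- (counts + alpha) / (rowSums(counts) + alpha * length(Y))
    if (alpha == 0) {
      # rows with zero count would be 0/0; treat as uniform
      bad <- rowSums(counts) == 0
      probs[bad, ] <- 1 / length(Y)
    }
    probs
  })
  names(tables) <- disc
  structure(list(tables = tables, class_values = Y, alpha = alpha),
            class = "cond_prob_table")
}

# conditional class distribution for one value (uniform when unseen)
cond_dist <- function(table, attr, value) {
  tab <- table$tables[[attr]]
  Y <- table$class_values
  if (!is.null(tab) && !is.na(value) && as.character(value) %in% rownames(tab)) {
    tab[as.character(value), ]
  } else {
    stats::setNames(rep(1 / length(Y), length(Y)), Y)
  }
}

#' Value-difference component for one discrete attribute
#'
#' Zero when the two values are identical. Returns `missing_penalty` when
#' either value is missing.
#'
#' @param i attribute name (or index into the schema)
#' @param t,r case lists sharing the schema
#' @param table a [estimate_cond_probs()] table
#' @param variant `"classic"` or `"as_printed"`
#' @param missing_penalty distance contributed for a missing value
#' @param base optional `case_base` used to resolve an integer `i` and check
#'   the attribute kind
#' @return non-negative number
#' @export
vdm_component <- function(i, t, r, table, variant = c("as_printed", "classic"),
                          missing_penalty = 1, base = NULL) {
  variant <- match.arg(variant)
  nm <- resolve_attr(i, t, base)
  if (!is.null(base) && base$schema$kind[base$schema$name == nm] != "discrete")
    stop(sprintf("attribute '%s' is not discrete; use diff2_component", nm))
  vt <- t$x[[nm]]; vr <- r$x[[nm]]
  if (is.null(vt) || is.null(vr) || is.na(vt) || is.na(vr)) return(missing_penalty)
  if (identical(as.character(vt), as.character(vr))) return(0)
  pt <- cond_dist(table, nm, vt)
  pr <- cond_dist(table, nm, vr)
  d <- sum((pt - pr)^2)
  if (variant == "as_printed") d <- d * sum(pt^2)
  d
}

#' Squared-difference component for one continuous attribute
#'
#' (x_t,i - x_r,i)^2 on values normalized to [0, 1]; `missing_penalty` when
#' either value is missing.
#'
#' @inheritParams vdm_component
#' @return non-negative number
#' @export
diff2_component <- function(i, t, r, missing_penalty = 1, base = NULL) {
  nm <- resolve_attr(i, t, base)
  if (!is.null(base) && base$schema$kind[base$schema$name == nm] != "continuous")
    stop(sprintf("attribute '%s' is not continuous; use vdm_component", nm))
  vt <- t$x[[nm]]; vr <- r$x[[nm]]
  if (is.null(vt) || is.null(vr) || is.na(vt) || is.na(vr)) return(missing_penalty)
  if (!is.numeric(vt) || !is.numeric(vr))
    stop(sprintf("attribute '%s' holds non-numeric values", nm))
  (vt - vr)^2
}

resolve_attr <- function(i, t, base) {
  if (is.character(i)) return(i)
  if (!is.null(base)) return(base$schema$name[i])
  names(t$x)[i]
}

#' WHVDM distance between two cases
#'
#' sum_i w_i * d_i^2(t, r): value-difference components for discrete
#' attributes, squared differences for continuous ones. Zero when t = r.
#'
#' @param t,r case lists sharing a schema (see [get_case()], [new_case()])
#' @param w a [weight_vector()] (or numeric vector satisfying its
#'   constraints), one weight per attribute in schema order
#' @param table a [estimate_cond_probs()] table
#' @param config a [distance_config()]
#' @param base optional `case_base` supplying the schema; defaults to
#'   inferring attribute kinds from the values in `t`
#' @return non-negative number
#' @export
whvdm_distance <- function(t, r, w, table, config = distance_config(), base = NULL) {
  w <- weight_vector(w)
  nms <- if (!is.null(base)) base$schema$name else names(t$x)
  if (length(w) != length(nms))
    stop(sprintf("weight vector length %d does not match %d attributes",
                 length(w), length(nms)))
  kinds <- if (!is.null(base)) stats::setNames(base$schema$kind, base$schema$name)
           else vapply(t$x, function(v) if (is.numeric(v)) "continuous" else "discrete",
                       character(1))
  total <- 0
  for (j in seq_along(nms)) {
    nm <- nms[j]
    d <- if (kinds[[nm]] == "discrete") {
      if (config$metric == "euclidean") {
        overlap_component(t$x[[nm]], r$x[[nm]], config$missing_penalty)
      } else {
        vdm_component(nm, t, r, table, variant = config$vdm_variant,
                      missing_penalty = config$missing_penalty)
      }
    } else {
      diff2_component(nm, t, r, missing_penalty = config$missing_penalty)
    }
    total <- total + w[j] * d
  }
  total
}

overlap_component <- function(vt, vr, missing_penalty) {
  if (is.null(vt) || is.null(vr) || is.na(vt) || is.na(vr)) return(missing_penalty)
  as.numeric(!identical(as.character(vt), as.character(vr)))
}

# ---- vectorized internals -------------------------------------------------
#
# component_matrices() precomputes, for each attribute, the |T| x |R| matrix
# of per-attribute component distances between every test and reference
# case. The weighted distance matrix for any weight vector is then a single
# matrix-vector product, which is what makes GA fitness evaluation cheap.

component_matrices <- function(test, reference, table, config) {
  sch <- reference$schema
  mp <- config$missing_penalty
  lapply(seq_len(nrow(sch)), function(j) {
    nm <- sch$name[j]
    tv <- test$x[[nm]]; rv <- reference$x[[nm]]
    if (sch$kind[j] == "continuous") {
      M <- outer(tv, rv, function(a, b) (a - b)^2)
    } else if (config$metric == "euclidean") {
      M <- outer(tv, rv, function(a, b) as.numeric(a != b))
    } else {
      tvals <- unique(tv[!is.na(tv)]); rvals <- unique(rv[!is.na(rv)])
      P_t <- t(vapply(tvals, function(v) cond_dist(table, nm, v),
                      numeric(length(table$class_values))))
      P_r <- t(vapply(rvals, function(v) cond_dist(table, nm, v),
                      numeric(length(table$class_values))))
      # VD[u, v] = sum_a (P_t[u,a] - P_r[v,a])^2, expanded for speed
      VD <- matrix(rowSums(P_t^2), length(tvals), length(rvals)) +
        matrix(rowSums(P_r^2), length(tvals), length(rvals), byrow = TRUE) -
        2 * P_t %*% t(P_r)
      if (config$vdm_variant == "as_printed") VD <- VD * rowSums(P_t^2)
      # identical values are at distance 0 by definition
      same <- outer(tvals, rvals, "==")
      VD[same] <- 0
      M <- VD[match(tv, tvals), match(rv, rvals), drop = FALSE]
      dim(M) <- c(length(tv), length(rv))
    }
    M[is.na(M)] <- mp
    miss_t <- is.na(tv); miss_r <- is.na(rv)
    if (any(miss_t)) M[miss_t, ] <- mp
    if (any(miss_r)) M[, miss_r] <- mp
    M
  })
}

# stack component matrices into (|T||R|) x n for fast weighting
stack_components <- function(comps) {
  vapply(comps, as.vector, numeric(length(comps[[1]])))
}

weighted_distance_matrix <- function(stacked, w, nt, nr) {
  matrix(stacked %*% w, nrow = nt, ncol = nr)
}

nn_predict_from_stack <- function(stacked, w, nt, nr, ref_y) {
  D <- weighted_distance_matrix(stacked, w, nt, nr)
  ref_y[max.col(-D, ties.method = "first")]
}

#' Retrieve the k nearest stored cases
#'
#' Cases are returned in non-decreasing WHVDM distance order; ties are
#' broken by case order in the base (earlier-stored first). If `k` exceeds
#' the base size, all cases are returned with a warning.
#'
#' @param t target case (list with `x`)
#' @param base the stored `case_base` (continuous attributes normalized)
#' @param w attribute [weight_vector()]
#' @param table a [estimate_cond_probs()] table (pass `NULL` to estimate
#'   from `base` with `config$alpha`)
#' @param config a [distance_config()]
#' @param k number of cases to retrieve (>= 1)
#' @return data.frame with `rank`, `case_id`, `distance`, `y` and the case
#'   index `i`
#' @export
retrieve_top_k <- function(t, base, w, table = NULL, config = distance_config(), k = 5) {
  stopifnot(k >= 1)
  n <- n_cases(base)
  if (!n) stop("empty case base")
  if (k > n) {
    warning(sprintf("k = %d exceeds base size %d; returning all cases", k, n))
    k <- n
  }
  if (is.null(table) && config$metric == "whvdm")
    table <- estimate_cond_probs(base, alpha = config$alpha)
  tb <- as_single_case_base(t, base)
  comps <- component_matrices(tb, base, table, config)
  d <- as.vector(weighted_distance_matrix(stack_components(comps),
                                          weight_vector(w), 1, n))
  ord <- order(d, seq_along(d))[seq_len(k)]
  data.frame(rank = seq_len(k), i = ord, case_id = base$case_id[ord],
             distance = d[ord], y = base$y[ord], stringsAsFactors = FALSE)
}

# wrap a single case as a one-row base sharing the reference schema
as_single_case_base <- function(t, base) {
  x <- base$x[0, , drop = FALSE]
  x[1, ] <- NA
  for (nm in names(x)) {
    v <- t$x[[nm]]
    if (!is.null(v) && !is.na(v)) {
      x[1, nm] <- if (base$schema$kind[base$schema$name == nm] == "continuous")
        as.numeric(v) else as.character(v)
    }
  }
  out <- base[0]
  out$x <- x
  out$case_id <- "target"
  out$patient_id <- "target"
  out$y <- NA_character_
  out$scores <- out$scores[0, , drop = FALSE][rep(NA, 1), , drop = FALSE]
  out$flags <- data.frame(high_quality = FALSE, well_known = FALSE, rare = FALSE)
  out
}

#' Predict the class of a target case by 1-NN WHVDM
#'
#' Returns the class label of the stored case s(t) = argmin_r WHVDM(t, r),
#' the reference case most similar to the target.
#'
#' @inheritParams retrieve_top_k
#' @return a class label
#' @export
predict_class <- function(t, base, w, table = NULL, config = distance_config()) {
  retrieve_top_k(t, base, w, table, config, k = 1)$y[1]
}

#' Evaluate 1-NN WHVDM prediction on a reference/test split
#'
#' Normalizes continuous attributes with reference statistics (clipping the
#' test values), estimates conditional probabilities from the reference set
#' only, predicts every test case by 1-NN, and reports accuracy
#' sum_t I(y_t = y_s(t)) / |T| and the macro-averaged F-value (unweighted
#' mean over classes of the harmonic mean of precision and recall; classes
#' never predicted contribute F = 0).
#'
#' @param reference,test labeled `case_base` objects sharing a schema
#' @param w attribute [weight_vector()]
#' @param config a [distance_config()]
#' @param normalize normalize continuous attributes from reference
#'   statistics first (default TRUE)
#' @return list with `accuracy`, `f_value`, `n_correct`, `per_class`
#'   (data.frame of precision/recall/f1) and `predictions`
#' @export
evaluate <- function(reference, test, w, config = distance_config(),
                     normalize = TRUE) {
  if (!n_cases(test)) stop("empty test set")
  if (!n_cases(reference)) stop("empty reference set")
  if (normalize) {
    nr <- normalize_continuous(reference)
    reference <- nr$base
    test <- apply_normalization(test, nr$map)
  }
  table <- if (config$metric == "whvdm")
    estimate_cond_probs(reference, alpha = config$alpha) else NULL
  comps <- component_matrices(test, reference, table, config)
  stacked <- stack_components(comps)
  pred <- nn_predict_from_stack(stacked, weight_vector(w),
                                n_cases(test), n_cases(reference), reference$y)
  truth <- test$y
  classes <- sort(unique(c(reference$class_values, truth[!is.na(truth)])))
  per_class <- do.call(rbind, lapply(classes, function(a) {
    tp <- sum(pred == a & truth == a, na.rm = TRUE)
    fp <- sum(pred == a & truth != a, na.rm = TRUE)
    fn <- sum(pred != a & truth == a, na.rm = TRUE)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = a, precision = prec, recall = rec, f1 = f1,
               support = sum(truth == a, na.rm = TRUE), stringsAsFactors = FALSE)
  }))
  n_correct <- sum(pred == truth, na.rm = TRUE)
  list(accuracy = n_correct / n_cases(test),
       f_value = mean(per_class$f1),
       n_correct = n_correct,
       per_class = per_class,
       predictions = pred)
}
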