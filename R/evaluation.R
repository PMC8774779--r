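# Evaluation utilities: Kendall's coefficient of concordance for rater
# agreement, a seeded method-comparison harness, and the end-to-end
# case-base construction pipeline.

#' Kendall's coefficient of concordance (W)
#'
#' Measures agreement among m raters ranking n items; W is in [0, 1], 1 for
#' identical rankings. Ranks are computed per rater with mean ranks for
#' ties; without ties W = 12 S / (m^2 (n^3 - n)) where S is the sum of
#' squared deviations of the item rank sums from their mean. With
#' `tie_correction` the denominator subtracts m * sum_j T_j, where
#' T_j = sum over tie groups of rater j of (t^3 - t). W is invariant under
#' any strictly monotone transform of each rater's scores.
#'
#' @param scores m x n numeric matrix of rater scores (rows = raters)
#' @param tie_correction apply the tie-corrected denominator (default TRUE)
#' @return W, a number in [0, 1]
#' @export
kendalls_w <- function(scores, tie_correction = TRUE) {
  stopifnot(is.matrix(scores), nrow(scores) >= 2, ncol(scores) >= 2)
  m <- nrow(scores); n <- ncol(scores)
  if (!tie_correction) {
    const <- apply(scores, 1, function(r) length(unique(r)) == 1)
    if (any(const))
      stop("W undefined: rater(s) with constant scores and no tie correction")
  }
  ranks <- t(apply(scores, 1, rank))  # mean ranks for ties
  R <- colSums(ranks)
  S <- sum((R - mean(R))^2)
  denom <- m^2 * (n^3 - n)
  if (tie_correction) {
    Tj <- apply(ranks, 1, function(r) {
      tl <- table(r)
      sum(tl^3 - tl)
    })
    denom <- denom - m * sum(Tj)
  }
  if (denom <= 0) {
    if (S == 0) stop("W undefined: all raters gave constant scores")
    stop("W undefined: tie correction removed the whole denominator")
  }
  W <- 12 * S / denom
  min(max(W, 0), 1)
}

#' Compare retrieval methods on synthetic case bases
#'
#' For each seed: generate a case base from `spec`, split it stratified
#' 70/30 into reference and test sets, and evaluate four methods by 1-NN:
#' \describe{
#'   \item{whvdm_ga}{WHVDM with GA-learned attribute weights}
#'   \item{whvdm_uniform}{WHVDM with uniform weights}
#'   \item{euclidean_uniform}{unweighted Euclidean baseline (squared
#'     differences; 0/1 discrete mismatch)}
#'   \item{expert_weights}{WHVDM with uniform mass on the generator's known
#'     informative attributes (ground truth standing in for
#'     physician-assigned weights)}
#' }
#'
#' @param spec a [case_gen_spec()]
#' @param ga a [ga_config()] (its seed is replaced per run)
#' @param dist a [distance_config()]
#' @param n_seeds number of replicate seeds (>= 1)
#' @param base_seed first seed; runs use `base_seed + 0:(n_seeds-1)`
#' @return list of class `comparison_report`: `per_seed` (data.frame of
#'   seed, method, accuracy, f_value), `summary` (per-method means),
#'   `deltas` (method mean minus `euclidean_uniform` mean), `weights`
#'   (learned weight vectors per seed), `informative_mass` (per-seed total
#'   learned mass on informative attributes)
#' @export
compare_methods <- function(spec = case_gen_spec(), ga = ga_config(),
                            dist = distance_config(), n_seeds = 5,
                            base_seed = 1) {
  if (n_seeds < 1) stop("n_seeds must be >= 1")
  rows <- list(); weights <- list(); inf_mass <- numeric(0)
  for (s in seq_len(n_seeds)) {
    seed <- base_seed + s - 1
    gspec <- spec; gspec$seed <- seed
    gen <- gen_case_base(gspec)
    sp <- split_case_base(gen$base, 0.7, seed = seed)
    ga_s <- ga; ga_s$seed <- seed
    lw <- learn_weights(sp$reference, sp$test, ga_s, dist)
    n_attr <- nrow(gen$base$schema)
    inf_idx <- match(gen$descriptor$informative, gen$base$schema$name)
    weights[[s]] <- lw$weights
    inf_mass <- c(inf_mass, sum(lw$weights[inf_idx]))
    expert_w <- rep(0, n_attr); expert_w[inf_idx] <- 1 / length(inf_idx)
    evals <- list(
      whvdm_ga = evaluate(sp$reference, sp$test, lw$weights, dist),
      whvdm_uniform = evaluate(sp$reference, sp$test, uniform_weights(n_attr), dist),
      euclidean_uniform = evaluate(sp$reference, sp$test, uniform_weights(n_attr),
                                   distance_config(metric = "euclidean",
                                                   missing_penalty = dist$missing_penalty)),
      expert_weights = evaluate(sp$reference, sp$test, weight_vector(expert_w), dist)
    )
    for (m in names(evals)) {
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, method = m, accuracy = evals[[m]]$accuracy,
        f_value = evals[[m]]$f_value, stringsAsFactors = FALSE)
    }
  }
  per_seed <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(accuracy, f_value) ~ method, per_seed, mean)
  base_acc <- summary$accuracy[summary$method == "euclidean_uniform"]
  base_f <- summary$f_value[summary$method == "euclidean_uniform"]
  deltas <- data.frame(method = summary$method,
                       d_accuracy = summary$accuracy - base_acc,
                       d_f_value = summary$f_value - base_f,
                       stringsAsFactors = FALSE)
  structure(list(per_seed = per_seed, summary = summary, deltas = deltas,
                 weights = weights, informative_mass = inf_mass,
                 n_seeds = n_seeds, spec = spec),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d seeds\n", x$n_seeds))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Run the case-base construction pipeline on a labeled corpus
#'
#' Executes the construction stages end to end: fuse ensemble segmentation
#' and entity tags, extract regex key data, assemble per-patient key
#' feature records, build the initial case base, score it (Score1/Score2),
#' select high-quality (Score1 >= sigma) and well-known (Score2 >= gamma)
#' cases, classify rare-disease cases (frequency < omega), and write the
#' filtered bases. Stage counts are monotone non-increasing from the
#' initial base to each filtered base.
#'
#' @param corpus a corpus list from [gen_emr_corpus()] or a path to a
#'   corpus JSONL file (see [read_emr_corpus()])
#' @param out_dir directory for the output case-base files (created);
#'   `NULL` skips writing
#' @param patterns named regex set for key-data extraction (defaults match
#'   the synthetic measurement phrases)
#' @param thresholds a [thresholds()] object (sigma, gamma, omega)
#' @param audit_config,readability_config [scoring_config()] objects;
#'   defaults score the two default audit features with unit weights
#' @param WS,WT ensemble weights (defaults: all 1)
#' @return list with `initial`, `high_quality`, `well_known`, `rare` case
#'   bases, `report` (stage counts) and `files` (paths written)
#' @export
run_pipeline <- function(corpus, out_dir = NULL,
                         patterns = default_key_patterns(),
                         thresholds = cbrmatch::thresholds(),
                         audit_config = NULL, readability_config = NULL,
                         WS = NULL, WT = NULL) {
  if (is.character(corpus)) {
    if (!file.exists(corpus)) stop("stage read: corpus file not found: ", corpus)
    corpus <- read_emr_corpus(corpus)
  }
  n_docs <- length(corpus)
  records <- lapply(corpus, function(doc) {
    M <- ncol(doc$seg_probs[[1]]); N <- ncol(doc$ent_probs[[1]])
    ws <- if (is.null(WS)) rep(1, M) else WS
    wt <- if (is.null(WT)) rep(1, N) else WT
    seg <- tryCatch(fuse_segmentation(doc$seg_probs, ws),
                    error = function(e) stop("stage segmentation: ", conditionMessage(e)))
    dec <- decode_words(seg$labels, doc$text)
    ent <- tryCatch(fuse_entity_tags(doc$ent_probs, wt),
                    error = function(e) stop("stage entity-tagging: ", conditionMessage(e)))
    # entity labels are per gold word; align spans via the gold word index
    words <- vapply(split(doc$text, doc$word_index), paste, character(1), collapse = " ")
    key_text <- data.frame(span = unname(words),
                           category = ent$labels[seq_along(words)],
                           stringsAsFactors = FALSE)
    text_str <- paste(doc$text, collapse = " ")
    key_data <- tryCatch(extract_key_data(text_str, patterns),
                         error = function(e) stop("stage key-data: ", conditionMessage(e)))
    rec <- assemble_key_features(key_data, key_text, doc$patient_id)
    rec$disease <- doc$disease
    rec$sections <- sections_from_key_text(key_text)
    rec
  })
  base <- case_base_from_records(records)
  base$audit_features <- default_audit_features(base)
  base$class_features <- default_audit_features(base)
  if (is.null(audit_config))
    audit_config <- scoring_config(c("richness", "key_data"), c(1, 1))
  if (is.null(readability_config))
    readability_config <- scoring_config(c("richness", "key_data"), c(1, 1))
  base <- score_case_base(base, audit_config, readability_config)
  hq <- select_cases(base, "score1", thresholds$sigma)
  base <- hq$base
  wk <- select_cases(base, "score2", thresholds$gamma)
  base <- wk$base
  rare <- if (n_cases(base) && any(!is.na(base$y))) classify_rare(base, thresholds$omega)
          else list(base = base, rare_labels = character(0), n_rare = 0)
  base <- rare$base
  high_quality <- base[base$flags$high_quality]
  well_known <- base[base$flags$well_known & base$flags$high_quality]
  rare_base <- base[base$flags$rare]
  report <- list(n_documents = n_docs, n_initial = n_cases(base),
                 n_high_quality = n_cases(high_quality),
                 n_well_known = n_cases(well_known),
                 n_rare = n_cases(rare_base),
                 rare_labels = rare$rare_labels)
  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- file.path(out_dir, c("initial.csv", "high_quality.csv",
                                  "well_known.csv", "rare.csv"))
    write_case_base(base, files[1])
    write_case_base(high_quality, files[2])
    write_case_base(well_known, files[3])
    write_case_base(rare_base, files[4])
  }
  list(initial = base, high_quality = high_quality, well_known = well_known,
       rare = rare_base, report = report, files = files)
}

sections_from_key_text <- function(key_text) {
  out <- character(0)
  for (cat in unique(key_text$category)) {
    out[cat] <- paste(key_text$span[key_text$category == cat], collapse = "; ")
  }
  out
}

#' Default key-data regex patterns
#'
#' Patterns for the synthetic measurement phrases (fasting/postprandial
#' blood glucose, glycosylated hemoglobin); each captures one numeric group.
#' @export
default_key_patterns <- function() {
  c("fasting blood glucose" = "fasting blood glucose\\s+([0-9]+(?:\\.[0-9]+)?)",
    "postprandial blood glucose" = "postprandial blood glucose\\s+([0-9]+(?:\\.[0-9]+)?)",
    "glycosylated hemoglobin" = "glycosylated hemoglobin\\s+([0-9]+(?:\\.[0-9]+)?)")
}

case_base_from_records <- function(records) {
  if (!length(records)) {
    return(case_base(data.frame(), y = NULL))
  }
  index_names <- unique(unlist(lapply(records, function(r) names(r$key_data))))
  cols <- lapply(index_names, function(nm) {
    vapply(records, function(r) {
      if (nm %in% names(r$key_data)) unname(r$key_data[[nm]]) else NA_real_
    }, numeric(1))
  })
  names(cols) <- index_names
  x <- if (length(cols)) as.data.frame(cols, check.names = FALSE)
       else data.frame(row.names = seq_along(records))[, 0]
  y <- vapply(records, function(r) if (is.null(r$disease)) NA_character_ else r$disease,
              character(1))
  pids <- vapply(records, `[[`, character(1), "patient_id")
  sections <- lapply(records, function(r) r$sections)
  case_base(x, y = if (all(is.na(y))) NULL else y,
            case_id = pids, patient_id = pids, sections = sections)
}
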