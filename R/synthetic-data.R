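# Seeded synthetic-data generators.
#
# These stand in for hospital records: mixed-type case bases with known
# informative attributes (so weight-recovery is checkable against ground
# truth), pseudo-EMR corpora with gold character-level BMES segmentation
# and word-level entity categories plus simulated ensemble outputs, and
# rater score matrices with a tunable concordance level. All generators are
# deterministic per seed.

#' Specification for a synthetic mixed-type case base
#'
#' The default spec is the standard noisy setting used throughout the
#' package's evaluation: 2 informative attributes (1 continuous + 1
#' discrete) plus 8 class-independent noise attributes (4 continuous + 4
#' discrete), class separation 2, 400 cases, 2 classes.
#'
#' @param n_cases number of cases
#' @param n_classes number of (non-planted) classes
#' @param n_cont_informative,n_disc_informative,n_noise attribute counts;
#'   noise attributes alternate continuous/discrete
#' @param separation effect size: class k shifts informative continuous
#'   attributes by `separation * (k - 1)` standard deviations
#' @param disc_cardinality number of values per discrete attribute
#' @param rare_label_freq optional frequency in (0, 1) of a planted rare
#'   disease label (an extra class)
#' @param seed integer seed
#' @return list of class `case_gen_spec`
#' @export
case_gen_spec <- function(n_cases = 400, n_classes = 2,
                          n_cont_informative = 1, n_disc_informative = 1,
                          n_noise = 8, separation = 2, disc_cardinality = 4,
                          rare_label_freq = NULL, seed = 1) {
  stopifnot(n_cases >= 1, n_classes >= 1, n_cont_informative >= 0,
            n_disc_informative >= 0, n_noise >= 0, separation >= 0,
            disc_cardinality >= 2)
  if (n_cont_informative + n_disc_informative + n_noise < 1)
    stop("need at least one attribute")
  if (!is.null(rare_label_freq))
    stopifnot(rare_label_freq > 0, rare_label_freq < 1)
  structure(as.list(environment()), class = "case_gen_spec")
}

#' Generate a synthetic case base with known informative attributes
#'
#' Continuous informative attributes are class-shifted unit-variance
#' Gaussians (shift = `separation` per class step). Discrete informative
#' attributes are class-dependent categoricals with 0.7 of the mass on a
#' class-linked value and the rest uniform. Noise attributes are
#' class-independent (standard Gaussian / uniform categorical). When
#' `rare_label_freq` is set, an extra planted label is drawn at that
#' frequency.
#'
#' @param spec a [case_gen_spec()]
#' @return list with `base` (a `case_base`) and `descriptor` (ground truth:
#'   informative and noise attribute names, class labels, planted label)
#' @export
gen_case_base <- function(spec = case_gen_spec()) {
  stopifnot(inherits(spec, "case_gen_spec"))
  set.seed(spec$seed)
  n <- spec$n_cases
  classes <- paste0("class_", seq_len(spec$n_classes))
  planted <- NULL
  if (!is.null(spec$rare_label_freq)) {
    planted <- "class_rare"
    p <- c(rep((1 - spec$rare_label_freq) / spec$n_classes, spec$n_classes),
           spec$rare_label_freq)
    y <- sample(c(classes, planted), n, replace = TRUE, prob = p)
  } else {
    y <- sample(classes, n, replace = TRUE)
  }
  all_classes <- c(classes, planted)
  ci <- match(y, all_classes)  # class index 1..K(+1)
  C <- spec$disc_cardinality
  cols <- list(); kinds <- character(0)
  informative <- character(0); noise <- character(0)
  for (j in seq_len(spec$n_cont_informative)) {
    nm <- paste0("cont_inf_", j)
    cols[[nm]] <- stats::rnorm(n, mean = spec$separation * (ci - 1), sd = 1)
    kinds[nm] <- "continuous"; informative <- c(informative, nm)
  }
  disc_vals <- paste0("v", seq_len(C))
  # discrete effect size scales with separation like the continuous one:
  # the class-linked majority mass interpolates from uniform (separation 0)
  # to 0.7 at the reference separation of 2
  maj <- 1 / C + (0.7 - 1 / C) * min(spec$separation / 2, 1)
  for (j in seq_len(spec$n_disc_informative)) {
    nm <- paste0("disc_inf_", j)
    linked <- ((ci - 1) %% C) + 1
    v <- vapply(seq_len(n), function(i) {
      probs <- rep((1 - maj) / (C - 1), C)
      probs[linked[i]] <- maj
      sample(disc_vals, 1, prob = probs)
    }, character(1))
    cols[[nm]] <- v
    kinds[nm] <- "discrete"; informative <- c(informative, nm)
  }
  for (j in seq_len(spec$n_noise)) {
    if (j %% 2 == 1) {
      nm <- paste0("noise_cont_", (j + 1) %/% 2)
      cols[[nm]] <- stats::rnorm(n)
      kinds[nm] <- "continuous"
    } else {
      nm <- paste0("noise_disc_", j %/% 2)
      cols[[nm]] <- sample(disc_vals, n, replace = TRUE)
      kinds[nm] <- "discrete"
    }
    noise <- c(noise, nm)
  }
  x <- as.data.frame(cols, stringsAsFactors = FALSE)
  base <- case_base(x, y = y, kinds = kinds, class_values = all_classes)
  list(base = base,
       descriptor = list(informative = informative, noise = noise,
                         classes = all_classes, planted_label = planted,
                         spec = spec))
}

# ---- pseudo-EMR corpus ----------------------------------------------------

default_templates <- function() {
  # each phrase is a list of words; each word is a vector of tokens, so
  # multi-token words exercise the B/M/E labels and single tokens the S label
  list(
    CL1 = list(list(c("patient"), c("zhang", "wei")),
               list(c("male"), c("aged"), c("58"))),
    CL2 = list(list(c("admitted"), c("2021", "03", "15")),
               list(c("onset"), c("two", "weeks", "ago"))),
    CL3 = list(list(c("type", "2", "diabetes")),
               list(c("hypertension")),
               list(c("breast", "tumor"))),
    CL4 = list(list(c("polyuria")), list(c("chest", "pain")),
               list(c("fatigue"), c("and"), c("thirst"))),
    CL5 = list(list(c("fasting", "blood", "glucose")),
               list(c("postprandial", "blood", "glucose")),
               list(c("glycosylated", "hemoglobin"))),
    CL6 = list(list(c("metformin"), c("500", "mg")),
               list(c("insulin", "therapy"))),
    CL7 = list(list(c("follow", "up")), list(c("noted")))
  )
}

#' Specification for a pseudo-EMR corpus
#'
#' @param n_docs number of documents
#' @param templates per-category phrase templates (must cover CL1..CL7);
#'   see the package default
#' @param classifier_fidelity probability q that a simulated classifier's
#'   top probability mass sits on the gold label; a scalar, or a length-M
#'   (and length-N) vector for per-classifier fidelities
#' @param M number of segmentation classifiers
#' @param N number of entity taggers
#' @param seed integer seed
#' @return list of class `corpus_gen_spec`
#' @export
corpus_gen_spec <- function(n_docs = 20, templates = default_templates(),
                            classifier_fidelity = 0.9, M = 3, N = 3, seed = 1) {
  stopifnot(n_docs >= 1, M >= 1, N >= 1,
            all(classifier_fidelity > 0), all(classifier_fidelity <= 1))
  missing_cat <- setdiff(ENTITY_CATEGORIES, names(templates))
  if (length(missing_cat))
    stop("templates missing categories: ", paste(missing_cat, collapse = ", "))
  structure(as.list(environment()), class = "corpus_gen_spec")
}

# one simulated probability column: mass q on a target row (gold with
# probability q, otherwise a uniformly drawn wrong row), the remaining
# 1 - q spread uniformly over the other rows; q = 1/k gives the exactly
# uniform column
sim_prob_column <- function(gold_idx, k, q) {
  target <- if (stats::runif(1) < q) gold_idx else sample(setdiff(seq_len(k), gold_idx), 1)
  col <- rep((1 - q) / (k - 1), k)
  col[target] <- q
  col
}

#' Generate a labeled pseudo-EMR corpus with simulated ensemble outputs
#'
#' Each document is a sequence of entity phrases drawn from the templates;
#' tokens play the role of characters, so gold BMES labels and gold entity
#' categories are known by construction. For every token (and every word) a
#' simulated ensemble emits per-classifier probability columns with
#' fidelity q: probability q on the gold row when uncorrupted, on a random
#' wrong row otherwise. Measurement phrases carry a numeric token so regex
#' key-data extraction is exercised end to end.
#'
#' @param spec a [corpus_gen_spec()]
#' @return list of documents; each has `patient_id`, `text` (token vector),
#'   `gold_bmes`, `gold_entities` (category per word), `word_index`,
#'   `disease` (the CL3 phrase text), `seg_probs` (list of 4 x M matrices),
#'   `ent_probs` (list of 7 x N matrices)
#' @export
gen_emr_corpus <- function(spec = corpus_gen_spec()) {
  stopifnot(inherits(spec, "corpus_gen_spec"))
  set.seed(spec$seed)
  qs_seg <- rep(spec$classifier_fidelity, length.out = spec$M)
  qs_ent <- rep(spec$classifier_fidelity, length.out = spec$N)
  measures <- list(c("fasting", "blood", "glucose"),
                   c("postprandial", "blood", "glucose"),
                   c("glycosylated", "hemoglobin"))
  lapply(seq_len(spec$n_docs), function(d) {
    # one patient-info phrase, one time, one disease, 1-2 symptoms,
    # 1-2 measurements with values, one treatment, one other
    pick <- function(cat) spec$templates[[cat]][[sample(length(spec$templates[[cat]]), 1)]]
    phrases <- list(list(cat = "CL1", words = pick("CL1")),
                    list(cat = "CL2", words = pick("CL2")),
                    list(cat = "CL3", words = pick("CL3")))
    for (s in seq_len(sample(1:2, 1)))
      phrases <- c(phrases, list(list(cat = "CL4", words = pick("CL4"))))
    n_meas <- sample(1:2, 1)
    meas_idx <- sample(length(measures), n_meas)
    for (mi in meas_idx) {
      val <- round(stats::runif(1, 4, 15), 1)
      phrases <- c(phrases, list(list(cat = "CL5",
                                      words = list(measures[[mi]],
                                                   c(format(val))))))
    }
    phrases <- c(phrases, list(list(cat = "CL6", words = pick("CL6"))),
                 list(list(cat = "CL7", words = pick("CL7"))))
    tokens <- character(0); gold_bmes <- character(0)
    gold_entities <- character(0); word_index <- integer(0)
    w <- 0L
    for (ph in phrases) {
      for (word in ph$words) {
        w <- w + 1L
        L <- length(word)
        lab <- if (L == 1) "S" else c("B", rep("M", L - 2), "E")
        tokens <- c(tokens, word)
        gold_bmes <- c(gold_bmes, lab)
        gold_entities <- c(gold_entities, ph$cat)
        word_index <- c(word_index, rep(w, L))
      }
    }
    seg_probs <- lapply(seq_along(tokens), function(p) {
      gi <- match(gold_bmes[p], BMES_LABELS)
      vapply(qs_seg, function(q) sim_prob_column(gi, 4, q), numeric(4))
    })
    ent_probs <- lapply(seq_len(w), function(q_) {
      gi <- match(gold_entities[q_], ENTITY_CATEGORIES)
      vapply(qs_ent, function(q) sim_prob_column(gi, 7, q), numeric(7))
    })
    disease_words <- phrases[[3]]$words
    list(patient_id = sprintf("P%04d", d),
         text = tokens, gold_bmes = gold_bmes,
         gold_entities = gold_entities, word_index = word_index,
         disease = paste(unlist(disease_words), collapse = " "),
         seg_probs = seg_probs, ent_probs = ent_probs)
  })
}

#' Write / read a labeled corpus as JSON lines
#'
#' One document per line with `text` (token list), `gold_bmes`,
#' `gold_entities` as `[start, end, category]` 0-based half-open token
#' offsets, plus the simulated ensemble probability columns.
#'
#' @param corpus list of documents from [gen_emr_corpus()]
#' @param path output path
#' @export
write_emr_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(doc) {
    spans <- word_spans(doc$word_index, doc$gold_entities)
    rec <- list(patient_id = doc$patient_id,
                text = as.list(doc$text),
                gold_bmes = paste(doc$gold_bmes, collapse = ""),
                gold_entities = spans,
                disease = doc$disease,
                seg_probs = lapply(doc$seg_probs, function(m) unclass(as.data.frame(m))),
                ent_probs = lapply(doc$ent_probs, function(m) unclass(as.data.frame(m))))
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(NULL)
}

word_spans <- function(word_index, gold_entities) {
  lapply(unique(word_index), function(wi) {
    pos <- which(word_index == wi)
    list(min(pos) - 1L, max(pos), gold_entities[wi])
  })
}

#' @rdname write_emr_corpus
#' @return `read_emr_corpus` returns the corpus as a list of documents
#' @export
read_emr_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    tokens <- unlist(rec$text)
    gold_bmes <- strsplit(rec$gold_bmes, "")[[1]]
    word_index <- integer(length(tokens))
    gold_entities <- character(length(rec$gold_entities))
    for (k in seq_along(rec$gold_entities)) {
      sp <- rec$gold_entities[[k]]
      idx <- (sp[[1]] + 1):sp[[2]]
      word_index[idx] <- k
      gold_entities[k] <- sp[[3]]
    }
    to_mat <- function(cols, k) {
      lapply(cols, function(m) {
        mm <- vapply(m, function(col) as.numeric(unlist(col)), numeric(k))
        matrix(mm, nrow = k)
      })
    }
    list(patient_id = rec$patient_id, text = tokens, gold_bmes = gold_bmes,
         gold_entities = gold_entities, word_index = word_index,
         disease = rec$disease,
         seg_probs = to_mat(rec$seg_probs, 4),
         ent_probs = to_mat(rec$ent_probs, 7))
  })
}

#' Generate a rater score matrix with a given concordance level
#'
#' At `agreement = 1` all raters score from an identical underlying
#' ranking; at `agreement = 0` raters are independent; intermediate values
#' interpolate by Gaussian noise injection.
#'
#' @param m_raters number of raters (>= 2)
#' @param n_items number of rated items (>= 2)
#' @param agreement concordance level in [0, 1]
#' @param seed integer seed
#' @return m x n numeric score matrix (rows = raters)
#' @export
gen_rater_scores <- function(m_raters, n_items, agreement, seed = 1) {
  stopifnot(m_raters >= 2, n_items >= 2, agreement >= 0, agreement <= 1)
  set.seed(seed)
  base <- as.numeric(scale(seq_len(n_items)))
  mat <- t(vapply(seq_len(m_raters), function(r) {
    agreement * base + (1 - agreement) * stats::rnorm(n_items)
  }, numeric(n_items)))
  dimnames(mat) <- list(paste0("rater_", seq_len(m_raters)),
                        paste0("item_", seq_len(n_items)))
  mat
}
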