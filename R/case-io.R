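# On-disk case-base formats.
#
# CSV dialect: UTF-8, comma-separated; first row is the header, second row
# declares column kinds (`id` / `discrete` / `continuous` / `class` / `text`).
# The first `id` column is the case ID, the second (if any) the patient ID.
# Missing cells hold the base's missing token (default empty string).
#
# JSON-lines: a leading schema object
#   {"schema":[{"name":...,"kind":...},...], "class_values":[...],
#    "missing_token":...}
# followed by one case object per line
#   {"case_id":..., "patient_id":..., "x":{...}, "y":..., "sections":{...}}

#' Read a case base from CSV or JSON-lines
#'
#' @param path file path
#' @param format `"csv"` or `"jsonl"`; default guessed from the extension
#' @return a validated [case_base()]
#' @export
read_case_base <- function(path, format = c("guess", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") read_case_base_csv(path) else read_case_base_jsonl(path)
}

read_case_base_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2) stop("malformed case-base CSV: need header and kinds rows")
  raw <- utils::read.csv(text = lines, header = TRUE, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  kinds_row <- as.character(unlist(raw[1, ], use.names = FALSE))
  names(kinds_row) <- names(raw)
  body <- raw[-1, , drop = FALSE]
  rownames(body) <- NULL
  valid_kinds <- c("id", "discrete", "continuous", "class", "text")
  if (!all(kinds_row %in% valid_kinds)) {
    stop("schema error: unknown attribute kind ",
         paste(setdiff(kinds_row, valid_kinds), collapse = ", "))
  }
  id_cols <- names(kinds_row)[kinds_row == "id"]
  class_col <- names(kinds_row)[kinds_row == "class"]
  if (length(class_col) > 1) stop("schema error: more than one class column")
  attr_cols <- names(kinds_row)[kinds_row %in% c("discrete", "continuous")]
  text_cols <- names(kinds_row)[kinds_row == "text"]
  missing_token <- ""
  n <- nrow(body)
  x <- body[, attr_cols, drop = FALSE]
  for (nm in attr_cols) {
    col <- x[[nm]]
    col[col == missing_token] <- NA
    if (kinds_row[[nm]] == "continuous") {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad)) {
        stop(sprintf("malformed row %d: non-numeric value '%s' in continuous attribute '%s'",
                     bad[1], col[bad[1]], nm))
      }
      col <- num
    }
    x[[nm]] <- col
  }
  y <- if (length(class_col)) {
    yy <- body[[class_col]]
    yy[yy == missing_token] <- NA
    yy
  } else NULL
  case_id <- if (length(id_cols) >= 1) body[[id_cols[1]]] else NULL
  patient_id <- if (length(id_cols) >= 2) body[[id_cols[2]]] else NULL
  sections <- NULL
  if (length(text_cols) && n > 0) {
    sections <- lapply(seq_len(n), function(i) {
      s <- vapply(text_cols, function(tc) body[i, tc], character(1))
      s[s != missing_token]
    })
  }
  case_base(x, y = y, case_id = case_id, patient_id = patient_id,
            kinds = kinds_row[attr_cols], sections = sections,
            missing_token = missing_token)
}

read_case_base_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("malformed case-base JSONL: missing schema line")
  head <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  if (is.null(head$schema)) stop("schema error: first line must carry the schema object")
  sch_names <- vapply(head$schema, `[[`, character(1), "name")
  sch_kinds <- vapply(head$schema, `[[`, character(1), "kind")
  names(sch_kinds) <- sch_names
  if (!all(sch_kinds %in% c("discrete", "continuous")))
    stop("schema error: unknown attribute kind")
  missing_token <- if (!is.null(head$missing_token)) head$missing_token else ""
  recs <- lapply(seq_along(lines[-1]), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i + 1], simplifyVector = FALSE),
                    error = function(e) stop(sprintf("malformed row %d: %s", i, conditionMessage(e))))
    rec
  })
  n <- length(recs)
  get_val <- function(rec, nm, kind) {
    v <- rec$x[[nm]]
    if (is.null(v)) return(if (kind == "continuous") NA_real_ else NA_character_)
    if (kind == "continuous") as.numeric(v) else as.character(v)
  }
  x <- as.data.frame(lapply(sch_names, function(nm) {
    kind <- sch_kinds[[nm]]
    vals <- vapply(recs, get_val, if (kind == "continuous") numeric(1) else character(1),
                   nm = nm, kind = kind)
    vals
  }), stringsAsFactors = FALSE)
  names(x) <- sch_names
  pick <- function(field, default) {
    vapply(recs, function(r) if (is.null(r[[field]])) default else as.character(r[[field]]),
           character(1))
  }
  y <- pick("y", NA_character_)
  sections <- lapply(recs, function(r) {
    if (is.null(r$sections)) character(0) else unlist(r$sections)
  })
  if (all(vapply(sections, length, integer(1)) == 0)) sections <- NULL
  case_base(x, y = if (all(is.na(y))) NULL else y,
            case_id = pick("case_id", NA_character_),
            patient_id = pick("patient_id", NA_character_),
            kinds = sch_kinds,
            class_values = unlist(head$class_values),
            sections = sections, missing_token = missing_token)
}

#' Write a case base to CSV or JSON-lines
#'
#' The output is re-readable by [read_case_base()] with identical content:
#' discrete values round-trip exactly, continuous values to at least 12
#' significant digits.
#'
#' @param base a `case_base`
#' @param path output file path
#' @param format `"csv"` or `"jsonl"`; default guessed from the extension
#' @export
write_case_base <- function(base, path, format = c("guess", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") write_case_base_csv(base, path) else write_case_base_jsonl(base, path)
  invisible(NULL)
}

fmt_num <- function(v) {
  ifelse(is.na(v), NA_character_, sprintf("%.15g", v))
}

write_case_base_csv <- function(base, path) {
  mt <- base$missing_token
  sch <- base$schema
  sec_names <- if (!is.null(base$sections))
    unique(unlist(lapply(base$sections, names))) else character(0)
  header <- c("case_id", "patient_id", sch$name, "class", sec_names)
  kinds <- c("id", "id", sch$kind, "class", rep("text", length(sec_names)))
  n <- n_cases(base)
  cols <- list(base$case_id, base$patient_id)
  for (j in seq_len(nrow(sch))) {
    v <- base$x[[sch$name[j]]]
    v <- if (sch$kind[j] == "continuous") fmt_num(v) else as.character(v)
    v[is.na(v)] <- mt
    cols <- c(cols, list(v))
  }
  yv <- base$y; yv[is.na(yv)] <- mt
  cols <- c(cols, list(yv))
  for (s in sec_names) {
    v <- vapply(seq_len(n), function(i) {
      sec <- base$sections[[i]]
      if (!is.null(sec) && s %in% names(sec)) sec[[s]] else mt
    }, character(1))
    cols <- c(cols, list(v))
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- header
  out <- rbind(as.list(stats::setNames(kinds, header)), df)
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write case base to ", path)
}

write_case_base_jsonl <- function(base, path) {
  sch <- base$schema
  head <- list(
    schema = lapply(seq_len(nrow(sch)), function(j)
      list(name = sch$name[j], kind = sch$kind[j])),
    class_values = as.list(base$class_values),
    missing_token = base$missing_token
  )
  lines <- jsonlite::toJSON(head, auto_unbox = TRUE, digits = NA, null = "null")
  n <- n_cases(base)
  for (i in seq_len(n)) {
    xs <- as.list(base$x[i, , drop = FALSE])
    xs <- lapply(xs, function(v) if (is.na(v)) NULL else v)
    xs <- xs[!vapply(xs, is.null, logical(1))]
    rec <- list(case_id = base$case_id[i], patient_id = base$patient_id[i],
                x = xs)
    if (!is.na(base$y[i])) rec$y <- base$y[i]
    if (!is.null(base$sections) && length(base$sections[[i]]))
      rec$sections <- as.list(base$sections[[i]])
    lines <- c(lines, jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  }
  ok <- tryCatch({
    writeLines(lines, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write case base to ", path)
}
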