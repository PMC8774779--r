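# YAML configuration: a single file with optional blocks
# `data`, `extraction`, `scoring`, `distance`, `ga`, `compare`.

#' Read a pipeline configuration file
#'
#' Parses a YAML configuration into the package's typed configuration
#' objects. Recognized blocks: `data` ([case_gen_spec()] fields),
#' `extraction` (`patterns`: list of `{name, regex}`), `scoring`
#' (`audit` / `readability`: lists of `{name, weight}`; `thresholds`:
#' `{sigma, gamma, omega}`), `distance` ([distance_config()] fields),
#' `ga` ([ga_config()] fields), `compare` (`n_seeds`, `base_seed`).
#' Missing blocks get package defaults.
#'
#' @param path YAML file path
#' @return list with `data`, `patterns`, `audit`, `readability`,
#'   `thresholds`, `distance`, `ga`, `compare`
#' @export
read_cbr_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  out$data <- do.call(case_gen_spec, cfg$data %||% list())
  out$patterns <- if (!is.null(cfg$extraction$patterns)) {
    pats <- vapply(cfg$extraction$patterns, `[[`, character(1), "regex")
    names(pats) <- vapply(cfg$extraction$patterns, `[[`, character(1), "name")
    pats
  } else default_key_patterns()
  mk_sc <- function(block) {
    if (is.null(block)) return(NULL)
    scoring_config(vapply(block, `[[`, character(1), "name"),
                   vapply(block, function(b) as.numeric(b$weight), numeric(1)))
  }
  out$audit <- mk_sc(cfg$scoring$audit)
  out$readability <- mk_sc(cfg$scoring$readability)
  out$thresholds <- do.call(thresholds, cfg$scoring$thresholds %||% list())
  out$distance <- do.call(distance_config, cfg$distance %||% list())
  out$ga <- do.call(ga_config, cfg$ga %||% list())
  out$compare <- utils::modifyList(list(n_seeds = 5, base_seed = 1),
                                   cfg$compare %||% list())
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
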