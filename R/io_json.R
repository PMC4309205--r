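#' Read phenotype patterns, environments and strategies from JSON
#'
#' Pattern and environment files are JSON objects mapping a name to a
#' partial assignment, e.g. `{"PA": {"A": 1, "B": 0}}`; patterns constrain
#' internal components, environments constrain inputs (unlisted inputs are
#' left free).  A strategies file is a JSON array of strategies; each
#' strategy is an array of phases `{"env": <name or assignment>,
#' "target": <pattern name or true>}`.  A single strategy (an array of
#' phase objects) is also accepted.
#'
#' @param path JSON file path.
#' @return `read_patterns()` and `read_environments()` return a named list
#'   of named integer vectors; `read_strategies()` a list of strategies in
#'   the form expected by [check_strategy()].
#' @export
read_patterns <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(obj) || is.null(names(obj)))
    stop_parse(paste0(path, ": expected a JSON object of named patterns"))
  lapply(obj, function(p) {
    stats::setNames(as.integer(unlist(p)), names(p))
  })
}

#' @rdname read_patterns
#' @export
read_environments <- read_patterns

#' @rdname read_patterns
#' @export
read_strategies <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(obj) || length(obj) == 0L)
    stop_parse(paste0(path, ": expected a JSON array of strategies"))
  as_phase <- function(ph) {
    if (is.null(ph$env)) stop_parse(paste0(path, ": phase without env"))
    env <- if (is.character(ph$env)) ph$env
           else stats::setNames(as.integer(unlist(ph$env)), names(ph$env))
    target <- if (is.null(ph$target) || isTRUE(ph$target)) TRUE
              else if (is.character(ph$target)) ph$target
              else stats::setNames(as.integer(unlist(ph$target)),
                                   names(ph$target))
    list(env = env, target = target)
  }
  is_phase <- function(x) is.list(x) && !is.null(x$env)
  if (is_phase(obj[[1]])) list(lapply(obj, as_phase))
  else lapply(obj, function(s) lapply(s, as_phase))
}

#' Write a check verdict as JSON
#'
#' @param verdict an [check_property()] or [check_strategy()] result.
#' @param file output path or `""` for stdout.
#' @export
write_verdict_json <- function(verdict, file = "") {
  if (inherits(verdict, "strategy_verdict")) verdict <- verdict$verdict
  obj <- list(true = verdict$true, n_init = verdict$n_init,
              counterexample = as.data.frame(verdict$counterexample),
              witness = as.data.frame(verdict$witness))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (nzchar(file)) writeLines(txt, file) else cat(txt, "\n")
  invisible(txt)
}
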