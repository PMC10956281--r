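#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed plus a stage label, so no stage depends on how much randomness an
#' earlier stage consumed. Kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param label character stage label.
#' @return an integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 2654435761) %% 1e6
  as.integer((abs(master) * 7919 + h) %% .Machine$integer.max)
}

run_log <- function(..., log = NULL) {
  msg <- paste0(...)
  if (!is.null(log) && is.environment(log)) {
    log$lines <- c(log$lines, msg)
  }
  invisible(msg)
}

new_log <- function() {
  e <- new.env(parent = emptyenv())
  e$lines <- character()
  e
}

stop_degenerate <- function(...) {
  stop(structure(class = c("degenerate_input_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_spec <- function(...) {
  stop(structure(class = c("specification_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_schema <- function(...) {
  stop(structure(class = c("schema_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
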