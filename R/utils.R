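`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sanitize attribute names to DBF field rules
#'
#' DBF field names are at most 10 bytes. Longer names are truncated; clashes
#' after truncation get a numeric suffix. The old -> new mapping is returned
#' and a warning is emitted whenever any name changed.
#'
#' @param names character vector of attribute names.
#' @return named character vector: `new_names`, with `names()` the originals.
#' @keywords internal
sanitize_dbf_names <- function(names) {
  out <- substr(names, 1L, 10L)
  dup <- duplicated(out)
  counter <- 1L
  while (any(dup)) {
    for (i in which(dup)) {
      suffix <- as.character(counter)
      out[i] <- paste0(substr(out[i], 1L, 10L - nchar(suffix)), suffix)
      counter <- counter + 1L
    }
    dup <- duplicated(out)
  }
  changed <- out != names
  if (any(changed)) {
    warning("DBF field names adjusted: ",
            paste0(names[changed], " -> ", out[changed], collapse = ", "),
            call. = FALSE)
  }
  stats::setNames(out, names)
}

# simple run log used by extraction/batch for per-plot failures
.log_env <- new.env(parent = emptyenv())
.log_env$messages <- character()

log_event <- function(...) {
  msg <- paste0(...)
  .log_env$messages <- c(.log_env$messages, msg)
  invisible(msg)
}

#' Retrieve or clear the package's run log
#'
#' Extraction records per-plot failures (failed external scripts, empty
#' clips, missing biomass inputs) here instead of aborting a batch.
#'
#' @return character vector of log messages.
#' @export
run_log <- function() .log_env$messages

#' @rdname run_log
#' @export
clear_run_log <- function() {
  .log_env$messages <- character()
  invisible(NULL)
}
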