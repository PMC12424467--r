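# Structured conditions and logging shared by all modules.

#' Signal a classed mclselect error
#'
#' All package errors carry class `mcl_error` plus a subclass naming the
#' failure family, so callers and tests can discriminate configuration
#' problems from data problems.
#'
#' @param subclass One of `"config"`, `"validation"`, `"parse"`,
#'   `"predictor"`, `"domain"`, `"assembly"`.
#' @param message Human-readable message.
#' @param ... Named fields stored on the condition (e.g. `id`, `row`).
#' @keywords internal
mcl_stop <- function(subclass, message, ...) {
  cond <- structure(
    class = c(paste0("mcl_", subclass, "_error"), "mcl_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

.mcl_log_levels <- c(debug = 10L, info = 20L, warn = 30L, error = 40L)

#' Set or query the logging threshold
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
mcl_log_level <- function(level = NULL) {
  cur <- getOption("mclselect.log_level", "warn")
  if (is.null(level)) return(cur)
  level <- match.arg(level, names(.mcl_log_levels))
  options(mclselect.log_level = level)
  invisible(cur)
}

#' @keywords internal
mcl_log <- function(level, fmt, ...) {
  thr <- .mcl_log_levels[[getOption("mclselect.log_level", "warn")]]
  if (.mcl_log_levels[[level]] < thr) return(invisible(NULL))
  msg <- if (...length() > 0L) sprintf(fmt, ...) else fmt
  message(sprintf("[%s] %s %s", toupper(level),
                  format(Sys.time(), "%H:%M:%S"), msg))
  invisible(NULL)
}

# stopifnot-style check that raises a classed error
check_that <- function(ok, subclass, message, ...) {
  if (!isTRUE(ok)) mcl_stop(subclass, message, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
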