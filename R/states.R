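#' Health states of the reconstruction model
#'
#' The model follows patients through five mutually exclusive health states:
#' an uncomplicated post-operative state, two complication outcomes (a
#' salvaged reconstruction and a lost reconstruction), an electively revised
#' state, and death. Death is absorbing, and a patient can experience at most
#' one complication pathway over the model horizon.
#'
#' @return Character vector of the five state labels, in matrix order.
#' @export
health_states <- function() {
  c("POSTOP_UNCOMPLICATED", "SALVAGED", "LOSS", "REVISED", "DEAD")
}

# state indices used throughout the engine
.S_POSTOP <- 1L
.S_SALVAGED <- 2L
.S_LOSS <- 3L
.S_REVISED <- 4L
.S_DEAD <- 5L

#' Strategy arms of the analysis
#'
#' @return Character vector of the three reconstruction strategies compared.
#' @export
strategy_names <- function() {
  c("O-FAFF", "ABDOMINAL_FLAP", "IMPLANT")
}

# default pairwise comparisons: intervention first, comparator second
default_pairs <- function() {
  list(
    c("O-FAFF", "IMPLANT"),
    c("O-FAFF", "ABDOMINAL_FLAP")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("configuration error at '%s': %s", field, msg), call. = FALSE)
}

check_probability <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_config(field, sprintf("probability must be in [0, 1], got %s",
                               paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_config(field, sprintf("must be a single non-negative number, got %s",
                               paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_present <- function(lst, fields, prefix) {
  missing <- setdiff(fields, names(lst))
  if (length(missing)) {
    stop_config(paste0(prefix, ".", missing[1L]), "missing required field")
  }
  invisible(lst)
}
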