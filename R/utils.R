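# Internal helpers shared across modules.

# Classed condition so callers can distinguish failure modes programmatically.
abort_ffl <- function(message, class, ...) {
  rlang::abort(message,
    class = c(paste0("fflscreen_", class, "_error"), "fflscreen_error"),
    ...
  )
}

warn_ffl <- function(message, class, ...) {
  rlang::warn(message,
    class = c(paste0("fflscreen_", class, "_warning"), "fflscreen_warning"),
    ...
  )
}

#' Map sampling times to experimental phase
#'
#' Samples collected while the stimulus is applied belong to the stimulation
#' phase; samples collected after its removal belong to the wash-out phase.
#' Under the default schedule the agent is removed at 8 h, so 0/2/8 h are
#' stimulation and 12 h is wash-out.
#'
#' @param time_h Numeric vector of sampling times in hours.
#' @param washout_after Time (hours) at which the stimulus is removed; times
#'   strictly greater are wash-out.
#' @return Character vector, `"stimulation"` or `"washout"`.
#' @export
#' @examples
#' phase_of_time(c(0, 2, 8, 12))
phase_of_time <- function(time_h, washout_after = 8) {
  if (any(!is.finite(time_h)) || any(time_h < 0)) {
    abort_ffl("`time_h` must be finite and non-negative.", "argument")
  }
  ifelse(time_h > washout_after, "washout", "stimulation")
}

# Keep a tibble's extra attributes through dplyr verbs that strip them.
set_ffl_attrs <- function(x, attrs, class = NULL) {
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  if (!is.null(class)) class(x) <- unique(c(class, class(x)))
  x
}
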