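#' Piecewise-constant treatment schedule
#'
#' A schedule partitions the treatment window `[0, T]` into intervals, each
#' with a fixed [treatment_setting()]. Single-type schedules have one
#' interval; sequential schemes alternate the two treatment types.
#'
#' @param breakpoints strictly increasing numeric vector starting at 0 and
#'   ending at the treatment duration `T`.
#' @param settings list of [treatment_setting()]s, one per interval
#'   (`length(breakpoints) - 1`).
#' @return An object of class `treatment_schedule`.
#' @export
treatment_schedule <- function(breakpoints, settings) {
  if (!is.numeric(breakpoints) || length(breakpoints) < 2L ||
      any(diff(breakpoints) <= 0) || breakpoints[1L] != 0)
    stop("'breakpoints' must start at 0 and be strictly increasing",
         call. = FALSE)
  if (!is.list(settings) || length(settings) != length(breakpoints) - 1L ||
      !all(vapply(settings, inherits, logical(1L), "treatment_setting")))
    stop("'settings' must be a list of treatment_setting objects, ",
         "one per interval", call. = FALSE)
  structure(list(breakpoints = as.numeric(breakpoints), settings = settings),
            class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat(sprintf("Treatment schedule on [0, %.4g] with %d interval(s)\n",
              x$breakpoints[length(x$breakpoints)], length(x$settings)))
  for (k in seq_along(x$settings)) {
    s <- x$settings[[k]]
    cat(sprintf("  [%.4g, %.4g]: delta = %.4g, m = %.4g\n",
                x$breakpoints[k], x$breakpoints[k + 1L], s$delta, s$m))
  }
  invisible(x)
}

#' Single-type treatment schedule
#'
#' @param type `"trait_dependent"` or `"trait_independent"`.
#' @param t_treat treatment duration.
#' @param delta trait-dependent mortality factor used when active.
#' @param m trait-independent mortality rate used when active.
#' @return A [treatment_schedule()] with one interval.
#' @export
single_type_schedule <- function(type = c("trait_dependent",
                                          "trait_independent"),
                                 t_treat = 150, delta = 2, m = 0.86) {
  type <- match.arg(type)
  s <- if (type == "trait_dependent") trait_dependent(delta)
       else trait_independent(m)
  treatment_schedule(c(0, t_treat), list(s))
}

# Normalize a pattern (logical/0-1/character) to logical: TRUE = trait-dep.
normalize_pattern <- function(pattern) {
  if (is.character(pattern)) {
    p <- match(pattern, c("trait_independent", "trait_dependent")) - 1L
    if (anyNA(p))
      stop("character patterns must use 'trait_dependent'/'trait_independent'",
           call. = FALSE)
    return(p == 1L)
  }
  if (is.numeric(pattern) && all(pattern %in% c(0, 1))) return(pattern == 1)
  if (is.logical(pattern) && !anyNA(pattern)) return(pattern)
  stop("'pattern' must be logical, 0/1, or treatment-type labels",
       call. = FALSE)
}

#' Sequential schedule from a binary treatment pattern
#'
#' Splits `[0, t_treat]` into `length(pattern)` equal intervals and assigns
#' the trait-dependent setting where the pattern is `TRUE` (or 1, or
#' `"trait_dependent"`) and the trait-independent setting elsewhere.
#'
#' @param pattern binary vector over the intervals; `TRUE`/1 means
#'   trait-dependent.
#' @inheritParams single_type_schedule
#' @return A [treatment_schedule()].
#' @export
sequence_schedule <- function(pattern, t_treat = 150, delta = 2, m = 0.86) {
  p <- normalize_pattern(pattern)
  n <- length(p)
  if (n < 1L) stop("empty pattern", call. = FALSE)
  treatment_schedule(
    seq(0, t_treat, length.out = n + 1L),
    lapply(p, function(dep) if (dep) trait_dependent(delta)
                            else trait_independent(m)))
}

#' Enumerate all predefined binary treatment sequences
#'
#' Lists every assignment of the two treatment types to `n_intervals`
#' equal-length intervals: `2^n_intervals` sequences in lexicographic order
#' (trait-independent sorting before trait-dependent), each tagged with its
#' proportion of trait-dependent intervals. The reference comparison uses 8
#' intervals, i.e. 256 sequences with at most 7 treatment alterations.
#'
#' @param n_intervals number of equal treatment intervals (1 to 20).
#' @return A list of `predefined_sequence` objects, each with elements
#'   `pattern` (logical, `TRUE` = trait-dependent), `id` (pattern string of
#'   `D`/`I`), and `prop_dep`.
#' @examples
#' length(enumerate_predefined(8))  # 256
#' @export
enumerate_predefined <- function(n_intervals) {
  if (!is.numeric(n_intervals) || length(n_intervals) != 1L ||
      is.na(n_intervals) || n_intervals < 1 || n_intervals > 20 ||
      n_intervals != round(n_intervals))
    stop("'n_intervals' must be an integer between 1 and 20", call. = FALSE)
  n <- as.integer(n_intervals)
  lapply(0:(2^n - 1L), function(s) {
    bits <- as.logical(bitwAnd(s, 2L^((n - 1L):0)) > 0)  # MSB first
    structure(list(pattern = bits,
                   id = paste(ifelse(bits, "D", "I"), collapse = ""),
                   prop_dep = mean(bits)),
              class = "predefined_sequence")
  })
}

#' @export
print.predefined_sequence <- function(x, ...) {
  cat(sprintf("Predefined sequence %s (%.3g trait-dependent)\n",
              x$id, x$prop_dep))
  invisible(x)
}
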