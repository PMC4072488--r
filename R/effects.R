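#' Effect specifications for the synthetic cohort generator
#'
#' An effect specification maps a covariate value to a contribution on the
#' log-hazard scale. Two shapes cover the relationships the cutpoint scan is
#' designed to recover: a step ("threshold") effect, e.g. excess mortality at
#' and above an HbA1c of 9.3%, and a continuous piecewise-linear effect, e.g.
#' a U-shaped BMI-mortality relationship. `null_effect()` contributes nothing
#' and is the building block of null simulations.
#'
#' @param threshold covariate value at which the step occurs (effect applies
#'   at and above it).
#' @param loghr log hazard ratio contributed at/above the threshold.
#' @name effect_spec
NULL

#' @rdname effect_spec
#' @export
threshold_effect <- function(threshold, loghr) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, is.finite(threshold),
            is.numeric(loghr), length(loghr) == 1L, is.finite(loghr))
  structure(list(threshold = threshold, loghr = loghr),
            class = c("threshold_effect", "effect_spec"))
}

#' @rdname effect_spec
#' @param breakpoints increasing covariate values where the slope changes.
#' @param slopes log-HR slope per covariate unit on each of the
#'   `length(breakpoints) + 1` segments. The effect is continuous, anchored at
#'   zero at the first breakpoint, and extrapolates linearly with the nearest
#'   segment's slope outside the breakpoint range.
#' @export
piecewise_effect <- function(breakpoints, slopes) {
  stopifnot(is.numeric(breakpoints), is.numeric(slopes),
            length(slopes) == length(breakpoints) + 1L,
            all(is.finite(breakpoints)), all(is.finite(slopes)))
  if (is.unsorted(breakpoints, strictly = TRUE))
    stop("piecewise_effect: 'breakpoints' must be strictly increasing", call. = FALSE)
  structure(list(breakpoints = breakpoints, slopes = slopes),
            class = c("piecewise_effect", "effect_spec"))
}

#' @rdname effect_spec
#' @export
null_effect <- function() {
  structure(list(), class = c("null_effect", "effect_spec"))
}

#' Evaluate an effect specification on the log-hazard scale
#'
#' @param spec an [effect_spec] object.
#' @param x numeric vector of covariate values.
#' @return numeric vector of log hazard-ratio contributions, same length as
#'   `x`. Values outside the specification's support are extrapolated with the
#'   nearest segment; evaluation never fails for finite `x`.
#' @examples
#' effect_loghr(threshold_effect(9.3, log(1.74)), c(9.2, 9.3))
#' effect_loghr(piecewise_effect(c(24, 30), c(-0.08, 0, -0.08)), c(20, 27, 34))
#' @export
effect_loghr <- function(spec, x) {
  UseMethod("effect_loghr")
}

#' @export
effect_loghr.null_effect <- function(spec, x) {
  rep(0, length(x))
}

#' @export
effect_loghr.threshold_effect <- function(spec, x) {
  ifelse(x >= spec$threshold, spec$loghr, 0)
}

#' @export
effect_loghr.piecewise_effect <- function(spec, x) {
  bp <- spec$breakpoints
  sl <- spec$slopes
  k <- length(bp)
  # cumulative value at each breakpoint, anchored at 0 at bp[1]
  val_bp <- c(0, cumsum(sl[seq_len(k)][-1] * diff(bp)))
  if (k == 1L) val_bp <- 0
  out <- numeric(length(x))
  seg <- findInterval(x, bp) # 0 = below bp[1], k = at/above bp[k]
  below <- seg == 0L
  out[below] <- sl[1L] * (x[below] - bp[1L])
  for (s in seq_len(k)) {
    in_s <- seg == s
    if (any(in_s)) out[in_s] <- val_bp[s] + sl[s + 1L] * (x[in_s] - bp[s])
  }
  out
}

#' @export
print.effect_spec <- function(x, ...) {
  if (inherits(x, "threshold_effect")) {
    cat(sprintf("threshold effect: +%.4f log-HR at x >= %g\n", x$loghr, x$threshold))
  } else if (inherits(x, "piecewise_effect")) {
    cat("piecewise-linear effect (log-HR per unit):\n")
    cat(sprintf("  breakpoints: %s\n", paste(x$breakpoints, collapse = ", ")))
    cat(sprintf("  slopes:      %s\n", paste(format(x$slopes), collapse = ", ")))
  } else {
    cat("null effect (0 everywhere)\n")
  }
  invisible(x)
}

# internal: (de)serialize effect specs for JSON configs
effect_to_list <- function(spec) {
  if (inherits(spec, "threshold_effect"))
    list(type = "threshold", threshold = spec$threshold, loghr = spec$loghr)
  else if (inherits(spec, "piecewise_effect"))
    list(type = "piecewise", breakpoints = spec$breakpoints, slopes = spec$slopes)
  else list(type = "null")
}

effect_from_list <- function(x) {
  switch(x$type,
    threshold = threshold_effect(x$threshold, x$loghr),
    piecewise = piecewise_effect(unlist(x$breakpoints), unlist(x$slopes)),
    null = null_effect(),
    stop("unknown effect type: ", x$type, call. = FALSE)
  )
}
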