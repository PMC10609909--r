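#' Invariant model parameters
#'
#' Constructs the set of season-invariant parameters of the cambial-activity
#' model. Defaults are the values fitted for *Larix sibirica* in the
#' forest-steppe of southern Siberia; all diameters are radial cell sizes in
#' micrometres, rates in micrometres per day, inhibitor quantities in relative
#' units.
#'
#' A cell's cell-cycle phase is determined by its diameter: G1 on
#' `[D_init, D_S)`, S on `[D_S, D_G2)`, G2 on `[D_G2, D_M)` and M on
#' `[D_M, D_div]`. A cell that reaches the critical diameter `D_div` divides
#' if its inhibitor concentration (amount / diameter) is at least `C_min`,
#' and otherwise is exported to the enlargement zone.
#'
#' @param D_S critical diameter for the G1 to S transition (micrometres).
#' @param D_G2 critical diameter for the S to G2 transition.
#' @param D_M critical diameter for the G2 to M transition.
#' @param D_div critical diameter for division.
#' @param C_min minimum inhibitor concentration required for division
#'   (relative units per micrometre).
#' @param V0 growth rate in the S, G2 and M phases (micrometres/day).
#' @param c_g1 Gompertz parameter of the G1 growth rate (relative units).
#' @param D_init diameter of the initial cell after dormancy (micrometres).
#' @param S_stress stress coefficient applied to the G1 rate of cells born
#'   from a stress-flagged division (relative units).
#' @param alpha proportion of the mother's inhibitor given to the proximal
#'   daughter (the one closer to the initial cell); must lie in (0, 1).
#' @param d_init period of the first division of the initial cell (days).
#'   The initial cell grows at the constant rate `(D_div - D_init) / d_init`
#'   until its first division.
#' @param stress_mode how `S_stress` enters the stressed G1 rate:
#'   `"literal"` multiplies the exponent argument (`c_g1 * S_stress * C`),
#'   `"reciprocal"` divides it (`c_g1 * C / S_stress`), which slows stressed
#'   cells down.
#' @param g1_env_coupling `"none"` (G1 rate depends on concentration only) or
#'   `"multiplicative"` (G1 rate additionally multiplied by the day's
#'   integral growth rate).
#' @param mad_scaled logical; if `TRUE` the seasonal mad statistic uses the
#'   1.4826 normal-consistency factor. Default `FALSE` (raw median absolute
#'   deviation).
#' @param skew_default skewness used for the season preceding the first one
#'   on record.
#'
#' @return An object of class `cambium_params` (a named list).
#' @examples
#' p <- cambium_params()
#' p$alpha
#' @export
cambium_params <- function(D_S = 8.5, D_G2 = 8.7, D_M = 9.0, D_div = 9.5,
                           C_min = 0.03, V0 = 0.68, c_g1 = 0.071,
                           D_init = 2.0, S_stress = 100, alpha = 0.8286,
                           d_init = 7.5,
                           stress_mode = c("literal", "reciprocal"),
                           g1_env_coupling = c("none", "multiplicative"),
                           mad_scaled = FALSE, skew_default = 0) {
  p <- list(
    D_S = D_S, D_G2 = D_G2, D_M = D_M, D_div = D_div,
    C_min = C_min, V0 = V0, c_g1 = c_g1, D_init = D_init,
    S_stress = S_stress, alpha = alpha, d_init = d_init,
    stress_mode = match.arg(stress_mode),
    g1_env_coupling = match.arg(g1_env_coupling),
    mad_scaled = isTRUE(mad_scaled), skew_default = skew_default
  )
  class(p) <- "cambium_params"
  validate_params(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a [cambium_params()] object:
#' ordered positive diameter thresholds `D_init < D_S < D_G2 < D_M < D_div`,
#' `alpha` strictly inside (0, 1) and positive `C_min`, `V0`, `d_init`.
#'
#' @param params a `cambium_params` object.
#' @return `params`, invisibly; errors if any invariant fails.
#' @export
validate_params <- function(params) {
  num <- c("D_S", "D_G2", "D_M", "D_div", "C_min", "V0", "c_g1",
           "D_init", "S_stress", "alpha", "d_init")
  for (f in num) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    }
  }
  d <- unlist(params[c("D_init", "D_S", "D_G2", "D_M", "D_div")])
  if (any(d <= 0) || any(diff(d) <= 0)) {
    stop("diameter thresholds must be positive and ordered ",
         "D_init < D_S < D_G2 < D_M < D_div", call. = FALSE)
  }
  if (params$alpha <= 0 || params$alpha >= 1) {
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  if (params$C_min <= 0) stop("C_min must be positive", call. = FALSE)
  if (params$V0 <= 0) stop("V0 must be positive", call. = FALSE)
  if (params$d_init <= 0) stop("d_init must be positive", call. = FALSE)
  invisible(params)
}

#' @export
print.cambium_params <- function(x, ...) {
  cat("Cambial model parameters\n")
  cat(sprintf("  phase thresholds (um): G1<%.2f S<%.2f G2<%.2f M<=%.2f (D_init %.2f)\n",
              x$D_S, x$D_G2, x$D_M, x$D_div, x$D_init))
  cat(sprintf("  V0 %.3f um/d, c %.4g, C_min %.3g, alpha %.4f, S %.4g (%s)\n",
              x$V0, x$c_g1, x$C_min, x$alpha, x$S_stress, x$stress_mode))
  cat(sprintf("  initial division period %.3g d, G1 env coupling: %s\n",
              x$d_init, x$g1_env_coupling))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced; the result is
#' re-validated.
#'
#' @param params a `cambium_params` object.
#' @param ... named replacement values.
#' @return a `cambium_params` object.
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  if (is.null(names(repl)) || any(!nzchar(names(repl)))) {
    stop("replacements must be named", call. = FALSE)
  }
  unknown <- setdiff(names(repl), names(unclass(params)))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params[names(repl)] <- repl
  validate_params(params)
  params
}
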