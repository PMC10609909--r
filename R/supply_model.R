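#' Seasonal inhibitor-supply regression model
#'
#' The inhibitor supply of the initial cell at the start of a growing season
#' quantifies the tree's capacity to produce new cells that year. It is
#' predicted linearly from summary statistics of the current season's daily
#' growth-rate distribution plus the skewness of the previous season's
#' distribution:
#'
#' \deqn{Inh_i = b_0 + b_{sd} sd(Gr_i) + b_{med} median(Gr_i) +
#'   b_{mad} mad(Gr_i) + b_{min} min(Gr_i) + b_{max} max(Gr_i) +
#'   b_{skew} skew(Gr_{i-1})}
#'
#' The default coefficients are those fitted by multiple linear
#' least-squares regression on southern-Siberian larch.
#'
#' @param intercept,beta_sd,beta_median,beta_mad,beta_min,beta_max,beta_skew_prev
#'   regression coefficients (relative units).
#' @return an object of class `supply_model`.
#' @examples
#' m <- supply_model()
#' coef(m)
#' @export
supply_model <- function(intercept = 1.184, beta_sd = 9.44,
                         beta_median = 2.0209, beta_mad = -3.4693,
                         beta_min = -16.5541, beta_max = -1.4214,
                         beta_skew_prev = -0.3408) {
  cf <- c(intercept = intercept, beta_sd = beta_sd, beta_median = beta_median,
          beta_mad = beta_mad, beta_min = beta_min, beta_max = beta_max,
          beta_skew_prev = beta_skew_prev)
  if (any(!is.finite(cf))) stop("all coefficients must be finite", call. = FALSE)
  structure(list(coefficients = cf), class = "supply_model")
}

#' @export
coef.supply_model <- function(object, ...) object$coefficients

#' @export
print.supply_model <- function(x, ...) {
  cat("Seasonal inhibitor-supply regression\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict the seasonal inhibitor supply
#'
#' Evaluates the linear supply predictor for one season given the current
#' season's growth-rate summary statistics and the previous season's
#' skewness. A non-positive prediction is returned unchanged but carries
#' the attribute `nonpositive = TRUE`; the season simulator treats such a
#' supply as "no growth possible".
#'
#' @param stats_current named vector from [season_stats()] (elements `sd`,
#'   `median`, `mad`, `min`, `max`).
#' @param skew_previous skewness of the previous season's rate distribution.
#' @param model a [supply_model()].
#' @return the predicted supply (relative units), with attribute
#'   `nonpositive` if it is `<= 0`.
#' @examples
#' predict_supply(c(sd = 0, median = 0, mad = 0, min = 0, max = 0), 0)
#' @export
predict_supply <- function(stats_current, skew_previous = 0,
                           model = supply_model()) {
  st <- stats_current
  need <- c("sd", "median", "mad", "min", "max")
  if (!all(need %in% names(st))) {
    stop("stats_current must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(c(unlist(st[need]), skew_previous)))) {
    stop("non-finite regressors", call. = FALSE)
  }
  cf <- coef(model)
  val <- unname(cf["intercept"] +
    cf["beta_sd"] * st[["sd"]] +
    cf["beta_median"] * st[["median"]] +
    cf["beta_mad"] * st[["mad"]] +
    cf["beta_min"] * st[["min"]] +
    cf["beta_max"] * st[["max"]] +
    cf["beta_skew_prev"] * skew_previous)
  if (val <= 0) attr(val, "nonpositive") <- TRUE
  val
}

#' @export
predict.supply_model <- function(object, newdata, ...) {
  if (missing(newdata)) stop("newdata required", call. = FALSE)
  vapply(seq_len(nrow(newdata)), function(i) {
    as.numeric(predict_supply(
      c(sd = newdata$sd[i], median = newdata$median[i], mad = newdata$mad[i],
        min = newdata$min[i], max = newdata$max[i]),
      skew_previous = newdata$skew_prev[i], model = object))
  }, numeric(1))
}

#' Refit the supply regression by ordinary least squares
#'
#' Fits the seven-coefficient supply predictor to per-season training pairs
#' by multiple linear least-squares regression (via [stats::lm()]).
#'
#' @param samples data frame with one row per season and columns `sd`,
#'   `median`, `mad`, `min`, `max`, `skew_prev` and `supply` (the target).
#' @return an object of classes `supply_lm` and `supply_model`: the
#'   coefficient vector plus `fitted`, `residuals`, `r.squared`, `se`
#'   (coefficient standard errors) and the underlying `lm` fit.
#' @examples
#' \dontrun{fit <- fit_supply_regression(training_df); summary(fit)}
#' @export
fit_supply_regression <- function(samples) {
  need <- c("sd", "median", "mad", "min", "max", "skew_prev", "supply")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop("samples must contain column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(samples) < 7L) {
    stop("need at least 7 seasons to identify 7 coefficients, got ",
         nrow(samples), call. = FALSE)
  }
  fit <- stats::lm(supply ~ sd + median + mad + min + max + skew_prev,
                   data = samples)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) stop("rank-deficient design matrix", call. = FALSE)
  sm <- suppressWarnings(summary(fit))  # exact interpolation warns harmlessly
  obj <- supply_model(intercept = cf[["(Intercept)"]], beta_sd = cf[["sd"]],
                      beta_median = cf[["median"]], beta_mad = cf[["mad"]],
                      beta_min = cf[["min"]], beta_max = cf[["max"]],
                      beta_skew_prev = cf[["skew_prev"]])
  obj$fitted <- unname(stats::fitted(fit))
  obj$residuals <- unname(stats::residuals(fit))
  obj$r.squared <- sm$r.squared
  obj$se <- stats::setNames(sm$coefficients[, "Std. Error"],
                            names(obj$coefficients))
  obj$lm <- fit
  class(obj) <- c("supply_lm", "supply_model")
  obj
}

#' @export
print.supply_lm <- function(x, ...) {
  cat("Refit seasonal inhibitor-supply regression (OLS)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("R-squared: %.4f on %d seasons\n",
              x$r.squared, length(x$fitted)))
  invisible(x)
}

#' @export
summary.supply_lm <- function(object, ...) {
  out <- data.frame(estimate = object$coefficients, std.error = object$se)
  cat("Seasonal inhibitor-supply regression fit\n")
  print(round(out, 4))
  cat(sprintf("R-squared: %.4f\n", object$r.squared))
  invisible(out)
}

#' Read or write supply-model coefficients as JSON
#'
#' Serialization of the seven regression coefficients, e.g. for use from the
#' command-line interface.
#'
#' @param model a `supply_model`.
#' @param path file path.
#' @return `write_supply_model` returns `path` invisibly;
#'   `read_supply_model` returns a `supply_model`.
#' @export
write_supply_model <- function(model, path) {
  jsonlite::write_json(as.list(coef(model)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_supply_model
#' @export
read_supply_model <- function(path) {
  cf <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(supply_model, as.list(cf))
}
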