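# Dose-response summarization and model-vs-experiment association.
#
# Potency is estimated with a four-parameter log-logistic model
#   y = bottom + (top - bottom) / (1 + 10^(hill * (log10 EC50 - log10 dose)))
# fit by Levenberg-Marquardt least squares. When a reference curve is
# supplied the fit assumes equal efficacy and parallelism: slope and
# asymptotes are shared across the two curves and only the midpoint shifts.

#' Dose-response curve container
#'
#' @param doses Strictly positive doses (micromolar); replicates appear as
#'   repeated doses.
#' @param responses Responses in %BaP_max (percent of the maximal
#'   benzo\[a\]pyrene response), same length as `doses`.
#' @param compound Compound name.
#' @return Data frame of class `"dose_response"` with columns `dose`,
#'   `response`, sorted by dose, and a `compound` attribute.
#' @export
dose_response <- function(doses, responses, compound = "compound") {
  doses <- as.numeric(doses); responses <- as.numeric(responses)
  if (length(doses) != length(responses) || length(doses) == 0L)
    stop("doses and responses must be non-empty and equal length")
  if (any(!is.finite(doses)) || any(doses <= 0)) stop("doses must be positive and finite")
  if (any(!is.finite(responses))) stop("responses must be finite")
  o <- order(doses)
  out <- data.frame(dose = doses[o], response = responses[o])
  attr(out, "compound") <- compound
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Normalize raw luminescence to %BaP_max
#'
#' @param raw Raw luminescence readings.
#' @param reference_max The maximal reference (50 nM benzo\[a\]pyrene)
#'   response; must be positive.
#' @return `100 * raw / reference_max`.
#' @examples
#' normalize_to_bapmax(c(500, 1000), 1000)
#' @export
normalize_to_bapmax <- function(raw, reference_max) {
  if (!is.finite(reference_max) || reference_max <= 0)
    stop("reference_max must be positive")
  100 * raw / reference_max
}

ll4_mean <- function(dose, bottom, top, hill, log_ec50) {
  bottom + (top - bottom) / (1 + 10^(hill * (log_ec50 - log10(dose))))
}

#' Fit a four-parameter log-logistic dose-response curve
#'
#' Estimates EC50 (micromolar) by Levenberg-Marquardt least squares. With a
#' `reference` curve, the equal-efficacy/parallelism assumption is imposed:
#' `bottom`, `top` and `hill` are shared between target and reference and
#' only the two midpoints differ.
#'
#' @param curve A [dose_response()] with at least 4 distinct doses.
#' @param reference Optional reference [dose_response()] fit jointly under
#'   the parallelism constraint.
#' @return Object of class `"ec50_fit"`: list with `ec50`, `log_ec50_se`,
#'   `top`, `bottom`, `hill`, `method`, `compound`, `fitted`, `data`,
#'   `convergence` (and `ec50_reference` for joint fits).
#' @examples
#' cv <- simulate_dose_response(fixture_spec(seed = 1, planted_ec50 = 5,
#'                                           noise_sd = 0))
#' fit_ec50(cv)
#' @export
fit_ec50 <- function(curve, reference = NULL) {
  stopifnot(inherits(curve, "dose_response"))
  if (length(unique(curve$dose)) < 4L)
    stop("need at least 4 distinct doses for a 4-parameter fit")
  if (stats::sd(curve$response) == 0) stop("no response variation; cannot fit")
  shared <- !is.null(reference)
  if (shared) stopifnot(inherits(reference, "dose_response"))

  dat <- rbind(
    data.frame(dose = curve$dose, response = curve$response, curve = 1L),
    if (shared) data.frame(dose = reference$dose, response = reference$response,
                           curve = 2L)
  )
  start <- c(bottom = min(dat$response), top = max(dat$response), hill = 1,
             le50 = log10(exp(mean(log(curve$dose)))))
  if (shared)
    start <- c(start, le50_ref = log10(exp(mean(log(reference$dose)))))

  resid_fn <- function(p) {
    le50 <- ifelse(dat$curve == 1L, p[["le50"]],
                   if (shared) p[["le50_ref"]] else p[["le50"]])
    dat$response - ll4_mean(dat$dose, p[["bottom"]], p[["top"]], p[["hill"]], le50)
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15)
  )
  if (fit$info == 0 || fit$info == 9)
    stop("EC50 fit did not converge: ", fit$message)
  p <- fit$par
  if (p[["hill"]] < 0) {  # sign-flipped parameterization of the same curve
    p[["hill"]] <- -p[["hill"]]
    tmp <- p[["top"]]; p[["top"]] <- p[["bottom"]]; p[["bottom"]] <- tmp
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["le50"]], error = function(e) NA_real_)
  structure(list(
    ec50 = 10^p[["le50"]],
    log_ec50_se = se,
    top = p[["top"]], bottom = p[["bottom"]], hill = p[["hill"]],
    ec50_reference = if (shared) 10^p[["le50_ref"]] else NULL,
    method = if (shared) "4PL shared slope/asymptotes (parallelism)" else "4PL",
    compound = attr(curve, "compound"),
    data = curve,
    fitted = ll4_mean(curve$dose, p[["bottom"]], p[["top"]], p[["hill"]], p[["le50"]]),
    convergence = fit$info
  ), class = "ec50_fit")
}

#' @export
print.ec50_fit <- function(x, ...) {
  cat(sprintf("<ec50_fit> %s: EC50 = %.4g uM (hill %.3f, bottom %.1f, top %.1f; %s)\n",
              x$compound, x$ec50, x$hill, x$bottom, x$top, x$method))
  if (!is.null(x$ec50_reference))
    cat(sprintf("  reference EC50 = %.4g uM\n", x$ec50_reference))
  invisible(x)
}

#' @export
coef.ec50_fit <- function(object, ...) {
  c(ec50 = object$ec50, bottom = object$bottom, top = object$top,
    hill = object$hill)
}

#' @export
predict.ec50_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$dose else newdata$dose
  ll4_mean(dose, object$bottom, object$top, object$hill, log10(object$ec50))
}

#' @export
residuals.ec50_fit <- function(object, ...) {
  object$data$response - object$fitted
}

#' @export
plot.ec50_fit <- function(x, ...) {
  graphics::plot(x$data$dose, x$data$response, log = "x",
                 xlab = "dose (uM)", ylab = "response (%BaP_max)",
                 main = x$compound, ...)
  dd <- 10^seq(log10(min(x$data$dose)), log10(max(x$data$dose)), length.out = 200)
  graphics::lines(dd, ll4_mean(dd, x$bottom, x$top, x$hill, log10(x$ec50)))
  graphics::abline(v = x$ec50, lty = 2)
  invisible(x)
}

#' Association between a model score and observed potency
#'
#' Computes either the squared Pearson correlation (`"pearson_r2"`) or the
#' Spearman rank correlation with mid-ranks for ties (`"spearman"`), with a
#' two-sided p-value. The transform is applied to the observed variable `y`
#' only (e.g. `"reciprocal"` turns EC50 into the potency scale 1/EC50).
#'
#' @param x Model scores (e.g. DRF).
#' @param y Observed values (e.g. EC50 in micromolar).
#' @param method `"pearson_r2"` or `"spearman"`.
#' @param transform `"identity"`, `"reciprocal"` or `"log10"`, applied to `y`.
#' @return Object of class `"drf_association"`: list with `method`,
#'   `statistic` (r^2 or rho), `p_value`, `n`, `transform`.
#' @examples
#' ref <- load_reference_tables()
#' association(ref$drf, ref$ec50_h4iie, "spearman", "reciprocal")
#' @export
association <- function(x, y, method = c("pearson_r2", "spearman"),
                        transform = c("identity", "reciprocal", "log10")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in input")
  y <- switch(transform, identity = y, reciprocal = 1 / y, log10 = log10(y))
  if (any(!is.finite(y))) stop("transform produced non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in a variable")
  if (method == "pearson_r2") {
    ct <- stats::cor.test(x, y, method = "pearson")
    stat <- unname(ct$estimate)^2
  } else {
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE))
    stat <- unname(ct$estimate)
  }
  structure(list(method = method, statistic = stat, p_value = ct$p.value,
                 n = length(x), transform = transform),
            class = "drf_association")
}

#' @export
print.drf_association <- function(x, ...) {
  lab <- if (x$method == "pearson_r2") "r^2" else "rho"
  cat(sprintf("<association> %s (%s transform): %s = %.4f, p = %.3g, n = %d\n",
              x$method, x$transform, lab, x$statistic, x$p_value, x$n))
  invisible(x)
}
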