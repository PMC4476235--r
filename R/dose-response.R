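#' Construct a dose-response curve
#'
#' @param compound_id compound identifier.
#' @param concentrations strictly ascending concentrations, uM, all >= 0.
#' @param responses percent inhibition, one per concentration.
#' @param source provenance of the responses: a model measure
#'   (`"predicted_nef"`, `"predicted_ned"`, `"predicted_nfd"`) or
#'   `"experimental"`.
#' @return an object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(compound_id, concentrations, responses,
                                source = c("predicted_nef", "predicted_ned",
                                           "predicted_nfd", "experimental")) {
  source <- match.arg(source)
  concentrations <- as.numeric(concentrations)
  responses <- as.numeric(responses)
  if (length(concentrations) != length(responses))
    stop_pathdose("concentrations and responses must have equal length",
                  "pathdose_validation_error")
  if (any(concentrations < 0) || any(diff(concentrations) <= 0))
    stop_pathdose("concentrations must be non-negative and strictly ascending",
                  "pathdose_validation_error")
  structure(list(compound_id = compound_id,
                 concentrations = concentrations,
                 responses = responses, source = source),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("dose_response_curve [%s] %s: %d points, response %.2f..%.2f%%\n",
              x$source, x$compound_id, length(x$concentrations),
              min(x$responses), max(x$responses)))
  invisible(x)
}

#' Predict a single-compound dose-response curve from the network model
#'
#' For each concentration the compound is applied alone to the network and
#' the chosen connectivity measure (percent) is recorded as the predicted
#' inhibition.  Responses are non-decreasing in concentration because every
#' edge resistance is non-decreasing in dose.
#'
#' @param net a `pathway_network`.
#' @param aff an `affinity_table`; the compound needs at least one record
#'   whose target is in `net`.
#' @param compound_id compound to evaluate.
#' @param concentrations ascending dose grid, uM.  When omitted, 12
#'   log-spaced points spanning two decades either side of the
#'   half-plateau dose.
#' @param measure `"nef"` (default), `"ned"` or `"nfd"`.
#' @param evaluator optional precomputed [nef_evaluator()] for `(net, aff)`.
#' @return a `dose_response_curve` with source `predicted_<measure>`.
#' @export
predict_curve <- function(net, aff, compound_id, concentrations = NULL,
                          measure = c("nef", "ned", "nfd"), evaluator = NULL) {
  measure <- match.arg(measure)
  aff <- if (inherits(aff, "affinity_table")) aff else affinity_table(aff)
  rec <- aff[aff$compound_id == compound_id, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop_pathdose(sprintf("compound '%s' has no affinity record", compound_id),
                  "pathdose_validation_error")
  f <- evaluator %||% nef_evaluator(net, aff)
  if (is.null(concentrations))
    concentrations <- default_grid(f, compound_id, rec$ki_uM, measure)
  if (length(concentrations) == 0L)
    stop_pathdose("empty concentration grid", "pathdose_validation_error")
  resp <- vapply(concentrations, function(c0) {
    f(dose_scenario(setNames(c0, compound_id)), measure)
  }, numeric(1))
  dose_response_curve(compound_id, concentrations, resp,
                      paste0("predicted_", measure))
}

# plateau of the single-compound measure (dose -> infinity limit,
# approximated at 1e9 times the largest Ki)
compound_plateau <- function(f, compound_id, ki, measure = "nef") {
  f(dose_scenario(setNames(max(ki) * 1e9, compound_id)), measure)
}

# 12 log-spaced points over [d50/100, 100*d50] where d50 is the dose at
# half the compound's saturating measure (coarse bisection)
default_grid <- function(f, compound_id, ki, measure = "nef", n = 12) {
  plateau <- compound_plateau(f, compound_id, ki, measure)
  if (plateau <= 0)
    stop_pathdose(sprintf("compound '%s' has no effect on the network",
                          compound_id), "pathdose_domain_error")
  half <- plateau / 2
  g <- function(c0) f(dose_scenario(setNames(c0, compound_id)), measure) - half
  upper <- min(ki)
  while (g(upper) < 0) upper <- upper * 4
  d50 <- uniroot(g, c(0, upper), tol = upper * 1e-6)$root
  10^seq(log10(d50 / 100), log10(d50 * 100), length.out = n)
}

#' Evaluate the Hill-type dose-response model
#'
#' `y(c) = e_max - (e_max - e_min) / (1 + (c / ec50)^n)`: a four-parameter
#' log-logistic curve rising from `e_min` at zero dose to `e_max` at
#' saturating dose, with half-maximal effect at `c = ec50` and slope `n`.
#'
#' @param conc concentration(s), uM, >= 0.
#' @param fit a `hill_fit` or a list/vector with elements `e_max`, `e_min`,
#'   `ec50`, `n`.
#' @return predicted response(s), percent.
#' @export
hill_eval <- function(conc, fit) {
  p <- as.list(fit)[c("e_max", "e_min", "ec50", "n")]
  if (any(vapply(p, is.null, TRUE)))
    stop_pathdose("fit must carry e_max, e_min, ec50, n", "pathdose_domain_error")
  with(p, e_max - (e_max - e_min) / (1 + (conc / ec50)^n))
}

#' Fit the Hill-type model to a dose-response curve
#'
#' Levenberg-Marquardt nonlinear least squares of the four-parameter model
#' of [hill_eval()].  Initialization: `e_max = max(y)`, `e_min = min(y)`,
#' `ec50` the concentration nearest the half-maximal response, `n = 1`.
#' Box constraints keep the asymptotes within 20 percentage points of the
#' observed extremes (e.g. data topping out near 100 percent admit
#' `e_max` in `[80, 120]`), which stabilizes the fit on sparse grids.
#'
#' @param curve a `dose_response_curve` (>= 5 points recommended, spanning
#'   both sides of the inflection).
#' @param asymptote_margin half-width of the asymptote boxes, percentage
#'   points (default 20).
#' @return an object of class `hill_fit`: `e_max`, `e_min`, `ec50`, `n`,
#'   `r2` and the underlying `nls.lm` optimizer output in `$fit`.
#' @export
fit_hill <- function(curve, asymptote_margin = 20) {
  stopifnot(inherits(curve, "dose_response_curve"))
  conc <- curve$concentrations
  y <- curve$responses
  if (length(y) < 5L)
    stop_pathdose("need at least 5 points to fit the 4-parameter model",
                  "pathdose_fit_error")
  if (diff(range(y)) < 1e-8)
    stop_pathdose("degenerate flat curve: response does not vary",
                  "pathdose_fit_error")
  half <- (max(y) + min(y)) / 2
  ec50_start <- conc[which.min(abs(y - half))]
  if (ec50_start <= 0) ec50_start <- min(conc[conc > 0])
  start <- c(e_max = max(y), e_min = min(y), ec50 = ec50_start, n = 1)
  lower <- c(e_max = max(y) - asymptote_margin,
             e_min = min(y) - asymptote_margin,
             ec50 = 1e-12, n = 1e-3)
  upper <- c(e_max = max(y) + asymptote_margin,
             e_min = min(y) + asymptote_margin,
             ec50 = Inf, n = 100)
  residuals_at <- function(p)
    y - (p[1] - (p[1] - p[2]) / (1 + (conc / p[3])^p[4]))
  out <- minpack.lm::nls.lm(
    par = start, fn = residuals_at, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  if (!out$info %in% 1:4)
    stop_pathdose(sprintf("Hill fit did not converge (info %d): %s",
                          out$info, out$message), "pathdose_fit_error")
  p <- as.list(out$par)
  r2 <- 1 - sum(out$fvec^2) / sum((y - mean(y))^2)
  structure(c(p, list(r2 = r2, fit = out, compound_id = curve$compound_id,
                      source = curve$source)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "hill_fit %s [%s]: E_max = %.2f%%  E_min = %.2f%%  EC50 = %.4g uM  n = %.3f  R2 = %.6f\n",
    x$compound_id %||% "", x$source %||% "", x$e_max, x$e_min, x$ec50, x$n, x$r2))
  invisible(x)
}

#' Agreement between predicted and experimental EC50 values
#'
#' Ordinary least-squares regression of experimental EC50 on predicted
#' EC50 across compounds.  Both the ordinary coefficient of determination
#' and its small-sample adjusted form are returned; the adjusted form is
#' the headline `r2`.  (For a simple regression the ordinary R-squared is
#' symmetric in the two variables, so which one is the regressor only
#' affects the fitted line, not R-squared.)
#'
#' @param predicted,experimental equal-length numeric vectors of EC50
#'   values, uM (n >= 3).
#' @return a list of class `ec50_correlation`: `r2` (adjusted), and
#'   `r2_ordinary`, `r2_adjusted`, `slope`, `intercept`, `n`.
#' @examples
#' ref <- pge2_reference_fits()
#' ec50_correlation(ref$ec50_pred, ref$ec50_exp)
#' @export
ec50_correlation <- function(predicted, experimental) {
  if (length(predicted) != length(experimental))
    stop_pathdose("lists must have equal length", "pathdose_validation_error")
  n <- length(predicted)
  if (n < 3L)
    stop_pathdose("need at least 3 compounds", "pathdose_validation_error")
  m <- lm(experimental ~ predicted)
  s <- summary(m)
  structure(list(r2 = s$adj.r.squared,
                 r2_ordinary = s$r.squared,
                 r2_adjusted = s$adj.r.squared,
                 slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
                 n = n),
            class = "ec50_correlation")
}

#' @export
print.ec50_correlation <- function(x, ...) {
  cat(sprintf("EC50 agreement over %d compounds: R2 = %.4f (adjusted; ordinary %.4f)\n",
              x$n, x$r2_adjusted, x$r2_ordinary))
  invisible(x)
}

#' Read / write a dose-response curve as TSV
#'
#' Columns `concentration_uM` and `response_pct`.
#'
#' @param curve a `dose_response_curve` (for writing).
#' @param path file path.
#' @param compound_id,source metadata for the curve being read.
#' @return [read_curve()] returns a `dose_response_curve`.
#' @export
write_curve <- function(curve, path) {
  write.table(data.frame(concentration_uM = curve$concentrations,
                         response_pct = curve$responses),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path, compound_id = "compound", source = "experimental") {
  tab <- read.delim(path)
  dose_response_curve(compound_id, tab$concentration_uM, tab$response_pct,
                      source)
}
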