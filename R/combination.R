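#' Two-drug dose-response surface
#'
#' Evaluates the network measure for every pair of doses on a grid: the
#' surface `response[i, j]` is the predicted percent inhibition when
#' compound A is at `grid_a[i]` and compound B at `grid_b[j]`.  Shared
#' targets combine the two occupancies in a single inhibition fraction;
#' exclusive targets are inhibited independently.  The first row / column
#' of a grid starting at 0 reproduces the single-drug curves.
#'
#' @param net a `pathway_network`.
#' @param aff an `affinity_table` with records for both compounds.
#' @param compound_a,compound_b compound ids.
#' @param grid_a,grid_b ascending dose grids, uM.  When omitted: 0 followed
#'   by 24 log-spaced points spanning two decades either side of the
#'   compound's half-plateau dose.
#' @param measure `"nef"` (default), `"ned"` or `"nfd"`.
#' @return an object of class `dose_response_surface` with the grids and
#'   the response matrix (rows = `grid_a`).
#' @export
dose_response_surface <- function(net, aff, compound_a, compound_b,
                                  grid_a = NULL, grid_b = NULL,
                                  measure = c("nef", "ned", "nfd")) {
  measure <- match.arg(measure)
  aff <- if (inherits(aff, "affinity_table")) aff else affinity_table(aff)
  f <- nef_evaluator(net, aff)
  grid_a <- grid_a %||% surface_grid(f, aff, compound_a, measure)
  grid_b <- grid_b %||% surface_grid(f, aff, compound_b, measure)
  if (any(diff(grid_a) <= 0) || any(diff(grid_b) <= 0))
    stop_pathdose("dose grids must be strictly ascending",
                  "pathdose_validation_error")
  resp <- matrix(NA_real_, length(grid_a), length(grid_b))
  for (i in seq_along(grid_a)) for (j in seq_along(grid_b)) {
    sc <- dose_scenario(setNames(c(grid_a[i], grid_b[j]),
                                 c(compound_a, compound_b)))
    resp[i, j] <- f(sc, measure)
  }
  structure(list(compound_a = compound_a, compound_b = compound_b,
                 grid_a = grid_a, grid_b = grid_b, response = resp,
                 measure = measure),
            class = "dose_response_surface")
}

surface_grid <- function(f, aff, compound_id, measure, n = 25) {
  rec <- aff[aff$compound_id == compound_id, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop_pathdose(sprintf("compound '%s' has no affinity record", compound_id),
                  "pathdose_validation_error")
  c(0, default_grid(f, compound_id, rec$ki_uM, measure, n = n - 1))
}

#' @export
print.dose_response_surface <- function(x, ...) {
  cat(sprintf("dose_response_surface [%s] %s x %s: %d x %d grid, max %.2f%%\n",
              x$measure, x$compound_a, x$compound_b,
              length(x$grid_a), length(x$grid_b), max(x$response)))
  invisible(x)
}

#' Write a dose-response surface
#'
#' The response matrix as a dense TSV (rows = compound A doses) plus two
#' axis files `<path>.axis_a.tsv` and `<path>.axis_b.tsv`.
#'
#' @param surf a `dose_response_surface`.
#' @param path destination TSV for the matrix.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surf, path) {
  write.table(surf$response, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(dose_uM = surf$grid_a), paste0(path, ".axis_a.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(dose_uM = surf$grid_b), paste0(path, ".axis_b.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Single dose producing a given effect
#'
#' Inverts the (monotone) single-compound dose-response relation of the
#' network model by bisection: the returned dose, applied alone, produces
#' the requested percent effect.
#'
#' @param net a `pathway_network`.
#' @param aff an `affinity_table`.
#' @param compound_id compound to dose.
#' @param effect target percent effect, strictly between 0 and the
#'   compound's saturating plateau.
#' @param measure `"nef"` (default), `"ned"` or `"nfd"`.
#' @param evaluator optional precomputed [nef_evaluator()].
#' @return dose in uM (relative accuracy about 1e-10).
#' @export
single_dose_for_effect <- function(net, aff, compound_id, effect,
                                   measure = c("nef", "ned", "nfd"),
                                   evaluator = NULL) {
  measure <- match.arg(measure)
  aff <- if (inherits(aff, "affinity_table")) aff else affinity_table(aff)
  rec <- aff[aff$compound_id == compound_id, , drop = FALSE]
  if (nrow(rec) == 0L)
    stop_pathdose(sprintf("compound '%s' has no affinity record", compound_id),
                  "pathdose_validation_error")
  if (effect <= 0 || effect >= 100)
    stop_pathdose("effect must lie strictly between 0 and 100 percent",
                  "pathdose_domain_error")
  f <- evaluator %||% nef_evaluator(net, aff)
  plateau <- compound_plateau(f, compound_id, rec$ki_uM, measure)
  if (effect >= plateau)
    stop_pathdose(sprintf(
      "effect %.3f%% is unattainable for '%s' (plateau %.3f%%)",
      effect, compound_id, plateau), "pathdose_attainability_error")
  g <- function(c0) f(dose_scenario(setNames(c0, compound_id)), measure) - effect
  upper <- min(rec$ki_uM)
  while (g(upper) < 0) upper <- upper * 4
  uniroot(g, c(0, upper), tol = upper * 1e-12)$root
}

#' Chou-Talalay combination index of a two-drug dose pair
#'
#' The combined scenario's effect `x` is measured, the dose of each drug
#' that would produce `x` alone is found by inverting its single-drug
#' curve, and the combination index is
#' `CI = dose_a / Dx_a + dose_b / Dx_b`.
#' `CI < 1` indicates synergism, `CI = 1` an additive (Loewe-consistent)
#' combination, `CI > 1` antagonism.
#'
#' @param net a `pathway_network`.
#' @param aff an `affinity_table`.
#' @param compound_a,compound_b compound ids.
#' @param dose_a,dose_b doses, uM (not both 0).
#' @param measure `"nef"` (default), `"ned"` or `"nfd"`.
#' @param evaluator optional precomputed [nef_evaluator()].
#' @return a list of class `combination_index`: `ci`, the effect `x`
#'   (percent), the single-drug equivalent doses `dx_a`, `dx_b`, and the
#'   inputs.
#' @export
combination_index <- function(net, aff, compound_a, compound_b,
                              dose_a, dose_b,
                              measure = c("nef", "ned", "nfd"),
                              evaluator = NULL) {
  measure <- match.arg(measure)
  aff <- if (inherits(aff, "affinity_table")) aff else affinity_table(aff)
  f <- evaluator %||% nef_evaluator(net, aff)
  if (dose_a < 0 || dose_b < 0 || (dose_a == 0 && dose_b == 0))
    stop_pathdose("need a non-trivial, non-negative dose pair",
                  "pathdose_domain_error")
  doses <- c(dose_a, dose_b)[c(dose_a, dose_b) > 0]
  ids <- c(compound_a, compound_b)[c(dose_a, dose_b) > 0]
  x <- f(dose_scenario(setNames(doses, ids)), measure)
  if (x <= 0 || x >= 100)
    stop_pathdose("combined effect outside (0, 100)%: CI undefined",
                  "pathdose_attainability_error")
  dx_a <- if (dose_a > 0)
    single_dose_for_effect(net, aff, compound_a, x, measure, evaluator = f)
    else NA_real_
  dx_b <- if (dose_b > 0)
    single_dose_for_effect(net, aff, compound_b, x, measure, evaluator = f)
    else NA_real_
  ci <- (if (dose_a > 0) dose_a / dx_a else 0) +
        (if (dose_b > 0) dose_b / dx_b else 0)
  structure(list(ci = ci, effect = x, dx_a = dx_a, dx_b = dx_b,
                 compound_a = compound_a, compound_b = compound_b,
                 dose_a = dose_a, dose_b = dose_b, measure = measure),
            class = "combination_index")
}

#' @export
print.combination_index <- function(x, ...) {
  verdict <- if (x$ci < 1 - 1e-9) "synergism"
             else if (x$ci > 1 + 1e-9) "antagonism" else "additive"
  cat(sprintf("CI = %.6f (%s) at effect %.2f%% [%s %.4g uM + %s %.4g uM]\n",
              x$ci, verdict, x$effect, x$compound_a, x$dose_a,
              x$compound_b, x$dose_b))
  invisible(x)
}

#' Isobologram at a fixed effect level
#'
#' The locus of dose pairs `(d_a, d_b)` that all produce the same percent
#' effect.  The sweep runs `d_a` from 0 to the single-drug equivalent dose
#' of compound A; for each `d_a` the complementary `d_b` is solved by
#' bisection on the monotone response.  Each point carries its
#' combination index, which along an isobole simplifies to
#' `d_a / Dx_a + d_b / Dx_b` with the axis intercepts `Dx`.
#'
#' @param net a `pathway_network`.
#' @param aff an `affinity_table`.
#' @param compound_a,compound_b compound ids.
#' @param effect percent effect level, attainable by each drug alone.
#' @param n_points number of dose pairs (default 21).
#' @param measure `"nef"` (default), `"ned"` or `"nfd"`.
#' @return a data frame of class `isobologram` with columns `dose_a`,
#'   `dose_b`, `effect`, `ci`; attributes `dx_a`, `dx_b` hold the axis
#'   intercepts.
#' @export
isobologram <- function(net, aff, compound_a, compound_b, effect,
                        n_points = 21, measure = c("nef", "ned", "nfd")) {
  measure <- match.arg(measure)
  aff <- if (inherits(aff, "affinity_table")) aff else affinity_table(aff)
  f <- nef_evaluator(net, aff)
  dx_a <- single_dose_for_effect(net, aff, compound_a, effect, measure,
                                 evaluator = f)
  dx_b <- single_dose_for_effect(net, aff, compound_b, effect, measure,
                                 evaluator = f)
  sweep_a <- seq(0, dx_a, length.out = n_points)
  dose_b <- vapply(sweep_a, function(da)
    isobole_db(f, compound_a, compound_b, da, effect, dx_b, measure),
    numeric(1))
  ci <- sweep_a / dx_a + dose_b / dx_b
  out <- data.frame(dose_a = sweep_a, dose_b = dose_b,
                    effect = effect, ci = ci)
  attr(out, "dx_a") <- dx_a
  attr(out, "dx_b") <- dx_b
  class(out) <- c("isobologram", "data.frame")
  out
}

# solve d_b such that measure(d_a fixed, d_b) == effect
isobole_db <- function(f, compound_a, compound_b, da, effect, dx_b, measure) {
  g <- function(db) {
    doses <- c(da, db)[c(da, db) > 0]
    ids <- c(compound_a, compound_b)[c(da, db) > 0]
    if (length(doses) == 0L) return(-effect)
    f(dose_scenario(setNames(doses, ids)), measure) - effect
  }
  if (g(0) >= 0) return(0)          # d_a alone already reaches the level
  upper <- dx_b
  while (g(upper) < 0) upper <- upper * 2
  uniroot(g, c(0, upper), tol = max(upper, 1e-12) * 1e-12)$root
}

#' Most synergistic dose pair at a fixed effect level
#'
#' Scans the isobole at the requested effect level and refines the dose
#' pair minimizing the combination index by golden-section search on the
#' sweep coordinate.  Also reports the optimal dose ratio `dose_a/dose_b`
#' and, for comparison, the ratio of the two compounds' model EC50s
#' (half-plateau doses), since maximal synergism is expected near the
#' EC50 ratio.
#'
#' @inheritParams isobologram
#' @param n_scan isobole points in the initial scan (default 41).
#' @return a list of class `optimal_combination`: `dose_a`, `dose_b`,
#'   `effect`, `ci`, `dose_ratio`, `ec50_ratio`, `flat` (TRUE when the CI
#'   landscape is constant, e.g. a sham combination), and the scanned
#'   `isobole`.
#' @export
optimal_combination <- function(net, aff, compound_a, compound_b, effect,
                                n_scan = 41, measure = c("nef", "ned", "nfd")) {
  measure <- match.arg(measure)
  aff <- if (inherits(aff, "affinity_table")) aff else affinity_table(aff)
  iso <- isobologram(net, aff, compound_a, compound_b, effect,
                     n_points = n_scan, measure = measure)
  dx_a <- attr(iso, "dx_a"); dx_b <- attr(iso, "dx_b")
  f <- nef_evaluator(net, aff)
  ci_at <- function(da) {
    db <- isobole_db(f, compound_a, compound_b, da, effect, dx_b, measure)
    da / dx_a + db / dx_b
  }
  flat <- diff(range(iso$ci)) < 1e-8
  if (flat) {
    best <- iso[ceiling(nrow(iso) / 2), ]
  } else {
    k <- which.min(iso$ci)
    lo <- iso$dose_a[max(1L, k - 1L)]
    hi <- iso$dose_a[min(nrow(iso), k + 1L)]
    opt <- optimize(ci_at, c(lo, hi), tol = max(dx_a, 1e-12) * 1e-8)
    db <- isobole_db(f, compound_a, compound_b, opt$minimum, effect, dx_b,
                     measure)
    best <- data.frame(dose_a = opt$minimum, dose_b = db, effect = effect,
                       ci = opt$objective)
    if (min(iso$ci) < best$ci) best <- iso[which.min(iso$ci), ]
  }
  rec_a <- aff[aff$compound_id == compound_a, , drop = FALSE]
  rec_b <- aff[aff$compound_id == compound_b, , drop = FALSE]
  ec50_a <- model_ec50(net, aff, compound_a, rec_a$ki_uM, measure, f)
  ec50_b <- model_ec50(net, aff, compound_b, rec_b$ki_uM, measure, f)
  structure(list(dose_a = best$dose_a, dose_b = best$dose_b,
                 effect = effect, ci = best$ci,
                 dose_ratio = best$dose_a / best$dose_b,
                 ec50_ratio = ec50_a / ec50_b,
                 flat = flat, isobole = iso,
                 compound_a = compound_a, compound_b = compound_b),
            class = "optimal_combination")
}

# half-plateau dose of the model's own single-drug curve
model_ec50 <- function(net, aff, compound_id, ki, measure, evaluator) {
  plateau <- compound_plateau(evaluator, compound_id, ki, measure)
  single_dose_for_effect(net, aff, compound_id, plateau / 2, measure,
                         evaluator = evaluator)
}

#' @export
print.optimal_combination <- function(x, ...) {
  cat(sprintf("optimal combination %s:%s at %.1f%% effect\n",
              x$compound_a, x$compound_b, x$effect))
  if (x$flat)
    cat("  CI landscape is flat (additive everywhere); midpoint reported\n")
  cat(sprintf("  dose_a = %.4g uM, dose_b = %.4g uM, CI = %.6f\n",
              x$dose_a, x$dose_b, x$ci))
  cat(sprintf("  dose ratio %.4g vs model EC50 ratio %.4g\n",
              x$dose_ratio, x$ec50_ratio))
  invisible(x)
}

#' Write isobole / combination-index points
#'
#' TSV with columns `dose_a  dose_b  effect  CI`.
#'
#' @param iso an `isobologram` data frame.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_isobole <- function(iso, path) {
  out <- data.frame(dose_a = iso$dose_a, dose_b = iso$dose_b,
                    effect = iso$effect, CI = iso$ci)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
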