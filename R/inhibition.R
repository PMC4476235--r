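#' Fraction of target inhibition under non-competitive kinetics
#'
#' For a non-competitive inhibitor at concentration `conc` with inhibition
#' constant `ki`, the residual enzyme activity is `1 / (1 + conc/ki)`
#' independent of substrate concentration, so the fraction of activity lost
#' ("fraction of affection") is
#' `fa = 1 - 1 / (1 + conc/ki)`.
#'
#' @param conc inhibitor concentration, uM (vectorized, each >= 0).
#' @param ki inhibition constant, uM (> 0).
#' @return fraction(s) in `[0, 1)`; 0 at `conc = 0`, 0.5 at `conc = ki`.
#' @examples
#' fraction_affected(c(0, 10, 1990), ki = 10)  # 0, 0.5, 0.995
#' @export
fraction_affected <- function(conc, ki) {
  if (any(!is.finite(ki)) || any(ki <= 0))
    stop_pathdose("ki must be strictly positive", "pathdose_domain_error")
  if (any(conc < 0))
    stop_pathdose("concentration must be non-negative", "pathdose_domain_error")
  1 - 1 / (1 + conc / ki)
}

#' Joint fraction of inhibition for mutually exclusive inhibitors
#'
#' When several mutually exclusive non-competitive inhibitors act on the
#' same target, their occupancies add in the denominator:
#' `fa = 1 - 1 / (1 + sum(conc_i / ki_i))`.  With a single inhibitor this
#' reduces to [fraction_affected()]; it is symmetric in the inhibitors and
#' depends only on the summed normalized dose.
#'
#' @param conc vector of concentrations, uM.
#' @param ki vector of inhibition constants, uM (same length).
#' @return a single fraction in `[0, 1)`; 0 for an empty dose list.
#' @export
fraction_affected_multi <- function(conc, ki) {
  if (length(conc) != length(ki))
    stop_pathdose("conc and ki must have equal length", "pathdose_domain_error")
  if (length(conc) == 0L) return(0)
  if (any(!is.finite(ki)) || any(ki <= 0))
    stop_pathdose("ki must be strictly positive", "pathdose_domain_error")
  if (any(conc < 0))
    stop_pathdose("concentration must be non-negative", "pathdose_domain_error")
  1 - 1 / (1 + sum(conc / ki))
}

#' Edge value of an inhibited signaling step
#'
#' Maps a fraction of target inhibition `fa` to the resistance of the edges
#' leaving that target: `ev = 10^(2.303 * fa)`.  An uninhibited target
#' (`fa = 0`) keeps the default resistance 1; full inhibition saturates at
#' `10^2.303` (about 200.9, chosen so that a 99.5%-blocked target has
#' resistance near `1/(1 - 0.995) = 200`).
#'
#' @param fa fraction(s) of inhibition in `[0, 1]`.
#' @return edge value(s) in `[1, 10^2.303]`.
#' @export
edge_value <- function(fa) {
  if (any(!is.finite(fa)) || any(fa < 0) || any(fa > 1))
    stop_pathdose("fa must lie in [0, 1]", "pathdose_domain_error")
  10^(2.303 * fa)
}

#' Convert pKi to an inhibition constant in uM
#'
#' `pki` is `-log10(Ki)` with Ki in mol/L, so `Ki[uM] = 10^(6 - pki)`.
#'
#' @param pki numeric vector of pKi values.
#' @return Ki in uM.
#' @export
pki_to_ki <- function(pki) {
  if (any(!is.finite(pki)))
    stop_pathdose("pki must be finite", "pathdose_domain_error")
  10^(6 - pki)
}

#' Construct a compound-target binding affinity table
#'
#' One record per (compound, target) pair with the docking- or assay-derived
#' pKi (`-log10` of the inhibition constant in mol/L).  A compound may have
#' records for several targets (polypharmacology); each target is then
#' inhibited independently from the same free concentration.
#'
#' @param records data frame with columns `compound_id`, `target_node`,
#'   `pki`.
#' @return an `affinity_table` (a validated data frame with a derived
#'   `ki_uM` column).
#' @export
affinity_table <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("compound_id", "target_node", "pki")
  if (!all(need %in% names(records)))
    stop_pathdose("affinity table needs compound_id, target_node, pki columns",
                  "pathdose_format_error")
  records$compound_id <- as.character(records$compound_id)
  records$target_node <- as.character(records$target_node)
  records$pki <- as.numeric(records$pki)
  if (any(!is.finite(records$pki)))
    stop_pathdose("pki values must be finite numbers", "pathdose_validation_error")
  key <- paste(records$compound_id, records$target_node, sep = "\r")
  if (anyDuplicated(key))
    stop_pathdose(sprintf("duplicate affinity record for %s",
                          gsub("\r", " @ ", key[duplicated(key)][1])),
                  "pathdose_validation_error")
  records$ki_uM <- pki_to_ki(records$pki)
  structure(records[, c(need, "ki_uM")],
            class = c("affinity_table", "data.frame"))
}

#' Read / write an affinity table
#'
#' Plain CSV or TSV with header `compound_id,target_node,pki` (separator
#' guessed from the extension, `.tsv` meaning tab).
#'
#' @param path file to read or write.
#' @param aff an `affinity_table` (for writing).
#' @return [read_affinity()] returns an `affinity_table`.
#' @export
read_affinity <- function(path) {
  if (!file.exists(path))
    stop_pathdose(sprintf("file not found: %s", path), "pathdose_io_error")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop_pathdose(
      sprintf("cannot parse %s: %s", path, conditionMessage(e)),
      "pathdose_format_error"))
  affinity_table(tab)
}

#' @rdname read_affinity
#' @export
write_affinity <- function(aff, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  write.table(aff[, c("compound_id", "target_node", "pki")], path,
              sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a dose scenario
#'
#' One evaluated condition: a set of compounds each at one concentration.
#' Represented as a named numeric vector of concentrations in uM.
#'
#' @param ... named concentrations (`compound = conc_uM`), or a single named
#'   numeric vector.
#' @return a named numeric vector of class `dose_scenario`.
#' @examples
#' dose_scenario(caffeic_acid = 30, scopoletin = 45)
#' @export
dose_scenario <- function(...) {
  args <- list(...)
  doses <- if (length(args) == 1L && is.numeric(args[[1]]) &&
               !is.null(names(args[[1]]))) args[[1]] else unlist(args)
  if (length(doses) == 0L) doses <- setNames(numeric(0), character(0))
  if (is.null(names(doses)) || any(!nzchar(names(doses))))
    stop_pathdose("every dose must be named by its compound id",
                  "pathdose_validation_error")
  if (anyDuplicated(names(doses)))
    stop_pathdose("at most one dose per compound", "pathdose_validation_error")
  if (any(doses < 0) || any(!is.finite(doses)))
    stop_pathdose("concentrations must be finite and >= 0",
                  "pathdose_validation_error")
  structure(as.numeric(doses), names = names(doses), class = "dose_scenario")
}

# fa per target node for a scenario, as a named numeric vector (targets of
# dosed compounds only; targets without any dosed inhibitor are absent)
scenario_fa <- function(aff, scenario) {
  dosed <- names(scenario)[unclass(scenario) > 0]
  rec <- aff[aff$compound_id %in% dosed, , drop = FALSE]
  targets <- unique(rec$target_node)
  fa <- vapply(targets, function(t) {
    r <- rec[rec$target_node == t, , drop = FALSE]
    fraction_affected_multi(unclass(scenario)[r$compound_id], r$ki_uM)
  }, numeric(1))
  setNames(fa, targets)
}

#' Apply a dose scenario to a pathway network
#'
#' For every target node with at least one dosed inhibitor, the joint
#' fraction of inhibition is computed with [fraction_affected_multi()] and
#' every edge leaving that target gets the resistance [edge_value()]
#' of that fraction; all other edges keep `ev = 1`.  Topology is never
#' altered.
#'
#' @param net a `pathway_network` (its current `ev` values are ignored; the
#'   perturbation is always applied to the unperturbed topology).
#' @param aff an `affinity_table`; every target node referenced by a dosed
#'   compound must exist in `net`.
#' @param scenario a [dose_scenario()]; compounds without any affinity
#'   record contribute nothing (with a warning).
#' @return a new `pathway_network` with updated edge values.
#' @export
apply_scenario <- function(net, aff, scenario) {
  stopifnot(inherits(net, "pathway_network"))
  if (!inherits(scenario, "dose_scenario")) scenario <- dose_scenario(scenario)
  aff <- if (inherits(aff, "affinity_table")) aff else affinity_table(aff)
  dosed <- names(scenario)[unclass(scenario) > 0]
  known <- dosed %in% aff$compound_id
  if (any(!known))
    warning(sprintf("no affinity record for compound(s): %s; ignored",
                    paste(dosed[!known], collapse = ", ")))
  rec <- aff[aff$compound_id %in% dosed, , drop = FALSE]
  missing <- setdiff(rec$target_node, net$nodes$id)
  if (length(missing))
    stop_pathdose(sprintf("affinity target(s) not in network: %s",
                          paste(missing, collapse = ", ")),
                  "pathdose_validation_error")
  fa <- scenario_fa(aff, scenario)
  out <- net
  out$edges$ev <- 1
  if (length(fa)) {
    idx <- match(out$edges$source, names(fa))
    hit <- !is.na(idx)
    out$edges$ev[hit] <- edge_value(fa[idx[hit]])
  }
  out
}
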