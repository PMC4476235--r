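#' All-pairs weighted shortest path lengths
#'
#' Directed shortest-path lengths with the edge values `ev` as weights
#' (Dijkstra; all `ev >= 1`, so weights are non-negative).  Unreachable
#' pairs have length `Inf`; the diagonal is 0 but is excluded from all
#' downstream sums.
#'
#' @param net a `pathway_network`.
#' @return a numeric matrix `d[i, j]` of path lengths, node ids as dimnames.
#' @export
shortest_path_lengths <- function(net) {
  if (any(net$edges$ev < 0))
    stop_pathdose("negative edge values are not allowed", "pathdose_domain_error")
  g <- as_igraph(net)
  igraph::distances(g, mode = "out", weights = igraph::E(g)$ev,
                    algorithm = "dijkstra")
}

ne_from_d <- function(d) {
  diag(d) <- Inf                 # exclude i == j
  sum(1 / d[is.finite(d)])
}

nf_from_d <- function(d, exit) {
  col <- d[, exit]
  col <- col[names(col) != exit]
  sum(1 / col[is.finite(col)])
}

#' Network efficiency
#'
#' Sum over all ordered node pairs `i != j` of the reciprocal weighted
#' shortest-path length, with unreachable pairs contributing 0.  A global
#' measure of network connectivity: inflating edge resistances lowers it.
#'
#' @param net a `pathway_network`.
#' @return a non-negative number.
#' @export
network_efficiency <- function(net) ne_from_d(shortest_path_lengths(net))

#' Network flux
#'
#' Sum of reciprocal shortest-path lengths from every node to the exit node
#' (unreachable contributions are 0).  Like [network_efficiency()] but
#' restricted to paths ending at the pathway's measurable end product, so
#' perturbations of downstream nodes weigh more.
#'
#' @param net a `pathway_network`.
#' @return a non-negative number.
#' @export
network_flux <- function(net) nf_from_d(shortest_path_lengths(net), net$exit_node)

#' Connectivity bounds of a topology
#'
#' NE and NF at the two reference states: all edge values 1 (the
#' unperturbed maximum) and all edge values 200 (the nominal fully
#' inhibited minimum, 200 = 1/(1 - 0.995) corresponding to a 99.5 percent
#' blocked target).
#'
#' @param net a `pathway_network` (its current `ev` are ignored).
#' @param ev_min_value edge value of the fully inhibited reference state
#'   (default 200).
#' @return a list of class `network_bounds` with `ne_max`, `ne_min`,
#'   `nf_max`, `nf_min`.
#' @export
network_bounds <- function(net, ev_min_value = EV_BOUND) {
  g <- as_igraph(net)
  one <- rep(1, nrow(net$edges))
  d1 <- igraph::distances(g, mode = "out", weights = one, algorithm = "dijkstra")
  dm <- d1 * ev_min_value   # uniform weights scale all path lengths uniformly
  structure(list(ne_max = ne_from_d(d1), ne_min = ne_from_d(dm),
                 nf_max = nf_from_d(d1, net$exit_node),
                 nf_min = nf_from_d(dm, net$exit_node)),
            class = "network_bounds")
}

#' Connectivity readout of a perturbed network
#'
#' Computes NE and NF of the network as perturbed, and normalizes them to
#' percent decreases relative to the topology's bounds:
#' `NEd = (NE_max - NE) / (NE_max - NE_min) * 100`, likewise `NFd`, and
#' their geometric mean `NEF = sqrt(NEd * NFd)` — the model's predictor of
#' percent inhibition of the pathway's output.  Because the edge-value map
#' saturates slightly above the nominal bound 200 (at `10^2.303`), `NEd`
#' and `NFd` can marginally exceed 100 and are clamped to `[0, 100]`.
#'
#' @param net a perturbed `pathway_network` (e.g. from [apply_scenario()]).
#' @param bounds optional precomputed [network_bounds()] for the same
#'   topology (computed on the fly when omitted).
#' @return a list of class `connectivity_result` with `ne`, `nf`, `ned`,
#'   `nfd`, `nef` (the last three in percent) and a `clamped` flag.
#' @export
connectivity_result <- function(net, bounds = NULL) {
  bounds <- bounds %||% network_bounds(net)
  d <- shortest_path_lengths(net)
  ne <- ne_from_d(d)
  nf <- nf_from_d(d, net$exit_node)
  denom_e <- bounds$ne_max - bounds$ne_min
  denom_f <- bounds$nf_max - bounds$nf_min
  if (denom_e <= 0 || denom_f <= 0)
    stop_pathdose("degenerate bounds: network is insensitive to perturbation",
                  "pathdose_domain_error")
  ned <- (bounds$ne_max - ne) / denom_e * 100
  nfd <- (bounds$nf_max - nf) / denom_f * 100
  clamped <- ned < 0 | ned > 100 | nfd < 0 | nfd > 100
  ned <- min(max(ned, 0), 100)
  nfd <- min(max(nfd, 0), 100)
  structure(list(ne = ne, nf = nf, ned = ned, nfd = nfd,
                 nef = sqrt(ned * nfd), clamped = clamped),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("NE = %.6g  NF = %.6g  NEd = %.3f%%  NFd = %.3f%%  NEF = %.3f%%\n",
              x$ne, x$nf, x$ned, x$nfd, x$nef))
  invisible(x)
}

#' Fast scenario evaluator for one (network, affinity) system
#'
#' Precomputes the igraph representation, the target-to-edge incidence and
#' the connectivity bounds so that repeated scenario evaluations (curves,
#' surfaces, isoboles, root finding) avoid rebuilding the graph.
#'
#' @param net a `pathway_network`.
#' @param aff an `affinity_table` whose targets all exist in `net`.
#' @return a function `f(scenario, measure = c("nef", "ned", "nfd"))`
#'   returning the requested percent measure; the full
#'   [connectivity_result()] is available via `attr(f, "result")(scenario)`
#'   and the bounds via `attr(f, "bounds")`.
#' @export
nef_evaluator <- function(net, aff) {
  aff <- if (inherits(aff, "affinity_table")) aff else affinity_table(aff)
  missing <- setdiff(unique(aff$target_node), net$nodes$id)
  if (length(missing))
    stop_pathdose(sprintf("affinity target(s) not in network: %s",
                          paste(missing, collapse = ", ")),
                  "pathdose_validation_error")
  g <- as_igraph(net)
  src <- net$edges$source
  exit <- net$exit_node
  bounds <- network_bounds(net)

  result <- function(scenario) {
    if (!inherits(scenario, "dose_scenario")) scenario <- dose_scenario(scenario)
    fa <- scenario_fa(aff, scenario)
    w <- rep(1, length(src))
    if (length(fa)) {
      idx <- match(src, names(fa))
      hit <- !is.na(idx)
      w[hit] <- edge_value(fa[idx[hit]])
    }
    d <- igraph::distances(g, mode = "out", weights = w, algorithm = "dijkstra")
    ne <- ne_from_d(d)
    nf <- nf_from_d(d, exit)
    ned <- (bounds$ne_max - ne) / (bounds$ne_max - bounds$ne_min) * 100
    nfd <- (bounds$nf_max - nf) / (bounds$nf_max - bounds$nf_min) * 100
    clamped <- ned < 0 | ned > 100 | nfd < 0 | nfd > 100
    ned <- min(max(ned, 0), 100); nfd <- min(max(nfd, 0), 100)
    structure(list(ne = ne, nf = nf, ned = ned, nfd = nfd,
                   nef = sqrt(ned * nfd), clamped = clamped),
              class = "connectivity_result")
  }
  f <- function(scenario, measure = c("nef", "ned", "nfd")) {
    measure <- match.arg(measure)
    result(scenario)[[measure]]
  }
  attr(f, "result") <- result
  attr(f, "bounds") <- bounds
  f
}

#' Write a connectivity report
#'
#' One row per evaluated scenario with columns
#' `scenario  NE  NF  NEd  NFd  NEF` as tab-separated text.
#'
#' @param results named list of `connectivity_result` objects.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_connectivity_report <- function(results, path) {
  rows <- do.call(rbind, lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(scenario = nm, NE = r$ne, NF = r$nf,
               NEd = r$ned, NFd = r$nfd, NEF = r$nef)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
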