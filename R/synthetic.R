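#' Random signal-flow pathway network
#'
#' Generates a layered, acyclic signal-flow network shaped like a
#' transduction cascade rather than an Erdos-Renyi graph: nodes are placed
#' in a topological order ending at the exit, a backbone edge links each
#' node to its successor (so every node lies on a path to the exit), and
#' the remaining edges are random forward shortcuts or branches.
#' Deterministic for a fixed seed.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param n_edges number of edges (`n_nodes - 1` up to the forward-pair
#'   maximum `n_nodes * (n_nodes - 1) / 2`).
#' @param seed RNG seed (the generator does not disturb the caller's RNG
#'   stream).
#' @return a validated `pathway_network`; node ids `N01`, `N02`, ... with
#'   the last node as exit.
#' @export
random_pathway <- function(n_nodes, n_edges, seed) {
  if (n_nodes < 3)
    stop_pathdose("need at least 3 nodes", "pathdose_validation_error")
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges < n_nodes - 1 || n_edges > max_edges)
    stop_pathdose(sprintf("n_edges must lie in [%d, %d]", n_nodes - 1,
                          max_edges), "pathdose_validation_error")
  ids <- sprintf("N%02d", seq_len(n_nodes))
  with_local_seed(seed, {
    backbone <- cbind(seq_len(n_nodes - 1), seq_len(n_nodes - 1) + 1L)
    extra <- n_edges - (n_nodes - 1L)
    pool <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    pool <- pool[pool[, 2] - pool[, 1] > 1L, , drop = FALSE]  # backbone excluded
    if (extra > 0) {
      pick <- sample(nrow(pool), extra)
      edges <- rbind(backbone, pool[pick, , drop = FALSE])
    } else edges <- backbone
    pathway_network(
      data.frame(source = ids[edges[, 1]], target = ids[edges[, 2]], ev = 1,
                 stringsAsFactors = FALSE),
      nodes = data.frame(id = ids, stringsAsFactors = FALSE),
      exit_node = ids[n_nodes])
  })
}

#' Random compound-target affinity table
#'
#' Emulates a docking campaign against a pathway: each synthetic compound
#' receives between 1 and `n_targets` records against nodes drawn from the
#' druggable pool (nodes with at least one outgoing edge, excluding the
#' exit — inhibiting a node with no outgoing signal has no effect), with
#' pKi uniform over `pki_range`.  Deterministic for a fixed seed.
#'
#' @param net a `pathway_network`.
#' @param n_compounds number of compounds (ids `C1`, `C2`, ...).
#' @param n_targets maximal targets per compound (capped by the pool size).
#' @param pki_range length-2 range of pKi values; the default `c(4, 6)`
#'   spans Ki from 100 uM down to 1 uM, typical of docking-scored ligands.
#' @param seed RNG seed.
#' @return an `affinity_table`.
#' @export
random_affinities <- function(net, n_compounds, n_targets,
                              pki_range = c(4, 6), seed) {
  pool <- setdiff(unique(net$edges$source), net$exit_node)
  if (n_targets > length(pool))
    stop_pathdose(sprintf("n_targets exceeds the %d druggable nodes",
                          length(pool)), "pathdose_validation_error")
  with_local_seed(seed, {
    rows <- lapply(seq_len(n_compounds), function(i) {
      k <- sample.int(n_targets, 1L)
      data.frame(compound_id = sprintf("C%d", i),
                 target_node = sample(pool, k),
                 pki = runif(k, pki_range[1], pki_range[2]),
                 stringsAsFactors = FALSE)
    })
    affinity_table(do.call(rbind, rows))
  })
}
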