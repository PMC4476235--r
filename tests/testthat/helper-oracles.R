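# Independent shortest-path oracles and small fixtures used across tests.
# These deliberately avoid igraph so that the package's Dijkstra-backed
# engine is checked against a different algorithm.

# Floyd-Warshall all-pairs shortest paths on a pathway_network
fw_distances <- function(net) {
  ids <- net$nodes$id
  n <- length(ids)
  d <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  for (k in seq_len(nrow(net$edges))) {
    e <- net$edges[k, ]
    d[e$source, e$target] <- min(d[e$source, e$target], e$ev)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# exhaustive simple-path enumeration (tiny networks only)
enum_distance <- function(net, from, to) {
  adj <- split(seq_len(nrow(net$edges)), net$edges$source)
  best <- Inf
  walk <- function(node, visited, len) {
    if (len >= best) return()
    if (node == to) { best <<- len; return() }
    for (k in adj[[node]]) {
      nxt <- net$edges$target[k]
      if (!(nxt %in% visited))
        walk(nxt, c(visited, nxt), len + net$edges$ev[k])
    }
  }
  walk(from, from, 0)
  best
}

ne_oracle <- function(net) {
  d <- fw_distances(net)
  diag(d) <- Inf
  sum(1 / d[is.finite(d)])
}

nf_oracle <- function(net) {
  d <- fw_distances(net)
  col <- d[, net$exit_node]
  col <- col[names(col) != net$exit_node]
  sum(1 / col[is.finite(col)])
}

make_chain <- function(ids = c("A", "B", "C"), ev = 1) {
  n <- length(ids)
  pathway_network(
    data.frame(source = ids[-n], target = ids[-1], ev = ev),
    exit_node = ids[n])
}

# duplicate one compound's affinity records under a second id, so the
# "combination" of the two pseudo-compounds is a sham self-combination
sham_affinity <- function(aff, compound, alias) {
  dup <- aff[aff$compound_id == compound, , drop = FALSE]
  dup$compound_id <- alias
  affinity_table(rbind(
    as.data.frame(aff)[, c("compound_id", "target_node", "pki")],
    dup[, c("compound_id", "target_node", "pki")]))
}

# a small toy system used by the combination tests: two drugs with
# disjoint targets, each hitting one arm plus one shared-path chokepoint,
# so both single-drug plateaus exceed 50% NEF
toy_two_arm <- function() {
  edges <- data.frame(
    source = c("S", "A1", "S", "B1", "M", "P"),
    target = c("A1", "M", "B1", "M", "P", "X"))
  net <- pathway_network(edges, exit_node = "X")
  aff <- affinity_table(data.frame(
    compound_id = c("dA", "dA", "dB", "dB"),
    target_node = c("A1", "M", "B1", "P"),
    pki = c(5, 5.3, 4.8, 5.1)))
  list(net = net, aff = aff)
}
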