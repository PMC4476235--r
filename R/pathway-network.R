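#' Construct a pathway network
#'
#' A pathway network is a directed graph whose nodes are proteins, small
#' molecules or processes and whose edges carry a positive edge value `ev`
#' representing the resistance of that signaling step (1 = unperturbed).
#' One node is designated the exit: the pathway's measurable end product
#' (e.g. PGE2 for the packaged LPS fixture).
#'
#' @param edges data frame with columns `source`, `target` and optionally
#'   `ev` (defaults to 1).
#' @param nodes optional data frame with columns `id` and optionally `label`
#'   (display name, defaults to `id`) and `kind` (one of `"protein"`,
#'   `"small_molecule"`, `"process"`; defaults to `"protein"`).  When
#'   omitted, nodes are inferred from the edge endpoints.
#' @param exit_node id of the exit node.
#' @param validate validate invariants (default `TRUE`).
#' @return an object of class `pathway_network` with elements `nodes`,
#'   `edges` and `exit_node`.
#' @examples
#' net <- pathway_network(data.frame(source = c("A", "B"), target = c("B", "C")),
#'                        exit_node = "C")
#' net
#' @export
pathway_network <- function(edges, nodes = NULL, exit_node, validate = TRUE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target") %in% names(edges)))
    stop_pathdose("edge table needs 'source' and 'target' columns",
                  "pathdose_format_error")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (is.null(edges$ev)) edges$ev <- rep(1, nrow(edges))
  edges <- edges[, c("source", "target", "ev")]

  if (is.null(nodes)) {
    ids <- unique(c(edges$source, edges$target))
    nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (is.null(nodes$id))
    stop_pathdose("node table needs an 'id' column", "pathdose_format_error")
  nodes$id <- as.character(nodes$id)
  if (is.null(nodes$label)) nodes$label <- nodes$id
  if (is.null(nodes$kind)) nodes$kind <- "protein"
  nodes <- nodes[, c("id", "label", "kind")]

  net <- structure(
    list(nodes = nodes, edges = edges, exit_node = as.character(exit_node)),
    class = "pathway_network"
  )
  if (validate) validate_network(net)
  net
}

#' Validate a pathway network
#'
#' Checks the structural invariants: unique non-empty node ids, known edge
#' endpoints, no duplicated directed edges, edge values in
#' `[1, ev_cap]`, a known exit node, and reachability of the exit from at
#' least one other node.
#'
#' @param net a `pathway_network`.
#' @param ev_cap maximal admissible edge value.  Defaults to the saturation
#'   of the edge-value map, `10^2.303` (about 200.9); the nominal bound 200
#'   is used only for the connectivity bounds, see [network_bounds()].
#' @return `net`, invisibly; errors of class `pathdose_validation_error`
#'   otherwise.
#' @export
validate_network <- function(net, ev_cap = EV_SATURATION) {
  nodes <- net$nodes; edges <- net$edges
  if (any(!nzchar(nodes$id)))
    stop_pathdose("empty node id", "pathdose_validation_error")
  if (anyDuplicated(nodes$id))
    stop_pathdose(sprintf("duplicate node id: %s",
                          nodes$id[duplicated(nodes$id)][1]),
                  "pathdose_validation_error")
  bad <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(bad))
    stop_pathdose(sprintf("edge endpoint not declared as node: %s", bad[1]),
                  "pathdose_validation_error")
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key))
    stop_pathdose(sprintf("duplicate edge: %s",
                          gsub("\r", " -> ", key[duplicated(key)][1])),
                  "pathdose_validation_error")
  if (any(!is.finite(edges$ev)) || any(edges$ev < 1) ||
      any(edges$ev > ev_cap + 1e-9))
    stop_pathdose(sprintf("edge values must lie in [1, %.4g]", ev_cap),
                  "pathdose_validation_error")
  if (!net$exit_node %in% nodes$id)
    stop_pathdose(sprintf("exit node '%s' is not in the network", net$exit_node),
                  "pathdose_validation_error")
  if (nrow(edges)) {
    g <- as_igraph(net)
    d <- igraph::distances(g, to = net$exit_node, mode = "out")
    reach <- sum(is.finite(d)) - 1L  # excludes the exit itself
    if (reach < 1L)
      stop_pathdose("no node can reach the exit node", "pathdose_validation_error")
  }
  invisible(net)
}

#' @export
print.pathway_network <- function(x, ...) {
  cat(sprintf("pathway_network: %d nodes, %d edges, exit = %s\n",
              nrow(x$nodes), nrow(x$edges), x$exit_node))
  perturbed <- sum(x$edges$ev != 1)
  if (perturbed)
    cat(sprintf("  %d edge(s) perturbed (ev > 1), max ev = %.4g\n",
                perturbed, max(x$edges$ev)))
  invisible(x)
}

#' Convert a pathway network to an igraph graph
#'
#' Edge attribute `ev`, vertex attributes `label` and `kind`, graph
#' attribute `exit_node`.
#'
#' @param net a `pathway_network`.
#' @return an `igraph` directed graph.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  g <- igraph::set_graph_attr(g, "exit_node", net$exit_node)
  g
}

#' Read a pathway network from a file
#'
#' Supported dialects:
#' * `tsv`: header `source<TAB>target<TAB>ev`; the `ev` column is optional
#'   and defaults to 1.
#' * `sif`: `source<TAB>interaction<TAB>target`; the interaction token is
#'   ignored on read.
#' * `graphml`: node attributes `kind` and `label`, edge attribute `ev`,
#'   graph attribute `exit_node`.
#'
#' All edge values are reset to 1 on load: a stored network describes
#' topology, not a perturbation state.
#'
#' @param path file to read.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`; guessed from the file
#'   extension when omitted.
#' @param exit_node exit node id; required for `tsv`/`sif`, optional for
#'   `graphml` (where it may be stored in the file).
#' @return a validated `pathway_network`.
#' @export
load_network <- function(path, format = NULL, exit_node = NULL) {
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("tsv", "sif", "graphml"))
  if (!file.exists(path))
    stop_pathdose(sprintf("file not found: %s", path), "pathdose_io_error")

  if (format == "graphml") {
    g <- tryCatch(igraph::read_graph(path, format = "graphml"),
                  error = function(e) stop_pathdose(
                    sprintf("cannot parse %s as GraphML: %s", path,
                            conditionMessage(e)), "pathdose_format_error"))
    va <- igraph::vertex_attr(g)
    ids <- va$name %||% va$id
    nodes <- data.frame(id = ids,
                        label = va$label %||% ids,
                        kind = va$kind %||% rep("protein", length(ids)),
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g, names = TRUE)
    edges <- data.frame(source = el[, 1], target = el[, 2],
                        stringsAsFactors = FALSE)
    exit_node <- exit_node %||% igraph::graph_attr(g, "exit_node")
    if (is.null(exit_node))
      stop_pathdose("no exit node stored in file or supplied",
                    "pathdose_validation_error")
    return(pathway_network(edges, nodes, exit_node))
  }

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "sif") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(vapply(parts, length, 1L) < 3L)
    if (length(bad))
      stop_pathdose(sprintf("%s: line %d is not 'source<TAB>interaction<TAB>target'",
                            path, bad[1]), "pathdose_format_error")
    edges <- data.frame(source = vapply(parts, `[[`, "", 1L),
                        target = vapply(parts, `[[`, "", 3L),
                        stringsAsFactors = FALSE)
  } else {
    tab <- tryCatch(read.delim(text = lines, sep = "\t",
                               stringsAsFactors = FALSE,
                               check.names = FALSE),
                    error = function(e) stop_pathdose(
                      sprintf("cannot parse %s as TSV: %s", path,
                              conditionMessage(e)), "pathdose_format_error"))
    if (!all(c("source", "target") %in% names(tab)))
      stop_pathdose(sprintf("%s: line 1 must be a header naming 'source' and 'target'",
                            path), "pathdose_format_error")
    edges <- tab[, intersect(c("source", "target"), names(tab))]
  }
  if (is.null(exit_node))
    stop_pathdose("exit_node must be supplied for tsv/sif input",
                  "pathdose_validation_error")
  edges$ev <- 1
  pathway_network(edges, nodes = NULL, exit_node = exit_node)
}

#' Write a pathway network to a file
#'
#' Round-trips with [load_network()]: nodes, edges, exit node and (for
#' GraphML) labels and kinds are reproduced exactly.  SIF writes the
#' interaction token `activates`.
#'
#' @param net a `pathway_network`.
#' @param path destination file.
#' @param format one of `"tsv"`, `"sif"`, `"graphml"`; guessed from the
#'   extension when omitted.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path, format = NULL) {
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("tsv", "sif", "graphml"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else if (format == "sif") {
    writeLines(sprintf("%s\tactivates\t%s", net$edges$source, net$edges$target),
               path)
  } else {
    write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext, sif = "sif", graphml = "graphml", xml = "graphml", "tsv")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
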