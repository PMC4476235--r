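#' The LPS-induced PGE2 production network
#'
#' Packaged transcription of the signaling pathway by which bacterial
#' lipopolysaccharide (LPS) drives prostaglandin E2 (PGE2) production in
#' macrophages: LPS binds CD14, the complex is recognized by TLR4, and the
#' signal splits into the MyD88-dependent and TRIF-dependent branches.
#' These converge on the transcription factors NF-kB, AP-1, IRF-5 and CREB
#' (the CREB arm via p38/MSK1 regulating COX-2 transcription), which induce
#' COX-2 and PGES; arachidonic acid released by cPLA2 is converted by COX-2
#' to PGH2 and by PGES to PGE2, the network's exit node.
#'
#' The transcription has 30 nodes and 38 directed edges; the 14 druggable
#' target proteins of [lps_pge2_targets()] are all present.  Node ids are
#' normalized ASCII tokens (e.g. `NFKB` for NF-kB); display names live in
#' the `label` column.
#'
#' @return a `pathway_network` with exit node `PGE2` and all edge values 1.
#' @seealso [lps_pge2_targets()] for the docking target table.
#' @export
lps_pge2_fixture <- function() {
  nodes <- data.frame(
    id = c("LPS", "CD14", "LPS_CD14", "TLR4", "MYD88", "TRIF",
           "IRAK4", "IRAK1", "TRAF6", "TRAF6_RIP1", "TAK1", "IKK",
           "NFKB", "IRF5", "MKK36", "P38", "MKK47", "JNK", "AP1",
           "TPL2", "MEK12", "ERK", "MSK1", "CREB", "COX2", "PGES",
           "CPLA2", "AA", "PGH2", "PGE2"),
    label = c("LPS", "CD14", "LPS:CD14", "TLR4", "MyD88", "TRIF",
              "IRAK4", "IRAK1", "TRAF6", "TRAF6:RIP1", "TAK1", "IKK",
              "NF-κB", "IRF-5", "MKK3/6", "p38", "MKK4/7", "JNK", "AP-1",
              "TPL2", "MEK1/2", "ERK", "MSK1", "CREB", "COX-2", "PGES",
              "cPLA2", "AA", "PGH2", "PGE2"),
    kind = "protein",
    stringsAsFactors = FALSE
  )
  nodes$kind[nodes$id %in% c("LPS", "AA", "PGH2", "PGE2")] <- "small_molecule"

  edges <- matrix(c(
    "LPS",        "LPS_CD14",
    "CD14",       "LPS_CD14",
    "LPS_CD14",   "TLR4",
    "TLR4",       "MYD88",
    "TLR4",       "TRIF",
    "MYD88",      "IRAK4",
    "IRAK4",      "IRAK1",
    "IRAK1",      "TRAF6",
    "TRAF6",      "TAK1",
    "TRIF",       "TRAF6_RIP1",
    "TRAF6_RIP1", "TAK1",
    "TRIF",       "IRF5",
    "MYD88",      "IRF5",
    "IRF5",       "COX2",
    "TAK1",       "IKK",
    "IKK",        "NFKB",
    "NFKB",       "COX2",
    "TAK1",       "MKK36",
    "MKK36",      "P38",
    "TAK1",       "MKK47",
    "MKK47",      "JNK",
    "JNK",        "AP1",
    "AP1",        "COX2",
    "IKK",        "TPL2",
    "TPL2",       "MEK12",
    "MEK12",      "ERK",
    "ERK",        "AP1",
    "P38",        "MSK1",
    "MSK1",       "CREB",
    "CREB",       "COX2",
    "NFKB",       "PGES",
    "P38",        "CPLA2",
    "ERK",        "CPLA2",
    "CPLA2",      "AA",
    "AA",         "COX2",
    "COX2",       "PGH2",
    "PGH2",       "PGES",
    "PGES",       "PGE2"
  ), ncol = 2, byrow = TRUE)
  edges <- data.frame(source = edges[, 1], target = edges[, 2], ev = 1,
                      stringsAsFactors = FALSE)
  pathway_network(edges, nodes, exit_node = "PGE2")
}

#' Docking target table for the LPS-PGE2 network
#'
#' The 14 druggable proteins of the pathway, with the display name, UniProt
#' accession and PDB structure used for docking.  The `id` column matches
#' node ids of [lps_pge2_fixture()].
#'
#' @return a data frame with columns `id`, `label`, `protein_name`,
#'   `uniprot`, `pdb`.
#' @export
lps_pge2_targets <- function() {
  data.frame(
    id = c("TLR4", "PGES", "TAK1", "AP1", "NFKB", "ERK", "COX2",
           "JNK", "MKK47", "MKK36", "P38", "MEK12", "TRAF6_RIP1", "TRAF6"),
    label = c("TLR4", "PGES", "TAK1", "AP-1", "NF-κB", "ERK", "COX-2",
              "JNK", "MKK4/7", "MKK3/6", "p38", "MEK1/2", "TRAF6:RIP1",
              "TRAF6"),
    protein_name = c("toll-like receptor 4", "Prostaglandin E synthase",
                     "MAP3K7", "Transcription factor AP-1",
                     "Nuclear factor NF-kappa-B", "ERK-1", "COX-2",
                     "c-Jun N-terminal kinase",
                     "mitogen-activated protein kinase kinase 4",
                     "mitogen-activated protein kinase kinase 6",
                     "p38 MAP kinase",
                     "mitogen-activated protein kinase kinase 1",
                     "RIP1", "TNF receptor-associated factor 6"),
    uniprot = c("O00206", "O14684", "O43318", "P05412", "P19838", "P27361",
                "P35354", "P45983", "P45985", "P52564", "P53778", "Q02750",
                "Q13546", "Q9Y4K3"),
    pdb = c("4G8A", "3DWW", "2YIY", "1FOS", "3GUT", "2ZOQ", "3LN1",
            "3PZE", "3ALN", "3FME", "1CM8", "3DY7", "4ITJ", "1LB5"),
    stringsAsFactors = FALSE
  )
}

#' Resolve display names to fixture node ids
#'
#' Maps a vector of names to node ids of a network, matching first on id,
#' then on display label (so `"NF-κB"` and `"NFKB"` both resolve).
#'
#' @param net a `pathway_network`.
#' @param names character vector of ids or labels.
#' @return character vector of node ids; `NA` where unresolved.
#' @export
resolve_nodes <- function(net, names) {
  out <- ifelse(names %in% net$nodes$id, names,
                net$nodes$id[match(names, net$nodes$label)])
  out
}

#' Reference dose-response parameters for five PGE2 inhibitors
#'
#' Fitted Hill parameters of the model-predicted (NEF) dose-response curves
#' and the experimentally measured EC50 values for the five active
#' compounds from Reduning Injection evaluated against LPS-induced PGE2
#' production in RAW264.7 cells: caffeic acid, coumarin, isochlorogenic
#' acid B, protocatechuic acid and scopoletin.  Used as the reference for
#' the predicted-versus-experimental EC50 agreement analysis (see
#' [ec50_correlation()]).
#'
#' @return a data frame with columns `compound`, `e_max` and `e_min`
#'   (percent asymptotes), `ec50_pred` and `ec50_exp` (uM), `n` (slope) and
#'   `r2` (curve-fit coefficient of determination).
#' @export
pge2_reference_fits <- function() {
  data.frame(
    compound = c("Caffeic acid", "Coumarin", "Isochlorogenic acid B",
                 "Protocatechuic acid", "Scopoletin"),
    e_max = c(99.49, 99.99, 111.20, 101.18, 100.72),
    e_min = c(0.28, 0.85, -3.63, -1.46, 0.60),
    ec50_pred = c(30.20, 52.95, 116.16, 42.82, 45.48),
    n = c(0.98, 1.12, 0.56, 0.77, 1.01),
    r2 = c(0.99994, 0.99996, 0.9998, 0.99995, 0.99994),
    ec50_exp = c(17.35, 49.14, 96.82, 46.34, 38.46),
    stringsAsFactors = FALSE
  )
}
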