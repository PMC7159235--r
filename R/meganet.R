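#' Direct gene-gene interaction kinds admitted into the integrated network
#'
#' Indirect kinds (genetic, regulatory, co-expression...) are excluded by the
#' whitelist; only physically direct interaction layers enter the graph.
#' @export
DIRECT_INTERACTION_TYPES <- c("protein-protein", "metabolic",
                              "phosphorylation", "signaling")

#' Build the integrated enhancer-gene network ("MegaNet")
#'
#' Constructs a heterogeneous directed graph with enhancer and gene nodes.
#' Directed regulation edges run enhancer -> gene, carry the set of tissue
#' groups in which the link is active and are weighted by the tissue count.
#' Undirected gene-gene interactions are stored as two opposite directed
#' edges, so that degree counts of unique neighbors are unaffected while
#' shortest-path, PageRank and eigenvector centralities treat them
#' symmetrically.
#'
#' Duplicate regulation rows for the same (enhancer, gene) pair are merged
#' ("without replica"), unioning their tissue sets. Duplicate interaction rows
#' for the same unordered gene pair collapse to one undirected edge. Genes
#' present only via interactions are retained as nodes (they shape gene-side
#' centralities).
#'
#' @param reg_edges tibble `enhancer`, `gene`, `tissues` (list column), as
#'   produced by [read_enhancer_network()]. A `weight` column is recomputed.
#' @param interactions tibble `gene_a`, `gene_b`, `type`, or NULL.
#' @param allowed_types interaction-type whitelist; rows with other types are
#'   dropped and counted.
#' @return object of class `meganet`: list with `graph` (igraph), `enhancers`,
#'   `genes` (character vectors), `reg_edges`, `interactions` (tibbles),
#'   `tissues` (sorted union of tissue groups), `n_dropped_interactions`.
#' @export
build_meganet <- function(reg_edges, interactions = NULL,
                          allowed_types = DIRECT_INTERACTION_TYPES) {
  stopifnot(all(c("enhancer", "gene", "tissues") %in% names(reg_edges)))
  reg <- reg_edges |>
    dplyr::group_by(.data$enhancer, .data$gene) |>
    dplyr::summarise(tissues = list(sort(unique(unlist(.data$tissues)))),
                     .groups = "drop") |>
    dplyr::mutate(weight = lengths(.data$tissues)) |>
    dplyr::arrange(.data$enhancer, .data$gene)
  if (any(reg$weight < 1)) {
    stop("regulation edge with empty tissue set", call. = FALSE)
  }
  n_dropped <- 0L
  if (!is.null(interactions) && nrow(interactions) > 0) {
    keep <- interactions$type %in% allowed_types
    n_dropped <- sum(!keep)
    interactions <- interactions[keep, , drop = FALSE]
    # canonical unordered pair; self-interactions dropped
    a <- pmin(interactions$gene_a, interactions$gene_b)
    b <- pmax(interactions$gene_a, interactions$gene_b)
    ok <- a != b
    interactions <- tibble::tibble(gene_a = a[ok], gene_b = b[ok],
                                   type = interactions$type[ok]) |>
      dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
      dplyr::arrange(.data$gene_a, .data$gene_b)
  } else {
    interactions <- tibble::tibble(gene_a = character(), gene_b = character(),
                                   type = character())
  }
  enh_ids <- sort(unique(reg$enhancer))
  gene_ids <- sort(unique(c(reg$gene, interactions$gene_a,
                            interactions$gene_b)))
  clash <- intersect(enh_ids, gene_ids)
  if (length(clash) > 0) {
    stop("id(s) used as both enhancer and gene: ",
         paste(utils::head(clash, 3), collapse = ", "), call. = FALSE)
  }
  nodes <- data.frame(name = c(enh_ids, gene_ids),
                      type = c(rep("enhancer", length(enh_ids)),
                               rep("gene", length(gene_ids))),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = reg$enhancer, to = reg$gene,
                      kind = rep("regulation", nrow(reg)),
                      weight = reg$weight,
                      tissues = vapply(reg$tissues, paste, character(1),
                                       collapse = ","),
                      stringsAsFactors = FALSE)
  if (nrow(interactions) > 0) {
    edges <- rbind(edges, data.frame(
      from = c(interactions$gene_a, interactions$gene_b),
      to = c(interactions$gene_b, interactions$gene_a),
      kind = "interaction", weight = rep(1, 2 * nrow(interactions)),
      tissues = NA_character_, stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  structure(list(graph = g, enhancers = enh_ids, genes = gene_ids,
                 reg_edges = reg, interactions = interactions,
                 tissues = sort(unique(unlist(reg$tissues))),
                 n_dropped_interactions = n_dropped),
            class = "meganet")
}

#' @export
print.meganet <- function(x, ...) {
  cat("<meganet> ", length(x$enhancers), " enhancers, ", length(x$genes),
      " genes; ", nrow(x$reg_edges), " regulation edges, ",
      nrow(x$interactions), " gene-gene interactions; ",
      length(x$tissues), " tissue groups\n", sep = "")
  invisible(x)
}

#' Extract a tissue-specific subnetwork
#'
#' Keeps the regulation edges active in the given tissue group (the tissue is
#' a member of the edge's tissue set), drops enhancers left without edges, and
#' retains all gene nodes and gene-gene interaction edges.
#'
#' @param net a `meganet`.
#' @param tissue tissue-group label.
#' @return object of class `tissue_subnetwork`: list with `tissue`,
#'   `reg_edges` (filtered tibble), `enhancers` (surviving enhancer ids),
#'   `genes`, `interactions`.
#' @export
extract_tissue_subnetwork <- function(net, tissue) {
  stopifnot(inherits(net, "meganet"))
  if (!tissue %in% net$tissues) {
    stop("unknown tissue '", tissue, "'; valid tissues: ",
         paste(net$tissues, collapse = ", "), call. = FALSE)
  }
  keep <- vapply(net$reg_edges$tissues, function(ts) tissue %in% ts,
                 logical(1))
  reg <- net$reg_edges[keep, , drop = FALSE]
  structure(list(tissue = tissue, reg_edges = reg,
                 enhancers = sort(unique(reg$enhancer)),
                 genes = net$genes, interactions = net$interactions),
            class = "tissue_subnetwork")
}

#' @export
print.tissue_subnetwork <- function(x, ...) {
  cat("<tissue_subnetwork '", x$tissue, "'> ", length(x$enhancers),
      " enhancers, ", nrow(x$reg_edges), " regulation edges\n", sep = "")
  invisible(x)
}

#' Distinct neighbors of a node
#'
#' @param net a `meganet`.
#' @param node_id node name.
#' @param kind edge-kind filter: `"any"`, `"regulation"` or `"interaction"`.
#' @return sorted character vector of adjacent node ids (a gene interaction
#'   partner counts once despite being stored as two directed edges).
#' @export
neighborhood <- function(net, node_id,
                         kind = c("any", "regulation", "interaction")) {
  stopifnot(inherits(net, "meganet"))
  kind <- match.arg(kind)
  if (!node_id %in% igraph::V(net$graph)$name) {
    stop("node '", node_id, "' not in the network", call. = FALSE)
  }
  g <- net$graph
  edge_seq <- igraph::incident(g, node_id, mode = "all")
  if (kind != "any") {
    keep <- igraph::edge_attr(g, "kind", edge_seq) == kind
    edge_seq <- edge_seq[as.logical(keep)]
  }
  if (length(edge_seq) == 0) return(character())
  ends <- igraph::ends(g, edge_seq)
  sort(unique(setdiff(as.character(ends), node_id)))
}
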