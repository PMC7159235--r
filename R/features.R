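#' Edge tissue-ubiquity statistics for one enhancer
#'
#' Given the per-edge tissue counts `(e_1, ..., e_n)` of an enhancer's `n`
#' regulation edges, returns their mean (`EGTUa`) and population variance
#' (`EGTUv`, denominator `n`). The worked example `(2, 1)` yields
#' `EGTUa = 1.5`, `EGTUv = 0.25`.
#'
#' @param values integer vector of per-edge tissue counts, all `>= 1`.
#' @return named numeric vector `c(EGTUa=, EGTUv=)`.
#' @export
edge_ubiquity_stats <- function(values) {
  if (length(values) == 0) {
    stop("enhancer with no regulation edges has no edge-ubiquity statistics",
         call. = FALSE)
  }
  if (any(values < 1)) stop("per-edge tissue counts must be >= 1",
                            call. = FALSE)
  m <- mean(values)
  c(EGTUa = m, EGTUv = mean((values - m)^2))
}

# population variance (denominator n) — the convention used for every "v"
# aggregate in the feature vocabulary
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}

# Principal eigenvector of a symmetric 0/1 adjacency matrix by shifted power
# iteration ((A + I)x avoids oscillation on bipartite components), scaled to
# max 1. A fixed start and fixed reduction order make the result
# bit-reproducible across runs, which Krylov solvers with random restarts are
# not; the feature matrix carries a reproducibility contract.
principal_eigenvector <- function(A, tol = 1e-15, max_iter = 100000L) {
  n <- nrow(A)
  if (n == 1) return(1)
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(max_iter)) {
    xn <- as.numeric(A %*% x) + x
    nrm <- sqrt(sum(xn^2))
    if (nrm == 0) return(rep(0, n))
    xn <- xn / nrm
    if (max(abs(xn - x)) < tol) { x <- xn; break }
    x <- xn
  }
  mx <- max(x)
  if (mx <= 0) rep(0, n) else x / mx
}

#' Node centralities on the integrated network
#'
#' Computes, for every node of the MegaNet (enhancers included, since they
#' shape the topology):
#' \describe{
#'   \item{closeness}{reachability-scaled reciprocal of summed shortest-path
#'     distances *into* the node: with `R` nodes reaching it at total distance
#'     `S` out of `n - 1` others, closeness `= (R / (n-1)) * (R / S)`
#'     (0 when unreached). Edges are followed in their stored direction, so
#'     gene-gene interactions count both ways.}
#'   \item{degree_frac}{fraction of the other `n - 1` nodes that are direct
#'     neighbors (unique neighbors, either direction).}
#'   \item{pagerank}{PageRank with damping 0.85 on the directed graph,
#'     unweighted; values over all nodes sum to 1.}
#'   \item{eigenvector}{eigenvector centrality on the undirected view of the
#'     graph (regulation edges symmetrized for this metric only, which
#'     guarantees a well-behaved principal eigenvector), scaled to max 1.}
#' }
#'
#' @param net a `meganet`.
#' @param damping PageRank damping factor.
#' @return tibble `node`, `type`, `closeness`, `degree_frac`, `pagerank`,
#'   `eigenvector`.
#' @export
node_centralities <- function(net, damping = 0.85) {
  stopifnot(inherits(net, "meganet"))
  g <- net$graph
  n <- igraph::vcount(g)
  dmat <- igraph::distances(g, mode = "in", weights = NA)
  # rows/cols are all nodes; distance d[i, j] with mode="in" is the distance
  # from j to i along directed edges
  closeness <- apply(dmat, 1, function(d) {
    d <- d[is.finite(d) & d > 0]
    r <- length(d)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(d))
  })
  und <- igraph::as_undirected(g, mode = "collapse")
  degree_frac <- igraph::degree(und) / (n - 1)
  pagerank <- igraph::page_rank(g, damping = damping, weights = NA)$vector
  eigenvector <- stats::setNames(
    principal_eigenvector(igraph::as_adjacency_matrix(und, sparse = TRUE)),
    igraph::V(und)$name)
  tibble::tibble(node = igraph::V(g)$name, type = igraph::V(g)$type,
                 closeness = unname(closeness[igraph::V(g)$name]),
                 degree_frac = unname(degree_frac[igraph::V(g)$name]),
                 pagerank = unname(pagerank[igraph::V(g)$name]),
                 eigenvector = unname(eigenvector[igraph::V(g)$name]))
}

#' Compute the per-enhancer feature matrix (unpruned)
#'
#' Produces one row per enhancer with the full network feature vocabulary:
#' \itemize{
#'   \item `EOD` — number of genes the enhancer regulates (out-degree);
#'   \item `ETU` — number of distinct tissues the enhancer is active in
#'     (union over its edges' tissue sets);
#'   \item `EGTUa`, `EGTUv` — mean and population variance of the per-edge
#'     tissue counts;
#'   \item gene aggregates `GIDa/v` (target-gene in-degree: number of
#'     enhancers regulating the gene), `GCCa/v` (closeness), `GDCa/v`
#'     (degree fraction), `GPRCa/v` (PageRank), `GECa/v` (eigenvector),
#'     `GISa/v` (gene indispensability) — each gene-level quantity averaged
#'     ("a") and population-varianced ("v") over the enhancer's target genes;
#'   \item per-tissue blocks `<tissue>__EOD` (out-degree within the tissue
#'     subnetwork) and `<tissue>__GIDa` (mean in-degree of the enhancer's
#'     target genes within the tissue subnetwork);
#'   \item `conservation` — per-enhancer sequence conservation in `[0, 1]`
#'     (NA when not provided; see [impute_missing()]).
#' }
#' Enhancers regulating a single gene get variance aggregates of 0. Targets
#' without an indispensability score leave `GISa`/`GISv` missing.
#'
#' @param net a `meganet`.
#' @param subnetworks list of `tissue_subnetwork`s; NULL extracts one per
#'   tissue group in `net`.
#' @param gis named numeric vector gene -> indispensability score in `[0,1]`.
#' @param conservation named numeric vector enhancer id -> score in `[0,1]`.
#' @param damping PageRank damping factor.
#' @return tibble with `enhancer` id column followed by numeric feature
#'   columns in a fixed, sortable schema.
#' @export
compute_enhancer_features <- function(net, subnetworks = NULL, gis = NULL,
                                      conservation = NULL, damping = 0.85) {
  stopifnot(inherits(net, "meganet"))
  if (is.null(subnetworks)) {
    subnetworks <- lapply(net$tissues, function(t)
      extract_tissue_subnetwork(net, t))
  }
  reg <- net$reg_edges
  cent <- node_centralities(net, damping = damping)
  gene_cent <- cent[cent$type == "gene", , drop = FALSE]
  gid <- table(reg$gene)
  gene_metrics <- data.frame(
    GID = as.numeric(gid[gene_cent$node]),
    GCC = gene_cent$closeness,
    GDC = gene_cent$degree_frac,
    GPRC = gene_cent$pagerank,
    GEC = gene_cent$eigenvector,
    GIS = if (is.null(gis)) NA_real_ else unname(gis[gene_cent$node]),
    row.names = gene_cent$node
  )
  gene_metrics$GID[is.na(gene_metrics$GID)] <- 0  # interaction-only genes

  enh_ids <- net$enhancers
  by_enh <- split(seq_len(nrow(reg)), reg$enhancer)

  base <- lapply(enh_ids, function(e) {
    rows <- by_enh[[e]]
    targets <- reg$gene[rows]
    e_counts <- reg$weight[rows]
    etu <- length(unique(unlist(reg$tissues[rows])))
    eg <- edge_ubiquity_stats(e_counts)
    gm <- gene_metrics[targets, , drop = FALSE]
    agg <- unlist(lapply(names(gm), function(col) {
      x <- gm[[col]]
      stats::setNames(c(mean(x), pop_var(x)), paste0(col, c("a", "v")))
    }))
    c(EOD = length(targets), ETU = etu, eg, agg)
  })
  mat <- tibble::as_tibble(do.call(rbind, base))
  mat <- tibble::add_column(mat, enhancer = enh_ids, .before = 1)

  # per-tissue blocks
  for (sub in subnetworks) {
    t <- sub$tissue
    sub_eod <- table(sub$reg_edges$enhancer)
    sub_gid <- table(sub$reg_edges$gene)
    eod_t <- as.numeric(sub_eod[enh_ids])
    eod_t[is.na(eod_t)] <- 0
    gida_t <- vapply(enh_ids, function(e) {
      targets <- reg$gene[by_enh[[e]]]
      g <- as.numeric(sub_gid[targets])
      g[is.na(g)] <- 0
      mean(g)
    }, numeric(1))
    mat[[paste0(t, "__EOD")]] <- eod_t
    mat[[paste0(t, "__GIDa")]] <- unname(gida_t)
  }

  mat$conservation <- if (is.null(conservation)) NA_real_ else
    unname(conservation[enh_ids])
  mat
}

#' Prune mutually correlated feature columns
#'
#' Greedy Spearman pruning: feature columns are visited in alphabetical
#' order; for every live pair with `|rho| >= threshold` the later-named
#' column is dropped. Columns named in `drop_list` (e.g. tissue blocks known
#' to be redundant) are removed first, regardless of correlation. Every drop
#' is recorded in the `pruning` attribute of the result.
#'
#' @param m feature tibble with an `enhancer` id column.
#' @param threshold absolute Spearman correlation cutoff in `(0, 1]`.
#' @param drop_list character vector of columns to drop unconditionally.
#' @return the pruned tibble; `attr(, "pruning")` is a tibble
#'   `dropped`, `against`, `rho`, `reason`.
#' @export
prune_correlated_features <- function(m, threshold = 0.9,
                                      drop_list = character()) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  feat_cols <- sort(setdiff(names(m), "enhancer"))
  if (length(feat_cols) < 2) stop("need at least 2 feature columns",
                                  call. = FALSE)
  prov <- list()
  alive <- setdiff(feat_cols, drop_list)
  for (d in intersect(drop_list, feat_cols)) {
    prov[[length(prov) + 1L]] <- tibble::tibble(
      dropped = d, against = NA_character_, rho = NA_real_,
      reason = "drop_list")
  }
  if (length(alive) >= 2) {
    cm <- suppressWarnings(stats::cor(as.matrix(m[alive]),
                                      method = "spearman",
                                      use = "pairwise.complete.obs"))
    # identical columns (including constant ones) correlate perfectly even
    # when rank correlation is undefined
    for (i in seq_along(alive)) {
      for (j in seq_along(alive)) {
        if (i < j && is.na(cm[i, j]) &&
            isTRUE(all(m[[alive[i]]] == m[[alive[j]]]))) {
          cm[i, j] <- cm[j, i] <- 1
        }
      }
    }
    dropped <- character()
    for (i in seq_along(alive)) {
      a <- alive[i]
      if (a %in% dropped) next
      for (j in seq_along(alive)) {
        if (j <= i) next
        b <- alive[j]
        if (b %in% dropped) next
        rho <- cm[i, j]
        if (!is.na(rho) && abs(rho) >= threshold) {
          dropped <- c(dropped, b)
          prov[[length(prov) + 1L]] <- tibble::tibble(
            dropped = b, against = a, rho = rho, reason = "correlated")
        }
      }
    }
    alive <- setdiff(alive, dropped)
  }
  out <- m[c("enhancer", alive)]
  attr(out, "pruning") <- if (length(prov) > 0) dplyr::bind_rows(prov) else
    tibble::tibble(dropped = character(), against = character(),
                   rho = numeric(), reason = character())
  out
}

#' Impute missing feature values
#'
#' @param m feature tibble with `enhancer` id column.
#' @param policy `"median"` (column median of observed values), `"zero"`, or
#'   `"droprow"` (remove rows with any missing value).
#' @param labels optional `label_set`; under `"droprow"`, removing a labeled
#'   training enhancer triggers a warning naming the ids.
#' @return tibble with no missing entries; `attr(, "imputation")` records the
#'   imputed cells (`enhancer`, `column`, `value`).
#' @export
impute_missing <- function(m, policy = c("median", "zero", "droprow"),
                           labels = NULL) {
  policy <- match.arg(policy)
  feat_cols <- setdiff(names(m), "enhancer")
  all_missing <- feat_cols[vapply(feat_cols, function(cl) all(is.na(m[[cl]])),
                                  logical(1))]
  if (length(all_missing) > 0 && policy != "droprow") {
    stop("column(s) entirely missing: ",
         paste(all_missing, collapse = ", "), call. = FALSE)
  }
  imputed <- list()
  if (policy == "droprow") {
    keep <- stats::complete.cases(m[feat_cols])
    removed <- m$enhancer[!keep]
    if (!is.null(labels)) {
      lab_removed <- intersect(removed, c(labels$lof_tolerant,
                                          labels$low_tolerance))
      if (length(lab_removed) > 0) {
        warning("droprow removed labeled training enhancer(s): ",
                paste(utils::head(lab_removed, 5), collapse = ", "),
                call. = FALSE)
      }
    }
    out <- m[keep, , drop = FALSE]
  } else {
    out <- m
    for (cl in feat_cols) {
      miss <- which(is.na(out[[cl]]))
      if (length(miss) == 0) next
      fill <- if (policy == "median") stats::median(out[[cl]], na.rm = TRUE)
      else 0
      out[[cl]][miss] <- fill
      imputed[[length(imputed) + 1L]] <- tibble::tibble(
        enhancer = out$enhancer[miss], column = cl, value = fill)
    }
  }
  attr(out, "imputation") <- if (length(imputed) > 0)
    dplyr::bind_rows(imputed) else
      tibble::tibble(enhancer = character(), column = character(),
                     value = numeric())
  attr(out, "pruning") <- attr(m, "pruning")
  out
}
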