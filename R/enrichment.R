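# Gene-set statistics: two-tailed Fisher enrichment of gene categories,
# ranking of pathway graphs by source-to-sink path disruption, and
# single-linkage clustering of categories by shared genes.

#' Build a category map
#'
#' @param df data.frame with columns `gene` and `category` (one row per
#'   association; a gene may belong to several categories)
#' @param background optional gene universe (default: all genes in `df`)
#' @return object of class `category_map`: list(categories = named list of
#'   gene sets, background = character vector)
#' @export
category_map <- function(df, background = NULL) {
  stopifnot(all(c("gene", "category") %in% names(df)))
  cats <- lapply(split(df$gene, df$category), unique)
  if (is.null(background)) background <- unique(df$gene)
  extra <- setdiff(unlist(cats), background)
  if (length(extra)) {
    stop("category genes missing from the background: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  structure(list(categories = cats, background = unique(background)),
            class = "category_map")
}

#' Read a two-column gene-to-category map
#'
#' Tab-delimited with header columns `gene` and `category` (GO terms, KEGG
#' pathway ids, ...).
#'
#' @param path file path
#' @param background optional gene universe
#' @return a [category_map()]
#' @export
read_category_map <- function(path, background = NULL) {
  category_map(utils::read.delim(path, stringsAsFactors = FALSE), background)
}

#' Two-tailed Fisher enrichment / depletion of gene categories
#'
#' For each category, the 2x2 table of (in input set / not) x (in category /
#' not) over the background is tested with a two-tailed Fisher exact test
#' (two-sided by summing hypergeometric outcomes no more probable than the
#' observed one). Input genes outside the background are dropped with a
#' warning. Rows are ranked by the fraction of the category's genes present
#' in the input, then by p-value.
#'
#' @param genes character vector of input gene ids
#' @param cmap a [category_map()]
#' @return data.frame: category, k (input genes in category), K (category
#'   size), n (input size), N (background size), fraction (k/K),
#'   p_two_tailed, direction ("enriched" / "depleted" / "none")
#' @export
fisher_enrichment <- function(genes, cmap) {
  stopifnot(inherits(cmap, "category_map"))
  if (!length(cmap$background)) stop("empty background", call. = FALSE)
  genes <- unique(genes)
  out_bg <- setdiff(genes, cmap$background)
  if (length(out_bg)) {
    warning("dropped ", length(out_bg), " input gene(s) absent from the background")
    genes <- setdiff(genes, out_bg)
  }
  N <- length(cmap$background)
  n <- length(genes)
  rows <- lapply(names(cmap$categories), function(cat) {
    set <- cmap$categories[[cat]]
    K <- length(set)
    k <- length(intersect(genes, set))
    tab <- matrix(c(k, n - k, K - k, N - K - (n - k)), 2L)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    expected <- n * K / N
    data.frame(category = cat, k = k, K = K, n = n, N = N,
               fraction = k / K, p_two_tailed = min(p, 1),
               direction = if (k > expected) "enriched"
                           else if (k < expected) "depleted" else "none",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$fraction, res$p_two_tailed, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a pathway graph
#'
#' A directed gene/compound graph. Sources are nodes with no incoming edge,
#' sinks nodes with no outgoing edge; both are recomputed from the current
#' edge set whenever nodes are removed.
#'
#' @param edges data.frame with columns `from`, `to` (node ids)
#' @param node_genes optional data.frame with columns `node`, `gene` mapping
#'   nodes to the gene(s) they represent (default: node ids are gene ids)
#' @param name pathway label
#' @return object of class `pathway_graph`
#' @export
pathway_graph <- function(edges, node_genes = NULL, name = "pathway") {
  stopifnot(all(c("from", "to") %in% names(edges)))
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = TRUE)
  if (is.null(node_genes)) {
    nodes <- igraph::V(g)$name
    node_genes <- data.frame(node = nodes, gene = nodes, stringsAsFactors = FALSE)
  }
  structure(list(graph = g, node_genes = node_genes, name = name),
            class = "pathway_graph")
}

#' Read a pathway edge list
#'
#' Tab-delimited with header columns `from` and `to`.
#'
#' @param path file path
#' @param node_genes optional node-to-gene map (see [pathway_graph()])
#' @param name pathway label (default: file name)
#' @return a `pathway_graph`
#' @export
read_edge_list <- function(path, node_genes = NULL, name = NULL) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  pathway_graph(utils::read.delim(path, stringsAsFactors = FALSE),
                node_genes, name)
}

graph_sources <- function(g) igraph::V(g)$name[igraph::degree(g, mode = "in") == 0]
graph_sinks <- function(g) igraph::V(g)$name[igraph::degree(g, mode = "out") == 0]

# DFS enumeration of simple source->sink paths (>= 1 edge), counting paths
# and total edge length only; errors out when the count exceeds `cap`.
count_paths_dfs <- function(g, cap) {
  adj <- igraph::as_adj_list(g, mode = "out")
  adj <- lapply(adj, as.integer)
  sink_set <- igraph::degree(g, mode = "out") == 0
  src <- which(igraph::degree(g, mode = "in") == 0)
  env <- new.env()
  env$n <- 0
  env$total_len <- 0
  nv <- igraph::vcount(g)
  visited <- logical(nv)
  recurse <- function(v, depth) {
    visited[v] <<- TRUE
    for (w in adj[[v]]) {
      if (visited[w]) next
      if (sink_set[w]) {
        env$n <- env$n + 1
        if (env$n > cap) {
          stop("path count exceeds cap (", cap, ") -- raise `cap` explicitly",
               call. = FALSE)
        }
        env$total_len <- env$total_len + depth + 1
      }
      if (length(adj[[w]])) recurse(w, depth + 1)
    }
    visited[v] <<- FALSE
  }
  for (s in src) {
    if (sink_set[s]) next  # isolated node: no edge, no path
    recurse(s, 0L)
  }
  list(n = env$n, total_len = env$total_len)
}

#' Source-to-sink path metrics of a pathway
#'
#' Exhaustively enumerates simple directed paths (at least one edge) from any
#' source to any sink and returns their count and mean edge length. Cycles
#' terminate naturally under the simple-path constraint; a cap guards
#' exponential blowup and raises an explicit error when exceeded.
#'
#' @param pg a `pathway_graph`
#' @param cap maximum number of paths before erroring (default 1e6)
#' @return list with `n_paths` and `mean_length` (NA when no path exists)
#' @export
pathway_path_metrics <- function(pg, cap = 1e6) {
  stopifnot(inherits(pg, "pathway_graph"))
  res <- count_paths_dfs(pg$graph, cap)
  list(n_paths = res$n,
       mean_length = if (res$n > 0) res$total_len / res$n else NA_real_)
}

# Remove the nodes carrying any of `genes`; sources/sinks derive from the
# reduced graph.
delete_gene_nodes <- function(pg, genes) {
  hit <- unique(pg$node_genes$node[pg$node_genes$gene %in% genes])
  hit <- intersect(hit, igraph::V(pg$graph)$name)
  out <- pg
  out$graph <- igraph::delete_vertices(pg$graph, hit)
  out$node_genes <- pg$node_genes[!pg$node_genes$node %in% hit, , drop = FALSE]
  out
}

#' Rank pathways by path disruption
#'
#' For each pathway, the source-to-sink path metrics are computed with and
#' without the nodes representing the input genes (node deletion; sources
#' and sinks are recomputed on the reduced graph). The changes
#' `delta_n_paths = n_before - n_after` and `delta_mean_length = mean_before
#' - mean_after` are reported, ranked by |delta mean length| then
#' |delta n paths|, descending. A graph left with no source-to-sink path
#' contributes mean length 0 to the difference.
#'
#' @param pathways list of `pathway_graph` objects
#' @param genes character vector of input gene ids
#' @param cap per-pathway path cap, see [pathway_path_metrics()]
#' @return ranked data.frame: pathway, n_before, n_after, mean_before,
#'   mean_after, delta_n_paths, delta_mean_length
#' @export
rank_pathways_disruption <- function(pathways, genes, cap = 1e6) {
  rows <- lapply(pathways, function(pg) {
    before <- pathway_path_metrics(pg, cap)
    after <- pathway_path_metrics(delete_gene_nodes(pg, genes), cap)
    mb <- if (before$n_paths > 0) before$mean_length else 0
    ma <- if (after$n_paths > 0) after$mean_length else 0
    data.frame(pathway = pg$name,
               n_before = before$n_paths, n_after = after$n_paths,
               mean_before = before$mean_length, mean_after = after$mean_length,
               delta_n_paths = before$n_paths - after$n_paths,
               delta_mean_length = mb - ma,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-abs(res$delta_mean_length), -abs(res$delta_n_paths),
                   res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cluster gene categories by shared genes
#'
#' Single-linkage: two categories link when their shared-gene fraction
#' `|intersection| / min(sizes)` is at least `threshold`; clusters are the
#' connected components of the link graph. Output is independent of input
#' order, and the number of clusters is non-decreasing in the threshold.
#'
#' @param sets named list of gene sets (character vectors)
#' @param threshold linking threshold in (0, 1]
#' @return list of clusters, each a sorted character vector of category
#'   names; clusters ordered by decreasing size then first member
#' @export
cluster_categories <- function(sets, threshold) {
  stopifnot(threshold > 0, threshold <= 1, !is.null(names(sets)))
  nm <- names(sets)
  k <- length(sets)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        ov <- length(intersect(sets[[i]], sets[[j]])) /
          min(length(sets[[i]]), length(sets[[j]]))
        if (ov >= threshold) parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(k), find, integer(1))
  cl <- lapply(split(nm, comp), function(x) sort(x))
  cl <- unname(cl)
  ord <- order(-lengths(cl), vapply(cl, `[`, character(1), 1L))
  cl[ord]
}
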