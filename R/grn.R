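#' Tree-ensemble regulatory-link inference
#'
#' For every target gene, its expression (standardized to unit variance)
#' is regressed on all candidate regulators except itself with a
#' random-forest ensemble (\code{mtry = floor(sqrt(p))}); the importance
#' of a regulator for a target is its impurity-reduction importance
#' averaged over trees. Links are pooled across targets and sorted by
#' descending importance. Zero-variance targets are skipped with a
#' warning.
#'
#' @param expr Genes x cells expression matrix.
#' @param regulators Candidate regulator genes (default: all genes).
#' @param targets Target genes (default: all genes). A gene may be both.
#' @param n_trees Trees per target (default 500).
#' @param seed Integer seed.
#' @return \code{data.frame} (\code{regulator}, \code{target},
#'   \code{importance}), sorted by descending importance, no self-links.
#' @export
inferLinks <- function(expr, regulators = rownames(expr),
                       targets = rownames(expr), n_trees = 500, seed = 1L) {
  missing <- setdiff(c(regulators, targets), rownames(expr))
  if (length(missing)) stop("genes outside the universe: ",
                            paste(head(missing), collapse = ", "))
  x <- t(as.matrix(expr))   # cells x genes for the regression
  out <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    y <- x[, tg]
    if (sd(y) == 0) {
      warning("target ", tg, " has zero variance; skipped")
      next
    }
    regs <- setdiff(regulators, tg)
    if (!length(regs)) next
    df <- data.frame(x[, regs, drop = FALSE], check.names = FALSE)
    df$..target.. <- y / sd(y)
    fit <- ranger::ranger(
      dependent.variable.name = "..target..", data = df,
      num.trees = n_trees, mtry = max(1L, floor(sqrt(length(regs)))),
      importance = "impurity", num.threads = 1L,
      seed = seed + ti)
    imp <- fit$variable.importance / n_trees
    out[[ti]] <- data.frame(regulator = names(imp), target = tg,
                            importance = pmax(unname(imp), 0),
                            stringsAsFactors = FALSE)
  }
  links <- do.call(rbind, out)
  if (is.null(links))
    return(data.frame(regulator = character(0), target = character(0),
                      importance = numeric(0)))
  links <- links[order(-links$importance, links$regulator, links$target), ]
  rownames(links) <- NULL
  links
}

## deterministic link ordering: importance desc, then (regulator, target)
.order_links <- function(links) {
  links[order(-links$importance, links$regulator, links$target), , drop = FALSE]
}

#' Marker-centered network from a link list
#'
#' Keeps links whose regulator or target is one of the marker genes, then
#' retains the \code{top_links} largest importances (ties at the cutoff
#' resolved by (regulator, target) lexicographic order). Nodes are the
#' endpoint genes of the retained links.
#'
#' @param links A link list from [inferLinks()].
#' @param markers Marker gene list (typically the top 10 cluster markers).
#' @param top_links Links to retain (default 300).
#' @return List with \code{edges} (the retained link rows) and
#'   \code{graph} (directed \code{igraph}).
#' @export
buildMarkerNetwork <- function(links, markers, top_links = 300) {
  sel <- links[links$regulator %in% markers | links$target %in% markers, ,
               drop = FALSE]
  sel <- .order_links(sel)
  if (nrow(sel) == 0) {
    warning("no links touch the marker genes; empty network")
  } else if (nrow(sel) < top_links) {
    warning("only ", nrow(sel), " qualifying links (requested ", top_links, ")")
  }
  edges <- head(sel, top_links)
  g <- igraph::graph_from_data_frame(
    edges[, c("regulator", "target", "importance")], directed = TRUE)
  list(edges = edges, graph = g)
}

#' Gene-centric network expansion
#'
#' Ring 1 contains the \code{top_k} strongest partners of \code{gene}
#' (counting links where it is regulator or target); ring 2 adds each
#' ring-1 gene's own \code{top_k} partners. Edges are all links of the
#' list whose endpoints both lie in the included node set.
#'
#' @param links A link list from [inferLinks()].
#' @param gene Center gene (must occur in the link list).
#' @param top_k Partners per ring (default 20; 0 gives the single node).
#' @return List with \code{nodes}, \code{edges}, \code{graph}.
#' @export
geneCentricNetwork <- function(links, gene, top_k = 20) {
  present <- gene %in% links$regulator | gene %in% links$target
  if (!present) stop("gene ", gene, " absent from the link list")
  partners_of <- function(g) {
    sel <- links[links$regulator == g | links$target == g, , drop = FALSE]
    sel <- .order_links(sel)
    p <- ifelse(sel$regulator == g, sel$target, sel$regulator)
    unique(p)[seq_len(min(top_k, length(unique(p))))]
  }
  ring1 <- if (top_k > 0) partners_of(gene) else character(0)
  if (top_k > 0 && length(ring1) < top_k)
    warning("only ", length(ring1), " partners of ", gene,
            " (requested ", top_k, ")")
  ring2 <- unique(unlist(lapply(ring1, partners_of)))
  nodes <- unique(c(gene, ring1, ring2))
  edges <- links[links$regulator %in% nodes & links$target %in% nodes, ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[, c("regulator", "target", "importance")], directed = TRUE,
    vertices = data.frame(name = nodes))
  list(nodes = nodes, edges = edges, graph = g)
}

#' Export a network as an edge-list TSV or GraphML file
#'
#' @param net A network list (from [buildMarkerNetwork()] or
#'   [geneCentricNetwork()]) or an \code{igraph} object.
#' @param path Output file.
#' @param format \code{"tsv"} (three-column edge list) or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  g <- if (igraph::is_igraph(net)) net else net$graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    names(el)[1:2] <- c("regulator", "target")
    write.table(el, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Component sizes and mean local clustering coefficient
#'
#' Metrics are computed on the undirected simple graph (directions,
#' self-loops and duplicate edges dropped). The clustering coefficient is
#' the mean over all nodes of the local coefficient, with nodes of degree
#' < 2 contributing 0.
#'
#' @param net A network list (from [buildMarkerNetwork()] or
#'   [geneCentricNetwork()]) or an \code{igraph} object.
#' @return List with \code{component_sizes} (descending) and
#'   \code{clustering_coefficient}.
#' @export
networkMetrics <- function(net) {
  g <- if (igraph::is_igraph(net)) net else net$graph
  if (igraph::vcount(g) == 0) {
    warning("empty network; clustering coefficient reported as 0")
    return(list(component_sizes = integer(0), clustering_coefficient = 0))
  }
  u <- igraph::as_undirected(igraph::simplify(g), mode = "collapse")
  u <- igraph::simplify(u)
  comp <- igraph::components(u)
  local <- igraph::transitivity(u, type = "local", isolates = "zero")
  local[is.na(local)] <- 0
  list(component_sizes = sort(unname(comp$csize), decreasing = TRUE),
       clustering_coefficient = mean(local))
}
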