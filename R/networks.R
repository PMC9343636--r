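#' Build a significance-thresholded association network
#'
#' Retains exactly the taxon pairs whose correlation magnitude strictly
#' exceeds `r_threshold` and whose FDR-adjusted p-value is below `fdr`.
#' Isolated nodes are dropped.
#'
#' @param rho correlation matrix from [sparcc()].
#' @param q FDR-adjusted p-value matrix from [sparcc_pvalues()].
#' @param tax optional [taxonomy_table()] used to annotate nodes.
#' @param r_threshold correlation magnitude threshold (default 0.3, strict).
#' @param fdr adjusted-p threshold (default 0.05, strict).
#' @param context list with `compartment` and `age` (or `"all"`).
#' @return list of class `assoc_network`: `edges` (otu_a, otu_b, rho, q,
#'   sign), `nodes` (otu_id plus kingdom/class/order when `tax` given),
#'   `context`.
#' @export
build_network <- function(rho, q, tax = NULL, r_threshold = 0.3, fdr = 0.05,
                          context = list(compartment = "all", age = "all")) {
  if (!identical(dim(rho), dim(q))) stop("rho and q must be aligned")
  ids <- rownames(rho)
  sel <- upper.tri(rho) & abs(rho) > r_threshold & q < fdr
  idx <- which(sel, arr.ind = TRUE)
  edges <- data.frame(otu_a = ids[idx[, 1]], otu_b = ids[idx[, 2]],
                      rho = rho[idx], q = q[idx],
                      sign = ifelse(rho[idx] > 0, "pos", "neg"),
                      stringsAsFactors = FALSE)
  used <- sort(unique(c(edges$otu_a, edges$otu_b)))
  nodes <- data.frame(otu_id = used, stringsAsFactors = FALSE)
  if (!is.null(tax)) {
    i <- match(used, tax$otu_id)
    nodes$kingdom <- tax$kingdom[i]
    nodes$class <- tax$class[i]
    nodes$order <- tax$order[i]
  }
  structure(list(edges = edges, nodes = nodes, context = context),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("<assoc_network %s@%s> %d nodes, %d edges\n",
              x$context$compartment, x$context$age,
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(n) {
  igraph::graph_from_data_frame(n$edges[, c("otu_a", "otu_b")],
                                directed = FALSE,
                                vertices = n$nodes$otu_id)
}

#' Node, hub and complexity statistics of an association network
#'
#' Standard unweighted node metrics (degree, betweenness, closeness, local
#' clustering coefficient), the hub set (the 10 highest-degree nodes, ties at
#' the cut broken lexicographically by OTU id), and three degree-based
#' complexity indices summed over edges or the degree sequence:
#' atom-bond connectivity `ABC = sum sqrt((d_u + d_v - 2) / (d_u d_v))`,
#' geometric-arithmetic `GA = sum 2 sqrt(d_u d_v) / (d_u + d_v)`, and the
#' Bertz information index `B = 2m log2(2m) - sum_v d_v log2(d_v)`.
#'
#' @param n [build_network()] result (non-empty).
#' @param n_hubs hub set size (default 10, capped at the node count).
#' @param seed seed for the Louvain modularity value reported alongside.
#' @return list of class `graph_stats`: `nodes` (per-node metrics), `hubs`,
#'   `abc`, `ga`, `bertz`, `modularity`, `n_nodes`, `n_edges`.
#' @export
graph_stats <- function(n, n_hubs = 10, seed = 1L) {
  if (!nrow(n$edges)) stop("empty graph")
  g <- as_igraph(n)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  cls <- suppressWarnings(igraph::closeness(g))
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  nodes <- data.frame(otu_id = igraph::V(g)$name, degree = deg,
                      betweenness = btw, closeness = cls,
                      clustering = cc, row.names = NULL,
                      stringsAsFactors = FALSE)
  ord <- order(-nodes$degree, nodes$otu_id)
  hubs <- nodes$otu_id[ord][seq_len(min(n_hubs, nrow(nodes)))]
  da <- deg[n$edges$otu_a]; db <- deg[n$edges$otu_b]
  abc <- sum(sqrt((da + db - 2) / (da * db)))
  ga <- sum(2 * sqrt(da * db) / (da + db))
  m <- nrow(n$edges)
  dpos <- deg[deg > 0]
  bertz <- 2 * m * log2(2 * m) - sum(dpos * log2(dpos))
  set.seed(seed)
  modQ <- igraph::modularity(igraph::cluster_louvain(g))
  structure(list(nodes = nodes, hubs = hubs, abc = abc, ga = ga,
                 bertz = bertz, modularity = modQ,
                 n_nodes = nrow(nodes), n_edges = m),
            class = "graph_stats")
}

edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Merge context networks into a meta-network
#'
#' Node and edge union over a list of context networks.  Edge identity is the
#' unordered OTU pair (sign-agnostic); each meta-edge keeps the full list of
#' contexts in which it was detected (with that context's correlation), and
#' its summary `rho` is the mean over those contexts.
#'
#' @param networks list of [build_network()] results sharing an OTU
#'   namespace.
#' @return list of class `meta_network`: `edges` (otu_a, otu_b, rho,
#'   n_contexts, contexts string), `provenance` (long data.frame edge,
#'   compartment, age, rho), `nodes`.
#' @export
merge_meta <- function(networks) {
  if (!length(networks)) stop("no networks to merge")
  prov <- do.call(rbind, lapply(networks, function(n) {
    if (!nrow(n$edges)) return(NULL)
    data.frame(edge = edge_key(n$edges$otu_a, n$edges$otu_b),
               compartment = as.character(n$context$compartment),
               age = as.character(n$context$age),
               rho = n$edges$rho, stringsAsFactors = FALSE)
  }))
  if (is.null(prov)) stop("all networks are empty")
  sp <- split(prov, prov$edge)
  edges <- do.call(rbind, lapply(sp, function(df) {
    ab <- strsplit(df$edge[1], "|", fixed = TRUE)[[1]]
    data.frame(otu_a = ab[1], otu_b = ab[2], rho = mean(df$rho),
               n_contexts = nrow(df),
               contexts = paste(df$compartment, df$age, sep = "@",
                                collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  node_ids <- sort(unique(c(edges$otu_a, edges$otu_b)))
  nodes_all <- do.call(rbind, lapply(networks, function(n) n$nodes))
  nodes <- nodes_all[!duplicated(nodes_all$otu_id), , drop = FALSE]
  nodes <- nodes[match(node_ids, nodes$otu_id), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(edges = edges, provenance = prov, nodes = nodes),
            class = "meta_network")
}

#' @export
print.meta_network <- function(x, ...) {
  cat(sprintf("<meta_network> %d nodes, %d edges, %d contexts\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(paste(x$provenance$compartment,
                                  x$provenance$age)))))
  invisible(x)
}

#' Louvain modules of a meta-network with context composition
#'
#' Seeded Louvain modularity maximization on the merged graph, plus the
#' per-module composition of edges by the compartment and age contexts in
#' which they were detected: each (edge, context) detection counts once, and
#' fractions are relative to the module's total detections.
#'
#' @param m [merge_meta()] result.
#' @param seed RNG seed (Louvain is deterministic given the seed).
#' @param resolution Louvain resolution parameter (default 1).
#' @return list of class `module_partition`: `membership` (named integer
#'   vector), `modularity`, `module_sizes`, `composition_compartment` and
#'   `composition_age` (module x context fraction matrices).
#' @export
detect_modules <- function(m, seed = 1L, resolution = 1.0) {
  g <- igraph::graph_from_data_frame(m$edges[, c("otu_a", "otu_b")],
                                     directed = FALSE,
                                     vertices = m$nodes$otu_id)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- setNames(igraph::membership(cl), igraph::V(g)$name)
  # module of an edge detection: both endpoints' module when they agree
  a <- sub("\\|.*", "", m$provenance$edge)
  b <- sub(".*\\|", "", m$provenance$edge)
  same <- memb[a] == memb[b]
  mod_of_det <- ifelse(same, memb[a], NA)
  comp_frac <- function(ctx) {
    tab <- table(module = mod_of_det[!is.na(mod_of_det)],
                 context = ctx[!is.na(mod_of_det)])
    sweep(tab, 1, rowSums(tab), "/")
  }
  structure(list(membership = memb,
                 modularity = igraph::modularity(cl),
                 module_sizes = sort(table(memb), decreasing = TRUE),
                 composition_compartment =
                   comp_frac(m$provenance$compartment),
                 composition_age = comp_frac(m$provenance$age)),
            class = "module_partition")
}

#' Edge-set Jaccard similarity between networks
#'
#' `J(A, B) = |E_A intersect E_B| / |E_A union E_B|` on unordered node-pair
#' identity (sign ignored).  An empty network has similarity 0 to every
#' other, with a warning.  Pairs above the display threshold form the
#' similarity graph.
#'
#' @param networks named list of [build_network()] results.
#' @param display_threshold edges of the similarity graph keep `J >` this
#'   value (default 0.02, strict).
#' @return list with `J` (matrix) and `similarity_edges` (data.frame net_a,
#'   net_b, jaccard for pairs above the threshold).
#' @export
edge_jaccard <- function(networks, display_threshold = 0.02) {
  if (length(networks) < 2) stop("need at least two networks")
  if (is.null(names(networks)))
    names(networks) <- paste0("net", seq_along(networks))
  sets <- lapply(networks, function(n)
    unique(edge_key(n$edges$otu_a, n$edges$otu_b)))
  if (any(lengths(sets) == 0)) warning("empty network(s): J defined as 0")
  k <- length(sets)
  J <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  diag(J) <- ifelse(lengths(sets) > 0, 1, 0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    u <- length(union(sets[[i]], sets[[j]]))
    J[i, j] <- J[j, i] <- if (u == 0) 0 else
      length(intersect(sets[[i]], sets[[j]])) / u
  }
  idx <- which(upper.tri(J) & J > display_threshold, arr.ind = TRUE)
  structure(list(J = J,
                 similarity_edges = data.frame(
                   net_a = rownames(J)[idx[, 1]],
                   net_b = colnames(J)[idx[, 2]],
                   jaccard = J[idx], stringsAsFactors = FALSE)),
            class = "edge_jaccard")
}

node_labels <- function(n, tax, level) {
  if (!level %in% c("class", "order")) stop("level must be class or order")
  lab <- as.character(tax[[level]][match(n$nodes$otu_id, tax$otu_id)])
  kg <- as.character(tax$kingdom[match(n$nodes$otu_id, tax$otu_id)])
  lab[is.na(lab) | lab == ""] <- "unclassified"
  pref <- ifelse(is.na(kg), "U", ifelse(kg == "Bacteria", "B", "F"))
  setNames(paste(pref, lab, sep = "_"), n$nodes$otu_id)
}

#' Hypergeometric over-representation of label-pair associations
#'
#' For every unordered pair of taxonomic labels (A, B) at the chosen rank:
#' the population is all edges of the graph, draws are the edges touching A
#' (at least one endpoint), successes are the edges touching B, and the
#' observed count k is the edges joining A and B; the upper-tail
#' hypergeometric probability P(X >= k) is BH-adjusted across all tested
#' pairs.  A pair is flagged over-represented when q < 0.05 and k exceeds its
#' expectation.
#'
#' @param n [build_network()] or [merge_meta()] result.
#' @param tax [taxonomy_table()]; labels are prefixed `B_`/`F_` by kingdom,
#'   missing labels binned as `unclassified`.
#' @param level `"class"` or `"order"`.
#' @return data.frame of class `enrichment_result`: class_a, class_b, k,
#'   n_draws, n_successes, n_edges, expected, p, q, flag.
#' @export
class_enrichment <- function(n, tax, level = c("class", "order")) {
  level <- match.arg(level)
  lab <- node_labels(n, tax, level)
  ea <- lab[n$edges$otu_a]; eb <- lab[n$edges$otu_b]
  ne <- length(ea)
  labels <- sort(unique(c(ea, eb)))
  touch <- vapply(labels, function(L) ea == L | eb == L,
                  logical(ne))
  pairs <- cbind(rep(seq_along(labels), times = seq_along(labels)),
                 unlist(lapply(seq_along(labels), seq_len)))
  res <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 2]; j <- pairs[r, 1]          # i <= j
    A <- labels[i]; B <- labels[j]
    k <- if (A == B) sum(ea == A & eb == A) else
      sum((ea == A & eb == B) | (ea == B & eb == A))
    nd <- sum(touch[, i]); ns <- sum(touch[, j])
    data.frame(class_a = A, class_b = B, k = k, n_draws = nd,
               n_successes = ns, n_edges = ne,
               expected = nd * ns / ne,
               p = phyper(k - 1, ns, ne - ns, nd, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, "BH")
  res$flag <- ifelse(res$q < 0.05 & res$k > res$expected,
                     "overrepresented", "random")
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Binomial sign-bias (co-occurrence vs co-exclusion) per label pair
#'
#' For each pair of taxonomic labels, the number of positive edges among the
#' pair's edges is tested against Binomial(n, pi0) with pi0 the global
#' positive-edge fraction; the two-sided p-value is
#' `min(1, 2 min(P(X <= k), P(X >= k)))`, BH-adjusted across pairs.
#'
#' @param n [build_network()] result (needs edge signs).
#' @param tax [taxonomy_table()].
#' @param level `"class"` or `"order"`.
#' @return data.frame: class_a, class_b, n_pos, n_total, pi0, p, q,
#'   direction (cooccurrence/coexclusion/none).
#' @export
binomial_cooccurrence <- function(n, tax, level = c("class", "order")) {
  level <- match.arg(level)
  lab <- node_labels(n, tax, level)
  ea <- lab[n$edges$otu_a]; eb <- lab[n$edges$otu_b]
  pos <- n$edges$sign == "pos"
  pi0 <- mean(pos)
  key <- edge_key(ea, eb)
  sp <- split(pos, key)
  res <- do.call(rbind, lapply(names(sp), function(k2) {
    v <- sp[[k2]]
    np <- sum(v); nt <- length(v)
    p_lo <- pbinom(np, nt, pi0)
    p_hi <- pbinom(np - 1, nt, pi0, lower.tail = FALSE)
    ab <- strsplit(k2, "|", fixed = TRUE)[[1]]
    data.frame(class_a = ab[1], class_b = ab[2], n_pos = np, n_total = nt,
               pi0 = pi0, p = min(1, 2 * min(p_lo, p_hi)),
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, "BH")
  res$direction <- ifelse(res$q >= 0.05, "none",
                          ifelse(res$n_pos / res$n_total > pi0,
                                 "cooccurrence", "coexclusion"))
  rownames(res) <- NULL
  res
}

#' Write a network as an edge-list TSV and GraphML
#'
#' @param n [build_network()] or [merge_meta()] result.
#' @param path_tsv,path_graphml output paths (either may be NULL to skip).
#' @export
write_network <- function(n, path_tsv = NULL, path_graphml = NULL) {
  if (!is.null(path_tsv)) write_tsv(n$edges, path_tsv)
  if (!is.null(path_graphml)) {
    g <- igraph::graph_from_data_frame(n$edges, directed = FALSE,
                                       vertices = n$nodes)
    igraph::write_graph(g, path_graphml, format = "graphml")
  }
  invisible(n)
}
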