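#' Build the contact network of a cell configuration
#'
#' Two cells are linked when their center distance is at most `threshold`
#' (inclusive; default one cell diameter).  Cells with no contact are not
#' part of the network: they are excluded from the node set and from every
#' degree denominator, but their count is reported.
#'
#' @param config a [cell_config()].
#' @param threshold link distance (default 1).
#' @return An object of class `contact_network`: `node_ids` (cell ids of
#'   the non-isolated cells), `adj` (adjacency list of indices into
#'   `node_ids`), `degrees`, `edges` (two-column index matrix, i < j),
#'   `n_nodes`, `n_links`, `n_isolated` and `threshold`.
#' @export
contact_network <- function(config, threshold = 1.0) {
  stopifnot(inherits(config, "cell_config"), threshold > 0)
  n_all <- nrow(config$pos)
  pr <- contact_pairs_cpp(config$pos[, 1], config$pos[, 2], threshold)
  deg_all <- tabulate(c(pr[, 1], pr[, 2]), nbins = n_all)
  keep <- which(deg_all > 0)
  remap <- integer(n_all)
  remap[keep] <- seq_along(keep)
  edges <- cbind(remap[pr[, 1]], remap[pr[, 2]])
  if (nrow(edges) > 0)
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  n <- length(keep)
  adj <- vector("list", n)
  if (n > 0) {
    adj_src <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
    adj <- rep(list(integer(0)), n)
    idx <- as.integer(names(adj_src))
    for (k in seq_along(adj_src)) adj[[idx[k]]] <- sort(adj_src[[k]])
  }
  structure(list(node_ids = config$ids[keep],
                 adj = adj,
                 degrees = deg_all[keep],
                 edges = edges,
                 n_nodes = n,
                 n_links = nrow(edges),
                 n_isolated = n_all - n,
                 threshold = threshold),
            class = "contact_network")
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf(
    "Contact network: %d nodes, %d links, %d isolated cells (threshold %g)\n",
    x$n_nodes, x$n_links, x$n_isolated, x$threshold))
  if (x$n_nodes > 0)
    cat(sprintf("  mean degree %.4f, max degree %d\n",
                mean(x$degrees), max(x$degrees)))
  invisible(x)
}

stop_if_empty <- function(net) {
  if (net$n_nodes == 0)
    stop("empty contact network: measure undefined")
}

#' Degree distribution P_k
#'
#' Fraction of network nodes with each degree k, for k = 1 up to the
#' observed maximum.  Isolated cells are not network nodes, so the support
#' starts at 1 and the fractions sum to one.
#'
#' @param net a [contact_network()].
#' @return Named numeric vector `P_k`, names are the degrees.
#' @export
degree_distribution <- function(net) {
  stop_if_empty(net)
  k_max <- max(net$degrees)
  pk <- tabulate(net$degrees, nbins = k_max) / net$n_nodes
  names(pk) <- seq_len(k_max)
  pk
}

#' Average degree of the contact network
#'
#' Mean node degree; equals both `sum(k * P_k)` and `2 L / N` by the
#' handshake identity.
#'
#' @param net a [contact_network()].
#' @return Scalar mean degree.
#' @export
average_degree <- function(net) {
  stop_if_empty(net)
  mean(net$degrees)
}

#' Average nearest-neighbor degree K_nn
#'
#' Mean over nodes of the average degree of their neighbors; a
#' degree-correlation (homogeneity) measure.
#'
#' @param net a [contact_network()].
#' @return Scalar K_nn.
#' @export
nearest_neighbor_degree <- function(net) {
  stop_if_empty(net)
  mean(vapply(seq_len(net$n_nodes),
              function(i) mean(net$degrees[net$adj[[i]]]),
              numeric(1)))
}

# number of links among the neighbors of node i
links_among_neighbors <- function(net, i) {
  nb <- net$adj[[i]]
  if (length(nb) < 2) return(0L)
  l <- 0L
  for (a in seq_len(length(nb) - 1)) {
    rest <- nb[(a + 1):length(nb)]
    l <- l + sum(rest %in% net$adj[[nb[a]]])
  }
  l
}

#' Transitivity (global clustering coefficient)
#'
#' Three times the number of distinct triangles over the number of
#' connected triples (`sum(k_i * (k_i - 1) / 2)`).  Equals 1 for a complete
#' triangle, 0 for any triangle-free graph, and 0 by convention when no
#' connected triple exists.
#'
#' @param net a [contact_network()].
#' @return Scalar in \[0, 1\].
#' @export
transitivity <- function(net) {
  stop_if_empty(net)
  triples <- sum(net$degrees * (net$degrees - 1)) / 2
  if (triples == 0) return(0)
  closed <- sum(vapply(seq_len(net$n_nodes),
                       function(i) links_among_neighbors(net, i),
                       integer(1)))   # = 3 * number of triangles
  closed / triples
}

#' Local clustering coefficients
#'
#' For each node, `C_i = 2 L_i / (k_i (k_i - 1))` where `L_i` counts links
#' among the node's neighbors; degree-1 nodes get `C_i = 0` by convention.
#'
#' @param net a [contact_network()].
#' @return List with per-node `C` (in `node_ids` order) and the network
#'   mean `mean_C`.
#' @export
clustering <- function(net) {
  stop_if_empty(net)
  C <- vapply(seq_len(net$n_nodes), function(i) {
    k <- net$degrees[i]
    if (k < 2) return(0)
    2 * links_among_neighbors(net, i) / (k * (k - 1))
  }, numeric(1))
  list(C = C, mean_C = mean(C))
}

#' Connected components by breadth-first search
#'
#' Labels every node by component using an explicit breadth-first
#' traversal and returns the component sizes.
#'
#' @param net a [contact_network()].
#' @return List with `labels` (integer component label per node, in
#'   `node_ids` order), `sizes` (component sizes), `n_components` and
#'   `s_max` (largest component size).
#' @export
connected_components <- function(net) {
  n <- net$n_nodes
  if (n == 0)
    return(list(labels = integer(0), sizes = integer(0),
                n_components = 0L, s_max = 0L))
  labels <- integer(n)
  comp <- 0L
  queue <- integer(n)
  for (start in seq_len(n)) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    labels[start] <- comp
    queue[1] <- start
    head_ <- 1L; tail_ <- 1L
    while (head_ <= tail_) {
      v <- queue[head_]; head_ <- head_ + 1L
      for (w in net$adj[[v]]) {
        if (labels[w] == 0L) {
          labels[w] <- comp
          tail_ <- tail_ + 1L
          queue[tail_] <- w
        }
      }
    }
  }
  sizes <- tabulate(labels, nbins = comp)
  list(labels = labels, sizes = sizes, n_components = comp,
       s_max = max(sizes))
}

#' Network summary of a contact network
#'
#' Computes every scalar and distributional measure in one pass: node and
#' link counts, degree distribution, mean degree, average nearest-neighbor
#' degree, transitivity, mean clustering, component structure and the
#' components-per-node ratio `rho_c = N_c / N` (a fragmentation proxy:
#' detached components can migrate independently).
#'
#' @param object a [contact_network()].
#' @param ... ignored.
#' @return An object of class `network_summary`.
#' @export
summary.contact_network <- function(object, ...) {
  stop_if_empty(object)
  pk <- degree_distribution(object)
  cl <- clustering(object)
  cc <- connected_components(object)
  structure(list(
    n_nodes = object$n_nodes,
    n_links = object$n_links,
    n_isolated = object$n_isolated,
    degree_dist = pk,
    mean_degree = average_degree(object),
    knn = nearest_neighbor_degree(object),
    transitivity = transitivity(object),
    mean_clustering = cl$mean_C,
    n_components = cc$n_components,
    component_sizes = cc$sizes,
    s_max = cc$s_max,
    rho_c = cc$n_components / object$n_nodes),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network summary: N = %d, L = %d (+%d isolated cells)\n",
              x$n_nodes, x$n_links, x$n_isolated))
  cat(sprintf("  <k> = %.4f, K_nn = %.4f, T = %.4f, <C> = %.4f\n",
              x$mean_degree, x$knn, x$transitivity, x$mean_clustering))
  cat(sprintf("  components: N_c = %d, S_max = %d, rho_c = %.4f\n",
              x$n_components, x$s_max, x$rho_c))
  invisible(x)
}

#' @export
as.data.frame.network_summary <- function(x, ...) {
  pk <- x$degree_dist
  p_of <- function(k) if (k <= length(pk)) unname(pk[k]) else 0
  data.frame(n_nodes = x$n_nodes, n_links = x$n_links,
             n_isolated = x$n_isolated,
             p1 = p_of(1), p2 = p_of(2), p6 = p_of(6),
             mean_degree = x$mean_degree, knn = x$knn,
             transitivity = x$transitivity,
             mean_clustering = x$mean_clustering,
             n_components = x$n_components, s_max = x$s_max,
             rho_c = x$rho_c)
}
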