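# K-nearest-neighbour nucleus graphs and degree-scaled multi-aggregator
# message passing.
#
# Edges connect a nucleus to its K nearest neighbours that lie strictly
# closer than a distance cutoff; the directed relation is symmetrised by
# union (or intersection).  Message passing aggregates neighbour messages
# with four statistics (mean, sd, max, min) under three degree scalings
# (identity, amplify, attenuate), concatenated in that order, and ends in
# a graph-level class head after global mean pooling.

#' Build the K-NN nucleus graph
#'
#' For every node, the K nearest other nodes by Euclidean distance are
#' selected among those strictly closer than `dmin`; ties at the K-th
#' distance are broken by lower node index.  The directed selection is
#' then symmetrised.
#'
#' @param centroids n x 2 matrix of (x, y) positions in pixels
#' @param features optional n x f node feature matrix (the 16 handcrafted
#'   features, typically z-scored)
#' @param K neighbours per node (default 5)
#' @param dmin distance cutoff in pixels (default 50)
#' @param symmetrize `"union"` (edge if either endpoint selects the
#'   other; default) or `"intersection"`
#' @return object of class `nuclei_graph`: `positions`, `features`,
#'   `edges` (m x 2, i < j), `adj` (neighbour index list), `degrees`,
#'   `out_nbrs` (the directed selection, for inspection), `K`, `dmin`
#' @export
build_knn_graph <- function(centroids, features = NULL, K = 5L,
                            dmin = 50, symmetrize = c("union",
                                                      "intersection")) {
  symmetrize <- match.arg(symmetrize)
  centroids <- as.matrix(centroids)
  n <- nrow(centroids)
  stopifnot(n >= 1L, K >= 1L, dmin > 0)
  if (!is.null(features)) {
    features <- as.matrix(features)
    stopifnot(nrow(features) == n)
  }
  out_nbrs <- vector("list", n)
  if (n > 1L) {
    D <- as.matrix(stats::dist(centroids))
    for (i in seq_len(n)) {
      cand <- setdiff(which(D[i, ] < dmin), i)
      if (length(cand)) {
        ord <- cand[order(D[i, cand], cand)]
        out_nbrs[[i]] <- ord[seq_len(min(K, length(ord)))]
      } else out_nbrs[[i]] <- integer(0)
    }
  } else out_nbrs[[1L]] <- integer(0)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    fwd <- out_nbrs[[i]]
    bwd <- which(vapply(out_nbrs, function(v) i %in% v, logical(1L)))
    adj[[i]] <- if (symmetrize == "union") sort(union(fwd, bwd))
                else sort(intersect(fwd, bwd))
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    js <- adj[[i]][adj[[i]] > i]
    if (length(js)) cbind(i = i, j = js) else NULL
  }))
  if (is.null(edges)) edges <- matrix(integer(0), 0L, 2L,
                                      dimnames = list(NULL, c("i", "j")))
  structure(list(positions = centroids, features = features,
                 edges = edges, adj = adj,
                 degrees = lengths(adj), out_nbrs = out_nbrs,
                 K = as.integer(K), dmin = dmin,
                 symmetrize = symmetrize),
            class = "nuclei_graph")
}

#' @export
print.nuclei_graph <- function(x, ...) {
  cat(sprintf("<nuclei_graph> %d nodes, %d undirected edges (K = %d, dmin = %g)\n",
              nrow(x$positions), nrow(x$edges), x$K, x$dmin))
  invisible(x)
}

#' Fit the degree normaliser over training graphs
#'
#' The normaliser is the mean of `log(degree + 1)` over every node of the
#' training graphs; it is computed once from the training split and then
#' frozen into the model.
#'
#' @param graphs list of [build_knn_graph()] objects
#' @return the scalar normaliser (> 0)
#' @export
fit_degree_normalizer <- function(graphs) {
  degs <- unlist(lapply(graphs, function(g) g$degrees))
  if (!length(degs)) stop("no nodes in training graphs")
  delta <- mean(log(degs + 1))
  if (delta <= 0)
    stop("training graphs have no edges; degree normaliser undefined")
  delta
}

#' Degree scaling factors
#'
#' `(log(d + 1) / delta)^alpha` per node; `alpha = 0` is the identity,
#' `+1` amplifies high-degree nodes, `-1` attenuates them.  Nodes of
#' degree 0 get factor 0 for `alpha != 0` (their aggregated message is
#' zeroed anyway) and 1 for `alpha = 0`.
#'
#' @param degrees integer vector of node degrees
#' @param delta normaliser from [fit_degree_normalizer()]
#' @param alpha -1, 0 or +1
#' @return numeric vector of per-node factors
#' @export
degree_scaler <- function(degrees, delta, alpha) {
  stopifnot(alpha %in% c(-1, 0, 1), delta > 0)
  if (alpha == 0) return(rep(1, length(degrees)))
  base <- log(degrees + 1) / delta
  ifelse(degrees > 0, base^alpha, 0)
}

# tape-level multi-aggregator: 12 blocks in fixed order
# [identity, amplify, attenuate] x [mean, sd, max, min]; isolated nodes
# contribute an all-zero row.
ad_aggregate <- function(msg, adj, degrees, delta) {
  mask <- as.numeric(degrees > 0)
  gm <- ad_group_mean(msg, adj)
  gm2 <- ad_group_mean(ad_square(msg), adj)
  gsd <- ad_sqrt0(ad_sub(gm2, ad_square(gm)))
  gmax <- ad_group_extreme(msg, adj, "max")
  gmin <- ad_group_extreme(msg, adj, "min")
  stats <- list(gm, gsd, gmax, gmin)
  blocks <- list()
  for (alpha in c(0, 1, -1)) {
    s <- degree_scaler(degrees, delta, alpha) * mask
    for (st in stats)
      blocks[[length(blocks) + 1L]] <- ad_rowscale(st, s)
  }
  ad_cbind(blocks)
}

#' Degree-scaled neighbourhood aggregation of node features
#'
#' For each node, the mean, standard deviation, maximum and minimum of
#' its neighbours' feature vectors are computed and each statistic is
#' repeated under the identity, amplifying and attenuating degree
#' scalers, giving a `r x 12 f` matrix with blocks ordered
#' `[identity, amplify, attenuate] x [mean, sd, max, min]`.  Isolated
#' nodes yield all-zero rows.
#'
#' @param graph a [build_knn_graph()] object
#' @param node_features r x f matrix (defaults to the graph's features)
#' @param delta degree normaliser
#' @return numeric `r x 12 f` matrix
#' @export
aggregate_neighbors <- function(graph, node_features = graph$features,
                                delta) {
  stopifnot(!is.null(node_features))
  tape <- ad_tape()
  x <- ad_leaf(tape, as.matrix(node_features))
  ad_aggregate(x, graph$adj, graph$degrees, delta)$val
}

#' Initialise message-passing network parameters
#'
#' Two linear maps per layer (message and update, ReLU nonlinearity), a
#' linear class head on the mean-pooled graph embedding, and a learned
#' null embedding used for empty graphs.
#'
#' @param in_dim node feature width (16)
#' @param hidden hidden width per layer
#' @param layers number of message-passing layers
#' @param classes number of classes
#' @param seed RNG seed for the initialisation
#' @return named list of parameter matrices
#' @export
gnn_init <- function(in_dim = 16L, hidden = 64L, layers = 2L,
                     classes = 2L, seed = 1L) {
  with_seed(seed, {
    pars <- list()
    d <- in_dim
    for (l in seq_len(layers)) {
      pars[[paste0("Wm", l)]] <- matrix(
        stats::rnorm(d * hidden, 0, sqrt(2 / (d + hidden))), d, hidden)
      pars[[paste0("bm", l)]] <- matrix(0, 1L, hidden)
      ud <- d + 12L * hidden
      pars[[paste0("Wu", l)]] <- matrix(
        stats::rnorm(ud * hidden, 0, sqrt(2 / (ud + hidden))), ud, hidden)
      pars[[paste0("bu", l)]] <- matrix(0, 1L, hidden)
      d <- hidden
    }
    pars$Whead <- matrix(stats::rnorm(hidden * classes, 0,
                                      sqrt(2 / (hidden + classes))),
                         hidden, classes)
    pars$bhead <- matrix(0, 1L, classes)
    pars$null_embed <- matrix(0, 1L, hidden)
    attr(pars, "layers") <- layers
    attr(pars, "hidden") <- hidden
    attr(pars, "in_dim") <- in_dim
    pars
  })
}

# tape forward of the message-passing network for one graph; `pn` is the
# named list of parameter leaf nodes
ad_gnn_forward <- function(tape, pn, graph, features, delta, layers) {
  r <- if (is.null(features)) 0L else nrow(features)
  if (r == 0L) {
    pooled <- pn$null_embed
    logits <- ad_add(ad_matmul(pooled, pn$Whead), pn$bhead)
    return(list(embeddings = NULL, logits = logits, empty = TRUE))
  }
  h <- ad_leaf(tape, as.matrix(features))
  for (l in seq_len(layers)) {
    msg <- ad_relu(ad_add(ad_matmul(h, pn[[paste0("Wm", l)]]),
                          pn[[paste0("bm", l)]]))
    agg <- ad_aggregate(msg, graph$adj, graph$degrees, delta)
    u_in <- ad_cbind(list(h, agg))
    h <- ad_relu(ad_add(ad_matmul(u_in, pn[[paste0("Wu", l)]]),
                        pn[[paste0("bu", l)]]))
  }
  pooled <- ad_mean_rows(h)
  logits <- ad_add(ad_matmul(pooled, pn$Whead), pn$bhead)
  list(embeddings = h, logits = logits, empty = FALSE)
}

#' Forward pass of the nuclei-level classifier on one graph
#'
#' Node features are message-passed for the configured number of layers,
#' mean-pooled, and mapped to class logits.  An empty graph (no nuclei)
#' is represented by the learned null embedding and flagged.
#'
#' @param graph a [build_knn_graph()] with features attached
#' @param params parameters from [gnn_init()]
#' @param delta degree normaliser
#' @return list with `node_embeddings` (r x hidden), `logits` (1 x 2)
#'   and `empty`
#' @export
nuclei_forward <- function(graph, params, delta) {
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_leaf(tape, p))
  fw <- ad_gnn_forward(tape, pn, graph, graph$features, delta,
                       attr(params, "layers") %||% 2L)
  list(node_embeddings = if (is.null(fw$embeddings)) NULL
                         else fw$embeddings$val,
       logits = fw$logits$val, empty = fw$empty)
}

#' Serialise a nuclei graph to JSON
#' @param graph a [build_knn_graph()] object
#' @param path output file
#' @export
graph_to_json <- function(graph, path) {
  obj <- list(
    K = graph$K, dmin = graph$dmin, symmetrize = graph$symmetrize,
    nodes = data.frame(x = graph$positions[, 1L],
                       y = graph$positions[, 2L]),
    features = if (is.null(graph$features)) NULL
               else as.data.frame(graph$features),
    edges = as.data.frame(graph$edges))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read a nuclei graph from JSON
#' @param path file written by [graph_to_json()]
#' @return a `nuclei_graph` (rebuilt from positions with stored K/dmin)
#' @export
graph_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_knn_graph(cbind(obj$nodes$x, obj$nodes$y),
                  features = if (!is.null(obj$features))
                    as.matrix(obj$features) else NULL,
                  K = obj$K, dmin = obj$dmin,
                  symmetrize = obj$symmetrize)
}
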