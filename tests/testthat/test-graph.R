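test_that("edge construction follows the K-NN-within-cutoff rule", {
  # 3 collinear points 10 px apart: complete graph
  g <- build_knn_graph(cbind(c(0, 10, 20), c(0, 0, 0)), K = 5, dmin = 50)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(unname(g$degrees), c(2L, 2L, 2L))

  # two points beyond the cutoff stay disconnected
  g2 <- build_knn_graph(cbind(c(0, 60), c(0, 0)), K = 5, dmin = 50)
  expect_equal(nrow(g2$edges), 0L)
  expect_equal(unname(g2$degrees), c(0L, 0L))

  # single node: valid isolated graph
  g3 <- build_knn_graph(cbind(5, 5))
  expect_equal(nrow(g3$edges), 0L)
})

test_that("the graph matches the brute-force all-pairs oracle", {
  set.seed(41)
  for (k in 1:20) {
    n <- sample(5:60, 1)
    pts <- cbind(stats::runif(n, 0, 150), stats::runif(n, 0, 150))
    K <- sample(1:6, 1)
    g <- build_knn_graph(pts, K = K, dmin = 50)
    want <- oracle_knn(pts, K, 50)
    # directed selection: at most K members, all within the cutoff
    for (i in seq_len(n)) {
      expect_identical(sort(g$out_nbrs[[i]]), sort(want[[i]]))
      expect_lte(length(g$out_nbrs[[i]]), K)
    }
    # union symmetrisation and degree bookkeeping
    for (i in seq_len(n)) {
      nb <- sort(unique(c(want[[i]],
                          which(vapply(want, function(v) i %in% v,
                                       logical(1))))))
      expect_identical(g$adj[[i]], nb)
    }
    expect_identical(unname(g$degrees), lengths(g$adj))
    # edge list symmetric and consistent with adjacency
    if (nrow(g$edges)) {
      expect_true(all(g$edges[, 1] < g$edges[, 2]))
      expect_equal(2L * nrow(g$edges), sum(g$degrees))
    }
  }
  # intersection symmetrisation is a subgraph of the union
  set.seed(42)
  pts <- cbind(stats::runif(40, 0, 100), stats::runif(40, 0, 100))
  gu <- build_knn_graph(pts, K = 3, dmin = 50)
  gi <- build_knn_graph(pts, K = 3, dmin = 50,
                        symmetrize = "intersection")
  expect_true(all(gi$degrees <= gu$degrees))
})

test_that("the degree normaliser is a node-weighted mean of log(d + 1)", {
  g <- build_knn_graph(cbind(c(0, 10, 20), c(0, 0, 0)), K = 5, dmin = 50)
  expect_equal(fit_degree_normalizer(list(g)), log(3))  # all degree 2
  # disjoint union: node-weighted mean across graphs
  g2 <- build_knn_graph(cbind(c(0, 10), c(0, 0)), K = 5, dmin = 50)
  expect_equal(fit_degree_normalizer(list(g, g2)),
               (3 * log(3) + 2 * log(2)) / 5)
  expect_equal(fit_degree_normalizer(list(g, g2)),
               mean(log(c(g$degrees, g2$degrees) + 1)))
  # graphs with no edges cannot normalise
  iso <- build_knn_graph(cbind(c(0, 60), c(0, 0)), K = 5, dmin = 50)
  expect_error(fit_degree_normalizer(list(iso)), "no edges")
})

test_that("degree scalers invert each other on connected nodes", {
  degs <- c(0L, 1L, 3L, 5L, 9L)
  delta <- mean(log(degs + 1))
  expect_equal(degree_scaler(degs, delta, 0), rep(1, 5))
  prod <- degree_scaler(degs, delta, 1) * degree_scaler(degs, delta, -1)
  expect_equal(prod[degs > 0], rep(1, 4))
  expect_equal(prod[degs == 0], 0)  # isolated nodes are masked
})

test_that("neighbourhood aggregation matches per-node statistics", {
  # star graph: centre 1 connected to 4 leaves
  pts <- cbind(c(0, 10, -10, 0, 0), c(0, 0, 0, 10, -10))
  feats <- matrix(c(1, 2, 4, 6, 8,
                    0, 1, 1, 2, 3), 5, 2)
  g <- build_knn_graph(pts, feats, K = 4, dmin = 12)  # leaf-leaf = 14.1 excluded
  delta <- fit_degree_normalizer(list(g))
  agg <- aggregate_neighbors(g, delta = delta)
  expect_equal(dim(agg), c(5L, 24L))
  # identity-scaled block of the centre node: stats over the 4 leaves
  leaves <- feats[2:5, ]
  popsd <- function(v) sqrt(mean(v^2) - mean(v)^2)
  expect_equal(agg[1, 1:2], colMeans(leaves))
  expect_equal(agg[1, 3:4], apply(leaves, 2, popsd))
  expect_equal(agg[1, 5:6], apply(leaves, 2, max))
  expect_equal(agg[1, 7:8], apply(leaves, 2, min))
  # every leaf sees only the centre: mean = max = min, sd = 0
  expect_equal(agg[2, 1:2], feats[1, ])
  expect_equal(agg[2, 3:4], c(0, 0))
  expect_equal(agg[2, 5:8], rep(feats[1, ], 2))
  # amplifying block = identity block times the centre scaler
  s1 <- degree_scaler(g$degrees, delta, 1)
  expect_equal(agg[, 9:16], agg[, 1:8] * s1)
})

test_that("the nuclei head is permutation invariant and trainable", {
  set.seed(43)
  pts <- cbind(stats::runif(20, 0, 80), stats::runif(20, 0, 80))
  feats <- matrix(stats::rnorm(20 * 16), 20, 16)
  g <- build_knn_graph(pts, feats, K = 5, dmin = 50)
  delta <- fit_degree_normalizer(list(g))
  pars <- gnn_init(16L, 16L, 2L, seed = 44)
  out <- nuclei_forward(g, pars, delta)
  expect_equal(dim(out$logits), c(1L, 2L))
  expect_false(out$empty)
  pm <- sample(20)
  g2 <- build_knn_graph(pts[pm, ], feats[pm, ], K = 5, dmin = 50)
  out2 <- nuclei_forward(g2, pars, delta)
  expect_equal(out$logits, out2$logits, tolerance = 1e-12)

  # one gradient step on a 2-graph toy problem reduces the loss
  g0 <- build_knn_graph(pts, feats - 1, K = 5, dmin = 50)
  graphs <- list(g0, g)
  labels <- c(0L, 1L)
  loss_of <- function(p) {
    mean(vapply(1:2, function(i) {
      lg <- nuclei_forward(graphs[[i]], p, delta)$logits
      pr <- exp(lg - max(lg)); pr <- pr / sum(pr)
      slide_ce(as.vector(pr), c(1 - labels[i], labels[i]))
    }, numeric(1)))
  }
  before <- loss_of(pars)
  opt <- nucmil:::adam_state(pars)
  for (step in 1:5) {
    grads <- pars
    for (nm in names(grads)) grads[[nm]][] <- 0
    for (i in 1:2) {
      tape <- nucmil:::ad_tape()
      pn <- lapply(pars, function(p) nucmil:::ad_leaf(tape, p))
      fw <- nucmil:::ad_gnn_forward(tape, pn, graphs[[i]],
                                    graphs[[i]]$features, delta, 2L)
      l <- nucmil:::ad_ce_from_logits(fw$logits,
                                      c(1 - labels[i], labels[i]))
      nucmil:::ad_backward(l)
      for (nm in names(pn))
        if (!is.null(pn[[nm]]$grad))
          grads[[nm]] <- grads[[nm]] + pn[[nm]]$grad / 2
    }
    up <- nucmil:::adam_step(pars, grads, opt, lr = 5e-3)
    pars <- up$params; opt <- up$state
  }
  expect_lt(loss_of(pars), before)
})

test_that("graphs survive a JSON round trip", {
  set.seed(45)
  pts <- cbind(stats::runif(12, 0, 60), stats::runif(12, 0, 60))
  feats <- matrix(stats::rnorm(12 * 16), 12, 16)
  g <- build_knn_graph(pts, feats, K = 4, dmin = 40)
  path <- withr::local_tempfile(fileext = ".json")
  graph_to_json(g, path)
  g2 <- graph_from_json(path)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$positions[, 1], g$positions[, 1])
  expect_equal(unname(as.matrix(g2$features)), unname(g$features),
               tolerance = 1e-12)
})
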