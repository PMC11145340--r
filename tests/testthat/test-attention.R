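test_that("attention scores form a proper weighting of the bag", {
  set.seed(51)
  pars <- mil_init(feat_dim = 32L, heads = 2L, dk = 8L, seed = 52)

  # singleton bag: softmax of one element
  b1 <- patch_bag(matrix(stats::rnorm(32), 1, 32))
  expect_equal(attention_scores(b1, pars), 1)

  # identical patches: uniform weights by symmetry
  X <- matrix(rep(stats::rnorm(32), each = 6), 6, 32)
  su <- attention_scores(patch_bag(X), pars)
  expect_equal(su, rep(1 / 6, 6), tolerance = 1e-12)

  # generic bag: positive, normalised, permutation-equivariant
  Xr <- matrix(stats::rnorm(7 * 32), 7, 32)
  s <- attention_scores(patch_bag(Xr), pars)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_true(all(s > 0))
  pm <- sample(7)
  expect_equal(attention_scores(patch_bag(Xr[pm, ]), pars), s[pm],
               tolerance = 1e-12)

  # the plain gated variant obeys the same contract
  pg <- mil_init(feat_dim = 32L, variant = "gated_plain", seed = 53)
  sg <- attention_scores(patch_bag(Xr), pg)
  expect_equal(sum(sg), 1, tolerance = 1e-12)
  expect_true(all(sg > 0))

  expect_error(patch_bag(matrix(c(1, NA), 1, 2)), "non-finite")
})

test_that("softmax weighting is shift invariant", {
  z <- c(0.3, -1, 2, 0.7)
  sm <- function(v) exp(v - max(v)) / sum(exp(v - max(v)))
  expect_equal(sm(z), sm(z + 5), tolerance = 1e-12)
  # and the tape op agrees with the closed form
  tape <- nucmil:::ad_tape()
  node <- nucmil:::ad_softmax_rows(nucmil:::ad_leaf(tape, matrix(z, 1)))
  expect_equal(as.vector(node$val), sm(z), tolerance = 1e-12)
})

test_that("pooling is the exact convex combination of the bag", {
  set.seed(54)
  X <- matrix(stats::rnorm(5 * 4), 5, 4)
  bag <- patch_bag(X)

  onehot <- c(0, 0, 1, 0, 0)
  expect_equal(pool_slide(bag, onehot)$f_slide, X[3, ])

  expect_equal(pool_slide(bag, rep(1 / 5, 5))$f_slide, colMeans(X))

  s <- c(0.1, 0.25, 0.3, 0.2, 0.15)
  want <- colSums(X * s)  # direct arithmetic
  got <- pool_slide(bag, s)$f_slide
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got >= apply(X, 2, min) - 1e-12 &
                  got <= apply(X, 2, max) + 1e-12))

  expect_error(pool_slide(bag, c(0.5, 0.5)), "length")
  expect_error(pool_slide(bag, rep(0.5, 5)), "sum")
})

test_that("top-c selection is deterministic and matches a full sort", {
  expect_equal(select_top_c(c(0.1, 0.5, 0.4), 2), c(2L, 3L))
  expect_equal(sort(select_top_c(stats::runif(5), 8)), 1:5)
  # ties break toward the lower index
  expect_equal(select_top_c(c(0.4, 0.4, 0.2), 1), 1L)
  set.seed(55)
  for (k in 1:100) {
    s <- stats::runif(sample(3:40, 1))
    c_sel <- sample(1:10, 1)
    want <- order(-s, seq_along(s))[seq_len(min(c_sel, length(s)))]
    expect_identical(select_top_c(s, c_sel), want)
  }
})

test_that("the class heads behave as linear classifiers", {
  set.seed(56)
  pars <- mil_init(feat_dim = 8L, heads = 2L, dk = 4L, seed = 57)
  X <- matrix(stats::rnorm(4 * 8), 4, 8)
  lg <- patch_head(X, pars)
  expect_equal(dim(lg), c(4L, 2L))
  expect_identical(lg, patch_head(X, pars))  # deterministic

  # a linearly separable toy set is fit to 100% training accuracy
  y <- rep(c(0L, 1L), each = 10)
  Xs <- matrix(stats::rnorm(20 * 8, mean = rep((2 * y - 1) * 3, 8)), 20, 8)
  p <- pars
  opt <- nucmil:::adam_state(p["Wpatch"])
  for (it in 1:200) {
    tape <- nucmil:::ad_tape()
    W <- nucmil:::ad_leaf(tape, p$Wpatch)
    logits <- nucmil:::ad_matmul(nucmil:::ad_leaf(tape, Xs), W)
    l <- nucmil:::ad_mean_rowloss(logits, y, nucmil:::ad_ce_from_logits)
    nucmil:::ad_backward(l)
    up <- nucmil:::adam_step(p["Wpatch"], list(Wpatch = W$grad), opt,
                             lr = 0.05)
    p$Wpatch <- up$params$Wpatch; opt <- up$state
  }
  pred <- apply(patch_head(Xs, p), 1, which.max) - 1L
  expect_equal(pred, y)

  # slide head: neutral logits, argmax class, monotonicity
  p0 <- mil_init(feat_dim = 2L, heads = 1L, dk = 2L, seed = 58)
  p0$Wslide <- matrix(0, 2, 2); p0$bslide <- matrix(0, 1, 2)
  out <- slide_head(c(1, 1), p0)
  expect_equal(out$PrePro, 0.5)
  p0$bslide <- matrix(c(0, 2), 1, 2)
  out2 <- slide_head(c(1, 1), p0)
  expect_equal(out2$PreCls, 1L)
  expect_gt(out2$prob[2], out$prob[2])
  expect_true(out2$PrePro > 0 && out2$PrePro < 1)
})
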