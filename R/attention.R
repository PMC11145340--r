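# Gated multi-head attention over patch bags, attention pooling, and the
# patch- and slide-level class heads.
#
# Score construction: each branch runs multi-head self-attention over the
# bag and reduces every transformed patch to a scalar with a learnable
# linear map; the sigmoid-gated branch and the tanh-gated branch are
# multiplied elementwise and softmax-normalised over the bag.  A simpler
# gated variant without the self-attention transforms is available for
# ablation.

#' Construct a patch bag
#'
#' @param features N x f matrix of patch feature vectors (f = 1024 for
#'   the default extractor)
#' @param coords N x 2 matrix of tile top-left (x, y) level-0 coordinates
#' @param slide_id identifier
#' @param label slide label 0/1 (NA for unlabeled inference)
#' @return object of class `patch_bag`
#' @export
patch_bag <- function(features, coords = NULL, slide_id = NA_character_,
                      label = NA_integer_) {
  features <- as.matrix(features)
  stopifnot(nrow(features) >= 1L)
  if (!all(is.finite(features))) stop("non-finite patch features")
  if (is.null(coords)) coords <- matrix(0, nrow(features), 2L)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == nrow(features))
  structure(list(features = features, coords = coords,
                 slide_id = slide_id, label = label),
            class = "patch_bag")
}

#' @export
print.patch_bag <- function(x, ...) {
  cat(sprintf("<patch_bag> %s: %d patches x %d features, label %s\n",
              x$slide_id, nrow(x$features), ncol(x$features),
              as.character(x$label)))
  invisible(x)
}

#' Initialise attention and head parameters
#'
#' @param feat_dim patch feature width (1024)
#' @param heads attention heads
#' @param dk key width per head
#' @param variant `"gated_sa"` (self-attention branches, default) or
#'   `"gated_plain"` (plain linear gate branches)
#' @param gate_dim hidden width of the plain-gate branches
#' @param classes number of classes
#' @param seed RNG seed
#' @return named list of parameter matrices with attached config
#' @export
mil_init <- function(feat_dim = 1024L, heads = 4L, dk = 64L,
                     variant = c("gated_sa", "gated_plain"),
                     gate_dim = 64L, classes = 2L, seed = 1L) {
  variant <- match.arg(variant)
  with_seed(seed, {
    gl <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0,
                                               sqrt(2 / (nr + nc))), nr, nc)
    pars <- list()
    if (variant == "gated_sa") {
      w <- heads * dk
      for (br in c("a", "b")) {
        pars[[paste0("Wq_", br)]] <- gl(feat_dim, w)
        pars[[paste0("Wk_", br)]] <- gl(feat_dim, w)
        pars[[paste0("Wv_", br)]] <- gl(feat_dim, w)
        # near-zero scalar projection: attention starts uniform with
        # unsaturated gates and learns its focus from the loss
        pars[[paste0("u_", br)]] <- gl(w, 1L) * 0.05
        pars[[paste0("c_", br)]] <- matrix(0, 1L, 1L)
      }
    } else {
      pars$Vg <- gl(feat_dim, gate_dim)
      pars$Ug <- gl(feat_dim, gate_dim)
      pars$wg <- gl(gate_dim, 1L) * 0.05
    }
    pars$Wslide <- gl(feat_dim, classes)
    pars$bslide <- matrix(0, 1L, classes)
    pars$Wpatch <- gl(feat_dim, classes)
    pars$bpatch <- matrix(0, 1L, classes)
    attr(pars, "heads") <- heads
    attr(pars, "dk") <- dk
    attr(pars, "variant") <- variant
    attr(pars, "feat_dim") <- feat_dim
    pars
  })
}

# one multi-head self-attention branch followed by the scalar projection
ad_sa_branch <- function(pn, X, heads, dk, br) {
  Q <- ad_matmul(X, pn[[paste0("Wq_", br)]])
  K <- ad_matmul(X, pn[[paste0("Wk_", br)]])
  V <- ad_matmul(X, pn[[paste0("Wv_", br)]])
  outs <- vector("list", heads)
  for (h in seq_len(heads)) {
    idx <- ((h - 1L) * dk + 1L):(h * dk)
    A <- ad_softmax_rows(ad_cmul(
      ad_matmul(ad_cols(Q, idx), ad_t(ad_cols(K, idx))), 1 / sqrt(dk)))
    outs[[h]] <- ad_matmul(A, ad_cols(V, idx))
  }
  O <- if (heads > 1L) ad_cbind(outs) else outs[[1L]]
  ad_add(ad_matmul(O, pn[[paste0("u_", br)]]), pn[[paste0("c_", br)]])
}

# tape attention scores: returns the 1 x N softmax-normalised weights
ad_attention_scores <- function(tape, pn, X, params) {
  variant <- attr(params, "variant")
  if (variant == "gated_sa") {
    heads <- attr(params, "heads"); dk <- attr(params, "dk")
    ga <- ad_sa_branch(pn, X, heads, dk, "a")
    gb <- ad_sa_branch(pn, X, heads, dk, "b")
    pre <- ad_mul(ad_sigmoid(ga), ad_tanh(gb))
  } else {
    gate <- ad_mul(ad_sigmoid(ad_matmul(X, pn$Ug)),
                   ad_tanh(ad_matmul(X, pn$Vg)))
    pre <- ad_matmul(gate, pn$wg)
  }
  ad_softmax_rows(ad_t(pre))
}

#' Attention scores of a patch bag
#'
#' Softmax-normalised, strictly positive weights summing to 1, one per
#' patch; permuting the bag permutes the scores identically.
#'
#' @param bag a [patch_bag()]
#' @param params parameters from [mil_init()]
#' @return numeric vector of length N
#' @export
attention_scores <- function(bag, params) {
  if (!all(is.finite(bag$features))) stop("non-finite patch features")
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_leaf(tape, p))
  X <- ad_leaf(tape, bag$features)
  as.vector(ad_attention_scores(tape, pn, X, params)$val)
}

#' Attention-pool a bag into a slide-level feature
#'
#' The slide feature is the score-weighted sum of the patch features; as
#' a convex combination it lies inside the per-dimension envelope of the
#' bag.
#'
#' @param bag a [patch_bag()]
#' @param s attention scores (length N, summing to 1)
#' @return list with `f_slide` (length-f numeric) and `scores`
#' @export
pool_slide <- function(bag, s) {
  if (length(s) != nrow(bag$features))
    stop("score length does not match bag size")
  if (abs(sum(s) - 1) > 1e-6) stop("scores must sum to 1")
  list(f_slide = as.vector(crossprod(bag$features, s)), scores = s)
}

#' Indices of the top-scoring instances
#'
#' Deterministic: ties are broken by lower index; if the bag holds fewer
#' than `c` patches all indices are returned.
#'
#' @param s attention scores
#' @param c number of instances to select (default 8)
#' @param decreasing select highest (default) or lowest scores
#' @return integer indices in selection order
#' @export
select_top_c <- function(s, c = 8L, decreasing = TRUE) {
  stopifnot(c >= 1L)
  ord <- if (decreasing) order(-s, seq_along(s)) else order(s, seq_along(s))
  ord[seq_len(min(c, length(s)))]
}

#' Patch-level class logits
#'
#' @param features k x f matrix of selected instance features
#' @param params parameters from [mil_init()]
#' @return k x 2 logit matrix
#' @export
patch_head <- function(features, params) {
  features <- as.matrix(features)
  stopifnot(nrow(features) >= 1L)
  sweep(features %*% params$Wpatch, 2L, params$bpatch, "+")
}

#' Slide-level prediction from the pooled feature
#'
#' @param f_slide pooled slide feature (length f)
#' @param params parameters from [mil_init()]
#' @return list with `logits`, class probabilities `prob`, `PreCls`
#'   (argmax class) and `PrePro` (probability of the predicted class)
#' @export
slide_head <- function(f_slide, params) {
  logits <- matrix(f_slide, 1L) %*% params$Wslide + params$bslide
  z <- logits - max(logits)
  prob <- exp(z) / sum(exp(z))
  cls <- which.max(prob) - 1L
  list(logits = logits, prob = as.vector(prob),
       PreCls = cls, PrePro = max(prob))
}
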