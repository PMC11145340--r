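# Training loop: attention scoring, top-c instance selection, nucleus
# graph forwarding, composite loss, Adam.

#' Training configuration
#'
#' @param seed master seed; every random draw of a run derives from it
#' @param epochs training epochs
#' @param lr Adam learning rate
#' @param weights loss weights (slide, patch, nuclei); the ablation
#'   switches: `c(1, 0, 0)` slide only, `c(0.8, 0.2, 0)` adds the patch
#'   constraint, `c(0.9, 0, 0.1)` adds the nuclei constraint
#' @param c_select instances with the highest attention used for the
#'   patch and nuclei constraints (default 8)
#' @param use_bottom_instances also supervise the `c_select` lowest-
#'   attention instances with label 0 in the patch branch
#' @param apl_A log-zero clip of the reverse cross-entropy term
#' @param apl_active active term of the instance losses
#' @param knn_k,dmin nucleus graph construction parameters
#' @param gnn_layers,gnn_hidden message-passing depth and width
#' @param heads,dk,attention_variant attention branch architecture
#' @param gray_levels texture quantisation bins
#' @param extractor_seed seed of the stub patch extractor
#' @param split train/validation/test fractions
#' @param patience early-stopping patience on validation total loss
#' @param weight_decay decoupled L2 decay applied by the optimiser;
#'   regularises the wide linear heads toward the stable class signal
#' @return list of class `train_config`
#' @export
train_config <- function(seed = 1L, epochs = 20L, lr = 1e-3,
                         weights = c(0.7, 0.2, 0.1), c_select = 8L,
                         use_bottom_instances = TRUE, apl_A = -4,
                         apl_active = "nce", knn_k = 5L, dmin = 50,
                         gnn_layers = 2L, gnn_hidden = 64L, heads = 4L,
                         dk = 64L, attention_variant = "gated_sa",
                         gray_levels = 8L, extractor_seed = 7L,
                         split = c(0.7, 0.1, 0.2), patience = 10L,
                         weight_decay = 0.01) {
  stopifnot(abs(sum(split) - 1) < 1e-9, all(split > 0))
  structure(as.list(environment()), class = "train_config")
}

#' Stratified train/validation/test split
#'
#' Rounds the train and validation fractions within each class and
#' assigns the remainder to the test split, after a seeded shuffle.
#'
#' @param labels slide labels (0/1)
#' @param fractions length-3 fractions summing to 1
#' @param seed RNG seed
#' @return list of integer index vectors `train`, `val`, `test`
#' @export
split_dataset <- function(labels, fractions = c(0.7, 0.1, 0.2),
                          seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (cl in unique(labels)) {
      members <- sample(which(labels == cl))
      n <- length(members)
      n_tr <- round(fractions[1L] * n)
      n_va <- round(fractions[2L] * n)
      if (n_tr < 1L || n_va < 1L || n - n_tr - n_va < 1L)
        stop(sprintf(paste0("class %s cannot populate all three splits ",
                            "(n = %d); provide more slides per class or ",
                            "coarser fractions"), cl, n))
      idx$train <- c(idx$train, members[seq_len(n_tr)])
      idx$val <- c(idx$val, members[n_tr + seq_len(n_va)])
      idx$test <- c(idx$test, members[(n_tr + n_va + 1L):n])
    }
  })
  lapply(idx, sort)
}

#' Fit a per-dimension standardiser for patch features
#' @param bags list of training [patch_bag()]s
#' @return list with per-dimension `mean` and `sd` (zero sds become 1)
#' @export
fit_patch_scaler <- function(bags) {
  m <- do.call(rbind, lapply(bags, `[[`, "features"))
  mu <- colMeans(m)
  sd <- apply(m, 2L, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mean = mu, sd = sd)
}

#' Apply a patch-feature standardiser
#' @param features N x f matrix
#' @param scaler output of [fit_patch_scaler()]
#' @return standardised matrix
#' @export
apply_patch_scaler <- function(features, scaler) {
  sweep(sweep(features, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}

# per-slide precomputation: bag + one nucleus graph per tile
prepare_slides <- function(dataset, config, extractor = NULL,
                           verbose = FALSE) {
  extractor <- extractor %||%
    stub_extractor(seed = config$extractor_seed)
  bags <- build_bags(dataset, extractor)
  feats <- vector("list", length(dataset))
  names(feats) <- names(dataset)
  for (nm in names(dataset)) {
    slide <- dataset[[nm]]
    feats[[nm]] <- lapply(seq_along(slide$tiles), function(t) {
      tl <- slide$tiles[[t]]
      featurize_mask(tl$image, tl$mask, config$gray_levels,
                     tile_id = sprintf("%s_t%03d", nm, t))
    })
    if (verbose) message("featurised ", nm)
  }
  list(bags = bags, tile_features = feats, extractor = extractor)
}

# build z-scored graphs for every tile of every slide
build_tile_graphs <- function(tile_features, scaler, config) {
  lapply(tile_features, function(per_tile) {
    lapply(per_tile, function(tf) {
      if (nrow(tf) == 0L) return(NULL)
      build_knn_graph(cbind(tf$x, tf$y),
                      features = scale_features(tf, scaler),
                      K = config$knn_k, dmin = config$dmin)
    })
  })
}

# one optimisation step for one slide; returns loss bundle and gradients
slide_step <- function(params, bag, graphs, delta, config) {
  w <- config$weights
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_leaf(tape, p))
  X <- ad_leaf(tape, bag$features)
  s <- ad_attention_scores(tape, pn, X, params)
  f <- ad_matmul(s, X)
  slide_logits <- ad_add(ad_matmul(f, pn$Wslide), pn$bslide)
  q <- c(1 - bag$label, bag$label)
  l_slide <- ad_ce_from_logits(slide_logits, q)
  sv <- as.vector(s$val)
  top <- select_top_c(sv, config$c_select)
  l_patch <- NULL
  if (w[2L] > 0) {
    sel <- top
    lab <- rep(bag$label, length(top))
    if (config$use_bottom_instances) {
      bot <- setdiff(select_top_c(sv, config$c_select,
                                  decreasing = FALSE), top)
      sel <- c(sel, bot)
      lab <- c(lab, rep(0L, length(bot)))
    }
    patch_logits <- ad_add(ad_matmul(ad_rows(X, sel), pn$Wpatch),
                           pn$bpatch)
    l_patch <- ad_mean_rowloss(patch_logits, lab, ad_apl_from_logits,
                               A = config$apl_A,
                               active = config$apl_active)
  }
  l_nuclei <- NULL
  if (w[3L] > 0) {
    terms <- list()
    for (t in top) {
      g <- graphs[[t]]
      if (is.null(g)) next
      fw <- ad_gnn_forward(tape, pn, g, g$features, delta,
                           config$gnn_layers)
      terms[[length(terms) + 1L]] <-
        ad_apl_from_logits(fw$logits, q, A = config$apl_A,
                           active = config$apl_active)
    }
    if (length(terms)) {
      l_nuclei <- terms[[1L]]
      if (length(terms) > 1L)
        for (i in 2:length(terms)) l_nuclei <- ad_add(l_nuclei, terms[[i]])
      l_nuclei <- ad_cmul(l_nuclei, 1 / length(terms))
    }
  }
  total <- ad_cmul(l_slide, w[1L])
  if (!is.null(l_patch)) total <- ad_add(total, ad_cmul(l_patch, w[2L]))
  if (!is.null(l_nuclei)) total <- ad_add(total, ad_cmul(l_nuclei, w[3L]))
  ad_backward(total)
  grads <- lapply(pn, function(nd) nd$grad)
  list(bundle = total_loss(l_slide$val[1L],
                           if (is.null(l_patch)) 0 else l_patch$val[1L],
                           if (is.null(l_nuclei)) 0 else l_nuclei$val[1L],
                           w),
       grads = grads)
}

#' Train the nuclei-constrained MIL classifier on a synthetic dataset
#'
#' Splits the slides (stratified, seeded), featurises nuclei from the
#' provided instance masks, fits the feature scaler and degree
#' normaliser on the training split, then runs Adam over the composite
#' loss.  Every epoch recomputes attention, selects the `c_select`
#' highest-attention tiles per slide, forwards their nucleus graphs, and
#' steps all parameters jointly.  The checkpoint with the best
#' validation total loss is returned.
#'
#' @param dataset output of [generate_dataset()] (or any list of slides
#'   with `tiles` carrying `image` and `mask` and a `label`)
#' @param config a [train_config()]
#' @param extractor optional conforming feature extractor
#' @param verbose print per-epoch losses
#' @return object of class `nucmil_model`: `params`, `delta`, `scaler`,
#'   `config`, `split`, `history` (per-epoch losses and validation
#'   accuracy), `extractor_seed`
#' @export
train_nucmil <- function(dataset, config = train_config(),
                         extractor = NULL, verbose = FALSE) {
  labels <- vapply(dataset, `[[`, integer(1L), "label")
  split <- split_dataset(labels, config$split, config$seed)
  prep <- prepare_slides(dataset, config, extractor, verbose)
  # standardise patch features per dimension on the training split; the
  # statistics are frozen into the checkpoint and reapplied at inference
  patch_scaler <- fit_patch_scaler(prep$bags[split$train])
  for (nm in names(prep$bags))
    prep$bags[[nm]]$features <-
      apply_patch_scaler(prep$bags[[nm]]$features, patch_scaler)
  train_nuc <- do.call(rbind,
    lapply(prep$tile_features[split$train], function(l) do.call(rbind, l)))
  scaler <- fit_feature_scaler(train_nuc)
  graphs <- build_tile_graphs(prep$tile_features, scaler, config)
  train_graphs <- unlist(graphs[split$train], recursive = FALSE)
  train_graphs <- train_graphs[!vapply(train_graphs, is.null, logical(1L))]
  delta <- fit_degree_normalizer(train_graphs)
  params <- c(mil_init(feat_dim = prep$extractor$width,
                       heads = config$heads, dk = config$dk,
                       variant = config$attention_variant,
                       seed = config$seed),
              gnn_init(in_dim = 16L, hidden = config$gnn_hidden,
                       layers = config$gnn_layers,
                       seed = config$seed + 1L))
  attr(params, "heads") <- config$heads
  attr(params, "dk") <- config$dk
  attr(params, "variant") <- config$attention_variant
  attr(params, "layers") <- config$gnn_layers
  opt <- adam_state(params)
  history <- list()
  best <- list(val = Inf, params = params, epoch = 0L)
  wait <- 0L
  for (epoch in seq_len(config$epochs)) {
    order_tr <- with_seed(config$seed * 1000L + epoch,
                          sample(split$train))
    ep <- c(Lslide = 0, Lpatch = 0, Lnuclei = 0, Ltotal = 0)
    for (i in order_tr) {
      nm <- names(dataset)[i]
      st <- slide_step(params, prep$bags[[nm]], graphs[[nm]], delta,
                       config)
      up <- adam_step(params, st$grads, opt, lr = config$lr,
                      weight_decay = config$weight_decay %||% 0)
      params <- up$params
      attr(params, "heads") <- config$heads
      attr(params, "dk") <- config$dk
      attr(params, "variant") <- config$attention_variant
      attr(params, "layers") <- config$gnn_layers
      opt <- up$state
      b <- st$bundle
      ep <- ep + c(b$Lslide, b$Lpatch, b$Lnuclei, b$Ltotal)
    }
    ep <- ep / length(order_tr)
    val <- validate_epoch(params, prep$bags, graphs, delta, config,
                          split$val, dataset)
    history[[epoch]] <- data.frame(epoch = epoch, Lslide = ep[1L],
                                   Lpatch = ep[2L], Lnuclei = ep[3L],
                                   Ltotal = ep[4L],
                                   val_Ltotal = val$loss,
                                   val_AC = val$ac)
    if (verbose)
      message(sprintf("epoch %02d  Ltotal %.4f  val %.4f  val AC %.1f%%",
                      epoch, ep[4L], val$loss, val$ac))
    if (val$loss < best$val - 1e-9) {
      best <- list(val = val$loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  structure(list(params = best$params, delta = delta, scaler = scaler,
                 patch_scaler = patch_scaler,
                 config = config, split = split,
                 history = do.call(rbind, history),
                 best_epoch = best$epoch,
                 extractor_seed = config$extractor_seed),
            class = "nucmil_model")
}

validate_epoch <- function(params, bags, graphs, delta, config, idx,
                           dataset) {
  if (!length(idx)) return(list(loss = NA_real_, ac = NA_real_))
  tot <- 0; correct <- 0L
  for (i in idx) {
    nm <- names(dataset)[i]
    st <- slide_forward_eval(params, bags[[nm]], graphs[[nm]], delta,
                             config)
    tot <- tot + st$bundle$Ltotal
    if (st$PreCls == bags[[nm]]$label) correct <- correct + 1L
  }
  list(loss = tot / length(idx), ac = 100 * correct / length(idx))
}

# forward-only evaluation of one slide (losses + prediction)
slide_forward_eval <- function(params, bag, graphs, delta, config) {
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_leaf(tape, p))
  X <- ad_leaf(tape, bag$features)
  s <- ad_attention_scores(tape, pn, X, params)
  f <- ad_matmul(s, X)
  pred <- slide_head(as.vector(f$val), params)
  q <- c(1 - bag$label, bag$label)
  l_slide <- slide_ce(pred$prob, q)
  sv <- as.vector(s$val)
  top <- select_top_c(sv, config$c_select)
  l_patch <- 0
  if (config$weights[2L] > 0) {
    pl <- patch_head(bag$features[top, , drop = FALSE], params)
    probs <- exp(pl - apply(pl, 1L, max))
    probs <- probs / rowSums(probs)
    l_patch <- mean(vapply(seq_len(nrow(probs)), function(k)
      apl_loss(probs[k, ], q, A = config$apl_A,
               active = config$apl_active), numeric(1L)))
  }
  l_nuclei <- 0
  if (config$weights[3L] > 0) {
    vals <- c()
    for (t in top) {
      g <- graphs[[t]]
      if (is.null(g)) next
      fw <- nuclei_forward(g, params, delta)
      z <- fw$logits - max(fw$logits)
      p <- as.vector(exp(z) / sum(exp(z)))
      vals <- c(vals, apl_loss(p, q, A = config$apl_A,
                               active = config$apl_active))
    }
    if (length(vals)) l_nuclei <- mean(vals)
  }
  c(pred,
    list(bundle = total_loss(l_slide, l_patch, l_nuclei,
                             config$weights),
         scores = sv, top = top))
}

#' Predict slide labels with a trained model
#'
#' @param model a [train_nucmil()] result
#' @param dataset the dataset to score
#' @param idx slide indices to score (default: the model's test split)
#' @param extractor optional extractor (defaults to the stub with the
#'   model's recorded seed)
#' @return data.frame with `slide_id`, `GT`, `PrePro`, `PreCls` and the
#'   positive-class probability `p_pos`
#' @export
predict_nucmil <- function(model, dataset, idx = model$split$test,
                           extractor = NULL) {
  extractor <- extractor %||% stub_extractor(seed = model$extractor_seed)
  rows <- lapply(idx, function(i) {
    slide <- dataset[[i]]
    tiles <- lapply(slide$tiles, `[[`, "image")
    coords <- do.call(rbind, lapply(slide$tiles, `[[`, "origin"))
    bag <- extract_features(tiles, extractor, coords, slide$slide_id,
                            slide$label)
    if (!is.null(model$patch_scaler))
      bag$features <- apply_patch_scaler(bag$features,
                                         model$patch_scaler)
    s <- attention_scores(bag, model$params)
    pooled <- pool_slide(bag, s)
    pred <- slide_head(pooled$f_slide, model$params)
    data.frame(slide_id = slide$slide_id, GT = slide$label,
               PrePro = pred$PrePro, PreCls = pred$PreCls,
               p_pos = pred$prob[2L])
  })
  do.call(rbind, rows)
}
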