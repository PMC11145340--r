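# Noise-robust composite losses.
#
# Instance-level supervision inherited from the slide label is noisy:
# a high-attention patch of a cancerous slide need not be cancerous.
# Patch- and nuclei-level branches therefore use an active-passive pair —
# normalised cross-entropy (active) plus reverse cross-entropy (passive) —
# while the slide-level branch keeps plain cross-entropy.

#' Active-passive loss of one prediction
#'
#' `NCE + RCE` where `NCE = log p(y|x) / sum_k log p(k|x)` (bounded in
#' \[0, 1\]) and `RCE = -sum_k p(k|x) log q(k|x)` with `log 0 := A`.  For
#' a one-hot truth the passive term reduces to `-A (1 - p(y|x))`.
#'
#' @param p predicted class distribution (floored at `eps`)
#' @param q truth distribution (one-hot or any point of the simplex)
#' @param A clip value standing in for `log 0` in the reverse term
#' @param active `"nce"` (default) or `"ce"` (plain cross-entropy active
#'   term, for ablation)
#' @param eps probability floor
#' @return nonnegative scalar loss
#' @export
apl_loss <- function(p, q, A = -4, active = c("nce", "ce"),
                     eps = 1e-12) {
  active <- match.arg(active)
  check_simplex(q, "q")
  check_simplex(p, "p")
  p <- pmax(p, eps); p <- p / sum(p)
  y <- which.max(q)
  act <- if (active == "nce") log(p[y]) / sum(log(p)) else -log(p[y])
  lq <- ifelse(q > 0, log(q), A)
  act - sum(p * lq)
}

check_simplex <- function(v, name) {
  if (any(!is.finite(v)) || any(v < -1e-9) || abs(sum(v) - 1) > 1e-6)
    stop(sprintf("%s is not a probability distribution", name))
  invisible(v)
}

#' Slide-level cross-entropy
#'
#' @param p predicted class distribution (floored at `eps`)
#' @param q truth distribution
#' @param eps probability floor
#' @return nonnegative scalar
#' @export
slide_ce <- function(p, q, eps = 1e-12) {
  check_simplex(q, "q")
  check_simplex(p, "p")
  p <- pmax(p, eps)
  -sum(q * log(p))
}

#' Weighted total loss bundle
#'
#' `Ltotal = w1 Lslide + w2 Lpatch + w3 Lnuclei`, exactly.  Setting a
#' weight to zero switches the corresponding constraint off — the
#' ablation structure: slide-only (1, 0, 0), slide + patch, slide +
#' nuclei, or the full model (default 0.7, 0.2, 0.1).
#'
#' @param l_slide,l_patch,l_nuclei branch losses (nonnegative)
#' @param weights numeric length 3, nonnegative
#' @return object of class `loss_bundle`
#' @export
total_loss <- function(l_slide, l_patch = 0, l_nuclei = 0,
                       weights = c(0.7, 0.2, 0.1)) {
  stopifnot(length(weights) == 3L)
  if (any(weights < 0)) stop("loss weights must be nonnegative")
  structure(list(Lslide = l_slide, Lpatch = l_patch, Lnuclei = l_nuclei,
                 weights = weights,
                 Ltotal = weights[1L] * l_slide + weights[2L] * l_patch +
                          weights[3L] * l_nuclei),
            class = "loss_bundle")
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat(sprintf("Ltotal %.4f = %.2f*Lslide(%.4f) + %.2f*Lpatch(%.4f) + %.2f*Lnuclei(%.4f)\n",
              x$Ltotal, x$weights[1L], x$Lslide, x$weights[2L], x$Lpatch,
              x$weights[3L], x$Lnuclei))
  invisible(x)
}

# --- tape versions operating on a 1 x K logit node ---------------------

ad_ce_from_logits <- function(logits, q) {
  lp <- ad_logsoftmax_rows(logits)
  ad_cmul(ad_sum(ad_cmul(lp, matrix(q, 1L))), -1)
}

ad_apl_from_logits <- function(logits, q, A = -4, active = "nce") {
  lp <- ad_logsoftmax_rows(logits)
  y <- which.max(q)
  act <- if (active == "nce") {
    ad_mul(ad_pick(lp, 1L, y), ad_recip(ad_sum(lp)))
  } else {
    ad_cmul(ad_pick(lp, 1L, y), -1)
  }
  lq <- matrix(ifelse(q > 0, log(q), A), 1L)
  rce <- ad_cmul(ad_sum(ad_cmul(ad_exp(lp), lq)), -1)
  ad_add(act, rce)
}

# mean loss over rows of an n x K logit node given per-row labels (0/1)
ad_mean_rowloss <- function(logits, labels, lossfn, ...) {
  n <- nrow(logits$val)
  terms <- lapply(seq_len(n), function(i) {
    q <- c(1 - labels[i], labels[i])
    lossfn(ad_rows(logits, i), q, ...)
  })
  out <- terms[[1L]]
  if (n > 1L) for (i in 2:n) out <- ad_add(out, terms[[i]])
  ad_cmul(out, 1 / n)
}
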