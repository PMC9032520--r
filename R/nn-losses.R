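#' Multi-similarity loss
#'
#' Pair-based metric-learning loss over a batch of unit-norm embeddings.
#' Cosine similarities are mined per anchor: a positive pair is kept when its
#' similarity is below the hardest negative plus `eps`, a negative pair when
#' its similarity exceeds the easiest positive minus `eps`. Kept pairs are
#' weighted through soft-plus pools with slopes `alpha` (positives) and
#' `beta` (negatives) around the `base` similarity. With perfectly separated
#' classes (all positive similarities at 1, all negatives at or below
#' `base - eps`) no pair is mined and the loss is 0. Defaults are the
#' canonical settings alpha = 2, beta = 50, base = 0.5, eps = 0.1.
#'
#' @param embeddings Numeric matrix (batch x dim), rows unit-norm.
#' @param labels Class labels, one per row; at least two distinct labels.
#' @param alpha,beta,base,eps Loss parameters (see description).
#' @return A list: `loss` (scalar >= 0) and `grad`, the gradient with
#'   respect to `embeddings` (same shape).
#' @export
multisimilarity_loss <- function(embeddings, labels, alpha = 2, beta = 50,
                                 base = 0.5, eps = 0.1) {
  B <- nrow(embeddings)
  labels <- as.vector(labels)
  if (length(labels) != B) stop("labels must match the batch size")
  if (length(unique(labels)) < 2)
    stop("batch contains a single class: no negative pairs exist")
  S <- tcrossprod(embeddings)
  G <- matrix(0, B, B)   # dLoss / dS
  loss <- 0
  for (i in seq_len(B)) {
    pos <- which(labels == labels[i])
    pos <- pos[pos != i]
    neg <- which(labels != labels[i])
    if (!length(pos) || !length(neg)) next
    sp <- S[i, pos]
    sn <- S[i, neg]
    keep_p <- sp < max(sn) + eps
    keep_n <- sn > min(sp) - eps
    if (any(keep_p)) {
      ep <- exp(-alpha * (sp[keep_p] - base))
      pool <- 1 + sum(ep)
      loss <- loss + log(pool) / alpha
      G[i, pos[keep_p]] <- G[i, pos[keep_p]] - ep / pool
    }
    if (any(keep_n)) {
      en <- exp(beta * (sn[keep_n] - base))
      pool <- 1 + sum(en)
      loss <- loss + log(pool) / beta
      G[i, neg[keep_n]] <- G[i, neg[keep_n]] + en / pool
    }
  }
  loss <- loss / B
  G <- G / B
  grad <- (G + t(G)) %*% embeddings
  list(loss = loss, grad = grad)
}

#' Additive angular margin (ArcFace) loss
#'
#' Margin-based softmax classification loss on the angle between an
#' embedding and its class weight vector: the target logit is
#' `cos(theta + margin)`, all logits are scaled by `scale`, and a standard
#' cross-entropy follows. Class weight rows are L2-normalized internally.
#' With `margin = 0, scale = 1` this reduces to softmax cross-entropy on
#' cosine logits.
#'
#' @param embeddings Numeric matrix (batch x dim), rows unit-norm.
#' @param labels Integer class indices in `1..nrow(class_weights)`.
#' @param class_weights Numeric matrix (n_classes x dim).
#' @param margin Additive angular margin in radians.
#' @param scale Logit scale.
#' @return A list: `loss` (mean cross-entropy), `grad` (w.r.t. embeddings)
#'   and `grad_weights` (w.r.t. the unnormalized class weights).
#' @export
arcface_loss <- function(embeddings, labels, class_weights,
                         margin = 0.5, scale = 64) {
  B <- nrow(embeddings)
  C <- nrow(class_weights)
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > C)) stop("labels outside the class range")
  wn <- sqrt(rowSums(class_weights^2))
  wn[wn == 0] <- 1
  Wn <- class_weights / wn
  cosm <- cos(margin)
  sinm <- sin(margin)

  cosine <- tcrossprod(embeddings, Wn)            # B x C
  cosine <- pmin(pmax(cosine, -1), 1)
  tgt <- cbind(seq_len(B), labels)
  ct <- cosine[tgt]
  st <- sqrt(pmax(1 - ct^2, 1e-12))
  phi <- ct * cosm - st * sinm                    # cos(theta + m)
  logits <- scale * cosine
  logits[tgt] <- scale * phi

  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  Z <- rowSums(ex)
  P <- ex / Z
  loss <- mean(-(logits[tgt] - mx) + log(Z))

  dlogits <- P
  dlogits[tgt] <- dlogits[tgt] - 1
  dlogits <- dlogits * scale / B
  # chain through the margin on the target logit: d phi / d cos
  dphi_dcos <- cosm + sinm * ct / st
  dcos <- dlogits
  dcos[tgt] <- dcos[tgt] * dphi_dcos
  grad <- dcos %*% Wn
  dWn <- crossprod(dcos, embeddings)              # C x dim
  # back through the row normalization of the class weights
  dots <- rowSums(dWn * Wn)
  grad_weights <- (dWn - Wn * dots) / wn
  list(loss = loss, grad = grad, grad_weights = grad_weights)
}
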