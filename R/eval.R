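#' Build genuine and imposter pairs
#'
#' Genuine pairs are all unordered same-subject pairs: with `S` subjects and
#' `k` samples each, `S * choose(k, 2)` pairs. Imposter pairs follow the
#' first-half/back-half rule: for every ordered pair of distinct subjects
#' `(i, j)`, each sample in the first half of subject `i`'s list is paired
#' with each sample in the back half of subject `j`'s list, giving
#' `S * (S - 1) * (k / 2)^2` pairs for even `k` (odd counts split
#' floor/ceiling). Same-subject pairs never enter the imposter set.
#'
#' @param subjects Vector of subject labels, one per sample, in each
#'   subject's temporal order.
#' @return An object of class `pair_set`: data frames `genuine` and
#'   `imposter` of sample index pairs (`a`, `b`), plus counts.
#' @examples
#' p <- build_pairs(rep(c("s1", "s2"), each = 4))
#' p$n_genuine   # 2 * choose(4, 2) = 12
#' p$n_imposter  # 2 * 1 * 2 * 2 = 8
#' @export
build_pairs <- function(subjects) {
  subjects <- as.character(subjects)
  ids <- unique(subjects)
  if (length(ids) < 2) stop("need at least 2 subjects to form imposter pairs")
  by_subj <- split(seq_along(subjects), subjects)[ids]

  gen <- lapply(by_subj, function(idx) {
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    data.frame(a = cmb[1, ], b = cmb[2, ])
  })
  genuine <- do.call(rbind, gen)

  halves <- lapply(by_subj, function(idx) {
    h <- length(idx) %/% 2
    list(first = idx[seq_len(h)],
         back = idx[setdiff(seq_along(idx), seq_len(h))])
  })
  imp <- vector("list", length(ids) * (length(ids) - 1))
  k <- 0L
  for (i in ids) for (j in ids) {
    if (i == j) next
    k <- k + 1L
    fi <- halves[[i]]$first
    bj <- halves[[j]]$back
    imp[[k]] <- data.frame(a = rep(fi, each = length(bj)),
                           b = rep(bj, times = length(fi)))
  }
  imposter <- do.call(rbind, imp)
  rownames(genuine) <- rownames(imposter) <- NULL
  structure(list(genuine = genuine, imposter = imposter,
                 n_genuine = nrow(genuine), n_imposter = nrow(imposter)),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("Pair set: %d genuine, %d imposter (genuine fraction %.2f%%)\n",
              x$n_genuine, x$n_imposter,
              100 * x$n_genuine / (x$n_genuine + x$n_imposter)))
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' @param v1,v2 Nonzero numeric vectors.
#' @return The cosine similarity in `[-1, 1]`.
#' @export
cosine_score <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity undefined for zero vectors")
  sum(v1 * v2) / (n1 * n2)
}

# similarity scores for a pair table against an embedding matrix
.pair_scores <- function(emb, pairs) {
  rowSums(emb[pairs$a, , drop = FALSE] * emb[pairs$b, , drop = FALSE])
}

#' ROC curve and equal error rate from verification scores
#'
#' Sweeps thresholds over the pooled unique scores. At threshold `t` the
#' false accept rate is the fraction of imposter scores `>= t` and the false
#' reject rate the fraction of genuine scores `< t`. The equal error rate is
#' located where FAR and FRR cross, with linear interpolation between
#' adjacent thresholds.
#'
#' @param genuine_scores,imposter_scores Numeric score vectors (higher =
#'   more similar).
#' @return An object of class `roc_result`: `thresholds`, `far`, `frr`,
#'   `eer` (fraction in `[0, 1]`) and `eer_threshold`.
#' @examples
#' compute_eer(c(0.9, 0.7, 0.4), c(0.5, 0.2, 0.1))$eer # 1/3
#' @export
compute_eer <- function(genuine_scores, imposter_scores) {
  if (!length(genuine_scores) || !length(imposter_scores))
    stop("both score lists must be non-empty")
  th <- sort(unique(c(genuine_scores, imposter_scores)))
  th <- c(th, th[length(th)] + 1)  # final point: reject everything
  ng <- length(genuine_scores)
  ni <- length(imposter_scores)
  gs <- sort(genuine_scores)
  is_ <- sort(imposter_scores)
  # counts below threshold via binary search on the sorted scores
  frr <- findInterval(th, gs, left.open = TRUE) / ng        # genuine < t
  far <- 1 - findInterval(th, is_, left.open = TRUE) / ni   # imposter >= t
  d <- far - frr
  cross <- which(d <= 0)[1]
  if (is.na(cross)) cross <- length(th)
  if (cross == 1 || d[cross] == 0) {
    eer <- (far[cross] + frr[cross]) / 2
    eer_t <- th[cross]
  } else {
    i0 <- cross - 1
    w <- d[i0] / (d[i0] - d[cross])
    eer_far <- far[i0] + w * (far[cross] - far[i0])
    eer_frr <- frr[i0] + w * (frr[cross] - frr[i0])
    eer <- (eer_far + eer_frr) / 2
    eer_t <- th[i0] + w * (th[cross] - th[i0])
  }
  structure(list(thresholds = th, far = far, frr = frr,
                 eer = eer, eer_threshold = eer_t,
                 n_genuine = ng, n_imposter = ni),
            class = "roc_result")
}

#' Score a pair set and compute its ROC/EER
#'
#' @param emb Embedding matrix (samples x dim).
#' @param pairs A `pair_set` from [build_pairs()].
#' @return A `roc_result` (see [compute_eer()]).
#' @export
evaluate_pairs <- function(emb, pairs) {
  stopifnot(inherits(pairs, "pair_set"))
  compute_eer(.pair_scores(emb, pairs$genuine),
              .pair_scores(emb, pairs$imposter))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d genuine / %d imposter scores: EER = %.2f%% at threshold %.4f\n",
              x$n_genuine, x$n_imposter, 100 * x$eer, x$eer_threshold))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$far, 1 - x$frr, type = "l", lwd = 2, col = "steelblue",
                 xlab = "False accept rate", ylab = "True accept rate",
                 main = "ROC", ...)
  graphics::abline(a = 1, b = -1, lty = 3, col = "grey50")
  graphics::points(x$eer, 1 - x$eer, pch = 19, col = "firebrick")
  invisible(x)
}
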