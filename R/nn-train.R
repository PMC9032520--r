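#' Training configuration
#'
#' Defaults follow the reference training protocols: open-set metric learning uses a
#' decoupled-weight-decay optimizer (AdamW) with learning rate 1e-4, weight
#' decay 1e-4 and batches of 8 subjects x 4 samples under the
#' multi-similarity loss; closed-set classification uses Adam with learning
#' rate 1e-3 and the additive angular margin loss. `max_steps` retains the
#' protocol ceilings (1e5 / 2e4); desk-scale runs pass a smaller value.
#'
#' @param mode `"open_set"` or `"closed_set"`.
#' @param lr Learning rate.
#' @param weight_decay Weight decay coefficient.
#' @param max_steps Number of optimizer steps.
#' @param batch_subjects Subjects sampled per batch.
#' @param batch_per_subject Samples drawn per sampled subject.
#' @param optimizer `"adamw"` (decoupled) or `"adam"` (L2-coupled).
#' @param loss_params Named list overriding loss defaults
#'   (see [multisimilarity_loss()], [arcface_loss()]).
#' @param eval_every Validation-EER evaluation period in steps (0 disables).
#' @param seed Seed for batch sampling and initialization.
#' @return A list of class `train_config`.
#' @export
train_config <- function(mode = c("open_set", "closed_set"), lr = NULL,
                         weight_decay = 1e-4, max_steps = NULL,
                         batch_subjects = 8, batch_per_subject = 4,
                         optimizer = NULL, loss_params = list(),
                         eval_every = 250, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(lr)) lr <- if (mode == "open_set") 1e-4 else 1e-3
  if (is.null(max_steps)) max_steps <- if (mode == "open_set") 1e5 else 2e4
  if (is.null(optimizer)) optimizer <- if (mode == "open_set") "adamw" else "adam"
  structure(list(mode = mode, lr = lr, weight_decay = weight_decay,
                 max_steps = as.integer(max_steps),
                 batch_subjects = as.integer(batch_subjects),
                 batch_per_subject = as.integer(batch_per_subject),
                 optimizer = optimizer, loss_params = loss_params,
                 eval_every = as.integer(eval_every), seed = seed),
            class = "train_config")
}

# Adam / AdamW update applied in place on a flat list of parameter tensors
.opt_step <- function(par, grads, state, cfg, step) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  bc1 <- 1 - b1^step
  bc2 <- 1 - b2^step
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      key <- paste0(nm, ".", f)
      decay <- f == "W" && cfg$weight_decay > 0
      if (decay && cfg$optimizer == "adam")
        g <- g + cfg$weight_decay * par[[nm]][[f]]
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- b1 * state$m[[key]] + (1 - b1) * g
      state$v[[key]] <- b2 * state$v[[key]] + (1 - b2) * g^2
      upd <- (state$m[[key]] / bc1) / (sqrt(state$v[[key]] / bc2) + eps)
      if (decay && cfg$optimizer == "adamw")
        upd <- upd + cfg$weight_decay * par[[nm]][[f]]
      par[[nm]][[f]] <- par[[nm]][[f]] - cfg$lr * upd
    }
  }
  list(par = par, state = state)
}

#' Train the embedding network
#'
#' Seeded training loop over a feature dataset. Each step samples
#' `batch_subjects` subjects and `batch_per_subject` samples per subject,
#' runs the two-branch network forward, applies the mode's loss
#' (multi-similarity for open-set metric learning, additive angular margin
#' for closed-set classification) and updates the weights with Adam/AdamW.
#' Every `eval_every` steps the validation samples are embedded in
#' evaluation mode, scored with genuine/imposter cosine pairs, and the
#' weights with the best validation EER are retained.
#'
#' @param data A list with `mi` (array `(2, len, n)` or `NULL`), `sdm`
#'   (array `(1, size^2, n)` or `NULL`) and `labels` (length-n subject
#'   labels), e.g. from [build_feature_dataset()].
#' @param config A [train_config()].
#' @param val Integer indices of validation samples. `NULL` holds out
#'   `val_fraction` of each subject's samples (the last ones, preserving
#'   temporal order).
#' @param val_fraction Per-subject fraction held out when `val` is `NULL`.
#' @param model Optionally a pre-built [gaze_embedder()] to (re)train.
#' @param verbose Print progress every evaluation.
#'
#' @return An object of class `gazeauth_model`: the fitted `gaze_embedder`
#'   (best-validation weights), `final_model` (last-step weights), training
#'   `history` (step, loss, val_eer), `best_val_eer`, the config and the
#'   class levels.
#' @export
gazeauth_train <- function(data, config = train_config(), val = NULL,
                           val_fraction = 0.25, model = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  labels <- as.character(data$labels)
  n <- length(labels)
  classes <- sort(unique(labels))
  if (length(classes) < config$batch_subjects)
    stop("dataset has fewer subjects than batch_subjects")
  set.seed(config$seed)

  if (is.null(val)) {
    val <- unlist(lapply(split(seq_len(n), labels), function(idx) {
      h <- max(1L, round(length(idx) * val_fraction))
      utils::tail(idx, h)
    }))
  }
  val <- sort(unique(as.integer(val)))
  train_idx <- setdiff(seq_len(n), val)
  by_subj <- split(train_idx, labels[train_idx])
  by_subj <- by_subj[lengths(by_subj) >= 1]
  if (length(by_subj) < config$batch_subjects)
    stop("too few subjects with training samples")

  use_mi <- !is.null(data$mi)
  use_sdm <- !is.null(data$sdm)
  if (is.null(model)) {
    variant <- if (use_mi && use_sdm) "both" else if (use_mi) "mi" else "sdm"
    model <- gaze_embedder(
      variant = variant,
      mi_len = if (use_mi) dim(data$mi)[2],
      sdm_size = if (use_sdm) as.integer(sqrt(dim(data$sdm)[2])) else 128,
      seed = config$seed)
  }
  closed <- config$mode == "closed_set"
  cls_w <- if (closed)
    .he_init(length(classes), model$spec$embed_dim, model$spec$embed_dim)

  lp <- config$loss_params
  history <- data.frame(step = integer(), loss = numeric(),
                        val_eer = numeric())
  best <- list(eer = Inf, par = model$par, stat = model$stat, cw = cls_w)
  val_pairs <- if (length(val) >= 2 &&
                   length(unique(labels[val])) >= 2) build_pairs(labels[val])

  eval_model <- function() {
    emb <- embed(model,
                 mi = if (use_mi) data$mi[, , val, drop = FALSE],
                 sdm = if (use_sdm) data$sdm[, , val, drop = FALSE])
    evaluate_pairs(emb, val_pairs)$eer
  }

  opt_state <- list(m = list(), v = list())
  for (step in seq_len(config$max_steps)) {
    subj <- sample(names(by_subj), config$batch_subjects)
    idx <- unlist(lapply(by_subj[subj], function(s)
      sample(rep(s, length.out = max(length(s), config$batch_per_subject)),
             config$batch_per_subject)))
    fw <- .net_fw(model,
                  mi = if (use_mi) data$mi[, , idx, drop = FALSE],
                  sdm = if (use_sdm) data$sdm[, , idx, drop = FALSE],
                  train = TRUE)
    model <- fw$model  # running batch-norm statistics
    if (closed) {
      li <- match(labels[idx], classes)
      ls <- do.call(arcface_loss,
                    c(list(fw$emb, li, cls_w), lp))
    } else {
      ls <- do.call(multisimilarity_loss,
                    c(list(fw$emb, labels[idx]), lp))
    }
    if (!is.finite(ls$loss))
      stop(sprintf("training diverged at step %d (loss = %g)", step, ls$loss))
    grads <- .net_bw(model, fw$caches, ls$grad)
    par <- model$par
    if (closed) {
      grads$.arcface <- list(W = ls$grad_weights)
      par$.arcface <- list(W = cls_w)
    }
    os <- .opt_step(par, grads, opt_state, config, step)
    opt_state <- os$state
    if (closed) {
      cls_w <- os$par$.arcface$W
      os$par$.arcface <- NULL
    }
    model$par <- os$par

    rec_eer <- NA_real_
    if (!is.null(val_pairs) && config$eval_every > 0 &&
        (step %% config$eval_every == 0 || step == config$max_steps)) {
      rec_eer <- eval_model()
      if (rec_eer < best$eer)
        best <- list(eer = rec_eer, par = model$par, stat = model$stat,
                     cw = cls_w)
      if (verbose)
        message(sprintf("step %d: loss %.4f, val EER %.3f",
                        step, ls$loss, rec_eer))
    }
    history <- rbind(history,
                     data.frame(step = step, loss = ls$loss,
                                val_eer = rec_eer))
  }

  final <- model
  if (is.finite(best$eer)) {
    model$par <- best$par
    model$stat <- best$stat
    cls_w <- best$cw
  }
  structure(list(model = model, final_model = final,
                 class_weights = cls_w, history = history,
                 best_val_eer = if (is.finite(best$eer)) best$eer else NA_real_,
                 config = config, classes = classes,
                 val_idx = val),
            class = "gazeauth_model")
}

#' @export
print.gazeauth_model <- function(x, ...) {
  cat(sprintf("Fitted gaze authentication model (%s, %s loss)\n",
              x$config$mode,
              if (x$config$mode == "open_set") "multi-similarity" else "ArcFace"))
  cat(sprintf("  %d training steps, %d subjects", nrow(x$history),
              length(x$classes)))
  if (!is.na(x$best_val_eer))
    cat(sprintf(", best validation EER %.2f%%", 100 * x$best_val_eer))
  cat("\n")
  invisible(x)
}

#' @export
summary.gazeauth_model <- function(object, ...) {
  h <- object$history
  cat("Training summary\n")
  print(object)
  cat(sprintf("  loss: first %.4f, last %.4f, min %.4f\n",
              h$loss[1], h$loss[nrow(h)], min(h$loss)))
  ev <- h[!is.na(h$val_eer), ]
  if (nrow(ev))
    cat(sprintf("  validation EER trajectory: %s\n",
                paste(sprintf("%.3f", ev$val_eer), collapse = " ")))
  invisible(object)
}

#' @export
plot.gazeauth_model <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(h$step, h$loss, type = "l", xlab = "step", ylab = "loss",
                 main = "Training loss", ...)
  ev <- h[!is.na(h$val_eer), ]
  if (nrow(ev))
    graphics::plot(ev$step, ev$val_eer, type = "b", xlab = "step",
                   ylab = "validation EER", main = "Validation EER",
                   ylim = c(0, max(0.5, ev$val_eer)))
  invisible(x)
}

#' Embeddings for new samples from a fitted model
#'
#' @param object A fitted `gazeauth_model`.
#' @param mi,sdm Feature inputs as in [embed()].
#' @param ... Unused.
#' @return Matrix of unit-norm embeddings (samples x dim).
#' @export
predict.gazeauth_model <- function(object, mi = NULL, sdm = NULL, ...) {
  embed(object$model, mi = mi, sdm = sdm)
}
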