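#' Build the two-branch convolutional embedding network
#'
#' The network maps eye-movement features to a 128-dimensional unit-norm
#' embedding. The 2-D branch (for saccade distribution maps) stacks four
#' convolutional layers with 64 filters, 5x5 kernels and dilation 1; the 1-D
#' branch (for motion-information channels) stacks four convolutional layers
#' with 64 filters, kernel 7 and dilation 7. Every convolution is followed by
#' batch normalization, a rectified-linear activation and max pooling (2x2
#' for the 2-D branch, width/stride 4 for the 1-D branch; pooling keeps a
#' partial final window so any input length survives). The flattened branch
#' outputs are concatenated and passed through two fully connected layers
#' (512 then `embed_dim`), and the result is L2-normalized.
#'
#' The network can be built with both branches or either one alone; the
#' MI-only variant is the strongest performer on most stimulus tasks.
#'
#' @param variant `"mi"`, `"sdm"` or `"both"` — which feature branches the
#'   network consumes.
#' @param mi_len Number of columns of the MI feature matrix (segment samples
#'   minus one). Required for variants using MI.
#' @param sdm_size Side length of the (square) SDM input grid.
#' @param n_filters Filters per convolutional layer.
#' @param kernel_1d,dilation_1d Kernel size and dilation of the 1-D branch.
#' @param kernel_2d Kernel size of the 2-D branch (dilation 1).
#' @param fc_hidden Width of the first fully connected layer.
#' @param embed_dim Embedding dimension.
#' @param n_layers Convolutional layers per branch.
#' @param seed Seed for weight initialization.
#'
#' @return An object of class `gaze_embedder` holding the weights, batch
#'   norm running statistics and the architecture description.
#' @export
gaze_embedder <- function(variant = c("mi", "sdm", "both"), mi_len = NULL,
                          sdm_size = 128, n_filters = 64, kernel_1d = 7,
                          dilation_1d = 7, kernel_2d = 5, fc_hidden = 512,
                          embed_dim = 128, n_layers = 4, seed = 1) {
  variant <- match.arg(variant)
  use_mi <- variant %in% c("mi", "both")
  use_sdm <- variant %in% c("sdm", "both")
  if (use_mi && (is.null(mi_len) || mi_len < 1))
    stop("mi_len must be given for MI-consuming variants")
  set.seed(seed)
  par <- list()
  stat <- list()
  flat <- 0L

  if (use_mi) {
    L <- mi_len
    cin <- 2L
    for (i in seq_len(n_layers)) {
      fan <- cin * kernel_1d
      par[[paste0("mi", i)]] <- list(
        W = .he_init(n_filters, fan, fan), b = numeric(n_filters),
        g = rep(1, n_filters), beta = numeric(n_filters))
      stat[[paste0("mi", i)]] <- list(mean = numeric(n_filters),
                                      var = rep(1, n_filters))
      cin <- n_filters
      L <- ceiling(L / 4)
    }
    flat <- flat + n_filters * L
    mi_flat <- n_filters * L
  } else mi_flat <- 0L

  if (use_sdm) {
    H <- sdm_size
    cin <- 1L
    for (i in seq_len(n_layers)) {
      fan <- cin * kernel_2d^2
      par[[paste0("sdm", i)]] <- list(
        W = .he_init(n_filters, fan, fan), b = numeric(n_filters),
        g = rep(1, n_filters), beta = numeric(n_filters))
      stat[[paste0("sdm", i)]] <- list(mean = numeric(n_filters),
                                       var = rep(1, n_filters))
      cin <- n_filters
      H <- ceiling(H / 2)
    }
    flat <- flat + n_filters * H * H
  }

  par$fc1 <- list(W = .he_init(fc_hidden, flat, flat), b = numeric(fc_hidden))
  par$fc2 <- list(W = .he_init(embed_dim, fc_hidden, fc_hidden),
                  b = numeric(embed_dim))

  structure(list(par = par, stat = stat,
                 spec = list(variant = variant, mi_len = mi_len,
                             sdm_size = sdm_size, n_filters = n_filters,
                             kernel_1d = kernel_1d, dilation_1d = dilation_1d,
                             kernel_2d = kernel_2d, fc_hidden = fc_hidden,
                             embed_dim = embed_dim, n_layers = n_layers,
                             mi_flat = mi_flat, flat = flat)),
            class = "gaze_embedder")
}

#' @export
print.gaze_embedder <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "Two-branch gaze embedder (variant %s): %d conv layers/branch, %d filters,\n  fusion %d -> %d -> %d, L2-normalized output\n",
    s$variant, s$n_layers, s$n_filters, s$flat, s$fc_hidden, s$embed_dim))
  invisible(x)
}

# full forward pass; returns embeddings (batch x dim) and, in training mode,
# the caches needed for backpropagation
.net_fw <- function(model, mi = NULL, sdm = NULL, train = FALSE) {
  s <- model$spec
  par <- model$par
  caches <- list()
  parts <- list()
  B <- NULL

  if (s$variant %in% c("mi", "both")) {
    if (is.null(mi)) stop("this model requires an MI input")
    if (dim(mi)[2] != s$mi_len)
      stop(sprintf("MI input length %d does not match the model's %d",
                   dim(mi)[2], s$mi_len))
    B <- dim(mi)[3]
    X <- mi
    for (i in seq_len(s$n_layers)) {
      nm <- paste0("mi", i)
      bl <- .block1d_fw(X, par[[nm]], model$stat[[nm]], s$kernel_1d,
                        s$dilation_1d, 4L, train)
      X <- bl$out
      caches[[nm]] <- bl$cache
      model$stat[[nm]] <- bl$stat
    }
    dim(X) <- c(s$mi_flat, B)
    parts$mi <- X
  }

  if (s$variant %in% c("sdm", "both")) {
    if (is.null(sdm)) stop("this model requires an SDM input")
    B2 <- dim(sdm)[3]
    if (!is.null(B) && B2 != B) stop("MI and SDM batch sizes differ")
    B <- B2
    X <- sdm
    H <- W <- s$sdm_size
    for (i in seq_len(s$n_layers)) {
      nm <- paste0("sdm", i)
      bl <- .block2d_fw(X, H, W, par[[nm]], model$stat[[nm]], s$kernel_2d,
                        1L, 2L, train)
      X <- bl$out
      H <- bl$H
      W <- bl$W
      caches[[nm]] <- bl$cache
      model$stat[[nm]] <- bl$stat
    }
    dim(X) <- c(s$flat - s$mi_flat, B)
    parts$sdm <- X
  }

  Z <- do.call(rbind, unname(parts))
  H1 <- .fc_fw(Z, par$fc1$W, par$fc1$b)
  M1 <- H1 > 0
  A1 <- H1 * M1
  H2 <- .fc_fw(A1, par$fc2$W, par$fc2$b)
  nrmd <- .l2norm_fw(H2)
  caches$fuse <- list(Z = Z, M1 = M1, A1 = A1, Y = nrmd$y, nrm = nrmd$nrm)
  list(emb = t(nrmd$y), caches = caches, model = model, B = B)
}

# backpropagate dEmb (batch x dim) through the network; returns gradients
# shaped like model$par
.net_bw <- function(model, caches, dEmb) {
  s <- model$spec
  par <- model$par
  grads <- list()
  fz <- caches$fuse
  dH2 <- .l2norm_bw(t(dEmb), fz$Y, fz$nrm)
  g2 <- .fc_bw(dH2, fz$A1, par$fc2$W)
  grads$fc2 <- list(W = g2$dW, b = g2$db)
  dA1 <- g2$dX * fz$M1
  g1 <- .fc_bw(dA1, fz$Z, par$fc1$W)
  grads$fc1 <- list(W = g1$dW, b = g1$db)
  dZ <- g1$dX
  B <- ncol(dZ)

  if (s$variant %in% c("mi", "both")) {
    dX <- dZ[seq_len(s$mi_flat), , drop = FALSE]
    nm_last <- paste0("mi", s$n_layers)
    Lo <- s$mi_flat / s$n_filters
    dim(dX) <- c(s$n_filters, Lo, B)
    for (i in rev(seq_len(s$n_layers))) {
      nm <- paste0("mi", i)
      bw <- .block1d_bw(dX, caches[[nm]], par[[nm]], s$kernel_1d,
                        s$dilation_1d)
      grads[[nm]] <- bw$grads
      dX <- bw$dX
    }
  }
  if (s$variant %in% c("sdm", "both")) {
    dX <- dZ[(s$mi_flat + 1):nrow(dZ), , drop = FALSE]
    HWo <- (s$flat - s$mi_flat) / s$n_filters
    dim(dX) <- c(s$n_filters, HWo, B)
    for (i in rev(seq_len(s$n_layers))) {
      nm <- paste0("sdm", i)
      bw <- .block2d_bw(dX, caches[[nm]], par[[nm]], s$kernel_2d, 1L)
      grads[[nm]] <- bw$grads
      dX <- bw$dX
    }
  }
  grads
}

#' Embed eye-movement features
#'
#' Runs the network in evaluation mode (batch norm uses running statistics,
#' so output is deterministic given weights and inputs) and returns one
#' unit-norm embedding per sample. Inputs are processed in chunks to bound
#' memory.
#'
#' @param model A [gaze_embedder()] or a fitted `gazeauth_model`.
#' @param mi MI inputs: an array `(2, mi_len, n)`, a single `mi_feature`, or
#'   a list of them.
#' @param sdm SDM inputs: an array `(1, size^2, n)`, a single `sdm`, or a
#'   list of them.
#' @param chunk Samples per forward pass.
#' @return A numeric matrix (n x embed_dim) with unit-norm rows.
#' @export
embed <- function(model, mi = NULL, sdm = NULL, chunk = 16) {
  if (inherits(model, "gazeauth_model")) model <- model$model
  stopifnot(inherits(model, "gaze_embedder"))
  s <- model$spec
  mi <- .as_mi_array(mi, s)
  sdm <- .as_sdm_array(sdm, s)
  n <- if (!is.null(mi)) dim(mi)[3] else dim(sdm)[3]
  if (is.null(n)) stop("at least one input must be supplied")
  out <- matrix(0, n, s$embed_dim)
  for (from in seq(1, n, by = chunk)) {
    to <- min(from + chunk - 1, n)
    fw <- .net_fw(model,
                  mi = if (!is.null(mi)) mi[, , from:to, drop = FALSE],
                  sdm = if (!is.null(sdm)) sdm[, , from:to, drop = FALSE],
                  train = FALSE)
    out[from:to, ] <- fw$emb
  }
  out
}

.as_mi_array <- function(mi, s) {
  if (is.null(mi)) return(NULL)
  if (inherits(mi, "mi_feature")) mi <- list(mi)
  if (is.list(mi)) {
    arr <- array(0, c(2, s$mi_len, length(mi)))
    for (i in seq_along(mi)) arr[, , i] <- mi[[i]]$channels
    return(arr)
  }
  if (length(dim(mi)) == 2) dim(mi) <- c(dim(mi), 1)
  mi
}

.as_sdm_array <- function(sdm, s) {
  if (is.null(sdm)) return(NULL)
  if (inherits(sdm, "sdm")) sdm <- list(sdm)
  if (is.list(sdm)) {
    arr <- array(0, c(1, s$sdm_size^2, length(sdm)))
    for (i in seq_along(sdm)) arr[1, , i] <- as.numeric(sdm[[i]]$grid)
    return(arr)
  }
  if (length(dim(sdm)) == 2) dim(sdm) <- c(1, prod(dim(sdm)), 1)
  sdm
}
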