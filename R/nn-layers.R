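# Internal building blocks of the embedding network. Activations are stored
# as arrays (channels, positions, batch); convolution and pooling kernels are
# compiled (src/convnet.cpp), batch norm / ReLU / fully connected layers and
# the L2-normalization head live here.

.he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

.bn_fw <- function(X, g, b, train, stat, momentum = 0.1, eps = 1e-5) {
  d <- dim(X)
  Xm <- X
  dim(Xm) <- c(d[1], prod(d[-1]))
  if (train) {
    mu <- rowMeans(Xm)
    va <- rowMeans(Xm^2) - mu^2
    stat$mean <- (1 - momentum) * stat$mean + momentum * mu
    stat$var <- (1 - momentum) * stat$var + momentum * va
  } else {
    mu <- stat$mean
    va <- stat$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (Xm - mu) * invstd
  Y <- g * xhat + b
  dim(Y) <- d
  list(y = Y, xhat = xhat, invstd = invstd, stat = stat)
}

.bn_bw <- function(dY, xhat, invstd, g) {
  d <- dim(dY)
  dYm <- dY
  dim(dYm) <- c(d[1], prod(d[-1]))
  dbeta <- rowSums(dYm)
  dg <- rowSums(dYm * xhat)
  dxhat <- dYm * g
  dX <- invstd * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  dim(dX) <- d
  list(dX = dX, dg = dg, dbeta = dbeta)
}

# one convolutional block: conv -> batch norm -> ReLU -> max pool
.block1d_fw <- function(X, par, stat, K, dil, pool, train) {
  Y <- .conv1d_fw(X, par$W, par$b, K, dil)
  bn <- .bn_fw(Y, par$g, par$beta, train, stat)
  mask <- bn$y > 0
  A <- bn$y * mask
  pl <- .maxpool1d_fw(A, pool, pool)
  list(out = pl$y,
       cache = list(X = X, xhat = bn$xhat, invstd = bn$invstd, mask = mask,
                    idx = pl$idx, C = dim(A)[1], L = dim(A)[2]),
       stat = bn$stat)
}

.block1d_bw <- function(dOut, cache, par, K, dil) {
  dA <- .maxpool1d_bw(dOut, cache$idx, cache$C, cache$L)
  dA <- dA * cache$mask
  bn <- .bn_bw(dA, cache$xhat, cache$invstd, par$g)
  cv <- .conv1d_bw(cache$X, par$W, bn$dX, K, dil)
  list(dX = cv$dX,
       grads = list(W = cv$dW, b = as.vector(cv$db), g = bn$dg,
                    beta = bn$dbeta))
}

.block2d_fw <- function(X, H, W, par, stat, K, dil, pool, train) {
  Y <- .conv2d_fw(X, par$W, par$b, H, W, K, K, dil)
  bn <- .bn_fw(Y, par$g, par$beta, train, stat)
  mask <- bn$y > 0
  A <- bn$y * mask
  pl <- .maxpool2d_fw(A, H, W, pool, pool)
  list(out = pl$y, H = ceiling(H / pool), W = ceiling(W / pool),
       cache = list(X = X, H = H, W = W, xhat = bn$xhat,
                    invstd = bn$invstd, mask = mask, idx = pl$idx,
                    C = dim(A)[1], HW = dim(A)[2]),
       stat = bn$stat)
}

.block2d_bw <- function(dOut, cache, par, K, dil) {
  dA <- .maxpool2d_bw(dOut, cache$idx, cache$C, cache$HW)
  dA <- dA * cache$mask
  bn <- .bn_bw(dA, cache$xhat, cache$invstd, par$g)
  cv <- .conv2d_bw(cache$X, par$W, bn$dX, cache$H, cache$W, K, K, dil)
  list(dX = cv$dX,
       grads = list(W = cv$dW, b = as.vector(cv$db), g = bn$dg,
                    beta = bn$dbeta))
}

.fc_fw <- function(X, W, b) W %*% X + b

.fc_bw <- function(dY, X, W) {
  list(dX = crossprod(W, dY), dW = tcrossprod(dY, X), db = rowSums(dY))
}

.l2norm_fw <- function(X) {
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  list(y = sweep(X, 2, nrm, "/"), nrm = nrm)
}

.l2norm_bw <- function(dY, Y, nrm) {
  dots <- colSums(Y * dY)
  sweep(dY - sweep(Y, 2, dots, "*"), 2, nrm, "/")
}
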