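ms_labels <- c(1, 1, 2, 2, 3)

test_that("multi-similarity loss vanishes for perfectly separated clusters", {
  emb <- rbind(c(1, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 1, 0, 0))
  l <- multisimilarity_loss(emb, c("a", "a", "b", "b"))
  expect_lt(l$loss, 1e-3)
  expect_equal(l$loss, 0)
})

test_that("multi-similarity loss matches a hand-computed value", {
  # batch of 4, 2 classes; similarities fixed by construction:
  # e1.e2 = 1 (genuine), e1.e3 = e1.e4 = 0.6 (imposters above base)
  a <- sqrt(c(0.5, 0.5, 0))
  emb <- rbind(c(1, 0, 0), c(1, 0, 0),
               c(0.6, 0.8, 0), c(0.6, -0.8, 0))
  labs <- c(1, 1, 2, 2)
  S <- tcrossprod(emb)
  l <- multisimilarity_loss(emb, labs, alpha = 2, beta = 50, base = 0.5,
                            eps = 0.1)
  # manual: anchors 1,2 mine no positives (s=1 >= 0.6+0.1) but both
  # negatives (0.6 > 1-0.1 is false) -> negatives kept iff s_in > 1-0.1=0.9:
  # none. anchors 3,4: positive s=-0.28 < max_neg 0.6+0.1 -> kept;
  # negatives 0.6 > min_pos-0.1 -> kept.
  p34 <- log(1 + exp(-2 * (S[3, 4] - 0.5))) / 2
  n3 <- log(1 + sum(exp(50 * (S[3, 1:2] - 0.5)))) / 50
  manual <- (2 * p34 + 2 * n3) / 4
  expect_equal(l$loss, manual, tolerance = 1e-12)
})

test_that("multi-similarity loss is permutation invariant and needs 2 classes", {
  set.seed(20)
  emb <- matrix(rnorm(6 * 8), 6, 8)
  emb <- emb / sqrt(rowSums(emb^2))
  labs <- c(1, 1, 2, 2, 3, 3)
  l0 <- multisimilarity_loss(emb, labs)$loss
  for (i in 1:5) {
    p <- sample(6)
    expect_equal(multisimilarity_loss(emb[p, ], labs[p])$loss, l0,
                 tolerance = 1e-12)
  }
  expect_error(multisimilarity_loss(emb, rep(1, 6)), "single class")
})

test_that("analytic multi-similarity gradients match finite differences", {
  set.seed(21)
  emb <- matrix(rnorm(5 * 6), 5, 6)
  emb <- emb / sqrt(rowSums(emb^2))
  l <- multisimilarity_loss(emb, ms_labels)
  eps <- 1e-6
  for (i in sample(length(emb), 20)) {
    ep <- emb; ep[i] <- ep[i] + eps
    em <- emb; em[i] <- em[i] - eps
    fd <- (multisimilarity_loss(ep, ms_labels)$loss -
             multisimilarity_loss(em, ms_labels)$loss) / (2 * eps)
    expect_equal(l$grad[i], fd, tolerance = 1e-4)
  }
})

test_that("arcface with zero margin and unit scale is softmax cross-entropy", {
  set.seed(22)
  emb <- matrix(rnorm(5 * 6), 5, 6)
  emb <- emb / sqrt(rowSums(emb^2))
  W <- matrix(rnorm(3 * 6), 3, 6)
  labs <- c(1, 2, 3, 1, 2)
  got <- arcface_loss(emb, labs, W, margin = 0, scale = 1)$loss
  Wn <- W / sqrt(rowSums(W^2))
  logits <- emb %*% t(Wn)
  want <- mean(-logits[cbind(1:5, labs)] + log(rowSums(exp(logits))))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("arcface matches the closed form for an aligned sample", {
  W <- rbind(c(1, 0, 0), c(0, 1, 0))
  e <- matrix(c(1, 0, 0), 1)
  got <- arcface_loss(e, 1L, W, margin = 0.5, scale = 64)$loss
  want <- -log(exp(64 * cos(0.5)) / (exp(64 * cos(0.5)) + 1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("arcface loss decreases as the sample aligns with its class", {
  W <- rbind(c(1, 0), c(-1, 0))
  angles <- seq(1.2, 0.1, by = -0.1)
  # moderate scale keeps the softmax away from float saturation
  losses <- vapply(angles, function(a)
    arcface_loss(matrix(c(cos(a), sin(a)), 1), 1L, W, scale = 4)$loss,
    numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("analytic arcface gradients match finite differences", {
  set.seed(23)
  emb <- matrix(rnorm(5 * 6), 5, 6)
  emb <- emb / sqrt(rowSums(emb^2))
  W <- matrix(rnorm(3 * 6), 3, 6)
  labs <- c(1, 2, 3, 1, 2)
  l <- arcface_loss(emb, labs, W)
  eps <- 1e-6
  for (i in sample(length(emb), 15)) {
    ep <- emb; ep[i] <- ep[i] + eps
    em <- emb; em[i] <- em[i] - eps
    fd <- (arcface_loss(ep, labs, W)$loss -
             arcface_loss(em, labs, W)$loss) / (2 * eps)
    expect_equal(l$grad[i], fd, tolerance = 1e-4)
  }
  for (i in sample(length(W), 15)) {
    wp <- W; wp[i] <- wp[i] + eps
    wm <- W; wm[i] <- wm[i] - eps
    fd <- (arcface_loss(emb, labs, wp)$loss -
             arcface_loss(emb, labs, wm)$loss) / (2 * eps)
    expect_equal(l$grad_weights[i], fd, tolerance = 1e-4)
  }
})

test_that("labels outside the class range are rejected", {
  W <- matrix(rnorm(6), 2, 3)
  expect_error(arcface_loss(matrix(1:3 / sqrt(14), 1), 5L, W), "class range")
})
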