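# Exact t-SNE (van der Maaten & Hinton's formulation): Gaussian input
# affinities calibrated to a target perplexity by binary search, Student-t
# output kernel, gradient descent with momentum and early exaggeration.
# O(N^2) — intended for cohort-scale inputs (a few thousand points).

# Per-point conditional affinities at the requested perplexity.
tsne_input_p <- function(X, perplexity) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(X), 0)
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { H <- 0 } else {
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-di * beta)
    P[i, -i] <- w / max(sum(w), .Machine$double.eps)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

tsne_exact <- function(X, perplexity = 30, seed = 0L, max_iter = 500L,
                       eta = 200, exaggeration = 12, exag_iter = 100L) {
  X <- as.matrix(X)
  n <- nrow(X)
  X <- scale(X, center = TRUE, scale = FALSE)
  if (ncol(X) > 50) {
    X <- X %*% svd(X, nu = 0, nv = 50)$v
  }
  P <- tsne_input_p(X, perplexity)

  # PCA initialization scaled small, plus a tiny seeded jitter to break ties
  sv <- svd(X, nu = 2, nv = 0)
  Y <- sv$u %*% diag(sv$d[1:2], 2)
  Y <- Y / stats::sd(Y[, 1]) * 1e-4
  Y <- Y + with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-6), n, 2))

  V <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  Pe <- P * exaggeration
  for (it in seq_len(max_iter)) {
    Puse <- if (it <= exag_iter) Pe else P
    sq <- rowSums(Y^2)
    num <- 1 / (1 + pmax(outer(sq, sq, "+") - 2 * tcrossprod(Y), 0))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Puse - Q) * num
    G <- 4 * (diag(rowSums(L)) - L) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- ifelse(sign(G) != sign(V), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    V <- mom * V - eta * gains * G
    Y <- Y + V
    Y <- scale(Y, center = TRUE, scale = FALSE)
  }
  Y
}
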