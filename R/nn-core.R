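#' @useDynLib cryptflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- seeded RNG helpers -----------------------------------------------------

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package internals never
#' perturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Deterministically derive a stage seed from a master seed and a tag,
# keeping the result inside the 32-bit integer range.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

# ---- array helpers ----------------------------------------------------------

# Promote a single [H,W,C] array to a 1-sample batch [H,W,C,1].
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  array(x, c(d[1:3], 1L))
}

# Stack a list of [H,W,C] arrays into [H,W,C,N].
stack_batch <- function(lst) {
  d <- dim(lst[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  out <- array(0, c(d, length(lst)))
  for (i in seq_along(lst)) out[, , , i] <- lst[[i]]
  out
}

# Concatenate two batches along the channel axis.
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- layers -----------------------------------------------------------------

# He-initialized conv parameters.
conv_init <- function(kh, kw, cin, cout) {
  sd <- sqrt(2 / (kh * kw * cin))
  list(w = array(stats::rnorm(kh * kw * cin * cout, sd = sd),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

conv_fwd <- function(x, par, stride = 1L, pad = 1L) {
  nn_conv_forward(x, par$w, par$b, as.integer(stride), as.integer(pad))
}

conv_bwd <- function(x, par, dy, stride = 1L, pad = 1L) {
  nn_conv_backward(x, par$w, dy, as.integer(stride), as.integer(pad))
}

relu_fwd <- function(z) {
  a <- z
  a[a < 0] <- 0
  a
}

relu_bwd <- function(z, da) {
  da * (z > 0)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable mean binary cross-entropy on logits, with gradient.
# pos_weight > 1 up-weights foreground pixels (class-imbalance guard for
# segmentation; glands cover ~10% of a slide).
# loss_i = pos_weight * t * softplus(-z) + (1 - t) * softplus(z)
bce_with_logits <- function(z, target, pos_weight = 1) {
  spp <- pmax(-z, 0) + log1p(exp(-abs(z)))  # softplus(-z) = -log sigmoid(z)
  spn <- pmax(z, 0) + log1p(exp(-abs(z)))   # softplus(z)
  loss <- mean(pos_weight * target * spp + (1 - target) * spn)
  s <- sigmoid(z)
  dz <- (pos_weight * target * (s - 1) + (1 - target) * s) / length(z)
  dim(dz) <- dim(z)
  list(loss = loss, dz = dz)
}

# ---- Adam over nested parameter lists ---------------------------------------

# Parameters are nested lists whose leaves are numeric arrays; gradients
# share the exact same shape. State holds first/second moments per leaf.
adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk)
    else list(m = array(0, dim = if (is.null(dim(p))) length(p) else dim(p)),
              v = array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  }
  list(t = 0L, mv = walk(params))
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  walk <- function(p, g, s) {
    if (is.list(p)) {
      for (k in seq_along(p)) {
        res <- walk(p[[k]], g[[k]], s[[k]])
        p[[k]] <- res$p; s[[k]] <- res$s
      }
      return(list(p = p, s = s))
    }
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    step <- lr * (s$m / bc1) / (sqrt(s$v / bc2) + eps)
    dim(step) <- dim(p)
    list(p = p - step, s = s)
  }
  res <- walk(params, grads, state$mv)
  list(params = res$p, state = list(t = state$t, mv = res$s))
}

# Elementwise sum of two gradient trees.
grad_add <- function(a, b) {
  if (is.list(a)) {
    for (k in seq_along(a)) a[[k]] <- grad_add(a[[k]], b[[k]])
    a
  } else a + b
}

# Count scalar parameters in a nested parameter list.
n_params <- function(params) {
  if (is.list(params)) sum(vapply(params, n_params, numeric(1)))
  else length(params)
}
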