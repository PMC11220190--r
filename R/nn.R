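# Minimal dense-prediction network primitives.
#
# Layers operate on H x W x C arrays. Convolutions are same-padding,
# stride 1, with weights stored as (K*K*Cin) x Cout matrices matching the
# C++ im2col column order. Parameter collections are nested lists whose
# leaves are list(W, b, k); gradients and momentum buffers mirror that
# structure exactly.

init_conv <- function(cin, cout, k = 3L) {
  # He initialization for ReLU networks
  sd <- sqrt(2 / (k * k * cin))
  list(W = matrix(rnorm(k * k * cin * cout, sd = sd), k * k * cin, cout),
       b = numeric(cout), k = as.integer(k))
}

conv_fw <- function(x, p) cpp_conv2d_fw(x, p$W, p$b, p$k)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Double 3x3 conv + ReLU block.
dconv_fw <- function(x, p1, p2) {
  a1 <- conv_fw(x, p1)
  r1 <- relu(a1)
  a2 <- conv_fw(r1, p2)
  r2 <- relu(a2)
  list(out = r2, cache = list(x = x, m1 = a1 > 0, r1 = r1, m2 = a2 > 0))
}

dconv_bw <- function(g, cache, p1, p2) {
  g2 <- g * cache$m2
  b2 <- cpp_conv2d_bw(cache$r1, p2$W, g2, p2$k)
  g1 <- b2$gx * cache$m1
  b1 <- cpp_conv2d_bw(cache$x, p1$W, g1, p1$k)
  list(gx = b1$gx,
       g1 = list(W = b1$gW, b = as.numeric(b1$gb)),
       g2 = list(W = b2$gW, b = as.numeric(b2$gb)))
}

softmax2 <- function(logits) {
  m <- pmax(logits[, , 1], logits[, , 2])
  e1 <- exp(logits[, , 1] - m)
  e2 <- exp(logits[, , 2] - m)
  s <- e1 + e2
  array(c(e1 / s, e2 / s), dim(logits))
}

# ---- parameter-tree helpers ------------------------------------------------

is_param_leaf <- function(x) is.list(x) && !is.null(x$W)

tree_map <- function(f, tree) {
  if (is_param_leaf(tree)) return(f(tree))
  lapply(tree, tree_map, f = f)
}

tree_map2 <- function(f, a, b) {
  if (is_param_leaf(a)) return(f(a, b))
  out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
  out
}

zero_like <- function(tree) {
  tree_map(function(p) list(W = p$W * 0, b = p$b * 0), tree)
}

tree_add <- function(a, b) {
  tree_map2(function(x, y) list(W = x$W + y$W, b = x$b + y$b), a, b)
}

tree_scale <- function(tree, s) {
  tree_map(function(p) list(W = p$W * s, b = p$b * s), tree)
}

n_params <- function(tree) {
  total <- 0
  walk <- function(t) {
    if (is_param_leaf(t)) {
      total <<- total + length(t$W) + length(t$b)
    } else {
      lapply(t, walk)
    }
    invisible(NULL)
  }
  walk(tree)
  total
}

# Classical momentum SGD; returns updated params and velocity.
sgd_step <- function(params, grads, vel, lr, momentum) {
  new_vel <- tree_map2(function(v, g) {
    list(W = momentum * v$W + g$W, b = momentum * v$b + g$b)
  }, vel, grads)
  new_par <- tree_map2(function(p, v) {
    p$W <- p$W - lr * v$W
    p$b <- p$b - lr * v$b
    p
  }, params, new_vel)
  list(params = new_par, vel = new_vel)
}
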