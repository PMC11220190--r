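# Independent brute-force oracles: literal pixel/class loops, sharing no
# code with the implementation they check.

oracle_ce <- function(probs, target) {
  H <- dim(probs)[1]; W <- dim(probs)[2]
  y <- if (length(dim(target)) == 3) target else {
    a <- array(0, dim(probs))
    for (i in 1:H) for (j in 1:W) a[i, j, target[i, j] + 1] <- 1
    a
  }
  total <- 0
  for (i in 1:H) for (j in 1:W) for (c in 1:2) {
    p <- min(max(probs[i, j, c], 1e-7), 1 - 1e-7)
    total <- total - y[i, j, c] * log(p)
  }
  total / (H * W)
}

oracle_dice <- function(probs, target, eps = 1e-5) {
  H <- dim(probs)[1]; W <- dim(probs)[2]
  y <- if (length(dim(target)) == 3) target else {
    a <- array(0, dim(probs))
    for (i in 1:H) for (j in 1:W) a[i, j, target[i, j] + 1] <- 1
    a
  }
  vals <- numeric(2)
  for (c in 1:2) {
    inter <- 0; sp <- 0; sy <- 0
    for (i in 1:H) for (j in 1:W) {
      inter <- inter + probs[i, j, c] * y[i, j, c]
      sp <- sp + probs[i, j, c]
      sy <- sy + y[i, j, c]
    }
    vals[c] <- 1 - (2 * inter + eps) / (sp + sy + eps)
  }
  mean(vals)
}

# naive double loop over ordered decoder pairs
oracle_multi_consistency <- function(maps, Temp = 0.5, mode = "hard") {
  n <- length(maps)
  if (n < 2) return(0)
  soft <- lapply(maps, function(m) {
    p <- matrix(m[, , 2], dim(m)[1], dim(m)[2])
    p^(1 / Temp) / (p^(1 / Temp) + (1 - p)^(1 / Temp))
  })
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    target <- if (mode == "hard") {
      matrix(as.integer(soft[[j]] > 0.5), nrow(soft[[j]]))
    } else {
      array(c(1 - soft[[j]], soft[[j]]), dim(maps[[i]]))
    }
    total <- total + oracle_ce(maps[[i]], target) +
      oracle_dice(maps[[i]], target)
  }
  total
}

random_prob_map <- function(H, W) {
  p <- matrix(runif(H * W), H, W)
  array(c(1 - p, p), c(H, W, 2))
}

tiny_cube <- function(H = 4, W = 4, C = 3, seed = 1) {
  set.seed(seed)
  hyper_cube(array(runif(H * W * C), c(H, W, C)),
             seq(550, 1000, length.out = C), "tiny")
}

# connected components of a binary mask, 4-connectivity (for ring checks)
n_components <- function(mask) {
  m <- unclass(mask)
  lab <- matrix(0L, nrow(m), ncol(m))
  comp <- 0L
  for (si in seq_len(nrow(m))) for (sj in seq_len(ncol(m))) {
    if (m[si, sj] == 1L && lab[si, sj] == 0L) {
      comp <- comp + 1L
      queue <- list(c(si, sj))
      lab[si, sj] <- comp
      while (length(queue)) {
        q <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          ni <- q[1] + d[1]; nj <- q[2] + d[2]
          if (ni >= 1 && ni <= nrow(m) && nj >= 1 && nj <= ncol(m) &&
              m[ni, nj] == 1L && lab[ni, nj] == 0L) {
            lab[ni, nj] <- comp
            queue <- c(queue, list(c(ni, nj)))
          }
        }
      }
    }
  }
  comp
}
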