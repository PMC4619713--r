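# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a root seed and a layer index.
# Keeps results < 2^31 so they are valid R integer seeds.
derive_seed <- function(seed, layer) {
  as.integer((as.numeric(seed) * 48271 + layer * 1299721) %% 2147483647L)
}

# Separable Gaussian smoothing of a matrix with replicate padding.
# `sigma` in cells; used to build smooth random fields and depth undulation.
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    stats::convolve(vp, rev(k), type = "filter")
  }
  m <- apply(m, 2, pad_conv)
  t(apply(t(m), 2, pad_conv))
}

# Survival function Q(lambda) of the Kolmogorov distribution,
# computed from the Jacobi-theta representation
#   Q(lambda) = 1 - sqrt(2*pi)/lambda * sum_{k>=1} exp(-(2k-1)^2 pi^2 / (8 lambda^2)),
# which converges quickly over the whole range needed here.
kolmogorov_q <- function(lambda) {
  vapply(lambda, function(l) {
    if (!is.finite(l)) return(NA_real_)
    if (l <= 1e-8) return(1)
    k <- 1:50
    s <- sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * l^2)))
    q <- 1 - sqrt(2 * pi) / l * s
    min(max(q, 0), 1)
  }, numeric(1))
}

# Connected components of a logical matrix under 4-connectivity.
# Returns an integer matrix of component labels (0 = background).
# Simple two-pass union-find; grids here are modest so base R suffices.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!mask[i, j]) next
      up <- if (i > 1L && mask[i - 1L, j]) lab[i - 1L, j] else 0L
      lt <- if (j > 1L && mask[i, j - 1L]) lab[i, j - 1L] else 0L
      if (up == 0L && lt == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else if (up != 0L && lt != 0L) {
        ru <- find(up); rl <- find(lt)
        lab[i, j] <- ru
        if (ru != rl) parent[rl] <- ru
      } else {
        lab[i, j] <- max(up, lt)
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relab <- match(roots, unique(roots))
    idx <- lab > 0L
    lab[idx] <- relab[lab[idx]]
  }
  lab
}
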