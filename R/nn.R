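## Minimal dense-network machinery (He-initialized ReLU stacks + Adam),
## shared by the variational latent model. All math is plain BLAS-backed
## matrix algebra; determinism comes from R's seeded RNG.

.nn_linear_init <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, 0, scale), n_in, n_out),
       b = rep(0, n_out))
}

.nn_mlp_init <- function(n_in, hidden, n_layers) {
  layers <- vector("list", n_layers)
  d <- n_in
  for (i in seq_len(n_layers)) {
    layers[[i]] <- .nn_linear_init(d, hidden)
    d <- hidden
  }
  layers
}

## forward through ReLU stack; returns output and per-layer caches
.nn_mlp_forward <- function(layers, X) {
  caches <- vector("list", length(layers))
  h <- X
  for (i in seq_along(layers)) {
    a <- h %*% layers[[i]]$W
    a <- sweep(a, 2, layers[[i]]$b, "+")
    caches[[i]] <- list(input = h, pre = a)
    h <- a * (a > 0)
  }
  list(out = h, caches = caches)
}

## backprop through ReLU stack; returns per-layer grads and input gradient
.nn_mlp_backward <- function(layers, caches, d_out) {
  grads <- vector("list", length(layers))
  d <- d_out
  for (i in rev(seq_along(layers))) {
    dA <- d * (caches[[i]]$pre > 0)
    grads[[i]] <- list(W = crossprod(caches[[i]]$input, dA),
                       b = colSums(dA))
    d <- tcrossprod(dA, layers[[i]]$W)
  }
  list(grads = grads, d_input = d)
}

## flat-list Adam; params/grads are nested lists of numeric arrays with
## identical shape
.adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in seq_along(p)) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t))
}

.softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Negative-binomial log-likelihood
#'
#' Log density of counts under NB with mean `mu` and inverse dispersion
#' (size) `theta`; as `theta -> Inf` this approaches the Poisson
#' log-likelihood.
#'
#' @param x counts.
#' @param mu means (same shape as `x`).
#' @param theta inverse dispersion (scalar or per-gene, recycled).
#' @return log-likelihood values, same shape as `x`.
#' @export
nb_loglik <- function(x, mu, theta) {
  mu <- pmax(mu, 1e-10)
  lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * log(theta / (theta + mu)) + x * log(mu / (theta + mu))
}
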