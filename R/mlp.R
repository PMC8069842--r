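# Internal two-hidden-layer MLP with tanh activations, exact backprop, and
# an AdamW optimizer.  Small fixed architecture; gradients are verified
# against finite differences in the test suite.

mlp_init <- function(d_in, hidden, d_out, last_zero = TRUE) {
  h1 <- hidden[1]; h2 <- hidden[2]
  sd1 <- 1 / sqrt(d_in); sd2 <- 1 / sqrt(h1); sd3 <- 1 / sqrt(h2)
  net <- list(
    W1 = matrix(stats::rnorm(h1 * d_in, sd = sd1), h1, d_in),
    b1 = numeric(h1),
    W2 = matrix(stats::rnorm(h2 * h1, sd = sd2), h2, h1),
    b2 = numeric(h2),
    W3 = if (last_zero) matrix(0, d_out, h2)
         else matrix(stats::rnorm(d_out * h2, sd = sd3), d_out, h2),
    b3 = numeric(d_out))
  net
}

# X: B x d_in matrix. Returns caches needed for the backward pass.
mlp_forward <- function(net, X) {
  Z1 <- tanh(sweep(X %*% t(net$W1), 2, net$b1, `+`))
  Z2 <- tanh(sweep(Z1 %*% t(net$W2), 2, net$b2, `+`))
  OUT <- sweep(Z2 %*% t(net$W3), 2, net$b3, `+`)
  list(X = X, Z1 = Z1, Z2 = Z2, out = OUT)
}

# G: B x d_out gradient of a scalar objective w.r.t. the outputs.
mlp_backward <- function(net, cache, G) {
  gW3 <- t(G) %*% cache$Z2
  gb3 <- colSums(G)
  G2 <- (G %*% net$W3) * (1 - cache$Z2^2)
  gW2 <- t(G2) %*% cache$Z1
  gb2 <- colSums(G2)
  G1 <- (G2 %*% net$W2) * (1 - cache$Z1^2)
  gW1 <- t(G1) %*% cache$X
  gb1 <- colSums(G1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

grads_scale <- function(g, s) lapply(g, function(x) x * s)

softmax_rows <- function(L) {
  M <- L - apply(L, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

entropy_rows <- function(P) {
  PL <- ifelse(P > 0, P * log(P), 0)
  -rowSums(PL)
}

adamw_init <- function(net) {
  list(m = lapply(net, function(x) x * 0), v = lapply(net, function(x) x * 0),
       t = 0L)
}

# Decoupled weight decay (AdamW); `maximize` flips to gradient ascent.
adamw_step <- function(net, grads, opt, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       maximize = FALSE) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(net)) {
    g <- grads[[nm]]
    if (maximize) g <- -g
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    step <- (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    net[[nm]] <- net[[nm]] - lr * (step + weight_decay * net[[nm]])
  }
  list(net = net, opt = opt)
}

flatten_params <- function(net) unlist(net, use.names = FALSE)

unflatten_params <- function(net, theta) {
  k <- 0L
  for (nm in names(net)) {
    n <- length(net[[nm]])
    net[[nm]][] <- theta[k + seq_len(n)]
    k <- k + n
  }
  net
}
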