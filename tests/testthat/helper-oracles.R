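# independent oracles, coded from scratch against textbook formulas; these
# share no code with the package implementation

# random-effects pooling, DerSimonian-Laird moment estimator
dl_pool_oracle <- function(beta, se) {
  k <- length(beta)
  w <- se^-2
  mu_fe <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - mu_fe)^2)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  mu <- sum(ws * beta) / sum(ws)
  list(mu = mu, se = sqrt(1 / sum(ws)), Q = Q, tau2 = tau2,
       I2 = max(0, (Q - (k - 1)) / Q) * 100)
}

# grid-search maximum likelihood for logistic y ~ b0 + b1 x, refined in stages
logistic_grid_oracle <- function(y, x) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * x
    sum(y * eta - log1p(exp(eta)))
  }
  ctr <- c(0, 0); width <- 8
  for (stage in 1:6) {
    b0s <- seq(ctr[1] - width, ctr[1] + width, length.out = 41)
    b1s <- seq(ctr[2] - width, ctr[2] + width, length.out = 41)
    vals <- outer(b0s, b1s, Vectorize(ll))
    best <- arrayInd(which.max(vals), dim(vals))
    ctr <- c(b0s[best[1]], b1s[best[2]])
    width <- width / 10
  }
  ctr
}

# brute-force haplotype-frequency ML for a 2-SNP panel: likelihood by direct
# enumeration of ordered haplotype pairs, maximized numerically over the
# simplex via a softmax parameterization with multiple starts
em_brute_force_2snp <- function(geno) {
  haps <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  negll <- function(theta) {
    f <- exp(c(0, theta)); f <- f / sum(f)
    ll <- 0
    for (i in seq_len(nrow(geno))) {
      p <- 0
      for (a in 1:4) for (b in 1:4) {
        if (all(haps[a, ] + haps[b, ] == geno[i, ])) p <- p + f[a] * f[b]
      }
      if (p <= 0) return(1e10)
      ll <- ll + log(p)
    }
    -ll
  }
  best <- NULL
  for (s in 1:8) {
    set.seed(1000 + s)
    fit <- stats::optim(stats::rnorm(3, 0, 2), negll, method = "BFGS",
                        control = list(maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  f <- exp(c(0, best$par)); f <- f / sum(f)
  names(f) <- apply(haps, 1, paste, collapse = "")
  f
}
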