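# Independent oracles, deliberately written as direct transcriptions of the
# definitions (loops, dense algebra) rather than reusing package internals.

# deterministic selection-mutation recursion for the equilibrium frequency of
# a deleterious allele: selection on HWE genotypes, then one-way mutation
msb_recursion_oracle <- function(mu, s, k, tol = 1e-13, max_iter = 5e6) {
  h <- (1 - k) / 2
  q <- 1e-5
  for (i in seq_len(max_iter)) {
    p <- 1 - q
    wbar <- 1 - s * q^2 - 2 * p * q * h * s
    q_sel <- (q^2 * (1 - s) + p * q * (1 - h * s)) / wbar
    q_new <- q_sel + mu * (1 - q_sel)
    if (abs(q_new - q) < tol) return(q_new)
    q <- q_new
  }
  q
}

# per-SNP brute-force block scorer: explicit loops over hybrids, blocks and
# member SNPs, with the 0 / (1+k) g / 2 g assignment
score_blocks_oracle <- function(f1, blocks, track, k_del, model) {
  gerp <- stats::setNames(track$gerp, track$site)
  keep <- which(blocks$n_gerp_snps > 0)
  out <- matrix(0, nrow(f1), length(keep),
                dimnames = list(rownames(f1), blocks$block[keep]))
  for (i in seq_len(nrow(f1))) {
    for (jj in seq_along(keep)) {
      total <- 0
      for (sid in blocks$sites[[keep[jj]]]) {
        g <- gerp[[sid]]
        if (g <= 0) next
        x <- f1[i, sid]
        if (is.na(x)) next
        kh <- switch(model,
                     additive = 0,
                     dominance = -1,
                     incomplete = {
                       kv <- k_del[[sid]]
                       if (is.null(kv) || is.na(kv)) 0 else min(max(kv, -1), 1)
                     })
        total <- total + switch(as.character(x),
                                "0" = 0,
                                "1" = (1 + kh) * g,
                                "2" = 2 * g)
      }
      out[i, jj] <- total
    }
  }
  out
}

# dense mixed-model-equation solver for the marker-effect BLUPs:
# [1'1      1'X          1'W        ] [mu]   [1'y]
# [X'1  X'X + I le/la    X'W        ] [al] = [X'y]
# [W'1      W'X      W'W + I le/ld  ] [d ]   [W'y]
mme_backsolve_oracle <- function(y, X, W, sigma2, sumA, sumD) {
  n <- length(y)
  la <- sigma2[["A"]] / sumA   # per-marker additive variance
  ld <- sigma2[["D"]] / sumD
  le <- sigma2[["E"]]
  one <- matrix(1, n, 1)
  C <- rbind(
    cbind(crossprod(one), crossprod(one, X), crossprod(one, W)),
    cbind(crossprod(X, one), crossprod(X) + diag(le / la, ncol(X)), crossprod(X, W)),
    cbind(crossprod(W, one), crossprod(W, X), crossprod(W) + diag(le / ld, ncol(W))))
  rhs <- rbind(crossprod(one, y), crossprod(X, y), crossprod(W, y))
  sol <- solve(C, rhs)
  list(mu = sol[1], alpha = sol[2:(1 + ncol(X))],
       d = sol[(2 + ncol(X)):nrow(sol)])
}

# closed-form ridge regression with intercept for the conjugate limit of the
# all-blocks-in BayesC model
ridge_oracle <- function(X, y, lambda) {
  Xc <- scale(X, scale = FALSE)
  b <- solve(crossprod(Xc) + diag(lambda, ncol(X)), crossprod(Xc, y))
  drop(b)
}
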