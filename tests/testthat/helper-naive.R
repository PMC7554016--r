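# Naive loop-based reference implementations used as independent oracles.
# They mirror the layer definitions pixel by pixel and stay deliberately
# independent of the package's vectorised/C++ code paths.

naive_conv2 <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  hr <- (nrow(k) - 1) / 2; hc <- (ncol(k) - 1) / 2
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    acc <- 0
    for (u in -hr:hr) for (v in -hc:hc) {
      rr <- r - u; cc <- c - v
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        acc <- acc + x[rr, cc] * k[u + hr + 1, v + hc + 1]
    }
    out[r, c] <- acc
  }
  out
}

naive_vdog <- function(P, params) {
  kk <- flyvis:::vdog_kernels(params)
  Pe <- naive_conv2(P, kk$e)
  Pi <- naive_conv2(P, kk$i)
  out <- matrix(0, nrow(P), ncol(P))
  for (r in seq_len(nrow(P))) for (c in seq_len(ncol(P))) {
    if (Pe[r, c] >= 0 && Pi[r, c] >= 0) out[r, c] <- abs(Pe[r, c] - Pi[r, c])
    else if (Pe[r, c] < 0 && Pi[r, c] < 0) out[r, c] <- -abs(Pe[r, c] - Pi[r, c])
  }
  out
}

naive_ds_maps <- function(M, Mhat, distances) {
  nr <- nrow(M); nc <- ncol(M)
  z <- matrix(0, nr, nc)
  out <- list(r = z, l = z, d = z, u = z)
  for (j in seq_along(distances)) {
    dd <- distances[j]
    Mh <- Mhat[[j]]
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (c + dd <= nc) {
        out$r[r, c] <- out$r[r, c] + Mh[r, c] * M[r, c + dd]
        out$l[r, c] <- out$l[r, c] + Mh[r, c + dd] * M[r, c]
      }
      if (r + dd <= nr) {
        out$d[r, c] <- out$d[r, c] + Mh[r, c] * M[r + dd, c]
        out$u[r, c] <- out$u[r, c] + Mh[r + dd, c] * M[r, c]
      }
    }
  }
  out
}

# Full per-frame pipeline on an array, scalar loops only.  Follows the same
# initialisation convention as run_model (first-frame outputs are zero).
naive_run_model <- function(frames, params) {
  R <- dim(frames)[1]; C <- dim(frames)[2]; T <- dim(frames)[3]
  frames <- frames / params$luminance_scale
  a <- flyvis::decay_coefficients(params$n_p)
  dists <- params$sd * seq_len(params$n_c)
  taus <- flyvis::dynamic_delay_tau(dists, params)
  a3 <- params$tau_i / (params$tau_i + taus)
  zero <- matrix(0, R, C)
  prevL <- frames[, , 1]
  Phist <- rep(list(zero), params$n_p)
  Lhat1 <- Lhat2 <- prev_L1 <- prev_L2 <- zero
  prev_M1 <- prev_M2 <- zero
  traces1 <- traces2 <- rep(list(zero), params$n_c)
  HS <- VS <- numeric(T)
  for (t in 2:T) {
    P <- frames[, , t] - prevL
    for (i in seq_along(a)) P <- P + a[i] * Phist[[i]]
    if (params$n_p > 0) Phist <- c(list(P), Phist[-params$n_p])
    prevL <- frames[, , t]
    LA <- if (params$enable_vdog) naive_vdog(P, params) else P
    L1 <- pmax(LA, 0); L2 <- -pmin(LA, 0)
    if (params$enable_fdsr) {
      al1 <- ifelse(L1 - prev_L1 >= 0, params$alpha1, params$alpha2)
      al2 <- ifelse(L2 - prev_L2 >= 0, params$alpha1, params$alpha2)
      base1 <- if (params$fdsr_recursive) Lhat1 else prev_L1
      base2 <- if (params$fdsr_recursive) Lhat2 else prev_L2
      Lhat1 <- al1 * L1 + (1 - al1) * base1
      Lhat2 <- al2 * L2 + (1 - al2) * base2
      M1 <- L1 - Lhat1; M2 <- L2 - Lhat2
      prev_L1 <- L1; prev_L2 <- L2
    } else {
      M1 <- L1; M2 <- L2
    }
    if (params$rectify_medulla) {
      M1 <- pmax(M1, 0); M2 <- pmax(M2, 0)
    }
    Mhat1 <- Mhat2 <- vector("list", params$n_c)
    for (j in seq_len(params$n_c)) {
      b1 <- if (params$delay_recursive) traces1[[j]] else prev_M1
      b2 <- if (params$delay_recursive) traces2[[j]] else prev_M2
      Mhat1[[j]] <- a3[j] * M1 + (1 - a3[j]) * b1
      Mhat2[[j]] <- a3[j] * M2 + (1 - a3[j]) * b2
    }
    traces1 <- Mhat1; traces2 <- Mhat2
    prev_M1 <- M1; prev_M2 <- M2
    T4 <- naive_ds_maps(M1, Mhat1, dists)
    T5 <- naive_ds_maps(M2, Mhat2, dists)
    LP <- c(r = 0, l = 0, d = 0, u = 0)
    for (d in names(LP)) {
      s <- 0
      for (r in seq_len(R)) for (c in seq_len(C))
        s <- s + T4[[d]][r, c] + T5[[d]][r, c]
      LP[d] <- s
    }
    HS[t] <- flyvis::activate(LP["r"] - LP["l"], params, C, R)
    VS[t] <- flyvis::activate(LP["d"] - LP["u"], params, C, R)
  }
  data.frame(HS = HS, VS = VS)
}
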