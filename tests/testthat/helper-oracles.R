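# Independent oracles, deliberately naive implementations that share no code
# with the package internals they check.

# --- exhaustive spanning-tree search ---------------------------------------
# all labelled trees on n nodes via Pruefer decoding
prufer_to_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_along(seq)) {
    leaf <- which(degree == 1L)[1]
    edges[k, ] <- c(leaf, seq[k])
    degree[leaf] <- degree[leaf] - 1L
    degree[seq[k]] <- degree[seq[k]] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

# maximum total weight over every spanning tree (n <= 7)
best_tree_weight <- function(w) {
  n <- nrow(w)
  if (n == 2) return(w[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- -Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_to_edges(seqs[r, ], n)
    tw <- sum(w[e])
    if (tw > best) best <- tw
  }
  best
}

# --- naive tree betweenness by path counting -------------------------------
# shortest paths in a tree are unique; walk every (s, t) pair
naive_tree_bc <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$i[k]; j <- edges$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  path <- function(s, t) {
    prev <- rep(NA_integer_, n); prev[s] <- s
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (u in adj[[v]]) if (is.na(prev[u])) { prev[u] <- v; q <- c(q, u) }
    }
    p <- t
    while (p[1] != s) p <- c(prev[p[1]], p)
    p
  }
  counts <- rep(0, n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    inner <- setdiff(path(s, t), c(s, t))
    counts[inner] <- counts[inner] + 1
  }
  counts / ((n - 1) * (n - 2) / 2)
}

# --- Mann-Whitney exact p by enumeration of all group assignments ----------
enumerate_mw_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stat <- function(ii) {
    r <- rank(pooled)
    sum(r[ii]) - m * (m + 1) / 2
  }
  u_obs <- stat(seq_len(m))
  combs <- utils::combn(m + n, m)
  u_all <- apply(combs, 2, stat)
  centered <- abs(u_all - m * n / 2)
  min(1, mean(centered >= abs(u_obs - m * n / 2)))
}

# --- PLI by literal sample-by-sample evaluation ----------------------------
# own Hilbert transform (direct DFT), own phase differences, triple loop
naive_pli <- function(epochs, margin_frac = 1 / 8) {
  hilbert1 <- function(x) {
    n <- length(x)
    X <- fft(x)
    h <- rep(0, n)
    h[1] <- 1
    if (n %% 2 == 0) { h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
    } else h[2:((n + 1) / 2)] <- 2
    fft(X * h, inverse = TRUE) / n
  }
  nch <- nrow(epochs[[1]])
  out <- matrix(0, nch, nch)
  for (e in epochs) {
    ns <- ncol(e)
    mrg <- floor(ns * margin_frac)
    keep <- (mrg + 1):(ns - mrg)
    ph <- t(sapply(seq_len(nch), function(ch) Arg(hilbert1(e[ch, ]))))
    for (i in 1:(nch - 1)) for (j in (i + 1):nch) {
      s <- 0
      for (k in keep) {
        v <- sin(ph[i, k] - ph[j, k])
        s <- s + if (abs(v) < 1e-12) 0 else sign(v)
      }
      out[i, j] <- out[i, j] + abs(s / length(keep))
    }
  }
  out <- out / length(epochs)
  out + t(out)
}

# --- small fixtures --------------------------------------------------------
quick_epochs <- function(n_channels = 3, n_epochs = 2, srate = 128,
                         epoch_s = 2, seed = 1, band = "alpha") {
  set.seed(seed)
  eps <- epoch_set(replicate(n_epochs,
                             matrix(rnorm(n_channels * srate * epoch_s),
                                    n_channels), simplify = FALSE),
                   epoch_s, srate, paste0("ch", seq_len(n_channels)))
  if (is.null(band)) eps else bandpass(eps, band_definition(band))
}

sinusoid_recording <- function(freqs, srate = 1024, duration = 64,
                               amp = 10) {
  t <- seq(0, duration - 1 / srate, by = 1 / srate)
  x <- t(sapply(seq_along(freqs), function(k)
    amp * sin(2 * pi * freqs[k] * t + k)))
  recording(x, srate, labels = paste0("ch", seq_along(freqs)))
}
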