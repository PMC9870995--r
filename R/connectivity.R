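# Functional connectivity: phase lag index and corrected amplitude envelope
# correlation. Both work on the analytic signal of band-filtered epochs and
# discard an edge margin of each epoch before averaging, because the FFT
# transforms behind filtering and the Hilbert transform wrap circularly and
# would otherwise bias phase estimates at the epoch boundaries.

new_connectivity <- function(values, metric, band, labels) {
  dimnames(values) <- list(labels, labels)
  diag(values) <- NA_real_
  structure(list(values = values, metric = metric, band = band,
                 labels = labels),
            class = "eeg_connectivity")
}

#' @export
print.eeg_connectivity <- function(x, ...) {
  cat(sprintf("<eeg_connectivity> %s, band %s, %d channels, mean %.4f\n",
              x$metric, x$band$name, length(x$labels), mean_connectivity(x)))
  invisible(x)
}

check_band_filtered <- function(eps, caller) {
  stopifnot(inherits(eps, "eeg_epochs"))
  if (is.null(eps$band))
    stop(sprintf("%s requires a band-filtered epoch set", caller),
         call. = FALSE)
}

margin_index <- function(n, edge_margin) {
  m <- floor(n * edge_margin)
  (m + 1L):(n - m)
}

check_nonconstant <- function(e, labels) {
  sds <- apply(e, 1, sd)
  if (any(sds <= 0))
    stop(sprintf("constant (zero-variance) channel: %s",
                 paste(labels[sds <= 0], collapse = ", ")), call. = FALSE)
}

#' Phase lag index
#'
#' For each channel pair, the absolute mean over samples of the sign of the
#' sine of the instantaneous phase difference, averaged over epochs. Exactly
#' zero-lag (or anti-phase) differences contribute 0, which makes the index
#' insensitive to instantaneous volume conduction; 1 means complete phase
#' locking at a non-zero lag.
#'
#' @param eps a band-filtered [epoch_set()].
#' @param edge_margin fraction of each epoch discarded at both edges
#'   (default 1/8).
#' @return an `eeg_connectivity` with values in `[0, 1]`.
#' @export
pli <- function(eps, edge_margin = 1 / 8) {
  check_band_filtered(eps, "pli")
  nch <- length(eps$labels)
  acc <- matrix(0, nch, nch)
  for (e in eps$epochs) {
    check_nonconstant(e, eps$labels)
    A <- analytic_rows(e)[, margin_index(ncol(e), edge_margin), drop = FALSE]
    Z <- A / Mod(A)
    m <- matrix(0, nch, nch)
    for (i in seq_len(nch - 1)) {
      js <- (i + 1):nch
      im <- Im(Z[js, , drop = FALSE] *
                 matrix(Conj(Z[i, ]), length(js), ncol(Z), byrow = TRUE))
      s <- sign(im)
      s[abs(im) < 1e-12] <- 0       # exact zero-lag contributes nothing
      v <- abs(rowMeans(s))
      m[i, js] <- v
      m[js, i] <- v
    }
    acc <- acc + m
  }
  new_connectivity(acc / length(eps$epochs), "PLI", eps$band, eps$labels)
}

#' Corrected amplitude envelope correlation (AEC-c)
#'
#' For each ordered pair the target's analytic signal is orthogonalized
#' sample-wise with respect to the seed's (removing the instantaneously
#' shared component), the Pearson correlation between the orthogonalized
#' target envelope and the seed envelope is taken, the two directions are
#' averaged, and the result is mapped to `[0, 1]` via `(r + 1) / 2` so that
#' 0.5 means no coupling and 1 perfect coupling.
#'
#' Exactly collinear pairs leave a zero orthogonalized residual; their value
#' is reported as 0.5 with a warning.
#'
#' @inheritParams pli
#' @return an `eeg_connectivity` with values in `[0, 1]`.
#' @export
aec_c <- function(eps, edge_margin = 1 / 8) {
  check_band_filtered(eps, "aec_c")
  nch <- length(eps$labels)
  acc <- matrix(0, nch, nch)
  cnt <- matrix(0, nch, nch)
  degenerate <- FALSE
  for (e in eps$epochs) {
    check_nonconstant(e, eps$labels)
    A <- analytic_rows(e)[, margin_index(ncol(e), edge_margin), drop = FALSE]
    env <- Mod(A)
    for (i in seq_len(nch)) {
      # all targets orthogonalized w.r.t. seed i at once
      u <- Conj(A[i, ]) / env[i, ]
      orth <- abs(Im(A * matrix(u, nch, ncol(A), byrow = TRUE)))
      osd <- apply(orth, 1, sd)
      r <- rep(NA_real_, nch)
      ok <- osd > 1e-10 * apply(env, 1, sd)
      ok[i] <- FALSE
      if (any(ok))
        r[ok] <- as.numeric(cor(env[i, ], t(orth[ok, , drop = FALSE])))
      bad <- !ok & seq_len(nch) != i
      if (any(bad)) degenerate <- TRUE
      acc[i, bad] <- acc[i, bad] + 0    # degenerate direction counts as r = 0
      cnt[i, ] <- cnt[i, ] + 1
      acc[i, ok] <- acc[i, ok] + r[ok]
    }
  }
  if (degenerate)
    warning("collinear channel pair(s): orthogonalized residual is zero; ",
            "AEC-c reported as 0.5", call. = FALSE)
  r_mean <- acc / cnt                       # mean r per direction over epochs
  r_sym <- (r_mean + t(r_mean)) / 2         # average the two directions
  new_connectivity((r_sym + 1) / 2, "AEC-c", eps$band, eps$labels)
}

#' Whole-brain mean connectivity
#'
#' Arithmetic mean over the strict upper triangle (all unordered electrode
#' pairs; 2016 pairs for 64 channels).
#'
#' @param cm an `eeg_connectivity`.
#' @return scalar mean coupling.
#' @export
mean_connectivity <- function(cm) {
  stopifnot(inherits(cm, "eeg_connectivity"))
  mean(cm$values[upper.tri(cm$values)])
}
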