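#' Idealized 64-channel 10-10 electrode montage
#'
#' Builds unit-sphere electrode positions for the standard 64-channel 10-10
#' layout (BioSemi ordering, labels `Fp1` ... `O2`). Positions are the usual
#' idealized spherical construction: the circumferential ring
#' (Fpz, Fp1/2, AF7/8, F7/8, FT7/8, T7/8, TP7/8, P7/8, PO7/8, O1/2, Oz) sits
#' at 72 degrees of inclination from the vertex with 18-degree azimuthal
#' spacing; midline electrodes step inward in 18-degree increments; lateral
#' electrodes are placed by spherical interpolation along the coronal arc
#' between the midline electrode and the ring electrode of the same row.
#' P9, P10 and Iz lie one 10%-step (18 degrees) below the ring.
#'
#' Coordinates: +x right ear, +y nasion, +z vertex, radius 1.
#'
#' @param n_channels number of channels (1--64); the first `n_channels`
#'   labels of the BioSemi A1--B32 ordering are returned.
#' @return list with `labels` (character) and `positions`
#'   (`n_channels` x 3 matrix, rows named by label).
#' @export
montage_1010 <- function(n_channels = 64) {
  if (n_channels < 1 || n_channels > 64)
    stop("'n_channels' must be between 1 and 64", call. = FALSE)
  m <- montage_1010_full()
  list(labels = m$labels[seq_len(n_channels)],
       positions = m$positions[seq_len(n_channels), , drop = FALSE])
}

# full montage, memoised at build time
montage_1010_full <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)

    vec <- function(incl, az) {
      a <- incl * pi / 180; t <- az * pi / 180
      c(sin(a) * cos(t), sin(a) * sin(t), cos(a))
    }
    slerp <- function(u, v, f) {
      w <- acos(clip(sum(u * v), -1, 1))
      if (w < 1e-12) return(u)
      (sin((1 - f) * w) * u + sin(f * w) * v) / sin(w)
    }

    pos <- list()
    # ring: inclination 72, azimuth from +x (right ear), counterclockwise
    ring_az <- c(Fpz = 90, Fp1 = 108, AF7 = 126, F7 = 144, FT7 = 162,
                 T7 = 180, TP7 = 198, P7 = 216, PO7 = 234, O1 = 252,
                 Oz = 270, O2 = 288, PO8 = 306, P8 = 324, TP8 = 342,
                 T8 = 0, FT8 = 18, F8 = 36, AF8 = 54, Fp2 = 72)
    for (lab in names(ring_az)) pos[[lab]] <- vec(72, ring_az[[lab]])
    # midline, front positive y
    mid <- c(AFz = 54, Fz = 36, FCz = 18, Cz = 0)
    for (lab in names(mid)) pos[[lab]] <- vec(mid[[lab]], 90)
    midb <- c(CPz = 18, Pz = 36, POz = 54)
    for (lab in names(midb)) pos[[lab]] <- vec(midb[[lab]], 270)
    # below-ring electrodes (one further 10% step)
    pos[["P9"]] <- vec(90, 216); pos[["P10"]] <- vec(90, 324)
    pos[["Iz"]] <- vec(90, 270)
    # lateral rows: slerp from midline (f = 0) to ring (f = 1)
    rows <- list(
      list(mid = "Fz",  ring = c("F7", "F8"),
           left = c(F5 = .75, F3 = .5, F1 = .25),
           right = c(F6 = .75, F4 = .5, F2 = .25)),
      list(mid = "FCz", ring = c("FT7", "FT8"),
           left = c(FC5 = .75, FC3 = .5, FC1 = .25),
           right = c(FC6 = .75, FC4 = .5, FC2 = .25)),
      list(mid = "Cz",  ring = c("T7", "T8"),
           left = c(C5 = .75, C3 = .5, C1 = .25),
           right = c(C6 = .75, C4 = .5, C2 = .25)),
      list(mid = "CPz", ring = c("TP7", "TP8"),
           left = c(CP5 = .75, CP3 = .5, CP1 = .25),
           right = c(CP6 = .75, CP4 = .5, CP2 = .25)),
      list(mid = "Pz",  ring = c("P7", "P8"),
           left = c(P5 = .75, P3 = .5, P1 = .25),
           right = c(P6 = .75, P4 = .5, P2 = .25)),
      list(mid = "AFz", ring = c("AF7", "AF8"),
           left = c(AF3 = .5), right = c(AF4 = .5)),
      list(mid = "POz", ring = c("PO7", "PO8"),
           left = c(PO3 = .5), right = c(PO4 = .5)))
    for (rw in rows) {
      for (lab in names(rw$left))
        pos[[lab]] <- slerp(pos[[rw$mid]], pos[[rw$ring[1]]], rw$left[[lab]])
      for (lab in names(rw$right))
        pos[[lab]] <- slerp(pos[[rw$mid]], pos[[rw$ring[2]]], rw$right[[lab]])
    }

    labels <- c(
      "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
      "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
      "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
      "Pz", "CPz",
      "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8",
      "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8",
      "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8",
      "PO4", "O2")
    P <- t(vapply(labels, function(l) pos[[l]], numeric(3)))
    P <- P / sqrt(rowSums(P^2))
    colnames(P) <- c("x", "y", "z")
    cache <<- list(labels = labels, positions = P)
    cache
  }
})
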