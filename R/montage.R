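#' Standard 17-channel 10/20 montage on a spherical scalp
#'
#' Electrode positions are constructed from the 10/20 placement rules on a
#' sphere: a horizontal ring at 90 degrees inclination (FP1/FP2, F7/F8,
#' T3/T4, T5/T6), midline electrodes FZ/CZ/PZ at 45/0/45 degrees, central
#' C3/C4 at 45 degrees inclination on the interaural line, and F3/F4
#' (P3/P4) as spherical midpoints between FZ and F7/F8 (PZ and T5/T6).
#' Coordinates use x = right, y = anterior, z = superior, in millimetres on
#' the scalp sphere.
#'
#' @param scalp_radius scalp sphere radius in mm (default 92, matching the
#'   outer shell of [head_model()]).
#' @return data.frame with columns `label`, `x`, `y`, `z`.
#' @export
montage_1020 <- function(scalp_radius = 92) {
  ang <- function(incl, azim) {
    # inclination from vertex (deg), azimuth from anterior midline,
    # positive clockwise seen from above (i.e. toward the right ear)
    ir <- incl * pi / 180
    ar <- azim * pi / 180
    c(x = sin(ir) * sin(ar), y = sin(ir) * cos(ar), z = cos(ir))
  }
  slerp_mid <- function(p, q) {
    m <- (p + q) / 2
    m / sqrt(sum(m^2))
  }
  pos <- list(
    FP1 = ang(90, -18), FP2 = ang(90, 18),
    F7  = ang(90, -54), F8  = ang(90, 54),
    T3  = ang(90, -90), T4  = ang(90, 90),
    T5  = ang(90, -126), T6 = ang(90, 126),
    FZ  = ang(45, 0), CZ = ang(0, 0), PZ = ang(45, 180),
    C3  = ang(45, -90), C4 = ang(45, 90)
  )
  pos$F3 <- slerp_mid(pos$FZ, pos$F7)
  pos$F4 <- slerp_mid(pos$FZ, pos$F8)
  pos$P3 <- slerp_mid(pos$PZ, pos$T5)
  pos$P4 <- slerp_mid(pos$PZ, pos$T6)
  labels <- c("FP1", "FP2", "F7", "F8", "F3", "F4", "C3", "C4",
              "P3", "P4", "FZ", "CZ", "PZ", "T3", "T4", "T5", "T6")
  m <- t(vapply(pos[labels], identity, numeric(3))) * scalp_radius
  data.frame(label = labels, x = m[, 1], y = m[, 2], z = m[, 3],
             stringsAsFactors = FALSE)
}

#' Channel labels of the 17-site 10/20 montage
#' @return character vector of the 17 labels in montage order.
#' @export
channel_labels_1020 <- function() montage_1020()$label
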