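#' @keywords internal
#' Grid coordinates (anterior-posterior, lateral) for the 64-channel 10-10 set.
#' ap runs +1 (front) to -1.2 (below inion); lat runs negative left to
#' positive right. These are schematic coordinates used only to place the
#' electrodes on a unit sphere with a sensible neighborhood structure.
.montage_grid <- function() {
  g <- list(
    Fp1 = c(1.0, -0.30), Fpz = c(1.0, 0), Fp2 = c(1.0, 0.30),
    AF7 = c(0.8, -0.70), AF3 = c(0.8, -0.35), AFz = c(0.8, 0),
    AF4 = c(0.8, 0.35), AF8 = c(0.8, 0.70),
    F7 = c(0.6, -0.95), F5 = c(0.6, -0.72), F3 = c(0.6, -0.48),
    F1 = c(0.6, -0.24), Fz = c(0.6, 0), F2 = c(0.6, 0.24),
    F4 = c(0.6, 0.48), F6 = c(0.6, 0.72), F8 = c(0.6, 0.95),
    FT7 = c(0.3, -0.95), FC5 = c(0.3, -0.72), FC3 = c(0.3, -0.48),
    FC1 = c(0.3, -0.24), FCz = c(0.3, 0), FC2 = c(0.3, 0.24),
    FC4 = c(0.3, 0.48), FC6 = c(0.3, 0.72), FT8 = c(0.3, 0.95),
    T7 = c(0, -0.95), C5 = c(0, -0.72), C3 = c(0, -0.48),
    C1 = c(0, -0.24), Cz = c(0, 0), C2 = c(0, 0.24),
    C4 = c(0, 0.48), C6 = c(0, 0.72), T8 = c(0, 0.95),
    TP7 = c(-0.3, -0.95), CP5 = c(-0.3, -0.72), CP3 = c(-0.3, -0.48),
    CP1 = c(-0.3, -0.24), CPz = c(-0.3, 0), CP2 = c(-0.3, 0.24),
    CP4 = c(-0.3, 0.48), CP6 = c(-0.3, 0.72), TP8 = c(-0.3, 0.95),
    P9 = c(-0.6, -1.20), P7 = c(-0.6, -0.95), P5 = c(-0.6, -0.72),
    P3 = c(-0.6, -0.48), P1 = c(-0.6, -0.24), Pz = c(-0.6, 0),
    P2 = c(-0.6, 0.24), P4 = c(-0.6, 0.48), P6 = c(-0.6, 0.72),
    P8 = c(-0.6, 0.95), P10 = c(-0.6, 1.20),
    PO7 = c(-0.8, -0.70), PO3 = c(-0.8, -0.35), POz = c(-0.8, 0),
    PO4 = c(-0.8, 0.35), PO8 = c(-0.8, 0.70),
    O1 = c(-1.0, -0.30), Oz = c(-1.0, 0), O2 = c(-1.0, 0.30),
    Iz = c(-1.2, 0)
  )
  m <- do.call(rbind, g)
  colnames(m) <- c("ap", "lat")
  m
}

# Preference order used when a montage with fewer than 64 channels is
# requested: keeps the electrodes the analysis clusters rely on.
.montage_preferred <- c(
  "FC1", "FCz", "FC2", "Cz", "Pz", "Oz", "O1", "O2", "F3", "Fz", "F4",
  "C3", "C4", "P3", "P4", "POz", "CP1", "CP2", "PO3", "PO4", "AFz", "CPz",
  "F1", "F2", "C1", "C2", "P1", "P2", "FC3", "FC4", "PO7", "PO8"
)

#' Default EEG montage
#'
#' Builds the 64-channel cap used by the recording system (10-10 labels) with
#' schematic unit-sphere electrode positions. Positions are used for
#' nearest-neighbor channel repair, cluster adjacency, and the spatial
#' topographies of the forward simulator; they are not digitized coordinates.
#'
#' For `n_channels < 64` a spatially spread subset is returned that always
#' contains the fronto-central and occipito-parietal electrodes the analysis
#' clusters are defined on.
#'
#' @param n_channels number of electrodes (default 64, the full cap).
#' @param reference label describing the reference (default linked mastoids).
#' @return A `vr_montage`: list with `channel_names`, `positions` (n x 3
#'   matrix of unit vectors), and `reference`.
#' @export
default_montage <- function(n_channels = 64, reference = "linked-mastoids") {
  grid <- .montage_grid()
  if (n_channels > nrow(grid)) stop("at most 64 channels available")
  if (n_channels < nrow(grid)) {
    keep <- .montage_preferred[seq_len(min(n_channels, length(.montage_preferred)))]
    if (n_channels > length(.montage_preferred)) {
      rest <- setdiff(rownames(grid), .montage_preferred)
      keep <- c(keep, rest[seq_len(n_channels - length(.montage_preferred))])
    }
    grid <- grid[keep, , drop = FALSE]
  }
  r <- sqrt(grid[, "ap"]^2 + grid[, "lat"]^2)
  theta <- pmin(r, 1.3) * (pi / 2)          # polar angle from vertex
  az <- atan2(grid[, "lat"], grid[, "ap"])  # 0 = straight ahead
  pos <- cbind(x = sin(theta) * sin(az),    # +x = right
               y = sin(theta) * cos(az),    # +y = front
               z = cos(theta))              # +z = vertex
  rownames(pos) <- rownames(grid)
  montage(rownames(grid), pos, reference)
}

#' Construct a montage
#'
#' @param channel_names unique channel labels.
#' @param positions n x 3 matrix of electrode positions (unit-sphere
#'   convention, arbitrary units).
#' @param reference reference description string.
#' @return A `vr_montage` object.
#' @export
montage <- function(channel_names, positions, reference = "unknown") {
  channel_names <- as.character(channel_names)
  positions <- as.matrix(positions)
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  if (nrow(positions) != length(channel_names) || ncol(positions) != 3) {
    stop("positions must be an n x 3 matrix matching channel_names")
  }
  if (any(!is.finite(positions))) stop("positions must be finite")
  rownames(positions) <- channel_names
  structure(list(channel_names = channel_names, positions = positions,
                 reference = reference),
            class = "vr_montage")
}

#' @export
print.vr_montage <- function(x, ...) {
  cat(sprintf("<vr_montage> %d channels, reference: %s\n",
              length(x$channel_names), x$reference))
  invisible(x)
}

#' Electrode clusters used by the analyses
#'
#' Returns the named electrode clusters (restricted to the channels present in
#' `montage`): `occipito_parietal` for alpha peak detection, `fronto_central`
#' for beta peak detection, `trf` (FC1/FCz/FC2) for TRF component extraction,
#' and `centro_parietal` for ERP component extraction.
#'
#' @param montage a `vr_montage`.
#' @return named list of character vectors.
#' @export
electrode_clusters <- function(montage) {
  full <- list(
    occipito_parietal = c("O1", "Oz", "O2", "PO7", "PO3", "POz", "PO4", "PO8",
                          "P3", "Pz", "P4"),
    fronto_central = c("F1", "Fz", "F2", "FC1", "FCz", "FC2", "F3", "F4",
                       "C1", "Cz", "C2"),
    trf = c("FC1", "FCz", "FC2"),
    centro_parietal = c("C1", "Cz", "C2", "CP1", "CPz", "CP2", "Pz",
                        "C3", "C4", "P3", "P4")
  )
  lapply(full, intersect, y = montage$channel_names)
}
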