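#' Synthetic EEG montage on the unit sphere
#'
#' Builds an electrode montage of `n_channels` sites spread over the upper
#' portion of a unit sphere by a Fibonacci spiral, with anatomical region
#' tags and a neighbor graph. Regions are assigned from coordinates
#' (x = right, y = anterior, z = superior):
#' * `face`: low anterior sites (z below `face_z`, y > 0.3), excluded from
#'   scalp statistics;
#' * `occipital`: a spherical cap around the occipital pole;
#' * `frontal`: anterior scalp sites (y > 0.45, z > 0);
#' * `other`: the remainder.
#' Neighbors are all pairs of channels closer than `neighbor_deg` degrees of
#' great-circle distance. The occipital region is a spherical cap of
#' `occ_deg` degrees around the occipital pole (low posterior midline), so
#' the region is spatially contiguous in the neighbor graph.
#'
#' @param n_channels Number of electrodes (default 64; larger nets such as
#'   256 channels are supported).
#' @param neighbor_deg Angular distance (degrees) under which two channels
#'   count as neighbors.
#' @param face_z z-coordinate below which anterior sites are tagged as face
#'   channels.
#' @param occ_deg Angular radius (degrees) of the occipital cap.
#' @return An object of class `eeg_montage`: list with `labels`, `positions`
#'   (n x 3, unit norm), `regions` (factor), `neighbors` (logical adjacency
#'   matrix, symmetric, empty diagonal).
#' @export
make_montage <- function(n_channels = 64, neighbor_deg = 30, face_z = -0.05,
                         occ_deg = 40) {
  n <- as.integer(n_channels)
  if (is.na(n) || n < 4L) stopf("make_montage: need at least 4 channels")
  # Fibonacci spiral over a spherical cap z in [zmin, 1]
  zmin <- -0.25
  i <- seq_len(n) - 0.5
  z <- 1 - (1 - zmin) * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(x = r * cos(phi), y = r * sin(phi), z = z)
  labels <- sprintf("E%03d", seq_len(n))
  rownames(pos) <- labels

  regions <- rep("other", n)
  face <- pos[, "z"] < face_z & pos[, "y"] > 0.3
  regions[face] <- "face"
  occ_pole <- c(0, -1, 0)
  occ_pole <- occ_pole / sqrt(sum(occ_pole^2))
  cosang_occ <- pos %*% occ_pole
  occ <- as.vector(cosang_occ) > cos(occ_deg * pi / 180) & !face
  regions[occ] <- "occipital"
  frontal <- pos[, "y"] > 0.45 & pos[, "z"] > 0 & !face & !occ
  regions[frontal & regions == "other"] <- "frontal"

  ang <- angular_distance(pos)
  nb <- ang < (neighbor_deg * pi / 180)
  diag(nb) <- FALSE

  structure(
    list(labels = labels, positions = pos,
         regions = factor(regions, levels = c("occipital", "frontal", "face", "other")),
         neighbors = nb, neighbor_deg = neighbor_deg),
    class = "eeg_montage")
}

# Pairwise great-circle distance (radians) between unit-norm rows of pos.
angular_distance <- function(pos) {
  g <- tcrossprod(pos)
  g[g > 1] <- 1; g[g < -1] <- -1
  acos(g)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels; regions: %s; neighbor radius %g deg\n",
              length(x$labels),
              paste(sprintf("%s=%d", levels(x$regions), tabulate(x$regions, nbins = nlevels(x$regions))),
                    collapse = " "),
              x$neighbor_deg))
  invisible(x)
}

#' Channel indices of a montage region
#'
#' @param montage An `eeg_montage`.
#' @param region One of `"occipital"`, `"frontal"`, `"face"`, `"other"`.
#' @return Integer indices of the channels tagged with `region`.
#' @export
region_channels <- function(montage, region) {
  which(montage$regions == region)
}

#' Write/read a montage as TSV
#'
#' Plain-text representation: columns `label`, `x`, `y`, `z`, `region`.
#' The neighbor graph is rebuilt on read from the stored positions.
#'
#' @param montage An `eeg_montage`.
#' @param path File path.
#' @rdname montage_io
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(label = montage$labels,
                   x = montage$positions[, 1], y = montage$positions[, 2],
                   z = montage$positions[, 3], region = as.character(montage$regions))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param neighbor_deg Neighbor radius in degrees used to rebuild adjacency.
#' @rdname montage_io
#' @export
read_montage <- function(path, neighbor_deg = 30) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  pos <- as.matrix(df[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2))
  rownames(pos) <- df$label
  ang <- angular_distance(pos)
  nb <- ang < (neighbor_deg * pi / 180)
  diag(nb) <- FALSE
  structure(
    list(labels = df$label, positions = pos,
         regions = factor(df$region, levels = c("occipital", "frontal", "face", "other")),
         neighbors = nb, neighbor_deg = neighbor_deg),
    class = "eeg_montage")
}
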