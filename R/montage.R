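#' Standard 61-channel 10-10 scalp montage
#'
#' Builds the 61-electrode subset of the international 10-10 system used for
#' movement-related beta analyses, with idealized positions on a unit sphere
#' (head-centred, dimensionless). Positions are constructed geometrically:
#' the outer ring sits at 72 degrees of inclination from the vertex with
#' 18-degree azimuthal spacing, midline electrodes step down the sagittal
#' arc in 18-degree increments, and lateral electrodes are placed by
#' spherical interpolation between the midline electrode of a row and the
#' row's outer-ring electrode. This reproduces the classic spherical 10-10
#' layout (e.g. C3 at 36 degrees left of the vertex).
#'
#' Coordinates: +x right, +y anterior, +z superior; every position has unit
#' norm.
#'
#' @return A tibble with columns `label`, `x`, `y`, `z`.
#' @export
#' @examples
#' m <- standard_montage()
#' nrow(m) # 61
standard_montage <- function() {
  deg <- pi / 180
  pos <- function(theta, azim) {
    # theta: inclination from vertex; azim: from anterior, positive leftward
    c(
      x = -sin(theta * deg) * sin(azim * deg),
      y = sin(theta * deg) * cos(azim * deg),
      z = cos(theta * deg)
    )
  }
  slerp <- function(p, q, t) {
    om <- acos(max(-1, min(1, sum(p * q))))
    out <- (sin((1 - t) * om) * p + sin(t * om) * q) / sin(om)
    out / sqrt(sum(out^2))
  }

  pts <- list()
  add <- function(label, p) pts[[label]] <<- p

  # midline (anterior azimuth 0, posterior 180)
  add("Fpz", pos(72, 0)); add("AFz", pos(54, 0)); add("Fz", pos(36, 0))
  add("FCz", pos(18, 0)); add("Cz", pos(0, 0)); add("CPz", pos(18, 180))
  add("Pz", pos(36, 180)); add("POz", pos(54, 180)); add("Oz", pos(72, 180))

  # outer ring, 18-degree azimuthal steps from the front
  ring <- c(
    Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
    TP7 = 108, P7 = 126, PO7 = 144, O1 = 162
  )
  for (lab in names(ring)) add(lab, pos(72, ring[[lab]]))
  right_of <- c(
    Fp1 = "Fp2", AF7 = "AF8", F7 = "F8", FT7 = "FT8", T7 = "T8",
    TP7 = "TP8", P7 = "P8", PO7 = "PO8", O1 = "O2"
  )
  for (lab in names(ring)) add(right_of[[lab]], pos(72, -ring[[lab]]))

  # lateral rows: spherical interpolation midline -> outer ring
  rows <- list(
    list(mid = "Fz", ringL = "F7", ringR = "F8",
         left = c(F1 = 0.25, F3 = 0.5, F5 = 0.75),
         right = c(F2 = 0.25, F4 = 0.5, F6 = 0.75)),
    list(mid = "FCz", ringL = "FT7", ringR = "FT8",
         left = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75),
         right = c(FC2 = 0.25, FC4 = 0.5, FC6 = 0.75)),
    list(mid = "Cz", ringL = "T7", ringR = "T8",
         left = c(C1 = 0.25, C3 = 0.5, C5 = 0.75),
         right = c(C2 = 0.25, C4 = 0.5, C6 = 0.75)),
    list(mid = "CPz", ringL = "TP7", ringR = "TP8",
         left = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75),
         right = c(CP2 = 0.25, CP4 = 0.5, CP6 = 0.75)),
    list(mid = "Pz", ringL = "P7", ringR = "P8",
         left = c(P1 = 0.25, P3 = 0.5, P5 = 0.75),
         right = c(P2 = 0.25, P4 = 0.5, P6 = 0.75)),
    list(mid = "AFz", ringL = "AF7", ringR = "AF8",
         left = c(AF3 = 0.5), right = c(AF4 = 0.5)),
    list(mid = "POz", ringL = "PO7", ringR = "PO8",
         left = c(PO3 = 0.5), right = c(PO4 = 0.5))
  )
  for (row in rows) {
    for (lab in names(row$left)) {
      add(lab, slerp(pts[[row$mid]], pts[[row$ringL]], row$left[[lab]]))
    }
    for (lab in names(row$right)) {
      add(lab, slerp(pts[[row$mid]], pts[[row$ringR]], row$right[[lab]]))
    }
  }

  mat <- do.call(rbind, pts)
  tibble::tibble(
    label = names(pts),
    x = mat[, 1], y = mat[, 2], z = mat[, 3]
  )
}

#' Candidate electrode regions for personalized-ROI search
#'
#' The three broad scalp regions within which the peak modulation electrode
#' is searched: frontal, "left sensorimotor" and "right sensorimotor". The
#' sets are kept verbatim as conventionally printed; note that under that
#' convention the "left sensorimotor" set lists even-numbered (right-scalp)
#' electrodes and vice versa -- the names refer to the hand/hemibody whose
#' movement the contralateral scalp region serves, not to the scalp side.
#' They are carried verbatim here rather than silently "corrected".
#'
#' @return Named list of character vectors of electrode labels.
#' @export
candidate_regions <- function() {
  list(
    frontal = c(
      "AFz", "AF3", "AF4", "Fz", "F1", "F2", "F3", "F4", "F5", "F6",
      "FCz", "FC1", "FC2", "FC3", "FC4"
    ),
    left_sensorimotor = c(
      "Cz", "C2", "C4", "C6", "CP6", "CP4", "CP2", "CPz",
      "P6", "P4", "P2", "Pz"
    ),
    right_sensorimotor = c(
      "Cz", "C1", "C3", "C5", "CPz", "CP1", "CP3", "CP5",
      "Pz", "P1", "P3", "P5"
    )
  )
}

montage_matrix <- function(montage) {
  m <- as.matrix(montage[, c("x", "y", "z")])
  rownames(m) <- montage$label
  m
}

#' Nearest neighbours of an electrode
#'
#' Euclidean 3-D distances on the unit-sphere positions; the electrode
#' itself is excluded. Ties are broken lexicographically for determinism.
#'
#' @param montage Montage tibble from [standard_montage()].
#' @param label Electrode whose neighbours are sought.
#' @param n Number of neighbours (default 6).
#' @return Character vector of `n` labels, nearest first.
#' @export
montage_neighbours <- function(montage, label, n = 6) {
  pm <- montage_matrix(montage)
  if (!label %in% rownames(pm)) {
    stop("electrode '", label, "' not in montage", call. = FALSE)
  }
  d <- sqrt(colSums((t(pm) - pm[label, ])^2))
  d <- d[names(d) != label]
  ord <- order(d, names(d))
  names(d)[ord][seq_len(n)]
}

#' Write / read a whitespace-delimited electrode position file
#'
#' Plain-text `label x y z` format, one electrode per line.
#'
#' @param montage Montage tibble.
#' @param path File path.
#' @return `read_montage()` returns a montage tibble.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage, path,
    quote = FALSE, row.names = FALSE,
    col.names = FALSE, sep = " "
  )
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.table(path,
    header = FALSE,
    col.names = c("label", "x", "y", "z"),
    stringsAsFactors = FALSE
  )
  tibble::as_tibble(df)
}

assert_montage <- function(montage) {
  stopifnot(
    all(c("label", "x", "y", "z") %in% names(montage)),
    !anyDuplicated(montage$label)
  )
  nrm <- sqrt(montage$x^2 + montage$y^2 + montage$z^2)
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("montage positions must lie on the unit sphere", call. = FALSE)
  }
  invisible(montage)
}
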