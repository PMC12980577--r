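#' Spherical-spline surface Laplacian (current source density)
#'
#' Reference-free spatial sharpening of scalp potentials. A spherical
#' spline with a constant term is fitted through the electrode potentials
#' at every timepoint (Perrin-style parameterization) and the current
#' source density -- the negative surface Laplacian of the interpolated
#' potential -- is evaluated at each electrode. The transform is linear in
#' the data, so it is applied as a single precomputed channels-by-channels
#' matrix. Output is invariant to adding a constant across channels
#' (reference-free by construction).
#'
#' @param epochs An `eeg_epochs` object (see [generate_session()]).
#' @param m Spline stiffness order (default 4, the conventional value).
#' @param lambda Ridge regularization added to the spline system
#'   (default `1e-5`).
#' @param nterms Truncation degree of the Legendre series (default 50).
#' @return The `eeg_epochs` object with `data` replaced by its CSD and a
#'   `units` field of `"CSD"`.
#' @export
csd_transform <- function(epochs, m = 4, lambda = 1e-5, nterms = 50) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  M <- csd_matrix(epochs$montage, m = m, lambda = lambda, nterms = nterms)
  d <- epochs$data
  dm <- dim(d)
  # channels are the second margin: reshape so the matrix acts on channels
  flat <- matrix(aperm(d, c(2, 1, 3)), nrow = dm[2])
  out <- M %*% flat
  epochs$data <- aperm(array(out, dim = c(dm[2], dm[1], dm[3])), c(2, 1, 3))
  epochs$units <- "CSD"
  epochs
}

#' CSD transform matrix for a montage
#'
#' The dense linear operator mapping a vector of electrode potentials to
#' current source density at the same electrodes.
#'
#' @inheritParams csd_transform
#' @param montage Montage tibble with unit-sphere positions.
#' @return A channels-by-channels matrix with dimnames set to the labels.
#' @export
csd_matrix <- function(montage, m = 4, lambda = 1e-5, nterms = 50) {
  assert_montage(montage)
  pm <- montage_matrix(montage)
  n <- nrow(pm)
  if (n < 6) stop("need at least 6 electrodes for CSD", call. = FALSE)
  cosang <- tcrossprod(pm)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  off <- cosang[upper.tri(cosang)]
  if (any(off > 1 - 1e-10)) {
    stop("duplicate electrode positions: spline system is singular",
      call. = FALSE
    )
  }

  P <- legendre_table(cosang, nterms) # list of P_n(cosang), n = 1..nterms
  ns <- seq_len(nterms)
  gw <- (2 * ns + 1) / (ns * (ns + 1))^m / (4 * pi)
  hw <- (2 * ns + 1) / (ns * (ns + 1))^(m - 1) / (4 * pi)
  G <- matrix(0, n, n)
  H <- matrix(0, n, n)
  for (k in ns) {
    G <- G + gw[k] * P[[k]]
    H <- H + hw[k] * P[[k]]
  }

  # bordered system: spline weights sum to zero, constant term absorbs
  # the reference
  B <- rbind(
    cbind(G + diag(lambda, n), rep(1, n)),
    c(rep(1, n), 0)
  )
  S <- solve(B)[seq_len(n), seq_len(n)]
  M <- H %*% S
  dimnames(M) <- list(rownames(pm), rownames(pm))
  M
}

# Legendre polynomials P_1..P_L evaluated elementwise on a matrix, by the
# three-term recursion.
legendre_table <- function(x, L) {
  out <- vector("list", L)
  pm1 <- matrix(1, nrow(x), ncol(x)) # P_0
  p <- x # P_1
  out[[1]] <- p
  if (L >= 2) {
    for (k in 2:L) {
      pn <- ((2 * k - 1) * x * p - (k - 1) * pm1) / k
      out[[k]] <- pn
      pm1 <- p
      p <- pn
    }
  }
  out
}

#' Spherical-spline interpolation of bad channels
#'
#' Reconstructs the potential at target electrodes from the remaining
#' channels with the same spherical-spline machinery used for the CSD
#' (interpolation of the potential itself, not its Laplacian). Intended
#' for real recordings with channels of poor signal quality; the synthetic
#' generator produces none.
#'
#' @param epochs An `eeg_epochs` object.
#' @param bad Character vector of channel labels to reconstruct.
#' @inheritParams csd_transform
#' @return The `eeg_epochs` object with the bad channels replaced by their
#'   spline interpolation.
#' @export
interpolate_channels <- function(epochs, bad, m = 4, lambda = 1e-5,
                                 nterms = 50) {
  stopifnot(inherits(epochs, "eeg_epochs"), all(bad %in% epochs$montage$label))
  good <- setdiff(epochs$montage$label, bad)
  pm <- montage_matrix(epochs$montage)
  cos_gg <- tcrossprod(pm[good, , drop = FALSE])
  cos_bg <- tcrossprod(pm[bad, , drop = FALSE], pm[good, , drop = FALSE])
  clamp <- function(x) pmin(pmax(x, -1), 1)
  ns <- seq_len(nterms)
  gw <- (2 * ns + 1) / (ns * (ns + 1))^m / (4 * pi)
  gsum <- function(cosang) {
    P <- legendre_table(clamp(cosang), nterms)
    Reduce(`+`, Map(function(w, p) w * p, gw, P))
  }
  G <- gsum(cos_gg)
  Gb <- gsum(cos_bg)
  ng <- length(good)
  B <- rbind(
    cbind(G + diag(lambda, ng), rep(1, ng)),
    c(rep(1, ng), 0)
  )
  Binv <- solve(B)
  # interpolated potential: Gb %*% c + c0
  A <- cbind(Gb, rep(1, length(bad))) %*% Binv[, seq_len(ng)]
  d <- epochs$data
  gi <- match(good, epochs$montage$label)
  bi <- match(bad, epochs$montage$label)
  for (tr in seq_len(dim(d)[1])) {
    d[tr, bi, ] <- A %*% d[tr, gi, ]
  }
  epochs$data <- d
  epochs
}
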