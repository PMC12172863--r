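# sLORETA distributed inverse operator and grid-search dipole fitting.
#
# The minimum-norm kernel is standardized by the diagonal of its resolution
# matrix (sLORETA). With the trace-normalized regularizer used here the
# kernel is algebraically independent of the scalar noise scale sigma (it
# cancels between the whitening and the inverse), so sigma only documents the
# assumed noise model.

#' Build an sLORETA inverse operator
#'
#' With the whitened gain `G = L / sigma`, the minimum-norm kernel is
#' `K = G' (G G' + lambda2 * trace(G G') / n_channels * I)^{-1}`, applied to
#' whitened data. The resolution diagonal `R_jj = (K G)_jj` standardizes the
#' estimate; it must be strictly positive (a silent source would make the
#' standardization ill-posed).
#'
#' @param leadfield A `leadfield`.
#' @param sigma Scalar noise standard deviation (see
#'   [estimate_noise_sigma()]); any positive value yields the same operator.
#' @param lambda2 Regularization (>= 0); the default 1/9 corresponds to a
#'   nominal amplitude SNR of 3.
#' @return An `inverse_operator`: `kernel` (n_sources x n_channels, applied to
#'   raw data), `resolution_diag`, `lambda2`, `sigma`.
#' @export
make_inverse <- function(leadfield, sigma = 1, lambda2 = 1 / 9) {
  if (lambda2 < 0) stop("`lambda2` must be >= 0")
  if (sigma <= 0) stop("`sigma` must be positive")
  g <- leadfield$gain / sigma
  gram <- tcrossprod(g)
  reg <- lambda2 * sum(diag(gram)) / nrow(g)
  k <- t(g) %*% solve(gram + diag(reg, nrow(gram)))
  resdiag <- rowSums(k * t(g))
  bad <- which(resdiag <= 0)
  if (length(bad))
    stop("non-positive resolution diagonal (silent source?) at: ",
         paste(utils::head(bad, 10), collapse = ", "))
  structure(list(kernel = k / sigma, resolution_diag = resdiag,
                 lambda2 = lambda2, sigma = sigma,
                 source_space = leadfield$source_space),
            class = "inverse_operator")
}

#' Estimate the scalar noise scale from the evoked baseline
#'
#' Median over channels of the per-channel standard deviation across baseline
#' samples (\[-50, 0) ms).
#'
#' @param evoked A `sef_evoked`.
#' @return Positive scalar (falls back to 1 for noiseless data).
#' @export
estimate_noise_sigma <- function(evoked) {
  bl <- which(evoked$times >= -50 & evoked$times < 0)
  if (!length(bl)) stop("evoked lacks a baseline interval")
  s <- stats::median(apply(evoked$data[, bl, drop = FALSE], 1, stats::sd))
  if (!is.finite(s) || s <= 0) 1 else s
}

#' Apply an sLORETA inverse operator to an evoked response
#'
#' @param inverse_operator An `inverse_operator`.
#' @param evoked A `sef_evoked` (channel set must match the operator).
#' @return A `source_estimate`: `values` (n_sources x n_times, standardized
#'   current density), `times` (ms).
#' @export
apply_sloreta <- function(inverse_operator, evoked) {
  inv <- inverse_operator
  if (ncol(inv$kernel) != nrow(evoked$data))
    stop("channel count mismatch between operator and evoked")
  vals <- (inv$kernel %*% evoked$data) / sqrt(inv$resolution_diag)
  structure(list(values = vals, times = evoked$times,
                 source_space = inv$source_space),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("source_estimate: %d sources x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Orthonormal bases of each source's free-orientation gain (3 columns per
# source, rank-deficient columns zeroed), cached on the leadfield. Projection
# norms onto these bases give the dipole goodness of fit in one matrix
# product.
dipole_bases <- function(leadfield) {
  cache <- leadfield$cache
  if (!is.null(cache$ubig)) return(cache$ubig)
  gf <- leadfield$gain_free
  if (is.null(gf)) stop("leadfield was built without the free-orientation gain")
  n <- ncol(gf) / 3L
  ubig <- matrix(0, 3L * n, nrow(gf))
  for (j in seq_len(n)) {
    a <- gf[, (3L * j - 2L):(3L * j)]
    sv <- svd(a)
    keep <- sv$d > max(sv$d) * 1e-10
    u <- sv$u
    u[, !keep] <- 0
    ubig[(3L * j - 2L):(3L * j), ] <- t(u)
  }
  cache$ubig <- ubig
  ubig
}

#' Fit an equivalent current dipole by exhaustive grid search
#'
#' For every sample in the closed window `center - half_width` to
#' `center + half_width` and every source-space node, solves the linear
#' least-squares free moment and computes the goodness of fit
#' `GOF = 100 (1 - |b - b_hat|^2 / |b|^2)`. Returns the node/sample pair with
#' maximal GOF (lowest node index, then earliest sample on exact ties). The
#' candidate grid is restricted to source-space nodes; no nonlinear
#' refinement is performed.
#'
#' @param evoked A `sef_evoked`.
#' @param leadfield A `leadfield` built with `store_free = TRUE`.
#' @param window_center Center of the fit window, ms post-stimulus.
#' @param half_width Half-width of the window, ms (0 fits a single sample).
#' @param kind Label for the fit (`"P20m"`, `"P40m"`, `"PMaxm"` or other).
#' @return A `dipole_fit`: `time` (ms), `position` (mm, surface RAS),
#'   `moment` (length-3, nA.m), `moment_magnitude` (nA.m), `gof` (percent),
#'   `kind`, `accepted` (NA until [reject_dipole()] is applied),
#'   `node` (source index of the fit).
#' @export
fit_dipole <- function(evoked, leadfield, window_center, half_width = 5,
                       kind = NA_character_) {
  sel <- which(evoked$times >= window_center - half_width &
               evoked$times <= window_center + half_width)
  if (!length(sel)) stop("fit window outside the evoked time axis")
  b <- evoked$data[, sel, drop = FALSE]
  denom <- colSums(b^2)
  if (all(denom == 0)) stop("all-zero data in the fit window: dipole undefined")
  ubig <- dipole_bases(leadfield)
  n <- nrow(ubig) / 3L
  proj <- ubig %*% b                                   # (3n) x T
  ssp <- colSums(array(proj^2, c(3L, n, length(sel)))) # n x T
  gof <- 100 * sweep(ssp, 2, pmax(denom, .Machine$double.xmin), "/")
  # t(gof) is scanned node-major: ties resolve to the lowest node index,
  # then the earliest sample within it
  best <- arrayInd(which.max(t(gof)), c(length(sel), n))
  t_i <- sel[best[1, 1]]
  node <- best[1, 2]
  a <- leadfield$gain_free[, (3L * node - 2L):(3L * node)]
  # least-squares moment via pseudo-inverse (robust to the silent component
  # of near-radial nodes)
  sv <- svd(a)
  keep <- sv$d > max(sv$d) * 1e-10
  m <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% evoked$data[, t_i]) / sv$d[keep])
  m <- as.vector(m)
  structure(list(time = evoked$times[t_i],
                 position = leadfield$source_space$positions[node, ],
                 moment = m, moment_magnitude = sqrt(sum(m^2)),
                 gof = gof[node, best[1, 1]], kind = kind,
                 accepted = NA, node = node),
            class = "dipole_fit")
}

#' @export
print.dipole_fit <- function(x, ...) {
  cat(sprintf(
    "dipole_fit %s: t=%g ms, GOF=%.1f%%, |Q|=%.1f nA.m, pos=(%.1f, %.1f, %.1f) mm, accepted=%s\n",
    x$kind, x$time, x$gof, x$moment_magnitude,
    x$position[1], x$position[2], x$position[3], x$accepted))
  invisible(x)
}

#' Accept or reject a dipole by distance to the contralateral sensorimotor ROI
#'
#' A dipole is accepted iff its position lies within 9 mm (inclusive) of some
#' source labeled precentral/postcentral gyrus or central/postcentral sulcus
#' in the hemisphere contralateral to the stimulated side.
#'
#' @param dipole A `dipole_fit`.
#' @param parcellation A `parcellation`.
#' @param source_space The matching `source_space`.
#' @param side `"UL"` or `"UR"`.
#' @param max_distance Rejection distance, mm.
#' @return The dipole with `accepted` set.
#' @export
reject_dipole <- function(dipole, parcellation, source_space, side,
                          max_distance = 9) {
  contra <- if (side == "UL") "right" else "left"
  lt <- parcellation$label_table
  ids <- lt$label_id[lt$hemisphere == contra &
                     lt$label_id %in% parcellation$roi_label_ids]
  roi <- which(parcellation$label_of %in% ids)
  d <- min(row_norms(sweep(source_space$positions[roi, , drop = FALSE], 2,
                           dipole$position)))
  dipole$accepted <- d <= max_distance + 1e-12
  dipole
}
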