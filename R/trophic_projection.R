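#' Probability triple to 4D trophic composition
#'
#' Adds the dependent "absence" dimension
#' `q_absence = mean(1 - p_i)` to the three capability probabilities and
#' normalises onto the simplex.  An all-zero triple maps to pure absence
#' `(0, 0, 0, 1)`.
#'
#' @param p_phago,p_photo,p_proto probabilities in `[0, 1]` (vectors of a
#'   common length).
#' @return Numeric matrix n x 4 with columns phago, photo, proto, absence;
#'   rows sum to 1.
#' @export
to_composition <- function(p_phago, p_photo, p_proto) {
  p <- cbind(phago = p_phago, photo = p_photo, proto = p_proto)
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  q <- cbind(p, absence = rowMeans(1 - p))
  s <- rowSums(q)
  s[s == 0] <- 1   # unreachable: absence is 1 whenever all p are 0
  q / s
}

# unit vertices of a regular tetrahedron, rows ordered
# (phago, photo, proto, absence)
tetra_vertices <- function() {
  rbind(phago = c(1, 1, 1), photo = c(1, -1, -1),
        proto = c(-1, 1, -1), absence = c(-1, -1, 1)) / sqrt(3)
}

#' Composition to spherical coordinates
#'
#' Embeds the 4-part composition as the barycentric combination of the
#' vertices of a regular tetrahedron and reads off the direction as
#' latitude/longitude (degrees).  The barycenter (zero vector) maps to
#' (0, 0) by convention.
#'
#' @param q numeric matrix n x 4 (rows on the simplex) from
#'   [to_composition()], or a length-4 vector.
#' @return Data.frame with `phi` (latitude, degrees in `[-90, 90]`) and
#'   `lambda` (longitude, degrees in `(-180, 180]`).
#' @export
composition_to_sphere <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  if (ncol(q) != 4) stopf("composition must have 4 parts")
  if (any(abs(rowSums(q) - 1) > 1e-9)) stopf("rows must sum to 1")
  r <- q %*% tetra_vertices()
  nr <- sqrt(rowSums(r^2))
  phi <- lambda <- numeric(nrow(q))
  ok <- nr >= 1e-12
  phi[ok] <- asin(r[ok, 3] / nr[ok]) * 180 / pi
  lambda[ok] <- atan2(r[ok, 2], r[ok, 1]) * 180 / pi
  data.frame(phi = phi, lambda = lambda)
}

#' Mollweide projection
#'
#' Solves the auxiliary-angle equation `2 theta + sin(2 theta) = pi sin(phi)`
#' by Newton iteration (tolerance 1e-10, start `theta = phi`; the poles are
#' handled analytically), then
#' `x = (2 sqrt(2) / pi) R lambda cos(theta)`, `y = sqrt(2) R sin(theta)`.
#' The projection is equal-area onto the `2 sqrt(2) R x sqrt(2) R` ellipse.
#'
#' @param phi latitude in degrees `[-90, 90]`.
#' @param lambda longitude in degrees `[-180, 180]`.
#' @param R map radius.
#' @return Data.frame with map coordinates `x`, `y`.
#' @export
mollweide <- function(phi, lambda, R = 1) {
  if (any(abs(phi) > 90) || any(abs(lambda) > 180))
    stopf("phi must lie in [-90, 90] and lambda in [-180, 180]")
  n <- max(length(phi), length(lambda))
  phi <- rep_len(phi, n); lambda <- rep_len(lambda, n)
  phi_r <- phi * pi / 180
  theta <- phi_r
  pole <- abs(phi) >= 90 - 1e-12
  theta[pole] <- sign(phi_r[pole]) * pi / 2
  act <- which(!pole)
  for (it in seq_len(100)) {
    if (length(act) == 0) break
    f <- 2 * theta[act] + sin(2 * theta[act]) - pi * sin(phi_r[act])
    fp <- 2 + 2 * cos(2 * theta[act])
    # f' vanishes at the poles; snap those iterates analytically
    flat <- fp < 1e-9
    theta[act][flat] <- sign(theta[act][flat]) * pi / 2
    step <- ifelse(flat, 0, f / pmax(fp, 1e-9))
    theta[act] <- pmin(pmax(theta[act] - step, -pi / 2), pi / 2)
    act <- act[abs(step) > 1e-10 & !flat]
  }
  if (length(act) > 0) stopf("Mollweide Newton iteration failed to converge")
  data.frame(x = 2 * sqrt(2) / pi * R * (lambda * pi / 180) * cos(theta),
             y = sqrt(2) * R * sin(theta))
}

#' Inverse Mollweide projection
#'
#' @param x,y map coordinates inside the projection ellipse.
#' @param R map radius.
#' @return Data.frame with `phi`, `lambda` in degrees.
#' @export
mollweide_inverse <- function(x, y, R = 1) {
  theta <- asin(pmin(pmax(y / (sqrt(2) * R), -1), 1))
  phi <- asin(pmin(pmax((2 * theta + sin(2 * theta)) / pi, -1), 1)) * 180 / pi
  ct <- cos(theta)
  lambda <- ifelse(ct < 1e-12, 0,
                   x * pi / (2 * sqrt(2) * R * ct) * 180 / pi)
  data.frame(phi = phi, lambda = lambda)
}

#' Map coordinates for a set of trophic predictions
#'
#' Composition -> tetrahedral sphere position -> Mollweide map, one row per
#' strain.
#'
#' @param predictions data.frame with `strain_id`, `p_phago`, `p_photo`,
#'   `p_proto` (and optionally `category`).
#' @param R map radius.
#' @return Data.frame: strain_id, phi, lambda, x, y (and category if
#'   present).
#' @export
trophic_map <- function(predictions, R = 1) {
  q <- to_composition(predictions$p_phago, predictions$p_photo,
                      predictions$p_proto)
  sph <- composition_to_sphere(q)
  xy <- mollweide(sph$phi, sph$lambda, R = R)
  out <- data.frame(strain_id = predictions$strain_id,
                    phi = sph$phi, lambda = sph$lambda,
                    x = xy$x, y = xy$y, stringsAsFactors = FALSE)
  if (!is.null(predictions$category)) out$category <- predictions$category
  out
}
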