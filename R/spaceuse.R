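# Utilization distributions: Lambert conformal conic projection, 2-stage
# multivariate plug-in bandwidth selection, FFT-binned Gaussian kernel
# density on a km grid, and probability contours.

#' Lambert conformal conic projection parameters
#'
#' Spherical LCC parameters for the study region (western Mediterranean /
#' northeast Atlantic). Distances are in km on a sphere of authalic radius
#' 6371.0088 km.
#'
#' @param sp1,sp2 standard parallels (degrees N).
#' @param lon0 central meridian (degrees E).
#' @param lat0 latitude of origin.
#' @return list of class `lcc_params`.
#' @export
lcc_params <- function(sp1 = 33, sp2 = 45, lon0 = 5, lat0 = 39) {
  structure(list(sp1 = sp1, sp2 = sp2, lon0 = lon0, lat0 = lat0,
                 R = 6371.0088), class = "lcc_params")
}

.lcc_n_F <- function(p) {
  phi1 <- .deg2rad(p$sp1); phi2 <- .deg2rad(p$sp2)
  n <- log(cos(phi1) / cos(phi2)) /
    log(tan(pi / 4 + phi2 / 2) / tan(pi / 4 + phi1 / 2))
  f <- cos(phi1) * tan(pi / 4 + phi1 / 2)^n / n
  list(n = n, f = f)
}

#' Project retained fixes to a conformal km grid
#'
#' Forward Lambert conformal conic projection of lon/lat positions.
#'
#' @param fixes data.frame with `lon`, `lat` (degrees); rows with missing
#'   coordinates are dropped. When a `retained` column is present only
#'   retained fixes are projected.
#' @param params a [lcc_params()] object.
#' @return data.frame of class `projected_points` with `x`, `y` in km and
#'   the projection parameters as attribute `params`.
#' @export
project_points <- function(fixes, params = lcc_params()) {
  if ("retained" %in% names(fixes)) fixes <- fixes[fixes$retained, , drop = FALSE]
  ok <- !is.na(fixes$lon) & !is.na(fixes$lat)
  fixes <- fixes[ok, , drop = FALSE]
  if (nrow(fixes) == 0) stop("no usable fixes to project")
  nf <- .lcc_n_F(params)
  phi <- .deg2rad(fixes$lat)
  if (any(abs(fixes$lat) >= 90)) stop("latitude at projection singularity")
  rho <- params$R * nf$f / tan(pi / 4 + phi / 2)^nf$n
  rho0 <- params$R * nf$f / tan(pi / 4 + .deg2rad(params$lat0) / 2)^nf$n
  gamma <- nf$n * .deg2rad(fixes$lon - params$lon0)
  structure(
    data.frame(x = rho * sin(gamma), y = rho0 - rho * cos(gamma)),
    params = params, class = c("projected_points", "data.frame"))
}

#' Inverse Lambert conformal conic projection
#'
#' @param x,y projected coordinates in km.
#' @param params a [lcc_params()] object.
#' @return data.frame with `lon`, `lat` in degrees.
#' @export
unproject_points <- function(x, y, params = lcc_params()) {
  nf <- .lcc_n_F(params)
  rho0 <- params$R * nf$f / tan(pi / 4 + .deg2rad(params$lat0) / 2)^nf$n
  rho <- sign(nf$n) * sqrt(x^2 + (rho0 - y)^2)
  theta <- atan2(x, rho0 - y)
  lon <- params$lon0 + .rad2deg(theta / nf$n)
  lat <- .rad2deg(2 * atan((params$R * nf$f / rho)^(1 / nf$n)) - pi / 2)
  data.frame(lon = lon, lat = lat)
}

# pairwise 4th-order density-derivative functionals psi_r of pre-sphered
# data, estimated with a spherically symmetric Gaussian pilot of SD g
.psi4_functionals <- function(z, g, chunk = 500L) {
  n <- nrow(z)
  he <- function(k, x) {
    switch(as.character(k),
           "0" = rep(1, length(x)),
           "1" = x,
           "2" = x^2 - 1,
           "3" = x^3 - 3 * x,
           "4" = x^4 - 6 * x^2 + 3)
  }
  acc <- c(psi40 = 0, psi04 = 0, psi22 = 0, psi31 = 0, psi13 = 0)
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1, n)
    dx <- outer(z[idx, 1], z[, 1], "-") / g
    dy <- outer(z[idx, 2], z[, 2], "-") / g
    w <- exp(-0.5 * (dx^2 + dy^2))
    acc["psi40"] <- acc["psi40"] + sum(he(4, dx) * w)
    acc["psi04"] <- acc["psi04"] + sum(he(4, dy) * w)
    acc["psi22"] <- acc["psi22"] + sum(he(2, dx) * he(2, dy) * w)
    acc["psi31"] <- acc["psi31"] + sum(he(3, dx) * he(1, dy) * w)
    acc["psi13"] <- acc["psi13"] + sum(he(1, dx) * he(3, dy) * w)
  }
  acc / (n^2 * g^4 * 2 * pi * g^2)
}

#' Plug-in bandwidth matrix
#'
#' Two-stage unconstrained plug-in selector for the bandwidth matrix of a
#' bivariate Gaussian kernel density estimate. The data are pre-sphered;
#' the fourth-order integrated density-derivative functionals are estimated
#' with a normal-scale Gaussian pilot, and the asymptotic mean integrated
#' squared error
#' \deqn{AMISE(H) = (4\pi)^{-1} n^{-1} |H|^{-1/2} + \frac14 \int
#'   \{tr(H \, \nabla^2 f)\}^2}
#' is minimised over symmetric positive-definite `H` (Cholesky
#' parameterisation, Nelder-Mead). The result is back-transformed to the
#' data scale, making the selector exactly equivariant under affine
#' rescaling. For Gaussian data the selector reproduces the normal
#' reference `H = n^{-1/3} \Sigma`.
#'
#' @param points a [project_points()] data.frame, or any two-column
#'   matrix/data.frame of coordinates (km).
#' @param pilot_g pilot SD on the sphered scale; default the normal-scale
#'   value `(4 / (6 n))^(1/8)`.
#' @return 2x2 symmetric positive-definite bandwidth matrix (km^2), with
#'   the pilot and the estimated functionals as attributes.
#' @export
plugin_bandwidth <- function(points, pilot_g = NULL) {
  x <- as.matrix(as.data.frame(points)[, c(1, 2), drop = FALSE])
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < 10) stop("need at least 10 points for bandwidth estimation")
  s <- stats::cov(x)
  ev <- eigen(s, symmetric = TRUE)
  if (ev$values[2] < 1e-10 * ev$values[1]) {
    warning("near-collinear points; ridging the covariance")
    s <- s + diag(1e-8 * max(ev$values[1], 1), 2)
    ev <- eigen(s, symmetric = TRUE)
  }
  s_half <- ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors)
  s_half_inv <- ev$vectors %*% diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  z <- x %*% s_half_inv

  if (is.null(pilot_g)) pilot_g <- (4 / (6 * n))^(1 / 8)
  psi <- .psi4_functionals(z, pilot_g)

  amise <- function(par) {
    l <- matrix(c(exp(par[1]), par[3], 0, exp(par[2])), 2, 2)
    h <- l %*% t(l)
    deth <- h[1, 1] * h[2, 2] - h[1, 2]^2
    if (deth <= 0) return(Inf)
    bias <- h[1, 1]^2 * psi["psi40"] + h[2, 2]^2 * psi["psi04"] +
      2 * (h[1, 1] * h[2, 2] + 2 * h[1, 2]^2) * psi["psi22"] +
      4 * h[1, 1] * h[1, 2] * psi["psi31"] +
      4 * h[1, 2] * h[2, 2] * psi["psi13"]
    1 / (4 * pi * n * sqrt(deth)) + 0.25 * bias
  }
  h0 <- n^(-1 / 3)
  par0 <- c(log(sqrt(h0)), log(sqrt(h0)), 0)
  opt <- stats::optim(par0, amise, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  l <- matrix(c(exp(opt$par[1]), opt$par[3], 0, exp(opt$par[2])), 2, 2)
  hz <- l %*% t(l)
  h <- s_half %*% hz %*% s_half
  h <- (h + t(h)) / 2
  attr(h, "pilot_g") <- pilot_g
  attr(h, "psi4") <- psi
  h
}

#' Gaussian kernel density estimate on a km grid
#'
#' Fixed-kernel density estimation with an unconstrained bandwidth matrix,
#' computed by linear binning of the points onto the grid and FFT
#' convolution with the (untruncated) Gaussian kernel. The grid covers the
#' data bounding box plus `pad_sd` kernel SDs, so that the discretised
#' density integrates to 1 within numerical tolerance.
#'
#' @param points two-column coordinates in km (e.g. [project_points()]).
#' @param bandwidth 2x2 SPD bandwidth matrix (km^2), e.g. from
#'   [plugin_bandwidth()].
#' @param cell_size grid cell edge in km (default 1).
#' @param pad_sd padding around the data bounding box in units of the
#'   largest kernel SD (default 4).
#' @param max_cells refuse to build grids larger than this (default 4e6)
#'   with a suggestion to coarsen `cell_size`.
#' @param weights optional non-negative point weights (normalised
#'   internally); used e.g. to weight birds equally in pooled population
#'   estimates.
#' @return object of class `density_grid`: list with `x`, `y` (cell-centre
#'   coordinates), `z` (density per km^2, `length(x)` x `length(y)`),
#'   `cell_size`, `bandwidth`, `n`.
#' @export
kernel_density <- function(points, bandwidth, cell_size = 1, pad_sd = 4,
                           max_cells = 4e6, weights = NULL) {
  x <- as.matrix(as.data.frame(points)[, c(1, 2), drop = FALSE])
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0)) stop("bad `weights`")
  weights <- weights / sum(weights)
  ev <- eigen(bandwidth, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("bandwidth matrix must be positive definite")
  pad <- pad_sd * sqrt(ev[1])
  x0 <- min(x[, 1]) - pad; x1 <- max(x[, 1]) + pad
  y0 <- min(x[, 2]) - pad; y1 <- max(x[, 2]) + pad
  nx <- ceiling((x1 - x0) / cell_size)
  ny <- ceiling((y1 - y0) / cell_size)
  if (as.numeric(nx) * ny > max_cells) {
    stop("grid would have ", nx, " x ", ny,
         " cells; increase `cell_size` (or `max_cells`)")
  }
  gx <- x0 + (seq_len(nx) - 0.5) * cell_size
  gy <- y0 + (seq_len(ny) - 0.5) * cell_size

  # linear binning onto cell centres
  ui <- (x[, 1] - gx[1]) / cell_size + 1
  vi <- (x[, 2] - gy[1]) / cell_size + 1
  i0 <- pmin(pmax(floor(ui), 1), nx - 1); wx <- ui - i0
  j0 <- pmin(pmax(floor(vi), 1), ny - 1); wy <- vi - j0
  counts <- numeric(nx * ny)
  add <- function(i, j, w) {
    idx <- (j - 1) * nx + i
    tab <- rowsum(w, idx)
    counts[as.integer(rownames(tab))] <<- counts[as.integer(rownames(tab))] + tab[, 1]
  }
  add(i0, j0, weights * (1 - wx) * (1 - wy))
  add(i0 + 1, j0, weights * wx * (1 - wy))
  add(i0, j0 + 1, weights * (1 - wx) * wy)
  add(i0 + 1, j0 + 1, weights * wx * wy)
  cmat <- matrix(counts, nx, ny)

  # FFT convolution with the kernel evaluated on wrapped offsets
  px <- stats::nextn(2 * nx, 2)
  py <- stats::nextn(2 * ny, 2)
  offx <- c(0:(px / 2 - 1), -(px / 2):-1) * cell_size
  offy <- c(0:(py / 2 - 1), -(py / 2):-1) * cell_size
  hinv <- solve(bandwidth)
  qf <- outer(offx^2 * hinv[1, 1], offy^2 * hinv[2, 2], "+") +
    2 * hinv[1, 2] * outer(offx, offy)
  kern <- exp(-0.5 * qf) / (2 * pi * sqrt(det(bandwidth)))
  cpad <- matrix(0, px, py)
  cpad[seq_len(nx), seq_len(ny)] <- cmat
  conv <- Re(stats::fft(stats::fft(cpad) * stats::fft(kern), inverse = TRUE)) / (px * py)
  z <- conv[seq_len(nx), seq_len(ny)]   # weights already sum to 1
  z[z < 0] <- 0

  structure(list(x = gx, y = gy, z = z, cell_size = cell_size,
                 bandwidth = bandwidth, n = n),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d cells of %.3g km, mass %.4f (n = %d)\n",
              length(x$x), length(x$y), x$cell_size,
              sum(x$z) * x$cell_size^2, x$n))
  invisible(x)
}

#' Probability contours of a density grid
#'
#' For each level p the highest-density region is built as the smallest set
#' of cells (taken in order of decreasing density) containing at least
#' p percent of the total grid mass. Masks are nested by construction.
#'
#' @param grid a [kernel_density()] object.
#' @param levels percentages in (0, 100); default `c(25, 50, 70, 90)`.
#' @return object of class `contour_set`: list with `levels`, `masks`
#'   (logical matrices), `thresholds` (density at the mask boundary),
#'   `areas` (km^2), `masses` (fraction of total mass actually enclosed)
#'   and the grid geometry.
#' @export
contour_levels <- function(grid, levels = c(25, 50, 70, 90)) {
  if (any(levels <= 0 | levels >= 100)) stop("levels must be inside (0, 100)")
  levels <- sort(levels)
  cell_area <- grid$cell_size^2
  zv <- as.vector(grid$z)
  o <- order(zv, decreasing = TRUE)
  cum <- cumsum(zv[o]) * cell_area
  total <- cum[length(cum)]
  masks <- list(); thresholds <- numeric(0); areas <- numeric(0); masses <- numeric(0)
  for (p in levels) {
    k <- which(cum >= p / 100 * total)[1]
    mask <- matrix(FALSE, nrow(grid$z), ncol(grid$z))
    mask[o[seq_len(k)]] <- TRUE
    masks[[as.character(p)]] <- mask
    thresholds <- c(thresholds, zv[o[k]])
    areas <- c(areas, k * cell_area)
    masses <- c(masses, cum[k] / total)
  }
  structure(list(levels = levels, masks = masks, thresholds = thresholds,
                 areas = areas, masses = masses,
                 x = grid$x, y = grid$y, cell_size = grid$cell_size),
            class = "contour_set")
}

#' @export
print.contour_set <- function(x, ...) {
  cat("<contour_set>\n")
  for (i in seq_along(x$levels)) {
    cat(sprintf("  %2d%%: area %.1f km^2 (mass %.3f)\n",
                x$levels[i], x$areas[i], x$masses[i]))
  }
  invisible(x)
}

#' Trace contour polygons
#'
#' Polygonises a contour set by tracing the density iso-lines at each mask
#' threshold.
#'
#' @param grid a [kernel_density()] object.
#' @param contours a [contour_levels()] object computed from it.
#' @return named list (one element per level) of lists of data.frames with
#'   `x`, `y` vertex columns (km).
#' @export
contour_polygons <- function(grid, contours) {
  out <- list()
  for (i in seq_along(contours$levels)) {
    cl <- grDevices::contourLines(grid$x, grid$y, grid$z,
                                  levels = contours$thresholds[i])
    out[[as.character(contours$levels[i])]] <-
      lapply(cl, function(p) data.frame(x = p$x, y = p$y))
  }
  out
}

#' Write a density grid as an ESRI ASCII raster
#'
#' @param grid a [kernel_density()] object.
#' @param path output file.
#' @export
write_ascii_grid <- function(grid, path) {
  nx <- length(grid$x); ny <- length(grid$y)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nx),
    sprintf("nrows %d", ny),
    sprintf("xllcorner %.6f", grid$x[1] - grid$cell_size / 2),
    sprintf("yllcorner %.6f", grid$y[1] - grid$cell_size / 2),
    sprintf("cellsize %.6f", grid$cell_size),
    "NODATA_value -9999"
  ), con)
  for (j in ny:1) {
    writeLines(paste(formatC(grid$z[, j], format = "g", digits = 7),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Write contour polygons as GeoJSON
#'
#' @param polygons a [contour_polygons()] list.
#' @param path output file.
#' @param params optional [lcc_params()]; when supplied, vertices are
#'   inverse-projected to lon/lat before writing.
#' @export
write_contours_geojson <- function(polygons, path, params = NULL) {
  feats <- list()
  for (lev in names(polygons)) {
    for (poly in polygons[[lev]]) {
      coords <- if (is.null(params)) {
        cbind(poly$x, poly$y)
      } else {
        ll <- unproject_points(poly$x, poly$y, params)
        cbind(ll$lon, ll$lat)
      }
      coords <- rbind(coords, coords[1, ])  # close the ring
      feats[[length(feats) + 1]] <- list(
        type = "Feature",
        properties = list(level = as.numeric(lev)),
        geometry = list(type = "Polygon",
                        coordinates = list(unname(split(coords, row(coords)) |>
                                                    lapply(as.numeric))))
      )
    }
  }
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}
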