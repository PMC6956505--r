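# Avian tetrahedral color space: spectrum processing, quantum catches and
# hull-volume overlap between fruit color categories.

#' The standard 5 nm wavelength grid (300-700 nm)
#' @return Numeric vector of band centers.
#' @export
spectral_grid <- function() seq(300, 700, by = 5)

#' Process a raw reflectance spectrum
#'
#' Bins a raw spectrum to 5 nm bands over 300-700 nm, applies a centered
#' running mean of `window` bands (which also damps background measurement
#' artifacts), and clamps negative reflectance to zero. A constant spectrum
#' passes through unchanged; edge bands use the partial window.
#'
#' @param spectrum A data frame with columns `wavelength` (nm) and
#'   `reflectance`, covering at least 300-700 nm.
#' @param window Odd running-mean width in bands (default 3).
#' @return A tibble with `wavelength` on the 5 nm grid and processed
#'   `reflectance`.
#' @export
process_spectrum <- function(spectrum, window = 3) {
  spectrum <- tibble::as_tibble(spectrum)
  stopifnot(all(c("wavelength", "reflectance") %in% names(spectrum)))
  wl <- spectrum$wavelength
  if (min(wl) > 300 || max(wl) < 700) {
    stop("spectrum covers ", min(wl), "-", max(wl),
         " nm; need at least 300-700 nm", call. = FALSE)
  }
  grid <- spectral_grid()
  # average raw points into 5 nm bands centered on the grid
  band <- grid[pmax(1L, pmin(length(grid), round((wl - 300) / 5) + 1L))]
  binned <- tapply(spectrum$reflectance, band, mean)
  refl <- as.numeric(binned[as.character(grid)])
  if (anyNA(refl)) { # sparse input: fill gaps by linear interpolation
    refl <- stats::approx(as.numeric(names(binned)), as.numeric(binned),
                          xout = grid, rule = 2)$y
  }
  refl <- running_mean(refl, window)
  refl[refl < 0] <- 0
  tibble::tibble(wavelength = grid, reflectance = refl)
}

# centered running mean with partial windows at the edges (constant-preserving)
running_mean <- function(x, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(x)
  h <- (window - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- max(1, i - h):min(n, i + h)
    mean(x[idx])
  }, numeric(1))
}

#' Mean spectrum across fruits of a species
#'
#' Pointwise arithmetic mean of processed spectra on a common grid.
#'
#' @param spectra Either a list of processed spectrum tibbles or a single
#'   long tibble with columns `wavelength`, `reflectance` and a grouping
#'   column named by `id`.
#' @param id Grouping column used when `spectra` is a long tibble.
#' @return A tibble with `wavelength` and mean `reflectance`.
#' @export
mean_spectrum <- function(spectra, id = "fruit") {
  if (is.data.frame(spectra)) {
    stopifnot(all(c("wavelength", "reflectance") %in% names(spectra)))
    out <- dplyr::summarise(dplyr::group_by(spectra, .data$wavelength),
                            reflectance = mean(.data$reflectance), .groups = "drop")
    return(dplyr::arrange(out, .data$wavelength))
  }
  grids <- lapply(spectra, `[[`, "wavelength")
  if (!all(vapply(grids, identical, logical(1), y = grids[[1]]))) {
    stop("spectra are not on a common wavelength grid", call. = FALSE)
  }
  refl <- rowMeans(do.call(cbind, lapply(spectra, `[[`, "reflectance")))
  tibble::tibble(wavelength = grids[[1]], reflectance = refl)
}

#' A UV-sensitive avian visual model
#'
#' Four Gaussian cone sensitivity curves (ultraviolet-, short-, medium- and
#' long-wave sensitive) on the 5 nm grid, each normalised to unit area, plus
#' an illuminant (flat by default). The peak wavelengths approximate an
#' average UV-sensitive bird; published templates can be substituted by
#' passing explicit curves.
#'
#' @param peaks Named numeric of peak wavelengths in nm for `u`, `s`, `m`,
#'   `l`.
#' @param bandwidth Gaussian standard deviation(s) in nm (recycled to 4).
#' @param illuminant Numeric vector on the grid, or `NULL` for flat.
#' @param sensitivities Optional 4-column matrix of explicit curves on the
#'   grid (columns u, s, m, l), overriding the Gaussians.
#' @return A list with `wavelength`, `sensitivities` (length(grid) x 4
#'   matrix, unit area columns) and `illuminant`.
#' @export
avian_visual_model <- function(peaks = c(u = 370, s = 445, m = 508, l = 565),
                               bandwidth = 40,
                               illuminant = NULL,
                               sensitivities = NULL) {
  grid <- spectral_grid()
  dl <- 5
  if (is.null(sensitivities)) {
    bandwidth <- rep_len(bandwidth, 4L)
    sensitivities <- vapply(seq_along(peaks), function(i) {
      s <- exp(-0.5 * ((grid - peaks[i]) / bandwidth[i])^2)
      s / (sum(s) * dl)
    }, numeric(length(grid)))
  } else {
    stopifnot(nrow(sensitivities) == length(grid), ncol(sensitivities) == 4)
    if (any(sensitivities < 0)) stop("sensitivities must be >= 0", call. = FALSE)
    sensitivities <- sweep(sensitivities, 2, colSums(sensitivities) * dl, "/")
  }
  colnames(sensitivities) <- c("u", "s", "m", "l")
  if (is.null(illuminant)) illuminant <- rep(1, length(grid))
  stopifnot(length(illuminant) == length(grid))
  structure(list(wavelength = grid, sensitivities = sensitivities,
                 illuminant = illuminant),
            class = "avian_visual_model")
}

#' Relative quantum catches of a spectrum
#'
#' For each cone class i, Q_i = sum_lambda R(lambda) S_i(lambda) I(lambda)
#' d(lambda), normalised so the four catches sum to 1. Relative catches are
#' invariant to overall spectrum brightness.
#'
#' @param spectrum A processed spectrum tibble on the 5 nm grid.
#' @param vm An [avian_visual_model()].
#' @return Named numeric `c(u, s, m, l)` summing to 1.
#' @export
quantum_catch <- function(spectrum, vm = avian_visual_model()) {
  stopifnot(inherits(vm, "avian_visual_model"))
  spectrum <- tibble::as_tibble(spectrum)
  if (!identical(as.numeric(spectrum$wavelength), as.numeric(vm$wavelength))) {
    stop("spectrum is not on the visual model's 5 nm grid; run process_spectrum()",
         call. = FALSE)
  }
  R <- spectrum$reflectance
  if (all(R == 0)) stop("all-zero spectrum: chromaticity undefined", call. = FALSE)
  q <- colSums(R * vm$illuminant * vm$sensitivities * 5)
  q / sum(q)
}

# vertices of a regular tetrahedron with centroid at the origin (rows u,s,m,l)
tetra_vertices <- function() {
  v <- rbind(u = c(1, 1, 1), s = c(1, -1, -1), m = c(-1, 1, -1), l = c(-1, -1, 1))
  v / sqrt(3) # unit circumradius
}

#' Map relative quantum catches into tetrahedral color space
#'
#' Barycentric-to-Cartesian map onto a regular tetrahedron with centroid at
#' the origin; the achromatic point (equal catches) maps to the origin and a
#' pure cone maps to its vertex.
#'
#' @param usml Numeric vector of 4 non-negative catches summing to 1, or a
#'   4-column matrix of them (rows = stimuli).
#' @return A numeric `xyz` vector, or an n x 3 matrix for matrix input.
#' @export
tetra_coords <- function(usml) {
  if (is.null(dim(usml))) usml <- matrix(usml, nrow = 1)
  if (ncol(usml) != 4) stop("usml must have 4 components", call. = FALSE)
  if (any(usml < -1e-9)) stop("usml components must be >= 0", call. = FALSE)
  if (any(abs(rowSums(usml) - 1) > 1e-6)) {
    stop("usml components must sum to 1", call. = FALSE)
  }
  xyz <- usml %*% tetra_vertices()
  colnames(xyz) <- c("x", "y", "z")
  if (nrow(xyz) == 1) xyz[1, ] else xyz
}

#' Species-level color points in avian visual space
#'
#' Processes every fruit spectrum, averages within species, computes relative
#' quantum catches and tetrahedral coordinates.
#'
#' @param spectra Long tibble with columns `species`, `fruit`, `wavelength`,
#'   `reflectance` (raw or processed).
#' @param vm An [avian_visual_model()].
#' @param window Running-mean window for [process_spectrum()].
#' @return A tibble with one row per species: `species`, `u`, `s`, `m`, `l`,
#'   `x`, `y`, `z`.
#' @export
species_color_points <- function(spectra, vm = avian_visual_model(), window = 3) {
  spectra <- tibble::as_tibble(spectra)
  stopifnot(all(c("species", "wavelength", "reflectance") %in% names(spectra)))
  spectra$species <- normalize_taxa(spectra$species)
  if (!"fruit" %in% names(spectra)) spectra$fruit <- 1L
  per_species <- dplyr::group_split(dplyr::group_by(spectra, .data$species))
  rows <- lapply(per_species, function(d) {
    fruits <- dplyr::group_split(dplyr::group_by(d, .data$fruit))
    proc <- lapply(fruits, process_spectrum, window = window)
    usml <- quantum_catch(mean_spectrum(proc), vm)
    xyz <- tetra_coords(usml)
    tibble::tibble(species = d$species[[1]],
                   u = usml[["u"]], s = usml[["s"]], m = usml[["m"]], l = usml[["l"]],
                   x = xyz[["x"]], y = xyz[["y"]], z = xyz[["z"]])
  })
  dplyr::bind_rows(rows)
}

## ---- convex hulls in 3D -------------------------------------------------

# Supporting half-spaces of the convex hull of a small 3D point set, by
# brute-force plane enumeration over point triples. Returns list(A, b) with
# the hull = {x : A x <= b}, or NULL if the set is degenerate (< 4 points or
# all coplanar).
hull_halfspaces <- function(pts, tol = 1e-9) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 4) return(NULL)
  scale <- max(1, max(abs(pts)))
  combs <- utils::combn(nrow(pts), 3)
  A <- NULL; b <- NULL
  for (k in seq_len(ncol(combs))) {
    i <- combs[, k]
    n <- crossprod_vec(pts[i[2], ] - pts[i[1], ], pts[i[3], ] - pts[i[1], ])
    nn <- sqrt(sum(n^2))
    if (nn < tol * scale^2) next
    n <- n / nn
    d <- sum(n * pts[i[1], ])
    s <- pts %*% n - d
    if (all(s <= tol * scale)) {
      A <- rbind(A, n); b <- c(b, d)
    } else if (all(s >= -tol * scale)) {
      A <- rbind(A, -n); b <- c(b, -d)
    }
  }
  if (is.null(A)) return(NULL)
  key <- paste(round(A[, 1], 7), round(A[, 2], 7), round(A[, 3], 7), round(b, 7))
  keep <- !duplicated(key)
  A <- A[keep, , drop = FALSE]; b <- b[keep]
  # degenerate (flat) hulls show up as a pair of opposite half-spaces at
  # (numerically) zero separation
  list(A = A, b = b)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

hull_contains <- function(x, hs, tol = 1e-9) {
  # x: m x 3 matrix; TRUE where x satisfies every supporting half-space

  rowSums(sweep(x %*% t(hs$A), 2, hs$b, "-") > tol) == 0
}

#' Convex-hull volumes and their overlap in color space
#'
#' Computes the convex hull of each point set and estimates hull volumes and
#' the volume of their intersection by Monte-Carlo rejection sampling over
#' the bounding box, with a declared sample count and seed. The overlap
#' fraction is reported relative to the smaller hull and, alternatively,
#' relative to the union.
#'
#' @param points_a,points_b Data frames or matrices of 3D points (columns
#'   x, y, z); at least 4 points in general position for a non-degenerate
#'   hull.
#' @param n_samples Monte-Carlo sample count (default 1e5).
#' @param seed Integer seed for the sampler.
#' @return A tibble with `vol_a`, `vol_b`, `overlap_vol`, `fraction`
#'   (overlap / smaller volume), `fraction_union`, `degenerate`,
#'   `n_samples` and `seed`.
#' @export
hull_volume_overlap <- function(points_a, points_b, n_samples = 1e5, seed = 1L) {
  pa <- as.matrix(as.data.frame(points_a)[, 1:3])
  pb <- as.matrix(as.data.frame(points_b)[, 1:3])
  ha <- hull_halfspaces(pa)
  hb <- hull_halfspaces(pb)
  mc_vol <- function(pts, hs, rng) {
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    box <- prod(hi - lo)
    if (box <= 0) return(0)
    x <- cbind(stats::runif(n_samples, lo[1], hi[1]),
               stats::runif(n_samples, lo[2], hi[2]),
               stats::runif(n_samples, lo[3], hi[3]))
    box * mean(hull_contains(x, hs))
  }
  degenerate <- is.null(ha) || is.null(hb)
  out <- withr_seed(seed, {
    vol_a <- if (is.null(ha)) 0 else mc_vol(pa, ha)
    vol_b <- if (is.null(hb)) 0 else mc_vol(pb, hb)
    if (degenerate || vol_a == 0 || vol_b == 0) {
      overlap <- 0
    } else {
      lo <- pmax(apply(pa, 2, min), apply(pb, 2, min))
      hi <- pmin(apply(pa, 2, max), apply(pb, 2, max))
      if (any(hi <= lo)) {
        overlap <- 0
      } else {
        x <- cbind(stats::runif(n_samples, lo[1], hi[1]),
                   stats::runif(n_samples, lo[2], hi[2]),
                   stats::runif(n_samples, lo[3], hi[3]))
        overlap <- prod(hi - lo) * mean(hull_contains(x, ha) & hull_contains(x, hb))
      }
    }
    list(vol_a = vol_a, vol_b = vol_b, overlap = overlap)
  })
  smaller <- min(out$vol_a, out$vol_b)
  union <- out$vol_a + out$vol_b - out$overlap
  tibble::tibble(
    vol_a = out$vol_a, vol_b = out$vol_b, overlap_vol = out$overlap,
    fraction = if (smaller > 0) min(1, out$overlap / smaller) else 0,
    fraction_union = if (union > 0) out$overlap / union else 0,
    degenerate = degenerate || out$vol_a == 0 || out$vol_b == 0,
    n_samples = n_samples, seed = as.integer(seed)
  )
}

#' Pairwise hull overlap between color categories
#'
#' @param points A tibble of species color points with `x`, `y`, `z` and a
#'   category column.
#' @param category Name of the category column (default `"category"`).
#' @param n_samples,seed Passed to [hull_volume_overlap()].
#' @return A tibble with one row per unordered category pair.
#' @export
category_overlap_matrix <- function(points, category = "category",
                                    n_samples = 1e5, seed = 1L) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("x", "y", "z", category) %in% names(points)))
  cats <- sort(unique(points[[category]]))
  pairs <- utils::combn(cats, 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    a <- points[points[[category]] == p[1], c("x", "y", "z")]
    b <- points[points[[category]] == p[2], c("x", "y", "z")]
    res <- hull_volume_overlap(a, b, n_samples = n_samples, seed = seed + i)
    dplyr::bind_cols(tibble::tibble(category_a = p[1], category_b = p[2]), res)
  })
  dplyr::bind_rows(rows)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  force(seed) # must be forced before the current RNG state is saved
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
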