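grid <- spectral_grid()

test_that("spectrum processing bins, smooths and clamps", {
  raw <- tibble::tibble(wavelength = seq(298, 702, by = 1), reflectance = 0.5)
  out <- process_spectrum(raw)
  expect_equal(out$wavelength, grid)
  expect_equal(out$reflectance, rep(0.5, length(grid)))

  dip <- tibble::tibble(wavelength = grid, reflectance = c(-0.02, rep(0.3, length(grid) - 1)))
  expect_true(all(process_spectrum(dip)$reflectance >= 0))

  # smoothing reduces variance of white noise; oracle = direct running mean
  set.seed(3)
  noise <- tibble::tibble(wavelength = grid, reflectance = 0.5 + rnorm(length(grid), 0, 0.1))
  out <- process_spectrum(noise, window = 3)
  expect_lt(var(out$reflectance), var(noise$reflectance))
  direct <- vapply(seq_along(grid), function(i) {
    idx <- max(1, i - 1):min(length(grid), i + 1)
    mean(noise$reflectance[idx])
  }, numeric(1))
  expect_equal(out$reflectance, pmax(direct, 0))

  expect_error(process_spectrum(tibble::tibble(wavelength = 400:700, reflectance = 1)),
               "300")
})

test_that("mean spectrum is a pointwise mean", {
  s <- tibble::tibble(wavelength = grid, reflectance = 0.2)
  expect_equal(mean_spectrum(list(s, s)), s)
  s2 <- tibble::tibble(wavelength = grid, reflectance = 0.4)
  expect_equal(mean_spectrum(list(s, s2))$reflectance, rep(0.3, length(grid)))
  bad <- tibble::tibble(wavelength = grid + 1, reflectance = 0.4)
  expect_error(mean_spectrum(list(s, bad)), "common")

  # CLT: mean of noisy replicates close to the template at every band
  set.seed(4)
  tmpl <- 0.3 + 0.2 * sin(grid / 50)
  reps <- lapply(1:20, function(i)
    tibble::tibble(wavelength = grid, reflectance = tmpl + rnorm(length(grid), 0, 0.05)))
  m <- mean_spectrum(reps)$reflectance
  se <- 0.05 / sqrt(20)
  expect_true(all(abs(m - tmpl) < 4 * se))
})

test_that("quantum catches are normalised, achromatic for flat spectra, and brightness-invariant", {
  vm <- avian_visual_model()
  flat <- tibble::tibble(wavelength = grid, reflectance = 0.37)
  q <- quantum_catch(flat, vm)
  expect_equal(sum(q), 1)
  expect_equal(unname(q), rep(0.25, 4), tolerance = 1e-10)

  set.seed(5)
  spec <- tibble::tibble(wavelength = grid, reflectance = runif(length(grid)))
  bright <- dplyr::mutate(spec, reflectance = reflectance * 7.3)
  expect_equal(quantum_catch(spec, vm), quantum_catch(bright, vm))

  # Gaussian peak at the short-wave cone peak makes s dominant
  peak <- tibble::tibble(wavelength = grid,
                         reflectance = exp(-0.5 * ((grid - 445) / 20)^2))
  qp <- quantum_catch(peak, vm)
  expect_equal(names(which.max(qp)), "s")
  # numeric-integration oracle with the model's own curves
  direct <- colSums(peak$reflectance * vm$illuminant * vm$sensitivities * 5)
  expect_equal(unname(qp), unname(direct / sum(direct)), tolerance = 1e-12)

  expect_error(quantum_catch(tibble::tibble(wavelength = grid, reflectance = 0), vm),
               "zero")
})

test_that("tetrahedral coordinates are the affine barycentric map", {
  expect_equal(unname(tetra_coords(c(0.25, 0.25, 0.25, 0.25))), c(0, 0, 0),
               tolerance = 1e-12)
  V <- drupevol:::tetra_vertices()
  expect_equal(unname(tetra_coords(c(1, 0, 0, 0))), unname(V["u", ]))
  # pairwise distances match direct affine evaluation on random simplex points
  set.seed(6)
  W <- matrix(rexp(40), 10, 4)
  W <- W / rowSums(W)
  X <- tetra_coords(W)
  expect_equal(as.matrix(dist(X)), as.matrix(dist(W %*% V)), tolerance = 1e-12)
  expect_error(tetra_coords(c(0.5, 0.5, 0.2, -0.2)), ">= 0")
  expect_error(tetra_coords(c(0.5, 0.5, 0.5, 0.5)), "sum")
})

test_that("hull overlap matches analytic volumes on boxes", {
  cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  self <- hull_volume_overlap(cube, cube, n_samples = 2e5, seed = 1)
  expect_equal(self$vol_a, 1, tolerance = 0.02)
  expect_equal(self$fraction, 1, tolerance = 0.02)

  far <- sweep(cube, 2, c(10, 0, 0), "+")
  expect_equal(hull_volume_overlap(cube, far, n_samples = 1e4, seed = 1)$overlap_vol, 0)

  shifted <- sweep(cube, 2, c(0.5, 0, 0), "+")
  res <- hull_volume_overlap(cube, shifted, n_samples = 5e5, seed = 2)
  expect_equal(res$overlap_vol, 0.5, tolerance = 0.02)
  expect_equal(res$fraction, res$overlap_vol / min(res$vol_a, res$vol_b))

  # coplanar points give a degenerate, zero-volume hull
  flat <- cbind(runif(6), runif(6), 0)
  deg <- hull_volume_overlap(flat, flat, n_samples = 1e4, seed = 3)
  expect_true(deg$degenerate)
  expect_equal(deg$overlap_vol, 0)
})

test_that("synthetic category templates order short-wave stimulation as observed", {
  vm <- avian_visual_model()
  tmpl <- spectrum_template(c("red", "black-sequential", "black-synchronous", "blue"))
  s_catch <- vapply(split(tmpl, tmpl$category), function(d)
    quantum_catch(tibble::tibble(wavelength = d$wavelength, reflectance = d$reflectance), vm)[["s"]],
    numeric(1))
  expect_equal(names(which.min(s_catch)), "red")
  expect_equal(names(which.max(s_catch)), "blue")
  expect_true(all(s_catch["blue"] > s_catch[c("black-sequential", "black-synchronous")]))
  expect_true(all(s_catch["red"] < s_catch[c("black-sequential", "black-synchronous")]))
})

test_that("overlap with a union of point sets dominates pairwise overlaps", {
  set.seed(8)
  a <- matrix(rnorm(30, sd = 0.3), ncol = 3)
  b1 <- sweep(matrix(rnorm(30, sd = 0.3), ncol = 3), 2, c(0.4, 0, 0), "+")
  b2 <- sweep(matrix(rnorm(30, sd = 0.3), ncol = 3), 2, c(-0.4, 0, 0), "+")
  o1 <- hull_volume_overlap(a, b1, n_samples = 2e5, seed = 4)$overlap_vol
  o2 <- hull_volume_overlap(a, b2, n_samples = 2e5, seed = 4)$overlap_vol
  ou <- hull_volume_overlap(a, rbind(b1, b2), n_samples = 2e5, seed = 4)$overlap_vol
  expect_gte(ou * 1.02 + 1e-6, max(o1, o2))
})
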