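# Pre-processing chain: registration recovery, bias correction, diffusion
# denoising, intensity normalisation, skull stripping.

fx_reg_fixed <- function() fx("reg_fixed", function() {
  tr <- build_anatomy(small_config())
  simulate_mri(tr, acquisition_spec(bias_amplitude = 0,
                                    noise_sigma = c(T1 = 0, T2 = 0),
                                    seed = 1))$t1
})

test_that("affine registration recovers known rigid perturbations", {
  fixv <- fx_reg_fixed()

  # identical images -> identity within 0.1 mm / 0.5 degrees
  est0 <- affine_register(fixv, fixv)
  expect_lt(sqrt(sum(est0$translation^2)), 0.1)
  expect_lt(rotation_angle_deg(est0), 0.5)

  # known (4, -3, 2) mm shift: the estimate maps fixed coords onto moving,
  # so it recovers the inverse displacement
  mov <- apply_affine(fixv, affine_transform(diag(3), c(4, -3, 2)), fill = 5)
  est <- affine_register(mov, fixv)
  expect_lt(max(abs(est$translation - c(-4, 3, -2))), 0.5)
  expect_lt(rotation_angle_deg(est), 0.5)

  # known 5 degree rotation about one axis
  movr <- apply_affine(fixv, cpinjury:::.rigid_from_params(c(0, 0, 0, 0, 0, 5)),
                       fill = 5)
  estr <- affine_register(movr, fixv)
  expect_lt(abs(rotation_angle_deg(estr) - 5), 0.5)
  expect_lt(sqrt(sum(estr$translation^2)), 0.5)

  # flat images cannot be registered
  flat <- image_volume(array(1, c(16, 16, 16)))
  expect_error(affine_register(flat, flat), "registration failure")
})

test_that("registration recovers random rigid perturbations (property)", {
  fixv <- fx_reg_fixed()
  withr::with_seed(21, {
    for (rep in 1:3) {
      p_true <- c(runif(3, -8, 8), runif(3, -5, 5))
      mov <- apply_affine(fixv, cpinjury:::.rigid_from_params(p_true), fill = 5)
      est <- affine_register(mov, fixv)
      truth <- invert_affine(cpinjury:::.rigid_from_params(p_true))
      expect_lt(max(abs(est$translation - truth$translation)), 0.5)
      rel <- compose_affine(invert_affine(truth), est)
      expect_lt(rotation_angle_deg(rel), 0.5)
    }
  })
})

test_that("affine transforms compose and invert exactly", {
  a <- cpinjury:::.rigid_from_params(c(3, -2, 1, 4, -7, 2))
  ia <- invert_affine(a)
  id <- compose_affine(a, ia)
  expect_lt(max(abs(id$matrix - diag(3))), 1e-9)
  expect_lt(max(abs(id$translation)), 1e-9)
  expect_error(affine_transform(matrix(0, 3, 3)), "invertible")
})

test_that("bias correction removes smooth multiplicative fields", {
  cfg <- cohort_phantom_config()
  tr <- fx_template()
  m0 <- simulate_mri(tr, acquisition_spec(bias_amplitude = 0,
                                          noise_sigma = c(T1 = 0, T2 = 0),
                                          seed = 2))
  mask <- tr$labels %in% c(2L, 3L, 4L, 5L) |> array(dim(tr$labels))
  wmi <- mask_erode(tr$labels == 4L, 4, cfg$spacing_mm)
  cv <- function(x) sd(x) / mean(x)

  # bias-free input passes through nearly unchanged inside the mask
  out0 <- correct_bias(m0$t1, mask)
  expect_lt(max(abs(out0$data[mask] - m0$t1$data[mask]) / m0$t1$data[mask]), 0.02)
  # in-mask mean preserved within 1%
  expect_lt(abs(mean(out0$data[mask]) - mean(m0$t1$data[mask])) /
              mean(m0$t1$data[mask]), 0.01)

  # +/-20% linear ramp: residual inhomogeneity of flat WM reduced >= 70%
  co <- cpinjury:::voxel_coords_mm(dim(tr$labels), cfg$spacing_mm)
  ramp <- 1 + 0.2 * co$x / max(abs(co$x))
  t1r <- image_volume(m0$t1$data * ramp, cfg$spacing_mm)
  before <- cv(t1r$data[wmi])
  after <- cv(correct_bias(t1r, mask)$data[wmi])
  expect_lt(after, 0.3 * before)

  # constant-scale bias leaves only a global constant
  t1c <- image_volume(m0$t1$data * 1.3, cfg$spacing_mm)
  outc <- correct_bias(t1c, mask)
  ratio <- outc$data[wmi] / m0$t1$data[wmi]
  expect_lt(diff(range(ratio)), 0.02 * mean(ratio))

  expect_error(correct_bias(m0$t1, array(FALSE, dim(tr$labels))), "empty mask")
})

test_that("curvature diffusion denoises flat regions and preserves edges", {
  # 0 iterations is the identity
  img <- image_volume(array(rnorm(16^3), c(16, 16, 16)))
  expect_identical(denoise_mcde(img, 0)$data, img$data)

  # flat region + Gaussian noise: sd reduced >= 30% in 5 iterations,
  # global mean preserved within 1%
  withr::with_seed(8, a <- array(100 + rnorm(32^3, 0, 5), c(32, 32, 32)))
  noisy <- image_volume(a)
  den <- denoise_mcde(noisy, 5, conductance = 10)
  core <- as.vector(den$data[5:28, 5:28, 5:28])
  expect_lt(sd(core), 0.7 * 5)
  expect_lt(abs(mean(den$data) - mean(noisy$data)) / mean(noisy$data), 0.01)

  # a step edge of contrast 10 kappa stays put (half-maximum crossing
  # moves < 1 voxel)
  kappa <- 2
  st <- array(0, c(32, 16, 16))
  st[17:32, , ] <- 10 * kappa
  eimg <- denoise_mcde(image_volume(st), 5, conductance = kappa)
  profile <- apply(eimg$data, 1, mean)
  crossing <- which(profile > 10 * kappa / 2)[1]
  expect_lte(abs(crossing - 17), 1)

  expect_error(denoise_mcde(img, 5, conductance = -1), "positive")
  expect_error(denoise_mcde(img, 5, dt = 0.2), "stability")
})

test_that("intensity normalisation maps the 1st/99th percentiles to 0/1", {
  withr::with_seed(3, a <- array(runif(20^3, 0, 100), c(20, 20, 20)))
  img <- image_volume(a)
  mask <- array(TRUE, dim(a))
  n1 <- normalize_intensity(img, mask)
  q <- quantile(n1$data[mask], c(0.01, 0.99), names = FALSE)
  expect_equal(q, c(0, 1), tolerance = 1e-10)

  # scale invariance: x10 input gives the identical output
  n10 <- normalize_intensity(image_volume(a * 10), mask)
  expect_equal(n10$data, n1$data, tolerance = 1e-12)

  # already-normalised input is a fixed point
  n2 <- normalize_intensity(n1, mask)
  expect_equal(n2$data, n1$data, tolerance = 1e-12)

  # a uniform ramp maps its in-mask median to ~0.5
  ramp <- image_volume(array(seq(0, 100, length.out = 20^3), c(20, 20, 20)))
  nr <- normalize_intensity(ramp, mask)
  expect_lt(abs(median(nr$data[mask]) - 0.5), 0.02)

  expect_error(normalize_intensity(image_volume(array(1, c(8, 8, 8))),
                                   array(TRUE, c(8, 8, 8))), "constant")
})

test_that("skull stripping isolates brain plus intradural CSF", {
  tr <- fx_lesion_truth()
  mri <- simulate_mri(tr, acquisition_spec(seed = 11))
  mask <- strip_skull(mri$t1)
  truthmask <- cpinjury:::arr_in(tr$labels, c(2L, 3L, 4L, 5L, 6L, 7L))
  dice <- 2 * sum(mask & truthmask) / (sum(mask) + sum(truthmask))
  expect_gte(dice, 0.95)

  # the (dark-on-T1) lesion stays inside the mask through hole filling
  expect_true(all(mask[tr$labels == 6L]))

  # pure noise cannot be stripped
  withr::with_seed(5, noise <- array(abs(rnorm(48^3, 0, 10)), c(48, 48, 48)))
  expect_error(strip_skull(image_volume(noise)), "stripping failure")
})
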