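test_that("multiplet areas encode proton stoichiometry", {
  g <- tiny_grid(8000)
  r3 <- synth_reference("a", list(multiplet(2.0, 3)), g)
  r9 <- synth_reference("b", list(multiplet(5.0, 9)), g)
  expect_equal(spectrum_integral(r9) / spectrum_integral(r3), 3,
               tolerance = 0.01)
  # multi-multiplet metabolite integrates to its total proton count ratio
  rm <- synth_reference("c", list(multiplet(1.5, 2, "doublet", J = 7),
                                  multiplet(3.5, 4, "triplet", J = 7)), g)
  expect_equal(spectrum_integral(rm) / spectrum_integral(r3), 2,
               tolerance = 0.01)
})

test_that("doublet line separation is J over the spectrometer frequency", {
  g <- ppm_grid(-0.32, 10.21, 46000)
  sep <- function(field) {
    d <- synth_reference("d", list(multiplet(4, 1, "doublet", J = 7)), g,
                         field_strength = field)
    x <- ppm_points(g)
    lo <- x < 4
    abs(x[!lo][which.max(d$intensity[!lo])] -
          x[lo][which.max(d$intensity[lo])])
  }
  expect_equal(sep(400), 7 / 400, tolerance = g$spacing / (7 / 400))
  # line separation in ppm is 8x larger at 100 than at 800 MHz
  expect_equal(sep(100) / sep(800), 8, tolerance = 0.02)
})

test_that("empty and invalid multiplet inputs are handled", {
  g <- tiny_grid(500)
  expect_warning(z <- synth_reference("none", list(), g), "zero reference")
  expect_true(all(z$intensity == 0))
  expect_error(multiplet(1, n_protons = -2), "positive integer")
  expect_warning(synth_reference("edge", list(multiplet(10.5, 1)), g),
                 "truncated")
})

test_that("anomer combination uses the aqueous equilibrium weights", {
  g <- tiny_grid(4000)
  alpha <- synth_reference("alpha", list(multiplet(5.2, 1, "doublet", J = 3.8),
                                         multiplet(3.4, 2)), g)
  beta <- synth_reference("beta", list(multiplet(4.6, 1, "doublet", J = 8.0),
                                       multiplet(3.2, 2)), g)
  glc <- combine_anomers(alpha, beta)
  expect_equal(glc$intensity, 0.36 * alpha$intensity + 0.64 * beta$intensity)
  # least-squares regression on the two anomers recovers the weights
  fit <- lm(glc$intensity ~ 0 + alpha$intensity + beta$intensity)
  expect_equal(unname(coef(fit)), c(0.36, 0.64), tolerance = 1e-8)
  # equal inputs: combination is the identity
  same <- combine_anomers(alpha, alpha)
  expect_equal(same$intensity, alpha$intensity)
  # complementary weights are order-independent
  swapped <- combine_anomers(beta, alpha, w_alpha = 0.64)
  expect_equal(swapped$intensity, glc$intensity)
  g2 <- tiny_grid(300)
  expect_error(combine_anomers(alpha, synth_reference("x", list(multiplet(1, 1)), g2)),
               "same grid")
})

test_that("reference file round-trip, padding and interpolation", {
  g <- tiny_grid(3000)
  ref <- synth_reference("met", list(multiplet(2.2, 2, "triplet", J = 7)), g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference(ref, path)
  back <- read_reference(path, g)
  expect_equal(back$intensity, ref$intensity, tolerance = 1e-8)

  # source covering 0-5 ppm only: zeros outside
  sub <- ppm_points(g)
  keep <- sub >= 0 & sub <= 5
  write.csv(data.frame(ppm = sub[keep], intensity = ref$intensity[keep]),
            path, row.names = FALSE)
  padded <- read_reference(path, g)
  expect_true(all(padded$intensity[!keep][abs(sub[!keep]) > 0.01] == 0))

  # two-row file: linear ramp between the two points
  writeLines(c("ppm,intensity", "0,0", "10,10"), path)
  ramp <- read_reference(path, g)
  inside <- sub >= 0 & sub <= 10
  expect_equal(ramp$intensity[inside], sub[inside], tolerance = 1e-8)

  writeLines(c("ppm,intensity", "0,1", "2,oops", "1,3"), path)
  expect_error(read_reference(path, g), "line")
})

test_that("synthetic library is deterministic with unique names and TSP", {
  lib1 <- default_library(8, seed = 1, grid = tiny_grid(1500))
  lib2 <- default_library(8, seed = 1, grid = tiny_grid(1500))
  expect_identical(ref_matrix(lib1), ref_matrix(lib2))
  expect_false(identical(ref_matrix(lib1),
                         ref_matrix(default_library(8, seed = 2,
                                                    grid = tiny_grid(1500)))))

  lib44 <- default_library(44, seed = 3, grid = tiny_grid(1500))
  expect_length(lib44$analytes, 44)
  expect_false(anyDuplicated(names(lib44$references)) > 0)
  expect_identical(lib44$tsp_name, "TSP")
  # TSP: 9-proton singlet at 0.0 ppm
  tsp <- lib44$references$TSP
  expect_equal(ppm_points(lib44$grid)[which.max(tsp$intensity)], 0,
               tolerance = 2 * lib44$grid$spacing)

  lib86 <- default_library(86, seed = 4, grid = tiny_grid(1200))
  expect_length(lib86$analytes, 86)
})

test_that("library rendering respects field-dependent dispersion at scale", {
  # crowding: most multiplet mass inside 1-4.5 ppm
  lib <- default_library(20, seed = 5, grid = tiny_grid(4000))
  x <- ppm_points(lib$grid)
  R <- ref_matrix(lib, analytes_only = TRUE)
  inside <- x >= 1 & x <= 4.5
  frac <- sum(R[inside, ]) / sum(R)
  expect_gt(frac, 0.5)
})

test_that("libraries round-trip through the manifest format", {
  lib <- tiny_library(3, 500)
  dir <- withr::local_tempdir()
  man <- write_library_manifest(lib, dir)
  back <- read_library_manifest(man)
  expect_identical(names(back$references), names(lib$references))
  expect_identical(back$tsp_name, "TSP")
  expect_equal(back$field_strength, lib$field_strength)
  expect_equal(ref_matrix(back), ref_matrix(lib), tolerance = 1e-8)
  expect_error(suppressWarnings(read_library_manifest(tempfile())),
               "cannot open|missing")
})
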