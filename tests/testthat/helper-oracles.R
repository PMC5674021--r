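# Independent oracles used across tests.

# Per-patch brute-force fill: expand each class into n_patches equal patches
# of its mean size, occupy every patch of size >= a, and sum patch by patch.
# Independent of the class-weighted sums in occupancy_point().
brute_force_fd <- function(classes, survival, sat_density, a) {
  patches <- unlist(mapply(function(s, n) rep(s, n),
                           classes$mean_size_ha, classes$n_patches,
                           SIMPLIFY = FALSE))
  occ <- patches[patches >= a]
  f <- nest_survival(occ, survival)
  d <- saturation_density(occ, sat_density)
  list(
    fecundity = sum(f * d * occ) / sum(d * occ),
    density = sum(d * occ) / sum(patches))
}

# Random small integer-count landscape whose class areas are exactly
# n_patches * mean_size, so the brute force and the class sums describe the
# same mosaic.
random_small_classes <- function(n_classes) {
  sizes <- sort(exp(runif(n_classes, log(0.5), log(400))))
  while (any(diff(sizes) < 1e-6)) {
    sizes <- sort(exp(runif(n_classes, log(0.5), log(400))))
  }
  n <- sample(1:20, n_classes, replace = TRUE)
  data.frame(class_label = sprintf("C%d", seq_len(n_classes)),
             mean_size_ha = sizes, n_patches = n,
             total_area_ha = n * sizes, stringsAsFactors = FALSE)
}

# Numerical-differentiation oracle for the Beverton-Holt curve, independent
# of the closed forms in the package. A plain real central difference of F
# loses all significant digits where the curve is nearly flat (small D,
# large gamma), so the first derivative uses the complex-step method -- a
# finite difference along the imaginary axis, free of subtractive
# cancellation -- and the second derivative is the real central difference
# of that complex-step slope.
bh_value_complex <- function(D, fit) {
  fit$F_max / (1 + (D / fit$K)^fit$gamma)
}
fd_slope <- function(D, fit, h = D * 1e-10) {
  Im(bh_value_complex(D + h * 1i, fit)) / h
}
fd_curvature <- function(D, fit, h = D * 1e-4) {
  (fd_slope(D + h, fit) - fd_slope(D - h, fit)) / (2 * h)
}

# Small reusable toy mosaic: two classes at 10 ha and 100 ha.
toy_dist <- function() {
  patch_dist(data.frame(class_label = c("small", "large"),
                        mean_size_ha = c(10, 100),
                        n_patches = c(5, 2),
                        total_area_ha = c(50, 200),
                        stringsAsFactors = FALSE))
}

# A temporary copy of a data frame written as csv; returns the path.
write_tmp_csv <- function(d) {
  f <- tempfile(fileext = ".csv")
  write.csv(d, f, row.names = FALSE)
  f
}
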