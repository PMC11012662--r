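# Shared fixtures and independent oracles for the test suite.

# Hand-drawn asymmetric fixture F1. Expected values below were frozen from
# an independent hand computation (per-pair trigonometry, dot products, and
# an explicit term-by-term shoelace sum), not from the package code.
f1_landmarks <- function() {
  back_landmarks("F1", list(
    shoulder_left = c(220, 370), shoulder_right = c(780, 410),
    axilla_left = c(280, 520), axilla_right = c(720, 500),
    waist_left = c(350, 820), waist_right = c(650, 840),
    iliac_left = c(300, 980), iliac_right = c(700, 970),
    c7 = c(500, 300)
  ), image_width = 1000, image_height = 1500)
}

f1_expected <- list(
  sha_deg = 4.0856167800, aha_deg = -2.6025622025, wha_deg = 3.8140748343,
  lwa_deg = 149.5119530573, rwa_deg = 147.3288549756, wad_deg = 2.1830980817,
  areas = c(shoulder_left_px2 = 37500, shoulder_right_px2 = 22500,
            waist_left_px2 = 55500, waist_right_px2 = 62900,
            pelvic_left_px2 = 28000, pelvic_right_px2 = 22750),
  sa_ratio = 1.6666666667, wa_ratio = 0.8823529412,
  pa_ratio = 1.2307692308, ta_ratio = 1.1188164586
)

# Independent two-way ICC oracle: computational sums-of-squares formulas
# (raw sums, not the mean-centred route the package uses), ICC formulas
# restated inline.
icc_oracle <- function(grid, form) {
  n <- nrow(grid)
  k <- ncol(grid)
  G <- sum(grid)
  C <- G^2 / (n * k)
  sst <- sum(grid^2) - C
  ssr <- sum(rowSums(grid)^2) / k - C
  ssc <- sum(colSums(grid)^2) / n - C
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  switch(form,
    single_consistency = (msr - mse) / (msr + (k - 1) * mse),
    single_agreement = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n),
    average_consistency = (msr - mse) / msr,
    average_agreement = (msr - mse) / (msr + (msc - mse) / n)
  )
}

# Monte-Carlo point-in-polygon area estimate (even-odd ray casting) with its
# standard error; independent of the shoelace route.
mc_polygon_area <- function(verts, n_points = 40000) {
  xr <- range(verts[, 1])
  yr <- range(verts[, 2])
  px <- stats::runif(n_points, xr[1], xr[2])
  py <- stats::runif(n_points, yr[1], yr[2])
  nv <- nrow(verts)
  inside <- logical(n_points)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    cross <- (yi > py) != (yj > py)
    slope_x <- xi + (py - yi) * (xj - xi) / (yj - yi)
    inside <- xor(inside, cross & (px < slope_x))
    j <- i
  }
  box <- diff(xr) * diff(yr)
  p_hat <- mean(inside)
  list(estimate = p_hat * box,
       se = box * sqrt(p_hat * (1 - p_hat) / n_points))
}

# Random convex polygon: points on a noisy ellipse at sorted angles.
random_convex_polygon <- function(n_vertices = 8) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  a <- stats::runif(1, 50, 200)
  b <- stats::runif(1, 50, 200)
  cbind(a * cos(th), b * sin(th))
}

# Reference-study summary tables shipped with the package.
reference_table <- function(name) {
  path <- system.file("extdata", "reference_study", paste0(name, ".csv"),
                      package = "trunkmetrics")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Small random deformed-landmark generator for property tests.
random_deformed <- function(template, tilt_sd = 3, shift_sd = 15, depth_sd = 10) {
  apply_deformity(template, list(
    sha_deg = stats::rnorm(1, 0, tilt_sd),
    aha_deg = stats::rnorm(1, 0, tilt_sd),
    wha_deg = stats::rnorm(1, 0, tilt_sd),
    trunk_shift_px = stats::rnorm(1, 0, shift_sd),
    waist_depth_left_px = stats::rnorm(1, 0, depth_sd),
    waist_depth_right_px = stats::rnorm(1, 0, depth_sd)
  ))
}
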