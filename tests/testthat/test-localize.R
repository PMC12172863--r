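toy_stc <- function(values, times) {
  structure(list(values = values, times = times), class = "source_estimate")
}

test_that("spatial filter averages same-label neighbors only", {
  wb <- cached_workbench(3)
  ss <- wb$source_space
  parc <- wb$parcellation
  n <- nrow(ss$positions)
  set.seed(4)
  vals <- matrix(rnorm(n * 5), n, 5)
  stc <- toy_stc(vals, times = 15:19)
  # radius 0 is the identity
  f0 <- spatial_filter(stc, ss, parc, radius = 0)
  expect_equal(f0$values, vals)
  # a spatially constant map is unchanged by averaging
  fc <- spatial_filter(toy_stc(matrix(1, n, 2), 15:16), ss, parc, radius = 5)
  expect_equal(fc$values, matrix(1, n, 2), tolerance = 1e-12)
  # direct check of the label-respecting mean at random sources
  f5 <- spatial_filter(stc, ss, parc, radius = 5)
  for (i in sample(n, 10)) {
    nb <- neighbors_within(ss, i, 5)
    nb <- nb[parc$label_of[nb] == parc$label_of[i]]
    expect_equal(f5$values[i, ], colMeans(vals[nb, , drop = FALSE]),
                 tolerance = 1e-12)
  }
  # a source whose 5 mm same-label neighborhood is only itself is unchanged
  op <- sefmapper:::spatial_filter_operator(ss, parc, 5)
  singles <- which(Matrix::rowSums(op != 0) == 1)
  if (length(singles))
    expect_equal(f5$values[singles[1], ], vals[singles[1], ])
})

test_that("windowed SVD satisfies the decomposition contract", {
  set.seed(11)
  n <- 200
  times <- seq(-50, 249)
  vals <- matrix(rnorm(n * 300), n, 300)
  dec <- svd_window(toy_stc(vals, times), window = c(15, 60))
  expect_identical(ncol(dec$U), 46L)  # closed window, 1 ms sampling
  expect_true(all(diff(dec$S) <= 0) && all(dec$S >= 0))
  x <- vals[, times >= 15 & times <= 60]
  expect_lt(norm(x - dec$U %*% diag(dec$S) %*% t(dec$V), "F") / norm(x, "F"),
            1e-10)
  expect_equal(crossprod(dec$U), diag(46), tolerance = 1e-10)
  expect_equal(crossprod(dec$V), diag(46), tolerance = 1e-10)
  # sign convention: peak of each temporal mode is positive
  expect_true(all(apply(dec$V, 2, function(v) v[which.max(abs(v))]) > 0))
  # rank-1 identity
  a <- rnorm(n); a <- a / sqrt(sum(a^2))
  b <- rnorm(46); b <- b / sqrt(sum(b^2))
  x1 <- matrix(0, n, 300)
  x1[, times >= 15 & times <= 60] <- 3 * a %o% b
  d1 <- svd_window(toy_stc(x1, times))
  expect_equal(d1$S[1], 3, tolerance = 1e-10)
  expect_lt(max(d1$S[-1]), 1e-10)
  expect_equal(abs(sum(d1$U[, 1] * a)), 1, tolerance = 1e-10)
  expect_error(svd_window(toy_stc(vals, times), window = c(500, 600)),
               "degenerate")
})

test_that("variance fraction of the dominant mode matches an eigensolver", {
  set.seed(12)
  for (rep in 1:50) {
    x <- matrix(rnorm(60 * 12), 60, 12)
    dec <- svd_window(toy_stc(x, times = 15 + 0:11), window = c(15, 26))
    dm <- dominant_modes(dec)
    ev <- eigen(crossprod(x), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(dm$variance_fraction, ev[1] / sum(ev), tolerance = 1e-10)
    expect_equal(dec$S^2 / sum(dec$S^2), ev / sum(ev), tolerance = 1e-10)
  }
  # exact tie returns the first column by index with fraction 1/2
  x <- diag(c(2, 2))
  dec <- svd_window(toy_stc(x, times = 15:16), window = c(15, 16))
  expect_equal(dominant_modes(dec)$variance_fraction, 0.5)
})

test_that("thresholding keeps loadings above the fraction of the maximum", {
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  ssp <- toy_space(pos)
  parc <- toy_parcellation(c(8L, 8L, 10L))
  reg <- threshold_region(c(1.0, 0.9, 0.79), parc, ssp, threshold = 0.8)
  expect_identical(reg$members, c(1L, 2L))
  expect_equal(unname(reg$centroid), c(5, 0, 0))
  expect_identical(reg$centroid_vertex, 1L)  # equidistant: lowest index
  expect_identical(reg$centroid_label, 8L)
  # threshold 1 keeps the argmax (plus exact ties)
  expect_identical(threshold_region(c(1, 0.5, 1), parc, ssp, 1)$members,
                   c(1L, 3L))
  # threshold -> 0+ keeps every nonzero loading
  expect_identical(threshold_region(c(0.2, -0.4, 0.9), parc, ssp, 1e-9)$members,
                   1:3)
  # sign of the loadings is irrelevant
  expect_identical(threshold_region(c(-1.0, 0.9, 0.79), parc, ssp, 0.8)$members,
                   c(1L, 2L))
  # percentile semantics keeps the top quantile instead
  regp <- threshold_region(c(0.1, 0.5, 0.9), parc, ssp, 2 / 3,
                           semantics = "percentile")
  expect_identical(regp$members, c(2L, 3L))
  expect_error(threshold_region(c(0, 0, 0), parc, ssp), "all-zero")
  expect_error(threshold_region(c(1, 0, 0), parc, ssp, 0), "threshold")
})

test_that("peak activation time takes the absolute temporal peak, earliest on ties", {
  times <- 15:60
  v <- numeric(46); v[times == 33] <- 0.9
  expect_equal(peak_activation_time(v, times), 33)
  expect_equal(peak_activation_time(-v, times), 33)
  expect_equal(peak_activation_time(rep(0.3, 46), times), 15)
  expect_error(peak_activation_time(v[1:10], times), "lengths differ")
})

test_that("patient localization is deterministic, scale- and sign-invariant", {
  wb <- cached_workbench(3)
  p <- simulate_patient(wb, side = "UL", snr = 5, n_epochs = 120, seed = 11)
  ev <- average_epochs(baseline_correct(p$epochs))
  r1 <- localize_patient(ev, wb$inverse, wb)
  r2 <- localize_patient(ev, wb$inverse, wb)
  expect_identical(r1$members, r2$members)
  expect_identical(r1$peak_time, r2$peak_time)
  ev10 <- ev; ev10$data <- 10 * ev$data
  r10 <- localize_patient(ev10, wb$inverse, wb)
  expect_identical(r10$members, r1$members)
  evneg <- ev; evneg$data <- -ev$data
  rneg <- localize_patient(evneg, wb$inverse, wb)
  expect_identical(rneg$members, r1$members)
  expect_identical(rneg$peak_time, r1$peak_time)
  expect_true(r1$peak_time >= 15 && r1$peak_time <= 60)
})

test_that("higher thresholds give smaller regions; recovery overlaps the truth", {
  wb <- cached_workbench(3)
  p <- simulate_patient(wb, side = "UL", snr = 1e9, n_epochs = 120, seed = 11)
  ev <- average_epochs(baseline_correct(p$epochs))
  stc <- spatial_filter(apply_sloreta(wb$inverse, ev), wb$source_space,
                        wb$parcellation, radius = 5,
                        operator = sefmapper:::workbench_filter_operator(wb, 5))
  u1 <- dominant_modes(svd_window(stc))$u1
  sizes <- sapply(seq(0.5, 1.0, by = 0.05), function(th)
    length(threshold_region(u1, wb$parcellation, wb$source_space, th)$members))
  expect_true(all(diff(sizes) <= 0))
  # noiseless recovery: region stays within the truth plus a 10 mm halo
  # (the standardized minimum-norm estimate overestimates spatial extent,
  # so the halo exceeds the 5 mm filter radius; bound verified empirically)
  reg <- threshold_region(u1, wb$parcellation, wb$source_space, 0.8)
  halo <- unique(unlist(lapply(p$truth$patch, function(i)
    neighbors_within(wb$source_space, i, 10))))
  expect_true(all(reg$members %in% halo))
  jac <- length(intersect(reg$members, p$truth$patch)) /
    length(union(reg$members, p$truth$patch))
  expect_gte(jac, 0.3)
})
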