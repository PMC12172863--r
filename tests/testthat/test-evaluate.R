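test_that("atlas overlap counts ROI members in either hemisphere", {
  parc <- toy_parcellation(c(3L, 3L, 8L, 10L, 5L))
  expect_equal(atlas_overlap(1:3, parc), 100)    # left+right ROI labels
  expect_equal(atlas_overlap(4:5, parc), 0)      # other in both hemispheres
  expect_equal(atlas_overlap(1:4, parc), 75)
  expect_error(atlas_overlap(integer(0), parc), "empty")
})

test_that("sphere overlap uses the 3 cm^3 radius with an inclusive boundary", {
  expect_equal((4 / 3) * pi * sphere_radius(3000)^3, 3000, tolerance = 1e-9)
  expect_equal(sphere_radius(3000), 8.947, tolerance = 1e-3)
  r <- sphere_radius(3000)
  pos <- rbind(c(0, 0, 0), c(r, 0, 0), c(r + 0.001, 0, 0), c(30, 0, 0))
  ssp <- toy_space(pos)
  expect_equal(sphere_overlap(1:4, ssp, c(0, 0, 0)), 50)  # member at r counts
  expect_equal(sphere_overlap(1:2, ssp, c(0, 0, 0)), 100)
  expect_equal(sphere_overlap(4L, ssp, c(-30, 0, 0)), 0)
  rejected <- structure(list(position = c(0, 0, 0), accepted = FALSE),
                        class = "dipole_fit")
  expect_true(is.na(sphere_overlap(1:2, ssp, rejected)))
})

test_that("centroid distance is the plain Euclidean distance", {
  reg <- structure(list(members = 1:2, centroid = c(0, 0, 0)),
                   class = "activation_region")
  expect_equal(centroid_distance(reg, c(3, 4, 0)), 5)
  expect_equal(centroid_distance(reg, c(0, 0, 0)), 0)
  shifted <- reg; shifted$centroid <- reg$centroid + c(1, 2, 3)
  expect_equal(centroid_distance(shifted, c(3, 4, 0) + c(1, 2, 3)), 5)
})

test_that("atlas projection matches an exhaustive nearest-vertex scan", {
  wb <- cached_workbench(3)
  ss <- wb$source_space
  parc <- wb$parcellation
  set.seed(13)
  for (rep in 1:100) {
    pt <- runif(3, -80, 80)
    got <- project_to_atlas(pt, ss, parc)
    d <- sqrt(colSums((t(ss$positions) - pt)^2))
    expect_identical(got$vertex, which.min(d))
    expect_identical(got$label, parc$label_of[which.min(d)])
  }
  # a point on a vertex projects to it; exact ties take the lowest index
  expect_identical(project_to_atlas(ss$positions[10, ], ss, parc)$vertex, 10L)
  ssp <- toy_space(rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_identical(project_to_atlas(c(0, 0, 0), ssp,
                                    toy_parcellation(c(5L, 5L)))$vertex, 1L)
})

test_that("permutation null draws size-exact patches reproducibly", {
  wb <- cached_workbench(2, compute_leadfield = FALSE)
  parc <- wb$parcellation
  sizes <- integer(0)
  null <- permutation_null(12, function(m) {
    sizes <<- c(sizes, length(m)); atlas_overlap(m, parc)
  }, wb, n = 300, seed = 7)
  expect_true(all(sizes == 12))
  expect_identical(length(null$values), 300L)
  null2 <- permutation_null(12, function(m) atlas_overlap(m, parc), wb,
                            n = 300, seed = 7)
  expect_identical(null$values, null2$values)
  # mean null overlap tracks the ROI source fraction
  expect_equal(mean(null$values) / 100, sefmapper:::roi_fraction(parc),
               tolerance = 0.5)
  # ROI covering the whole cortex makes every null overlap 100
  all_roi <- parc; all_roi$roi_label_ids <- 1:10
  null3 <- permutation_null(12, function(m) atlas_overlap(m, all_roi), wb,
                            n = 50, seed = 7)
  expect_true(all(null3$values == 100))
})

test_that("beats_chance is a strict comparison against the null median", {
  null <- structure(list(values = c(0, 9, 18), median = 9),
                    class = "null_distribution")
  expect_true(beats_chance(97.6, null))
  expect_false(beats_chance(9, null))
  expect_false(beats_chance(0, null))
  expect_true(beats_chance(1, c(0, 0, 0)))
})

test_that("binomial cohort p-values: printed all-success masses and exact tails", {
  # 0.05^58 and 0.05^50, the cohort values printed for 58 and 50 patients
  expect_equal(signif(cohort_binomial(57, 58, 0.05, "all_success_mass"), 2),
               3.5e-76)
  expect_equal(cohort_binomial(49, 50, 0.05, "all_success_mass"), 8.8e-66,
               tolerance = 0.01)
  # exact tails against direct big-sum evaluation for all k at several n
  direct <- function(k, n, p) sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
  for (n in c(10, 35, 58)) {
    for (k in c(0, 1, floor(n / 2), n - 1, n)) {
      expect_equal(cohort_binomial(k, n, 0.05, "tail"), direct(k, n, 0.05),
                   tolerance = 1e-10)
      expect_equal(cohort_binomial(k, n, 0.5, "tail"), direct(k, n, 0.5),
                   tolerance = 1e-10)
    }
  }
  expect_equal(cohort_binomial(57, 58, 0.5, "tail"), 59 * 0.5^58,
               tolerance = 1e-12)
  expect_equal(cohort_binomial(0, 20, 0.05, "tail"), 1)
  expect_error(cohort_binomial(5, 4, 0.05), "n_success")
  expect_error(cohort_binomial(3, 4, 1.5), "p0")
})

test_that("signed-rank test: exact enumeration, symmetry, edge cases", {
  # 5 positive unit differences: two-sided p = 2/32
  r <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(r$statistic, 15)
  expect_equal(r$p.value, 0.0625)
  # swapping the arguments leaves p unchanged
  r2 <- wilcoxon_signed_rank(c(1, 1, 1, 1, 1), c(2, 3, 4, 5, 6))
  expect_equal(r2$p.value, r$p.value)
  # single nonzero difference: p = 1 two-sided
  expect_equal(wilcoxon_signed_rank(c(1, 5), c(1, 3))$p.value, 1)
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "equal length")
  # full sign-enumeration oracle at n <= 10, with and without ties
  enum_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- signs %*% r
    min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  }
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    d <- sample(-6:6, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_signed_rank(d, numeric(n))
    expect_equal(got$p.value, enum_p(d), tolerance = 1e-12)
  }
  # tie-free exact path also agrees with the classical null distribution
  d <- c(3, -1, 4, 2, -5, 7, 6)
  w <- sum(rank(abs(d))[d > 0])
  p_ref <- 2 * min(psignrank(w, 7), 1 - psignrank(w - 1, 7))
  expect_equal(wilcoxon_signed_rank(d, numeric(7))$p.value, min(1, p_ref),
               tolerance = 1e-12)
  # large-n path returns a sane normal-approximation p
  set.seed(15)
  big <- rnorm(40, mean = 0.5)
  pa <- wilcoxon_signed_rank(big, numeric(40))
  expect_true(pa$method == "normal approximation with tie correction")
  expect_true(pa$p.value > 0 && pa$p.value < 1)
})

test_that("chi-squared location test matches hand computation", {
  tab <- rbind(a = c(20, 10), b = c(10, 20))
  res <- chi2_location_test(tab)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)  # 6.667
  expect_equal(res$df, 1)
  expect_equal(res$p.value, 0.009823, tolerance = 1e-3)
  # identical rows give statistic 0, p 1
  same <- chi2_location_test(rbind(c(5, 7, 3), c(5, 7, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # row swap leaves the statistic unchanged
  expect_equal(chi2_location_test(tab[2:1, ])$statistic, res$statistic)
  # zero columns are dropped with a message
  expect_message(res0 <- chi2_location_test(cbind(tab, c(0, 0))), "dropping")
  expect_equal(res0$statistic, res$statistic)
  expect_error(suppressMessages(chi2_location_test(rbind(c(1, 0), c(3, 0)))),
               "degenerate")
  expect_error(chi2_location_test(rbind(c(-1, 2), c(1, 1))), "non-negative")
})

test_that("cohort evaluation assembles per-patient metrics and statistics", {
  wb <- cached_workbench(3)
  analyses <- list()
  sides <- c("UL", "UR", "UL")
  for (i in 1:3) {
    p <- simulate_patient(wb, side = sides[i], snr = 5, n_epochs = 110,
                          seed = 30 + i)
    analyses[[i]] <- analyze_patient(wb, p$epochs, sides[i])
  }
  res <- evaluate_cohort(wb, analyses, sides, n_permutations = 200, seed = 2)
  expect_identical(res$n_patients, 3L)
  expect_true(all(res$patients$atlas_overlap >= 0 &
                  res$patients$atlas_overlap <= 100))
  expect_true(res$n_success >= 0 && res$n_success <= 3)
  expect_true(res$binomial_tail >= 0 && res$binomial_tail <= 1)
  expect_identical(dim(res$location_table), c(4L, 5L))
  expect_true(all(c("sphere_overlap_P20m", "dist_PMaxm", "label_P40m") %in%
                  names(res$patients)))
})
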