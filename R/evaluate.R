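# Evaluation metrics and cohort statistics: atlas overlap, dipole-sphere
# overlap, centroid distances, nearest-vertex atlas projection, size-matched
# random-patch permutation nulls, and binomial / Wilcoxon / chi-squared tests.

#' Percent of region members in the sensorimotor ROI
#'
#' Sources labeled pre-/post-central gyrus or central/post-central sulcus in
#' either hemisphere count as anatomically correct (ipsilateral responses are
#' accepted as correct too).
#'
#' @param region An `activation_region` (or an integer vector of members).
#' @param parcellation A `parcellation`.
#' @return Percent in \[0, 100\].
#' @export
atlas_overlap <- function(region, parcellation) {
  members <- if (inherits(region, "activation_region")) region$members else region
  if (!length(members)) stop("empty region")
  100 * mean(parcellation$label_of[members] %in% parcellation$roi_label_ids)
}

#' Radius of a sphere of given volume
#'
#' @param volume_mm3 Volume in mm^3 (3 cm^3 = 3000 mm^3 gives ~8.947 mm).
#' @return Radius in mm.
#' @export
sphere_radius <- function(volume_mm3) (3 * volume_mm3 / (4 * pi))^(1 / 3)

#' Percent of region members inside a sphere around a dipole
#'
#' The sphere has the given volume (default 3 cm^3, the 95% confidence volume
#' conventionally used for dipole localization of evoked fields); membership
#' at exactly the radius counts (inclusive).
#'
#' @param region An `activation_region` or member indices.
#' @param source_space A `source_space`.
#' @param dipole_position Length-3 position, mm (or a `dipole_fit`).
#' @param volume_mm3 Sphere volume, mm^3.
#' @return Percent in \[0, 100\], or `NA` for a rejected dipole.
#' @export
sphere_overlap <- function(region, source_space, dipole_position,
                           volume_mm3 = 3000) {
  if (volume_mm3 <= 0) stop("`volume_mm3` must be positive")
  if (inherits(dipole_position, "dipole_fit")) {
    if (isFALSE(dipole_position$accepted)) return(NA_real_)
    dipole_position <- dipole_position$position
  }
  members <- if (inherits(region, "activation_region")) region$members else region
  if (!length(members)) stop("empty region")
  r <- sphere_radius(volume_mm3)
  d <- row_norms(sweep(source_space$positions[members, , drop = FALSE], 2,
                       dipole_position))
  100 * mean(d <= r + 1e-12)
}

#' Distance from a region centroid to a dipole
#'
#' @param region An `activation_region` (must carry `centroid`).
#' @param dipole_position Length-3, mm (or a `dipole_fit`).
#' @return Euclidean distance, mm (`NA` for a rejected dipole).
#' @export
centroid_distance <- function(region, dipole_position) {
  if (inherits(dipole_position, "dipole_fit")) {
    if (isFALSE(dipole_position$accepted)) return(NA_real_)
    dipole_position <- dipole_position$position
  }
  sqrt(sum((region$centroid - dipole_position)^2))
}

#' Project a point to the nearest cortical source and its label
#'
#' @param point Length-3, mm.
#' @param source_space A `source_space`.
#' @param parcellation A `parcellation`.
#' @return List with `vertex` (lowest index on exact ties), `label` (id) and
#'   `label_name`.
#' @export
project_to_atlas <- function(point, source_space, parcellation) {
  d2 <- colSums((t(source_space$positions) - point)^2)
  v <- which.min(d2)
  lab <- parcellation$label_of[v]
  list(vertex = v, label = lab,
       label_name = label_names_of(parcellation, lab))
}

#' Permutation null of a region metric over random cortical patches
#'
#' For each repetition, a seed vertex is drawn uniformly over all sources and
#' a contiguous patch of exactly `region_size` members is grown over the
#' entire cortical surface; `metric_fn` (a function of the member index
#' vector) is evaluated on it. Bit-reproducible for a fixed seed.
#'
#' @param region_size Patch size (members).
#' @param metric_fn Function of an integer member vector returning a scalar,
#'   e.g. `function(m) atlas_overlap(m, parcellation)`.
#' @param workbench A [build_workbench()] bundle.
#' @param n Number of permutations (default 10,000).
#' @param seed RNG seed.
#' @return A `null_distribution`: `values`, `n`, `median`, `seed`,
#'   `region_size`.
#' @export
permutation_null <- function(region_size, metric_fn, workbench, n = 10000,
                             seed = 1) {
  if (n < 1) stop("`n` must be >= 1")
  wb <- workbench
  set.seed(as.integer(seed) %% .Machine$integer.max)
  seeds <- sample.int(n_sources(wb$source_space), n, replace = TRUE)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    patch <- grow_patch(wb$source_space, wb$cortex, seeds[i], region_size,
                        adjacency = wb$adjacency)
    vals[i] <- metric_fn(patch)
  }
  structure(list(values = vals, n = n, median = stats::median(vals),
                 seed = seed, region_size = region_size),
            class = "null_distribution")
}

#' Does an observed metric beat the permutation null?
#'
#' Strictly greater than the null median ("greater than" is the acceptance
#' rule; equality does not count).
#'
#' @param observed_metric Scalar.
#' @param null A `null_distribution` (or a numeric vector of null values).
#' @return Logical.
#' @export
beats_chance <- function(observed_metric, null) {
  med <- if (inherits(null, "null_distribution")) null$median
         else stats::median(null)
  observed_metric > med
}

#' Cohort binomial p-value
#'
#' Two formulations are provided. `"all_success_mass"` returns the binomial
#' probability mass at `k = n_patients` under success probability `p0`, i.e.
#' `p0^n_patients` — the quantity that matches the cohort p-values printed in
#' clinical reports of this design (e.g. 0.05^58 = 3.5e-76). `"tail"` is the
#' conventional one-sided exact test `P(X >= n_success)` under
#' `Binomial(n_patients, p0)`. Both are computed in log space.
#'
#' @param n_success Number of successes (0..n_patients).
#' @param n_patients Cohort size.
#' @param p0 Null success probability, in (0, 1).
#' @param mode `"all_success_mass"` or `"tail"`.
#' @return p-value.
#' @export
cohort_binomial <- function(n_success, n_patients, p0 = 0.05,
                            mode = c("tail", "all_success_mass")) {
  mode <- match.arg(mode)
  if (p0 <= 0 || p0 >= 1) stop("`p0` must be in (0, 1)")
  if (n_success < 0 || n_success > n_patients)
    stop("`n_success` must be in [0, n_patients]")
  if (mode == "all_success_mass") return(exp(n_patients * log(p0)))
  lp <- stats::dbinom(n_success:n_patients, n_patients, p0, log = TRUE)
  m <- max(lp)
  min(1, exp(m + log(sum(exp(lp - m)))))
}

#' Wilcoxon signed-rank test (exact by enumeration for small n)
#'
#' Two-sided paired test on `a - b` with zero differences dropped and
#' midranks for ties. For up to 25 nonzero differences the null distribution
#' of the positive-rank sum is enumerated exactly (dynamic program over
#' doubled midranks, equivalent to summing over all 2^n sign assignments);
#' otherwise a normal approximation with tie correction is used.
#'
#' @param a,b Equal-length numeric vectors.
#' @return List: `statistic` (positive-rank sum W), `p.value`, `n` (nonzero
#'   differences), `method`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("`a` and `b` must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero: test undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    ir <- as.integer(round(2 * r))       # doubled midranks are integers
    tot <- sum(ir)
    cnt <- c(1, numeric(tot))            # counts over 2W = 0..tot
    for (ri in ir) {
      shifted <- c(numeric(ri), cnt[seq_len(tot + 1L - ri)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(probs[seq_len(w2 + 1L)])
    p_ge <- sum(probs[(w2 + 1L):(tot + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = w, p.value = p, n = n, method = method)
}

#' Chi-squared test of anatomical location counts
#'
#' Pearson chi-squared (no continuity correction) on a methods x location
#' contingency table; all-zero rows/columns are dropped first with a message.
#'
#' @param contingency Matrix of non-negative counts (methods x locations).
#' @return List: `statistic`, `df`, `p.value`, `dropped` (names of dropped
#'   rows/columns).
#' @export
chi2_location_test <- function(contingency) {
  tab <- as.matrix(contingency)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("contingency must hold non-negative integer counts")
  dropped <- character(0)
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    dropped <- c(rownames(tab)[zr], colnames(tab)[zc])
    dropped <- dropped[!is.na(dropped)]
    message("dropping all-zero rows/columns: ",
            paste(dropped, collapse = ", "))
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate table after pruning (need >= 2 rows and columns)")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, dropped = dropped)
}

# ---- cohort orchestration ----------------------------------------------------

#' Evaluate a localized cohort against anatomy, dipoles and chance
#'
#' Computes per-patient metrics (atlas overlap; 3 cm^3 sphere overlap and
#' centroid distance per accepted dipole; beats-chance flag against a
#' size-matched random-patch null of the atlas overlap) and cohort statistics
#' (binomial p in both formulations, Wilcoxon signed-rank comparing UL vs UR
#' overlaps where both sides exist, and a chi-squared location test of each
#' dipole kind against the distributed-source centroid labels).
#'
#' Permutation nulls are cached per region size, so patients whose regions
#' tie in size share one null.
#'
#' @param workbench A [build_workbench()] bundle.
#' @param analyses List of [analyze_patient()] results.
#' @param sides Character vector of sides, one per analysis.
#' @param n_permutations Permutations per null (default 10,000).
#' @param p0 Null per-patient success probability for the binomial test.
#' @param seed RNG seed for the permutation nulls.
#' @return A `cohort_result`: `patients` (data.frame of per-patient metrics),
#'   `n_patients`, `n_success`, `binomial_tail`, `binomial_all_success_mass`,
#'   `wilcoxon_ul_ur`, `chi2` (per dipole kind), `location_table`,
#'   `null_medians` (per region size).
#' @export
evaluate_cohort <- function(workbench, analyses, sides,
                            n_permutations = 10000, p0 = 0.05, seed = 1) {
  wb <- workbench
  if (length(analyses) < 1) stop("need at least one analyzed patient")
  parc <- wb$parcellation
  ss <- wb$source_space
  metric <- function(m) atlas_overlap(m, parc)

  nulls <- list()
  rows <- vector("list", length(analyses))
  for (i in seq_along(analyses)) {
    an <- analyses[[i]]
    reg <- an$region
    size <- length(reg$members)
    key <- as.character(size)
    if (is.null(nulls[[key]]))
      nulls[[key]] <- permutation_null(size, metric, wb, n = n_permutations,
                                       seed = derive_seed(seed, size))
    ov <- atlas_overlap(reg, parc)
    row <- data.frame(
      patient_id = if (!is.null(names(analyses))) names(analyses)[i] else
        sprintf("P%03d", i),
      side = sides[i], region_size = size, atlas_overlap = ov,
      beats_chance = beats_chance(ov, nulls[[key]]),
      null_median = nulls[[key]]$median,
      peak_time_ms = reg$peak_time,
      centroid_label = label_names_of(parc, reg$centroid_label),
      stringsAsFactors = FALSE)
    for (k in c("P20m", "P40m", "PMaxm")) {
      dip <- an$dipoles[[k]]
      if (is.null(dip)) {
        row[[paste0("sphere_overlap_", k)]] <- NA_real_
        row[[paste0("dist_", k)]] <- NA_real_
        row[[paste0("label_", k)]] <- NA_character_
        row[[paste0("gof_", k)]] <- NA_real_
        row[[paste0("accepted_", k)]] <- NA
      } else {
        row[[paste0("sphere_overlap_", k)]] <- sphere_overlap(reg, ss, dip)
        row[[paste0("dist_", k)]] <- centroid_distance(reg, dip)
        row[[paste0("label_", k)]] <-
          project_to_atlas(dip$position, ss, parc)$label_name
        row[[paste0("gof_", k)]] <- dip$gof
        row[[paste0("accepted_", k)]] <- dip$accepted
      }
    }
    rows[[i]] <- row
  }
  patients <- do.call(rbind, rows)

  n_patients <- nrow(patients)
  n_success <- sum(patients$beats_chance)
  res <- list(
    patients = patients, n_patients = n_patients, n_success = n_success,
    binomial_tail = cohort_binomial(n_success, n_patients, p0, "tail"),
    binomial_all_success_mass =
      cohort_binomial(n_success, n_patients, p0, "all_success_mass"),
    null_medians = vapply(nulls, `[[`, 0, "median"))

  ul <- patients$atlas_overlap[patients$side == "UL"]
  ur <- patients$atlas_overlap[patients$side == "UR"]
  res$wilcoxon_ul_ur <- if (length(ul) && length(ur)) {
    m <- min(length(ul), length(ur))
    # pair i-th UL with i-th UR patient (simulated patients are exchangeable)
    tryCatch(wilcoxon_signed_rank(ul[seq_len(m)], ur[seq_len(m)]),
             error = function(e) NULL)
  } else NULL

  cats <- SEF_LABELS
  ds_counts <- table(factor(patients$centroid_label, levels = cats))
  loc <- list(DS = as.integer(ds_counts))
  chi2 <- list()
  for (k in c("P20m", "P40m", "PMaxm")) {
    lab <- patients[[paste0("label_", k)]]
    acc <- patients[[paste0("accepted_", k)]]
    lab <- lab[!is.na(lab) & !is.na(acc) & acc]
    loc[[k]] <- as.integer(table(factor(lab, levels = cats)))
    tab <- rbind(DS = loc$DS, dipole = loc[[k]])
    colnames(tab) <- cats
    chi2[[k]] <- tryCatch(suppressMessages(chi2_location_test(tab)),
                          error = function(e) NULL)
  }
  res$location_table <- do.call(rbind, loc)
  colnames(res$location_table) <- cats
  res$chi2 <- chi2
  class(res) <- "cohort_result"
  res
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("cohort_result: %d patients, %d beat chance (tail p = %.3g)\n",
              x$n_patients, x$n_success, x$binomial_tail))
  cat(sprintf("  median atlas overlap: %.1f%%\n",
              stats::median(x$patients$atlas_overlap)))
  invisible(x)
}
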