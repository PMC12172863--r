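# Synthetic somatosensory-evoked MEG data with known ground truth.
#
# The generator emulates the acquisition conditions of a clinical
# median-nerve mapping session: a 306-channel array sampled at 1 kHz, epochs
# from 50 ms before to 250 ms after the stimulus (300 samples, stimulus at
# sample 51), and per-patient event counts drawn from Normal(197, 31)
# truncated to [160, 230]. The cortical source is a contiguous patch in the
# hemisphere contralateral to the stimulated side, confined to the
# sensorimotor label bands, with a smooth amplitude taper and an
# evoked waveform made of causal Gaussian components peaking near 20 and
# 35 ms post-stimulus.

#' Somatosensory evoked waveform
#'
#' Sum of Gaussian components `amplitude * exp(-(t - latency)^2 / (2 width^2))`
#' multiplied by the causal indicator `t >= 0`. Defaults place components at
#' 20 and 35 ms, matching the typical latencies of the early median-nerve
#' deflections.
#'
#' @param times Time axis, ms (stimulus at 0).
#' @param components List of lists with fields `latency` (ms), `width` (ms,
#'   > 0) and `amplitude`.
#' @return Numeric vector, same length as `times`.
#' @export
sef_waveform <- function(times,
                         components = list(
                           list(latency = 20, width = 3, amplitude = 0.7),
                           list(latency = 35, width = 6, amplitude = 1.0))) {
  w <- numeric(length(times))
  for (cmp in components) {
    if (cmp$width <= 0) stop("component widths must be positive")
    w <- w + cmp$amplitude * exp(-(times - cmp$latency)^2 / (2 * cmp$width^2))
  }
  w * (times >= 0)
}

default_epoch_times <- function() seq(-50, 249)

truncated_event_count <- function(mean = 197, sd = 31, lower = 160, upper = 230) {
  repeat {
    n <- round(rnorm(1, mean, sd))
    if (n >= lower && n <= upper) return(as.integer(n))
  }
}

#' Simulate one patient's evoked MEG epochs with ground truth
#'
#' A contiguous activation patch is seeded uniformly within the contralateral
#' postcentral_gyrus and central_sulcus labels and grown (within the
#' sensorimotor label bands) to `patch_size` sources. Source currents are the
#' outer product of a Gaussian spatial taper and the evoked waveform, scaled
#' so the summed moment at the waveform peak equals `peak_moment`. Epochs are
#' the projected fields plus independent Gaussian sensor noise; the noise
#' standard deviation is set per channel kind so that
#' peak evoked RMS / (per-epoch noise RMS / sqrt(n_epochs)) = `snr`
#' on the gradiometers (and likewise on the magnetometers).
#'
#' @param workbench A [build_workbench()] bundle.
#' @param side `"UL"` (left median nerve) or `"UR"`; the patch is placed in
#'   the contralateral hemisphere.
#' @param snr Evoked signal-to-noise ratio (> 0) as defined above.
#' @param n_epochs Number of stimulation events; drawn from the truncated
#'   normal above when `NULL`.
#' @param patch_size Patch size in sources; computed from `patch_area_mm2`
#'   when `NULL`.
#' @param patch_area_mm2 Target patch area (default 300 mm2, a ~3 cm2 hand
#'   representation).
#' @param peak_moment Total dipole moment at the waveform peak, nA.m.
#' @param components Waveform components, see [sef_waveform()].
#' @param seed Integer seed (bit-reproducible output).
#' @return List with `epochs` (a `sef_epochs`) and `truth` (a `ground_truth`:
#'   patch, taper, amplitudes, waveform, peak_latencies, side, seed_vertex).
#' @export
simulate_patient <- function(workbench, side = c("UL", "UR"), snr = 5,
                             n_epochs = NULL, patch_size = NULL,
                             patch_area_mm2 = 300, peak_moment = 50,
                             components = NULL, seed = 1) {
  side <- match.arg(side)
  wb <- workbench
  ss <- wb$source_space
  parc <- wb$parcellation
  if (snr <= 0) stop("`snr` must be positive")
  set.seed(as.integer(seed) %% .Machine$integer.max)

  contra <- if (side == "UL") "right" else "left"
  seed_names <- c("postcentral_gyrus", "central_sulcus")
  lt <- parc$label_table
  seed_ids <- lt$label_id[lt$hemisphere == contra & lt$label_name %in% seed_names]
  roi_ids <- lt$label_id[lt$hemisphere == contra &
                         lt$label_id %in% parc$roi_label_ids]
  cand <- which(parc$label_of %in% seed_ids)
  if (!length(cand))
    stop("no ", contra, "-hemisphere seed labels in the parcellation")
  allowed <- which(parc$label_of %in% roi_ids)

  if (is.null(patch_size)) {
    patch_size <- max(1L, round(patch_area_mm2 / mean_vertex_area(wb)))
  }
  patch_size <- min(patch_size, length(allowed))
  seed_vertex <- cand[sample.int(length(cand), 1)]
  patch <- grow_patch(ss, wb$cortex, seed_vertex, patch_size,
                      adjacency = wb$adjacency, allowed = allowed)

  d <- row_norms(sweep(ss$positions[patch, , drop = FALSE], 2,
                       ss$positions[seed_vertex, ]))
  s <- max(max(d) / 1.5, 1)
  taper <- exp(-d^2 / (2 * s^2))
  amplitudes <- taper / sum(taper) * peak_moment

  times <- default_epoch_times()
  if (is.null(components)) w <- sef_waveform(times)
  else w <- sef_waveform(times, components)

  activation <- matrix(0, n_sources(ss), length(times))
  activation[patch, ] <- amplitudes %o% w
  clean <- project_activation(wb$leadfield, activation)

  if (is.null(n_epochs)) n_epochs <- truncated_event_count()
  n_epochs <- as.integer(n_epochs)
  if (n_epochs < 1) stop("`n_epochs` must be >= 1")

  kind <- wb$leadfield$sensors$kind
  sd_chan <- numeric(length(kind))
  for (k in unique(kind)) {
    rows <- kind == k
    peak_rms <- max(sqrt(colMeans(clean[rows, , drop = FALSE]^2)))
    sd_chan[rows] <- peak_rms * sqrt(n_epochs) / snr
  }

  nc <- nrow(clean); ns <- ncol(clean)
  data <- array(rnorm(n_epochs * nc * ns), c(n_epochs, nc, ns)) *
    rep(sd_chan, each = n_epochs)
  for (e in seq_len(n_epochs)) data[e, , ] <- data[e, , ] + clean

  epochs <- structure(list(data = data, times = times, sfreq = 1000,
                           stim_sample = which(times == 0),
                           ch_kind = kind),
                      class = "sef_epochs")
  truth <- structure(list(patch = patch, taper = taper,
                          amplitudes = amplitudes, waveform = w,
                          peak_latencies = c(20, 35), side = side,
                          seed_vertex = seed_vertex,
                          peak_moment = peak_moment, snr = snr,
                          n_epochs = n_epochs, seed = seed),
                     class = "ground_truth")
  list(epochs = epochs, truth = truth)
}

#' @export
print.sef_epochs <- function(x, ...) {
  cat(sprintf("sef_epochs: %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq))
  invisible(x)
}

# Derive a per-patient sub-seed from a master seed (kept below 2^31 - 1).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 1009 + k * 9973) %% 2147483647)
}

#' Simulate a cohort of patients
#'
#' Each patient gets an independent sub-seed derived deterministically from
#' the master seed; all other settings are shared.
#'
#' @param workbench A [build_workbench()] bundle.
#' @param n_patients Number of patients (>= 1).
#' @param sides Character vector of `"UL"`/`"UR"` per patient, a single value,
#'   or `"alternate"` (default) to alternate UL/UR.
#' @param seed Master seed.
#' @param ... Passed on to [simulate_patient()].
#' @return List with `patients` (list of [simulate_patient()] results plus
#'   `patient_id`) and `manifest` (data.frame: patient_id, side, n_epochs,
#'   seed, patch_size, seed_vertex).
#' @export
simulate_cohort <- function(workbench, n_patients, sides = "alternate",
                            seed = 1, ...) {
  if (n_patients < 1) stop("`n_patients` must be >= 1")
  if (identical(sides, "alternate"))
    sides <- rep(c("UL", "UR"), length.out = n_patients)
  else if (length(sides) == 1L) sides <- rep(sides, n_patients)
  if (length(sides) != n_patients)
    stop("`sides` must have length 1 or n_patients")

  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    sub <- derive_seed(seed, i)
    p <- simulate_patient(workbench, side = sides[i], seed = sub, ...)
    p$patient_id <- sprintf("P%03d", i)
    p$seed <- sub
    patients[[i]] <- p
  }
  manifest <- data.frame(
    patient_id = vapply(patients, `[[`, "", "patient_id"),
    side = sides,
    n_epochs = vapply(patients, function(p) p$truth$n_epochs, 1L),
    seed = vapply(patients, function(p) p$seed, 1L),
    patch_size = vapply(patients, function(p) length(p$truth$patch), 1L),
    seed_vertex = vapply(patients, function(p) p$truth$seed_vertex, 1L),
    stringsAsFactors = FALSE)
  list(patients = patients, manifest = manifest)
}
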