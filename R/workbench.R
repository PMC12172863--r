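# The synthetic MEG workbench: geometry, parcellation, sensors, lead field
# and inverse operator bundled for the simulation and evaluation pipeline.

#' Build a complete synthetic MEG workbench
#'
#' Constructs the two-hemisphere cortex, source space (with near-radial
#' orientations tilted tangentially), band parcellation, sensor array, lead
#' field and sLORETA inverse operator, plus the mesh adjacency used for patch
#' growth. Subdivision level 5 reproduces the full-scale 10,242-sources-per-
#' hemisphere grid; levels 3–4 are desk-scale workbenches.
#'
#' @param subdivisions Icosphere subdivision level per hemisphere.
#' @param radius,fold_amplitude,hemisphere_gap See [build_synthetic_cortex()].
#' @param band_width,band_center See [synthetic_parcellation()].
#' @param head_radius Conductor sphere radius, mm.
#' @param helmet_radius,pair_offset,n_mag,n_grad_pairs See
#'   [build_sensor_array()].
#' @param lambda2 sLORETA regularization.
#' @param compute_leadfield Set `FALSE` for geometry-only workbenches.
#' @param seed Seed for the fold pattern.
#' @return A `sef_workbench` list: `cortex`, `source_space`, `parcellation`,
#'   `sensors`, `leadfield`, `inverse`, `adjacency`, `head_radius`, `cache`.
#' @export
build_workbench <- function(subdivisions = 5, radius = 35, fold_amplitude = 3,
                            hemisphere_gap = 4, band_width = 8.1,
                            band_center = 0, head_radius = 90,
                            helmet_radius = 120, pair_offset = 17,
                            n_mag = 102, n_grad_pairs = 102, lambda2 = 1 / 9,
                            compute_leadfield = TRUE, seed = 1) {
  cortex <- build_synthetic_cortex(subdivisions, radius = radius,
                                   fold_amplitude = fold_amplitude,
                                   hemisphere_gap = hemisphere_gap, seed = seed)
  ss <- make_source_space(cortex)
  ss <- regularize_orientations(ss, center = c(0, 0, 0))
  parc <- synthetic_parcellation(ss, band_width = band_width,
                                 band_center = band_center)
  wb <- list(cortex = cortex, source_space = ss, parcellation = parc,
             adjacency = cortex_adjacency(cortex), head_radius = head_radius,
             subdivisions = subdivisions, seed = seed,
             cache = new.env(parent = emptyenv()))
  if (compute_leadfield) {
    wb$sensors <- build_sensor_array(n_mag = n_mag,
                                     n_grad_pairs = n_grad_pairs,
                                     helmet_radius = helmet_radius,
                                     pair_offset = pair_offset)
    wb$leadfield <- build_leadfield(ss, wb$sensors, head_radius = head_radius)
    wb$inverse <- make_inverse(wb$leadfield, sigma = 1, lambda2 = lambda2)
  }
  structure(wb, class = "sef_workbench")
}

#' @export
print.sef_workbench <- function(x, ...) {
  cat(sprintf("sef_workbench: ico-%d, %d sources, %s channels\n",
              x$subdivisions, n_sources(x$source_space),
              if (is.null(x$sensors)) "no" else nrow(x$sensors)))
  invisible(x)
}

# Mean per-vertex surface area (total face area / vertex count), mm^2.
mean_vertex_area <- function(workbench) {
  cache <- workbench$cache
  if (!is.null(cache$mean_vertex_area)) return(cache$mean_vertex_area)
  area <- 0
  for (h in c("left", "right")) {
    m <- workbench$cortex[[h]]
    v <- m$vertices
    f <- m$faces
    fn <- cross3(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
    area <- area + sum(row_norms(fn)) / 2
  }
  out <- area / n_sources(workbench$source_space)
  cache$mean_vertex_area <- out
  out
}

# Cached spatial-filter operator per radius.
workbench_filter_operator <- function(workbench, radius) {
  key <- sprintf("filter_%g", radius)
  cache <- workbench$cache
  if (is.null(cache[[key]]))
    cache[[key]] <- spatial_filter_operator(workbench$source_space,
                                            workbench$parcellation, radius)
  cache[[key]]
}

#' Analyze one patient's epochs end to end
#'
#' Baseline-corrects and averages the epochs, applies the sLORETA +
#' spatial-filter + SVD + threshold pipeline, and fits the three comparator
#' dipoles (P20m at 20 +/- 5 ms, P40m at 40 +/- 5 ms, PMaxm at the time of
#' maximum gradiometer RMS in 15-60 ms) with the 9 mm anatomical rejection
#' rule.
#'
#' @param workbench A [build_workbench()] bundle (with lead field).
#' @param epochs A `sef_epochs`.
#' @param side `"UL"` or `"UR"`.
#' @param filter_radius,window,threshold,semantics See [localize_patient()].
#' @param fit_dipoles Set `FALSE` to skip the dipole comparators.
#' @return List with `evoked`, `region`, `dipoles` (named list
#'   P20m/P40m/PMaxm of `dipole_fit`), `pmax_ms`, `sigma`.
#' @export
analyze_patient <- function(workbench, epochs, side,
                            filter_radius = 5, window = c(15, 60),
                            threshold = 0.80, semantics = "fraction_of_max",
                            fit_dipoles = TRUE) {
  wb <- workbench
  evoked <- average_epochs(baseline_correct(epochs))
  sigma <- estimate_noise_sigma(evoked)
  region <- localize_patient(evoked, wb$inverse, wb,
                             filter_radius = filter_radius, window = window,
                             threshold = threshold, semantics = semantics)
  dipoles <- NULL
  pmax_ms <- pmax_time(evoked)
  if (fit_dipoles) {
    dipoles <- list(
      P20m = fit_dipole(evoked, wb$leadfield, 20, 5, kind = "P20m"),
      P40m = fit_dipole(evoked, wb$leadfield, 40, 5, kind = "P40m"),
      PMaxm = fit_dipole(evoked, wb$leadfield, pmax_ms, 0, kind = "PMaxm"))
    dipoles <- lapply(dipoles, reject_dipole, parcellation = wb$parcellation,
                      source_space = wb$source_space, side = side)
  }
  list(evoked = evoked, region = region, dipoles = dipoles,
       pmax_ms = pmax_ms, sigma = sigma)
}
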