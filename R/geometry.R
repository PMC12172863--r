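# ---- internal vector helpers -------------------------------------------------

row_norms <- function(m) sqrt(rowSums(m^2))

normalize_rows <- function(m) m / row_norms(m)

cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# ---- icosphere ---------------------------------------------------------------

#' Build a subdivided icosahedral sphere mesh
#'
#' Starts from the regular icosahedron (12 vertices, 20 faces) and applies
#' `subdivisions` rounds of 4-to-1 triangle subdivision, projecting every new
#' vertex back onto the sphere. The resulting mesh has `10 * 4^subdivisions + 2`
#' vertices; five subdivisions give the 10,242-vertex grid commonly used as a
#' per-hemisphere cortical source space ("ico-5").
#'
#' @param subdivisions Non-negative integer number of subdivision rounds
#'   (at most 7).
#' @param radius Sphere radius in mm.
#' @return A `triangle_mesh`: list with `vertices` (n x 3 matrix, mm),
#'   `faces` (m x 3 integer matrix, 1-based, outward-oriented),
#'   `hemisphere` (`"left"`, `"right"` or `NA`) and `center` (length-3).
#' @examples
#' mesh <- build_icosphere(2, radius = 10)
#' nrow(mesh$vertices)  # 162
#' @export
build_icosphere <- function(subdivisions, radius = 1) {
  if (!is.numeric(subdivisions) || length(subdivisions) != 1L ||
      is.na(subdivisions) || subdivisions != floor(subdivisions) || subdivisions < 0)
    stop("`subdivisions` must be a single non-negative integer")
  if (subdivisions > 7) stop("`subdivisions` must be <= 7")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("`radius` must be a positive scalar")

  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- 1L + rbind(
    c(0L, 11L, 5L), c(0L, 5L, 1L), c(0L, 1L, 7L), c(0L, 7L, 10L), c(0L, 10L, 11L),
    c(1L, 5L, 9L), c(5L, 11L, 4L), c(11L, 10L, 2L), c(10L, 7L, 6L), c(7L, 1L, 8L),
    c(3L, 9L, 4L), c(3L, 4L, 2L), c(3L, 2L, 6L), c(3L, 6L, 8L), c(3L, 8L, 9L),
    c(4L, 9L, 5L), c(2L, 4L, 11L), c(6L, 2L, 10L), c(8L, 6L, 7L), c(9L, 8L, 1L))

  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    first <- !duplicated(key)
    mid_id <- nrow(v) + match(key, key[first])
    mids <- normalize_rows((v[e[first, 1], , drop = FALSE] +
                            v[e[first, 2], , drop = FALSE]) / 2)
    v <- rbind(v, mids)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m31 <- mid_id[2L * nf + seq_len(nf)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
    storage.mode(f) <- "integer"
  }

  # enforce outward winding (normal . centroid > 0 on a sphere)
  fn <- cross3(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
  cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  flip <- rowSums(fn * cen) < 0
  if (any(flip)) f[flip, 2:3] <- f[flip, 3:2]
  dimnames(f) <- NULL

  structure(list(vertices = v * radius, faces = f,
                 hemisphere = NA_character_, center = c(0, 0, 0)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, hemisphere=%s\n",
              nrow(x$vertices), nrow(x$faces), x$hemisphere))
  invisible(x)
}

# ---- synthetic cortex --------------------------------------------------------

#' Build a synthetic two-hemisphere cortical surface
#'
#' Each hemisphere is a subdivided icosphere whose radius is perturbed by a
#' smooth angular sinusoid, creating alternating ridges and valleys that stand
#' in for gyri and sulci. The folds run parallel to the band parcellation
#' produced by [synthetic_parcellation()]. The right hemisphere is generated
#' first; the left is its mirror image in x. Hemispheres are translated apart
#' along x so that the two surfaces are separated by at least `hemisphere_gap`.
#'
#' @param subdivisions Icosphere subdivision level per hemisphere.
#' @param radius Nominal hemisphere radius, mm.
#' @param fold_amplitude Maximum radial perturbation, mm (must be < radius/4).
#' @param hemisphere_gap Minimum left/right separation along x, mm.
#' @param seed Integer seed controlling the fold pattern (deterministic).
#' @return A `synthetic_cortex`: list with elements `left` and `right`
#'   (`triangle_mesh` objects carrying their `center`).
#' @export
build_synthetic_cortex <- function(subdivisions, radius = 35, fold_amplitude = 3,
                                   hemisphere_gap = 4, seed = 1) {
  if (fold_amplitude < 0) stop("`fold_amplitude` must be >= 0")
  if (fold_amplitude >= radius / 4)
    stop("`fold_amplitude` must be smaller than radius/4")
  base <- build_icosphere(subdivisions, radius)
  u <- base$vertices / radius

  set.seed(as.integer(seed) %% .Machine$integer.max)
  k1 <- sample(4:7, 1)
  k2 <- sample(2:4, 1)
  ph1 <- stats::runif(1, 0, 2 * pi)
  ph2 <- stats::runif(1, 0, 2 * pi)

  # fold coordinate: angle around the x axis (0 = +z, positive toward +y);
  # folds therefore parallel the anterior-posterior label bands
  alpha <- atan2(u[, 2], u[, 3])
  beta <- asin(pmin(1, pmax(-1, u[, 1])))
  raw <- 0.75 * sin(k1 * alpha + ph1) + 0.25 * sin(k2 * beta + ph2)
  delta <- if (fold_amplitude > 0 && max(abs(raw)) > 0)
    fold_amplitude * raw / max(abs(raw)) else 0

  vr <- u * (radius + delta)
  cx <- radius + fold_amplitude + hemisphere_gap / 2

  right <- base
  right$vertices <- sweep(vr, 2, c(cx, 0, 0), "+")
  right$hemisphere <- "right"
  right$center <- c(cx, 0, 0)

  left <- base
  vl <- vr
  vl[, 1] <- -vl[, 1]
  left$vertices <- sweep(vl, 2, c(-cx, 0, 0), "+")
  left$faces <- base$faces[, c(1L, 3L, 2L)]  # mirroring flips winding
  left$hemisphere <- "left"
  left$center <- c(-cx, 0, 0)

  structure(list(left = left, right = right, radius = radius,
                 fold_amplitude = fold_amplitude, hemisphere_gap = hemisphere_gap,
                 seed = seed),
            class = "synthetic_cortex")
}

# ---- source space ------------------------------------------------------------

vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  fn <- cross3(v[f[, 2], ] - v[f[, 1], ], v[f[, 3], ] - v[f[, 1], ])
  nrm <- row_norms(fn)
  scale <- stats::median(nrm)
  bad <- which(nrm <= 1e-12 * max(scale, .Machine$double.eps))
  if (length(bad))
    stop("degenerate (zero-area) face(s): ", paste(bad, collapse = ", "))
  # |face normal| = 2 * area, so summing raw cross products area-weights
  acc <- rowsum(fn[rep(seq_len(nrow(f)), 3L), ], group = as.vector(f))
  acc <- acc[order(as.integer(rownames(acc))), , drop = FALSE]
  dimnames(acc) <- NULL
  normalize_rows(acc)
}

#' Build a source space from one mesh or a two-hemisphere cortex
#'
#' Places one current source at every mesh vertex. Source orientation is the
#' area-weighted average of adjacent face normals (the outward surface normal),
#' normalized to unit length. For a two-hemisphere `synthetic_cortex`, sources
#' are concatenated left-then-right and the global source index is
#' `hemisphere offset + vertex id`.
#'
#' @param x A `triangle_mesh` or a `synthetic_cortex`.
#' @return A `source_space`: list with `positions` (n x 3, mm), `orientations`
#'   (n x 3, unit rows), `hemisphere` (character), `vertex_id` (1-based, per
#'   hemisphere), `n_left`, and `centers` (named list of hemisphere centers).
#' @export
make_source_space <- function(x) {
  if (inherits(x, "synthetic_cortex")) {
    l <- make_source_space(x$left)
    r <- make_source_space(x$right)
    return(structure(list(
      positions = rbind(l$positions, r$positions),
      orientations = rbind(l$orientations, r$orientations),
      hemisphere = c(l$hemisphere, r$hemisphere),
      vertex_id = c(l$vertex_id, r$vertex_id),
      n_left = nrow(l$positions),
      centers = list(left = x$left$center, right = x$right$center)),
      class = "source_space"))
  }
  if (!inherits(x, "triangle_mesh")) stop("`x` must be a triangle_mesh or synthetic_cortex")
  n <- nrow(x$vertices)
  hemi <- if (is.na(x$hemisphere)) "right" else x$hemisphere
  centers <- list(x$center)
  names(centers) <- hemi
  structure(list(positions = x$vertices,
                 orientations = vertex_normals(x),
                 hemisphere = rep(hemi, n),
                 vertex_id = seq_len(n),
                 n_left = if (hemi == "left") n else 0L,
                 centers = centers),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("source_space: %d sources (%d left, %d right)\n",
              nrow(x$positions), sum(x$hemisphere == "left"),
              sum(x$hemisphere == "right")))
  invisible(x)
}

n_sources <- function(ss) nrow(ss$positions)

# ---- parcellation ------------------------------------------------------------

SEF_LABELS <- c("precentral_gyrus", "central_sulcus",
                "postcentral_gyrus", "postcentral_sulcus", "other")

#' Synthetic band parcellation of the source space
#'
#' Assigns every source an anatomical label from a deterministic angular band
#' construction that stands in for a cortical atlas. In each hemisphere, four
#' contiguous bands of width `band_width` degrees (in the angle around the x
#' axis, measured from +z toward +y, relative to the hemisphere center) are
#' labeled, in anterior-to-posterior order: precentral_gyrus, central_sulcus,
#' postcentral_gyrus, postcentral_sulcus. All remaining sources are labeled
#' `other`. A wedge of width w degrees covers exactly w/360 of a sphere, so the
#' default 8.1-degree bands put 4 x 8.1 / 360 = 9% of sources in the
#' sensorimotor region of interest.
#'
#' @param source_space A `source_space`.
#' @param band_width Width of each band, degrees.
#' @param band_center Angle (degrees) of the central_sulcus/postcentral_gyrus
#'   boundary; 0 puts the strip across the top of the hemisphere.
#' @return A `parcellation`: `label_of` (integer per source), `label_table`
#'   (data.frame: label_id, label_name, hemisphere), `roi_label_ids` (the eight
#'   sensorimotor label ids, both hemispheres).
#' @export
synthetic_parcellation <- function(source_space, band_width = 8.1, band_center = 0) {
  if (band_width < 0) stop("`band_width` must be >= 0")
  if (4 * band_width / 360 > 0.5)
    stop("bands would cover more than 50% of the surface")
  ss <- source_space
  n <- n_sources(ss)
  label_table <- data.frame(
    label_id = 1:10,
    label_name = rep(SEF_LABELS, 2),
    hemisphere = rep(c("left", "right"), each = 5),
    stringsAsFactors = FALSE)

  label_of <- integer(n)
  for (h in c("left", "right")) {
    idx <- which(ss$hemisphere == h)
    if (!length(idx)) next
    ctr <- ss$centers[[h]]
    dy <- ss$positions[idx, 2] - ctr[2]
    dz <- ss$positions[idx, 3] - ctr[3]
    alpha <- atan2(dy, dz) * 180 / pi
    # boundaries, anterior (high alpha) to posterior (low alpha)
    b <- band_center + band_width * c(2, 1, 0, -1, -2)
    band <- rep(5L, length(idx))                        # other
    band[alpha <= b[1] & alpha > b[2]] <- 1L            # precentral_gyrus
    band[alpha <= b[2] & alpha > b[3]] <- 2L            # central_sulcus
    band[alpha <= b[3] & alpha > b[4]] <- 3L            # postcentral_gyrus
    band[alpha <= b[4] & alpha > b[5]] <- 4L            # postcentral_sulcus
    label_of[idx] <- band + if (h == "left") 0L else 5L
  }
  structure(list(label_of = label_of, label_table = label_table,
                 roi_label_ids = c(1:4, 6:9),
                 band_width = band_width, band_center = band_center),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  tab <- table(factor(x$label_of, levels = x$label_table$label_id))
  cat("parcellation:\n")
  print(stats::setNames(as.integer(tab),
                        paste(x$label_table$hemisphere, x$label_table$label_name)))
  invisible(x)
}

label_names_of <- function(parcellation, ids) {
  parcellation$label_table$label_name[match(ids, parcellation$label_table$label_id)]
}

roi_fraction <- function(parcellation) {
  mean(parcellation$label_of %in% parcellation$roi_label_ids)
}

# ---- neighborhoods -----------------------------------------------------------

#' Sources within a Euclidean radius of one source
#'
#' @param source_space A `source_space`.
#' @param index Source index (1-based).
#' @param radius Search radius, mm (inclusive; the source itself is included).
#' @return Integer vector of source indices.
#' @export
neighbors_within <- function(source_space, index, radius) {
  n <- n_sources(source_space)
  if (length(index) != 1L || is.na(index) || index < 1 || index > n)
    stop("`index` out of range")
  if (radius < 0) stop("`radius` must be >= 0")
  d2 <- colSums((t(source_space$positions) - source_space$positions[index, ])^2)
  which(d2 <= radius^2 + 1e-12)
}

# All-pairs radius neighborhoods via voxel binning; returns a list of integer
# vectors (each including self). Used by the spatial filter.
radius_neighbors <- function(positions, radius) {
  n <- nrow(positions)
  if (radius <= 0) return(lapply(seq_len(n), identity))
  cell <- floor(positions / radius)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = ",")
  bins <- split(seq_len(n), key)
  bin_env <- list2env(bins, hash = TRUE)
  out <- vector("list", n)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (b in names(bins)) {
    members <- bins[[b]]
    cc <- cell[members[1], ]
    cand <- integer(0)
    for (k in seq_len(27)) {
      kk <- paste(cc[1] + offs[k, 1], cc[2] + offs[k, 2], cc[3] + offs[k, 3],
                  sep = ",")
      hit <- bin_env[[kk]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    cp <- positions[cand, , drop = FALSE]
    for (i in members) {
      d2 <- colSums((t(cp) - positions[i, ])^2)
      out[[i]] <- cand[d2 <= radius^2 + 1e-12]
    }
  }
  out
}

# ---- mesh adjacency and patch growth -----------------------------------------

# Adjacency over global source indices for one mesh (offset shifts vertex ids).
mesh_adjacency_offset <- function(mesh, offset = 0L) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- rbind(e, e[, 2:1])
  n <- nrow(mesh$vertices)
  adj <- split(e[, 2] + offset, factor(e[, 1], levels = seq_len(n)))
  lapply(adj, function(x) sort(unique(x)))
}

#' Graph adjacency of a two-hemisphere cortex
#'
#' Hemispheres are disjoint graphs: no edge crosses the midline, so grown
#' patches never span hemispheres.
#'
#' @param cortex A `synthetic_cortex` (or a single `triangle_mesh`).
#' @return List of integer vectors, one per global source index.
#' @export
cortex_adjacency <- function(cortex) {
  if (inherits(cortex, "triangle_mesh"))
    return(mesh_adjacency_offset(cortex, 0L))
  adj_l <- mesh_adjacency_offset(cortex$left, 0L)
  adj_r <- mesh_adjacency_offset(cortex$right, length(adj_l))
  c(adj_l, adj_r)
}

#' Grow a contiguous cortical patch of exact size
#'
#' Breadth-first growth over mesh edges starting from `seed_vertex`. Whole
#' graph rings are added while they fit; the final partial ring is ordered by
#' ascending Euclidean distance to the seed, then ascending vertex id, so the
#' result is deterministic.
#'
#' @param source_space A `source_space` (global indexing).
#' @param cortex The matching `synthetic_cortex` (or `triangle_mesh`); ignored
#'   when `adjacency` is supplied.
#' @param seed_vertex Global source index to start from.
#' @param size Number of members required (>= 1).
#' @param adjacency Optional precomputed [cortex_adjacency()] list.
#' @param allowed Optional integer vector restricting growth to an induced
#'   subgraph (must contain `seed_vertex`).
#' @return Sorted integer vector of exactly `size` member indices.
#' @export
grow_patch <- function(source_space, cortex, seed_vertex, size,
                       adjacency = NULL, allowed = NULL) {
  n <- n_sources(source_space)
  if (size < 1 || size > n) stop("`size` must be in [1, number of sources]")
  if (seed_vertex < 1 || seed_vertex > n) stop("`seed_vertex` out of range")
  seed_vertex <- as.integer(seed_vertex)
  size <- as.integer(size)
  if (is.null(adjacency)) adjacency <- cortex_adjacency(cortex)
  ok <- if (is.null(allowed)) NULL else {
    if (!(seed_vertex %in% allowed)) stop("`seed_vertex` not in `allowed`")
    okv <- logical(n); okv[allowed] <- TRUE; okv
  }
  pos <- source_space$positions
  seedp <- pos[seed_vertex, ]
  members <- seed_vertex
  frontier <- seed_vertex
  in_set <- logical(n)
  in_set[seed_vertex] <- TRUE
  while (length(members) < size) {
    ring <- unique(unlist(adjacency[frontier], use.names = FALSE))
    ring <- ring[!in_set[ring]]
    if (!is.null(ok)) ring <- ring[ok[ring]]
    if (!length(ring))
      stop("`size` exceeds the seed's connected component")
    need <- size - length(members)
    if (length(ring) > need) {
      d2 <- colSums((t(pos[ring, , drop = FALSE]) - seedp)^2)
      ring <- ring[order(d2, ring)][seq_len(need)]
    }
    members <- c(members, ring)
    in_set[ring] <- TRUE
    frontier <- ring
  }
  as.integer(sort(members))
}
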