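# Round-trip file handling: ASCII PLY meshes, TSV tables, JSON records and
# RDS containers for the large numeric arrays (epochs, lead fields).

#' Write a mesh as ASCII PLY
#'
#' Vertex coordinates in mm; face lines `3 i j k` with 0-based indices per
#' the PLY convention.
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output file.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment hemisphere %s center %s", mesh$hemisphere,
                       paste(format(mesh$center, digits = 17), collapse = " ")),
               sprintf("element vertex %d", nrow(v)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(format(v[, 1], digits = 17), format(v[, 2], digits = 17),
                   format(v[, 3], digits = 17)), con)
  writeLines(paste(3L, f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' Read an ASCII PLY mesh written by [write_ply()]
#'
#' @param path Input file.
#' @return A `triangle_mesh`.
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  end <- match("end_header", lines)
  if (is.na(end)) stop("not an ASCII PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)))
  hemi <- NA_character_
  center <- c(0, 0, 0)
  cm <- grep("^comment hemisphere ", lines, value = TRUE)
  if (length(cm)) {
    parts <- strsplit(cm[1], " +")[[1]]
    hemi <- parts[3]
    center <- as.numeric(parts[5:7])
  }
  v <- matrix(scan(text = lines[end + seq_len(nv)], quiet = TRUE),
              nv, 3, byrow = TRUE)
  f <- matrix(scan(text = lines[end + nv + seq_len(nf)], quiet = TRUE),
              nf, 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  storage.mode(f) <- "integer"
  structure(list(vertices = v, faces = f,
                 hemisphere = if (identical(hemi, "NA")) NA_character_ else hemi,
                 center = center),
            class = "triangle_mesh")
}

#' Write a parcellation as TSV tables
#'
#' `<stem>_labels.tsv` holds columns source_id, label_id; `<stem>_table.tsv`
#' holds label_id, label_name, hemisphere.
#'
#' @param parcellation A `parcellation`.
#' @param stem Path stem (no extension).
#' @export
write_parcellation <- function(parcellation, stem) {
  labs <- data.frame(source_id = seq_along(parcellation$label_of),
                     label_id = parcellation$label_of)
  write.table(labs, paste0(stem, "_labels.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write.table(parcellation$label_table, paste0(stem, "_table.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' Read a parcellation written by [write_parcellation()]
#'
#' @param stem Path stem.
#' @param roi_label_names ROI label names (matched in both hemispheres).
#' @return A `parcellation`.
#' @export
read_parcellation <- function(stem, roi_label_names = SEF_LABELS[1:4]) {
  labs <- read.delim(paste0(stem, "_labels.tsv"))
  tab <- read.delim(paste0(stem, "_table.tsv"), stringsAsFactors = FALSE)
  structure(list(label_of = labs$label_id[order(labs$source_id)],
                 label_table = tab,
                 roi_label_ids = tab$label_id[tab$label_name %in%
                                              roi_label_names]),
            class = "parcellation")
}

#' Write/read a sensor array as TSV
#'
#' @param sensors A `sensor_array`.
#' @param path TSV path.
#' @export
write_sensors <- function(sensors, path) {
  df <- as.data.frame(sensors)
  attr(df, "helmet_radius") <- NULL
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensors
#' @export
read_sensors <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("sensor_array", "data.frame")
  df
}

#' Serialize an activation region to JSON
#'
#' Keys are written in a fixed canonical order so reruns are byte-identical.
#'
#' @param region An `activation_region`.
#' @param path JSON path.
#' @export
write_region_json <- function(region, path) {
  obj <- list(members = region$members,
              loadings = round(region$loadings, 12),
              centroid = round(unname(region$centroid), 9),
              centroid_vertex = region$centroid_vertex,
              centroid_label = region$centroid_label,
              peak_time = region$peak_time,
              threshold = region$threshold,
              semantics = region$semantics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_region_json
#' @export
read_region_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(members = as.integer(obj$members), loadings = obj$loadings,
                 centroid = obj$centroid,
                 centroid_vertex = as.integer(obj$centroid_vertex),
                 centroid_label = as.integer(obj$centroid_label),
                 threshold = obj$threshold, semantics = obj$semantics,
                 peak_time = obj$peak_time),
            class = "activation_region")
}

#' Serialize dipole fits to JSON
#'
#' Records mirror the clinical report columns: kind, time, gof, moment,
#' x/y/z (surface RAS, mm), accepted.
#'
#' @param dipoles Named list of `dipole_fit`s.
#' @param path JSON path.
#' @export
write_dipoles_json <- function(dipoles, path) {
  recs <- lapply(dipoles, function(d) list(
    kind = d$kind, time = d$time, gof = d$gof,
    moment = round(unname(d$moment), 9),
    moment_magnitude = d$moment_magnitude,
    x = unname(d$position[1]), y = unname(d$position[2]),
    z = unname(d$position[3]),
    accepted = d$accepted, node = d$node))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dipoles_json
#' @export
read_dipoles_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(r) structure(list(
    time = r$time, position = c(r$x, r$y, r$z),
    moment = unlist(r$moment), moment_magnitude = r$moment_magnitude,
    gof = r$gof, kind = r$kind, accepted = r$accepted,
    node = as.integer(r$node)), class = "dipole_fit"))
}

#' Write/read epochs (RDS container)
#'
#' @param epochs A `sef_epochs`.
#' @param path RDS path.
#' @export
write_epochs <- function(epochs, path) {
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) readRDS(path)
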