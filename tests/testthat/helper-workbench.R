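# Shared fixtures, built once per test run and cached.

.wb_cache <- new.env(parent = emptyenv())

cached_workbench <- function(subdivisions, ...) {
  key <- paste0("wb", subdivisions, "_", paste(c(...), collapse = "_"))
  if (is.null(.wb_cache[[key]]))
    .wb_cache[[key]] <- build_workbench(subdivisions, ...)
  .wb_cache[[key]]
}

# Minimal epochs object for unit tests of the evoked module.
toy_epochs <- function(data, times = seq(-50, 249),
                       ch_kind = rep("grad", dim(data)[2])) {
  structure(list(data = data, times = times, sfreq = 1000,
                 stim_sample = which(times == 0), ch_kind = ch_kind),
            class = "sef_epochs")
}

toy_evoked <- function(data, times = seq(-50, 249),
                       ch_kind = rep("grad", nrow(data))) {
  structure(list(data = data, times = times, n_ave = 1L, ch_kind = ch_kind),
            class = "sef_evoked")
}

# Tiny hand-built source space + parcellation for threshold/metric tests.
toy_space <- function(positions, hemisphere = NULL) {
  n <- nrow(positions)
  if (is.null(hemisphere)) hemisphere <- rep("right", n)
  structure(list(positions = positions,
                 orientations = matrix(rep(c(0, 0, 1), n), n, 3, byrow = TRUE),
                 hemisphere = hemisphere, vertex_id = seq_len(n),
                 n_left = sum(hemisphere == "left"),
                 centers = list(left = c(-40, 0, 0), right = c(40, 0, 0))),
            class = "source_space")
}

toy_parcellation <- function(label_of) {
  structure(list(
    label_of = label_of,
    label_table = data.frame(
      label_id = 1:10,
      label_name = rep(c("precentral_gyrus", "central_sulcus",
                         "postcentral_gyrus", "postcentral_sulcus", "other"), 2),
      hemisphere = rep(c("left", "right"), each = 5),
      stringsAsFactors = FALSE),
    roi_label_ids = c(1:4, 6:9)),
    class = "parcellation")
}

# Independent connectivity check (iterative BFS, no package code).
is_connected_subset <- function(members, adjacency) {
  inset <- logical(length(adjacency))
  inset[members] <- TRUE
  seen <- members[1]
  frontier <- members[1]
  while (length(frontier)) {
    nxt <- unique(unlist(adjacency[frontier], use.names = FALSE))
    nxt <- nxt[inset[nxt] & !(nxt %in% seen)]
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(members)
}
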