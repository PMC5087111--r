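#' Generate a synthetic labelled field with exact ground-truth counts
#'
#' Places non-overlapping disk-shaped "nuclei" on a regular grid (jittered
#' within their grid cell), selects exactly `n_probe_positive` of them to be
#' fully covered by the probe mask and exactly `n_protein_positive` of those
#' to be covered by the protein mask, and adds `n_host_cells` larger host
#' labels on a separate grid. The closed loop with [colocalize()] /
#' [protein_positivity()] recovers the requested counts exactly.
#'
#' @param n_nuclei number of prokaryote-scale objects
#' @param n_probe_positive number of probe-covered objects (<= n_nuclei)
#' @param n_host_cells number of host cell labels
#' @param n_protein_positive number of protein-covered objects among the
#'   probe-positive ones (default 0)
#' @param pixel_size micrometres per pixel (default 0.1)
#' @param nucleus_radius_px object radius in pixels (default 2)
#' @param field_id identifier
#' @param seed integer seed or `NULL`
#' @return a [label_field()]; ground truth in attribute `"truth"`
#' @export
generate_label_field <- function(n_nuclei, n_probe_positive,
                                 n_host_cells = 0L,
                                 n_protein_positive = 0L,
                                 pixel_size = 0.1,
                                 nucleus_radius_px = 2L,
                                 field_id = "field1", seed = NULL) {
  stopifnot(n_probe_positive <= n_nuclei,
            n_protein_positive <= n_probe_positive)
  set_seed_if(seed)
  r <- nucleus_radius_px
  cell <- 2L * r + 2L                       # grid cell edge, 1 px margin
  ngrid <- ceiling(sqrt(max(n_nuclei, 1)))
  side <- ngrid * cell
  # host cells on their own (coarser) grid below the nuclei area
  host_r <- 4L * r
  host_cell <- 2L * host_r + 2L
  host_ngrid <- ceiling(sqrt(max(n_host_cells, 1)))
  host_side <- host_ngrid * host_cell
  nr <- side + (if (n_host_cells > 0) host_side else 0L)
  nc <- max(side, if (n_host_cells > 0) host_side else 0L)

  nuclei <- matrix(0L, nr, nc)
  probe <- matrix(FALSE, nr, nc)
  protein <- matrix(FALSE, nr, nc)
  host <- matrix(0L, nr, nc)

  if (n_nuclei > ngrid^2) {
    stop("capacity error: field cannot host the requested nuclei")
  }
  slots <- sample(ngrid^2, n_nuclei)
  pos_ids <- sample(n_nuclei, n_probe_positive)
  prot_ids <- if (n_protein_positive > 0)
    sample(pos_ids, n_protein_positive) else integer(0)
  disk <- disk_offsets(r)
  for (i in seq_len(n_nuclei)) {
    gi <- (slots[i] - 1L) %/% ngrid
    gj <- (slots[i] - 1L) %% ngrid
    ci <- gi * cell + r + 1L + sample(0:1, 1)
    cj <- gj * cell + r + 1L + sample(0:1, 1)
    px <- cbind(ci + disk[, 1], cj + disk[, 2])
    nuclei[px] <- i
    if (i %in% pos_ids) probe[px] <- TRUE
    if (i %in% prot_ids) protein[px] <- TRUE
  }
  if (n_host_cells > 0) {
    if (n_host_cells > host_ngrid^2) {
      stop("capacity error: field cannot host the requested host cells")
    }
    hdisk <- disk_offsets(host_r)
    hslots <- sample(host_ngrid^2, n_host_cells)
    for (i in seq_len(n_host_cells)) {
      gi <- (hslots[i] - 1L) %/% host_ngrid
      gj <- (hslots[i] - 1L) %% host_ngrid
      ci <- side + gi * host_cell + host_r + 1L
      cj <- gj * host_cell + host_r + 1L
      host[cbind(ci + hdisk[, 1], cj + hdisk[, 2])] <- i
    }
  }
  f <- label_field(nuclei, host, probe, protein, pixel_size, field_id)
  attr(f, "truth") <- list(n_nuclei = n_nuclei,
                           n_probe_positive = n_probe_positive,
                           n_protein_positive = n_protein_positive,
                           n_host_cells = n_host_cells,
                           probe_labels = sort(pos_ids),
                           protein_labels = sort(prot_ids))
  f
}

#' @keywords internal
disk_offsets <- function(r) {
  g <- expand.grid(di = -r:r, dj = -r:r)
  as.matrix(g[g$di^2 + g$dj^2 <= r^2, ])
}

#' Generate a synthetic voxel cell with planted granules
#'
#' Digitises an ellipsoidal cell (semi-axes in micrometres) on an
#' anisotropic voxel grid and plants spherical granules at chosen fractional
#' positions along the cell's long (x) axis — by default two bipolar
#' granules at opposite poles, emulating the reconstructed symbiont cells.
#'
#' @param semi_axes_um cell ellipsoid semi-axes (x, y, z) in um
#' @param granule_radius_um radius of each granule (recycled)
#' @param granule_positions fractional positions along the x semi-axis in
#'   `[-1, 1]`; default `c(-0.7, 0.7)` (bipolar)
#' @param voxel_size um per voxel along (x, y, z)
#' @param seed integer seed or `NULL` (jitters granule y/z slightly)
#' @return a [voxel_model()]; planted parameters in attribute `"truth"`
#' @export
generate_voxel_cell <- function(semi_axes_um = c(0.925, 0.525, 0.525),
                                granule_radius_um = 0.084,
                                granule_positions = c(-0.7, 0.7),
                                voxel_size = c(0.01, 0.01, 0.01),
                                seed = NULL) {
  set_seed_if(seed)
  a <- semi_axes_um
  if (any(granule_radius_um >= min(a))) {
    stop("capacity error: granule radius does not fit inside the cell")
  }
  margin <- max(granule_radius_um) + 2 * max(voxel_size)
  dims <- ceiling(2 * (a + margin) / voxel_size)
  centre <- (a + margin)
  cx <- (seq_len(dims[1]) - 0.5) * voxel_size[1]
  cy <- (seq_len(dims[2]) - 0.5) * voxel_size[2]
  cz <- (seq_len(dims[3]) - 0.5) * voxel_size[3]
  # ellipsoid membership, outer product over the separable quadratic form
  qx <- ((cx - centre[1]) / a[1])^2
  qy <- ((cy - centre[2]) / a[2])^2
  qz <- ((cz - centre[3]) / a[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  cell <- q <= 1
  granules <- array(0L, dim = dims)
  radii <- rep_len(granule_radius_um, length(granule_positions))
  for (k in seq_along(granule_positions)) {
    gc <- centre
    gc[1] <- centre[1] + granule_positions[k] * a[1] *
      (1 - radii[k] / a[1])                     # keep the sphere inside
    dx2 <- ((cx - gc[1]))^2
    dy2 <- ((cy - gc[2]))^2
    dz2 <- ((cz - gc[3]))^2
    d <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    granules[d <= radii[k]^2 & cell] <- k
  }
  m <- voxel_model(cell, granules, voxel_size)
  attr(m, "truth") <- list(semi_axes_um = a, granule_radius_um = radii,
                           granule_positions = granule_positions)
  m
}

#' Digitise a solid sphere on an isotropic voxel grid
#'
#' Analytic-oracle fixture for volume/diameter convergence checks: the voxel
#' volume of the digitised sphere converges to `(4/3) pi r^3` as the voxel
#' size shrinks.
#' @param radius_um sphere radius (um)
#' @param voxel_um voxel edge (um, isotropic)
#' @return a [voxel_model()] whose single granule is the sphere (the cell
#'   mask is the enclosing box)
#' @export
voxel_sphere <- function(radius_um, voxel_um) {
  n <- ceiling(2 * (radius_um + 2 * voxel_um) / voxel_um)
  centre <- (radius_um + 2 * voxel_um)
  cx <- (seq_len(n) - 0.5) * voxel_um
  d <- outer(outer((cx - centre)^2, (cx - centre)^2, `+`),
             (cx - centre)^2, `+`)
  sphere <- array(d <= radius_um^2, dim = c(n, n, n))
  voxel_model(array(TRUE, dim = c(n, n, n)),
              array(as.integer(sphere), dim = c(n, n, n)),
              rep(voxel_um, 3))
}

#' Write/read integer arrays in a plain text container
#'
#' Lossless, documented plain array format: line 1 `sagscope-array 1`,
#' line 2 `dims: d1 d2 [d3 ...]`, then the array values in R's
#' column-major order, whitespace-separated. Logical masks are stored as
#' 0/1.
#'
#' @param x integer/logical matrix or array
#' @param path output path
#' @return invisible `path`
#' @export
write_array <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("sagscope-array 1",
               paste("dims:", paste(dim(x), collapse = " "))), con)
  writeLines(paste(as.integer(x), collapse = " "), con)
  invisible(path)
}

#' @rdname write_array
#' @return for `read_array`, the integer array
#' @export
read_array <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "sagscope-array")) {
    stop("not a sagscope array file")
  }
  dims <- as.integer(strsplit(sub("^dims: *", "", lines[2]), " +")[[1]])
  vals <- as.integer(strsplit(paste(lines[-(1:2)], collapse = " "),
                              " +")[[1]])
  if (length(vals) != prod(dims)) stop("array payload truncated")
  array(vals, dim = dims)
}
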