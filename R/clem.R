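#' Labelled 2D field for co-localization quantification
#'
#' Bundles the aligned 2D masks of one imaged area: prokaryote-scale
#' DAPI-detected objects as an integer label image (0 = background, k =
#' object k), host cell nuclei as a second label image, and binary probe
#' (taxon-specific FISH) and protein (IHC) signal masks.
#'
#' @param nuclei integer label matrix of prokaryotic DAPI objects
#' @param host integer label matrix of host cells (may be all zero)
#' @param probe,protein logical matrices, same shape as `nuclei`
#' @param pixel_size micrometres per pixel (> 0)
#' @param field_id identifier string
#' @param field_area area in mm^2; default derived from the image shape and
#'   `pixel_size`
#' @return object of class `sagscope_label_field`
#' @export
label_field <- function(nuclei, host, probe, protein,
                        pixel_size, field_id = "field1",
                        field_area = NULL) {
  stopifnot(pixel_size > 0)
  dims <- dim(nuclei)
  for (m in list(host, probe, protein)) {
    if (!identical(dim(m), dims)) stop("field masks differ in shape")
  }
  if (min(nuclei) < 0 || min(host) < 0) stop("labels must be non-negative")
  area <- field_area %||% (prod(dims) * pixel_size^2 / 1e6)
  structure(list(field_id = field_id, nuclei = nuclei, host = host,
                 probe = probe != 0, protein = protein != 0,
                 pixel_size = pixel_size, field_area = area),
            class = "sagscope_label_field")
}

#' Probe/DAPI co-localization of labelled objects
#'
#' An object is probe-positive when at least `min_overlap_fraction` of its
#' pixels fall on the probe mask (a fraction-of-object rule rather than
#' any-pixel, robust to mask dilation). Deterministic.
#'
#' @param field a [label_field()]
#' @param min_overlap_fraction required fraction of object pixels on the
#'   probe mask (default 0.25)
#' @return list: `objects` (tibble: label, n_px, probe_px, overlap_frac,
#'   positive), `n_nuclei`, `n_positive`, `percent_positive`
#' @export
colocalize <- function(field, min_overlap_fraction = 0.25) {
  labs <- field$nuclei
  nmax <- max(labs)
  if (nmax == 0) {
    return(list(objects = tibble::tibble(
      label = integer(), n_px = integer(), probe_px = integer(),
      overlap_frac = numeric(), positive = logical()
    ), n_nuclei = 0L, n_positive = 0L, percent_positive = NA_real_))
  }
  n_px <- tabulate(labs[labs > 0], nbins = nmax)
  probe_px <- tabulate(labs[labs > 0 & field$probe], nbins = nmax)
  present <- which(n_px > 0)
  frac <- probe_px[present] / n_px[present]
  pos <- frac >= min_overlap_fraction
  objects <- tibble::tibble(label = present, n_px = n_px[present],
                            probe_px = probe_px[present],
                            overlap_frac = frac, positive = pos)
  list(objects = objects,
       n_nuclei = length(present),
       n_positive = sum(pos),
       percent_positive = 100 * sum(pos) / length(present))
}

#' Protein positivity among probe-positive objects
#'
#' Percent of probe-positive objects whose pixels overlap the protein (IHC)
#' mask under the same fraction-of-object rule. The denominator is the
#' probe-positive objects only.
#'
#' @param field a [label_field()]
#' @param coloc result of [colocalize()] on the same field
#' @param min_overlap_fraction overlap rule threshold (default 0.25)
#' @return list: `n_positive` (denominator), `n_protein`, `percent`
#'   (`NA` with `undefined = TRUE` when there are no probe-positive objects)
#' @export
protein_positivity <- function(field, coloc, min_overlap_fraction = 0.25) {
  pos_labels <- coloc$objects$label[coloc$objects$positive]
  if (length(pos_labels) == 0) {
    return(list(n_positive = 0L, n_protein = 0L, percent = NA_real_,
                undefined = TRUE))
  }
  labs <- field$nuclei
  nmax <- max(labs)
  n_px <- tabulate(labs[labs > 0], nbins = nmax)
  prot_px <- tabulate(labs[labs > 0 & field$protein], nbins = nmax)
  frac <- prot_px[pos_labels] / n_px[pos_labels]
  n_prot <- sum(frac >= min_overlap_fraction)
  list(n_positive = length(pos_labels), n_protein = n_prot,
       percent = 100 * n_prot / length(pos_labels), undefined = FALSE)
}

#' Areal density and per-host-cell ratio of probe-positive cells
#'
#' @param field a [label_field()]
#' @param coloc result of [colocalize()]
#' @return list: `density_per_mm2` (= n_positive / field area),
#'   `n_host_cells`, `cells_per_host` (`NA` + `undefined` when no host cells)
#' @export
density_and_ratio <- function(field, coloc) {
  if (field$field_area <= 0) stop("field area must be positive")
  n_host <- length(unique(field$host[field$host > 0]))
  list(
    density_per_mm2 = coloc$n_positive / field$field_area,
    n_host_cells = n_host,
    cells_per_host = if (n_host == 0) NA_real_ else
      coloc$n_positive / n_host,
    undefined = n_host == 0
  )
}

#' Per-field summary rows combined across areas
#'
#' Unweighted mean and sample standard deviation (n - 1) of every numeric
#' column across fields; with a single field the sd is `NA` (flagged).
#'
#' @param rows tibble/data frame, one row per field, numeric summary columns
#' @return tibble: column, mean, sd, n
#' @export
summarize_fields <- function(rows) {
  rows <- as.data.frame(rows)
  stopifnot(nrow(rows) >= 1)
  num <- vapply(rows, is.numeric, logical(1))
  dplyr::bind_rows(lapply(names(rows)[num], function(cn) {
    x <- rows[[cn]]
    tibble::tibble(column = cn, mean = mean(x),
                   sd = if (length(x) < 2) NA_real_ else stats::sd(x),
                   n = length(x))
  }))
}

#' 3D voxel model of a cell and its granules
#'
#' @param cell 3D logical (or 0/1) array of cell voxels
#' @param granules 3D integer label array (0 = background, k = granule k);
#'   granule voxels must lie inside the cell mask
#' @param voxel_size micrometres per voxel along (x, y, z); z defaults to
#'   0.1 um, the serial-section spacing
#' @return object of class `sagscope_voxel_model`
#' @export
voxel_model <- function(cell, granules, voxel_size = c(0.01, 0.01, 0.1)) {
  stopifnot(length(dim(cell)) == 3, identical(dim(cell), dim(granules)),
            all(voxel_size > 0), length(voxel_size) == 3)
  cell <- cell != 0
  if (any(granules[!cell] != 0)) {
    stop("granule voxels outside the cell mask")
  }
  structure(list(cell = cell, granules = granules,
                 voxel_size = as.numeric(voxel_size)),
            class = "sagscope_voxel_model")
}

#' 3D granule morphometry
#'
#' Per granule: volume (voxel count times voxel volume, um^3) and
#' equivalent spherical diameter `(6V/pi)^(1/3)` in nm. Per cell: granule
#' count, total granule volume fraction of the cell volume, and a bipolarity
#' score — granule centroids are projected onto the cell's principal axis
#' (first principal component of the cell voxel coordinates in physical
#' units); the score is 1 when the two largest granules fall in opposite
#' axial halves of the cell, 0 otherwise, `NA` (flagged) with fewer than two
#' granules.
#'
#' @param model a [voxel_model()]
#' @return object of class `sagscope_morphometry`: list with `granules`
#'   (tibble: label, n_voxels, volume_um3, eq_diameter_nm, axis_position),
#'   `cell_volume_um3`, `n_granules`, `volume_fraction`, `polarity_score`,
#'   `polarity_undefined`
#' @export
granule_morphometry <- function(model) {
  vox_vol <- prod(model$voxel_size)
  n_cell <- sum(model$cell)
  if (n_cell == 0) stop("empty cell mask")
  cell_vol <- n_cell * vox_vol

  labs <- sort(unique(model$granules[model$granules > 0]))
  if (length(labs) == 0) {
    return(structure(list(
      granules = tibble::tibble(label = integer(), n_voxels = integer(),
                                volume_um3 = numeric(),
                                eq_diameter_nm = numeric(),
                                axis_position = numeric()),
      cell_volume_um3 = cell_vol, n_granules = 0L, volume_fraction = 0,
      polarity_score = NA_real_, polarity_undefined = TRUE
    ), class = "sagscope_morphometry"))
  }

  # physical coordinates of cell voxels; principal axis through the centroid
  cc <- voxel_coords(model$cell, model$voxel_size)
  centroid <- colMeans(cc)
  axis <- stats::prcomp(cc, center = TRUE, scale. = FALSE)$rotation[, 1]

  rows <- lapply(labs, function(k) {
    mask <- model$granules == k
    nv <- sum(mask)
    vol <- nv * vox_vol
    gc <- colMeans(voxel_coords(mask, model$voxel_size))
    tibble::tibble(
      label = as.integer(k), n_voxels = nv, volume_um3 = vol,
      eq_diameter_nm = 1000 * (6 * vol / pi)^(1 / 3),
      axis_position = sum((gc - centroid) * axis)
    )
  })
  gr <- dplyr::bind_rows(rows)
  polarity <- NA_real_
  undef <- nrow(gr) < 2
  if (!undef) {
    two <- gr[order(-gr$volume_um3), ][1:2, ]
    polarity <- as.numeric(two$axis_position[1] * two$axis_position[2] < 0)
  }
  structure(list(
    granules = gr, cell_volume_um3 = cell_vol, n_granules = nrow(gr),
    volume_fraction = sum(gr$volume_um3) / cell_vol,
    polarity_score = polarity, polarity_undefined = undef
  ), class = "sagscope_morphometry")
}

#' @export
print.sagscope_morphometry <- function(x, ...) {
  cat(sprintf(
    "<morphometry> %d granule(s); cell %.4g um^3; granule fraction %.3g%%\n",
    x$n_granules, x$cell_volume_um3, 100 * x$volume_fraction))
  invisible(x)
}

# (i,j,k) voxel indices of TRUE entries scaled to physical units, voxel
# centres at (index - 0.5) * size.
#' @keywords internal
voxel_coords <- function(mask, voxel_size) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx - 0.5, 2, voxel_size, `*`)
}
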