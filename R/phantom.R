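#' Load a phantom specification
#'
#' Reads a JSON phantom specification: grid shape, voxel spacing and a list
#' of geometric structure primitives (ellipsoids and z-axis cylinders). The
#' shipped default (`system.file("extdata", "default_phantom.json",
#' package = "planqm")`) is an 80 x 80 x 80 grid at 2 mm spacing holding
#' three nested ellipsoidal PTVs (high/intermediate/low risk, prescriptions
#' 69.96/59.4/54 Gy in 33 fractions) and the ten organs at risk scored by
#' the default scheme. Geometry is configuration, not code.
#'
#' @param path path to a phantom JSON file; default is the shipped spec.
#' @return An object of class `phantom_spec`.
#' @export
load_phantom_spec <- function(path = system.file("extdata", "default_phantom.json",
                                                 package = "planqm")) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("grid_shape", "spacing_mm", "structures")
  missing <- setdiff(required, names(spec))
  if (length(missing))
    stop("phantom spec missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  spec$grid_shape <- as.integer(spec$grid_shape)
  spec$spacing_mm <- as.numeric(spec$spacing_mm)
  class(spec) <- "phantom_spec"
  spec
}

oar_names <- function() {
  c("spinal_canal", "parotid_left", "parotid_right", "brainstem",
    "brachial_plexus", "brain", "esophagus", "glottis", "mandible",
    "oral_cavity")
}

# Voxel-centre coordinates (mm) along one axis
axis_coords <- function(n, spacing) (seq_len(n) - 0.5) * spacing

# Normalised radial coordinate of every voxel for one primitive:
# <= 1 inside. Ellipsoid: sqrt(sum(((x - c)/r)^2)); cylinder (z-axis):
# max(radial distance / radius, |z - zc| / half-length).
primitive_radius <- function(shape, center, size, grid_shape, spacing_mm) {
  x <- axis_coords(grid_shape[1], spacing_mm[1])
  y <- axis_coords(grid_shape[2], spacing_mm[2])
  z <- axis_coords(grid_shape[3], spacing_mm[3])
  if (shape == "ellipsoid") {
    rx <- ((x - center[1]) / size[1])^2
    ry <- ((y - center[2]) / size[2])^2
    rz <- ((z - center[3]) / size[3])^2
    sqrt(outer(outer(rx, ry, "+"), rz, "+"))
  } else if (shape == "cylinder") {
    # size = (radius_x, radius_y, half_length_z)
    rx <- ((x - center[1]) / size[1])^2
    ry <- ((y - center[2]) / size[2])^2
    rxy <- sqrt(outer(rx, ry, "+"))            # nx x ny cross-section
    rz <- abs(z - center[3]) / size[3]
    r3 <- array(rxy, dim = c(length(x), length(y), length(z)))
    rz3 <- aperm(array(rz, dim = c(length(z), length(x), length(y))), c(2, 3, 1))
    pmax(r3, rz3)
  } else {
    stop(sprintf("unknown primitive shape '%s'", shape), call. = FALSE)
  }
}

# Analytic bounding box of a primitive, in mm
primitive_extent <- function(shape, center, size) {
  rbind(center - size, center + size)
}

#' Build a voxel phantom
#'
#' Rasterises every structure of a [load_phantom_spec()] specification onto
#' the common grid and validates the geometry: the three PTVs must be
#' strictly nested (PTV1 inside PTV2 inside PTV3), all ten OARs must be
#' present, every structure must have positive volume and lie inside the
#' grid. The result also carries pre-computed painting helpers (per-region
#' voxel orderings and the background falloff field) so that a cohort of
#' dose distributions can be painted on one phantom cheaply.
#'
#' @param spec a `phantom_spec`.
#' @return An object of class `hn_phantom`: named list of
#'   [structure_mask()]s (`$masks`), grid metadata, and painting helpers.
#' @export
build_phantom <- function(spec = load_phantom_spec()) {
  gs <- spec$grid_shape
  sp <- spec$spacing_mm
  grid_mm <- gs * sp
  st <- spec$structures
  if (is.data.frame(st)) st <- split(st, seq_len(nrow(st)))

  masks <- list()
  radius <- list()
  for (s in st) {
    name <- as.character(s$name)
    center <- as.numeric(unlist(s$center_mm))
    size <- as.numeric(unlist(s$size_mm))
    ext <- primitive_extent(s$shape, center, size)
    if (any(ext[1, ] < 0) || any(ext[2, ] > grid_mm))
      stop(sprintf("structure '%s' extends beyond grid bounds", name),
           call. = FALSE)
    r <- primitive_radius(as.character(s$shape), center, size, gs, sp)
    vox <- r <= 1
    if (!any(vox))
      stop(sprintf("structure '%s' has zero volume on this grid", name),
           call. = FALSE)
    masks[[name]] <- structure_mask(name, vox, sp)
    radius[[name]] <- r
  }

  for (p in c("ptv1", "ptv2", "ptv3"))
    if (is.null(masks[[p]]))
      stop(sprintf("phantom must define structure '%s'", p), call. = FALSE)
  missing_oars <- setdiff(oar_names(), names(masks))
  if (length(missing_oars))
    stop("phantom missing OARs: ", paste(missing_oars, collapse = ", "),
         call. = FALSE)

  check_nested <- function(inner, outer) {
    vi <- masks[[inner]]$voxels; vo <- masks[[outer]]$voxels
    if (any(vi & !vo) || sum(vo) <= sum(vi))
      stop(sprintf("PTV nesting violated: '%s' is not a strict subset of '%s'",
                   inner, outer), call. = FALSE)
  }
  check_nested("ptv1", "ptv2")
  check_nested("ptv2", "ptv3")

  # disjoint painting regions; rank order = hotter towards structure centre
  region_order <- function(idx, r) idx[order(r[idx])]
  v1 <- which(masks$ptv1$voxels)
  v2 <- which(masks$ptv2$voxels & !masks$ptv1$voxels)
  v3 <- which(masks$ptv3$voxels & !masks$ptv2$voxels)
  regions <- list(
    ptv1 = region_order(v1, radius[["ptv1"]]),
    ptv2_ring = region_order(v2, radius[["ptv2"]]),
    ptv3_ring = region_order(v3, radius[["ptv3"]])
  )
  for (o in oar_names())
    regions[[o]] <- region_order(which(masks[[o]]$voxels), radius[[o]])

  any_structure <- masks$ptv3$voxels
  for (o in oar_names()) any_structure <- any_structure | masks[[o]]$voxels
  bg_idx <- which(!any_structure)
  bg_r <- radius[["ptv3"]][bg_idx]

  structure(
    list(masks = masks, grid_shape = gs, spacing_mm = sp,
         regions = regions,
         frac_ptv1_in_ptv2 = sum(masks$ptv1$voxels) / sum(masks$ptv2$voxels),
         frac_ptv2_in_ptv3 = sum(masks$ptv2$voxels) / sum(masks$ptv3$voxels),
         background_idx = bg_idx, background_radius = bg_r,
         spec = spec),
    class = "hn_phantom"
  )
}

#' @export
print.hn_phantom <- function(x, ...) {
  cat(sprintf("<hn_phantom> %s grid @ %s mm, %d structures\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$spacing_mm, collapse = "x"), length(x$masks)))
  vols <- vapply(x$masks, structure_volume_cc, numeric(1))
  for (n in names(vols)) cat(sprintf("  %-16s %8.2f cc\n", n, vols[n]))
  invisible(x)
}

#' Structure volumes of a phantom
#' @param phantom an `hn_phantom`.
#' @return Named numeric vector of volumes in cc.
#' @export
phantom_volumes_cc <- function(phantom) {
  vapply(phantom$masks, structure_volume_cc, numeric(1))
}
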