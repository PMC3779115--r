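#' Voxel geometries for tissue simulation
#'
#' An `atrial_geometry` is a voxel grid (1D cable or ring, 2D sheet, 3D
#' block) with spacing `dx` (mm), a tissue mask `inside`, a per-voxel
#' region label, optional per-voxel fibre unit vectors, and the diffusion
#' coefficients `d_iso` (isotropic tissue) and `d_long`/`d_trans`
#' (fibre-bundle tissue, default anisotropy ratio 9:1), all in mm^2/ms.
#' The constructors below are pure functions of their arguments.
#'
#' @name atrial_geometry
NULL

.new_geometry <- function(dims, dx, inside, region, fibre = NULL,
                          d_iso = NULL, d_long = NULL, d_trans = NULL,
                          periodic = FALSE, blend = NULL, blend_regions = NULL) {
  if (is.null(d_iso)) d_iso <- .calibrated$d_iso
  if (is.null(d_long)) d_long <- .calibrated$d_long
  if (is.null(d_trans)) d_trans <- d_long / 9
  stopifnot(dx > 0, length(inside) == prod(dims),
            length(region) == prod(dims))
  if (!is.null(fibre)) {
    stopifnot(is.matrix(fibre), nrow(fibre) == prod(dims), ncol(fibre) == 3)
    nrm <- sqrt(rowSums(fibre^2))
    has <- nrm > 0
    if (any(abs(nrm[has] - 1) > 1e-8))
      stop("fibre vectors must be unit-norm where present")
  }
  structure(list(dims = as.integer(dims), dx = dx, inside = inside,
                 region = region, fibre = fibre,
                 d_iso = d_iso, d_long = d_long, d_trans = d_trans,
                 periodic = periodic, blend = blend,
                 blend_regions = blend_regions),
            class = "atrial_geometry")
}

#' @export
print.atrial_geometry <- function(x, ...) {
  cat("<atrial_geometry> ", paste(x$dims, collapse = " x "),
      " voxels @ ", x$dx, " mm (", sum(x$inside), " tissue)\n", sep = "")
  cat("  regions: ", paste(unique(x$region[x$inside]), collapse = ", "),
      if (x$periodic) "  [periodic]", "\n", sep = "")
  invisible(x)
}

#' Number of tissue nodes
#' @param geom an `atrial_geometry`.
#' @return Integer count of voxels inside the tissue mask.
#' @export
n_nodes <- function(geom) sum(geom$inside)

# voxel-centre coordinates (mm) of the tissue nodes, n x 3
node_coords <- function(geom) {
  dims <- geom$dims
  nd <- length(dims)
  idx <- which(geom$inside)
  ij <- arrayInd(idx, .dim = dims)
  xyz <- matrix(0, length(idx), 3)
  xyz[, seq_len(nd)] <- (ij - 1) * geom$dx
  xyz
}

#' Make a 1D cable geometry
#'
#' @param n_nodes number of nodes (cable length = `n_nodes * dx`).
#' @param dx spacing (mm, default 0.33).
#' @param region_layout named list mapping region ids to index ranges,
#'   e.g. `list(RA = 1:100, CT = 101:200)`; default: all RA.
#' @param ... diffusion-coefficient overrides (`d_iso`, `d_long`,
#'   `d_trans`).
#' @return An `atrial_geometry`.
#' @export
make_cable <- function(n_nodes, dx = 0.33, region_layout = NULL, ...) {
  region <- rep("RA", n_nodes)
  if (!is.null(region_layout)) {
    covered <- sort(unname(unlist(region_layout)))
    if (!identical(as.integer(covered), seq_len(n_nodes)))
      stop("region_layout must cover every node exactly once")
    for (rg in names(region_layout)) region[region_layout[[rg]]] <- rg
  }
  .new_geometry(dims = n_nodes, dx = dx, inside = rep(TRUE, n_nodes),
                region = region, ...)
}

#' Make a 1D ring (periodic cable)
#'
#' A periodic 1D domain for measuring re-entry cycle length and wavelength;
#' supports unidirectional initiation via a transient conduction-block
#' segment (see [run_simulation()]'s `clamp` argument).
#'
#' @param circumference_nodes number of nodes around the ring.
#' @param dx spacing (mm).
#' @param region region id for the whole ring.
#' @param ... diffusion-coefficient overrides.
#' @return An `atrial_geometry` with `periodic = TRUE`.
#' @export
make_ring <- function(circumference_nodes, dx = 0.33, region = "RA", ...) {
  .new_geometry(dims = circumference_nodes, dx = dx,
                inside = rep(TRUE, circumference_nodes),
                region = rep(region, circumference_nodes),
                periodic = TRUE, ...)
}

#' Make a two-region junction sheet
#'
#' A 2D sheet split by a straight vertical interface into two regions (the
#' desk-scale surrogate for the CT/PM and LA/PV junction experiments),
#' optionally with a horizontal bundle strip carrying fibre vectors along
#' its axis (anisotropy 9:1).
#'
#' @param nx,ny grid size (default 91 x 91: a 30 x 30 mm sheet at 0.33 mm).
#' @param dx spacing (mm).
#' @param region_a region id left of the interface.
#' @param region_b region id right of the interface.
#' @param interface column index of the first `region_b` column
#'   (default: midline).
#' @param bundle_strip optional list(`region`, `rows`): rows of the sheet
#'   replaced by a fibre bundle with fibres along x.
#' @param ... diffusion-coefficient overrides.
#' @return An `atrial_geometry`.
#' @export
make_junction_sheet <- function(nx = 91, ny = 91, dx = 0.33,
                                region_a = "PM", region_b = "CT",
                                interface = NULL, bundle_strip = NULL, ...) {
  if (is.null(interface)) interface <- floor(nx / 2) + 1
  stopifnot(interface > 1, interface <= nx)
  region <- matrix(region_a, nx, ny)
  region[interface:nx, ] <- region_b
  fibre <- NULL
  if (!is.null(bundle_strip)) {
    rows <- bundle_strip$rows
    if (any(rows < 1 | rows > ny)) stop("bundle strip outside sheet")
    region[, rows] <- bundle_strip$region
    fibre <- matrix(0, nx * ny, 3)
    m <- matrix(FALSE, nx, ny); m[, rows] <- TRUE
    fibre[as.vector(m), 1] <- 1
  }
  .new_geometry(dims = c(nx, ny), dx = dx, inside = rep(TRUE, nx * ny),
                region = as.vector(region), fibre = fibre, ...)
}

#' Stimulus-site mask at the junction interface
#'
#' Returns the tissue-node indices of a disc of radius `radius_mm`
#' (default 3.3 mm, the standard stimulus-electrode size) centred on the
#' given point, by default the centre of the sheet's region interface.
#'
#' @param geom an `atrial_geometry`.
#' @param centre_mm centre of the disc (mm, length = dimensionality);
#'   default: centre of the domain.
#' @param radius_mm disc radius (mm, default 3.3).
#' @return Integer vector of tissue-node indices.
#' @export
stim_disc <- function(geom, centre_mm = NULL, radius_mm = 3.3) {
  stopifnot(radius_mm > 0)
  xyz <- node_coords(geom)
  nd <- length(geom$dims)
  if (is.null(centre_mm)) centre_mm <- (geom$dims - 1) * geom$dx / 2
  ctr <- c(centre_mm, 0, 0)[1:3]
  d2 <- rowSums((xyz - matrix(ctr, nrow(xyz), 3, byrow = TRUE))^2)
  which(d2 <= radius_mm^2)
}

#' Graded parameter blending across a junction
#'
#' Replaces the stepwise change in cellular properties at a two-region
#' interface by a linear per-voxel blend of the two regions'
#' channel parameters over `width_mm`. With `width_mm = 0` the geometry is
#' returned unchanged (stepwise junction).
#'
#' @param geom a junction sheet made by [make_junction_sheet()].
#' @param width_mm blend-zone width (mm), centred on the interface.
#' @return The geometry with per-voxel blend weights attached; the tissue
#'   layer builds blended parameter sets from them.
#' @export
graded_junction <- function(geom, width_mm) {
  stopifnot(inherits(geom, "atrial_geometry"), width_mm >= 0)
  regs <- unique(geom$region[geom$inside])
  if (length(regs) != 2)
    stop("graded_junction requires a two-region geometry")
  if (width_mm == 0) return(geom)
  xyz <- node_coords(geom)
  xa <- xyz[geom$region[geom$inside] == regs[1], 1]
  xb <- xyz[geom$region[geom$inside] == regs[2], 1]
  x_if <- (max(xa) + min(xb)) / 2       # interface plane
  w <- (xyz[, 1] - x_if) / width_mm + 0.5
  w <- pmin(1, pmax(0, w))
  geom$blend <- w
  geom$blend_regions <- regs
  geom
}
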