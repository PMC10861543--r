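# Synthetic test objects: PVP vial series, short-axis cardiac annulus with
# transmural fiber helix and injury regions, and seeded subject cohorts.
#
# Every phantom carries its ground truth: a region table with the true mean
# diffusivity of each labelled region, a per-voxel tensor field (mm^2/s,
# upper-triangle order Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), and an S0 map. The
# simulator reads the tensor field; reconstruction accuracy is always judged
# against the region table.

D_UNIT_GUARD <- 0.05  # mm^2/s; free water is ~3e-3, so anything larger is a unit slip

check_diffusivity <- function(d) {
  if (any(d <= 0))
    stop("diffusivities must be positive (mm^2/s)")
  if (any(d > D_UNIT_GUARD))
    stop("diffusivity > 0.05 mm^2/s: values are expected in mm^2/s ",
         "(e.g. 1.578e-3), not 1e-3 mm^2/s units")
  invisible(d)
}

#' Construct a phantom specification
#'
#' Low-level constructor; most users want [make_pvp_phantom()] or
#' [make_cardiac_phantom()].
#'
#' @param region_map Integer label array (3-D); 0 is background.
#' @param region_table Data frame with columns `label`, `name`, `md`
#'   (ground-truth mean diffusivity, mm^2/s) and `s0`.
#' @param tensor_field 4-D array `dim(region_map) x 6` of tensor components
#'   (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) in mm^2/s.
#' @param voxel_size Voxel edge lengths (mm), length 3.
#' @param s0_map Array of S0 values; defaults to the region table lookup.
#' @param motion A [motion_state()] describing bulk motion of the phantom.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(region_map, region_table, tensor_field, voxel_size,
                         s0_map = NULL, motion = motion_state()) {
  region_map <- as.array(region_map)
  if (length(dim(region_map)) == 2) dim(region_map) <- c(dim(region_map), 1L)
  labs <- sort(unique(as.vector(region_map)))
  labs <- labs[labs > 0]
  if (!all(labs %in% region_table$label))
    stop("every nonzero label in region_map must appear in region_table")
  check_diffusivity(region_table$md)
  if (is.null(s0_map)) {
    s0_map <- array(0, dim(region_map))
    for (i in seq_len(nrow(region_table)))
      s0_map[region_map == region_table$label[i]] <- region_table$s0[i]
  }
  structure(list(region_map = region_map, region_table = region_table,
                 tensor_field = tensor_field, s0_map = s0_map,
                 voxel_size = as.numeric(voxel_size), motion = motion),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  d <- dim(x$region_map)
  cat(sprintf("<phantom_spec> %d x %d x %d grid, voxel %s mm\n", d[1], d[2], d[3],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  tb <- x$region_table
  for (i in seq_len(nrow(tb)))
    cat(sprintf("  [%d] %-18s MD = %.3f e-3 mm^2/s, %d voxels\n",
                tb$label[i], tb$name[i], tb$md[i] * 1e3,
                sum(x$region_map == tb$label[i])))
  invisible(x)
}

# fill an isotropic tensor field from a region table
isotropic_field <- function(region_map, region_table) {
  dims <- dim(region_map)
  tf <- array(0, c(dims, 6))
  for (i in seq_len(nrow(region_table))) {
    sel <- region_map == region_table$label[i]
    for (c_ in 1:3) {
      comp <- array(tf[, , , c_], dims)
      comp[sel] <- region_table$md[i]
      tf[, , , c_] <- comp
    }
  }
  tf
}

#' Six-vial PVP diffusion phantom
#'
#' A single-slice phantom with six disjoint circular vials whose isotropic
#' diffusivities are supplied by the caller, emulating a dilution series of
#' polyvinylpyrrolidone (PVP) in water: higher polymer concentration, lower
#' diffusivity. Vials are arranged in a 3 x 2 layout; background is label 0,
#' vials are labels 1..6 in the order given.
#'
#' @param diffusivities Six positive diffusivities (mm^2/s), e.g. a series
#'   spanning 1.3e-3 to 2.2e-3 covering 0-50% w/v PVP at room temperature.
#' @param s0 Baseline signal for every vial.
#' @param grid Grid size (nx, ny); a single slice is generated.
#' @param voxel_size Voxel edge lengths (mm), length 3.
#' @param vial_radius Vial radius (mm).
#' @return A [phantom_spec()] with static motion.
#' @export
make_pvp_phantom <- function(diffusivities, s0 = 100,
                             grid = c(64, 32), voxel_size = c(0.39, 0.39, 2),
                             vial_radius = 1.5) {
  if (length(diffusivities) != 6)
    stop("exactly six vial diffusivities are required")
  check_diffusivity(diffusivities)
  nx <- grid[1]; ny <- grid[2]
  fov <- c(nx, ny) * voxel_size[1:2]
  cx <- fov[1] * c(0.25, 0.50, 0.75)
  cy <- fov[2] * c(1 / 3, 2 / 3)
  centers <- cbind(rep(cx, times = 2), rep(cy, each = 3))
  x <- (seq_len(nx) - 0.5) * voxel_size[1]
  y <- (seq_len(ny) - 0.5) * voxel_size[2]
  xg <- matrix(x, nx, ny)
  yg <- matrix(y, nx, ny, byrow = TRUE)
  region <- matrix(0L, nx, ny)
  for (k in 1:6) {
    inside <- (xg - centers[k, 1])^2 + (yg - centers[k, 2])^2 <= vial_radius^2
    region[inside] <- k
  }
  region <- array(region, c(nx, ny, 1L))
  tb <- data.frame(label = 1:6,
                   name = paste0("vial", 1:6),
                   md = as.numeric(diffusivities),
                   s0 = s0)
  phantom_spec(region, tb, isotropic_field(region, tb), voxel_size)
}

#' Short-axis cardiac annulus geometry
#'
#' @param center Annulus center (mm), length 2; `NULL` centers on the grid.
#' @param r_endo Endocardial radius (mm).
#' @param r_epi Epicardial radius (mm).
#' @param injury Injury pattern: `"none"`, `"subendocardial_ring"` (inner
#'   third of the wall) or `"sector"` (transmural wedge).
#' @param sector_angle Angular width of the sector injury (degrees).
#' @param sector_start Starting angle of the sector (degrees).
#' @param ring_fraction Transmural thickness fraction of the ring injury.
#' @param helix_range Fiber helix angle at endo- and epicardium (degrees).
#' @return An object of class `cardiac_geometry`.
#' @export
cardiac_geometry <- function(center = NULL, r_endo = 2.2, r_epi = 4.2,
                             injury = c("none", "subendocardial_ring", "sector"),
                             sector_angle = 90, sector_start = 0,
                             ring_fraction = 1 / 3,
                             helix_range = c(60, -60)) {
  injury <- match.arg(injury)
  stopifnot(r_endo > 0, r_epi > r_endo, length(helix_range) == 2)
  structure(list(center = center, r_endo = r_endo, r_epi = r_epi,
                 injury = injury, sector_angle = sector_angle,
                 sector_start = sector_start, ring_fraction = ring_fraction,
                 helix_range = helix_range),
            class = "cardiac_geometry")
}

#' Short-axis cardiac phantom with fiber helix and optional injury
#'
#' An annular left-ventricular myocardium on a single short-axis slice. Each
#' myocardial voxel gets an axially symmetric tensor whose primary
#' eigenvector follows the local circumferential direction tilted
#' through-plane by the transmural helix angle (linear from
#' `geom$helix_range[1]` at the endocardium to `helix_range[2]` at the
#' epicardium). Eigenvalues satisfy trace/3 = target MD exactly and
#' lambda1/lambda3 = `anisotropy`. The blood cavity is labelled separately
#' with free-water-like isotropic diffusivity.
#'
#' Labels: 0 background, 1 cavity, 2 (remote) myocardium, 3 injury.
#'
#' @param geom A [cardiac_geometry()].
#' @param myo_md Myocardial mean diffusivity (mm^2/s).
#' @param injury_md Mean diffusivity of the injury region (mm^2/s); ignored
#'   when `geom$injury == "none"`.
#' @param anisotropy Ratio lambda1 / lambda3 (>= 1); 1 gives isotropic
#'   tensors (FA = 0).
#' @param motion A [motion_state()]; default models end-systolic residual
#'   bulk motion with 10 mm/s intravoxel velocity spread.
#' @param s0 Baseline myocardial signal.
#' @param cavity_md Diffusivity of the blood pool (mm^2/s).
#' @param grid Grid size (nx, ny).
#' @param voxel_size Voxel edge lengths (mm).
#' @return A [phantom_spec()]; the helix-angle map (degrees, NA outside the
#'   myocardium) is attached as attribute `"helix_angle"`.
#' @export
make_cardiac_phantom <- function(geom = cardiac_geometry(),
                                 myo_md = 1.578e-3, injury_md = 1.847e-3,
                                 anisotropy = 2,
                                 motion = motion_state(v = c(0.02, 0, 0),
                                                       a = c(2, 0, 0),
                                                       v_spread = 0.01),
                                 s0 = 100, cavity_md = 3.0e-3,
                                 grid = c(64, 32),
                                 voxel_size = c(0.39, 0.39, 2)) {
  stopifnot(inherits(geom, "cardiac_geometry"), anisotropy >= 1)
  check_diffusivity(c(myo_md, cavity_md,
                      if (geom$injury != "none") injury_md))
  nx <- grid[1]; ny <- grid[2]
  fov <- c(nx, ny) * voxel_size[1:2]
  ctr <- if (is.null(geom$center)) fov / 2 else geom$center
  x <- (seq_len(nx) - 0.5) * voxel_size[1]
  y <- (seq_len(ny) - 0.5) * voxel_size[2]
  xg <- matrix(x, nx, ny) - ctr[1]
  yg <- matrix(y, nx, ny, byrow = TRUE) - ctr[2]
  r <- sqrt(xg^2 + yg^2)
  theta <- atan2(yg, xg)
  myo <- r >= geom$r_endo & r <= geom$r_epi
  cavity <- r < geom$r_endo
  if (!any(myo)) stop("degenerate geometry: no myocardial voxels on the grid")

  injury <- matrix(FALSE, nx, ny)
  if (geom$injury == "subendocardial_ring") {
    r_inj <- geom$r_endo + geom$ring_fraction * (geom$r_epi - geom$r_endo)
    injury <- myo & r <= r_inj
  } else if (geom$injury == "sector") {
    a0 <- geom$sector_start * pi / 180
    width <- geom$sector_angle * pi / 180
    rel <- (theta - a0) %% (2 * pi)
    injury <- myo & rel <= width
  }
  region <- matrix(0L, nx, ny)
  region[cavity] <- 1L
  region[myo] <- 2L
  region[injury] <- 3L

  # transmural helix angle, linear endo -> epi
  frac <- pmin(pmax((r - geom$r_endo) / (geom$r_epi - geom$r_endo), 0), 1)
  ha <- geom$helix_range[1] + frac * (geom$helix_range[2] - geom$helix_range[1])
  ha_rad <- ha * pi / 180

  # primary eigenvector: circumferential tilted through-plane by helix angle
  e1x <- -sin(theta) * cos(ha_rad)
  e1y <-  cos(theta) * cos(ha_rad)
  e1z <-  sin(ha_rad)

  md_map <- matrix(0, nx, ny)
  md_map[cavity] <- cavity_md
  md_map[myo] <- myo_md
  md_map[injury] <- injury_md
  # axially symmetric tensor D = lt I + (rho - 1) lt e1 e1', trace = 3 MD
  lt <- 3 * md_map / (anisotropy + 2)
  excess <- (anisotropy - 1) * lt
  excess[cavity] <- 0          # blood pool isotropic
  lt[cavity] <- cavity_md

  dims <- c(nx, ny, 1L)
  tf <- array(0, c(dims, 6))
  tf[, , 1, 1] <- lt + excess * e1x^2
  tf[, , 1, 2] <- lt + excess * e1y^2
  tf[, , 1, 3] <- lt + excess * e1z^2
  tf[, , 1, 4] <- excess * e1x * e1y
  tf[, , 1, 5] <- excess * e1x * e1z
  tf[, , 1, 6] <- excess * e1y * e1z

  labs <- c(1L, 2L, if (any(injury)) 3L)
  tb <- data.frame(label = labs,
                   name = c("cavity", "myocardium",
                            if (any(injury)) "injury"),
                   md = c(cavity_md, myo_md, if (any(injury)) injury_md),
                   s0 = s0)
  ph <- phantom_spec(array(region, dims), tb, tf, voxel_size, motion = motion)
  ha[!myo] <- NA
  attr(ph, "helix_angle") <- array(ha, dims)
  ph
}

#' Cohort specification
#'
#' @param n Number of subjects.
#' @param mean_md Population mean myocardial MD (mm^2/s).
#' @param sd_md Between-subject SD of MD (mm^2/s).
#' @param injury_offset Added to the subject MD inside the injury region
#'   (mm^2/s); 0 disables the injury region.
#' @param seed RNG seed for the subject draws.
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(n, mean_md, sd_md, injury_offset = 0, seed = 1) {
  stopifnot(n >= 1, sd_md >= 0)
  structure(list(n = as.integer(n), mean_md = mean_md, sd_md = sd_md,
                 injury_offset = injury_offset, seed = as.integer(seed)),
            class = "group_spec")
}

#' Sample a cohort of cardiac phantoms
#'
#' Draws each subject's myocardial MD from Normal(`mean_md`, `sd_md`),
#' truncated below at 0.5e-3 mm^2/s (values below are redrawn), and builds a
#' cardiac phantom per subject. Reproducible for a given `spec$seed`.
#'
#' @param spec A [group_spec()].
#' @param geom A [cardiac_geometry()] shared by the cohort.
#' @param ... Further arguments passed to [make_cardiac_phantom()].
#' @return A list of [phantom_spec()] objects; the drawn subject MDs are
#'   attached as attribute `"subject_md"`.
#' @export
sample_group <- function(spec, geom = cardiac_geometry(), ...) {
  stopifnot(inherits(spec, "group_spec"))
  mds <- withr_seed(spec$seed, {
    draw <- function(n) stats::rnorm(n, spec$mean_md, spec$sd_md)
    v <- draw(spec$n)
    while (any(bad <- v < 0.5e-3)) v[bad] <- draw(sum(bad))
    v
  })
  if (spec$injury_offset != 0 && geom$injury == "none")
    geom$injury <- "subendocardial_ring"
  phantoms <- lapply(mds, function(md) {
    if (spec$injury_offset != 0)
      make_cardiac_phantom(geom, myo_md = md,
                           injury_md = md + spec$injury_offset, ...)
    else {
      g <- geom; g$injury <- "none"
      make_cardiac_phantom(g, myo_md = md, ...)
    }
  })
  attr(phantoms, "subject_md") <- mds
  phantoms
}
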