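#' Parameters for the synthetic trabecular-meshwork stack generator
#'
#' The generator emulates the phenomenology of two-photon stacks of the
#' corneoscleral meshwork: an orthogonal lattice of autofluorescent beams
#' (tubes) with intervening pores, Hoechst-like ellipsoidal nuclei mixed
#' into the green channel, cortical F-actin shells wrapped around beams in
#' the control condition, and — in the treated (actin-depolymerised)
#' condition — globally reduced F-actin partly relocated into punctate
#' perinuclear aggregates, with beams eroded so pores enlarge. Photon noise
#' is a scaled-Poisson model plus Gaussian read noise.
#'
#' @param nz,ny,nx Stack dimensions in voxels (z, y, x).
#' @param cal A [calibration()].
#' @param beam_radius_um Beam (tube) radius.
#' @param beam_spacing_um Centre-to-centre beam spacing; the in-plane pore
#'   gap is `beam_spacing_um - 2 * beam_radius_um` (kept below 40 um, the
#'   conventional upper bound for corneoscleral pores).
#' @param beam_z_um Physical z positions of the beam layers.
#' @param af_beam_intensity Autofluorescence intensity of beam voxels.
#' @param n_nuclei Number of nuclei to place.
#' @param nucleus_semiaxes_um Ellipsoid semi-axes (x, y, z) of a nucleus.
#' @param nucleus_intensity Green intensity of nucleus voxels.
#' @param actin_shell_thickness_um Cortical actin shell thickness.
#' @param actin_base_intensity Red intensity of the control cortical shell.
#' @param actin_effect Multiplicative factor in (0, 1] applied to the total
#'   treated F-actin signal (1 = null treatment).
#' @param aggregate_fraction Fraction of the surviving treated actin signal
#'   relocated into punctate perinuclear aggregates; the applied fraction is
#'   scaled by the disruption severity, `aggregate_fraction * (1 -
#'   actin_effect)`, so a null treatment renders a scene identical to the
#'   control.
#' @param aggregate_radius_um Radius of one punctate aggregate.
#' @param aggregate_intensity Target red intensity of aggregate voxels (the
#'   realised value is set exactly so that treated/control total signal
#'   equals `actin_effect`).
#' @param pore_dilation_um Extra beam erosion in the treated condition
#'   (enlarges pores).
#' @param background Constant background offset added to every scene voxel.
#' @param photon_gain Scaled-Poisson gain g: photon noise variance at scene
#'   level S is `g * S`.
#' @param read_noise_sd Additive Gaussian read noise SD.
#' @param noise Logical; apply the noise model.
#' @param seed Integer seed; identical parameters and seed give
#'   bit-identical stacks.
#' @return An object of class `"synth_params"`.
#' @export
synth_params <- function(nz = 38L, ny = 256L, nx = 256L,
                         cal = calibration(),
                         beam_radius_um = 6, beam_spacing_um = 30,
                         beam_z_um = 19,
                         af_beam_intensity = 4000,
                         n_nuclei = 12L,
                         nucleus_semiaxes_um = c(4.5, 3.5, 5.2),
                         nucleus_intensity = 20000,
                         actin_shell_thickness_um = 1.5,
                         actin_base_intensity = 30000,
                         actin_effect = 0.5,
                         aggregate_fraction = 0.6,
                         aggregate_radius_um = 1.5,
                         aggregate_intensity = 25000,
                         pore_dilation_um = 1.5,
                         background = 20,
                         photon_gain = 300,
                         read_noise_sd = 200,
                         noise = TRUE,
                         seed = 1L) {
  stopifnot(nz >= 1, ny >= 1, nx >= 1,
            beam_radius_um > 0, beam_spacing_um > 2 * beam_radius_um,
            actin_shell_thickness_um > 0, actin_base_intensity > 0,
            actin_effect > 0, actin_effect <= 1,
            aggregate_fraction >= 0, aggregate_fraction <= 1,
            aggregate_radius_um > 0, pore_dilation_um >= 0,
            pore_dilation_um < beam_radius_um,
            background >= 0, photon_gain > 0, read_noise_sd >= 0,
            length(nucleus_semiaxes_um) == 3)
  structure(as.list(environment()), class = "synth_params")
}

# voxel-centre coordinate vectors (physical um) for 0-based grid
.axis_centres <- function(n, step) (seq_len(n) - 0.5) * step

# boolean (na, nz) mask of tubes running perpendicular to axis `a`,
# at in-plane positions pos_a (um) crossed with layers z_um, radius r
.tube_section_mask <- function(ac, zc, pos_a, z_um, r) {
  m <- matrix(FALSE, length(ac), length(zc))
  for (a0 in pos_a) for (z0 in z_um) {
    d2 <- outer((ac - a0)^2, (zc - z0)^2, "+")
    m <- m | (d2 <= r^2)
  }
  m
}

# distance from points (a, z) to the nearest tube axis in one direction
.tube_dist <- function(a, z, pos_a, z_um) {
  d <- Inf
  for (a0 in pos_a) for (z0 in z_um)
    d <- pmin(d, sqrt((a - a0)^2 + (z - z0)^2))
  d
}

# expand (ny, nz) and (nx, nz) section masks into a (nz, ny, nx) OR-mask
.expand_lattice <- function(yz, xz, nz, ny, nx) {
  a1 <- aperm(array(yz, dim = c(ny, nz, nx)), c(2, 1, 3))
  a2 <- aperm(array(xz, dim = c(nx, nz, ny)), c(2, 3, 1))
  a1 | a2
}

# linear indices of ellipsoid voxels (voxel-centre inclusion test)
.ellipsoid_indices <- function(dims, cal, centre_um, semi_um) {
  zc <- .axis_centres(dims[1], cal$dz)
  yc <- .axis_centres(dims[2], cal$dy)
  xc <- .axis_centres(dims[3], cal$dx)
  zi <- which(abs(zc - centre_um[3]) <= semi_um[3])
  yi <- which(abs(yc - centre_um[2]) <= semi_um[2])
  xi <- which(abs(xc - centre_um[1]) <= semi_um[1])
  if (!length(zi) || !length(yi) || !length(xi)) return(integer(0))
  g <- expand.grid(z = zi, y = yi, x = xi)
  u <- ((zc[g$z] - centre_um[3]) / semi_um[3])^2 +
       ((yc[g$y] - centre_um[2]) / semi_um[2])^2 +
       ((xc[g$x] - centre_um[1]) / semi_um[1])^2
  keep <- u <= 1
  (g$z + (g$y - 1) * dims[1] + (g$x - 1) * dims[1] * dims[2])[keep]
}

# dart-throwing placement of nuclei clear of beams, the frame border and
# one another (centre separation > 2 x nuclear z-extent)
.place_nuclei <- function(p, beam_pos_y, beam_pos_x, clearance) {
  sa <- p$nucleus_semiaxes_um
  Lx <- p$nx * p$cal$dx; Ly <- p$ny * p$cal$dy; Lz <- p$nz * p$cal$dz
  min_sep <- 2 * (2 * sa[3]) + 0.1
  margin <- 0.5
  lo <- sa + margin; hi <- c(Lx, Ly, Lz) - sa - margin
  if (any(hi <= lo)) stop("nuclei do not fit in the frame")
  centres <- matrix(NA_real_, 0, 3)
  attempts <- 0L
  while (nrow(centres) < p$n_nuclei) {
    attempts <- attempts + 1L
    if (attempts > 2000L * p$n_nuclei)
      stop("could not place ", p$n_nuclei,
           " nuclei with the required separation; scene too crowded")
    cand <- stats::runif(3, lo, hi)  # (x, y, z) um
    dbeam <- min(.tube_dist(cand[2], cand[3], beam_pos_y, p$beam_z_um),
                 .tube_dist(cand[1], cand[3], beam_pos_x, p$beam_z_um))
    if (dbeam < clearance + max(sa)) next
    if (nrow(centres) &&
        min(sqrt(rowSums(sweep(centres, 2, cand)^2))) <= min_sep) next
    centres <- rbind(centres, cand)
  }
  centres
}

.apply_noise <- function(scene, p, noise_seed) {
  if (!p$noise) return(round(scene))
  set.seed(noise_seed %% .Machine$integer.max)
  n <- length(scene)
  g <- p$photon_gain
  obs <- g * stats::rpois(n, as.vector(scene) / g) +
    stats::rnorm(n, 0, p$read_noise_sd)
  out <- round(pmin(pmax(obs, 0), p$cal$max_intensity))
  array(out, dim = dim(scene))
}

#' Generate a paired control / treated synthetic tissue stack set
#'
#' Renders two two-channel stacks sharing one tissue geometry (beam lattice
#' and nuclei): a vehicle-control condition with cortical actin shells on
#' the beams, and a treated condition in which the total F-actin signal is
#' scaled by `actin_effect`, part of the surviving signal is relocated into
#' punctate perinuclear aggregates, and beams are eroded by
#' `pore_dilation_um` so pores enlarge. Noise fields for corresponding
#' channels are drawn from per-channel streams shared across conditions, so
#' a null treatment (`actin_effect = 1`, `pore_dilation_um = 0`) yields
#' bit-identical control and treated stacks.
#'
#' @param params A [synth_params()].
#' @return A list with elements `control` and `treated`, each a list of
#'   `green` and `red` [channel_stack()]s plus `truth` (ground truth: nuclei
#'   table, logical `actin_mask` and `beam_mask`, pore gap, analytic beam
#'   volume, programmed effect sizes), and `params`.
#' @export
generate_tissue_pair <- function(params) {
  p <- params
  stopifnot(inherits(p, "synth_params"))
  set.seed(p$seed)
  cal <- p$cal
  dims <- c(p$nz, p$ny, p$nx)
  zc <- .axis_centres(p$nz, cal$dz)
  yc <- .axis_centres(p$ny, cal$dy)
  xc <- .axis_centres(p$nx, cal$dx)
  Ly <- p$ny * cal$dy; Lx <- p$nx * cal$dx

  s <- p$beam_spacing_um
  beam_pos_y <- seq(s / 2, Ly - 1e-9, by = s)
  beam_pos_x <- seq(s / 2, Lx - 1e-9, by = s)
  if (!length(beam_pos_y) || !length(beam_pos_x))
    stop("beam lattice does not fit in the frame")

  t <- p$actin_shell_thickness_um
  masks_for_radius <- function(r) {
    beam <- .expand_lattice(
      .tube_section_mask(yc, zc, beam_pos_y, p$beam_z_um, r),
      .tube_section_mask(xc, zc, beam_pos_x, p$beam_z_um, r),
      p$nz, p$ny, p$nx)
    shell <- .expand_lattice(
      .tube_section_mask(yc, zc, beam_pos_y, p$beam_z_um, r + t),
      .tube_section_mask(xc, zc, beam_pos_x, p$beam_z_um, r + t),
      p$nz, p$ny, p$nx) & !beam
    list(beam = beam, shell = shell)
  }
  ctrl <- masks_for_radius(p$beam_radius_um)
  r_treated <- p$beam_radius_um - p$pore_dilation_um
  trt <- if (p$pore_dilation_um > 0) masks_for_radius(r_treated) else ctrl

  clearance <- p$beam_radius_um + t + 2
  centres <- .place_nuclei(p, beam_pos_y, beam_pos_x, clearance)
  sa <- p$nucleus_semiaxes_um
  nuc_idx <- lapply(seq_len(nrow(centres)), function(i)
    .ellipsoid_indices(dims, cal, centres[i, ], sa))

  nuclei_tab <- if (nrow(centres) == 0) data.frame(
    x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
    x = integer(0), y = integer(0), z = integer(0),
    sx_um = numeric(0), sy_um = numeric(0), sz_um = numeric(0))
  else data.frame(
    x_um = centres[, 1], y_um = centres[, 2], z_um = centres[, 3],
    x = physical_to_index(centres[, 1], "x", cal),
    y = physical_to_index(centres[, 2], "y", cal),
    z = physical_to_index(centres[, 3], "z", cal),
    sx_um = sa[1], sy_um = sa[2], sz_um = sa[3])

  green_scene <- function(beam) {
    g <- array(p$background, dims)
    g[beam] <- p$background + p$af_beam_intensity
    for (ix in nuc_idx) g[ix] <- pmax(g[ix], p$nucleus_intensity)
    g
  }

  n_shell_c <- sum(ctrl$shell)
  total_signal <- p$actin_base_intensity * n_shell_c
  red_c <- array(p$background, dims)
  red_c[ctrl$shell] <- red_c[ctrl$shell] + p$actin_base_intensity

  # treated actin budget: total = actin_effect * control total; the
  # aggregated share scales with disruption severity so effect = 1 is a
  # true null
  af_eff <- p$aggregate_fraction * (1 - p$actin_effect)
  target_total <- p$actin_effect * total_signal
  n_shell_t <- sum(trt$shell)
  agg_mask <- array(FALSE, dims)
  if (af_eff > 0 && target_total > 0 && nrow(centres) > 0) {
    agg_budget <- af_eff * target_total
    n_target <- agg_budget / p$aggregate_intensity
    max_blobs <- ceiling(4 * n_target /
                           max(1, (4 / 3) * pi * p$aggregate_radius_um^3 /
                                 voxel_volume(cal)))
    placed <- 0L
    while (sum(agg_mask) < n_target && placed < max_blobs) {
      placed <- placed + 1L
      i <- sample.int(nrow(centres), 1)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      r_ell <- 1 / sqrt(sum((u / sa)^2))
      cpos <- centres[i, ] + u * (r_ell + p$aggregate_radius_um +
                                    stats::runif(1, 0, 2))
      ra <- p$aggregate_radius_um
      if (any(cpos < ra + 0.3) ||
          any(cpos > c(Lx, Ly, p$nz * cal$dz) - ra - 0.3)) next
      dbeam <- min(.tube_dist(cpos[2], cpos[3], beam_pos_y, p$beam_z_um),
                   .tube_dist(cpos[1], cpos[3], beam_pos_x, p$beam_z_um))
      if (dbeam < r_treated + t + ra) next
      agg_mask[.ellipsoid_indices(dims, cal, cpos, rep(ra, 3))] <- TRUE
    }
    agg_mask <- agg_mask & !trt$shell
  }
  n_agg <- sum(agg_mask)
  shell_budget <- (1 - af_eff) * target_total
  agg_budget_real <- if (n_agg > 0) af_eff * target_total else 0
  if (n_agg == 0) shell_budget <- target_total
  i_shell <- if (n_shell_t > 0) shell_budget / n_shell_t else 0
  i_agg <- if (n_agg > 0) agg_budget_real / n_agg else 0
  if (max(i_shell, i_agg) + p$background > cal$max_intensity)
    warning("treated actin intensity clips at the bit-depth ceiling; ",
            "totals will not scale exactly with actin_effect")
  red_t <- array(p$background, dims)
  red_t[trt$shell] <- red_t[trt$shell] + i_shell
  red_t[agg_mask] <- red_t[agg_mask] + i_agg

  tube_len <- length(beam_pos_y) * length(p$beam_z_um) * Lx +
    length(beam_pos_x) * length(p$beam_z_um) * Ly
  truth_for <- function(beam, actin_mask, r_eff, effect) {
    list(nuclei = nuclei_tab, beam_mask = beam, actin_mask = actin_mask,
         pore_gap_um = p$beam_spacing_um - 2 * r_eff,
         beam_radius_um = r_eff,
         analytic_beam_volume_um3 = pi * r_eff^2 * tube_len,
         actin_effect = effect, pore_dilation_um = p$pore_dilation_um)
  }

  finish <- function(green, red, seed_g, seed_r) {
    clipI <- function(a) array(as.integer(pmin(pmax(a, 0), cal$max_intensity)),
                               dim = dims)
    list(green = channel_stack(clipI(.apply_noise(green, p, seed_g)), cal,
                               "autofluor_nuclei"),
         red = channel_stack(clipI(.apply_noise(red, p, seed_r)), cal,
                             "factin"))
  }

  control <- finish(green_scene(ctrl$beam), red_c,
                    p$seed + 101L, p$seed + 202L)
  control$truth <- truth_for(ctrl$beam, ctrl$shell, p$beam_radius_um, 1)
  treated <- finish(green_scene(trt$beam), red_t,
                    p$seed + 101L, p$seed + 202L)
  treated$truth <- truth_for(trt$beam, trt$shell | agg_mask, r_treated,
                             p$actin_effect)
  list(control = control, treated = treated, params = p)
}

#' Generate a synthetic live/dead viability stack pair
#'
#' Live cells are rendered as cytosolic spheres in the calcein channel, dead
#' cells as smaller nuclear spheres in the propidium-iodide channel, all
#' placed with separations large enough that blob counting is well-posed.
#'
#' @param n_live,n_dead Numbers of live (calcein-positive) and dead
#'   (PI-positive) cells; either may be 0.
#' @param params A [synth_params()] (frame, calibration, noise and seed are
#'   used).
#' @param live_radius_um,dead_radius_um Cell and dead-nucleus radii.
#' @param cell_intensity Rendered intensity of both classes.
#' @return A list with `calcein` and `pi` [channel_stack()]s and `truth`
#'   (centre tables and programmed counts).
#' @export
generate_viability_stack <- function(n_live, n_dead, params,
                                     live_radius_um = 5,
                                     dead_radius_um = 3.5,
                                     cell_intensity = 15000) {
  p <- params
  stopifnot(n_live >= 0, n_dead >= 0)
  set.seed(p$seed)
  cal <- p$cal
  dims <- c(p$nz, p$ny, p$nx)
  Lx <- p$nx * cal$dx; Ly <- p$ny * cal$dy; Lz <- p$nz * cal$dz
  radii <- c(rep(live_radius_um, n_live), rep(dead_radius_um, n_dead))
  cls <- c(rep("live", n_live), rep("dead", n_dead))
  centres <- matrix(NA_real_, 0, 3)
  for (i in seq_along(radii)) {
    r <- radii[i]
    lo <- r + 0.3; hiv <- c(Lx, Ly, Lz) - r - 0.3
    if (any(hiv <= lo)) stop("cells do not fit in the frame")
    ok <- FALSE
    for (a in seq_len(4000L)) {
      cand <- stats::runif(3, lo, hiv)
      if (nrow(centres)) {
        sep <- sqrt(rowSums(sweep(centres, 2, cand)^2))
        need <- radii[seq_len(nrow(centres))] + r + 2
        if (any(sep <= need)) next
      }
      ok <- TRUE; break
    }
    if (!ok) stop("could not place cell ", i, "; scene too crowded")
    centres <- rbind(centres, cand)
  }
  scene_for <- function(keep) {
    sc <- array(p$background, dims)
    for (i in which(keep))
      sc[.ellipsoid_indices(dims, cal, centres[i, ],
                            rep(radii[i], 3))] <- cell_intensity
    sc
  }
  clipI <- function(a) array(as.integer(pmin(pmax(a, 0), cal$max_intensity)),
                             dim = dims)
  calcein <- channel_stack(
    clipI(.apply_noise(scene_for(cls == "live"), p, p$seed + 303L)),
    cal, "calcein")
  pistk <- channel_stack(
    clipI(.apply_noise(scene_for(cls == "dead"), p, p$seed + 404L)),
    cal, "pi")
  cells <- if (length(radii))
    data.frame(class = cls, x_um = centres[, 1], y_um = centres[, 2],
               z_um = centres[, 3], radius_um = radii)
  else
    data.frame(class = character(0), x_um = numeric(0), y_um = numeric(0),
               z_um = numeric(0), radius_um = numeric(0))
  list(calcein = calcein, pi = pistk,
       truth = list(cells = cells, n_live = n_live, n_dead = n_dead))
}

#' Write a synthetic pair to disk in the formats the readers accept
#'
#' One multi-page TIFF per channel per condition, a YAML config with the
#' calibration and seed, ground-truth nuclei as CSV and ground-truth masks
#' as boolean TIFFs.
#'
#' @param pair Result of [generate_tissue_pair()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tissue_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cond in c("control", "treated")) {
    for (ch in c("green", "red"))
      write_stack(pair[[cond]][[ch]],
                  file.path(dir, sprintf("%s_%s.tif", cond, ch)))
    tr <- pair[[cond]]$truth
    utils::write.csv(tr$nuclei,
                     file.path(dir, sprintf("%s_nuclei.csv", cond)),
                     row.names = FALSE)
    for (mk in c("beam_mask", "actin_mask")) {
      m <- tr[[mk]]
      pages <- lapply(seq_len(dim(m)[1]), function(z) m[z, , ] * 1)
      tiff::writeTIFF(pages, file.path(dir, sprintf("%s_%s.tif", cond, mk)),
                      bits.per.sample = 8)
    }
  }
  p <- pair$params
  yaml::write_yaml(list(
    voxel_size_um = list(dx = p$cal$dx, dy = p$cal$dy, dz = p$cal$dz),
    bit_depth = p$cal$bit_depth, seed = p$seed,
    actin_effect = p$actin_effect, pore_dilation_um = p$pore_dilation_um),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
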