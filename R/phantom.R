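# Dynamic digital phantom with known regional kinetics.

#' Ground-truth regional kinetics of the default phantom
#'
#' Eight brain regions spanning the binding range of a hippocampus-rich
#' GABA-A alpha5 tracer: hippocampus highest (VT 9.0), anterior cingulate
#' next, three intermediate cortical regions, occipital lobes low (VT 4.0,
#' hippocampus/occipital ratio 2.25), and cerebellum slightly above the
#' brainstem at the bottom (VT 2.7 and 2.4; both pseudo-reference regions
#' retain a little specific binding). All regions share a non-displaceable
#' volume K1/k2 = 1.5 and k4 = 0.2 min^-1; binding differences are carried
#' by k3. The exchange rates are deliberately fast-equilibrating so that
#' every quantification family (compartmental, graphical, spectral,
#' reference-tissue) can identify the kinetics within the 90.5-min window --
#' the phantom validates the estimators, it does not reproduce the slower
#' kinetics of real tracers.
#'
#' @return A tibble with one row per region: `region`, `K1`, `k2`, `k3`,
#'   `k4`, `bv`, `vt_true`, `reference` (logical), `gm_masked`.
#' @export
phantom_regions <- function() {
  tbl <- tibble(
    region = c("hippocampus", "acg", "insula", "fusiform",
               "inferior_frontal", "occipital", "cerebellum", "brainstem",
               "rest_of_brain"),
    K1 = c(0.42, 0.45, 0.44, 0.42, 0.43, 0.46, 0.44, 0.36, 0.30),
    k4 = 0.2,
    bv = c(0.040, 0.045, 0.050, 0.040, 0.045, 0.035, 0.040, 0.030, 0.035),
    vt_true = c(9.0, 7.5, 6.6, 6.3, 6.0, 4.0, 2.7, 2.4, 3.5),
    reference = c(rep(FALSE, 6), TRUE, TRUE, FALSE),
    gm_masked = c(rep(TRUE, 7), FALSE, FALSE)
  )
  tbl$k2 <- tbl$K1 / 1.5
  tbl$k3 <- tbl$k4 * (tbl$vt_true / 1.5 - 1)
  tbl[c("region", "K1", "k2", "k3", "k4", "bv", "vt_true",
        "reference", "gm_masked")]
}

#' Phantom specification
#'
#' Geometry, ground-truth kinetics, noise model and test-retest variance
#' structure of the synthetic study. Defaults give a 32 x 32 x 16 grid of
#' 4 mm voxels (thousands of in-brain voxels, yet seconds-scale voxelwise
#' fits), count-scaled Gaussian noise, 10% between-subject and 3%
#' within-subject (test-retest) CV of true VT.
#'
#' @param grid_dim Integer length-3 image dimensions.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param regions Ground-truth kinetics table; see [phantom_regions()].
#' @param count_scale Counts per (kBq/ml x s); voxel noise variance is
#'   `TAC / (duration * count_scale)` on non-decay-corrected data, so longer
#'   frames and higher count rates are less noisy. 0 disables noise.
#' @param bs_cv_true,ws_cv_true Between-subject and within-subject
#'   (session-to-session) coefficient of variation (%) of true VT in the
#'   cohort generator.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_dim = c(32L, 32L, 16L), voxel_mm = 4,
                         regions = phantom_regions(),
                         count_scale = 0.1,
                         bs_cv_true = 10, ws_cv_true = 3) {
  if (any(grid_dim < 5)) abort("Grid must be at least 5 voxels per dimension.")
  if (count_scale < 0) abort("`count_scale` must be non-negative.")
  if (bs_cv_true < 0 || ws_cv_true < 0) abort("CVs must be non-negative.")
  stopifnot(all(diff(match(
    c("hippocampus", "occipital"), regions$region)) > 0))
  structure(
    list(grid_dim = as.integer(grid_dim), voxel_mm = voxel_mm,
         regions = regions, count_scale = count_scale,
         bs_cv_true = bs_cv_true, ws_cv_true = ws_cv_true),
    class = "phantom_spec"
  )
}

# cuboid ROI layout on the 32x32x16 grid, intersected with an ellipsoidal
# brain; bilateral pairs get labels (2i-1, 2i)
phantom_geometry <- function(grid_dim) {
  d <- grid_dim
  sx <- d[1] / 32; sy <- d[2] / 32; sz <- d[3] / 16
  rng <- function(a, b, s, dmax) max(1L, round(a * s)):min(dmax, round(b * s))
  ax <- function(x, y, z) list(x = x, y = y, z = z)
  blocks <- list(
    acg              = ax(c(6, 11, 22, 27), c(19, 24), c(9, 12)),
    fusiform         = ax(c(6, 11, 22, 27), c(7, 12), c(5, 8)),
    hippocampus      = ax(c(6, 11, 22, 27), c(13, 18), c(5, 8)),
    inferior_frontal = ax(c(6, 11, 22, 27), c(25, 29), c(7, 10)),
    insula           = ax(c(6, 11, 22, 27), c(13, 18), c(9, 12)),
    occipital        = ax(c(6, 11, 22, 27), c(3, 7), c(9, 12)),
    cerebellum       = ax(c(10, 16, 17, 23), c(4, 9), c(2, 4)),
    brainstem        = ax(c(14, 19, NA, NA), c(10, 15), c(2, 5))
  )
  ctr <- (d + 1) / 2
  semi <- c(d[1] * 0.45, d[2] * 0.45, d[3] * 0.45)
  coords <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  brain <- ((coords$x - ctr[1]) / semi[1])^2 +
    ((coords$y - ctr[2]) / semi[2])^2 +
    ((coords$z - ctr[3]) / semi[3])^2 <= 1
  brain <- array(brain, d)
  labels <- array(0L, d)
  roi_rows <- list()
  lab <- 0L
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    ids <- integer(0)
    sides <- if (is.na(b$x[3])) list(b$x[1:2]) else list(b$x[1:2], b$x[3:4])
    for (side in sides) {
      lab <- lab + 1L
      xs <- rng(side[1], side[2], sx, d[1])
      ys <- rng(b$y[1], b$y[2], sy, d[2])
      zs <- rng(b$z[1], b$z[2], sz, d[3])
      sel <- array(FALSE, d)
      sel[xs, ys, zs] <- TRUE
      sel <- sel & brain
      if (any(labels[sel] != 0L)) abort("Phantom regions overlap.")
      if (sum(sel) < 8) abort(sprintf("Region '%s' has too few voxels.", nm))
      labels[sel] <- lab
      ids <- c(ids, lab)
    }
    roi_rows[[nm]] <- ids
  }
  lab <- lab + 1L
  labels[brain & labels == 0L] <- lab
  roi_rows[["rest_of_brain"]] <- lab
  list(labels = labels, brain = brain, roi_labels = roi_rows)
}

#' ROI definition table of the phantom
#'
#' Maps each phantom region to its label ids (both homologues for bilateral
#' regions) and records which regions are sampled through the grey-matter
#' mask (the brainstem is unpaired and never grey-matter masked).
#'
#' @param spec A [phantom_spec()].
#' @return A tibble: `region`, `labels` (list column), `gm_masked`.
#' @export
phantom_rois <- function(spec = phantom_spec()) {
  geo <- phantom_geometry(spec$grid_dim)
  tibble(
    region = names(geo$roi_labels),
    labels = unname(geo$roi_labels),
    gm_masked = spec$regions$gm_masked[
      match(names(geo$roi_labels), spec$regions$region)]
  )
}

# deterministic pseudo-random grey-matter exclusions (~1/7 of ROI voxels),
# so grey-matter masking has a real effect without a second RNG stream
phantom_gm_mask <- function(labels, geo, regions) {
  d <- dim(labels)
  coords <- arrayInd(seq_along(labels), d)
  gm_regions <- regions$region[regions$gm_masked]
  gm_ids <- unlist(geo$roi_labels[names(geo$roi_labels) %in% gm_regions])
  gm <- array(labels %in% gm_ids, d)
  drop <- (coords[, 1] + 2L * coords[, 2] + 3L * coords[, 3]) %% 7L == 0L
  gm & !array(drop, d)
}

#' Generate one dynamic phantom scan
#'
#' Builds the noiseless per-region TACs from the two-tissue forward model
#' (with each region's blood-volume fraction and the scan's whole-blood
#' curve), fills the label geometry, and adds count-scaled Gaussian noise on
#' the non-decay-corrected data: `sd = sqrt(TAC_ndc / (L_i * count_scale))`
#' per voxel and frame. The returned dynamic image is decay-corrected, as
#' output by image reconstruction. The per-frame true-coincidence rate is
#' the non-decay-corrected whole-image activity per frame (times voxel
#' volume and count scale), which drives the frame weights.
#'
#' @param spec A [phantom_spec()].
#' @param input A `plasma_input` (the scan's arterial input).
#' @param schedule A [frame_schedule()].
#' @param vt_scale Multiplier applied to every region's true VT (subject and
#'   session effects); binding changes are carried by k3, reflecting
#'   receptor-density differences rather than delivery differences.
#' @param seed Integer seed (same seed, same spec: bit-identical output).
#' @return A list: `dyn` (4D decay-corrected image), `labels`, `gm_mask`,
#'   `brain_mask`, `trues_rate`, `rois` (the [phantom_rois()] table),
#'   `truth` (region table with the scaled true VT and the true BPND against
#'   each reference region), `tacs_true` (noiseless region [pet_tac()]).
#' @export
sim_phantom_dynamic <- function(spec = phantom_spec(),
                                input,
                                schedule = frame_schedule(),
                                vt_scale = 1,
                                seed = 1L) {
  assert_input(input)
  assert_schedule(schedule)
  if (vt_scale <= 0) abort("`vt_scale` must be positive.")
  set.seed(seed)
  geo <- phantom_geometry(spec$grid_dim)
  regions <- spec$regions
  # apply the VT multiplier through k3 (minimum 0 keeps rates valid)
  vt_scaled <- regions$vt_true * vt_scale
  k3_scaled <- pmax(regions$k4 * (vt_scaled / (regions$K1 / regions$k2) - 1), 0)

  tg <- fine_grid(schedule, 1)
  cur <- input_on_grid(input, tg)
  op <- frame_avg_op(schedule, tg)
  nf <- n_frames(schedule)
  region_tac <- matrix(0, nf, nrow(regions),
                       dimnames = list(NULL, regions$region))
  for (i in seq_len(nrow(regions))) {
    p <- kinetic_params(regions$K1[i], regions$k2[i], k3_scaled[i],
                        regions$k4[i], bv = regions$bv[i])
    ct <- tissue_curve(p, cur$parent_plasma, tg)
    meas <- (1 - p$bv) * ct + p$bv * cur$whole_blood
    region_tac[, i] <- as.vector(op %*% meas)
  }

  d <- spec$grid_dim
  labels <- geo$labels
  lab2region <- match(
    names(geo$roi_labels)[
      rep(seq_along(geo$roi_labels), lengths(geo$roi_labels))],
    regions$region
  )
  # region row index per voxel (0 outside the brain)
  region_of_voxel <- integer(length(labels))
  region_of_voxel[labels > 0] <-
    lab2region[match(labels[labels > 0], unlist(geo$roi_labels))]

  mids <- frame_midpoints(schedule)
  decay <- exp(-attr(schedule, "decay_constant") * mids)
  dyn <- array(0, c(d, nf))
  nvox <- prod(d)
  inb <- which(region_of_voxel > 0)
  for (f in seq_len(nf)) {
    vol <- numeric(nvox)
    mu_dc <- region_tac[f, region_of_voxel[inb]]
    if (spec$count_scale > 0) {
      mu_ndc <- mu_dc * decay[f]
      sdv <- sqrt(pmax(mu_ndc, 1e-3) /
                    (schedule$duration[f] * spec$count_scale))
      vol[inb] <- (mu_ndc + stats::rnorm(length(inb), 0, sdv)) / decay[f]
    } else {
      vol[inb] <- mu_dc
    }
    dyn[, , , f] <- vol
  }

  voxel_ml <- (spec$voxel_mm / 10)^3
  total_ndc <- vapply(seq_len(nf), function(f) {
    sum(region_tac[f, region_of_voxel[inb]]) * decay[f]
  }, numeric(1))
  trues_rate <- pmax(total_ndc * voxel_ml * max(spec$count_scale, 1e-3), 1e-9)

  vt_ref <- setNames(vt_scaled, regions$region)
  truth <- regions
  truth$k3 <- k3_scaled
  truth$vt_true <- vt_scaled
  truth$bp_vs_brainstem <- vt_scaled / vt_ref[["brainstem"]] - 1
  truth$bp_vs_cerebellum <- vt_scaled / vt_ref[["cerebellum"]] - 1

  list(
    dyn = dyn,
    labels = labels,
    gm_mask = phantom_gm_mask(labels, geo, regions),
    brain_mask = geo$brain,
    trues_rate = trues_rate,
    rois = phantom_rois(spec),
    truth = truth,
    tacs_true = pet_tac(schedule, region_tac, region = colnames(region_tac))
  )
}
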