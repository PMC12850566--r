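#' Synthetic hip-implant-in-water-bath phantom
#'
#' Deterministic analogue of a total hip replacement in a water bath: a
#' cobalt-chromium femoral head (sphere) attached to a titanium femoral stem
#' (tilted cylinder), immersed in a water box surrounded by an air margin.
#' Geometry is fully determined by the arguments; regenerating with the same
#' arguments gives identical volumes.
#'
#' @param grid_spacing_mm isotropic fine-grid spacing (<= 1 mm recommended;
#'   coarser grids under-resolve the field at implant edges).
#' @param bath_size_mm edge lengths of the water box (length 1 or 3).
#' @param margin_mm air margin around the bath, mm.
#' @param head_radius_mm,stem_length_mm,stem_radius_mm implant geometry.
#' @param stem_tilt_deg stem tilt from the -z (inferior) direction, degrees.
#' @param head_material,stem_material material names in `materials`.
#' @param materials a [material_table()].
#' @return list: `labels` (a [label_volume()]), `materials`, `implant_mask`
#'   (logical array), `head_mask`.
#' @export
make_water_bath_phantom <- function(grid_spacing_mm = 1,
                                    bath_size_mm = c(96, 96, 96),
                                    margin_mm = 6,
                                    head_radius_mm = 14,
                                    stem_length_mm = 40,
                                    stem_radius_mm = 6,
                                    stem_tilt_deg = 10,
                                    head_material = "cocr",
                                    stem_material = "titanium",
                                    materials = default_materials()) {
  bath <- rep_len(bath_size_mm, 3)
  extent <- bath + 2 * margin_mm
  shape <- pmax(1L, as.integer(round(extent / grid_spacing_mm)))
  grid <- voxel_grid(shape, grid_spacing_mm)
  cc <- grid_coord_arrays(grid)
  in_bath <- abs(cc$x) <= bath[1] / 2 & abs(cc$y) <= bath[2] / 2 &
    abs(cc$z) <= bath[3] / 2
  labels <- array(material_row(materials, "air")$label, dim = shape)
  labels[in_bath] <- material_row(materials, "water")$label
  head_center <- c(0, 0, bath[3] / 6)
  head <- make_sphere_mask(grid, head_center, head_radius_mm)
  tilt <- stem_tilt_deg * pi / 180
  stem_dir <- c(sin(tilt), 0, -cos(tilt))
  stem <- make_cylinder_mask(grid, head_center,
                             head_center + stem_dir * stem_length_mm,
                             stem_radius_mm)
  if (any((head | stem) & !in_bath))
    stop("implant extends outside the water bath")
  anatomy <- label_volume(grid, labels)
  merged <- merge_masks(anatomy, list(
    list(mask = head, material = head_material),
    list(mask = stem, material = stem_material)), materials)
  list(labels = merged, materials = materials,
       implant_mask = head | stem, head_mask = head)
}

#' Synthetic layered-tissue hip phantom
#'
#' Deterministic layered anatomy (fat shell over muscle, femur of cortical
#' bone with marrow core) with a four-component hip implant: acetabular cup
#' and liner (spherical-cap shells), femoral head (sphere) and stem
#' (cylinder down the femur axis). Component materials are configurable, so
#' e.g. a CoCr-head and a Ti/ceramic-head configuration differ only in the
#' head/cup labels.
#'
#' @param grid_spacing_mm isotropic fine-grid spacing, mm.
#' @param config list: `head_material`, `cup_material`, `liner_material`,
#'   `stem_material`, `with_implant` (default TRUE), `body_size_mm`,
#'   `head_radius_mm`.
#' @param materials a [material_table()].
#' @return list as in [make_water_bath_phantom()].
#' @export
make_hip_phantom <- function(grid_spacing_mm = 1, config = list(),
                             materials = default_materials()) {
  cfg <- utils::modifyList(list(
    head_material = "cocr", cup_material = "cocr",
    liner_material = "polyethylene", stem_material = "titanium",
    with_implant = TRUE, body_size_mm = c(110, 90, 130),
    head_radius_mm = 14, fat_thickness_mm = 8), config)
  for (m in c("head_material", "cup_material", "liner_material",
              "stem_material"))
    material_row(materials, cfg[[m]])  # errors on unknown material
  body <- rep_len(cfg$body_size_mm, 3)
  margin <- 6
  shape <- pmax(1L, as.integer(round((body + 2 * margin) / grid_spacing_mm)))
  grid <- voxel_grid(shape, grid_spacing_mm)
  cc <- grid_coord_arrays(grid)
  in_body <- abs(cc$x) <= body[1] / 2 & abs(cc$y) <= body[2] / 2 &
    abs(cc$z) <= body[3] / 2
  ft <- cfg$fat_thickness_mm
  in_core <- abs(cc$x) <= body[1] / 2 - ft & abs(cc$y) <= body[2] / 2 - ft &
    abs(cc$z) <= body[3] / 2 - ft
  lab_of <- function(m) material_row(materials, m)$label
  labels <- array(lab_of("air"), dim = shape)
  labels[in_body] <- lab_of("fat")
  labels[in_core] <- lab_of("muscle")
  # femur: cortical shell with marrow core, running inferior from the head
  hip_center <- c(-body[1] / 6, 0, body[3] / 6)
  fem_top <- hip_center + c(6, 0, -10)
  fem_bot <- fem_top + c(4, 0, -(body[3] / 2 + fem_top[3] - margin - ft - 4))
  femur <- make_cylinder_mask(grid, fem_top, fem_bot, 11)
  marrow <- make_cylinder_mask(grid, fem_top, fem_bot, 6)
  labels[femur] <- lab_of("cortical_bone")
  labels[marrow] <- lab_of("bone_marrow")
  anatomy <- label_volume(grid, labels)
  if (!isTRUE(cfg$with_implant))
    return(list(labels = anatomy, materials = materials,
                implant_mask = array(FALSE, dim = shape),
                head_mask = array(FALSE, dim = shape)))
  r_head <- cfg$head_radius_mm
  cup_axis <- c(0.4, 0, 1); cup_axis <- cup_axis / sqrt(sum(cup_axis^2))
  cup <- make_cap_shell_mask(grid, hip_center, r_head + 6, r_head + 3,
                             cup_axis, 90)
  liner <- make_cap_shell_mask(grid, hip_center, r_head + 3, r_head + 0.2,
                               cup_axis, 90)
  head <- make_sphere_mask(grid, hip_center, r_head)
  stem_dir <- fem_bot - fem_top
  stem_dir <- stem_dir / sqrt(sum(stem_dir^2))
  stem <- make_cylinder_mask(grid, hip_center,
                             fem_top + stem_dir * 45, 5)
  merged <- merge_masks(anatomy, list(
    list(mask = cup, material = cfg$cup_material),
    list(mask = liner, material = cfg$liner_material),
    list(mask = stem, material = cfg$stem_material),
    list(mask = head, material = cfg$head_material)), materials)
  list(labels = merged, materials = materials,
       implant_mask = cup | liner | head | stem, head_mask = head)
}

#' Demonstration sweep configurations
#'
#' A named list of pipeline configurations mirroring the package's standard
#' parameter sweeps around a common baseline (TR = 2000 ms, TE = 34 ms,
#' readout bandwidth 400 Hz/px, RF bandwidth 1 kHz, 1 x 1 mm in-plane
#' resolution, 3 mm slices): a B0 sweep over 0.05-5 T, SEMAC factors
#' 4/6/12/18/24, RF bandwidths 0.5-1.5 kHz at 0.55 T, readout bandwidths
#' 100-800 Hz/px comparing TSE and VAT. The listed configurations describe
#' full-FOV studies; tests and examples shrink the grids.
#'
#' @return named list of configuration lists (YAML-serializable via
#'   [write_config_yaml()]).
#' @export
make_demo_configs <- function() {
  baseline <- list(
    phantom = list(type = "hip", args = list(grid_spacing_mm = 0.5)),
    b0 = 0.55,
    fieldmap = list(pad_factor = 2),
    sequence = list(seq_type = "SEMAC", tr_ms = 2000, te_ms = 34,
                    fov_mm = c(400, 200), matrix = c(400, 200),
                    slice_thickness_mm = 3, n_slices = 8,
                    readout_bw_hz_per_px = 400, rf_bw_hz = 1000,
                    vat_fraction = 1, n_bins = 12, nex = 1,
                    freq_axis = 3, phase_axis = 1, slice_axis = 2,
                    rf_profile = "rect"),
    noise = list(sigma_ref = 0.024, b0_ref = 0.55, bw_ref = 400,
                 nex_ref = 1, v_ref = 3),
    metrics = list(threshold_fraction = 0.5))
  b0s <- c(0.05, 0.1, 0.2, 0.3, 0.55, 1, 1.5, 3, 5)
  configs <- list(baseline = baseline)
  for (b in b0s) {
    cfg <- baseline; cfg$b0 <- b
    configs[[sprintf("b0_sweep_%gT", b)]] <- cfg
  }
  for (nb in c(4, 6, 12, 18, 24)) {
    cfg <- baseline; cfg$sequence$n_bins <- nb
    configs[[sprintf("semac_factor_%d", nb)]] <- cfg
  }
  for (bw in c(500, 750, 1000, 1250, 1500)) {
    cfg <- baseline; cfg$sequence$rf_bw_hz <- bw; cfg$sequence$n_bins <- 6
    configs[[sprintf("rf_bw_%dHz", bw)]] <- cfg
  }
  for (rbw in c(100, 200, 400, 600, 800)) {
    for (st in c("TSE", "VAT")) {
      cfg <- baseline
      cfg$sequence$seq_type <- st
      cfg$sequence$n_bins <- 1
      cfg$sequence$readout_bw_hz_per_px <- rbw
      cfg$sequence$vat_fraction <- if (st == "VAT") 1 else 0
      configs[[sprintf("readout_bw_%dHz_%s", rbw, st)]] <- cfg
    }
  }
  configs
}
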