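#' Synthetic cine phantom configuration
#'
#' Parameters of the synthetic short-axis cine study: a bright left
#' ventricular blood pool (disk) with papillary-muscle inclusions inside a
#' darker myocardial ring, an optional right ventricular crescent, a dark
#' background, cosinusoidal contraction from end-diastole (phase 0) to
#' end-systole (phase `floor(n_phases/2)`) and back, per-slice apical
#' tapering, and additive Gaussian noise.
#'
#' Defaults emulate a typical adult acquisition: 10 slices of 25 phases on a
#' 156 x 192 matrix with 2.083 mm pixels and 6 mm slices; blood/myocardium/
#' background intensities 200/80/30; an end-diastolic cavity radius of 17 px
#' tapering to 55% at the apex (left ventricular EDV close to 150 mL) and an
#' end-systolic radius of 11 px (ejection fraction near 58%); papillary
#' muscles at 30% of the cavity radius so the 9 x 9 seed kernel straddles
#' blood and muscle; noise sd 10 gray levels (blood-to-noise ratio ~20).
#'
#' @param n_slices,n_phases grid dimensions.
#' @param image_size (rows, cols) in pixels.
#' @param lv_center 0-based (row, col) of the LV cavity centre.
#' @param lv_radius_ed_px,lv_radius_es_px end-diastolic / end-systolic LV
#'   cavity radii at the most basal slice (ES < ED).
#' @param wall_px myocardial wall thickness in pixels.
#' @param rv_enabled logical; draw the right ventricular crescent.
#' @param rv_radius_ed_px,rv_radius_es_px radii of the outer disk of the RV
#'   crescent (the crescent is this disk minus the LV epicardial disk).
#' @param rv_offset_frac centre offset of the RV disk from the LV epicardium
#'   as a fraction of the RV radius (controls crescent thickness).
#' @param rv_wall_px RV free-wall thickness in pixels.
#' @param rv_trabeculae data frame with columns `offset_row`, `offset_col`
#'   (pixel offsets from the crescent centroid) and `radius_frac` (fraction
#'   of the current RV radius): trabecular inclusions at myocardial
#'   intensity, clipped to the crescent.  The right ventricle is heavily
#'   trabeculated, and these dark intracavitary structures are what gives a
#'   seed kernel inside the RV pool a bimodal intensity sample.
#' @param apical_taper per-slice radius scale factors, base to apex.
#' @param intensities named vector `blood`, `myocardium`, `background`
#'   (0--255, decreasing).
#' @param papillary data frame with columns `angle_deg`, `dist_frac`,
#'   `radius_frac`: papillary-muscle inclusions at myocardial intensity,
#'   positioned and sized relative to the current cavity radius.
#' @param noise_sd additive Gaussian noise, gray levels.
#' @param pixel_spacing_mm,slice_thickness_mm,gap_fraction geometry metadata.
#' @param es_apex_dropout number of apical slices whose cavity vanishes
#'   around end-systole (through-plane motion), default 0.
#' @param rng_seed integer seed for the noise.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 10L, n_phases = 25L,
                           image_size = c(156L, 192L),
                           lv_center = c(78L, 115L),
                           lv_radius_ed_px = 17, lv_radius_es_px = 11,
                           wall_px = 5,
                           rv_enabled = TRUE,
                           rv_radius_ed_px = 19, rv_radius_es_px = 14,
                           rv_offset_frac = 0.45, rv_wall_px = 3,
                           rv_trabeculae = data.frame(
                             offset_row = c(-3, 3),
                             offset_col = c(-2, 1),
                             radius_frac = c(0.12, 0.12)),
                           apical_taper = seq(1, 0.55, length.out = n_slices),
                           intensities = c(blood = 200, myocardium = 80,
                                           background = 30),
                           papillary = data.frame(
                             angle_deg = c(45, 225),
                             dist_frac = c(0.30, 0.33),
                             radius_frac = c(0.15, 0.15)),
                           noise_sd = 10,
                           pixel_spacing_mm = c(2.083, 2.083),
                           slice_thickness_mm = 6, gap_fraction = 0,
                           es_apex_dropout = 0L,
                           rng_seed = 1L) {
  cfg <- list(n_slices = as.integer(n_slices), n_phases = as.integer(n_phases),
              image_size = as.integer(image_size), lv_center = as.numeric(lv_center),
              lv_radius_ed_px = lv_radius_ed_px, lv_radius_es_px = lv_radius_es_px,
              wall_px = wall_px, rv_enabled = isTRUE(rv_enabled),
              rv_radius_ed_px = rv_radius_ed_px, rv_radius_es_px = rv_radius_es_px,
              rv_offset_frac = rv_offset_frac, rv_wall_px = rv_wall_px,
              rv_trabeculae = rv_trabeculae,
              apical_taper = as.numeric(apical_taper),
              intensities = intensities, papillary = papillary,
              noise_sd = noise_sd,
              pixel_spacing_mm = as.numeric(pixel_spacing_mm),
              slice_thickness_mm = slice_thickness_mm,
              gap_fraction = gap_fraction,
              es_apex_dropout = as.integer(es_apex_dropout),
              rng_seed = as.integer(rng_seed))
  for (nm in c("lv_radius_ed_px", "lv_radius_es_px", "wall_px",
               "rv_radius_ed_px", "rv_radius_es_px", "rv_offset_frac",
               "rv_wall_px", "noise_sd", "slice_thickness_mm", "gap_fraction"))
    cfg[[nm]] <- as.numeric(cfg[[nm]])
  ints <- cfg$intensities
  if (!(ints["blood"] > ints["myocardium"] && ints["myocardium"] > ints["background"]))
    cardioseg_error("intensities must satisfy blood > myocardium > background",
                    class = "cardioseg_config_error")
  if (any(ints < 0) || any(ints > 255))
    cardioseg_error("intensities must be in 0..255", class = "cardioseg_config_error")
  if (cfg$lv_radius_es_px >= cfg$lv_radius_ed_px || cfg$lv_radius_es_px <= 0)
    cardioseg_error("need 0 < lv_radius_es_px < lv_radius_ed_px",
                    class = "cardioseg_config_error")
  if (length(cfg$apical_taper) != cfg$n_slices || any(cfg$apical_taper <= 0) ||
      any(cfg$apical_taper > 1))
    cardioseg_error("apical_taper must have one factor in (0, 1] per slice",
                    class = "cardioseg_config_error")
  reach <- cfg$lv_radius_ed_px + cfg$wall_px + 1
  if (cfg$lv_center[1] - reach < 0 || cfg$lv_center[1] + reach >= cfg$image_size[1] ||
      cfg$lv_center[2] - reach < 0 || cfg$lv_center[2] + reach >= cfg$image_size[2])
    cardioseg_error("LV cavity and wall exceed the image bounds",
                    class = "cardioseg_config_error")
  if (cfg$rv_enabled) {
    d <- cfg$lv_radius_ed_px + cfg$wall_px + cfg$rv_offset_frac * cfg$rv_radius_ed_px
    left <- cfg$lv_center[2] - d - cfg$rv_radius_ed_px - cfg$rv_wall_px - 1
    if (left < 0)
      cardioseg_error("RV crescent exceeds the image bounds",
                      class = "cardioseg_config_error")
  }
  structure(cfg, class = "phantom_config")
}

# Cosinusoidal contraction scale: 1 at phase 0, `es_ratio` at mid-cycle.
contraction_scale <- function(phase, n_phases, es_ratio) {
  es_ratio + (1 - es_ratio) * (1 + cos(2 * pi * phase / n_phases)) / 2
}

#' Generate a synthetic cine study with ground truth
#'
#' Rasterizes the phantom described by a [phantom_config()] and returns the
#' resulting [cine_study()] together with its ground truth.  Truth masks are
#' the noiseless rasterized cavities (papillary pixels included, matching
#' the convention that papillary muscles belong to the cavity); truth
#' volumes are computed from those rasterized masks through
#' [simpson_volume()], so segmentation accuracy is not confounded with
#' rasterization error.  A cavity rasterizes as empty once its radius drops
#' below half a pixel.
#'
#' @param config a [phantom_config()].
#' @return list with `study` (a `cine_study`) and `truth` (a
#'   `phantom_truth`: per-ventricle `masks[[slice]][[phase]]`, per-phase
#'   pixel-count matrix `areas_px`, `ed_phase`, `es_phase`, `edv_ml`,
#'   `esv_ml`, `ef_percent` per ventricle, and the `config`).
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  nr <- config$image_size[1]; nc <- config$image_size[2]
  ints <- config$intensities
  es_phase <- config$n_phases %/% 2L

  # 0-based pixel-centre coordinate grids and static distance maps.
  rows <- matrix(0:(nr - 1L), nr, nc)
  cols <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)
  dist_lv <- sqrt((rows - config$lv_center[1])^2 + (cols - config$lv_center[2])^2)
  if (config$rv_enabled) {
    d_off <- config$lv_radius_ed_px + config$wall_px +
      config$rv_offset_frac * config$rv_radius_ed_px
    rv_center <- c(config$lv_center[1], config$lv_center[2] - d_off)
    dist_rv <- sqrt((rows - rv_center[1])^2 + (cols - rv_center[2])^2)
  }

  lv_ratio <- config$lv_radius_es_px / config$lv_radius_ed_px
  rv_ratio <- if (config$rv_enabled) config$rv_radius_es_px / config$rv_radius_ed_px else NA
  dropout_from <- config$n_slices - config$es_apex_dropout   # 0-based slice index

  disk <- function(dist, r) if (r >= 0.5) dist <= r else matrix(FALSE, nr, nc)

  frames <- vector("list", config$n_slices)
  lv_masks <- vector("list", config$n_slices)
  rv_masks <- if (config$rv_enabled) vector("list", config$n_slices)
  lv_areas <- matrix(0, config$n_slices, config$n_phases)
  rv_areas <- matrix(0, config$n_slices, config$n_phases)

  with_seed(config$rng_seed, {
    for (s in seq_len(config$n_slices)) {
      taper <- config$apical_taper[s]
      frames[[s]] <- vector("list", config$n_phases)
      lv_masks[[s]] <- vector("list", config$n_phases)
      if (config$rv_enabled) rv_masks[[s]] <- vector("list", config$n_phases)
      for (p in seq_len(config$n_phases)) {
        ph <- p - 1L
        # through-plane dropout: apical slices vanish around end-systole
        drop_f <- if (s - 1L >= dropout_from)
          (1 + cos(2 * pi * ph / config$n_phases)) / 2 else 1
        r_lv <- config$lv_radius_ed_px * taper * drop_f *
          contraction_scale(ph, config$n_phases, lv_ratio)
        img <- matrix(ints[["background"]], nr, nc)

        if (config$rv_enabled) {
          r_rv <- config$rv_radius_ed_px * taper * drop_f *
            contraction_scale(ph, config$n_phases, rv_ratio)
          rv_out <- disk(dist_rv, r_rv + config$rv_wall_px * drop_f)
          rv_cav <- disk(dist_rv, r_rv)
          img[rv_out] <- ints[["myocardium"]]
          img[rv_cav] <- ints[["blood"]]
        }

        lv_epi <- disk(dist_lv, r_lv + config$wall_px * drop_f)
        lv_cav <- disk(dist_lv, r_lv)
        img[lv_epi] <- ints[["myocardium"]]
        img[lv_cav] <- ints[["blood"]]
        if (config$rv_enabled) {
          rv_cav <- rv_cav & !lv_epi
          # trabecular inclusions around the crescent centroid
          if (nrow(config$rv_trabeculae) && any(rv_cav)) {
            idx <- which(rv_cav)
            ctr <- c(mean((idx - 1L) %% nr), mean((idx - 1L) %/% nr))
            for (k in seq_len(nrow(config$rv_trabeculae))) {
              tb <- config$rv_trabeculae[k, ]
              tr <- tb$radius_frac * r_rv
              if (tr >= 0.5) {
                dt <- sqrt((rows - ctr[1] - tb$offset_row)^2 +
                           (cols - ctr[2] - tb$offset_col)^2)
                img[dt <= tr & rv_cav] <- ints[["myocardium"]]
              }
            }
          }
        }

        # papillary muscles: dark inclusions strictly inside the cavity
        if (nrow(config$papillary) && r_lv >= 0.5) {
          for (k in seq_len(nrow(config$papillary))) {
            pp <- config$papillary[k, ]
            a <- pp$angle_deg * pi / 180
            pc <- config$lv_center + r_lv * pp$dist_frac * c(sin(a), cos(a))
            pr <- pp$radius_frac * r_lv
            if (pr >= 0.5) {
              dp <- sqrt((rows - pc[1])^2 + (cols - pc[2])^2)
              img[dp <= pr & lv_cav] <- ints[["myocardium"]]
            }
          }
        }

        if (config$noise_sd > 0) {
          img <- img + stats::rnorm(nr * nc, sd = config$noise_sd)
          img <- pmin(pmax(round_half_up(img), 0), 255)
        }
        storage.mode(img) <- "integer"
        frames[[s]][[p]] <- img

        lv_m <- lv_cav; mode(lv_m) <- "integer"
        lv_masks[[s]][[p]] <- lv_m
        lv_areas[s, p] <- sum(lv_m)
        if (config$rv_enabled) {
          rv_m <- rv_cav; mode(rv_m) <- "integer"
          rv_masks[[s]][[p]] <- rv_m
          rv_areas[s, p] <- sum(rv_m)
        }
      }
    }
  })

  study <- cine_study(frames, config$pixel_spacing_mm,
                      config$slice_thickness_mm, config$gap_fraction)

  px_area <- prod(config$pixel_spacing_mm)
  ventricle_truth <- function(masks, areas_px) {
    edv <- simpson_volume(areas_px[, 1L] * px_area,
                          config$slice_thickness_mm, config$gap_fraction)
    esv <- simpson_volume(areas_px[, es_phase + 1L] * px_area,
                          config$slice_thickness_mm, config$gap_fraction)
    list(masks = masks, areas_px = areas_px,
         edv_ml = edv, esv_ml = esv,
         ef_percent = ejection_fraction(edv, esv))
  }
  truth <- structure(list(
    lv = ventricle_truth(lv_masks, lv_areas),
    rv = if (config$rv_enabled) ventricle_truth(rv_masks, rv_areas),
    ed_phase = 0L, es_phase = es_phase,
    config = config
  ), class = "phantom_truth")

  list(study = study, truth = truth)
}

#' Perturb a cine study
#'
#' Applies a reproducible degradation to every frame: a multiplicative
#' low-frequency bias field (`kind = "bias_field"`, parameter `amplitude`)
#' or additional Gaussian noise (`kind = "extra_noise"`, parameter `sd`).
#' Results are clipped to 0--255.
#'
#' @param study a [cine_study()].
#' @param kind `"bias_field"` or `"extra_noise"`.
#' @param params named list: `amplitude` (relative, default 0.2) for the
#'   bias field, `sd` (gray levels, default 5) for noise.
#' @param rng_seed seed for the noise (unused by the bias field).
#' @return a perturbed `cine_study`.
#' @export
perturb_study <- function(study, kind = c("bias_field", "extra_noise"),
                          params = list(), rng_seed = 1L) {
  stopifnot(inherits(study, "cine_study"))
  kind <- match.arg(kind)
  nr <- study$n_rows; nc <- study$n_cols
  frames <- study$frames
  if (kind == "bias_field") {
    amplitude <- if (is.null(params$amplitude)) 0.2 else params$amplitude
    field <- 1 + amplitude *
      outer(sin(pi * (0:(nr - 1)) / (nr - 1)), sin(pi * (0:(nc - 1)) / (nc - 1)))
    for (s in seq_along(frames)) for (p in seq_along(frames[[s]])) {
      img <- pmin(pmax(round_half_up(frames[[s]][[p]] * field), 0), 255)
      storage.mode(img) <- "integer"
      frames[[s]][[p]] <- img
    }
  } else {
    sd <- if (is.null(params$sd)) 5 else params$sd
    with_seed(rng_seed, {
      for (s in seq_along(frames)) for (p in seq_along(frames[[s]])) {
        img <- frames[[s]][[p]] + stats::rnorm(nr * nc, sd = sd)
        img <- pmin(pmax(round_half_up(img), 0), 255)
        storage.mode(img) <- "integer"
        frames[[s]][[p]] <- img
      }
    })
  }
  cine_study(frames, study$pixel_spacing_mm, study$slice_thickness_mm,
             study$gap_fraction)
}
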