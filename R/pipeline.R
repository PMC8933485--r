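#' Study design for stability / discriminative-power analysis
#'
#' @param groups data.frame with columns `group`, `algorithm`,
#'   `n_projections`.
#' @param A sinogram noise level.
#' @param repetitions repetitions per group (distinct noise seeds).
#' @param base_seed base RNG seed; repetition `r` of group `g` uses seed
#'   `base_seed + 100 * g + r`.
#' @return Object of class `study_design`.
#' @export
study_design <- function(groups, A = 1e-4, repetitions = 10L,
                         base_seed = 1L) {
  stopifnot(nrow(groups) >= 2L, repetitions >= 2L,
            all(c("group", "algorithm", "n_projections") %in% names(groups)))
  structure(list(groups = groups, A = A,
                 repetitions = as.integer(repetitions),
                 base_seed = as.integer(base_seed)),
            class = "study_design")
}

#' The 8-group simulation design
#'
#' SIRT and FBP reconstructions at 150, 200, 250 and 300 projections, noise
#' level `A = 1e-4` (roughly a 10 mGy dose), 10 repetitions per group via
#' distinct Poisson seeds.
#'
#' @inheritParams study_design
#' @return A [study_design()] with 8 groups.
#' @export
build_table2_design <- function(A = 1e-4, repetitions = 10L,
                                base_seed = 1L) {
  groups <- data.frame(
    group = 1:8,
    algorithm = rep(c("SIRT", "FBP"), each = 4),
    n_projections = rep(c(150L, 200L, 250L, 300L), 2))
  study_design(groups, A = A, repetitions = repetitions,
               base_seed = base_seed)
}

#' Enumerate the empirical test-retest acquisition design
#'
#' Metadata records replicating the tandem phantom protocol: 8 parameter
#' variation groups, each with 20 repetitions without repositioning
#' followed by 10 repetitions with repositioning between measurements (240
#' records total). Repositioning is realised in simulation as a small
#' seeded rigid perturbation of the phantom pose.
#'
#' @param n_groups number of variation groups (8).
#' @param n_fixed repetitions without repositioning (20).
#' @param n_repositioned repetitions with repositioning (10).
#' @param max_translation_mm,max_rotation_deg perturbation bounds for
#'   repositioned records.
#' @param base_seed seed controlling the perturbation draws.
#' @return data.frame of acquisition records: `group`, `repetition`,
#'   `repositioned`, `seed`, `shift_x_mm`, `shift_y_mm`, `rot_z_deg`.
#' @export
replicate_empirical_design <- function(n_groups = 8L, n_fixed = 20L,
                                       n_repositioned = 10L,
                                       max_translation_mm = 1,
                                       max_rotation_deg = 1,
                                       base_seed = 1L) {
  recs <- expand.grid(repetition = seq_len(n_fixed + n_repositioned),
                      group = seq_len(n_groups))[, c("group", "repetition")]
  recs$repositioned <- recs$repetition > n_fixed
  recs$seed <- base_seed + 100L * recs$group + recs$repetition
  n <- nrow(recs)
  recs$shift_x_mm <- 0; recs$shift_y_mm <- 0; recs$rot_z_deg <- 0
  pert <- with_seed(base_seed, matrix(runif(3 * n, -1, 1), ncol = 3))
  sel <- recs$repositioned
  recs$shift_x_mm[sel] <- pert[sel, 1] * max_translation_mm
  recs$shift_y_mm[sel] <- pert[sel, 2] * max_translation_mm
  recs$rot_z_deg[sel] <- pert[sel, 3] * max_rotation_deg
  recs
}

#' Multi-center simulation preset
#'
#' Projection counts fixed to 200 and 250 (mimicking the fixed slice
#' reconstruction thickness), iterative (SIRT) reconstruction only, and a
#' noise grid spanning an extended image-domain variance range (default
#' 2.5e-3 to 2.9e-3 in the calibration's variance units), mapped to noise
#' levels through a [fit_variance_vs_A()] calibration.
#'
#' @param fit a `calibration_fit`; required (run [calibrate_noise()]
#'   first).
#' @param sigma2_range length-2 variance range to span.
#' @param n_levels number of noise levels across the range.
#' @inheritParams study_design
#' @return A [study_design()] whose groups carry an extra `A` column.
#' @export
build_multicenter_preset <- function(fit, sigma2_range = c(2.5e-3, 2.9e-3),
                                     n_levels = 3L, repetitions = 10L,
                                     base_seed = 1L) {
  if (missing(fit) || !inherits(fit, "calibration_fit"))
    stop("missing calibration: run calibrate_noise() and pass its fit")
  s2 <- seq(sigma2_range[1], sigma2_range[2], length.out = n_levels)
  As <- vapply(s2, function(t) solve_A_for_variance(fit, t), 0)
  groups <- expand.grid(n_projections = c(200L, 250L), A = As)
  groups$algorithm <- "SIRT"
  groups$group <- seq_len(nrow(groups))
  design <- study_design(groups[, c("group", "algorithm", "n_projections",
                                    "A")],
                         A = As[1], repetitions = repetitions,
                         base_seed = base_seed)
  design$A_grid <- As
  design
}

#' Study configuration
#'
#' @param phantom a [phantom_spec()] (default: [fast_phantom_spec()], the
#'   single-slice fast mode).
#' @param design a [study_design()] (default: [build_table2_design()]).
#' @param extraction an [extraction_config()].
#' @param recon_iterations SIRT iteration count used inside the study
#'   (default 100: a runtime scale-down of the 500-iteration default for
#'   desk-scale studies).
#' @param detector `c(rows, cols, pixel_mm)` for the circular fast-mode
#'   geometry.
#' @param out_dir optional output directory; when given, `features.csv`,
#'   `stability_report.csv`, `rankings.csv` and `provenance.json` are
#'   written there.
#' @return Object of class `study_config`.
#' @export
study_config <- function(phantom = fast_phantom_spec(),
                         design = build_table2_design(),
                         extraction = extraction_config(),
                         recon_iterations = 100L,
                         detector = c(1, 192, 1),
                         out_dir = NULL) {
  structure(list(phantom = phantom, design = design,
                 extraction = extraction,
                 recon_iterations = as.integer(recon_iterations),
                 detector = detector, out_dir = out_dir),
            class = "study_config")
}

#' Run an end-to-end simulation study
#'
#' For every (group, repetition): forward-project the phantom, add Poisson
#' noise with the record's seed, reconstruct with the group's algorithm,
#' and extract the 86 features for every ROI. Noiseless sinograms and SIRT
#' normalization volumes are cached per distinct projection count. The
#' result is deterministic given the design's base seed.
#'
#' @param config a [study_config()].
#' @param verbose print per-group progress.
#' @return List with `features` (data.frame: metadata + 86 feature
#'   columns), `report` (a [stability_report()]), and `provenance`.
#' @export
run_study <- function(config, verbose = FALSE) {
  design <- config$design
  ph <- generate_phantom(config$phantom)
  mu <- hu_to_mu(ph$volume)
  grid <- empty_grid(dim(ph$volume$values), ph$volume$spacing,
                     ph$volume$origin)
  sino_cache <- list()
  get_sino <- function(npr) {
    key <- as.character(npr)
    if (is.null(sino_cache[[key]])) {
      geom <- build_circular_geometry(npr, detector = config$detector)
      sino_cache[[key]] <<- forward_project(mu, geom)
    }
    sino_cache[[key]]
  }
  rows <- list()
  for (gi in seq_len(nrow(design$groups))) {
    g <- design$groups[gi, ]
    A <- if ("A" %in% names(design$groups)) g$A else design$A
    sino <- get_sino(g$n_projections)
    spec <- if (g$algorithm == "SIRT")
      recon_spec("SIRT", n_iterations = config$recon_iterations)
    else recon_spec("FBP")
    if (verbose)
      message(sprintf("group %s: %s, %d projections, A = %g",
                      g$group, g$algorithm, g$n_projections, A))
    for (r in seq_len(design$repetitions)) {
      seed <- design$base_seed + 100L * as.integer(g$group) + r
      noisy <- add_poisson_noise(sino, noise_model(A, seed))
      vol <- reconstruct(noisy, spec, grid)
      for (mk in ph$masks) {
        fv <- extract_features(vol, mk, config$extraction)
        rows[[length(rows) + 1L]] <- c(
          list(group = g$group, algorithm = g$algorithm,
               n_projections = g$n_projections, A = A, seed = seed,
               repetition = r, roi = mk$name,
               tissue_class = mk$tissue_class),
          as.list(unclass(fv)))
      }
    }
  }
  features <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, check.names = FALSE)))
  report <- stability_report(features)
  prov <- list(package_version = as.character(utils::packageVersion("radphantom")),
               base_seed = design$base_seed, A = design$A,
               repetitions = design$repetitions,
               groups = design$groups,
               recon_iterations = config$recon_iterations,
               phantom_seed = config$phantom$seed,
               detector = config$detector)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(features, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    write.csv(report$table,
              file.path(config$out_dir, "stability_report.csv"),
              row.names = FALSE)
    write.csv(data.frame(rank = seq_along(report$ranking_stability),
                         stability = report$ranking_stability,
                         discriminative = report$ranking_discriminative),
              file.path(config$out_dir, "rankings.csv"), row.names = FALSE)
    jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(features = features, report = report, provenance = prov)
}

#' Rigidly perturb a phantom pose (repositioning analogue)
#'
#' In-plane rigid motion: rotation about the volume's z axis followed by a
#' translation, resampled with trilinear interpolation (nearest-neighbour
#' for masks). Emulates physically repositioning a phantom between scans.
#'
#' @param volume a [voxel_volume()].
#' @param masks list of [roi_mask()] (optional).
#' @param shift_mm length-2 in-plane translation (mm).
#' @param rot_z_deg rotation about z, degrees.
#' @param fill value for voxels sampled outside the volume (default -100).
#' @return List with perturbed `volume` and `masks`.
#' @export
perturb_pose <- function(volume, masks = list(), shift_mm = c(0, 0),
                         rot_z_deg = 0, fill = -100) {
  d <- dim(volume$values)
  sp <- volume$spacing
  th <- rot_z_deg * pi / 180
  cx <- d[1] * sp[1] / 2; cy <- d[2] * sp[2] / 2
  xs <- (seq_len(d[1]) - 0.5) * sp[1] - cx
  ys <- (seq_len(d[2]) - 0.5) * sp[2] - cy
  gx <- matrix(xs, d[1], d[2])
  gy <- matrix(ys, d[1], d[2], byrow = TRUE)
  # inverse map: output voxel samples input at rotated/shifted location
  sx <- cos(th) * (gx - shift_mm[1]) + sin(th) * (gy - shift_mm[2])
  sy <- -sin(th) * (gx - shift_mm[1]) + cos(th) * (gy - shift_mm[2])
  fx <- (sx + cx) / sp[1] - 0.5
  fy <- (sy + cy) / sp[2] - 0.5
  interp_slice <- function(sl, nearest = FALSE) {
    if (nearest) {
      ix <- round(fx) + 1L; iy <- round(fy) + 1L
      ok <- ix >= 1L & ix <= d[1] & iy >= 1L & iy <= d[2]
      out <- matrix(fill, d[1], d[2])
      out[ok] <- sl[cbind(ix[ok], iy[ok])]
      return(out)
    }
    i0 <- floor(fx); j0 <- floor(fy)
    wx <- fx - i0; wy <- fy - j0
    out <- matrix(0, d[1], d[2]); wt <- matrix(0, d[1], d[2])
    for (di in 0:1) for (dj in 0:1) {
      ii <- i0 + di + 1L; jj <- j0 + dj + 1L
      ok <- ii >= 1L & ii <= d[1] & jj >= 1L & jj <= d[2]
      w <- (if (di) wx else 1 - wx) * (if (dj) wy else 1 - wy)
      out[ok] <- out[ok] + w[ok] * sl[cbind(ii[ok], jj[ok])]
      wt[ok] <- wt[ok] + w[ok]
    }
    out[wt < 0.999] <- fill
    out
  }
  vals <- volume$values
  for (k in seq_len(d[3])) vals[, , k] <- interp_slice(volume$values[, , k])
  new_masks <- lapply(masks, function(mk) {
    m <- mk$mask
    for (k in seq_len(d[3]))
      m[, , k] <- interp_slice(mk$mask[, , k] + 0, nearest = TRUE) > 0.5
    roi_mask(m, mk$name, mk$tissue_class)
  })
  list(volume = voxel_volume(vals, spacing = sp, origin = volume$origin),
       masks = new_masks)
}
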