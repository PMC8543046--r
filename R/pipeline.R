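# End-to-end orchestration: phantom generation or sidecar input, the three
# misalignment-correction stages, surface reconstruction, tetrahedralization,
# optional activation simulation, the per-stage distance ladder, and a
# reproducibility manifest.

#' Calibrate in-plane misalignment amplitude
#'
#' Scales a template of uniform misalignment ranges (proportions tx : ty :
#' gamma fixed) so that the pooled mean distance from the perturbed contour
#' points to the ground-truth phantom surfaces hits `target` mm. A few secant
#' iterations suffice because the distance grows nearly linearly with the
#' amplitude.
#'
#' @param planes,contours the unperturbed study.
#' @param truth `make_phantom_surfaces()` output (the reference surfaces).
#' @param target desired pooled pre-correction mean distance, mm.
#' @param base_ranges range template at amplitude 1.
#' @param seed seed for the misalignment draws being calibrated.
#' @param iters secant iterations.
#' @return list with `ranges` (scaled), `amplitude`, `achieved` (mm).
#' @export
calibrate_misalignment <- function(planes, contours, truth, target = 1.8,
                                   base_ranges = list(tx = c(-5, 5), ty = c(-5, 5),
                                                      gamma = c(-7, 7)),
                                   seed = 1L, iters = 4) {
  bvhs <- list(mesh_bvh(truth$lv_endo), mesh_bvh(truth$epi))
  if (!is.null(truth$rv_endo)) bvhs <- c(bvhs, list(mesh_bvh(truth$rv_endo)))
  measure <- function(amplitude) {
    rg <- lapply(base_ranges, function(r) r * amplitude)
    inj <- inject_misalignment(planes, rg, seed = seed)
    tot <- 0; m <- 0L
    for (k in seq_along(planes)) {
      for (cc in contours[[k]]) {
        P <- contour_to_3d(cc, inj$planes[[k]])
        d <- do.call(pmin, lapply(bvhs, function(b) point_to_mesh_distance(P, b)))
        tot <- tot + sum(d); m <- m + length(d)
      }
    }
    tot / m
  }
  amp <- 1
  d <- measure(amp)
  for (it in seq_len(iters)) {
    if (abs(d - target) < 0.02) break
    amp <- amp * target / d
    d <- measure(amp)
  }
  list(ranges = lapply(base_ranges, function(r) r * amp),
       amplitude = amp, achieved = d)
}

#' Per-stage contour-to-mesh distance ladder
#'
#' For each correction stage, lifts every contour point with that stage's
#' slice poses and measures its distance to the final reconstructed surface,
#' reported per label and pooled (the pooled mean is the point-count-weighted
#' mean over labels).
#'
#' @param planes list of `slice_plane`s (original poses).
#' @param contours per-slice contour lists.
#' @param stage_thetas named list: stage name -> list of per-slice
#'   `rigid_params` (NULL entries mean identity poses).
#' @param mesh the final `surface_mesh` the distances refer to.
#' @return data.frame with columns `stage`, `label`, `mean`, `sd`, `n`.
#' @export
distance_ladder_report <- function(planes, contours, stage_thetas, mesh) {
  bvh <- mesh_bvh(mesh)
  rows <- list()
  for (st in names(stage_thetas)) {
    thetas <- stage_thetas[[st]]
    if (is.null(thetas)) thetas <- replicate(length(planes), rigid_params(),
                                             simplify = FALSE)
    pt <- mapply(apply_rigid, planes, thetas, SIMPLIFY = FALSE)
    dists <- list(); labs <- list()
    for (k in seq_along(planes)) {
      for (cc in contours[[k]]) {
        P <- contour_to_3d(cc, pt[[k]])
        dists[[length(dists) + 1L]] <- point_to_mesh_distance(P, bvh)
        labs[[length(labs) + 1L]] <- rep(cc$label, nrow(P))
      }
    }
    d <- unlist(dists); l <- unlist(labs)
    for (L in unique(l)) {
      rows[[length(rows) + 1L]] <- data.frame(stage = st, label = L,
                                              mean = mean(d[l == L]),
                                              sd = sd(d[l == L]),
                                              n = sum(l == L))
    }
    rows[[length(rows) + 1L]] <- data.frame(stage = st, label = "POOLED",
                                            mean = mean(d), sd = sd(d),
                                            n = length(d))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default pipeline configuration
#'
#' @param seed master seed.
#' @param output_dir artifact directory (NULL = nothing written).
#' @param stages stages to run, in order.
#' @param misalign_tz optional `c(lo, hi)` through-plane offsets, mm.
#' @param calibrate_to pre-correction pooled contour-to-truth distance target,
#'   mm (NULL = use `misalign_ranges` as given).
#' @param misalign_ranges in-plane misalignment ranges template.
#' @param n_sax,sax_gap,n_lax,fov_n,px_spacing acquisition layout.
#' @param ssm_samples,ssm_modes synthetic shape-model population controls.
#' @param target_edge tetrahedral element size, mm.
#' @param contours_from `"analytic"` (exact phantom contours) or `"masks"`.
#' @return nested configuration list for [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, output_dir = NULL,
                            stages = c("intensity", "contours", "ssm",
                                       "surface", "volmesh"),
                            misalign_tz = NULL, calibrate_to = 1.8,
                            misalign_ranges = list(tx = c(-5, 5), ty = c(-5, 5),
                                                   gamma = c(-7, 7)),
                            n_sax = 12, sax_gap = 8, n_lax = 4,
                            fov_n = 128, px_spacing = 1.3672,
                            ssm_samples = 200, ssm_modes = 100,
                            target_edge = 1.5,
                            contours_from = c("analytic", "masks")) {
  list(seed = as.integer(seed), output_dir = output_dir, stages = stages,
       phantom = list(n_sax = n_sax, sax_gap = sax_gap, n_lax = n_lax,
                      fov_n = fov_n, px_spacing = px_spacing,
                      misalign_ranges = misalign_ranges,
                      misalign_tz = misalign_tz, calibrate_to = calibrate_to),
       ssm = list(n_samples = ssm_samples, n_modes = ssm_modes),
       volmesh = list(target_edge = target_edge),
       contours_from = match.arg(contours_from))
}

#' Run the reconstruction pipeline on the synthetic phantom
#'
#' Generates the phantom acquisition, injects seeded (optionally calibrated)
#' misalignments, runs the configured correction stages
#' (intensity -> contours -> optional SSM), reconstructs the biventricular
#' surface, builds the tetrahedral mesh with its quality audit, and computes
#' the per-stage distance ladder. When `config$output_dir` is set, all
#' artifacts (sidecar poses per stage, contours, meshes, quality and ladder
#' CSVs, GM traces) and an md5 manifest are persisted; re-running the same
#' configuration reproduces the outputs bit-identically.
#'
#' @param config a [pipeline_config()] (or path to a YAML file with the same
#'   structure).
#' @param spec a [phantom_spec()]; default phantom when NULL.
#' @param model optional prebuilt [shape_model()] (else built from `config`).
#' @return list with `thetas` (per stage), `truth`, `recon`, `tet_mesh`,
#'   `quality`, `ladder`, `gm_traces`, `config`, and `manifest` when written.
#' @export
run_pipeline <- function(config = pipeline_config(), spec = NULL, model = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(spec)) spec <- phantom_spec()
  set.seed(config$seed)
  spec$seed <- config$seed   # pixel noise varies with the run seed too
  ph <- config$phantom
  planes <- default_study_planes(spec, n_sax = ph$n_sax, sax_gap = ph$sax_gap,
                                 n_lax = ph$n_lax, fov_n = ph$fov_n,
                                 spacing = ph$px_spacing)
  truth <- make_phantom_surfaces(spec)
  # images + masks + contours at true poses
  imgs <- lapply(planes, function(p) slice_phantom(spec, p))
  planes_px <- lapply(imgs, `[[`, "plane")
  masks <- lapply(imgs, `[[`, "mask")
  contours <- if (identical(config$contours_from, "masks")) {
    mapply(masks_to_contours, masks, planes, SIMPLIFY = FALSE)
  } else {
    lapply(planes, function(p) analytic_contours(spec, p))
  }
  # misalignment injection (calibrated amplitude when requested)
  ranges <- ph$misalign_ranges
  calib <- NULL
  if (!is.null(ph$calibrate_to)) {
    calib <- calibrate_misalignment(planes, contours, truth,
                                    target = ph$calibrate_to,
                                    base_ranges = ranges, seed = config$seed)
    ranges <- calib$ranges
  }
  if (!is.null(ph$misalign_tz)) ranges$tz <- ph$misalign_tz
  inj <- inject_misalignment(planes, ranges, seed = config$seed)
  planes_mis <- mapply(function(p, px) { p$pixels <- px$pixels; p },
                       inj$planes, planes_px, SIMPLIFY = FALSE)
  stage_thetas <- list(uncorrected = NULL)
  gm_traces <- list()
  thetas <- NULL
  in_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  if ("intensity" %in% config$stages) {
    resA <- in_stage("intensity", correct_intensity(planes_mis))
    thetas <- resA$thetas
    gm_traces$intensity <- resA$gm_trace
    stage_thetas$intensity <- thetas
  }
  if ("contours" %in% config$stages) {
    resB <- in_stage("contours", correct_contours(planes_mis, contours, thetas0 = thetas))
    thetas <- resB$thetas
    gm_traces$contours <- resB$gm_trace
    stage_thetas$contours <- thetas
  }
  fit <- NULL
  if ("ssm" %in% config$stages) {
    if (is.null(model))
      model <- make_synthetic_ssm(spec, n_samples = config$ssm$n_samples,
                                  n_modes = config$ssm$n_modes,
                                  seed = config$seed)
    pt <- if (is.null(thetas)) planes_mis
          else mapply(apply_rigid, planes_mis, thetas, SIMPLIFY = FALSE)
    pts <- list(); labs <- list()
    for (k in seq_along(planes_mis)) for (cc in contours[[k]]) {
      pts[[length(pts) + 1L]] <- contour_to_3d(cc, pt[[k]])
      labs[[length(labs) + 1L]] <- rep(cc$label, nrow(cc$points))
    }
    fit <- in_stage("ssm", fit_ssm(model, do.call(rbind, pts), unlist(labs)))
    resC <- in_stage("ssm", align_slices_to_model(planes_mis, contours, fit,
                                                  thetas0 = thetas))
    thetas <- resC$thetas
    stage_thetas$ssm <- thetas
    # the fitted model is now discarded: downstream sees only re-posed slices
  }
  recon <- in_stage("surface", reconstruct_surfaces(planes_mis, contours, thetas))
  tet <- NULL; qual <- NULL
  if ("volmesh" %in% config$stages) {
    tet <- in_stage("volmesh",
                    tetrahedralize(recon$biventricular,
                                   target_edge = config$volmesh$target_edge))
    qual <- quality_summary(tet)
  }
  ladder <- distance_ladder_report(planes_mis, contours, stage_thetas,
                                   recon$biventricular)
  out <- list(planes = planes_mis, contours = contours, injected = inj,
              calibration = calib, thetas = stage_thetas, truth = truth,
              ssm_fit = if (is.null(fit)) NULL else fit["residual"],
              recon = recon, tet_mesh = tet, quality = qual, ladder = ladder,
              gm_traces = gm_traces, config = config)
  if (!is.null(config$output_dir)) out$manifest <- .write_artifacts(out)
  invisible(out)
}

.write_artifacts <- function(run) {
  dir <- run$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wp <- function(fun, obj, name, ...) {
    path <- file.path(dir, name)
    fun(obj, path, ...)
    files <<- c(files, path)
    path
  }
  wp(write_geometry_sidecar, run$planes, "slices.json")
  wp(function(o, p) write_contours_json(o, run$planes, p), run$contours, "contours.json")
  for (st in names(run$thetas)) {
    th <- run$thetas[[st]]
    if (is.null(th)) next
    df <- do.call(rbind, lapply(th, function(t)
      data.frame(tx = t$tx, ty = t$ty, tz = t$tz, alpha = t$alpha,
                 beta = t$beta, gamma = t$gamma)))
    wp(function(o, p) write.csv(o, p, row.names = FALSE), df,
       sprintf("poses_%s.csv", st))
  }
  wp(write_ply, run$recon$biventricular, "biventricular.ply")
  wp(write_ply, run$recon$lv_endo, "lv_endo.ply")
  wp(write_ply, run$recon$epi, "epi.ply")
  if (!is.null(run$recon$rv_endo)) wp(write_ply, run$recon$rv_endo, "rv_endo.ply")
  if (!is.null(run$tet_mesh)) {
    wp(write_vtk_tets, run$tet_mesh, "tet_mesh.vtk")
    wp(function(o, p) write.csv(o, p, row.names = FALSE),
       data.frame(knupp = run$quality$indices), "quality.csv")
  }
  wp(function(o, p) write.csv(o, p, row.names = FALSE), run$ladder, "ladder.csv")
  for (st in names(run$gm_traces)) {
    wp(function(o, p) write.csv(data.frame(sweep = seq_along(o), gm = o), p,
                                row.names = FALSE),
       run$gm_traces[[st]], sprintf("gm_trace_%s.csv", st))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("cinemesh")),
                   seed = run$config$seed,
                   config = run$config[setdiff(names(run$config), "output_dir")],
                   files = as.list(unname(tools::md5sum(files))))
  names(manifest$files) <- basename(files)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  manifest
}
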