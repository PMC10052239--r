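#' Default pipeline configuration
#'
#' One structured, fully serializable configuration drives the end-to-end
#' workflow; a run's effective configuration is written next to its
#' outputs and every numeric artifact is traceable to its hash. All
#' randomness flows from the single root `seed`.
#'
#' @param out_dir artifact directory.
#' @param seed root RNG seed.
#' @param ... overrides of the nested stage settings (`simulate`,
#'   `preprocess`, `register`, `decompose`, `opls`, `fuse`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 0, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed, log_level = "info",
    simulate = list(enabled = TRUE, grid = c(64, 64), upscale = 2,
                    block_widths = c(60, 50, 20), n_features = 6,
                    feature_diameter = c(50, 100)),
    preprocess = list(noise_factor = 0, normalize = TRUE),
    register = list(enabled = TRUE, n_control_points = 5,
                    control_point_jitter = 0, max_iterations = 100),
    decompose = list(n_global = 1, n_local = list("1,2" = 1),
                     n_unique = 1),
    opls = list(n_predictive = 2, n_orthogonal = 1, vip_threshold = 1),
    fuse = list(enabled = TRUE, max_ions = 5, n_comp = 8))
  utils::modifyList(cfg, list(...))
}

config_hash <- function(cfg) {
  # polynomial rolling hash over the serialized JSON: provenance tag, not
  # a cryptographic digest (none is available offline)
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 268435456
  sprintf("%07x", h)
}

plog <- function(state, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  cat(msg, "\n", file = state$log, append = TRUE)
  invisible(NULL)
}

stage_done <- function(state, stage) {
  marker <- file.path(state$dir, stage, ".done.json")
  if (!file.exists(marker)) return(FALSE)
  done <- jsonlite::read_json(marker)
  identical(done$config_hash, state$hash)
}

mark_done <- function(state, stage, extra = list()) {
  jsonlite::write_json(
    c(list(stage = stage, config_hash = state$hash), extra),
    file.path(state$dir, stage, ".done.json"),
    auto_unbox = TRUE, digits = NA)
}

#' Run the end-to-end multimodal imaging pipeline
#'
#' Executes the stages in order — simulate (or load inputs), preprocess,
#' register, assemble + OnPLS decomposition, OPLS/VIP, fusion — each
#' emitting artifacts under `config$out_dir/<stage>/`. A completed stage
#' whose configuration hash matches is skipped on resume, so rerunning a
#' finished pipeline performs no recomputation; a stage failure halts with
#' a stage-named diagnostic and preserves partial outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the stage outputs and the artifact
#'   directory; exit status is signalled by error vs normal return.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- list(dir = config$out_dir,
                hash = config_hash(config),
                log = file.path(config$out_dir, "pipeline.log"))
  jsonlite::write_json(config,
                       file.path(config$out_dir, "effective_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  plog(state, "pipeline start, config hash %s, root seed %d",
       state$hash, config$seed)
  run_stage <- function(stage, fun) {
    sdir <- file.path(state$dir, stage)
    dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
    if (stage_done(state, stage)) {
      plog(state, "stage %s: up to date, skipped", stage)
      return(jsonlite::read_json(file.path(sdir, ".done.json")))
    }
    plog(state, "stage %s: running", stage)
    out <- tryCatch(fun(sdir),
                    error = function(e)
                      stop(sprintf("stage '%s' failed: %s", stage,
                                   conditionMessage(e)), call. = FALSE))
    mark_done(state, stage, out)
    plog(state, "stage %s: done", stage)
    out
  }

  # -- simulate ------------------------------------------------------
  sim <- run_stage("simulate", function(sdir) {
    if (!isTRUE(config$simulate$enabled)) {
      if (is.null(config$inputs))
        stop("simulate disabled and no `inputs` provided in config")
      return(config$inputs)
    }
    set.seed(config$seed)
    spec <- phantom_spec(grid = unlist(config$simulate$grid),
                         upscale = config$simulate$upscale,
                         block_widths = unlist(config$simulate$block_widths),
                         n_features = config$simulate$n_features,
                         feature_diameter =
                           unlist(config$simulate$feature_diameter),
                         seed = config$seed)
    paths <- write_fixture_suite(sdir, spec)
    lapply(paths, as.character)
  })

  # -- preprocess ----------------------------------------------------
  pre <- run_stage("preprocess", function(sdir) {
    set.seed(config$seed + 1)
    tags <- c("lipid_neg", "lipid_pos", "peptide")
    out <- list()
    for (b in 1:3) {
      cube <- read_imzml(sim[[sprintf("msi_block%d", b)]],
                         modality = tags[b])
      if (config$preprocess$noise_factor > 0)
        cube <- peak_extract(cube, config$preprocess$noise_factor)
      if (isTRUE(config$preprocess$normalize))
        cube <- rms_normalize(cube)
      p <- file.path(sdir, sprintf("block%d.imzML", b))
      write_imzml(cube, p, skip_black = TRUE)
      out[[sprintf("block%d", b)]] <- p
    }
    out
  })

  truth <- jsonlite::read_json(sim$truth, simplifyVector = TRUE)

  # -- register ------------------------------------------------------
  reg <- run_stage("register", function(sdir) {
    set.seed(config$seed + 2)
    tags <- c("lipid_neg", "lipid_pos", "peptide")
    cubes <- lapply(1:3, function(b)
      read_imzml(pre[[sprintf("block%d", b)]], modality = tags[b]))
    out <- list(block1 = pre$block1)
    metrics <- list()
    for (b in 2:3) {
      if (!isTRUE(config$register$enabled)) {
        out[[sprintf("block%d", b)]] <- pre[[sprintf("block%d", b)]]
        next
      }
      tt <- affine2d(matrix(unlist(truth$transforms[[sprintf("block%d", b)]]),
                            3, 3))
      pts_fixed <- control_points_on_mask(dim(cubes[[1]]$values)[1:2],
                                          config$register$n_control_points)
      pts_moving <- transform_points(invert_affine(tt), pts_fixed)
      jit <- config$register$control_point_jitter
      if (jit > 0)
        pts_moving <- pts_moving +
          matrix(stats::runif(length(pts_moving), -jit, jit),
                 ncol = 2)
      rr <- register_modalities(
        cubes[[1]], cubes[[b]],
        control_points = list(fixed = pts_fixed, moving = pts_moving),
        config = list(seed = config$seed,
                      max_iterations = config$register$max_iterations))
      p <- file.path(sdir, sprintf("block%d_registered.imzML", b))
      write_imzml(rr$registered_cube, p, skip_black = TRUE)
      jsonlite::write_json(
        list(matrix = rr$transform$matrix,
             metrics = rr$result$final_metrics),
        file.path(sdir, sprintf("block%d_transform.json", b)),
        auto_unbox = TRUE, digits = NA)
      out[[sprintf("block%d", b)]] <- p
      metrics[[sprintf("block%d", b)]] <- rr$result$final_metrics
    }
    c(out, list(metrics = metrics))
  })

  # -- decompose -----------------------------------------------------
  dec <- run_stage("decompose", function(sdir) {
    set.seed(config$seed + 3)
    tags <- c("lipid_neg", "lipid_pos", "peptide")
    cubes <- lapply(1:3, function(b)
      read_imzml(reg[[sprintf("block%d", b)]], modality = tags[b]))
    ds <- assemble_multimodal(cubes)
    ds <- center_scale(ds, "mean_center")
    n_local <- config$decompose$n_local
    model <- fit_onpls(ds, n_global = config$decompose$n_global,
                       n_local = n_local,
                       n_unique = unlist(config$decompose$n_unique))
    vs <- do.call(rbind, lapply(model$variance_shares, function(v)
      as.data.frame(as.list(v))))
    vs$block <- seq_len(nrow(vs))
    utils::write.csv(vs, file.path(sdir, "variance_shares.csv"),
                     row.names = FALSE)
    for (b in seq_along(cubes)) {
      img <- onpls_score_images(model, "global", 1)[[b]]
      utils::write.table(img,
                         file.path(sdir, sprintf("tg1_block%d.csv", b)),
                         sep = ",", row.names = FALSE, col.names = FALSE)
    }
    list(variance_shares = file.path(sdir, "variance_shares.csv"))
  })

  # -- OPLS / VIP ----------------------------------------------------
  vip_out <- run_stage("opls_vip", function(sdir) {
    set.seed(config$seed + 4)
    tags <- c("lipid_neg", "lipid_pos", "peptide")
    cubes <- lapply(1:3, function(b)
      read_imzml(reg[[sprintf("block%d", b)]], modality = tags[b]))
    ds <- assemble_multimodal(cubes)
    ds_uv <- center_scale(ds, "unit_variance")
    x <- concat_blocks(ds_uv)
    hyper <- read_hyperspectral_csv(sim$hyperspectral)
    t_h <- affine2d(matrix(unlist(truth$transform_hyper), 3, 3))
    y <- downsample_hyperspectral(hyper, ds$partition, t_h)
    model <- fit_opls(x, y, n_predictive = config$opls$n_predictive,
                      n_orthogonal = config$opls$n_orthogonal)
    v <- vip(model, threshold = config$opls$vip_threshold)
    utils::write.csv(
      data.frame(variable = x$variables, vip = unname(v$vip),
                 selected = unname(v$selected)),
      file.path(sdir, "vip.csv"), row.names = FALSE)
    list(vip = file.path(sdir, "vip.csv"),
         n_selected = sum(v$selected))
  })

  # -- fuse ----------------------------------------------------------
  fus <- run_stage("fuse", function(sdir) {
    if (!isTRUE(config$fuse$enabled)) return(list(skipped = TRUE))
    set.seed(config$seed + 5)
    tags <- c("lipid_neg", "lipid_pos", "peptide")
    cubes <- lapply(1:3, function(b)
      read_imzml(reg[[sprintf("block%d", b)]], modality = tags[b]))
    ds <- assemble_multimodal(cubes)
    ds_uv <- center_scale(ds, "unit_variance")
    x <- concat_blocks(ds_uv)
    vt <- utils::read.csv(vip_out$vip)
    vres <- structure(list(vip = vt$vip, selected = vt$selected,
                           threshold = config$opls$vip_threshold),
                      class = "vip_result")
    xs <- select_variables(x, vres)
    if (ncol(xs$values) > config$fuse$max_ions) {
      keep <- order(vt$vip[vt$selected], decreasing = TRUE)[
        seq_len(config$fuse$max_ions)]
      xs$values <- xs$values[, keep, drop = FALSE]
      xs$variables <- xs$variables[keep]
    }
    hyper <- read_hyperspectral_csv(sim$hyperspectral)
    t_h <- affine2d(matrix(unlist(truth$transform_hyper), 3, 3))
    fm <- fuse(xs, hyper, t_h, config = list(n_comp = config$fuse$n_comp))
    fusion_report(fm, sdir)
    list(scores = file.path(sdir, "reconstruction_scores.csv"))
  })

  plog(state, "pipeline complete")
  invisible(list(simulate = sim, preprocess = pre, register = reg,
                 decompose = dec, opls_vip = vip_out, fuse = fus,
                 out_dir = config$out_dir, config_hash = state$hash))
}

# deterministic, well-spread control points inside the central tissue area
control_points_on_mask <- function(grid, n = 5) {
  h <- grid[1]; w <- grid[2]
  base <- cbind(
    x = w * c(0.5, 0.3, 0.7, 0.35, 0.65, 0.5, 0.4, 0.6),
    y = h * c(0.5, 0.35, 0.35, 0.68, 0.68, 0.3, 0.55, 0.45))
  base[seq_len(min(n, nrow(base))), , drop = FALSE]
}
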