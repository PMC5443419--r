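#' Pipeline configuration
#'
#' Reads a YAML configuration covering phantom, noise, preprocessing and
#' reconstruction settings, filling unspecified keys with the package
#' defaults. Unknown top-level keys are an error (schema check).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Named list of top-level overrides (e.g. from CLI flags);
#'   recorded in the run manifest.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L,
    out_dir = "ccodot_run",
    phantom = list(spacing = 2, size_mm = c(120, 72, 40),
                   blob = list(center = NULL, radius = 15,
                               amplitudes = c(HbO2 = 1.0, HHb = -0.3,
                                              oxCCO = 0.1))),
    noise = list(sd = 5e-4),
    preprocess = list(low_hz = 0.01, high_hz = 0.25, order = 5,
                      grid_nm = seq(740, 900, by = 10)),
    reconstruction = list(lambda_reg = 1e-4, max_iter = 50, tol = 1e-5,
                          background = c(HbO2 = 56, HHb = 24, oxCCO = 12.8),
                          frames_s = c(2, 10, 20, 30, 40)),
    residuals = list(time_s = 20)
  )
  cfg <- defaults
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  merge <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
        merge(base[[k]], upd[[k]]) else upd[[k]]
    }
    base
  }
  cfg <- merge(cfg, user)
  cfg <- merge(cfg, overrides)
  cfg$overrides <- overrides
  class(cfg) <- "pipeline_config"
  cfg
}

.stage_order <- c("simulate", "preprocess", "spectroscopy", "reconstruct",
                  "residuals")

#' Run the synthetic DOT pipeline
#'
#' Orchestrates simulate -> preprocess -> spectroscopy -> reconstruct ->
#' residuals on the synthetic phantom described by the configuration,
#' writing each stage's outputs to `out_dir` before the next stage starts,
#' and finally a run manifest (JSON) with the config snapshot, seed, output
#' file hashes, per-stage timings and solver iteration counts. Stages are
#' deterministic given the seed, so re-running an unchanged configuration
#' reproduces identical hashes for all deterministic outputs.
#'
#' @param config A `pipeline_config`, or a YAML path.
#' @param stages Subset of stages to run, in dependency order; an empty
#'   character vector validates the config and returns it without outputs.
#' @param quiet Suppress progress messages.
#' @return The run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = .stage_order,
                         quiet = FALSE) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (length(stages) == 0)
    return(invisible(list(config = unclass(config), outputs = list())))
  stages <- match.arg(stages, .stage_order, several.ok = TRUE)
  stages <- .stage_order[.stage_order %in% stages]
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[ccodot] ", ...)

  manifest <- list(config = unclass(config), seed = config$seed,
                   stages = list(), outputs = list(),
                   versions = list(ccodot = as.character(
                     utils::packageVersion("ccodot")), R = R.version.string))
  state <- new.env(parent = emptyenv())

  record <- function(stage, t0, files, extra = list()) {
    manifest$stages[[stage]] <<- c(list(
      seconds = round(as.numeric(Sys.time()) - t0, 3)), extra)
    for (f in files)
      manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
  }

  for (stage in stages) {
    t0 <- as.numeric(Sys.time())
    say("stage: ", stage)
    switch(stage,
      simulate = {
        ph <- phantom_default(spacing = config$phantom$spacing,
                              size_mm = unlist(config$phantom$size_mm))
        bl <- config$phantom$blob
        center <- if (is.null(bl$center)) ph$blob$center
                  else unlist(bl$center)
        ph$blob <- activation_blob(center, bl$radius, unlist(bl$amplitudes))
        sim <- simulate_experiment(ph$geometry, ph$optics, ph$array, ph$blob,
                                   ph$paradigm,
                                   noise = noise_model(config$noise$sd,
                                                       seed = config$seed))
        state$phantom <- ph; state$sim <- sim
        f1 <- file.path(out, "intensity.csv")
        write_series_csv(sim$intensity, f1)
        write_array_csv(ph$array, file.path(out, "array"))
        f2 <- file.path(out, "paradigm.json")
        jsonlite::write_json(unclass(ph$paradigm), f2, auto_unbox = TRUE,
                             digits = NA)
        f3 <- write_image_nifti(sim$truth, out, "truth")
        f4 <- file.path(out, "labels.nii.gz")
        write_labels_nifti(ph$geometry, f4)
        record(stage, t0, c(f1, file.path(out, c("array_optodes.csv",
                                                 "array_channels.csv")),
                            f2, f3, f4))
      },
      preprocess = {
        if (is.null(state$sim)) {
          f <- file.path(out, "intensity.csv")
          if (!file.exists(f))
            stop("missing upstream output for 'preprocess': ", f)
          state$phantom <- phantom_default(
            spacing = config$phantom$spacing,
            size_mm = unlist(config$phantom$size_mm))
          state$sim <- list(intensity = read_series_csv(f))
        }
        pp <- config$preprocess
        atten <- intensity_to_attenuation(state$sim$intensity)
        filt <- bandpass(atten, pp$low_hz, pp$high_hz, pp$order)
        blocked <- block_average(filt, paradigm())
        sel <- select_wavelengths(blocked, unlist(pp$grid_nm))
        state$block <- sel
        f <- file.path(out, "attenuation_block.csv")
        write_series_csv(sel, f)
        record(stage, t0, f)
      },
      spectroscopy = {
        .require_state(state, "block", out, "attenuation_block.csv",
                       read_series_csv)
        E <- extinction_matrix(c("HbO2", "HHb", "oxCCO"),
                               state$block$wavelengths_nm)
        dists <- channel_distances(state$phantom$array)
        conc <- ucln_fit(state$block, E, dists)
        f <- file.path(out, "spectroscopy.csv")
        write_concentrations_csv(conc, f)
        state$conc <- conc
        record(stage, t0, f)
      },
      reconstruct = {
        .require_state(state, "block", out, "attenuation_block.csv",
                       read_series_csv)
        rc <- config$reconstruction
        ph <- state$phantom
        jacs <- lapply(state$block$wavelengths_nm, function(wl)
          compute_jacobian(ph$geometry, ph$optics, ph$array, wl))
        E3 <- extinction_matrix(c("HbO2", "HHb", "oxCCO"),
                                state$block$wavelengths_nm)
        sys3 <- multispectral_system(jacs, E3)
        cfg3 <- recon_config(rc$lambda_reg, unlist(rc$background),
                             rc$max_iter, rc$tol)
        files <- character(0); iters <- integer(0)
        state$images3 <- list()
        nt <- dim(state$block$data)[3]
        for (fr in unlist(rc$frames_s)) {
          # the final frame of the epoch window stands in for t = epoch end
          k <- min(round(fr * state$block$sample_rate) + 1L, nt)
          img <- reconstruct(state$block$data[, , k], sys3, cfg3)
          img$time_s <- fr
          state$images3[[as.character(fr)]] <- img
          files <- c(files, write_image_nifti(img, out,
                                              paste0("recon_t", fr)))
          iters <- c(iters, attr(img, "iterations"))
        }
        state$sys3 <- sys3
        record(stage, t0, files, list(iterations = iters))
      },
      residuals = {
        if (is.null(state$sys3))
          stop("missing upstream output for 'residuals': run 'reconstruct'",
               " in the same call")
        rc <- config$reconstruction
        tR <- config$residuals$time_s
        k <- min(round(tR * state$block$sample_rate) + 1L,
                 dim(state$block$data)[3])
        E2 <- extinction_matrix(c("HbO2", "HHb"),
                                state$block$wavelengths_nm)
        jacs2 <- lapply(seq_along(state$sys3$wavelengths), function(l)
          structure(list(J = state$sys3$jacobians[[l]],
                         wavelength = state$sys3$wavelengths[l],
                         grid = state$sys3$grid),
                    class = "wavelength_jacobian"))
        sys2 <- multispectral_system(jacs2, E2)
        cfg2 <- recon_config(rc$lambda_reg,
                             unlist(rc$background)[c("HbO2", "HHb")],
                             rc$max_iter, rc$tol)
        frame <- state$block$data[, , k]
        img3 <- state$images3[[as.character(tR)]]
        if (is.null(img3)) img3 <- reconstruct(frame, state$sys3,
          recon_config(rc$lambda_reg, unlist(rc$background), rc$max_iter,
                       rc$tol))
        img2 <- reconstruct(frame, sys2, cfg2)
        res <- residual_difference(frame, img3, img2, state$sys3, sys2,
                                   time_s = tR)
        f <- file.path(out, "residuals.csv")
        utils::write.csv(tidy_residuals(res), f, row.names = FALSE)
        record(stage, t0, f)
      })
  }
  mf <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null")
  say("manifest: ", mf)
  invisible(manifest)
}

.require_state <- function(state, field, out, filename, reader) {
  if (!is.null(state[[field]])) return(invisible())
  f <- file.path(out, filename)
  if (!file.exists(f))
    stop("missing upstream output: ", f)
  state[[field]] <- reader(f)
  if (is.null(state$phantom)) state$phantom <- phantom_default()
  invisible()
}
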