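#' Pipeline configuration
#'
#' Collects every knob of the end-to-end workflow: simulation conditions,
#' landscape size, cleaning thresholds, HMM restarts, buffer radii, available
#' points per stratum and the correlation-screen threshold. All stages derive
#' their randomness from `seed`.
#'
#' @param outdir Output directory for artifacts (created if missing).
#' @param seed Integer master seed.
#' @param sim A [sim_config()]; its own seed is overridden by `seed`.
#' @param n_rows,n_cols Landscape grid size (30-m cells).
#' @param dop_max DOP retention threshold.
#' @param buffers A [buffer_spec()].
#' @param n_available Available points per stratum.
#' @param n_restarts HMM optimizer restarts.
#' @param hmm_init Starting values for the HMM ([default_hmm_init()]).
#' @param cor_threshold Correlation-screen flag threshold.
#' @param min_strata Smallest period x state block worth fitting.
#' @param write_grids Also write landscape/raster grids as TSV?
#' @return A `recursel_pipeline_config` list.
#' @export
pipeline_config <- function(outdir = file.path(tempdir(), "recursel_run"),
                            seed = 1L,
                            sim = sim_config(),
                            n_rows = 60, n_cols = 60,
                            dop_max = 7,
                            buffers = buffer_spec(),
                            n_available = 100,
                            n_restarts = 2,
                            hmm_init = default_hmm_init(),
                            cor_threshold = 0.7,
                            min_strata = 30,
                            write_grids = FALSE) {
  sim$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 n_rows = n_rows, n_cols = n_cols, dop_max = dop_max,
                 buffers = buffers, n_available = n_available,
                 n_restarts = n_restarts, hmm_init = hmm_init,
                 cor_threshold = cor_threshold, min_strata = min_strata,
                 write_grids = write_grids),
            class = "recursel_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML file override the [pipeline_config()] defaults;
#' `sim:` entries override the [sim_config()] defaults (matrix-valued
#' parameters are given row-wise).
#'
#' @param path YAML file path.
#' @return A `recursel_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  for (m in c("transition_matrix", "gamma_params", "vm_params")) {
    if (!is.null(sim_args[[m]])) {
      sim_args[[m]] <- matrix(unlist(sim_args[[m]]),
                              nrow = length(sim_args[[m]]), byrow = TRUE)
    }
  }
  sim <- do.call(sim_config, sim_args)
  top <- y[setdiff(names(y), "sim")]
  if (!is.null(top$buffers)) top$buffers <- do.call(buffer_spec, as.list(top$buffers))
  do.call(pipeline_config, c(top, list(sim = sim)))
}

pipeline_stage <- function(name, expr) {
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
  res
}

#' Run the full pipeline
#'
#' Executes simulate -> preprocess -> HMM -> recursion -> rasters -> strata ->
#' model selection in order, writes the artifacts to `config$outdir`, and
#' returns all intermediate objects together with a manifest (file, bytes,
#' md5, seed) that makes reruns verifiable: the same config and seed
#' reproduce identical hashes.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return List: `landscape`, `fixes`, `clean`, `steps`, `hmm_fit`, `decoded`,
#'   `state_props`, `recursion`, `rasters`, `strata`, `screens`, `blocks`
#'   (model tables keyed `period.state.metric`), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "recursel_pipeline_config"))
  t0 <- Sys.time()
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0)),
                        sprintf(fmt, ...))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  say("simulate: landscape %dx%d + %d brood(s)", config$n_rows, config$n_cols,
      config$sim$n_broods)
  landscape <- pipeline_stage("simulate",
    generate_landscape(config$n_rows, config$n_cols, seed = config$seed))
  fixes <- pipeline_stage("simulate", simulate_broods(config$sim, landscape))

  say("preprocess: %d raw fixes", nrow(fixes))
  clean <- pipeline_stage("preprocess",
    fixes |> filter_dop(config$dop_max) |> drop_roost_fixes())
  steps <- pipeline_stage("preprocess", build_steps(clean))

  say("hmm: fitting 3 states to %d steps", nrow(steps))
  hmm_fit <- pipeline_stage("hmm",
    fit_hmm(steps, init = config$hmm_init, n_restarts = config$n_restarts,
            seed = config$seed))
  decoded <- pipeline_stage("hmm", viterbi(hmm_fit, steps))
  state_props <- state_proportions(decoded$merged)

  say("recursion: per-fix statistics")
  clean_st <- pipeline_stage("recursion", fix_states(clean, decoded))
  recursion <- pipeline_stage("recursion",
    recursion_stats(clean_st, config$buffers))

  say("rasters: recursion intensity maps")
  rasters <- pipeline_stage("rasters",
    build_recursion_rasters(clean_st, recursion, landscape, config$buffers))
  dist <- pipeline_stage("rasters", distance_rasters(landscape))

  say("ssf: strata with %d available points each", config$n_available)
  strata <- pipeline_stage("ssf",
    build_strata(decoded, hmm_fit, landscape, dist, rasters,
                 n_available = config$n_available, seed = config$seed))

  say("select: candidate models per period x state x metric")
  blocks <- list()
  screens <- list()
  model_cols <- c("dist_roads", "dist_hardwood", "dist_mixed", "ndvi",
                  "dist_open", "dist_pine", "dist_shrub", "revisit", "residence")
  for (period in c("ground", "tree")) {
    for (state in c("restricted", "mobile")) {
      sub <- dplyr::filter(strata, .data$period == !!period, .data$state == !!state)
      ns <- length(unique(sub$stratum_id))
      if (ns < config$min_strata) {
        warn(sprintf("block %s/%s has only %d strata; skipped", period, state, ns))
        next
      }
      sc <- pipeline_stage("select", scale_center(sub, cols = model_cols))
      key0 <- paste(period, state, sep = ".")
      screens[[key0]] <- suppressWarnings(
        correlation_screen(sc$table, cols = model_cols,
                           threshold = config$cor_threshold))
      for (metric in c("revisit", "residence")) {
        fits <- list()
        for (spec in candidate_set(period, state, metric)) {
          f <- tryCatch(fit_ssf(sc$table, spec),
                        error = function(e) {
                          warn(sprintf("fit %s (%s.%s.%s) failed: %s", spec$name,
                                       period, state, metric, conditionMessage(e)))
                          NULL
                        })
          if (!is.null(f)) fits[[spec$name]] <- f
        }
        if (length(fits) == 0) {
          abort(sprintf("pipeline stage 'select' failed: no model of block %s.%s.%s could be fitted",
                        period, state, metric))
        }
        blocks[[paste(period, state, metric, sep = ".")]] <-
          report_block(fits, sc$table)
      }
    }
  }

  say("write: artifacts -> %s", config$outdir)
  manifest <- write_artifacts(config, landscape, clean_st, decoded, hmm_fit,
                              recursion, rasters, blocks)
  say("done: %d model block(s), %d strata", length(blocks),
      length(unique(strata$stratum_id)))
  list(landscape = landscape, fixes = fixes, clean = clean_st, steps = steps,
       hmm_fit = hmm_fit, decoded = decoded, state_props = state_props,
       recursion = recursion, rasters = rasters, strata = strata,
       screens = screens, blocks = blocks, manifest = manifest)
}

write_artifacts <- function(config, landscape, clean_st, decoded, hmm_fit,
                            recursion, rasters, blocks) {
  out <- config$outdir
  paths <- character()
  add <- function(p) { paths[[length(paths) + 1]] <<- p; p }

  write_fixes(clean_st, add(file.path(out, "fixes_clean.csv")))
  dd <- decoded
  dd$t_end <- format(dd$t_end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(dd, add(file.path(out, "steps_decoded.csv")), row.names = FALSE)
  write_hmm_fit(hmm_fit, add(file.path(out, "hmm_fit.json")))
  write.csv(as.data.frame(recursion), add(file.path(out, "recursion_stats.csv")),
            row.names = FALSE)
  for (key in names(blocks)) {
    write_model_table(blocks[[key]],
                      add(file.path(out, sprintf("model_table_%s.csv", key))))
  }
  if (config$write_grids) {
    write_grid_tsv(landscape$landcover, landscape$origin, landscape$cell_size,
                   add(file.path(out, "landcover.tsv")))
    write_grid_tsv(landscape$ndvi, landscape$origin, landscape$cell_size,
                   add(file.path(out, "ndvi.tsv")))
    for (b in names(rasters)) {
      for (s in names(rasters[[b]])) {
        for (m in names(rasters[[b]][[s]])) {
          r <- rasters[[b]][[s]][[m]]
          write_grid_tsv(r$values, r$origin, r$cell_size,
                         add(file.path(out, sprintf("%s_%s_%s.tsv", b, s, m))))
        }
      }
    }
  }
  paths <- unlist(paths)
  manifest <- tibble::tibble(
    file = basename(paths),
    bytes = file.size(paths),
    md5 = unname(tools::md5sum(paths)),
    seed = config$seed)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
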