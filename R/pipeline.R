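# Pipeline presets, configuration and provenance.
#
# Configuration is JSON (read with jsonlite) rather than a binary or
# session-dependent format, so a run is fully described by one text file
# plus the global seed; every stochastic step derives from that seed and
# all outputs are deterministic given (config, seed).

#' Build a run configuration
#'
#' @param preset `"trunk-demo"` (linear dispersal, two groups, ANCOVA) or
#'   `"tip-demo"` (quadratic dispersal, three groups, pairwise Hotelling
#'   T-squared with FDR), or `NULL` for a fully manual config.
#' @param seed global seed; every stochastic stage derives its seed from it.
#' @param overrides named list of config entries that replace preset
#'   defaults (nested lists are merged shallowly).
#' @return a `run_config` list.
#' @export
run_config <- function(preset = "trunk-demo", seed = 1, overrides = list()) {
  base <- list(
    seed = as.integer(seed),
    dt = 10,                 # min/frame
    pixel_size = 0.5,        # um/px, metadata
    stages = c("simulate", "piv", "similarity", "dispersal"),
    flow = list(kind = "rotation", angular_rate = 0.04,
                shape = c(13, 160, 160), n_frames = 3, density = 0.02,
                particle_sigma = 1.5, noise_sigma = 0.05),
    piv = list(window = c(32, 32, 7), overlap = c(8, 8, 3),
               margin = c(10, 10, 3)),
    similarity = list(mode = "normalized", n_lines = 3, axis = "x"),
    dispersal = list(radius = 15, min_size = 4, max_size = 8,
                     region = "trunk", window_hours = 8),
    tips = list(n_trees = 3, n_bifurcations = 5, noise_sigma = 5)
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("trunk-demo", "tip-demo"))
    if (preset == "trunk-demo") {
      base$groups <- list(
        control = list(model = list(type = "linear", a = 0.045, b = 8),
                       n_clusters = 6),
        mutant  = list(model = list(type = "linear", a = 0.015, b = 8),
                       n_clusters = 6))
      base$dispersal$region <- "trunk"
      base$dispersal$window_hours <- 8
    } else {
      base$groups <- list(
        control = list(model = list(type = "quadratic", a = 4e-4, b = 0.02, c = 6),
                       n_clusters = 12),
        mutant  = list(model = list(type = "quadratic", a = 1e-4, b = 0.005, c = 6),
                       n_clusters = 12),
        treated = list(model = list(type = "quadratic", a = 3.5e-4, b = 0.018, c = 6),
                       n_clusters = 12))
      base$dispersal$region <- "tip"
      base$dispersal$window_hours <- 2
    }
    base$preset <- preset
  }
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(base[[nm]]))
      for (k in names(overrides[[nm]])) base[[nm]][[k]] <- overrides[[nm]][[k]]
    else base[[nm]] <- overrides[[nm]]
  }
  structure(base, class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  assert_that(file.exists(path), "config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(preset = cfg$preset %||% NULL, seed = cfg$seed %||% 1,
             overrides = cfg[setdiff(names(cfg), c("preset", "seed"))])
}

# derive a child seed from the global seed; keeps values in 32-bit range
derive_seed <- function(seed, k) (as.integer(seed) * 1103L + k * 12347L) %% 2147483629L

#' Run the analysis pipeline
#'
#' Executes the selected stages in order (simulate, piv, similarity,
#' dispersal, tips), collects numeric results into a JSON report, and
#' writes a provenance record (tool version, config hash, warnings,
#' timestamp) alongside. The report contains only computed numbers and is
#' byte-identical across runs with the same config and seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return list with `report` (named list), `report_path`,
#'   `provenance_path`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("morphoflow_run_")) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(preset = config$preset %||% "custom", seed = config$seed)
  warnings_log <- character(0)
  run_stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop_mf("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  sim <- NULL
  if ("simulate" %in% config$stages) {
    sim <- run_stage("simulate", {
      piv_p <- do.call(piv_params, config$piv)
      fargs <- config$flow
      fargs$seed <- derive_seed(config$seed, 1L)
      movie <- generate_flow_movie(do.call(flow_spec, fargs), piv = piv_p)
      groups <- list()
      for (gi in seq_along(config$groups)) {
        g <- config$groups[[gi]]
        n_frames <- round(config$dispersal$window_hours * 60 / config$dt) + 1
        spec <- cluster_dynamics_spec(
          n_clusters = g$n_clusters, model = g$model, dt = config$dt,
          n_frames = n_frames, jitter_sigma = g$jitter_sigma %||% 0.5,
          seed = derive_seed(config$seed, 100L + gi))
        groups[[names(config$groups)[gi]]] <- generate_cluster_trajectories(spec)
      }
      list(movie = movie, groups = groups, piv_p = piv_p)
    })
    report$simulate <- list(
      n_groups = length(sim$groups),
      movie_frames = length(sim$movie$volumes),
      movie_shape = sim$movie$volumes$dim)
  }
  if ("piv" %in% config$stages) {
    assert_that(!is.null(sim), "piv stage needs the simulate stage")
    piv_out <- run_stage("piv", {
      f <- sim$movie$volumes$frames
      fields <- lapply(seq_len(length(f) - 1), function(t)
        compute_piv(f[[t]], f[[t + 1]], sim$piv_p))
      list(fields = fields,
           speeds = vapply(fields, mean_speed, numeric(1)),
           rms = mapply(field_rms_error, fields, sim$movie$truth))
    })
    sim$fields <- piv_out$fields
    report$piv <- list(mean_speed_px_frame = piv_out$speeds,
                       rms_error_vs_truth = piv_out$rms,
                       n_valid = vapply(piv_out$fields, function(x) sum(x$valid),
                                        integer(1)))
  }
  if ("similarity" %in% config$stages) {
    assert_that(!is.null(sim$fields), "similarity stage needs the piv stage")
    simil <- run_stage("similarity", {
      maps <- lapply(sim$fields, motion_similarity_map,
                     mode = config$similarity$mode)
      profs <- lapply(maps, coherence_profile,
                      n_lines = config$similarity$n_lines,
                      axis = config$similarity$axis)
      list(maps = maps, profs = profs)
    })
    report$similarity <- list(
      grid_mean = vapply(simil$maps, function(m) mean(m$values[m$valid]),
                         numeric(1)),
      coherence_lines = lapply(simil$profs, function(p)
        p[, c("line", "mean", "sd", "n")]))
  }
  if ("dispersal" %in% config$stages) {
    assert_that(!is.null(sim), "dispersal stage needs the simulate stage")
    disp <- run_stage("dispersal", {
      region <- config$dispersal$region
      series_by_group <- list()
      fits <- list()
      for (gname in names(sim$groups)) {
        g <- sim$groups[[gname]]
        t_end <- max(g$tracks$frame)
        sl <- lapply(seq_along(g$clusters), function(i)
          dispersal_series(g$clusters[[i]], g$tracks, t_end,
                           group = gname, cluster_id = i))
        series_by_group[[gname]] <- sl
        fits[[gname]] <- if (region == "trunk")
          lapply(sl, fit_linear_trend) else lapply(sl, fit_quadratic_trend)
      }
      out <- list(series = series_by_group, fits = fits)
      gn <- names(sim$groups)
      if (region == "trunk") {
        out$ancova <- compare_slopes_ancova(series_by_group[[1]],
                                            series_by_group[[2]],
                                            labels = gn[1:2])
      } else {
        pairs <- combn(gn, 2, simplify = FALSE)
        tests <- lapply(pairs, function(pr) {
          cf <- function(g) t(vapply(fits[[g]], function(f) c(f$a, f$b, f$c),
                                     numeric(3)))
          hotelling_t2(cf(pr[1]), cf(pr[2]), labels = pr)
        })
        padj <- adjust_fdr(vapply(tests, function(x) x$p, numeric(1)))
        out$hotelling <- lapply(seq_along(tests), function(i)
          list(pair = pairs[[i]], T2 = tests[[i]]$T2, F = tests[[i]]$F,
               df = tests[[i]]$df, p = tests[[i]]$p, p_adj = padj[i]))
      }
      out
    })
    report$dispersal <- list(
      region = config$dispersal$region,
      sd_series = lapply(disp$series, function(gr)
        lapply(gr, function(s) list(time = s$time, sd = s$sd))),
      fits = lapply(disp$fits, function(gr) lapply(gr, function(f)
        list(model = f$model, a = f$a, b = f$b, c = f$c))))
    if (!is.null(disp$ancova))
      report$dispersal$ancova <- disp$ancova[c("F", "df", "p", "slopes")]
    if (!is.null(disp$hotelling))
      report$dispersal$hotelling <- disp$hotelling
  }
  if ("tips" %in% config$stages) {
    tips_out <- run_stage("tips", {
      lapply(seq_len(config$tips$n_trees), function(i) {
        spec <- random_tree_spec(n_bifurcations = config$tips$n_bifurcations,
                                 seed = derive_seed(config$seed, 200L + i),
                                 noise_sigma = config$tips$noise_sigma)
        img <- generate_tree_image(spec)
        res <- count_tips(img$image,
                          tip_count_params(background_radius = 25))
        list(truth = img$tips, counted = res$tip_count)
      })
    })
    report$tips <- list(
      truth = vapply(tips_out, function(x) x$truth, integer(1)),
      counted = vapply(tips_out, function(x) x$counted, integer(1)))
  }

  report_path <- file.path(out_dir, "report.json")
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), report_path)
  prov <- list(tool = "morphoflow",
               version = as.character(utils::packageVersion("morphoflow")),
               config_hash = object_hash(unclass(config)),
               seed = config$seed,
               timestamp = format(Sys.time(), tz = "UTC"),
               warnings = warnings_log)
  prov_path <- file.path(out_dir, "provenance.json")
  writeLines(jsonlite::toJSON(prov, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), prov_path)
  list(report = report, report_path = report_path, provenance_path = prov_path)
}
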