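#' Reconstruct all columns of a dataset
#'
#' Fits a [fit_column_path()] per animal, intersects it with the nucleus
#' boundary ([intersect_boundary()]), and expresses all cells in unit-column
#' coordinates ([unitize()]).
#'
#' @param cells Cell tibble (as [read_cells()]).
#' @param mesh A [nucleus_mesh()].
#' @param n_breaks Interior spline breaks (default 5).
#' @param span_trim Passed to [fit_column_path()].
#' @return List with `paths` (named list of `column_path`) and
#'   `unit_columns` (tibble from [unitize()] pooled over animals).
#' @export
reconstruct_columns <- function(cells, mesh, n_breaks = 5L, span_trim = 0.05) {
  ids <- unique(cells$animal_id)
  paths <- list()
  ucs <- list()
  for (id in ids) {
    sub <- dplyr::filter(cells, .data$animal_id == id)
    path <- tryCatch(
      intersect_boundary(fit_column_path(sub, n_breaks = n_breaks,
                                         span_trim = span_trim), mesh),
      error = function(e) {
        abort(paste0("reconstruct failed for animal ", id, ": ",
                     conditionMessage(e)))
      })
    paths[[id]] <- path
    ucs[[id]] <- unitize(sub, path)
  }
  list(paths = paths, unit_columns = bind_rows(ucs))
}

#' Run the full analysis pipeline from a configuration
#'
#' Chains simulation (or data loading), column reconstruction, depth
#' profiling, map-stack alignment, order metrics and the PLS latent scan,
#' writing per-stage CSV tables and a JSON summary to `out_dir`. The run is
#' deterministic given the configuration's `seed` (per-stage seeds derive
#' from it via [derive_seed()]); stage timings are logged, not written into
#' the summary, so identical configurations produce byte-identical JSON.
#'
#' @param config A list, or path to a YAML/JSON file, with fields:
#'   `seed` (required), `out_dir` (default `"results"`), optional `data`
#'   (paths `cells`, `injections`, `mesh`), optional `simulate` (arguments
#'   for [simulate_columns()] / [simulate_mesh()]), `n_perm` (default 199),
#'   `pls` (`max_latents`, `folds`), `quiet`.
#' @return Invisibly, the summary list (also written as `summary.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  if (is.null(cfg$seed)) abort("invalid config: missing required field 'seed'")
  seed <- as.integer(cfg$seed)
  out_dir <- cfg$out_dir %||% "results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_perm <- cfg$n_perm %||% 199
  quiet <- isTRUE(cfg$quiet)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
    say("stage %-12s %.2fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  # -- data: simulate or load -------------------------------------------------
  ds <- stage("simulate", {
    if (!is.null(cfg$data)) {
      list(cells = read_cells(cfg$data$cells),
           injections = read_injections(cfg$data$injections),
           mesh = read_mesh(cfg$data$mesh,
                            cfg$data$pial %||% paste0(cfg$data$mesh, ".pial")),
           truth = NULL)
    } else {
      sim_args <- cfg$simulate %||% list()
      mesh_args <- sim_args$mesh %||% list()
      sim_args$mesh <- NULL
      do.call(simulate_dataset,
              c(list(seed = derive_seed(seed, 1L), mesh_args = mesh_args),
                sim_args))
    }
  })
  write_cells(ds$cells, file.path(out_dir, "cells.csv"))
  write_injections(ds$injections, file.path(out_dir, "injections.csv"))
  write_mesh(ds$mesh, file.path(out_dir, "mesh.off"))

  group <- as.character(ds$cells$group[1])

  rec <- stage("reconstruct", reconstruct_columns(ds$cells, ds$mesh))
  readr::write_csv(rec$unit_columns, file.path(out_dir, "unit_columns.csv"))

  profiles <- stage("profiles", {
    bind_rows(count_profile(rec$unit_columns, group = group),
              spread_profile(rec$unit_columns, group = group))
  })
  readr::write_csv(profiles, file.path(out_dir, "profiles.csv"))

  stack <- stage("maps", percentile_maps(rec$paths))
  readr::write_csv(stack$points, file.path(out_dir, "maps.csv"))
  steps <- stage("align", align_stack(stack))
  traj <- cumulative_trajectory(steps)
  readr::write_csv(traj, file.path(out_dir, "trajectory.csv"))

  order_tbl <- stage("order", {
    bind_rows(
      topology_profile(stack, n_perm = n_perm, seed = derive_seed(seed, 2L)),
      end_to_end_order(stack, n_perm = n_perm, seed = derive_seed(seed, 3L)),
      topography_profile(ds$injections, stack, n_perm = n_perm,
                         seed = derive_seed(seed, 4L))
    )
  })
  readr::write_csv(order_tbl, file.path(out_dir, "order.csv"))

  scan <- stage("latents", {
    prof_list <- function(kind) {
      setNames(list(dplyr::filter(profiles, .data$kind == !!kind)), group)
    }
    pm <- assemble_profiles(
      counts = prof_list("count"), spreads = prof_list("spread"),
      topology = setNames(list(dplyr::filter(order_tbl, .data$comparison == "topology")), group),
      topography = setNames(list(dplyr::filter(order_tbl, .data$comparison == "topography")), group))
    pls_latent_scan(pm, folds = cfg$pls$folds %||% "loo",
                    max_latents = cfg$pls$max_latents %||% (min(dim(pm)) - 1L),
                    seed = derive_seed(seed, 5L))
  })
  readr::write_csv(tidy(scan), file.path(out_dir, "latent_scan.csv"))

  summary <- list(
    pipeline_version = as.character(utils::packageVersion("geniculate")),
    seed = seed,
    n_columns = length(rec$paths),
    n_cells = nrow(ds$cells),
    n_clipped = sum(rec$unit_columns$clipped),
    column_length_um = list(
      mean = mean(purrr::map_dbl(rec$paths, "total_length")),
      min = min(purrr::map_dbl(rec$paths, "total_length")),
      max = max(purrr::map_dbl(rec$paths, "total_length"))),
    profile_kinds = c("count", "spread", "topology", "topography"),
    cumulative_rotation_rad = traj$cum_rotation_rad[nrow(traj)],
    cumulative_expansion = traj$cum_expansion[nrow(traj)],
    end_to_end = as.list(dplyr::filter(order_tbl, .data$comparison == "end_to_end")[
      c("norm_pt", "p_value", "n_points")]),
    mean_topology_pt = mean(dplyr::filter(order_tbl, .data$comparison == "topology")$norm_pt),
    mean_topography_pt = mean(dplyr::filter(order_tbl, .data$comparison == "topography")$norm_pt),
    latent_scan = as.list(glance(scan))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("summary written to %s", file.path(out_dir, "summary.json"))
  invisible(summary)
}

load_config <- function(config) {
  if (is.list(config)) return(config)
  if (!is.character(config) || !file.exists(config)) {
    abort("config must be a list or the path of a YAML/JSON file")
  }
  if (grepl("\\.json$", config)) {
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(config)
  }
}
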