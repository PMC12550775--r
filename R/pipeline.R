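#' Configuration of the six-model comparative study
#'
#' Bundles every tunable of the pipeline: phantom, calibration, resection,
#' implant catalog and baseplate dimensions, mesh settings, material
#' model, load cases, and output/seed bookkeeping. All reference constants
#' (the material laws, the stem catalog, the load protocol) enter as
#' defaults here and are never hard-coded downstream.
#'
#' @param phantom a [phantom_spec()].
#' @param calibration a [density_calibration()].
#' @param resection a [resection_plan()].
#' @param models integer vector of catalog model ids to run.
#' @param implant_args named list of overrides passed to [implant_spec()]
#'   (baseplate dimensions, fin geometry, ...).
#' @param mesh a [mesh_settings()].
#' @param material a [material_model()].
#' @param implant_mat an [implant_material()].
#' @param body_weight body weight, N.
#' @param medial_fraction medial plateau load share.
#' @param bw_multiples body-weight multiples of the load cases.
#' @param criterion a [fracture_criterion()].
#' @param quadrature_order Gauss order of the density mapping.
#' @param independent_solves if TRUE each load case is solved
#'   independently; default scales one unit-load solve (exact under
#'   linearity).
#' @param output_dir directory for artifacts, or NULL to skip writing.
#' @param seed integer seed recorded in provenance (phantom noise).
#' @return object of class `study_config`.
#' @export
study_config <- function(phantom = phantom_spec(),
                         calibration = density_calibration(),
                         resection = resection_plan(),
                         models = 1:6,
                         implant_args = list(),
                         mesh = mesh_settings(),
                         material = material_model(),
                         implant_mat = implant_material(),
                         body_weight = 750,
                         medial_fraction = 0.60,
                         bw_multiples = c(3, 5, 12),
                         criterion = fracture_criterion(),
                         quadrature_order = 4,
                         independent_solves = FALSE,
                         output_dir = NULL,
                         seed = 1L) {
  if (!length(models)) stop("model list must be non-empty")
  structure(list(phantom = phantom, calibration = calibration,
                 resection = resection, models = models,
                 implant_args = implant_args, mesh = mesh,
                 material = material, implant_mat = implant_mat,
                 body_weight = body_weight,
                 medial_fraction = medial_fraction,
                 bw_multiples = bw_multiples, criterion = criterion,
                 quadrature_order = quadrature_order,
                 independent_solves = independent_solves,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "study_config")
}

#' Desk-scale preset: coarse mesh on the default phantom
#'
#' Overrides the mesh size to 3 mm (ROI offset widened to one element
#' layer) so the full six-model study runs in minutes on one CPU.
#' @param config a [study_config()].
#' @param size coarse element size, mm.
#' @export
coarse_preset <- function(config, size = 3) {
  config$mesh <- mesh_settings(global_size = size, contact_size = size,
                               roi_offset = max(size,
                                                config$mesh$roi_offset),
                               convergence_tolerance =
                                 config$mesh$convergence_tolerance)
  config
}

#' Serialize / restore a study configuration (YAML)
#'
#' @param config a [study_config()].
#' @param path file path.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  study_config(phantom = do.call(phantom_spec, raw$phantom),
               calibration = do.call(density_calibration, raw$calibration),
               resection = resection_plan(raw$resection$depth,
                                          raw$resection$jlo_angle),
               models = unlist(raw$models),
               implant_args = raw$implant_args %||% list(),
               mesh = do.call(mesh_settings, raw$mesh),
               material = do.call(material_model,
                                  raw$material[setdiff(names(raw$material),
                                                       "tissue_threshold")]),
               implant_mat = do.call(implant_material, raw$implant_mat),
               body_weight = raw$body_weight,
               medial_fraction = raw$medial_fraction,
               bw_multiples = unlist(raw$bw_multiples),
               criterion = fracture_criterion(
                 raw$criterion$compressive_strain_limit,
                 raw$criterion$fraction),
               quadrature_order = raw$quadrature_order,
               independent_solves = raw$independent_solves,
               output_dir = raw$output_dir,
               seed = raw$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## shared per-study context: phantom, CT, resected bone (identical across
## the six models, so built once)
study_context <- function(config) {
  tibia <- generate_phantom_surface(config$phantom)
  ras <- rasterize_phantom(config$phantom, config$calibration)
  resected <- resect_tibia(tibia, config$resection)
  list(tibia = tibia, ct = ras$ct, truth = ras$truth, resected = resected)
}

#' Run one implant configuration through the full pipeline
#'
#' Phantom/geometry -> conformal mesh -> density mapping -> unit-load
#' solve -> load-case scaling -> summary rows. Load cases are obtained by
#' scaling a single unit-load solution (exact for this linear model)
#' unless `config$independent_solves` is TRUE.
#'
#' @param config a [study_config()].
#' @param model_id catalog model id (1-6).
#' @param context optional shared [study_context] (built if NULL).
#' @return list with `rows` (one per load case), `mesh`, `materials`,
#'   `fields` (per case), `coverage`, `log`.
#' @export
run_model <- function(config, model_id, context = NULL) {
  cat <- implant_catalog()
  if (!model_id %in% cat$model_id)
    stop("invalid model_id ", model_id, "; valid ids: ",
         paste(cat$model_id, collapse = ", "))
  if (is.null(context)) context <- study_context(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for model ", model_id, ": ",
           conditionMessage(e), call. = FALSE))
  }
  implant <- stage("geometry", {
    sp <- do.call(implant_spec, c(list(model_id = model_id),
                                  config$implant_args))
    place_implant(build_implant(sp), context$resected)
  })
  cavity <- stage("geometry", carve_cavity(context$resected, implant))
  coverage <- stage("geometry", check_coverage(context$resected, implant))
  mesh <- stage("meshing", mesh_assembly(cavity, implant, config$mesh))
  audit <- mesh_audit(mesh)
  if (!audit$ok) stop("mesh audit failed for model ", model_id)
  rho <- stage("material_mapping",
               element_density(context$ct, mesh, config$calibration,
                               config$material,
                               order = config$quadrature_order))
  materials <- stage("material_mapping",
                     assign_materials(mesh, rho, config$material,
                                      config$implant_mat))
  K <- stage("fe_solver", assemble(mesh, materials))
  cut <- context$resected$meta$cut
  cases <- lapply(config$bw_multiples, load_case,
                  body_weight = config$body_weight,
                  medial_fraction = config$medial_fraction)
  rows <- list(); fields <- list()
  if (config$independent_solves) {
    for (cs in cases) {
      bc <- apply_loads(mesh, cs)
      sol <- solve_fe(K, bc)
      fl <- recover_fields(mesh, sol$u, materials)
      fields[[cs$name]] <- fl
      rows[[cs$name]] <- summarize_case(mesh, fl, materials,
                                        config$criterion, model_id,
                                        cs$name, cut = cut)
    }
  } else {
    unit_case <- load_case(bw_multiple = 1, body_weight = 1,
                           medial_fraction = config$medial_fraction,
                           name = "unit")
    bc <- apply_loads(mesh, unit_case)
    sol <- stage("fe_solver", solve_fe(K, bc))
    f0 <- recover_fields(mesh, sol$u, materials)
    for (cs in cases) {
      fl <- structure(list(strain = f0$strain * cs$total_force,
                           stress = f0$stress * cs$total_force),
                      class = "tensor_field")
      fields[[cs$name]] <- fl
      rows[[cs$name]] <- summarize_case(mesh, fl, materials,
                                        config$criterion, model_id,
                                        cs$name, cut = cut)
    }
  }
  rm(K); gc(verbose = FALSE)       # drop the factorised system promptly
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  log <- list(model_id = model_id, n_elements = nrow(mesh$conn),
              n_nodes = nrow(mesh$nodes),
              n_floored = attr(rho, "n_floored"),
              residual = sol$residual,
              min_jacobian = audit$min_jacobian,
              coverage = coverage)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    base <- file.path(config$output_dir, sprintf("model%d", model_id))
    pv <- principal_values(fields[[length(fields)]]$strain)
    write_vtu(mesh, paste0(base, ".vtu"),
              cell_data = list(density = ifelse(is.na(materials$rho), 0,
                                                materials$rho),
                               E = materials$E,
                               von_mises = von_mises(
                                 fields[[length(fields)]]$stress),
                               e1 = pv[, 1], e3 = pv[, 3]))
    jsonlite::write_json(log, paste0(base, "_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  list(rows = rows, mesh = mesh, materials = materials, fields = fields,
       coverage = coverage, log = log)
}

#' Run the full multi-model comparative study
#'
#' Executes every configured model, assembles the summary table, and
#' appends per-quantity deltas against the stemless reference (model 1)
#' when it is part of the study. Per-model failures are reported and do
#' not abort the remaining models.
#'
#' @param config a [study_config()].
#' @param keep_fields if TRUE, keep per-model meshes/fields in the report
#'   (memory-heavy); default drops them.
#' @return object of class `study_report`: list with `rows`, `table`
#'   (reference layout), `deltas_vs_model1`, `logs`, `failed`, `config`.
#' @export
run_study <- function(config, keep_fields = FALSE) {
  context <- study_context(config)
  rows <- list(); logs <- list(); failed <- character()
  details <- list()
  for (m in config$models) {
    res <- tryCatch(run_model(config, m, context),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning("model ", m, " failed: ", conditionMessage(res))
      failed <- c(failed, sprintf("model %d: %s", m,
                                  conditionMessage(res)))
      next
    }
    rows[[as.character(m)]] <- res$rows
    logs[[as.character(m)]] <- res$log
    if (keep_fields) details[[as.character(m)]] <- res
    rm(res); gc(verbose = FALSE)     # large meshes: return memory eagerly
  }
  if (!length(rows)) stop("all models failed")
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  deltas <- NULL
  if (1 %in% rows$model_id) {
    qcols <- c("max_von_mises_mpa", "max_equivalent_strain",
               "max_fracture_risk_pct", "roi_median_min_principal_ue",
               "roi_p90_min_principal_ue", "sub_plate_mean_ustrain")
    ref <- rows[rows$model_id == 1, c("case", qcols)]
    deltas <- rows[, c("model_id", "case", qcols)]
    for (q in qcols)
      deltas[[q]] <- deltas[[q]] -
        ref[[q]][match(deltas$case, ref$case)]
  }
  report <- structure(list(rows = rows, table = summary_table(rows),
                           deltas_vs_model1 = deltas, logs = logs,
                           failed = failed, config = config,
                           details = if (keep_fields) details else NULL),
                      class = "study_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(rows, file.path(config$output_dir,
                                     "summary_rows.csv"),
                     row.names = FALSE)
    utils::write.csv(report$table, file.path(config$output_dir,
                                             "summary_table.csv"),
                     row.names = FALSE)
    write_study_config(config, file.path(config$output_dir,
                                         "study_config.yaml"))
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>", length(unique(x$rows$model_id)), "models x",
      length(unique(x$rows$case)), "load cases\n")
  print(x$rows, digits = 4)
  if (length(x$failed)) cat("failed:", paste(x$failed, collapse = "; "),
                            "\n")
  invisible(x)
}

#' Configuration for the mesh-convergence suite
#'
#' A half-scale phantom with a proportionally scaled implant, so the
#' finest sizes of the convergence ladder stay tractable on one CPU.
#' The stem (22 mm x 5 mm) is an off-catalog size matched to the
#' phantom's medullary canal.
#'
#' @param ... overrides forwarded to [study_config()].
#' @export
coarse_convergence_config <- function(...) {
  study_config(phantom = coarse_phantom_spec(),
               implant_args = list(baseplate_width = 29,
                                   baseplate_depth = 19,
                                   baseplate_thickness = 3,
                                   stem_length = 22, stem_diameter = 5,
                                   fin_reach = 8,
                                   fin_half_thickness = 0.8,
                                   fin_height = 5, boss_radius = 3.5,
                                   taper_length = 3),
               ...)
}

#' Run the mesh-convergence protocol on the pipeline
#'
#' Re-meshes one implant configuration at each element size on the
#' descending ladder, solves the reference walking load case, and applies
#' the acceptance rule of [convergence_study()] to the monitored outputs
#' (max von Mises stress, max equivalent elastic strain, max fracture
#' risk over bone).
#'
#' @param config a [study_config()] whose `implant_args` fully describe
#'   the implant (including `stem_length`/`stem_diameter`), e.g.
#'   [coarse_convergence_config()].
#' @param sizes descending element sizes, mm.
#' @return the [convergence_study()] result (selected size, flag, table).
#' @export
run_convergence <- function(config = coarse_convergence_config(),
                            sizes = c(3, 2, 1.5)) {
  context <- study_context(config)
  sp <- suppressWarnings(do.call(implant_spec, config$implant_args))
  implant <- place_implant(build_implant(sp), context$resected)
  cavity <- carve_cavity(context$resected, implant)
  cut <- context$resected$meta$cut
  case <- load_case(config$bw_multiples[1],
                    body_weight = config$body_weight,
                    medial_fraction = config$medial_fraction)
  run1 <- function(size) {
    st <- mesh_settings(size, size,
                        roi_offset = max(config$mesh$roi_offset, size),
                        convergence_tolerance =
                          config$mesh$convergence_tolerance)
    mesh <- mesh_assembly(cavity, implant, st)
    rho <- element_density(context$ct, mesh, config$calibration,
                           config$material,
                           order = config$quadrature_order)
    mat <- assign_materials(mesh, rho, config$material,
                            config$implant_mat)
    sol <- solve_fe(assemble(mesh, mat), apply_loads(mesh, case))
    row <- summarize_case(mesh, recover_fields(mesh, sol$u, mat), mat,
                          config$criterion, case_name = case$name,
                          cut = cut)
    c(max_stress_mpa = row$max_von_mises_mpa,
      max_equiv_strain = row$max_equivalent_strain,
      max_fracture_risk_pct = row$max_fracture_risk_pct)
  }
  convergence_study(run1, sizes, config$mesh$convergence_tolerance)
}
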