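# Writers for the standard output formats (long-format CSV, legacy VTK
# structured grids, JSON reports) and the flat run configuration that ties
# the pipeline stages together.

#' Write a field to CSV (long format)
#'
#' One row per grid node, columns `x`, `y` followed by the field
#' components (`Qxx`, `Qxy` for tensor fields; `Fx`, `Fy` for vector
#' fields; the label for scalar fields).  Units are recorded on a leading
#' comment line.
#'
#' @param field a `tensor_field`, `vector_field` or `scalar_field`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  df <- field_as_df(field)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", field$units), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a field CSV written by [write_field_csv()]
#' @param path file path.
#' @return data frame with the node columns.
#' @export
read_field_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

field_as_df <- function(field) {
  pts <- as_points(field$grid)
  base <- data.frame(x = pts$x, y = pts$y)
  if (inherits(field, "tensor_field"))
    cbind(base, Qxx = field$Qxx, Qxy = field$Qxy)
  else if (inherits(field, "vector_field"))
    cbind(base, Fx = field$Fx, Fy = field$Fy)
  else if (inherits(field, "scalar_field")) {
    out <- cbind(base, value = field$value)
    names(out)[3] <- if (!is.null(field$label)) field$label else "value"
    out
  } else stop("not a field object")
}

#' Write a field as a legacy VTK structured grid
#'
#' ASCII legacy-VTK `STRUCTURED_GRID` output for rectangle and disc grids
#' (z = 0 plane), with scalar fields as `SCALARS` and vector fields as
#' `VECTORS` point data, loadable in standard viewers.
#'
#' @param field a field object on a [make_grid()] grid.
#' @param path output file.
#' @param name data array name.
#' @return `path`, invisibly.
#' @export
write_field_vtk <- function(field, path, name = "field") {
  grid <- field$grid
  if (!inherits(grid, "grid2d")) stop("VTK output requires a grid2d")
  pts <- grid_points(grid)
  dims <- if (grid$domain == "rectangle")
    c(length(grid$x), length(grid$y), 1L)
  else c(length(grid$r), length(grid$phi), 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "nematicdefects field", "ASCII",
               "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d %d", dims[1], dims[2], dims[3]),
               sprintf("POINTS %d double", nrow(pts))), con)
  writeLines(sprintf("%.10g %.10g 0", pts$x, pts$y), con)
  writeLines(sprintf("POINT_DATA %d", nrow(pts)), con)
  if (inherits(field, "vector_field")) {
    writeLines(sprintf("VECTORS %s double", name), con)
    writeLines(sprintf("%.10g %.10g 0", field$Fx, field$Fy), con)
  } else if (inherits(field, "scalar_field")) {
    writeLines(c(sprintf("SCALARS %s double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", field$value), con)
  } else if (inherits(field, "tensor_field")) {
    writeLines(c(sprintf("SCALARS %s_Qxx double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", field$Qxx), con)
    writeLines(c(sprintf("SCALARS %s_Qxy double 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.10g", field$Qxy), con)
  }
  invisible(path)
}

#' Write a profile curve to CSV
#'
#' Columns `x_v` (units of `ell_d`), `value`, `abs_error`.
#'
#' @param curve a [profile_curve()] or data frame with those columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  tab <- if (inherits(curve, "profile_curve")) curve$table else curve
  stopifnot(all(c("x_v", "value", "abs_error") %in% names(tab)))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flat run configuration
#'
#' A single flat key-value document describing one pipeline run: the
#' subcommand (`forcefield`, `kinematics`, `profilefns`, `discsolve` or
#' `dynamics`), the defect, activity profile and medium parameters, grid
#' or solver sizes and tolerances.  The configuration serializes losslessly
#' to JSON ([write_run_config()] / [read_run_config()]) and every
#' [execute_run()] writes its resolved configuration next to its outputs.
#'
#' @param subcommand pipeline stage to run.
#' @param charge,theta0,S0 defect parameters.
#' @param kind,alpha0,alphag,dalpha,xv activity-profile parameters.
#' @param Gamma,eta,K,g,gamma_rot medium parameters.
#' @param domain,L,radius,resolution,n_phi grid / disc-solver sizes.
#' @param pressure_mode pressure treatment for `kinematics`.
#' @param rel_tol quadrature tolerance.
#' @param xv_grid wall-distance grid for `profilefns` (numeric vector).
#' @param theta0_init,xv_init,t_end dynamics parameters.
#' @param seed RNG seed (recorded; only randomized checks consume it).
#' @return Object of class `run_config` (named list).
#' @export
run_config <- function(subcommand = c("kinematics", "forcefield",
                                      "profilefns", "discsolve", "dynamics"),
                       charge = 0.5, theta0 = 0, S0 = 2,
                       kind = "uniform", alpha0 = 1, alphag = 0,
                       dalpha = 0, xv = 1,
                       Gamma = 1, eta = 1, K = 1, g = 1, gamma_rot = 1,
                       domain = "rectangle", L = 2, radius = 5,
                       resolution = 64, n_phi = 64,
                       pressure_mode = "uniform_term_only",
                       rel_tol = 1e-8,
                       xv_grid = seq(0.1, 5, by = 0.1),
                       theta0_init = pi / 3, xv_init = 2, t_end = 100,
                       seed = 1L) {
  cfg <- list(subcommand = match.arg(subcommand), charge = charge,
              theta0 = theta0, S0 = S0, kind = kind, alpha0 = alpha0,
              alphag = alphag, dalpha = dalpha, xv = xv, Gamma = Gamma,
              eta = eta, K = K, g = g, gamma_rot = gamma_rot,
              domain = domain, L = L, radius = radius,
              resolution = resolution, n_phi = n_phi,
              pressure_mode = pressure_mode, rel_tol = rel_tol,
              xv_grid = xv_grid, theta0_init = theta0_init,
              xv_init = xv_init, t_end = t_end, seed = seed)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  required <- c("subcommand", "charge", "theta0", "kind", "alpha0")
  missing <- setdiff(required, names(cfg)[!vapply(cfg, is.null, logical(1))])
  if (length(missing))
    stop("run config is missing keys: ", paste(missing, collapse = ", "))
  if (!cfg$kind %in% c("uniform", "linear", "step"))
    stop("invalid config key 'kind': ", cfg$kind)
  if (!cfg$subcommand %in% c("kinematics", "forcefield", "profilefns",
                             "discsolve", "dynamics"))
    stop("invalid config key 'subcommand': ", cfg$subcommand)
  invisible(cfg)
}

#' @rdname run_config
#' @param cfg a `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

cfg_objects <- function(cfg) {
  list(defect = defect_config(cfg$charge, cfg$theta0, S0 = cfg$S0),
       profile = activity_profile(cfg$kind, alpha0 = cfg$alpha0,
                                  alphag = cfg$alphag, dalpha = cfg$dalpha,
                                  x_v = cfg$xv),
       medium = medium_params(cfg$Gamma, cfg$eta, cfg$K, cfg$g,
                              cfg$gamma_rot))
}

#' Execute a configured pipeline run
#'
#' Dispatches on the configured subcommand, writes the artifacts (CSV /
#' VTK / JSON) and the resolved configuration into `out_dir`, and logs the
#' quadrature error estimates or solver residuals so tolerances are
#' machine-checkable from the outputs.  Runs are deterministic for a fixed
#' configuration.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Named character vector of files written, invisibly.
#' @export
execute_run <- function(cfg, out_dir, quiet = FALSE) {
  validate_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ob <- cfg_objects(cfg)
  say <- function(...) if (!quiet) message(sprintf(...))
  files <- c(config = file.path(out_dir, "config.json"))
  write_run_config(cfg, files[["config"]])
  set.seed(cfg$seed)
  out <- switch(cfg$subcommand,
    forcefield = {
      grid <- if (cfg$domain == "disc")
        make_grid("disc", R = cfg$radius, resolution = cfg$resolution)
      else make_grid("rectangle", L = cfg$L, resolution = cfg$resolution)
      ff <- active_force(ob$defect, ob$profile, grid, mode = "closed_form",
                         r_core = if (cfg$domain == "rectangle" &&
                                      cfg$resolution %% 2 == 1) 1e-9 else NULL)
      fb <- file.path(out_dir, "force_bulk.csv")
      write_field_csv(ff$F_B, fb)
      files <- c(files, force_bulk = fb)
      if (inherits(ff$F_I, "vector_field")) {
        fi <- file.path(out_dir, "force_interfacial.csv")
        write_field_csv(ff$F_I, fi)
        files <- c(files, force_interfacial = fi)
      } else say("interfacial force is a delta line at x = %g (not sampled)",
                 ff$F_I$x_at)
      vtk <- file.path(out_dir, "force_bulk.vtk")
      write_field_vtk(ff$F_B, vtk, name = "F_B")
      c(files, force_bulk_vtk = vtk)
    },
    kinematics = {
      v <- core_velocity(ob$defect, ob$profile, ob$medium,
                         pressure_mode = cfg$pressure_mode,
                         rel_tol = cfg$rel_tol)
      w <- core_vorticity(ob$defect, ob$profile, ob$medium,
                          rel_tol = cfg$rel_tol)
      say("v = (%.8g, %.8g), omega = %.8g (quadrature err %.2g)",
          v$v[1], v$v[2], w$omega, v$abs_error + w$abs_error)
      jp <- file.path(out_dir, "kinematics.json")
      jsonlite::write_json(list(
        v = v$v, v_I = v$v_I, v_B = v$v_B, omega = w$omega,
        omega_I = w$omega_I, omega_B = w$omega_B,
        pressure_mode = v$pressure_mode,
        abs_error = v$abs_error + w$abs_error, units = "rescaled"),
        jp, auto_unbox = TRUE, digits = NA)
      c(files, kinematics = jp)
    },
    profilefns = {
      for (which in c("f_v_plus", "f_omega_plus", "f_v_minus",
                      "f_omega_minus")) {
        cv <- profile_curve(which, x_v = cfg$xv_grid, rel_tol = cfg$rel_tol)
        fp <- file.path(out_dir, paste0(which, ".csv"))
        write_curve_csv(cv, fp)
        files <- c(files, stats::setNames(fp, which))
      }
      files
    },
    discsolve = {
      prob <- disc_problem(cfg$radius, ob$defect, ob$profile, ob$medium,
                           resolution = cfg$resolution, n_phi = cfg$n_phi)
      sol <- solve_disc(prob)
      say("u(0) = (%.6g, %.6g), omega(0) = %.6g; no-slip %.2g, div %.2g",
          sol$core$u0[1], sol$core$u0[2], sol$core$omega0,
          sol$residuals$no_slip, sol$residuals$divergence)
      jp <- file.path(out_dir, "disc_core.json")
      jsonlite::write_json(list(R = cfg$radius, u0 = sol$core$u0,
                                omega0 = sol$core$omega0,
                                residuals = sol$residuals),
                           jp, auto_unbox = TRUE, digits = NA)
      vtk <- file.path(out_dir, "disc_omega.vtk")
      wfield <- structure(list(
        grid = structure(list(domain = "disc", r = sol$r, phi = sol$phi,
                              R = cfg$radius,
                              resolution = prob$resolution,
                              spacing = prob$h), class = "grid2d"),
        value = as.vector(sol$omega), label = "omega", units = "rescaled"),
        class = "scalar_field")
      vtk_ok <- tryCatch({write_field_vtk(wfield, vtk, "omega"); TRUE},
                         error = function(e) FALSE)
      if (vtk_ok) c(files, disc_core = jp, disc_omega_vtk = vtk)
      else c(files, disc_core = jp)
    },
    dynamics = {
      d <- defect_config(cfg$charge, cfg$theta0_init)
      ser <- integrate_trajectory(d, cfg$xv_init, cfg$alpha0,
                                  dalpha = cfg$dalpha,
                                  medium = ob$medium,
                                  t_span = c(0, cfg$t_end))
      fp <- file.path(out_dir, "trajectory.csv")
      utils::write.csv(ser, fp, row.names = FALSE)
      rep <- stationary_orientations(cfg$charge, max(cfg$xv, 1e-2),
                                     cfg$alpha0,
                                     dalpha = if (cfg$dalpha != 0)
                                       cfg$dalpha else cfg$alpha0,
                                     medium = ob$medium)
      jp <- file.path(out_dir, "fixed_points.json")
      jsonlite::write_json(list(regime = attr(rep, "regime"),
                                f_omega = attr(rep, "f_omega"),
                                roots = as.data.frame(rep)),
                           jp, auto_unbox = TRUE, digits = NA)
      c(files, trajectory = fp, fixed_points = jp)
    })
  invisible(out)
}
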