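# End-to-end pipeline driven by a YAML/JSON config file. The run_* functions
# are the programmatic interface; inst/cli/neeiav.R is a thin command-line
# wrapper over them.

#' Load and validate a pipeline run configuration
#'
#' The config is a YAML (or JSON) file with top-level keys: exactly one of
#' `simulate` (arguments for [sim_config()]) or `inputs` (with `fieldset`, a
#' NetCDF path, and optionally `variable_map`), plus optional `seed`,
#' `output_dir`, `excluded_years` (default 1982, 1991, 1992),
#' `band_boundary` (default 25) and `seasons`.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @param overrides named list of keys overriding the file contents (the CLI
#'   maps flags onto this).
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(config, overrides = list()) {
  src <- NULL
  if (is.character(config)) {
    src <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  config <- utils::modifyList(config, overrides)
  has_sim <- !is.null(config$simulate)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp)
    stop("config must contain exactly one of 'simulate' or 'inputs'")
  if (has_inp && is.null(config$inputs$fieldset))
    stop("config 'inputs' block needs a 'fieldset' path")
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(config$output_dir)) config$output_dir <- "."
  config$excluded_years <- if (is.null(config$excluded_years))
    c(1982L, 1991L, 1992L) else as.integer(config$excluded_years)
  if (is.null(config$band_boundary)) config$band_boundary <- 25
  attr(config, "source_file") <- src
  class(config) <- c("run_config", "list")
  config
}

load_or_simulate <- function(config) {
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- config$seed
    sim <- simulate_fieldset(do.call(sim_config, args))
    list(fieldset = sim$fieldset, truth = sim$truth)
  } else {
    vm <- config$inputs$variable_map
    fs <- if (is.null(vm)) read_fieldset(config$inputs$fieldset)
          else read_fieldset(config$inputs$fieldset, unlist(vm))
    list(fieldset = fs, truth = NULL)
  }
}

write_provenance <- function(config, outdir, stage) {
  src <- attr(config, "source_file")
  prov <- list(
    stage = stage,
    seed = config$seed,
    config = unclass(config),
    config_md5 = if (!is.null(src)) unname(tools::md5sum(src)) else NA,
    package_version = as.character(utils::packageVersion("neeiav")),
    r_version = R.version.string
  )
  jsonlite::write_json(prov, file.path(outdir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the simulate stage: generate and write a synthetic fieldset
#'
#' Writes `fieldset.nc`, the planted truth (`truth.nc` with the sensitivity
#' maps, `truth.json` with expected shares and the config) and a provenance
#' record to the output directory.
#'
#' @param config path or list accepted by [read_run_config()]; must contain a
#'   `simulate` block.
#' @param overrides named list of config overrides.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config, overrides = list()) {
  config <- read_run_config(config, overrides)
  if (is.null(config$simulate)) stop("run_simulate needs a 'simulate' block")
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- load_or_simulate(config)
  fs_path <- file.path(outdir, "fieldset.nc")
  write_fieldset(sim$fieldset, fs_path)
  truth_nc <- file.path(outdir, "truth.nc")
  write_truth(sim$truth, truth_nc)
  truth_json <- file.path(outdir, "truth.json")
  jsonlite::write_json(list(expected_shares = sim$truth$expected_shares,
                            config = unclass(sim$truth$config)),
                       truth_json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(config, outdir, "simulate")
  invisible(list(fieldset = fs_path, truth = truth_nc, truth_json = truth_json))
}

# planted sensitivity maps as NetCDF
write_truth <- function(truth, path) {
  g_dim <- dim(truth$a_tws)
  dlat <- ncdf4::ncdim_def("lat", "index", seq_len(g_dim[1]))
  dlon <- ncdf4::ncdim_def("lon", "index", seq_len(g_dim[2]))
  dmon <- ncdf4::ncdim_def("month", "calendar month", 1:12)
  vars <- list(
    ncdf4::ncvar_def("a_tws", "PgC month-1 mm-1", list(dlon, dlat, dmon),
                     prec = "double"),
    ncdf4::ncvar_def("a_t", "PgC month-1 degC-1", list(dlon, dlat, dmon),
                     prec = "double"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, "a_tws", aperm(truth$a_tws, c(2, 1, 3)))
  ncdf4::ncvar_put(nc, "a_t", aperm(truth$a_t, c(2, 1, 3)))
  invisible(path)
}

#' Run the decompose stage: correlations, contributions and aggregation
#'
#' Loads or simulates the fieldset, fits the decomposition, writes
#' `contributions.nc`, a tidy `summary.csv` (whole globe plus latitudinal
#' bands, annual plus the four boreal seasons) and a provenance record. The
#' additivity residual of the decomposition is reported via `message()` as a
#' built-in self-check.
#'
#' @inheritParams run_simulate
#' @return Invisibly, a list with the fitted `nee_decomposition` and paths.
#' @export
run_decompose <- function(config, overrides = list()) {
  config <- read_run_config(config, overrides)
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fs <- load_or_simulate(config)$fieldset
  fit <- nee_decompose(fs, excluded_years = config$excluded_years)
  message(sprintf("additivity residual: sum(C_T)-r_T = %.3e, sum(C_TWS)+r_TWS = %.3e",
                  sum(fit$C_T) - fit$r_T, sum(fit$C_TWS) + fit$r_TWS))
  nc_path <- file.path(outdir, "contributions.nc")
  write_contribution_map(fit, nc_path)
  globe <- region_mask("globe", fit$geometry$land_mask, fit$geometry)
  bands <- default_bands(fit$geometry, boundary = config$band_boundary)
  tab <- aggregate_contributions(fit, regions = c(list(globe = globe), bands))
  csv_path <- file.path(outdir, "summary.csv")
  utils::write.csv(tab, csv_path, row.names = FALSE)
  write_provenance(config, outdir, "decompose")
  invisible(list(fit = fit, contributions = nc_path, summary = csv_path))
}

#' Run the sensitivity stage: per-cell seasonal regressions
#'
#' Fits the seasonal multiple regression of NEE on TWS and temperature for
#' each requested season (default: the four boreal seasons plus the per-cell
#' tropical dry and wet seasons) and writes one NetCDF per season.
#'
#' @inheritParams run_simulate
#' @param seasons character vector among `"MAM"`, `"JJA"`, `"SON"`, `"DJF"`,
#'   `"dry"`, `"wet"`.
#' @return Invisibly, a named list of `nee_sensitivity` fits and paths.
#' @export
run_sensitivity <- function(config, overrides = list(),
                            seasons = c("MAM", "JJA", "SON", "DJF", "dry", "wet")) {
  config <- read_run_config(config, overrides)
  outdir <- config$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fs <- load_or_simulate(config)$fieldset
  month_sets <- nh_seasons()
  mask <- if (any(seasons %in% c("dry", "wet"))) classify_dry_wet(fs) else NULL
  fits <- list(); paths <- character(0)
  for (sn in seasons) {
    fit <- if (sn %in% names(month_sets)) {
      seasonal_sensitivity(fs, month_sets[[sn]],
                           excluded_years = config$excluded_years)
    } else if (sn %in% c("dry", "wet")) {
      seasonal_sensitivity(fs, mask, which = sn,
                           excluded_years = config$excluded_years)
    } else stop(sprintf("unknown season '%s'", sn))
    p <- file.path(outdir, sprintf("sensitivity_%s.nc", sn))
    write_sensitivity(fit, p)
    fits[[sn]] <- fit
    paths[sn] <- p
  }
  write_provenance(config, outdir, "sensitivity")
  invisible(list(fits = fits, paths = paths))
}

write_sensitivity <- function(fit, path) {
  g <- fit$geometry
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", g$lat)
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", g$lon)
  mv <- -9999
  vd <- function(nm, units)
    ncdf4::ncvar_def(nm, units, list(dlon, dlat), missval = mv, prec = "double")
  vars <- list(vd("a_tws", "PgC month-1 mm-1"), vd("a_t", "PgC month-1 degC-1"),
               vd("se_tws", "PgC month-1 mm-1"), vd("se_t", "PgC month-1 degC-1"),
               vd("resid_sd", "PgC month-1"))
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (nm in c("a_tws", "a_t", "se_tws", "se_t", "resid_sd"))
    ncdf4::ncvar_put(nc, nm, t(fit[[nm]]))
  ncdf4::ncatt_put(nc, 0, "season", fit$season)
  ncdf4::ncatt_put(nc, 0, "n_years", fit$n_years, prec = "int")
  invisible(path)
}

#' Run the report stage: region x season contribution table
#'
#' Reads the contribution map written by [run_decompose()] and emits a tidy
#' CSV of band x season contributions and shares.
#'
#' @inheritParams run_simulate
#' @return Invisibly, the report data.frame.
#' @export
run_report <- function(config, overrides = list()) {
  config <- read_run_config(config, overrides)
  outdir <- config$output_dir
  fit <- read_contribution_map(file.path(outdir, "contributions.nc"))
  bands <- default_bands(fit$geometry, boundary = config$band_boundary)
  tab <- aggregate_contributions(fit, regions = bands)
  utils::write.csv(tab, file.path(outdir, "report.csv"), row.names = FALSE)
  invisible(tab)
}
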