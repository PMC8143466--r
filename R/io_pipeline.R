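# CSV readers/writers for the pipeline schemas.  Parsing is by column name
# (order-insensitive), UTF-8, dot decimal separator.

.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a fluorescence titration CSV
#'
#' Expected columns: `pH`, `CP_M`, `L_total_M`, `Fn` (one row per vesicle
#' addition).  Column order is irrelevant; extra columns are kept.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_fluorescence_csv <- function(path)
  .read_csv_checked(path, c("pH", "CP_M", "L_total_M", "Fn"))

#' Read a zeta titration CSV
#'
#' Expected columns: `P_over_L_half`, `zeta_mV`, `DH_nm`, `pH`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_zeta_csv <- function(path)
  .read_csv_checked(path, c("P_over_L_half", "zeta_mV", "DH_nm", "pH"))

#' Read a per-residue protonation-fraction CSV
#'
#' Expected columns: `peptide`, `environment`, `residue`, `pH`, `fraction`,
#' `sd`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_protonation_csv <- function(path)
  .read_csv_checked(path, c("peptide", "environment", "residue", "pH",
                            "fraction", "sd"))

#' Write a data frame as a pipeline CSV
#'
#' UTF-8, dot decimals, no row names; the paired readers recover the table
#' with full fidelity.
#'
#' @param df Data frame.
#' @param path Output path (directories are created as needed).
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

.load_config <- function(config) {
  if (is.null(config)) return(list())
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    if (ext %in% c("yml", "yaml")) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read ", config)
      return(yaml::read_yaml(config))
    }
    return(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  stopifnot(is.list(config))
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates the stages of the analysis over the bundled protonation
#' fixtures and a synthetic titration scenario: (1) bare-membrane
#' electrostatics (surface potential and surface pH per bulk pH); (2)
#' Langmuir partition fit on a synthetic fluorescence series; (3)
#' Gouy-Chapman reduction of the same series and intrinsic-constant fit;
#' (4) zeta titration, shear-plane recovery and surface potentials; (5)
#' Hill-equation pKa report and net charges from the protonation table.
#' Each stage writes a CSV under `output_dir` and the run ends with a
#' versioned JSON summary.  A stage failure aborts with an error naming the
#' stage; outputs of earlier stages are retained.
#'
#' @param config `NULL` (all defaults), a list, or a path to a YAML/JSON
#'   file.  Recognized keys: `seed` (default 1), `scenario` (name of a
#'   [default_scenarios()] entry, default `"MP1_pH5.5"`), `pH_mode`,
#'   `protonation_csv` (default: the bundled fixture), `n_points`,
#'   `x_shear_A`.
#' @param output_dir Directory for the per-stage CSVs and `summary.json`.
#' @return The summary list, invisibly.
#' @export
run_pipeline <- function(config = NULL, output_dir = tempfile("gcreg_run_")) {
  cfg <- .load_config(config)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  scen_name <- if (is.null(cfg$scenario)) "MP1_pH5.5" else cfg$scenario
  scen <- default_scenarios()[[scen_name]]
  if (is.null(scen)) stop("unknown scenario: ", scen_name)
  if (!is.null(cfg$pH_mode)) scen$pH_mode <- cfg$pH_mode
  n_points <- if (is.null(cfg$n_points)) 12L else as.integer(cfg$n_points)
  x_shear_A <- if (is.null(cfg$x_shear_A)) 3.7 else cfg$x_shear_A
  prot_csv <- if (is.null(cfg$protonation_csv))
    system.file("extdata", "cphmd_protonation_fractions.csv",
                package = "gcreg", mustWork = TRUE) else cfg$protonation_csv
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(force(expr),
             error = function(e) stop("pipeline stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  sol <- .scenario_solution(scen)
  mem <- scen$membrane

  electro <- stage("electrostatics", {
    psi0 <- solve_surface_potential(mem, sol)
    df <- data.frame(pH_bulk = c(5.5, 6.5, 7.4))
    df$psi0_mV <- 1e3 * psi0
    df$pH_surface <- surface_pH(df$pH_bulk, psi0, sol$temperature_K)
    write_pipeline_csv(df, file.path(output_dir, "electrostatics.csv"))
    df
  })

  fluor <- stage("fluorescence", {
    tit <- gen_fluorescence_titration(scen, n_points = n_points, seed = seed)
    write_pipeline_csv(tit, file.path(output_dir, "fluorescence.csv"))
    tit
  })

  part <- stage("partition_fit", {
    # Langmuir reduction of the same series: I/I0 rescaled from Fn
    I_ratio <- 1 + (scen$Imax_over_I0 - 1) * fluor$Fn
    fit_partition(fluor$L_total_M, I_ratio)
  })

  gc <- stage("gc_fit", {
    pts <- fluorescence_to_binding(fluor$Fn, scen$CP_M, fluor$L_total_M)
    write_pipeline_csv(pts, file.path(output_dir, "binding_points.csv"))
    fit_kint(pts, mem, sol, scen$peptide, pH_mode = scen$pH_mode)
  })

  zeta <- stage("zeta", {
    zt <- gen_zeta_titration(scen, P_over_L = seq(0.005, 0.1, length.out = 8),
                             x_shear_A = x_shear_A, seed = seed + 1L)
    write_pipeline_csv(zt, file.path(output_dir, "zeta.csv"))
    truth <- attr(zt, "truth")
    psi_inv <- surface_from_zeta(zt$zeta_mV * 1e-3, debye_kappa(sol),
                                 x_shear_A * 1e-10, sol$temperature_K)
    write_pipeline_csv(
      data.frame(P_over_L_half = zt$P_over_L_half, psi_mV = 1e3 * psi_inv,
                 psi_model_mV = 1e3 * truth$psi_V, Xb = truth$Xb),
      file.path(output_dir, "surface_potentials.csv"))
    zt
  })

  pka <- stage("pka", {
    tab <- read_protonation_csv(prot_csv)
    rep <- hill_pka_report(tab)
    write_pipeline_csv(rep, file.path(output_dir, "pka_report.csv"))
    charges <- do.call(rbind, lapply(unique(tab$peptide), function(p) {
      sub <- tab[tab$peptide == p & tab$environment == "adsorbed", ]
      do.call(rbind, lapply(unique(sub$pH), function(ph) {
        z <- cphmd_net_charge(sub, ph)
        data.frame(peptide = p, pH = ph, zp = z$zp, sd = z$sd)
      }))
    }))
    write_pipeline_csv(charges, file.path(output_dir, "net_charges.csv"))
    list(report = rep, charges = charges)
  })

  summary <- list(
    schema_version = 1L,
    scenario = scen_name, seed = seed, pH_mode = scen$pH_mode,
    psi0_mV = electro$psi0_mV[1],
    surface_pH = stats::setNames(electro$pH_surface,
                                 paste0("bulk_", electro$pH_bulk)),
    Kp = part$Kp, Kp_sd = part$Kp_sd,
    Kint = gc$Kint, Kint_sd = gc$Kint_sd,
    zp_mean = gc$zp_mean, zp_sd = gc$zp_sd,
    pKa = stats::setNames(pka$report$pKa,
                          paste(pka$report$peptide, pka$report$residue,
                                sep = "_")),
    delta_pKa = stats::setNames(pka$report$delta_pKa,
                                paste(pka$report$peptide, pka$report$residue,
                                      sep = "_")),
    net_charges = pka$charges)
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
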