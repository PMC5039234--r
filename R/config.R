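#' Read a model configuration file
#'
#' Reads a flat key--value file (YAML by default, JSON if the extension is
#' `.json`) holding the 14 model parameters under their standard symbol
#' names (`tau_p`, `tau_s`, `k_l`, `m`, `P`, `q`, `mu_a`, `mu_s`, `e`,
#' `sigma`, `h`, `k_s`, `k_r`, `mu_r`) and, optionally, the scenario fields
#' `A0`, `R0`, `S_init`, `L_init`, `t_end`, `step`, `out_dt` and
#' `h_offset`. Missing required keys and unknown keys are each reported by
#' name; values are validated through [kw_params()].
#'
#' When `h_offset` is present (and `h` may then be omitted), the handling
#' time is meant to be resolved at run time as
#' `critical_handling_time(params) + h_offset`, which is how the scenario
#' presets encode their relation to the threshold.
#'
#' @param path path to a YAML or JSON configuration file.
#' @return list with elements `params` (a [kw_params()] object) and
#'   `scenario` (named list of the optional fields present).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  scen_names <- c("A0", "R0", "S_init", "L_init", "t_end", "step",
                  "out_dt", "h_offset", "name")
  required <- kw_param_names()
  optional_h <- "h_offset" %in% names(raw)
  need <- if (optional_h) setdiff(required, "h") else required

  unknown <- setdiff(names(raw), c(required, scen_names))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(sort(unknown), collapse = ", "))
  }
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("missing required config key(s): ",
         paste(sort(missing), collapse = ", "))
  }
  fields <- raw[intersect(required, names(raw))]
  if (!"h" %in% names(fields)) fields$h <- NA_real_
  params <- build_kw_params(fields)
  list(params = params,
       scenario = raw[intersect(scen_names, names(raw))])
}

#' Write a model configuration file
#'
#' Serialises the 14 parameter fields (plus any scenario fields) to YAML or
#' JSON, at full double precision so that a write/load round trip
#' reproduces the parameters bit-exactly.
#'
#' @param params a [kw_params()] object.
#' @param path output path; `.json` selects JSON, anything else YAML.
#' @param scenario optional named list of scenario fields (see
#'   [load_config()]).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, scenario = list()) {
  stopifnot(inherits(params, "kw_params"))
  x <- c(params[kw_param_names()], scenario)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  } else {
    writeLines(yaml::as.yaml(x, precision = 17), path)
  }
  invisible(path)
}

#' Scenario presets
#'
#' Named parameter-and-history bundles for the standard simulation
#' experiments. `fig1`--`fig5` use the simulation parameter set with
#' `A0 = 50`, `R0 = 500` and handling time resolved at run time as
#' `h_crit + offset` with offsets -1, +5, +10, +10 and +15 days per unit
#' biomass (`fig4` is the detail view of the `fig3` regime). `insect-free`
#' starts the same stand with no psyllids, and `table1` uses the larger
#' tabulated egg-laying rate `P = 23.9798`.
#'
#' @param name preset name: `"fig1"`, `"fig2"`, `"fig3"`, `"fig4"`,
#'   `"fig5"`, `"insect-free"`, or `"table1"`.
#' @return An object of class `"kw_scenario"`: `name`, `params` (with `h`
#'   still `NA`), `A0`, `R0`, `h_offset`, `t_end`.
#' @export
scenario_preset <- function(name = c("fig1", "fig2", "fig3", "fig4", "fig5",
                                     "insect-free", "table1")) {
  name <- match.arg(name)
  offs <- c(fig1 = -1, fig2 = 5, fig3 = 10, fig4 = 10, fig5 = 15,
            `insect-free` = 0, table1 = -1)
  tend <- c(fig1 = 3000, fig2 = 3000, fig3 = 3000, fig4 = 3000, fig5 = 2000,
            `insect-free` = 900, table1 = 3000)
  params <- kw_params(preset = if (name == "table1") "table1" else "eq52")
  structure(list(
    name = name, params = params,
    A0 = if (name == "insect-free") 0 else 50,
    R0 = 500,
    h_offset = unname(offs[name]),
    t_end = unname(tend[name])
  ), class = "kw_scenario")
}

#' Run a scenario preset end to end
#'
#' Resolves the handling time as `h_crit + offset`, simulates the stand,
#' and attaches the analytical context: the insect-free classification and
#' growth rate, `h_crit`, the coexistence equilibrium (when it exists) and
#' the numerical regime classification.
#'
#' @param scenario a [scenario_preset()] object or a preset name.
#' @param t_end,step,out_dt overrides of the preset's simulation controls.
#' @param out_dir optional directory; when given, the trajectory is written
#'   to `<name>_trajectory.csv` (columns `t,L,A,S,R`) and the report to
#'   `<name>_report.json`.
#' @return list with `trajectory` (a `kw_trajectory`) and `report` (named
#'   list of scalars: `h`, `h_crit`, `h_vs_hcrit`, `insect_free`,
#'   `insect_free_rate`, `regime`, equilibrium components).
#' @export
run_scenario <- function(scenario, t_end = NULL, step = 0.05, out_dt = 0.5,
                         out_dir = NULL) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  stopifnot(inherits(scenario, "kw_scenario"))
  p <- scenario$params
  hc <- critical_handling_time(p)
  p <- set_handling_time(p, hc + scenario$h_offset)
  if (is.null(t_end)) t_end <- scenario$t_end

  hist <- make_history(p, A0 = scenario$A0, R0 = scenario$R0)
  traj <- simulate_stand(p, hist, t_end = t_end, step = step,
                         out_dt = out_dt)
  eq <- solve_equilibrium(p)
  regime <- classify_regime_numeric(traj)

  report <- list(
    scenario = scenario$name,
    h = p$h, h_crit = hc,
    h_vs_hcrit = if (p$h < hc) "below" else "above",
    insect_free = classify_insect_free(p),
    insect_free_rate = insect_free_growth_rate(p),
    regime = regime,
    equilibrium_exists = eq$exists,
    L_star = eq$L_star, A_star = eq$A_star,
    S_star = eq$S_star, R_star = eq$R_star
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(traj),
                     file.path(out_dir, paste0(scenario$name, "_trajectory.csv")),
                     row.names = FALSE)
    jsonlite::write_json(report,
                         file.path(out_dir, paste0(scenario$name, "_report.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  list(trajectory = traj, report = report)
}

#' @export
print.kw_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s': A0 = %g, R0 = %g, h = h_crit %+g, t_end = %g d\n",
    x$name, x$A0, x$R0, x$h_offset, x$t_end))
  invisible(x)
}
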