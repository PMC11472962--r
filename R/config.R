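#' Load a run configuration
#'
#' Flat `key = value` text file (`#` comments and blank lines allowed).
#' Recognized keys are the model parameter names (see [addiction_params()]),
#' the initial compartments `init_S .. init_T`, the horizon `t_final`, grid
#' size `n_steps`, weights `psi1..psi6` and `D1..D6`, `strategy`, `seed`,
#' `out_dir`, and `icer_input` (path to an outcomes CSV for the `icer`
#' command). Unknown keys are rejected. An empty file yields the full default
#' configuration. Parameter validation runs on load.
#'
#' @param path path to the configuration file (`NULL` for pure defaults).
#' @return Object of class `"run_config"`: list with `params`, `init`,
#'   `t_final`, `n_steps`, `weights`, `strategy`, `seed`, `out_dir`,
#'   `icer_input`.
#' @export
load_config <- function(path = NULL) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) stop("unparsable config line: '", ln, "'")
      kv[[m[2]]] <- trimws(m[3])
    }
  }
  pnames <- names(default_params())
  inames <- paste0("init_", state_names("full"))
  wnames <- c(paste0("psi", 1:6), paste0("D", 1:6))
  snames <- c("t_final", "n_steps", "strategy", "seed", "out_dir",
              "icer_input")
  unknown <- setdiff(names(kv), c(pnames, inames, wnames, snames))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  num <- function(key, default) {
    if (is.null(kv[[key]])) return(default)
    x <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(x)) stop("config key ", key, ": unparsable value '",
                       kv[[key]], "'")
    x
  }
  over <- kv[intersect(names(kv), pnames)]
  params <- do.call(addiction_params,
                    lapply(over, function(v) num_value(v)))
  init <- addiction_state()
  for (nm in state_names("full"))
    init[[nm]] <- num(paste0("init_", nm), init[[nm]])
  weights <- control_weights(
    psi = vapply(1:6, function(i) num(paste0("psi", i), 10), numeric(1)),
    D = vapply(1:6, function(i) num(paste0("D", i), 7), numeric(1)))
  structure(list(params = params, init = init,
                 t_final = num("t_final", 5),
                 n_steps = as.integer(num("n_steps", 1000)),
                 weights = weights,
                 strategy = kv[["strategy"]] %||% "I",
                 seed = as.integer(num("seed", 1)),
                 out_dir = kv[["out_dir"]] %||% ".",
                 icer_input = kv[["icer_input"]]),
            class = "run_config")
}

num_value <- function(v) {
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) stop("unparsable numeric value '", v, "'")
  x
}

#' Serialize a run configuration
#'
#' Writes every resolved field back out as flat `key = value` text, so a
#' round trip through [load_config()] reproduces the configuration exactly;
#' used to log the resolved configuration next to pipeline outputs.
#'
#' @param config a `"run_config"` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- function(x) format(x, digits = 17)
  lines <- c(
    vapply(names(config$params), function(nm)
      paste(nm, "=", fmt(config$params[[nm]])), character(1)),
    vapply(state_names("full"), function(nm)
      paste0("init_", nm, " = ", fmt(config$init[[nm]])), character(1)),
    paste("t_final =", fmt(config$t_final)),
    paste("n_steps =", config$n_steps),
    vapply(1:6, function(i)
      paste0("psi", i, " = ", fmt(config$weights$psi[i])), character(1)),
    vapply(1:6, function(i)
      paste0("D", i, " = ", fmt(config$weights$D[i])), character(1)),
    paste("strategy =", config$strategy),
    paste("seed =", config$seed),
    paste("out_dir =", config$out_dir))
  if (!is.null(config$icer_input))
    lines <- c(lines, paste("icer_input =", config$icer_input))
  writeLines(lines, path)
  invisible(path)
}

#' Run an analysis pipeline command
#'
#' Deterministic orchestration of the package's analyses. Commands:
#' \describe{
#'   \item{`simulate`}{full-model trajectory CSV.}
#'   \item{`r0`}{closed-form and NGM reproduction numbers with their
#'     cross-check delta (JSON).}
#'   \item{`bifurcation`}{bifurcation curve CSV for the dominant pathway.}
#'   \item{`sensitivity`}{ranked elasticity table CSV.}
#'   \item{`control`}{forward-backward sweep for `config$strategy`:
#'     trajectory CSV, control schedule CSV and a JSON summary.}
#'   \item{`icer`}{ICER ranking plus dominance elimination of the outcomes in
#'     `config$icer_input` (CSV `strategy,averted,cost`): table CSV and JSON
#'     elimination log.}
#' }
#' The resolved configuration is serialized next to the outputs for
#' provenance. All commands are pure functions of (config, seed).
#'
#' @param config a `"run_config"` object (see [load_config()]).
#' @param command one of the commands above.
#' @param quiet suppress progress messages.
#' @return Named list of output file paths, invisibly; plus a `summary`
#'   element with the command's headline numbers.
#' @export
run_pipeline <- function(config, command = c("simulate", "r0", "bifurcation",
                                             "sensitivity", "control",
                                             "icer"),
                         quiet = FALSE) {
  command <- match.arg(command)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- function(name) file.path(config$out_dir, name)
  set.seed(config$seed)
  files <- list(config = write_config(config, out("config_resolved.txt")))
  say("[", command, "] resolved config written")
  summary <- NULL
  if (command == "simulate") {
    tr <- simulate_addiction(config$params, config$init, config$t_final,
                             config$n_steps, "full")
    files$trajectory <- write_trajectory(tr, out("trajectory.csv"))
    summary <- list(final_N = tr$N[nrow(tr)])
  } else if (command == "r0") {
    rn <- reproduction_numbers(config$params)
    ngm <- c(ngm_r0(config$params, "alcohol"), ngm_r0(config$params, "smoking"))
    summary <- list(R0A = rn[["R0A"]], R0S = rn[["R0S"]], R0AS = rn[["R0AS"]],
                    ngm_delta = max(abs(c(rn[["R0A"]], rn[["R0S"]]) - ngm)))
    jsonlite::write_json(summary, out("r0.json"), auto_unbox = TRUE,
                         digits = NA)
    files$r0 <- out("r0.json")
  } else if (command == "bifurcation") {
    rn <- reproduction_numbers(config$params)
    pathway <- if (rn[["R0A"]] >= rn[["R0S"]]) "alcohol" else "smoking"
    bkey <- if (pathway == "alcohol") "beta1" else "beta2"
    bstar <- config$params[[bkey]] / rn[[if (pathway == "alcohol") "R0A" else "R0S"]]
    grid <- seq(0.2, 1.6, by = 0.1) * bstar
    bc <- bifurcation_curve(config$params, pathway, grid)
    utils::write.csv(bc, out("bifurcation.csv"), row.names = FALSE)
    files$bifurcation <- out("bifurcation.csv")
    summary <- list(pathway = pathway, beta_star = bstar,
                    endemic_points = sum(bc$branch == "endemic"))
  } else if (command == "sensitivity") {
    tab <- sensitivity_table(config$params, "dual")
    utils::write.csv(tab, out("sensitivity.csv"), row.names = FALSE)
    files$sensitivity <- out("sensitivity.csv")
    summary <- list(top = tab$parameter[1], top_index = tab$index[1])
  } else if (command == "control") {
    sol <- forward_backward_sweep(config$params, config$weights,
                                  config$strategy, config$init,
                                  config$t_final, config$n_steps)
    files$trajectory <- write_trajectory(sol$trajectory,
                                         out("controlled_trajectory.csv"))
    utils::write.csv(sol$controls, out("controls.csv"), row.names = FALSE)
    files$controls <- out("controls.csv")
    summary <- list(strategy = sol$strategy, objective = sol$objective,
                    objective_uncontrolled = sol$objective_uncontrolled,
                    iterations = sol$iterations, converged = sol$converged)
    jsonlite::write_json(summary, out("control_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files$summary <- out("control_summary.json")
  } else if (command == "icer") {
    outcomes <- if (!is.null(config$icer_input)) read_outcomes(config$icer_input)
                else reference_outcomes("overall")
    final <- eliminate_dominated(build_icer_table(outcomes))
    hist <- attr(final, "elimination")
    rounds <- attr(final, "rounds")
    utils::write.csv(as.data.frame(rounds[[1]]), out("icer_table.csv"),
                     row.names = FALSE)
    files$icer_table <- out("icer_table.csv")
    summary <- list(winner = attr(final, "winner"),
                    eliminated = hist$removed, icers = hist$icer)
    jsonlite::write_json(summary, out("icer_elimination.json"),
                         auto_unbox = TRUE, digits = NA)
    files$elimination <- out("icer_elimination.json")
  }
  say("[", command, "] done")
  files$summary_values <- summary
  invisible(files)
}
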