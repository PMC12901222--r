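#' Load a scenario configuration
#'
#' A scenario file (YAML or JSON, chosen by extension) describes a complete
#' simulation: disease preset, parameter overrides, initial conditions, unit
#' conventions, dose schedule, which system to integrate, and an optional
#' adaptive-dosing block. Clinical units are used in the file (weeks, hours,
#' mg, mg/L) and normalized to SI-molar on load.
#'
#' Recognized top-level fields:
#' \describe{
#'   \item{preset}{`"CD"`, `"UC"` or `"custom"`.}
#'   \item{params}{named overrides of [ifx_params()] fields.}
#'   \item{init}{named overrides `L0`, `r0`, `A0`, `C0` (molar /
#'     dimensionless).}
#'   \item{conventions}{overrides of [unit_conventions()] fields.}
#'   \item{schedule}{either `events`, a list of
#'     `{start_weeks, duration_hours, dose_mg}` records plus optional
#'     `horizon_weeks`, or `regular`,
#'     `{dose_mg, n_doses, interval_weeks, duration_hours}`.}
#'   \item{system}{`"full"`, `"constant_production"` or `"reduced"`.}
#'   \item{adaptive}{optional block `{delta_a0, dose_mg, n_doses,
#'     interval_weeks, threshold_mgL, hill: {V, K, n}}`.}
#'   \item{seed}{optional integer pinning any randomness.}
#' }
#'
#' @param path file to read.
#' @return Object of class `ifx_config`: resolved `preset`, `params`
#'   ([ifx_params()]), `init` ([ifx_state()]), `conv`
#'   ([unit_conventions()]), `schedule` (`ifx_schedule` or `NULL`),
#'   `system`, `adaptive` (resolved list or `NULL`), `seed`, and `raw` (the
#'   file-level representation, used by [save_config()]).
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' writeLines("preset: CD", path)
#' cfg <- load_config(path)
#' cfg$init
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  resolve_config(raw)
}

resolve_config <- function(raw) {
  known <- c("preset", "params", "init", "conventions", "schedule",
             "system", "adaptive", "seed", "output")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  preset <- raw$preset %||% "custom"
  if (!preset %in% c("CD", "UC", "custom")) {
    stop("unknown preset '", preset, "' (expected CD, UC or custom)",
         call. = FALSE)
  }

  check_num <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop("config field '", field, "' must be a single finite number",
           call. = FALSE)
    }
    x
  }

  par_over <- raw$params %||% list()
  bad <- setdiff(names(par_over), names(formals(ifx_params)))
  if (length(bad)) {
    stop("unknown params field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(par_over)) {
    par_over[[nm]] <- check_num(par_over[[nm]], paste0("params.", nm))
  }
  params <- do.call(ifx_params, par_over)

  init_over <- raw$init %||% list()
  bad <- setdiff(names(init_over), c("L0", "r0", "A0", "C0"))
  if (length(bad)) {
    stop("unknown init field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(init_over)) {
    init_over[[nm]] <- check_num(init_over[[nm]], paste0("init.", nm))
  }
  base_init <- if (preset %in% c("CD", "UC")) {
    ifx_preset(preset)$init
  } else {
    if (is.null(init_over$L0) || is.null(init_over$r0)) {
      stop("custom preset requires init.L0 and init.r0", call. = FALSE)
    }
    ifx_state(init_over$L0, init_over$r0, 0, 0)
  }
  init <- ifx_state(L = init_over$L0 %||% base_init[["L"]],
                    r = init_over$r0 %||% base_init[["r"]],
                    A = init_over$A0 %||% base_init[["A"]],
                    C = init_over$C0 %||% base_init[["C"]])

  conv_over <- raw$conventions %||% list()
  bad <- setdiff(names(conv_over), names(formals(unit_conventions)))
  if (length(bad)) {
    stop("unknown conventions field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(conv_over)) {
    conv_over[[nm]] <- check_num(conv_over[[nm]], paste0("conventions.", nm))
  }
  conv <- do.call(unit_conventions, conv_over)

  schedule <- NULL
  if (!is.null(raw$schedule)) {
    sc <- raw$schedule
    bad <- setdiff(names(sc), c("events", "regular", "horizon_weeks"))
    if (length(bad)) {
      stop("unknown schedule field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!is.null(sc$regular)) {
      rg <- sc$regular
      schedule <- regular_schedule(
        dose_mg = check_num(rg$dose_mg, "schedule.regular.dose_mg"),
        n_doses = check_num(rg$n_doses, "schedule.regular.n_doses"),
        interval = weeks(check_num(rg$interval_weeks %||% 4,
                                   "schedule.regular.interval_weeks")),
        duration = hours(check_num(rg$duration_hours %||% 2,
                                   "schedule.regular.duration_hours")))
    } else if (!is.null(sc$events)) {
      events <- lapply(seq_along(sc$events), function(i) {
        e <- sc$events[[i]]
        fld <- function(nm) {
          check_num(e[[nm]], sprintf("schedule.events[%d].%s", i, nm))
        }
        infusion_event(start = weeks(fld("start_weeks")),
                       duration = hours(fld("duration_hours")),
                       dose_mg = fld("dose_mg"))
      })
      horizon <- if (!is.null(sc$horizon_weeks)) {
        weeks(check_num(sc$horizon_weeks, "schedule.horizon_weeks"))
      } else NULL
      schedule <- dose_schedule(events, horizon = horizon)
    } else if (!is.null(sc$horizon_weeks)) {
      schedule <- dose_schedule(
        list(), horizon = weeks(check_num(sc$horizon_weeks,
                                          "schedule.horizon_weeks")))
    }
  }

  system <- raw$system %||% "full"
  if (!system %in% c("full", "constant_production", "reduced")) {
    stop("unknown system '", system, "'", call. = FALSE)
  }

  adaptive <- NULL
  if (!is.null(raw$adaptive)) {
    ad <- raw$adaptive
    bad <- setdiff(names(ad), c("delta_a0", "dose_mg", "n_doses",
                                "interval_weeks", "threshold_mgL", "hill"))
    if (length(bad)) {
      stop("unknown adaptive field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    hill <- if (is.null(ad$hill)) hill_params() else {
      hill_params(V = check_num(ad$hill$V %||% 6.8939e-6, "adaptive.hill.V"),
                  K = check_num(ad$hill$K %||% 0.5809e-9, "adaptive.hill.K"),
                  n = check_num(ad$hill$n %||% 0.2590, "adaptive.hill.n"))
    }
    adaptive <- list(
      delta_a0 = check_num(ad$delta_a0 %||% 3.5e-6, "adaptive.delta_a0"),
      dose_mg = check_num(ad$dose_mg %||% 350, "adaptive.dose_mg"),
      n_doses = check_num(ad$n_doses %||% 13, "adaptive.n_doses"),
      interval = weeks(check_num(ad$interval_weeks %||% 4,
                                 "adaptive.interval_weeks")),
      threshold = mass_to_molar_conc(
        check_num(ad$threshold_mgL %||% 3, "adaptive.threshold_mgL"),
        conv$ifx_molar_mass),
      hill = hill)
  }

  seed <- raw$seed
  if (!is.null(seed)) seed <- check_num(seed, "seed")

  structure(list(preset = preset, params = params, init = init,
                 conv = conv, schedule = schedule, system = system,
                 adaptive = adaptive, seed = seed, output = raw$output,
                 raw = raw),
            class = "ifx_config")
}

#' Save a scenario configuration
#'
#' Writes the file-level representation of a config back to YAML or JSON.
#' `load_config(save_config(cfg, path))` restores an identical
#' configuration.
#'
#' @param config an `ifx_config` (or the raw list form).
#' @param path output file; extension selects YAML (default) or JSON.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  raw <- if (inherits(config, "ifx_config")) config$raw else config
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(raw, path)
  }
  invisible(path)
}

#' Generate example scenario and dataset fixtures
#'
#' Writes a set of small plain-text fixtures: the CD and UC preset
#' scenarios, the irregular induction-style schedule (weeks 0, 2, 6, 10),
#' the standard three-dose protocol, the one-year adaptive regimen (13
#' four-weekly 500 mg doses), and two inverted-Hill datasets — one exact
#' and one with 1% multiplicative noise under a recorded seed (regeneration
#' with the same seed is byte-identical).
#'
#' @param out_dir writable directory (created if missing).
#' @param seed integer seed for the noisy dataset.
#' @return Character vector of the written paths, invisibly.
#' @export
generate_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wr <- function(raw, name) {
    p <- file.path(out_dir, name)
    save_config(raw, p)
    paths <<- c(paths, p)
  }
  std3 <- list(regular = list(dose_mg = 350, n_doses = 3,
                              interval_weeks = 4, duration_hours = 2))
  wr(list(preset = "CD", schedule = std3, system = "full"), "cd.yaml")
  wr(list(preset = "UC", schedule = std3, system = "full"), "uc.yaml")
  wr(list(preset = "CD", system = "full",
          schedule = list(events = lapply(c(0, 2, 6, 10), function(w) {
            list(start_weeks = w, duration_hours = 2, dose_mg = 350)
          }), horizon_weeks = 14)),
     "schedule_induction.yaml")
  wr(list(preset = "CD", schedule = std3, system = "full"),
     "schedule_standard.yaml")
  wr(list(preset = "CD", system = "full",
          schedule = list(regular = list(dose_mg = 500, n_doses = 13,
                                         interval_weeks = 4,
                                         duration_hours = 2)),
          adaptive = list(delta_a0 = 3.5e-6, dose_mg = 500, n_doses = 13,
                          interval_weeks = 4, threshold_mgL = 3)),
     "adaptive_500mg.yaml")

  hp <- hill_params()
  A <- 10^seq(-11, -7, length.out = 30)
  exact <- data.frame(A_min_M = A, delta_a = hill_clearance(A, hp))
  p <- file.path(out_dir, "hill_noiseless.csv")
  utils::write.csv(format(exact, digits = 15), p, row.names = FALSE,
                   quote = FALSE)
  paths <- c(paths, p)

  set.seed(seed)
  noisy <- data.frame(A_min_M = A,
                      delta_a = hill_clearance(A, hp) *
                        (1 + 0.01 * stats::rnorm(length(A))))
  p <- file.path(out_dir, "hill_noisy.csv")
  con <- file(p, "w")
  writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.table(format(noisy, digits = 15), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  close(con)
  paths <- c(paths, p)

  invisible(paths)
}
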