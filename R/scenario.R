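#' Load and validate a scenario configuration file
#'
#' Scenarios are flat YAML files with explicit units in the key names
#' (rates in \code{*_per_day}, times in \code{*_days}). A scenario selects
#' a model variant, the cohort sizes, and either explicit rate constants
#' (a \code{rates} block) or observed timescales to fit them from (a
#' \code{fit} block with \code{t1_days}, \code{t99_days}, \code{tau_days}).
#' An optional \code{deaths} block supplies per-compartment death rates for
#' the mortality analyses, and an optional \code{grid} block
#' (\code{t_max_days}, \code{dt_days}) controls trajectory output.
#'
#' @param path Path to the YAML file. The package ships a fixture for the
#'   historical example:
#'   \code{system.file("extdata", "haiti.yaml", package = "surgekinetics")}.
#' @return A validated list of class \code{"surge_scenario"}.
#' @examples
#' sc <- load_scenario(system.file("extdata", "haiti.yaml",
#'                                 package = "surgekinetics"))
#' sc$fit
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw)) {
    stop("empty scenario file; required keys: model, and a 'rates' or 'fit' block")
  }
  validate_scenario(raw)
}

validate_scenario <- function(raw) {
  known_top <- c("name", "model", "n0", "a0", "p0", "threshold",
                 "rates", "fit", "deaths", "grid")
  extra <- setdiff(names(raw), known_top)
  if (length(extra)) {
    warning("ignoring unknown scenario keys: ", paste(extra, collapse = ", "))
  }
  if (is.null(raw$model)) stop("scenario is missing the required key 'model'")
  model <- match.arg(raw$model,
                     c("simple", "delayed", "capacity", "ptc", "mortality"))
  n0 <- raw$n0 %||% 1
  if (!is.numeric(n0) || n0 <= 0) stop("'n0' must be a positive count")
  threshold <- raw$threshold %||% 0.99
  if (threshold <= 0 || threshold >= 1) stop("'threshold' must be in (0, 1)")

  if (is.null(raw$rates) && is.null(raw$fit)) {
    stop("scenario needs a 'rates' block or a 'fit' block ",
         "(t1_days, t99_days, tau_days)")
  }
  fit <- NULL
  if (!is.null(raw$fit)) {
    need <- c("t1_days", "t99_days", "tau_days")
    miss <- setdiff(need, names(raw$fit))
    if (length(miss)) {
      stop("fit block is missing: ", paste(miss, collapse = ", "))
    }
    fit <- list(t1 = raw$fit$t1_days, t99 = raw$fit$t99_days,
                tau = raw$fit$tau_days,
                branch = raw$fit$branch %||% "ka<kd")
  }
  rates <- NULL
  if (!is.null(raw$rates)) {
    rates <- scenario_rates(model, raw$rates)
  }
  a0 <- raw$a0; p0 <- raw$p0
  if (model %in% c("ptc", "mortality")) {
    if (!is.null(a0) && !is.null(p0) && abs(a0 + p0 - n0) > 1e-9 * n0) {
      stop("cohort split must satisfy a0 + p0 = n0 (got ", a0, " + ", p0,
           " != ", n0, ")")
    }
    if (is.null(p0)) p0 <- n0
  }
  deaths <- NULL
  if (!is.null(raw$deaths)) {
    d <- raw$deaths
    need <- c("omega_s_per_day", "omega_a_per_day", "omega_p_per_day",
              "omega_d_per_day")
    miss <- setdiff(need, names(d))
    if (length(miss)) stop("deaths block is missing: ",
                           paste(miss, collapse = ", "))
    deaths <- death_rate_set(
      omega_s = d$omega_s_per_day, omega_a = d$omega_a_per_day,
      omega_p = d$omega_p_per_day, omega_d = d$omega_d_per_day,
      omega_a_prime = d$omega_a_prime_per_day %||% d$omega_a_per_day,
      omega_p_prime = d$omega_p_prime_per_day %||% d$omega_p_per_day)
  }
  if (model == "mortality" && is.null(deaths)) {
    stop("the mortality variant requires a 'deaths' block")
  }
  grid <- list(t_max = raw$grid$t_max_days %||% NA_real_,
               dt = raw$grid$dt_days %||% 0.1)
  structure(list(name = raw$name %||% "scenario", model = model, n0 = n0,
                 a0 = a0, p0 = p0, threshold = threshold, rates = rates,
                 fit = fit, deaths = deaths, grid = grid),
            class = "surge_scenario")
}

scenario_rates <- function(model, rb) {
  get <- function(key) {
    if (is.null(rb[[key]])) stop("rates block is missing '", key, "'")
    rb[[key]]
  }
  switch(model,
    simple = rate_set(get("ka_per_day"), get("kd_per_day"),
                      rb$kprime_per_day %||% NA_real_),
    capacity = rate_set(get("ka_per_day"), get("kd_per_day"),
                        get("kprime_per_day")),
    delayed = delayed_rate_set(get("ks_per_day"), get("ka_per_day"),
                               get("kd_per_day")),
    ptc = ,
    mortality = ptc_rate_set(get("kpaa_per_day"), get("kpap_per_day"),
                             get("kpda_per_day"), get("kpdp_per_day"),
                             get("ka_prime_per_day"),
                             get("kp_prime_per_day")))
}

#' Serialize a scenario back to YAML
#'
#' Writes a [load_scenario()] object in the same flat, unit-suffixed format
#' it is read from, so that load -> dump -> load is an identity.
#'
#' @param scenario A \code{"surge_scenario"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "surge_scenario"))
  out <- list(name = scenario$name, model = scenario$model, n0 = scenario$n0)
  if (!is.null(scenario$a0)) out$a0 <- scenario$a0
  if (!is.null(scenario$p0)) out$p0 <- scenario$p0
  out$threshold <- scenario$threshold
  if (!is.null(scenario$rates)) {
    r <- scenario$rates
    out$rates <- if (inherits(r, "ptc_rate_set")) {
      list(kpaa_per_day = r$kpaa, kpap_per_day = r$kpap,
           kpda_per_day = r$kpda, kpdp_per_day = r$kpdp,
           ka_prime_per_day = r$ka_prime, kp_prime_per_day = r$kp_prime)
    } else if (inherits(r, "delayed_rate_set")) {
      list(ks_per_day = r$ks, ka_per_day = r$ka, kd_per_day = r$kd)
    } else {
      rl <- list(ka_per_day = r$ka, kd_per_day = r$kd)
      if (!is.na(r$kprime)) rl$kprime_per_day <- r$kprime
      rl
    }
  }
  if (!is.null(scenario$fit)) {
    out$fit <- list(t1_days = scenario$fit$t1, t99_days = scenario$fit$t99,
                    tau_days = scenario$fit$tau, branch = scenario$fit$branch)
  }
  if (!is.null(scenario$deaths)) {
    d <- scenario$deaths
    out$deaths <- list(omega_s_per_day = d$omega_s,
                       omega_a_per_day = d$omega_a,
                       omega_p_per_day = d$omega_p,
                       omega_d_per_day = d$omega_d,
                       omega_a_prime_per_day = d$omega_a_prime,
                       omega_p_prime_per_day = d$omega_p_prime)
  }
  if (!is.na(scenario$grid$t_max)) {
    out$grid <- list(t_max_days = scenario$grid$t_max,
                     dt_days = scenario$grid$dt)
  }
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Build the surge model described by a scenario
#'
#' Resolves a scenario to a concrete [surge_model()], running the timescale
#' fit first when the scenario supplies observations instead of rates. For
#' the two-center variants a scenario fitted from single-center data uses
#' the fitted rates for the adult center and a rate-matched PTC.
#'
#' @param scenario A \code{"surge_scenario"}.
#' @return A [surge_model()].
#' @export
scenario_model <- function(scenario) {
  stopifnot(inherits(scenario, "surge_scenario"))
  rates <- scenario$rates
  if (is.null(rates)) {
    f <- surge_fit(scenario$fit$t1, scenario$fit$t99, scenario$fit$tau,
                   branch = scenario$fit$branch,
                   threshold = scenario$threshold)
    rates <- f$rates
    if (scenario$model %in% c("ptc", "mortality")) {
      rates <- ptc_rate_set(kpaa = rates$ka, kpap = rates$ka,
                            kpda = rates$kd, kpdp = rates$kd,
                            ka_prime = rates$kprime,
                            kp_prime = rates$kprime)
    }
  }
  n0 <- if (scenario$model %in% c("ptc", "mortality"))
    scenario$p0 %||% scenario$n0 else scenario$n0
  surge_model(scenario$model, rates, deaths = scenario$deaths,
              n0 = n0, threshold = scenario$threshold)
}

# Stable content hash of a scenario, recorded in CSV output headers.
scenario_hash <- function(scenario) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_scenario(scenario, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a trajectory as CSV with a provenance comment
#'
#' @param trajectory A trajectory data.frame from one of the evaluators.
#' @param path Output path.
#' @param scenario Optional \code{"surge_scenario"}; when given, its
#'   content hash is recorded in a leading comment line.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path, scenario = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(scenario)) {
    writeLines(paste0("# scenario_md5: ", scenario_hash(scenario)), con)
  }
  utils::write.csv(trajectory, con, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
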