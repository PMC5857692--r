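# Configuration: the whole parameter set and scenario serialise to a plain
# YAML or JSON document (tables inline as column lists, or referenced as
# CSV paths), load back with defaults applied and logged, and hash into a
# run manifest that makes any result reproducible from (seed, digest).

# ---- serialisation of components ------------------------------------------

engine_to_list <- function(e) {
  list(engine_name = e$engine_name, horizon = e$horizon,
       baseline_survival = e$baseline_survival,
       terms = list(term = e$terms$term, transform = e$terms$transform,
                    weight = e$terms$weight))
}

engine_from_list <- function(l) {
  risk_coefficients(
    engine_name = l$engine_name, horizon = l$horizon,
    baseline_survival = l$baseline_survival,
    terms = data.frame(term = unlist(l$terms$term),
                       transform = unlist(l$terms$transform),
                       weight = unlist(l$terms$weight),
                       stringsAsFactors = FALSE)
  )
}

df_to_list <- function(d) lapply(as.list(d), function(col) unname(col))

df_from_list <- function(l) {
  data.frame(lapply(l, unlist), stringsAsFactors = FALSE)
}

#' Serialise a parameter set and scenario to a config document
#'
#' Writes the fully resolved configuration (every default made explicit,
#' tables inline) as YAML or JSON, chosen by the file extension. A document
#' written here reloads to an identical parameter set via [load_config()].
#'
#' @param params a [default_parameters()] parameter set.
#' @param scenario a [scenario_config()].
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @export
save_config <- function(params, scenario, path) {
  doc <- list(
    scenario = list(arm = scenario$arm,
                    polypill_version = scenario$polypill_version,
                    master_seed = scenario$master_seed, n = scenario$n),
    parameters = list(
      discount_rate = params$discount_rate,
      age_cap = params$age_cap,
      update_interval = params$update_interval,
      inclusion_threshold = params$inclusion_threshold,
      baseline_gi_hazard = params$baseline_gi_hazard,
      primary_engine = engine_to_list(params$primary_engine),
      secondary_engine = engine_to_list(params$secondary_engine),
      diabetes_engine = engine_to_list(params$diabetes_engine),
      hf_table = df_to_list(params$hf_table),
      rel_incidence = as.list(params$rel_incidence),
      treatment_effects = unclass(params$treatment_effects),
      adherence_model = list(
        intercept = params$adherence_model$intercept,
        cessation_hazard = params$adherence_model$cessation_hazard,
        terms = list(term = params$adherence_model$terms$term,
                     transform = params$adherence_model$terms$transform,
                     weight = params$adherence_model$terms$weight)
      ),
      adherence_rr = list(rr = params$adherence_rr$rr,
                          ci_low = params$adherence_rr$ci_low,
                          ci_high = params$adherence_rr$ci_high,
                          se_log = params$adherence_rr$se_log),
      case_fatality = list(stroke = as.list(params$case_fatality$stroke),
                           mi = as.list(params$case_fatality$mi)),
      life_table = df_to_list(params$life_table),
      costs = list(
        acute = as.list(params$costs$acute),
        state_annual = as.list(params$costs$state_annual),
        med_annual = as.list(params$costs$med_annual),
        polypill_annual = params$costs$polypill_annual,
        monitoring_annual = params$costs$monitoring_annual,
        stopping = params$costs$stopping,
        currency_year = params$costs$currency_year
      ),
      utilities = list(
        baseline = df_to_list(params$utilities$baseline),
        decrements = as.list(params$utilities$decrements),
        transient = lapply(params$utilities$transient, as.list)
      )
    )
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    writeLines(yaml::as.yaml(doc, precision = 15), path)
  } else if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    stop("save_config: path must end in .yaml, .yml or .json", call. = FALSE)
  }
  invisible(path)
}

num1 <- function(x) as.numeric(x)[1]

#' Load and validate a configuration document
#'
#' Reads a YAML or JSON config (as written by [save_config()], or a partial
#' document), fills in every missing field from the packaged defaults —
#' logging each applied default — and validates everything, reporting all
#' violations with their field paths rather than the first.
#'
#' @param path config file path (`.yaml`, `.yml` or `.json`).
#' @param quiet suppress the applied-defaults log messages?
#' @return List with `params` (a `parameter_set`) and `scenario` (a
#'   `scenario_config`).
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("load_config: path must end in .yaml, .yml or .json", call. = FALSE)
  }

  note <- function(field) {
    if (!quiet) message(sprintf("config: '%s' not given; packaged default applied", field))
  }
  p <- doc$parameters %||% list()
  getp <- function(field, default) {
    if (is.null(p[[field]])) {
      note(paste0("parameters.", field))
      default
    } else {
      p[[field]]
    }
  }

  params <- default_parameters(
    primary_engine = if (is.null(p$primary_engine)) {
      note("parameters.primary_engine"); default_primary_engine()
    } else engine_from_list(p$primary_engine),
    secondary_engine = if (is.null(p$secondary_engine)) {
      note("parameters.secondary_engine"); default_secondary_engine()
    } else engine_from_list(p$secondary_engine),
    diabetes_engine = if (is.null(p$diabetes_engine)) {
      note("parameters.diabetes_engine"); default_diabetes_engine()
    } else engine_from_list(p$diabetes_engine),
    hf_table = if (is.null(p$hf_table)) {
      note("parameters.hf_table"); default_hf_table()
    } else df_from_list(p$hf_table),
    rel_incidence = if (is.null(p$rel_incidence)) {
      note("parameters.rel_incidence"); default_rel_incidence()
    } else unlist(p$rel_incidence),
    treatment_effects = if (is.null(p$treatment_effects)) {
      note("parameters.treatment_effects"); treatment_effects()
    } else do.call(treatment_effects, lapply(p$treatment_effects, num1)),
    adherence_model = if (is.null(p$adherence_model)) {
      note("parameters.adherence_model"); default_adherence_model()
    } else adherence_model(
      intercept = num1(p$adherence_model$intercept),
      terms = data.frame(term = unlist(p$adherence_model$terms$term),
                         transform = unlist(p$adherence_model$terms$transform),
                         weight = unlist(p$adherence_model$terms$weight),
                         stringsAsFactors = FALSE),
      cessation_hazard = num1(p$adherence_model$cessation_hazard)
    ),
    adherence_rr = if (is.null(p$adherence_rr)) {
      note("parameters.adherence_rr"); default_adherence_rr()
    } else adherence_rr(num1(p$adherence_rr$rr), num1(p$adherence_rr$ci_low),
                        num1(p$adherence_rr$ci_high),
                        se_log = if (is.null(p$adherence_rr$se_log)) {
                          NA_real_
                        } else num1(p$adherence_rr$se_log)),
    case_fatality = if (is.null(p$case_fatality)) {
      note("parameters.case_fatality"); case_fatality()
    } else case_fatality(stroke = unlist(p$case_fatality$stroke),
                         mi = unlist(p$case_fatality$mi)),
    life_table = if (is.null(p$life_table)) {
      note("parameters.life_table"); default_life_table()
    } else df_from_list(p$life_table),
    costs = if (is.null(p$costs)) {
      note("parameters.costs"); cost_table()
    } else cost_table(
      acute = unlist(p$costs$acute),
      state_annual = unlist(p$costs$state_annual),
      med_annual = unlist(p$costs$med_annual),
      polypill_annual = if (is.null(p$costs$polypill_annual)) NULL else
        num1(p$costs$polypill_annual),
      monitoring_annual = num1(p$costs$monitoring_annual),
      stopping = num1(p$costs$stopping),
      currency_year = num1(p$costs$currency_year)
    ),
    utilities = if (is.null(p$utilities)) {
      note("parameters.utilities"); utility_table()
    } else utility_table(
      baseline = df_from_list(p$utilities$baseline),
      decrements = unlist(p$utilities$decrements),
      transient = lapply(p$utilities$transient, unlist)
    ),
    baseline_gi_hazard = getp("baseline_gi_hazard", 0.001),
    discount_rate = getp("discount_rate", 0.035),
    age_cap = getp("age_cap", 100),
    update_interval = getp("update_interval", 10),
    inclusion_threshold = getp("inclusion_threshold", 0.15)
  )

  s <- doc$scenario %||% list()
  gets <- function(field, default) {
    if (is.null(s[[field]])) {
      note(paste0("scenario.", field))
      default
    } else {
      s[[field]]
    }
  }
  scenario <- scenario_config(
    arm = gets("arm", "usual"),
    polypill_version = gets("polypill_version", "v1"),
    master_seed = gets("master_seed", 1L),
    n = gets("n", 1000L)
  )
  list(params = params, scenario = scenario)
}

#' Run manifest: seed plus parameter digest
#'
#' A manifest pins everything needed to reproduce a run bit-for-bit: the
#' master seed, a digest of the fully resolved configuration, and version
#' metadata.
#'
#' @param params a `parameter_set`.
#' @param scenario a `scenario_config`.
#' @return List with `master_seed`, `n`, `parameter_digest`, `package` and
#'   `r_version`.
#' @export
run_manifest <- function(params, scenario) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(params, scenario, tmp)
  digest <- fnv1a(paste(readLines(tmp, warn = FALSE), collapse = "\n"))
  list(
    master_seed = scenario$master_seed,
    n = scenario$n,
    arm = scenario$arm,
    parameter_digest = digest,
    package = as.character(utils::packageVersion("polypillCEA")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  )
}

#' Write a run manifest as JSON
#' @param manifest a [run_manifest()] list.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write cost and utility tables to CSV
#'
#' Costs serialise as `item`, `category`, `value` rows; utilities as two
#' CSVs would lose the band structure, so the baseline table goes out as-is
#' with decrement rows appended (`age = NA`).
#' @param costs a [cost_table()].
#' @param path file path.
#' @export
write_cost_table <- function(costs, path) {
  rows <- rbind(
    data.frame(category = "acute", item = names(costs$acute),
               value = unname(costs$acute)),
    data.frame(category = "state_annual", item = names(costs$state_annual),
               value = unname(costs$state_annual)),
    data.frame(category = "med_annual", item = names(costs$med_annual),
               value = unname(costs$med_annual)),
    data.frame(category = "scalar",
               item = c("monitoring_annual", "stopping", "currency_year"),
               value = c(costs$monitoring_annual, costs$stopping,
                         costs$currency_year))
  )
  if (!is.null(costs$polypill_annual)) {
    rows <- rbind(rows, data.frame(category = "scalar",
                                   item = "polypill_annual",
                                   value = costs$polypill_annual))
  }
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a cost table CSV written by [write_cost_table()]
#' @param path file path.
#' @export
read_cost_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  pick <- function(cat) {
    r <- d[d$category == cat, , drop = FALSE]
    setNames(r$value, r$item)
  }
  sc <- pick("scalar")
  cost_table(
    acute = pick("acute"), state_annual = pick("state_annual"),
    med_annual = pick("med_annual"),
    polypill_annual = if ("polypill_annual" %in% names(sc)) {
      unname(sc[["polypill_annual"]])
    } else NULL,
    monitoring_annual = unname(sc[["monitoring_annual"]]),
    stopping = unname(sc[["stopping"]]),
    currency_year = unname(sc[["currency_year"]])
  )
}
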