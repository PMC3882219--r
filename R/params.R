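#' @useDynLib xenopkpd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim uniroot rnorm sd approx median quantile setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

.xeno_env <- new.env(parent = emptyenv())

#' Configuration schema with units and defaults
#'
#' Every numeric default of the package lives in one schema file
#' (`inst/extdata/config-schema.json`); this returns it parsed.
#'
#' @return Nested list: sections (`parameters`, `simulation`, `protocol`,
#'   `synthetic`, `scenario`), each a named list of field descriptors with
#'   `unit`, `min`/`max`, `default` and `description`.
#' @export
config_schema <- function() {
  if (is.null(.xeno_env$schema)) {
    path <- system.file("extdata", "config-schema.json", package = "xenopkpd")
    .xeno_env$schema <- jsonlite::read_json(path, simplifyVector = FALSE)
  }
  .xeno_env$schema
}

schema_defaults <- function(section) {
  sch <- config_schema()[[section]]
  out <- lapply(sch, function(f) {
    d <- f$default
    if (is.list(d)) d <- unlist(d)
    d
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Construct a validated model parameter set
#'
#' Builds the full parameter list of the coupled model: logistic growth and
#' treatment-response parameters, both drugs' three-compartment PK constants,
#' and the Bcl-xL/Bax network rate constants.  Unspecified fields take the
#' schema defaults.  The constitutive free-Bax level `bax_baseline` is not a
#' free parameter: it is recomputed here as the drug-free equilibrium of the
#' network, so that the proliferating death rate is zero in an untreated
#' tumor (baseline turnover is folded into the net growth rate).
#'
#' @param ... named overrides of schema fields (see [config_schema()]).
#' @return Object of class `xeno_params` (named list of numerics).
#' @examples
#' p <- model_params(growth_rate = 0.1)
#' p$carrying_capacity
#' @export
model_params <- function(...) {
  ov <- list(...)
  if (length(ov) == 1L && is.list(ov[[1]]) && is.null(names(ov)[1]))
    ov <- ov[[1]]
  p <- schema_defaults("parameters")
  unknown <- setdiff(names(ov), c(names(p), "bax_baseline"))
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p <- validate_params(p)
  p$bax_baseline <- bcl_equilibrium(p, a_i = 0)[["x_B"]]
  class(p) <- "xeno_params"
  p
}

#' Validate a model parameter list against the schema
#'
#' @param p named list of parameter values.
#' @return `p` invisibly-checked (an error is thrown on violation).
#' @export
validate_params <- function(p) {
  sch <- config_schema()$parameters
  for (nm in names(sch)) {
    if (is.null(p[[nm]]))
      stop("missing parameter: ", nm)
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
    if (!is.null(sch[[nm]]$min) && v < sch[[nm]]$min)
      stop("parameter '", nm, "' = ", v, " below minimum ", sch[[nm]]$min,
           " [", sch[[nm]]$unit, "]")
    if (!is.null(sch[[nm]]$max) && v > sch[[nm]]$max)
      stop("parameter '", nm, "' = ", v, " above maximum ", sch[[nm]]$max)
  }
  if (p$bcl_kon_bax <= 0 || p$bcl_kon_abt <= 0)
    stop("association rates must be > 0 so dissociation constants are defined")
  p
}

#' @export
print.xeno_params <- function(x, ...) {
  cat("<xeno_params> ", length(x), " fields\n", sep = "")
  cat("  growth: g =", x$growth_rate, "/day, K =", x$carrying_capacity,
      "million cells\n")
  cat("  arrest: alpha_max =", x$arrest_max, "/day, psi =",
      x$arrest_duration, "day, lambda_s =", x$bax_sensitivity, "\n")
  cat("  baseline free Bax:", signif(x$bax_baseline, 4), "nM\n")
  invisible(x)
}

#' Read a run configuration file
#'
#' Configurations are a single human-editable JSON file with sections
#' `parameters`, `simulation`, `protocol`, `synthetic` and `scenario`;
#' every field is validated against [config_schema()] and missing fields are
#' filled from the schema defaults.
#'
#' @param path file path of the JSON configuration.
#' @return Named list with one element per schema section plus a
#'   `parameters` entry of class `xeno_params`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  resolve_config(raw)
}

#' Resolve and validate a configuration list
#'
#' @param raw nested list as read from a config file (may be empty).
#' @return fully-resolved configuration (all defaults materialized).
#' @export
resolve_config <- function(raw = list()) {
  sch <- config_schema()
  secs <- setdiff(names(sch), "_comment")
  bad <- setdiff(names(raw), secs)
  if (length(bad))
    stop("unknown config section(s): ", paste(bad, collapse = ", "))
  cfg <- list()
  for (sec in secs) {
    given <- if (is.null(raw[[sec]])) list() else as.list(raw[[sec]])
    if (sec == "parameters")
      given$bax_baseline <- NULL    # derived field; recomputed on build
    unknown <- setdiff(names(given), names(sch[[sec]]))
    if (length(unknown))
      stop("unknown field(s) in [", sec, "]: ",
           paste(unknown, collapse = ", "))
    out <- schema_defaults(sec)
    out[names(given)] <- given
    for (nm in names(sch[[sec]])) {
      f <- sch[[sec]][[nm]]
      v <- out[[nm]]
      if (is.null(v)) next  # required-by-scenario fields checked downstream
      if (identical(f$unit, "categorical")) next
      if (!is.numeric(v) || any(!is.finite(v)))
        stop("config field [", sec, "] ", nm, " must be numeric")
      if (!is.null(f$min) && any(v < f$min))
        stop("config field [", sec, "] ", nm, " below minimum ", f$min)
      if (!is.null(f$max) && any(v > f$max))
        stop("config field [", sec, "] ", nm, " above maximum ", f$max)
    }
    cfg[[sec]] <- out
  }
  cfg$parameters <- do.call(model_params, cfg$parameters)
  cfg
}

#' Write a resolved configuration to disk
#'
#' @param cfg configuration list (see [resolve_config()]).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  cfg$parameters <- unclass(cfg$parameters)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
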