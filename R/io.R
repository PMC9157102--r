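# Table and configuration I/O.  All tables are comma-delimited UTF-8 with
# mandatory headers; generation indices are 0-based (generation 0 is the
# founder release).  Validation errors name the offending row.

#' Read / write cage observation tables
#'
#' CSV with header `generation,carriers,noncarriers`.  Lines starting with
#' `#` are treated as comments.
#'
#' @param path CSV file path.
#' @param obs A [cage_observations()] table.
#' @return `read_cage_observations` returns a [cage_observations()];
#'   `write_cage_observations` returns `path` invisibly.
#' @export
read_cage_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("generation", "carriers", "noncarriers")
  if (!all(need %in% names(df)))
    stop("malformed cage table '", path, "': header must contain ",
         paste(need, collapse = ","))
  cage_observations(df)
}

#' @rdname read_cage_observations
#' @export
write_cage_observations <- function(obs, path) {
  stopifnot(inherits(obs, "cage_observations"))
  utils::write.csv(as.data.frame(unclass(obs)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read drive parameters and fitness model from a config file
#'
#' Flat key-value YAML whose keys are named exactly like the
#' [drive_params()] fields, plus optional `model` and
#' `homozygote_fitness` keys for the [fitness_spec()].  Missing parameter
#' keys take the measured defaults.
#'
#' @param path Config file path.
#' @return A list with elements `params` ([drive_params()]) and `spec`
#'   ([fitness_spec()]).
#' @examples
#' cfg <- read_drive_config(system.file("extdata", "params_measured.yaml",
#'                                      package = "suppdrive"))
#' cfg$params
#' @export
read_drive_config <- function(path) {
  kv <- yaml::read_yaml(path)
  if (!is.list(kv)) stop("config '", path, "' is not a flat key-value file")
  par_names <- names(formals(drive_params))
  unknown <- setdiff(names(kv), c(par_names, "model", "homozygote_fitness"))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  params <- do.call(drive_params, kv[intersect(names(kv), par_names)])
  spec <- fitness_spec(if (is.null(kv$model)) "NEUTRAL" else kv$model,
                       if (is.null(kv$homozygote_fitness)) 1
                       else kv$homozygote_fitness)
  list(params = params, spec = spec)
}

#' @rdname read_drive_config
#' @param params A [drive_params()] object.
#' @param spec Optional [fitness_spec()] to include.
#' @export
write_drive_config <- function(params, path, spec = NULL) {
  stopifnot(inherits(params, "drive_params"))
  kv <- unclass(params)
  if (!is.null(spec)) {
    kv$model <- spec$model
    kv$homozygote_fitness <- spec$homozygote_fitness
  }
  yaml::write_yaml(kv, path)
  invisible(path)
}

#' Read / write a fitted-model report
#'
#' Flat key-value (YAML) serialization of a [fit_fitness_model()] result:
#' `model`, `mle`, `loglik`, `aicc`, `ci_low`, `ci_high`, `n_transitions`.
#'
#' @param fit A `fit_result`.
#' @param path File path.
#' @return `read_fit_result` returns the key-value list;
#'   `write_fit_result` returns `path` invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  yaml::write_yaml(list(model = fit$model,
                        mle = fit$mle_fitness,
                        loglik = fit$loglik,
                        aicc = fit$aicc,
                        ci_low = fit$ci95[1],
                        ci_high = fit$ci95[2],
                        n_transitions = fit$n_transitions), path)
  invisible(path)
}

#' @rdname write_fit_result
#' @export
read_fit_result <- function(path) yaml::read_yaml(path)

#' Write simulator output as a delimited table
#'
#' One row per generation: `generation,carriers,noncarriers,load,popsize`,
#' directly readable by [read_cage_observations()].
#'
#' @param out A `sim_output`.
#' @param path CSV file path.
#' @param header Optional character vector written as leading `#` comment
#'   lines (e.g. the resolved run configuration).
#' @return `path`, invisibly.
#' @export
write_sim_output <- function(out, path, header = NULL) {
  stopifnot(inherits(out, "sim_output"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(out$generations, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
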