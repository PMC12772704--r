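#' Validate a run configuration
#'
#' Checks a plain list of sweep/run settings against the known fields,
#' rejects unknown keys, fills defaults, and re-validates parameter ranges
#' through the same constructors the computations use. The returned object
#' round-trips: `run_config(unclass(cfg))` is identical.
#'
#' @param x A named list; recognised keys are `N`, `g`, `geff`, `tau`,
#'   `tau_grid`, `N_list`, `n_realizations`, `seed`, `diagonal_policy`, and
#'   the [sim_config()] fields.
#' @return A validated `run_config` list with defaults filled.
#' @export
run_config <- function(x = list()) {
  if (inherits(x, "run_config")) x <- unclass(x)
  stopifnot(is.list(x))
  sim_fields <- names(formals(sim_config))
  known <- c("N", "g", "geff", "tau", "tau_grid", "N_list",
             "n_realizations", "seed", "diagonal_policy", sim_fields)
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  defaults <- list(N = 500L, tau = 0, n_realizations = 20L, seed = 1L,
                   diagonal_policy = "correlated_gaussian")
  for (k in names(defaults)) if (is.null(x[[k]])) x[[k]] <- defaults[[k]]
  if (is.null(x[["g"]]) && is.null(x[["geff"]])) x[["geff"]] <- 1.2
  # range validation via the constructors used downstream ([[ ]] indexing:
  # $ would partial-match g against geff)
  ensemble_params(N = x[["N"]], g = x[["g"]], geff = x[["geff"]],
                  tau = x[["tau"]], seed = x[["seed"]],
                  diagonal_policy = x[["diagonal_policy"]])
  sim_args <- x[intersect(names(x), sim_fields)]
  do.call(sim_config, sim_args)
  if (!is.null(x[["tau_grid"]]))
    stopifnot(all(is.finite(x[["tau_grid"]])), all(abs(x[["tau_grid"]]) <= 1))
  if (!is.null(x[["N_list"]]))
    stopifnot(all(x[["N_list"]] >= 1))
  structure(x, class = "run_config")
}

#' Write a result table with a metadata sidecar
#'
#' Writes `<path>` as CSV (header, stable column order) and
#' `<path>.meta.json` recording the provenance: supplied parameters, seeds,
#' package version, and a timestamp. Reruns with identical inputs produce
#' byte-identical CSVs (the timestamp lives only in the sidecar).
#'
#' @param table A data.frame.
#' @param path Output CSV path; parent directories are created.
#' @param meta Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, meta = list()) {
  stopifnot(is.data.frame(table))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(table, path, row.names = FALSE)
  sidecar <- c(meta, list(
    n_rows = nrow(table),
    columns = names(table),
    package_version = as.character(packageVersion("recipnet")),
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  jsonlite::write_json(sidecar, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Read a result table and its metadata sidecar
#'
#' @param path CSV path written by [write_results()].
#' @return List with `table` (data.frame) and `meta` (list, NULL when the
#'   sidecar is absent).
#' @export
read_results <- function(path) {
  table <- read.csv(path)
  side <- paste0(path, ".meta.json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  list(table = table, meta = meta)
}
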