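# Flat key-value run configuration and provenance manifests for the CLI.

#' Read a flat run configuration
#'
#' Reads model parameters from a flat key-value file of `key: value` or
#' `key = value` lines (`#` comments allowed) — the flat subset of YAML.
#' A dedicated parser is used rather than a YAML library because YAML 1.1
#' silently converts the key `N` (the most important parameter here) to a
#' boolean. Recognized keys include `N`, `U`, `s`, `u`, `s_eff`, `seed`,
#' `replicates`, `model`, `dt`, `sample_fraction`, `u_convention`;
#' numeric-looking values are converted.
#'
#' @param path Path to the configuration file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*[:=]\\s*")
  cfg <- list()
  for (p in kv) {
    if (length(p) != 2) stop("cannot parse config line: ", paste(p, collapse = " "))
    cfg[[p[1]]] <- utils::type.convert(p[2], as.is = TRUE)
  }
  cfg
}

#' Write a run manifest
#'
#' Records the parameters, derived quantities and run metadata of a
#' simulation for provenance, as JSON (via `jsonlite` when installed,
#' otherwise as R `dput` text).
#'
#' @param x Named list of manifest entries.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(x, path) {
  stopifnot(is.list(x))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
  } else {
    dput(x, file = path)
  }
  invisible(path)
}

#' Derived-quantity echo for manifests
#'
#' Expands a parameter object into the full set of derived quantities a
#' manifest should record.
#'
#' @param params A [full_params()] or [twoclass_params()] object.
#' @return Named list of parameters plus derived values.
#' @export
manifest_params <- function(params) {
  if (inherits(params, "full_params")) {
    lam <- lambda_full(params)
    tc <- suppressWarnings(map_parameters(params))
    list(model_class = "full", N = params$N, U = params$U, s = params$s,
         lambda = lam, n_bar_equilibrium = params$N * exp(-lam),
         mapped = manifest_params(tc))
  } else if (inherits(params, "twoclass_params")) {
    list(model_class = "twoclass", N = params$N, u = params$u,
         s_eff = params$s_eff, lambda0 = lambda_twoclass(params),
         x_star = x_star(params),
         n_star = params$N * x_star(params))
  } else stop("unsupported parameter object")
}
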