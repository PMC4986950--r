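#' Load the sub-model coefficient configuration
#'
#' All fitted sub-model coefficients (time to ignition, leaf flame duration
#' and length, plume decay, flame tilt, flame merging, canopy wind
#' attenuation, the litter pilot-fire model and its validity domain, and the
#' default-trait rules) live in a versioned YAML file shipped with the
#' package, not in code. Each block records the functional form, its
#' coefficients, the input range over which it is considered valid, and a
#' provenance note.
#'
#' @param path Path to a YAML coefficient file. Defaults to the file shipped
#'   in `inst/extdata/submodels.yaml`.
#' @param ... Named overrides merged recursively over the file contents, e.g.
#'   `ffm_config(flame = list(temperature_c = 1000))`.
#' @return A nested list of class `ffm_config`.
#' @examples
#' cfg <- ffm_config()
#' cfg$flame$temperature_c
#' @export
ffm_config <- function(path = NULL, ...) {
  if (is.null(path)) {
    path <- system.file("extdata", "submodels.yaml", package = "ffmr")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("coefficient file not found: ", path)
  }
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  if (length(dots)) {
    cfg <- modifyList(cfg, dots)
  }
  structure(cfg, class = "ffm_config")
}

#' @export
print.ffm_config <- function(x, ...) {
  cat("Flammability sub-model configuration\n")
  blocks <- setdiff(names(x), "provenance")
  for (b in blocks) {
    prov <- x[[b]][["provenance"]]
    cat(sprintf("  %-18s %s\n", b,
                if (is.null(prov)) "" else paste0("(", prov, ")")))
  }
  invisible(x)
}

# internal: fetch a config block, failing loudly on malformed configs
cfg_block <- function(config, name, fields = character()) {
  blk <- config[[name]]
  if (is.null(blk)) stop("config is missing the '", name, "' block")
  missing <- setdiff(fields, names(blk))
  if (length(missing)) {
    stop("config block '", name, "' is missing: ",
         paste(missing, collapse = ", "))
  }
  blk
}
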