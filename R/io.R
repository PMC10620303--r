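# Serialization beyond the parameter JSON: field CSV export, reports, run
# manifests, and accessors for the packaged fixture parameter sets.

#' Packaged admissible parameter fixtures
#'
#' Two parameter sets found by [search_admissible()] ship with the package
#' as JSON (their seeds and try indices are stored in the file): `"general"`
#' (independently drawn alleles; distinct unpatterned parents, patterned
#' F1) and `"symmetric"` (phenotypically identical parents differing from
#' the F1 only through trans/cis binding efficacies). Both can be
#' regenerated with the seed recorded in their metadata.
#'
#' @param name `"general"` or `"symmetric"`.
#' @return A validated `mg_params` with search provenance in `attr(, "meta")`.
#' @export
mg_fixture <- function(name = c("general", "symmetric")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("fixture_", name, ".json"),
                      package = "mgturing", mustWork = TRUE)
  load_params(path)
}

#' Write a simulated field to CSV plus a JSON sidecar
#'
#' One CSV matrix per species (`<prefix>_<species>.csv`, no headers) and a
#' `<prefix>_meta.json` sidecar holding grid, time, convergence record, and
#' classification.
#'
#' @param field A `field2d`.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_field_csv <- function(field, prefix) {
  files <- character()
  for (s in names(field$values)) {
    f <- paste0(prefix, "_", s, ".csv")
    utils::write.table(field$values[[s]], f, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, f)
  }
  meta <- list(species = field$species, tf = field$tf, dx = field$dx,
               dt = field$dt, t = field$t, d = field$d,
               converged = field$converged, steps = field$steps,
               homogeneous = field$homogeneous, clamped = field$clamped)
  mf <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)], mf,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}

#' Read a field back from its CSV export
#'
#' @param prefix The prefix passed to [write_field_csv()].
#' @return A `field2d` (without solver caches).
#' @export
read_field_csv <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  values <- lapply(meta$species, function(s)
    as.matrix(utils::read.csv(paste0(prefix, "_", s, ".csv"),
                              header = FALSE)))
  names(values) <- meta$species
  values <- lapply(values, function(m) {
    dimnames(m) <- NULL
    m
  })
  structure(c(list(values = values), meta[setdiff(names(meta), "species")],
              list(species = meta$species)), class = "field2d")
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a pipeline run bit-for-bit: the
#' MD5 of the parameter file, genotype, diffusion ratio, full simulation
#' configuration, seed, package version, and a timestamp.
#'
#' @param path Output JSON path.
#' @param params_file Parameter JSON used (hashed with [tools::md5sum()]).
#' @param genotype Genotype string.
#' @param d Diffusion ratio.
#' @param config A [sim_config()].
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, params_file = NULL, genotype = NULL,
                           d = NULL, config = NULL) {
  manifest <- list(
    params_file = params_file,
    params_md5 = if (!is.null(params_file) && file.exists(params_file))
      unname(tools::md5sum(params_file)) else NULL,
    genotype = genotype, d = d, config = unclass(config),
    package_version = as.character(utils::packageVersion("mgturing")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest[!vapply(manifest, is.null, TRUE)], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
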