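#' Serialize a registry bundle to delimited text tables
#'
#' Writes `persons.tsv`, `dispensations.tsv`, `diagnoses.tsv` and
#' `outcomes.tsv` with ISO-8601 dates, plus `manifest.yaml` recording the
#' seed, a hash of the generating configuration, row counts and the
#' covariate specification needed to read the bundle back.
#'
#' @param bundle a `registry_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_registry <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tb in c("persons", "dispensations", "diagnoses", "outcomes"))
    fwrite(bundle[[tb]], file.path(dir, paste0(tb, ".tsv")), sep = "\t")
  info <- bundle$meta$covinfo
  manifest <- list(
    seed = bundle$meta$seed,
    config_hash = bundle$meta$config_hash,
    rows = lapply(bundle[c("persons", "dispensations", "diagnoses",
                           "outcomes")], nrow),
    covariates = lapply(seq_along(info$names), function(i) {
      nm <- info$names[i]
      list(name = nm, kind = unname(info$kinds[[nm]]),
           mean = if (!is.na(info$means[[nm]])) info$means[[nm]],
           sd = if (!is.na(info$sds[[nm]])) info$sds[[nm]],
           levels = info$levels[[nm]])
    })
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a registry bundle from a directory of delimited tables
#'
#' @param dir directory written by [write_registry()].
#' @return a `registry_bundle` (without the full generator config; the
#'   manifest's covariate specification is restored).
#' @export
read_registry <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  kinds <- vapply(manifest$covariates, `[[`, "", "kind")
  names(kinds) <- vapply(manifest$covariates, `[[`, "", "name")
  info <- list(
    names = names(kinds), kinds = kinds,
    means = vapply(manifest$covariates, function(cv)
      cv$mean %||% NA_real_, 0),
    sds = vapply(manifest$covariates, function(cv) cv$sd %||% NA_real_, 0),
    levels = lapply(manifest$covariates, function(cv) cv$levels)
  )
  names(info$means) <- names(info$sds) <- names(info$levels) <- info$names

  rd <- function(tb, date_cols) {
    x <- fread(file.path(dir, paste0(tb, ".tsv")), sep = "\t")
    for (dc in date_cols) x[[dc]] <- as.Date(x[[dc]])
    x
  }
  bundle <- list(
    persons = rd("persons", c("index_date", "angio_date")),
    dispensations = rd("dispensations", "dispense_date"),
    diagnoses = rd("diagnoses", "date"),
    outcomes = rd("outcomes", "date"),
    meta = list(config = NULL, seed = manifest$seed, covinfo = info,
                config_hash = manifest$config_hash)
  )
  class(bundle) <- "registry_bundle"
  bundle
}

#' @export
print.registry_bundle <- function(x, ...) {
  cat("Synthetic registry bundle\n")
  cat(sprintf("  persons:       %8d\n", nrow(x$persons)))
  cat(sprintf("  dispensations: %8d\n", nrow(x$dispensations)))
  cat(sprintf("  diagnoses:     %8d\n", nrow(x$diagnoses)))
  cat(sprintf("  outcomes:      %8d\n", nrow(x$outcomes)))
  if (!is.null(x$meta$seed)) cat("  seed:", x$meta$seed, "\n")
  invisible(x)
}
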