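#' Inject missingness into continuous baseline covariates
#'
#' Sets continuous covariate values in the persons table to `NA`
#' independently at the per-covariate rates in `config$missingness`,
#' emulating labs that were never measured.  All other fields are left
#' untouched.  Uses the current RNG state; [generate_registry()] calls it
#' within its seeded stream.
#'
#' @param bundle a `registry_bundle`.
#' @param config a [generator_config()] (only `missingness` is used).
#' @return the modified bundle.
#' @export
inject_missingness <- function(bundle, config) {
  rates <- config$missingness
  if (!length(rates)) return(bundle)
  assert_prob(rates, "missingness")
  persons <- copy(bundle$persons)
  for (nm in names(rates)) {
    if (!nm %in% names(persons)) next
    hit <- runif(nrow(persons)) < rates[[nm]]
    persons[hit, (nm) := NA_real_]
  }
  bundle$persons <- persons
  bundle
}
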