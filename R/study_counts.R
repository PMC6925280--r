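#' Published cohort description counts
#'
#' Event and sample counts describing the UK Biobank British-white
#' ischaemic-stroke (IS) cohort on which the metaGRS methodology was
#' validated (derivation set enriched for stroke events; validation set
#' with prevalent and incident IS before age 75). These counts
#' parameterise the evaluation machinery: the derivation-set enrichment
#' fraction, the total IS burden, and the population prevalence `K` used
#' for liability-scale conversion.
#'
#' @return Named numeric vector of counts.
#' @export
study_counts <- function() {
  path <- system.file("extdata", "ukb_is_cohort_counts.tsv",
                      package = "metagrs", mustWork = TRUE)
  df <- data.table::fread(path, data.table = FALSE)
  setNames(as.numeric(df$value), df$quantity)
}

#' Arithmetic summaries of the cohort description
#'
#' Recomputes, from the raw counts in [study_counts()]:
#' \describe{
#'   \item{total_is_events}{prevalent + incident IS events in the
#'     validation set.}
#'   \item{derivation_is_fraction}{IS enrichment of the derivation set
#'     (IS events / derivation size).}
#'   \item{prevalence_K}{IS prevalence in the validation set (total IS
#'     events / validation size), the `K` of the liability-scale
#'     conversion.}
#' }
#'
#' @param counts Named counts as returned by [study_counts()].
#' @return Named numeric vector with the three derived quantities.
#' @export
cohort_arithmetic <- function(counts = study_counts()) {
  total_is <- counts[["validation_prevalent_is"]] +
    counts[["validation_incident_is"]]
  c(total_is_events = total_is,
    derivation_is_fraction = counts[["derivation_is_events"]] /
      counts[["derivation_n"]],
    prevalence_K = total_is / counts[["validation_n"]])
}
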