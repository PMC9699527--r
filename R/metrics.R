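#' IARC carcinogenicity categories, most hazardous first
#'
#' Group 1 (carcinogenic to humans), 2A (probably), 2B (possibly),
#' 3 (not classifiable based on evidence), NC (not classified).
#'
#' @return Character vector of category labels in hazard-descending order.
#' @export
iarc_levels <- function() c("1", "2A", "2B", "3", "NC")

#' Default toxicity-metric registry
#'
#' One row per metric the prioritization schemes understand. `direction`
#' states how raw values map to hazard: `"lower"` (reference dose/
#' concentration and benchmark concentration: smaller value = more
#' hazardous), `"higher"` (cancer potencies and equivalency factors:
#' larger value = more hazardous), or `"ordinal"` (IARC category).
#' `weightable` marks metrics eligible for abundance weighting.
#' `ABUNDANCE` is the pseudo-metric carrying the air concentration itself.
#'
#' @return A data.frame with columns `metric_id`, `direction`, `weightable`.
#' @export
#' @examples
#' default_metric_registry()
default_metric_registry <- function() {
  data.frame(
    metric_id  = c("RfC", "RfD", "IUR", "OSF", "CPV",
                   "RPF", "TEF", "IARC", "BMC", "ABUNDANCE"),
    direction  = c("lower", "lower", "higher", "higher", "higher",
                   "higher", "higher", "ordinal", "lower", "higher"),
    weightable = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                   TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

metric_direction <- function(metric_id, registry = default_metric_registry()) {
  i <- match(metric_id, registry$metric_id)
  if (anyNA(i)) {
    stop("unknown metric id(s): ",
         paste(metric_id[is.na(i)], collapse = ", "), call. = FALSE)
  }
  registry$direction[i]
}
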