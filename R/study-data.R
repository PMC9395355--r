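#' Reference contingency counts from the field screening study
#'
#' The six tier-versus-tier comparisons of the multicentre dual-mode
#' screening study the package models, as printed contingency counts:
#' onsite specialist versus histology, remote (tele)diagnosis versus
#' onsite specialist, frontline health worker versus remote and versus
#' onsite specialist, the phone CNN versus remote diagnosis, and the
#' cloud Bayesian CNN (uncertainty below 0.15) versus remote diagnosis.
#' These counts are the inputs for the golden diagnostic-accuracy
#' checks: every metric the package reports can be recomputed from them.
#'
#' @return a `data.frame` with columns `comparison`, `test`, `reference`,
#'   `tp`, `fp`, `fn`, `tn`.
#' @examples
#' counts <- study_contingency_tables()
#' tab <- with(counts[counts$comparison == "fhw_vs_remote", ],
#'             contingency_table(tp, fp, fn, tn, test, reference))
#' metrics_report(tab)
#' @export
study_contingency_tables <- function() {
  data.frame(
    comparison = c("onsite_vs_histology", "remote_vs_onsite",
                   "fhw_vs_remote", "fhw_vs_onsite",
                   "mobilenet_vs_remote", "vgg19bdl_vs_remote"),
    test = c("onsite_specialist", "remote_specialist", "fhw", "fhw",
             "mobilenet", "vgg19_bdl"),
    reference = c("histology", "onsite_specialist", "remote_specialist",
                  "onsite_specialist", "remote_specialist",
                  "remote_specialist"),
    tp = c(89L, 489L, 1203L, 507L, 493L, 420L),
    fp = c(2L, 39L, 604L, 113L, 191L, 94L),
    fn = c(6L, 26L, 801L, 8L, 110L, 62L),
    tn = c(5L, 198L, 2120L, 124L, 622L, 591L),
    stringsAsFactors = FALSE)
}
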