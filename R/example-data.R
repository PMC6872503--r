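#' Published ROI-to-AD causal screening table
#'
#' ROI-level CGAN/C2ST causal-test p-values between diffusion-image regions
#' of interest and Alzheimer's disease status at four study visits (baseline,
#' 6, 12 and 24 months), as reported in a published DTI study of 151 subjects
#' whose relevance analysis selected 23 regions. Entries below the printed
#' resolution appear as `"<0.00005"` tokens. The table only lists ROIs with
#' p < 0.05. It is bundled as the worked example for [screen_results()].
#'
#' @return Data frame with columns `timepoint` (baseline, m06, m12, m24),
#'   `roi_index`, `p_value` (character; numeric or `"<bound"`).
#' @export
roi_ad_screen_table <- function() {
  read.delim(system.file("extdata", "roi_ad_causal_pvalues.tsv",
                         package = "neurocausal"),
             colClasses = c("character", "integer", "character"))
}
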