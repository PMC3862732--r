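#' Published compartment mean concentrations (worked-example fixture)
#'
#' Mean concentrations (uM) of ten representative metabolites in bone
#' marrow and peripheral blood at diagnosis (day 0) and at the end of
#' induction therapy (day 29) in pediatric ALL, together with the printed
#' compartment differences. Used to calibrate the synthetic panel's scales
#' and as worked examples for the paired-difference arithmetic. Note that
#' the printed table contains an internally inconsistent glycerol row
#' (its compartment means duplicate glycine's yet the differences differ);
#' the data are shipped as printed, with no attempt at repair, and the
#' worked examples use only internally consistent rows.
#'
#' @return Data frame with columns `metabolite`, `b0_um`, `p0_um`,
#'   `b0_minus_p0_um`, `b29_um`, `p29_um`, `b29_minus_p29_um`.
#' @export
reference_compartment_means <- function() {
  path <- system.file("extdata", "reference_compartment_means.tsv",
                      package = "marrownet", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE)
}
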