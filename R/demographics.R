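#' Sociodemographic composition of the study sample
#'
#' The packaged per-category counts of the 40-participant sample (gender,
#' age group, education, hormonal contraceptive use, recent life stress,
#' weekly video-game hours) together with the percentages as printed, and a
#' recomputation of each percentage from its count.
#'
#' @param n_total total sample size the percentages refer to (40).
#' @return `data.frame` with columns `category`, `level`, `n`,
#'   `pct_printed`, `pct_recomputed` (= `100 * n / n_total`).
#' @export
#' @examples
#' d <- demographics_table()
#' d[d$category == "life_stress", ]
demographics_table <- function(n_total = 40L) {
  path <- system.file("extdata", "demographics.tsv", package = "stressres")
  d <- as.data.frame(data.table::fread(path, sep = "\t", showProgress = FALSE))
  d$pct_recomputed <- 100 * d$n / n_total
  d
}
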