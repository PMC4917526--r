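#' DiffCovBin: differential-coverage binning for two-sample metagenomes
#'
#' See the package vignette for the methodological background:
#' \code{vignette(package = "DiffCovBin")}.
#'
#' @useDynLib DiffCovBin, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"
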