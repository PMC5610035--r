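#' @keywords internal
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor sd
#' @importFrom utils write.csv packageVersion
#' @useDynLib haircycle, .registration = TRUE
"_PACKAGE"
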