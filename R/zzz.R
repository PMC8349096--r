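#' @importFrom stats median quantile rnorm runif loess predict approxfun
#'   chisq.test lm.fit plogis
#' @importFrom utils read.table read.csv write.csv write.table
NULL

utils::globalVariables(c("phys", "gen", "scaled"))
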