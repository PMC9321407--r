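.datatable.aware <- TRUE

#' @importFrom data.table := .N .SD
#' @importFrom stats pgamma rnorm runif sd t.test
NULL
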