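#' @keywords internal
#' @importFrom rlang %||% .data
"_PACKAGE"

# exact (Clopper-Pearson) binomial confidence interval
binom_ci <- function(x, n, conf_level = 0.95) {
  as.numeric(stats::binom.test(x, n, conf.level = conf_level)$conf.int)
}

# derive a stream of reproducible 31-bit sub-seeds from a master seed
derive_subseeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
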