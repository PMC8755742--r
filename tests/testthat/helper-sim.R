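# small cohort configuration used across tests: same structure as the
# full design, scaled down for speed
small_config <- function(seed = 1L, ...) {
  args <- list(n_analytes = 220L, n_controls = 5L,
               module_sizes = c(20L, 16L, 14L),
               n_tissues = 3L, signature_size = 4L, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sc <- function(x) sum(choose(x, 2))
  si <- sc(tab); sr <- sc(rowSums(tab)); scl <- sc(colSums(tab))
  expected <- sr * scl / choose(n, 2)
  (si - expected) / ((sr + scl) / 2 - expected)
}

# log2 signal matrix of a simulation, as an af_abundance (bypasses the
# planted assay factors: the clean biology the normalization chain
# should recover)
signal_abundance <- function(sim) {
  af_abundance(sim$truth$log2_signal, scale = "log2")
}

truth_of <- function(sim, de) {
  sim$truth$analytes[match(de$analyte_id, sim$truth$analytes$analyte_id), ]
}
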