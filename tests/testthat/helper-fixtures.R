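# shared fixtures, all generated in code

# small beta matrix with named dims
toy_beta <- function(n_probes = 5, n_samples = 4, seed = 1) {
  set.seed(seed)
  matrix(runif(n_probes * n_samples), n_probes, n_samples,
         dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                         sprintf("S%02d", seq_len(n_samples))))
}

toy_sheet <- function(beta, passages = NULL) {
  n <- ncol(beta)
  if (is.null(passages)) passages <- rep(c(10, 12, 14, 16, 18, 20),
                                         length.out = n)
  data.frame(sample_id = colnames(beta), passage = passages,
             stringsAsFactors = FALSE)
}

# a compact simulated cohort reused by several tests (cheap: 1500 probes)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cohort(simulate_config(n_probes = 1500, seed = 42))
    cache
  }
})
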