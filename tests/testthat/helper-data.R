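# Shared fixtures for the test suite.

# Small balanced trial: v genotypes x l environments x b blocks with a known
# rank-1 interaction surface and optional residual noise.
toy_records <- function(v = 4, l = 3, b = 2, noise_sd = 0, seed = 42,
                        mu = 10) {
  set.seed(seed)
  g <- seq_len(v) - mean(seq_len(v))          # genotype main effects
  e <- seq_len(l) * 0.5                       # environment effects
  blk <- matrix(seq_len(b * l) / 10, b, l)    # block-within-environment
  a1 <- (seq_len(v) - mean(seq_len(v))); a1 <- a1 / sqrt(sum(a1^2))
  g1 <- (seq_len(l) - mean(seq_len(l))); g1 <- g1 / sqrt(sum(g1^2))
  lam <- 3
  df <- expand.grid(genotype = paste0("G", seq_len(v)),
                    environment = paste0("E", seq_len(l)),
                    block = paste0("B", seq_len(b)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- as.integer(sub("G", "", df$genotype))
  ei <- as.integer(sub("E", "", df$environment))
  bi <- as.integer(sub("B", "", df$block))
  df$yield <- mu + g[gi] + e[ei] + blk[cbind(bi, ei)] +
    lam * a1[gi] * g1[ei] + rnorm(nrow(df), 0, noise_sd)
  df
}

toy_met <- function(...)
  met_table(toy_records(...), col_map = c(response = "yield"))

# A moderate simulated dataset reused by several integration tests.
shared_sim <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_met(sim_config(), seed = 101)
    val
  }
})

# Short-but-usable sampling plan for integration tests.
quick_plan <- function(n_keep = 400, thin = 2, burn_in = 600)
  mcmc_plan(n_keep = n_keep, thin = thin, burn_in = burn_in)

# One entropy-prior full fit on the shared simulated trial, cached across
# test files.
shared_fit <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- bgge(shared_sim()$met, variant = "entropy",
                   plan = quick_plan(), seed = 77)
    val
  }
})
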