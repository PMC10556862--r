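# Shared fixture builders: everything is generated in code at test time.

# Pooled-dose contrast design: one compound at dose codes 1..4 (3 reps each)
# vs solvent control, i.e. 12 treated vs 4 control samples.
pooled_groups <- function(n_ctrl = 4L) {
  rbind(data.frame(compound = "DEHP", dose_code = 1:4, n_replicates = 3L),
        data.frame(compound = "DMSO", dose_code = 0L, n_replicates = n_ctrl))
}

# Single compound dose series (codes 1..5, triplicate) plus 5 controls.
series_groups <- function() {
  rbind(data.frame(compound = "DEHP", dose_code = 1:5, n_replicates = 3L),
        data.frame(compound = "DMSO", dose_code = 0L, n_replicates = 5L))
}

# Small deterministic count matrix with gene/sample names.
tiny_counts <- function(n_genes = 20, n_samples = 6, seed = 1, mu = 50,
                        size = 10) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
              n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  m
}

# Brute-force BH step-up, straight from the definition.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- Inf
  for (i in m:1) {
    running_min <- min(running_min, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running_min, 1)
  }
  adj
}

# Brute-force Simes: enumerate i, no sorting tricks.
simes_brute <- function(p) {
  p <- p[!is.na(p)]
  m <- length(p)
  s <- sort(p)
  min(sapply(seq_len(m), function(i) s[i] * m / i))
}
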