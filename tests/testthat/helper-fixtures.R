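# Shared fixtures: constructed envelopes and small simulated designs.

# Build an envelope from a piecewise-constant description: `segments` is a
# data.frame(level, dur_s); threshold defaults to 1.
step_envelope <- function(segments, fs = 100, threshold = 1) {
  samples <- unlist(mapply(
    function(lv, d) rep(lv, round(d * fs)),
    segments$level, segments$dur_s, SIMPLIFY = FALSE
  ))
  mua_envelope(samples, fs, threshold = threshold)
}

# Random step-function envelope on a coarse grid: alternating runs with
# random levels straddling the threshold. Total duration <= max_s.
random_step_envelope <- function(max_s = 60, fs = 20, threshold = 1) {
  n_seg <- sample(3:30, 1)
  durs <- stats::runif(n_seg, 0.05, max_s / n_seg)
  levels <- stats::runif(n_seg, 0, 2)  # some above, some below threshold
  step_envelope(data.frame(level = levels, dur_s = durs),
                fs = fs, threshold = threshold)
}

# Balanced factorial cohort data frame with standard-normal noise and
# optional additive cell means (named "<genotype>:<drug>").
balanced_cohort <- function(n_per_cell, genotypes = c("WT", "KO"),
                            drugs = c("SAL", "Acamp"), cell_means = NULL,
                            sd = 1) {
  d <- expand.grid(rep = seq_len(n_per_cell), genotype = genotypes,
                   drug = drugs, stringsAsFactors = FALSE)
  d$group <- paste(d$genotype, d$drug, sep = ":")
  mu <- if (is.null(cell_means)) 0 else cell_means[d$group]
  d$value <- stats::rnorm(nrow(d), mu, sd)
  d
}

# Hand step-up BH adjustment, written as the textbook loop.
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}
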