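# small builders shared across test files

toy_se <- function(n_feat = 4, n_samp = 10, seed = 1,
                   feature_class = "prok_asv") {
  set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, 50), n_feat, n_samp,
              dimnames = list(paste0("f", seq_len(n_feat)),
                              paste0("s", seq_len(n_samp))))
  SeasonalExperiment(m, as.Date("2016-01-01") + seq(0, by = 14,
                                                    length.out = n_samp),
                     feature_class = feature_class)
}

# uniform weekly grid over n_years synthetic years starting Jan 1 2016
grid_dates <- function(n_years = 4, by = 7) {
  as.Date("2016-01-01") + seq(0, n_years * 365, by = by)
}

# brute-force Benjamini-Hochberg step-up, independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- p[ord] * m / seq_len(m)
  q[ord] <- rev(cummin(rev(adj)))
  pmin(q, 1)
}

# hand Bray-Curtis between two abundance vectors
bc_hand <- function(x, y) sum(abs(x - y)) / sum(x + y)

# hand Shannon diversity (nats) of a count/abundance vector
shannon_hand <- function(x) {
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}
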