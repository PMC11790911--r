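test_that("pairwise correlations, p and BH q match a brute-force oracle", {
  set.seed(21)
  sig <- matrix(rnorm(15 * 40), 15, 40,
                dimnames = list(paste0("f", 1:15), NULL))
  res <- pairwiseOscillationCorrelation(sig)
  # brute force over every unordered pair
  pr <- t(combn(15, 2))
  r_bf <- p_bf <- numeric(nrow(pr))
  for (i in seq_len(nrow(pr))) {
    ct <- cor.test(sig[pr[i, 1], ], sig[pr[i, 2], ])
    r_bf[i] <- unname(ct$estimate)
    p_bf[i] <- ct$p.value
  }
  q_bf <- bh_oracle(p_bf)
  for (i in seq_len(nrow(pr))) {
    a <- pr[i, 1]; b <- pr[i, 2]
    expect_equal(res$r[a, b], r_bf[i], tolerance = 1e-12)
    expect_equal(res$p[a, b], p_bf[i], tolerance = 1e-12)
    expect_equal(res$q[a, b], q_bf[i], tolerance = 1e-12)
  }
  expect_equal(res$r, t(res$r))
  expect_true(all(diag(res$r) == 1))
})

test_that("BH step-up formula agrees with the hand example", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
})

test_that("degenerate and anti-correlated signals are handled", {
  sig <- rbind(a = sin(1:50), b = sin(1:50), c = -sin(1:50),
               flat = rep(2, 50))
  res <- pairwiseOscillationCorrelation(sig)
  expect_equal(res$r["a", "b"], 1)
  expect_equal(res$r["a", "c"], -1)
  expect_true(all(is.na(res$r["flat", ])))
})

test_that("edges require r above threshold, q below alpha, positive only", {
  mk <- function(r_ab, q_ab) {
    r <- diag(3); r[1, 2] <- r[2, 1] <- r_ab
    r[1, 3] <- r[3, 1] <- 0.99; r[2, 3] <- r[3, 2] <- 0.99
    q <- matrix(0.001, 3, 3); q[1, 2] <- q[2, 1] <- q_ab
    dimnames(r) <- dimnames(q) <- list(letters[1:3], letters[1:3])
    buildNetwork(list(r = r, q = q))
  }
  has_edge <- function(net, a, b)
    igraph::are_adjacent(networkGraph(net), a, b)
  expect_true(has_edge(mk(0.71, 0.01), "a", "b"))
  expect_false(has_edge(mk(0.9, 0.2), "a", "b"))
  expect_false(has_edge(mk(-0.9, 0.001), "a", "b"))   # positive-only
  expect_false(has_edge(mk(0.7, 0.01), "a", "b"))     # strict > 0.7
})

two_cliques <- function() {
  r <- matrix(0, 10, 10, dimnames = list(paste0("n", 1:10),
                                         paste0("n", 1:10)))
  r[1:5, 1:5] <- 0.9; r[6:10, 6:10] <- 0.9; diag(r) <- 1
  q <- matrix(1, 10, 10); q[1:5, 1:5] <- 0.001; q[6:10, 6:10] <- 0.001
  buildNetwork(list(r = r, q = q))
}

test_that("Louvain recovers planted cliques and beats the trivial partition", {
  net <- detectModules(two_cliques(), seed = 1)
  mod <- moduleAssignment(net)
  expect_equal(nlevels(mod), 2)
  expect_equal(length(unique(mod[paste0("n", 1:5)])), 1)
  expect_equal(length(unique(mod[paste0("n", 6:10)])), 1)

  g <- networkGraph(net)
  q_detected <- igraph::modularity(g, as.integer(mod),
                                   weights = igraph::E(g)$weight)
  q_trivial <- igraph::modularity(g, rep(1, igraph::vcount(g)),
                                  weights = igraph::E(g)$weight)
  expect_gt(q_detected, q_trivial)

  # determinism under a fixed seed
  net2 <- detectModules(two_cliques(), seed = 1)
  expect_identical(moduleAssignment(net2), mod)

  # single clique collapses to one module
  r <- matrix(0.9, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(r) <- 1
  q <- matrix(0.001, 4, 4)
  one <- detectModules(buildNetwork(list(r = r, q = q)), seed = 1)
  expect_equal(nlevels(moduleAssignment(one)), 1)
})

test_that("module profiles sum member abundances per class", {
  ra <- rbind(a = c(0.5, 0.1), b = c(0.2, 0.6), c = c(0.3, 0.3))
  colnames(ra) <- c("s1", "s2")
  cls <- c(a = "prok_asv", b = "prok_asv", c = "euk_asv")
  mods <- factor(c(a = "M1", b = "M1", c = "M1"))
  prof <- moduleProfiles(ra, mods, cls)
  prok <- prof[prof$feature_class == "prok_asv", ]
  expect_equal(prok$abundance[prok$sample_id == "s1"], 0.7)
  expect_equal(prok$abundance[prok$sample_id == "s2"], 0.7)
  euk <- prof[prof$feature_class == "euk_asv", ]
  expect_equal(euk$abundance, c(0.3, 0.3))

  # partitioned modules never exceed the community total
  mods2 <- factor(c(a = "M1", b = "M2", c = "M2"))
  prof2 <- moduleProfiles(ra, mods2, cls)
  tot <- tapply(prof2$abundance, prof2$sample_id, sum)
  expect_true(all(tot <= colSums(ra) + 1e-12))
})

test_that("module-environment correlations flag exact relationships", {
  prof <- data.frame(module = "M1", feature_class = "prok_asv",
                     sample_id = paste0("s", 1:20),
                     abundance = sin(1:20))
  env <- data.frame(match = sin(1:20), const = rep(3, 20),
                    noise = cos(5 * (1:20)))
  res <- moduleEnvCorrelations(prof, env)
  expect_equal(res$r[res$covariate == "match"], 1, tolerance = 1e-9)
  expect_true(res$significant[res$covariate == "match"])
  expect_true(is.na(res$r[res$covariate == "const"]))
  expect_equal(res$q[!is.na(res$p)], bh_oracle(res$p[!is.na(res$p)]),
               tolerance = 1e-12)
})

test_that("subsampling robustness is exact in degenerate settings", {
  set.seed(3)
  counts <- matrix(rpois(40, 50), 4, 10,
                   dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  counts[, 1] <- counts[, 1] + 5    # unequal depths
  mods <- factor(setNames(c("M1", "M1", "M2", "M2"), rownames(counts)))
  # equal-depth table: rarefying to the (full) minimum changes nothing
  eq <- matrix(30, 4, 3, dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  res_eq <- moduleRobustnessSubsample(eq, mods, iterations = 5, seed = 1)
  expect_true(all(res_eq$richness_sd == 0))
  expect_true(all(res_eq$retained_fraction == 1))

  # one sample per month: monthly mode equals depth mode
  dates <- as.Date(c("2016-01-10", "2016-02-10", "2016-03-10",
                     "2016-04-10", "2016-05-10", "2016-06-10",
                     "2016-07-10", "2016-08-10", "2016-09-10",
                     "2016-10-10"))
  rd <- moduleRobustnessSubsample(counts, mods, iterations = 10, seed = 2)
  rm_ <- moduleRobustnessSubsample(counts, mods, dates = dates,
                                   mode = "monthly", iterations = 10,
                                   seed = 2)
  expect_equal(rd$richness_mean, rm_$richness_mean)
  expect_equal(rd$shannon_mean, rm_$shannon_mean)
  expect_error(moduleRobustnessSubsample(counts, mods, mode = "weekly"))
})
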