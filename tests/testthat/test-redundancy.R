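test_that("function abundances are member sums and conserve totals", {
  g <- rbind(g1 = c(0.1, 0.2), g2 = c(0.2, 0.1), g3 = c(0.7, 0.7))
  colnames(g) <- c("s1", "s2")
  map <- data.frame(gene_id = c("g1", "g2", "g3"),
                    function_id = c("F1", "F1", "F2"))
  f <- functionAbundanceTable(g, map)
  expect_equal(unname(f["F1", ]), c(0.3, 0.3))
  expect_equal(unname(f["F2", ]), c(0.7, 0.7))     # single member: identity
  expect_equal(colSums(f), colSums(g))             # total partition
  expect_length(attr(f, "unmapped"), 0)

  part <- functionAbundanceTable(g, map[1:2, ])
  expect_identical(attr(part, "unmapped"), "g3")
  expect_error(functionAbundanceTable(g, map[0, ]), "empty")
  dup <- rbind(map, data.frame(gene_id = "g1", function_id = "F2"))
  expect_error(functionAbundanceTable(g, dup), "g1")
})

test_that("multi-cluster fractions count functions with >= 2 members", {
  map <- data.frame(
    gene_id = sprintf("g%02d", 1:15),
    function_id = rep(sprintf("F%02d", 1:10), c(2, 2, 2, 2, 2, 1, 1, 1, 1, 1)))
  res <- multiClusterFraction(map)
  expect_equal(res$multi_fraction, 0.5)
  single <- data.frame(gene_id = letters[1:4], function_id = LETTERS[1:4])
  expect_equal(multiClusterFraction(single)$multi_fraction, 0)
})

test_that("diversity-abundance regression flags only genuine coupling", {
  # members in fixed ratio: constant diversity, nothing to test
  t <- 1:20
  fixed <- rbind(m1 = 2 * t, m2 = t)
  res <- diversityAbundanceAssociation(colSums(fixed), fixed)
  expect_false(res$flag)
  expect_equal(res$slope, 0)

  # anti-coupled: diversity falls as abundance rises
  ab <- seq(1, 5, length.out = 20)
  frac1 <- seq(0.5, 0.95, length.out = 20)
  anti <- rbind(m1 = ab * frac1, m2 = ab * (1 - frac1))
  res2 <- diversityAbundanceAssociation(colSums(anti), anti)
  expect_lt(res2$slope, 0)
  expect_false(res2$flag)

  # coupled: evenness and abundance rise together
  frac <- seq(0.95, 0.5, length.out = 20)
  pos <- rbind(m1 = ab * frac, m2 = ab * (1 - frac))
  res3 <- diversityAbundanceAssociation(colSums(pos), pos)
  expect_gt(res3$slope, 0)
  expect_true(res3$flag)

  expect_error(diversityAbundanceAssociation(ab, rbind(m1 = ab)), "2 member")
  expect_error(diversityAbundanceAssociation(ab[1:5], anti[, 1:5]), "8")
})

test_that("dominance consistency tracks the member atop each year's peak", {
  yi <- rep(1:3, each = 4)
  dom <- rbind(m1 = rep(c(1, 9, 1, 1), 3), m2 = rep(1, 12))
  expect_equal(dominanceConsistency(dom, yi)$status, "same")

  # rotating dominant member
  sw <- rbind(m1 = c(9, 9, 9, 9, 1, 1, 1, 1, 1, 1, 1, 1),
              m2 = c(1, 1, 1, 1, 9, 9, 9, 9, 1, 1, 1, 1),
              m3 = c(1, 1, 1, 1, 1, 1, 1, 1, 9, 9, 9, 9))
  res <- dominanceConsistency(sw, yi)
  expect_equal(res$status, "different")
  expect_equal(unname(res$dominant), c("m1", "m2", "m3"))

  # exact tie every year: deterministic lexicographic break, tie flagged
  tie <- rbind(mB = rep(5, 8), mA = rep(5, 8))
  res2 <- dominanceConsistency(tie, rep(1:2, each = 4))
  expect_equal(res2$status, "same")
  expect_true(res2$tie)
  expect_equal(unname(res2$dominant[1]), "mA")

  expect_error(dominanceConsistency(dom, rep(1, 12)), "2 years")
})

test_that("statistics are invariant to member ordering", {
  set.seed(4)
  mm <- matrix(runif(3 * 16), 3, 16, dimnames = list(c("a", "b", "c"), NULL))
  fs <- colSums(mm)
  r1 <- diversityAbundanceAssociation(fs, mm)
  r2 <- diversityAbundanceAssociation(fs, mm[c(3, 1, 2), ])
  expect_equal(r1$slope, r2$slope, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  d1 <- dominanceConsistency(mm, rep(1:2, each = 8))
  d2 <- dominanceConsistency(mm[c(2, 3, 1), ], rep(1:2, each = 8))
  expect_equal(d1$status, d2$status)
})

test_that("per-module redundancy report recovers planted structure", {
  sim <- simulateSeasonalCommunity(syntheticSpec(seed = 5))
  cls <- featureClass(sim$se)
  gr <- relAbundance(sim$se)[cls == "gene_cluster", ]
  fc <- sim$function_classes
  mods <- setNames(fc$cohort, fc$function_id)
  rep_ <- redundancyReport(gr, sim$function_map, modules = mods,
                           year_index = yearIndex(sim$se))
  planted <- mean(table(sim$function_map$function_id) >= 2)
  expect_true(all(abs(rep_$summary$multi_fraction - planted) <= 0.05))
  det <- rep_$detail
  cov_ids <- fc$function_id[fc$redundancy_class == "multi-covarying"]
  sw_ids <- fc$function_id[fc$redundancy_class == "multi-switching"]
  expect_gte(mean(det$coupling_flag[det$function_id %in% cov_ids]), 0.9)
  expect_gte(mean(det$dominance[det$function_id %in% sw_ids] == "different"),
             0.9)
})
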