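# siRNA screen processing: replicate QC, single-knockdown normalization,
# measured synergies and the predicted-vs-measured comparison.

test_that("replicate QC averages, drops discordant edge wells, warns otherwise", {
  rec <- data.frame(
    gene_a = c("g1", "g1", "g2", "g2", "g3", "g3"),
    gene_b = c("h", "h", "h", "h", "h", "h"),
    inhibition = c(40, 44, 30, 50, 30, 50),
    edge = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_warning(out <- qc_and_average(rec), "discordant")
  expect_equal(out$inhibition[out$gene_a == "g1"], 42)   # plain mean
  expect_equal(out$flag[out$gene_a == "g1"], "ok")
  # 20 > 15 and one edge flag: edge replicate excluded
  expect_equal(out$inhibition[out$gene_a == "g2"], 30)
  expect_equal(out$flag[out$gene_a == "g2"], "edge_dropped")
  # discordant but no edge flag: keep both, flagged
  expect_equal(out$inhibition[out$gene_a == "g3"], 40)
  expect_equal(out$flag[out$gene_a == "g3"], "discordant_kept")
  # output always within the replicate range
  expect_true(all(out$inhibition >= 30 & out$inhibition <= 50))
})

test_that("edge wells are the outer rows and columns of the plate", {
  expect_true(edge_well(1, 5))
  expect_true(edge_well(16, 5))
  expect_true(edge_well(8, 24))
  expect_false(edge_well(8, 12))
})

test_that("single-knockdown normalization averages in lower doubles only", {
  singles <- data.frame(gene = c("g", "h", "k"), inhibition = c(50, 50, 35))
  doubles <- data.frame(gene_a = c("g", "g", "g", "h", "h"),
                        gene_b = c("x", "y", "z", "x", "y"),
                        inhibition = c(40, 30, 60, 60, 70))
  n <- normalize_single_knockdown(singles, doubles)
  expect_equal(n$normalized[n$gene == "g"], mean(c(50, 40, 30)))
  expect_equal(n$normalized[n$gene == "h"], 50)    # no doubles below 50
  expect_equal(n$normalized[n$gene == "k"], 35)    # absent from doubles
  # never increases a single value
  expect_true(all(n$normalized <= n$inhibition))
})

test_that("measured synergies use the shared null on the percent scale", {
  singles <- data.frame(gene = c("a", "b", "c"),
                        inhibition = c(0, 0, 20),
                        normalized = c(0, 0, 20))
  doubles <- data.frame(gene_a = c("a", "c"), gene_b = c("b", "b2"),
                        inhibition = c(63.399, 44))
  singles2 <- rbind(singles,
                    data.frame(gene = "b2", inhibition = 30, normalized = 30))
  syn <- sirna_synergy(singles2, doubles)
  # both singles zero: the double is pure synergy
  expect_equal(syn$synergy[1L], 63.399)
  # exactly at the Bliss null (20 + 30 - 6 = 44): zero synergy
  expect_equal(syn$synergy[2L], 0, tolerance = 1e-12)
  # missing single gives NA
  syn_na <- sirna_synergy(singles, doubles)
  expect_true(is.na(syn_na$synergy[2L]))
})

test_that("replicate rank correlation approaches 1 as plate noise vanishes", {
  set.seed(161)
  true_vals <- runif(40, 0, 100)
  for (noise in c(10, 1, 0.01)) {
    r1 <- true_vals + rnorm(40, 0, noise)
    r2 <- true_vals + rnorm(40, 0, noise)
    rho <- cor(r1, r2, method = "spearman")
    if (noise == 0.01) expect_gt(rho, 0.999)
  }
})

test_that("predicted-vs-measured comparison reproduces exact rank statistics", {
  pred <- data.frame(node_a = c("N1", "N1", "N2", "N1", "N2"),
                     node_b = c("N2", "N3", "N3", "N4", "N4"),
                     synergy = c(0.5, 0.3, 0.2, 0.4, 0.1),
                     efficacy = c(0.8, 0.7, 0.3, 0.6, 0.2))
  mapping <- data.frame(gene = c("gA", "gB", "gC", "gD", "gE"),
                        node = c("N1", "N2", "N3", "N4", "N3"))
  mk_meas <- function(syn) data.frame(
    entity_a = c("gA", "gA", "gB", "gA", "gB"),
    entity_b = c("gB", "gC", "gC", "gD", "gD"),
    synergy = syn)
  # identical ranks: tau = 1; reversed: tau = -1
  cmp1 <- compare_predicted_measured(pred, mk_meas(c(50, 30, 20, 40, 10)),
                                     mapping)
  expect_equal(cmp1$kendall$tau, 1)
  cmp2 <- compare_predicted_measured(pred, mk_meas(c(10, 30, 40, 20, 50)),
                                     mapping)
  expect_equal(cmp2$kendall$tau, -1)
  # arbitrary values equal the exhaustive pair-counting tau
  meas <- mk_meas(c(33, 12, 48, 27, 5))
  cmp3 <- compare_predicted_measured(pred, meas, mapping)
  cc <- stats::complete.cases(cmp3$pairs[c("predicted", "measured")])
  expect_equal(cmp3$kendall$tau,
               naive_kendall(cmp3$pairs$predicted[cc],
                             cmp3$pairs$measured[cc]))
  expect_true(is.finite(cmp3$groups$p_high_vs_low))
  # fewer than three mapped pairs: correlation NA
  cmp4 <- compare_predicted_measured(pred[1:2, ], meas[1:2, ],
                                     mapping[1:3, ])
  expect_true(is.na(cmp4$kendall$tau))
})

test_that("gene pairs averaging within node pairs pools duplicates", {
  pred <- data.frame(node_a = "N1", node_b = "N3", synergy = 0.3)
  mapping <- data.frame(gene = c("gA", "gC", "gE"),
                        node = c("N1", "N3", "N3"))
  meas <- data.frame(entity_a = c("gA", "gA"), entity_b = c("gC", "gE"),
                     synergy = c(10, 30))
  cmp <- compare_predicted_measured(pred, meas, mapping)
  expect_equal(cmp$pairs$measured, 20)   # mean of the two mapped gene pairs
})
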