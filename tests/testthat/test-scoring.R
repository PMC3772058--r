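# Synergy and synthetic-lethality scoring on the predicted efficacy matrix.

# small model whose single and pair efficacies are fully controlled through
# identical-set matches
controlled_matrix <- function(yA, yB, yAB, extra = NULL) {
  rows <- list(c(1, 0), c(0, 1), c(1, 1), c(0, 0))
  y <- c(yA, yB, yAB, 0)
  X <- toy_binary(rows, c("A", "B"))
  enumerate_efficacy_matrix(timma_model(X, y))
}

test_that("efficacy matrix enumerates all states and honours training matches", {
  d <- toy_binary(list(c(1, 0), c(0, 1), c(1, 1)), c("A", "B"))
  m <- timma_model(d, c(0.2, 0.3, 0.8))
  M <- enumerate_efficacy_matrix(m)
  expect_equal(nrow(M), 4L)
  expect_equal(M$efficacy[M$targets == "A + B"], 0.8)   # identical-set
  expect_equal(M$efficacy[M$targets == "A"], 0.2)
  # pairwise mode: empty + singles + pairs
  d3 <- toy_binary(list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1)),
                   c("A", "B", "C"))
  M3 <- enumerate_efficacy_matrix(timma_model(d3, c(0.2, 0.3, 0.8)),
                                  mode = "pairwise")
  expect_equal(nrow(M3), 1L + 3L + 3L)
  expect_true(all(M3$n_targets <= 2L))
  # matrix values agree with a per-state oracle scan
  profs <- list("A", "B", c("A", "B", "C"))
  for (r in seq_len(nrow(M3))) {
    want <- naive_timma(profs, c(0.2, 0.3, 0.8),
                        unmask(M3$state[r], c("A", "B", "C")))$prediction
    if (M3$state[r] == 0L && is.na(want)) want <- 0   # baseline default
    expect_equal(M3$efficacy[r], want)
  }
})

test_that("target-pair synergy follows the chosen null model", {
  # zero singles: the pair efficacy is pure synergy under either null
  M <- controlled_matrix(0, 0, 0.723)
  expect_equal(synergy_target_pair(M, "A", "B"), 0.723)
  expect_equal(synergy_target_pair(M, "A", "B", null = "product"), 0.723)
  # pair exactly at the Bliss expectation scores zero; the product null
  # diverges by yA*yB
  M2 <- controlled_matrix(0.3, 0.4, 0.58)
  expect_equal(synergy_target_pair(M2, "A", "B"), 0)
  expect_equal(synergy_target_pair(M2, "A", "B", null = "product"), 0.46)
  # symmetry
  expect_equal(synergy_target_pair(M2, "B", "A"),
               synergy_target_pair(M2, "A", "B"))
})

test_that("drug-pair synergy averages valid cross pairs and skips shared nodes", {
  rows <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0), c(1, 0, 1),
               c(0, 1, 1), c(1, 1, 1), c(0, 0, 0))
  y <- c(0.1, 0.2, 0.15, 0.5, 0.6, 0.55, 0.9, 0)
  X <- toy_binary(rows, c("a", "b", "c"))
  M <- enumerate_efficacy_matrix(timma_model(X, y))
  s_ab <- synergy_target_pair(M, "a", "b")
  s_ac <- synergy_target_pair(M, "a", "c")
  expect_equal(synergy_drug_pair(M, "a", c("b", "c")),
               mean(c(s_ab, s_ac)))
  expect_equal(synergy_drug_pair(M, "a", "b"), s_ab)
  # identical single-node drugs have no valid cross pair
  expect_true(is.na(synergy_drug_pair(M, "a", "a")))
  # symmetry in the two drugs
  expect_equal(synergy_drug_pair(M, c("a", "b"), "c"),
               synergy_drug_pair(M, "c", c("a", "b")))
  # table view is consistent with the pair function
  tab <- synergy_table(M)
  row <- tab[tab$entity_a == "a" & tab$entity_b == "b", ]
  expect_equal(row$synergy, s_ab)
})

test_that("synthetic lethality hits its sentinels on perfect AND / OR data", {
  rows <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
               c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  X <- toy_binary(rows, c("A", "B"))
  and_y <- c(0, 0, 0, 1, 0, 0, 0, 1)
  or_y <- c(0, 1, 1, 1, 0, 1, 1, 1)
  and_score <- synthetic_lethality_score(X, and_y, "A", "B")
  expect_equal(and_score$tss_parallel, 0)
  expect_identical(and_score$score, Inf)
  or_score <- synthetic_lethality_score(X, or_y, "A", "B")
  expect_equal(or_score$tss_series, 0)
  expect_equal(or_score$score, 0)
  # swapping A and B changes nothing
  sw <- synthetic_lethality_score(X, and_y, "B", "A")
  expect_identical(sw$score, and_score$score)
})

test_that("noisy AND pattern reproduces a hand-computed TSS table", {
  rows <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1),
               c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  X <- toy_binary(rows, c("A", "B"))
  y <- c(0.05, 0.1, 0.12, 0.9, 0.08, 0.15, 0.1, 0.95)
  s <- synthetic_lethality_score(X, y, "A", "B")
  tss <- function(groups) sum(vapply(groups, function(g)
    sum((y[g] - mean(y[g]))^2), 0))
  expect_equal(s$tss_parallel, tss(list(c(4, 8), c(1, 2, 3, 5, 6, 7))))
  expect_equal(s$tss_series, tss(list(c(2, 3, 4, 6, 7, 8), c(1, 5))))
  expect_equal(s$tss_singleton,
               min(tss(list(c(2, 4, 6, 8), c(1, 3, 5, 7))),
                   tss(list(c(3, 4, 7, 8), c(1, 2, 5, 6)))))
  expect_equal(s$score, min(s$tss_series, s$tss_singleton) / s$tss_parallel)
  expect_gt(s$score, 1)
})

test_that("anchor ranking returns only above-baseline partners with tied ranks", {
  rows <- list(c(0, 0, 0, 0), c(1, 0, 0, 0), c(0, 1, 1, 0), c(1, 1, 1, 0),
               c(0, 0, 0, 1), c(1, 0, 0, 1), c(0, 1, 1, 1), c(1, 1, 1, 1))
  X <- toy_binary(rows, c("ANC", "P1", "P2", "N"))
  # AND pattern between ANC and P1 (and the identical column P2)
  y <- as.numeric(vapply(rows, function(r) r[1] == 1 && r[2] == 1, TRUE))
  r <- rank_synthetic_lethal_partners(X, y, "ANC")
  expect_equal(r$baseline, 1)
  expect_true(all(c("P1", "P2") %in% r$partners$target))
  # identical columns score identically and share a rank
  p <- r$partners
  expect_equal(p$score[p$target == "P1"], p$score[p$target == "P2"])
  expect_equal(p$rank[p$target == "P1"], p$rank[p$target == "P2"])
  expect_false("N" %in% p$target)
  # an anchor whose column is duplicated everywhere yields no partners
  X2 <- toy_binary(list(c(0, 0), c(1, 1), c(0, 0), c(1, 1)), c("A", "B"))
  y2 <- c(0, 1, 0.1, 0.9)
  r2 <- rank_synthetic_lethal_partners(X2, y2, "A")
  expect_equal(nrow(r2$partners), 0L)
})

test_that("ROC analysis matches brute-force pair counting and tie conventions", {
  # perfectly separating predictions
  r <- roc_sensitive_drugs(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auc, 1)
  # all-identical predictions: midrank AUC 0.5
  r2 <- roc_sensitive_drugs(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(r2$auc, 0.5)
  # 6-point toy with ties equals exhaustive pair counting
  pred <- c(0.1, 0.4, 0.4, 0.35, 0.8, 0.2)
  lab <- c(0, 1, 0, 1, 1, 0)
  r3 <- roc_sensitive_drugs(pred, lab)
  expect_equal(r3$auc, naive_auc(pred, lab))
  expect_error(roc_sensitive_drugs(pred, rep(1, 6)), "single class")
})
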