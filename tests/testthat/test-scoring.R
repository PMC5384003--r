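test_that("phenotype scores count distinct valid reporters", {
  sc <- score_phenotypes(cohort_t1())
  expect_equal(sc$score[match(c("Height", "Weight", "Eye Color"),
                              sc$phenotype)],
               c(2L, 1L, 1L))

  empty <- as_cohort(data.frame(participant_id = character(),
                                phenotype = character(),
                                value = character()))
  expect_equal(nrow(score_phenotypes(empty)), 0L)

  # two distinct values still contribute a single point
  co <- as_cohort(data.frame(participant_id = c("A", "A"),
                             phenotype = c("Height", "Height"),
                             value = c("170", "171")))
  expect_equal(score_phenotypes(co)$score, 1L)

  # a phenotype seen only with invalid values stays listed at score 0
  co0 <- as_cohort(data.frame(participant_id = "A", phenotype = "Mood",
                              value = "unsure"))
  expect_equal(score_phenotypes(co0),
               tibble::tibble(phenotype = "Mood", score = 0L))
})

test_that("validity filtering drops administrative, genotype and singleton entries", {
  sc <- tibble::tibble(
    phenotype = c("Height", "Weight", "enrolled",
                  "whole-genome sequencing data", "Rare trait"),
    score = c(5L, 3L, 100L, 50L, 1L)
  )
  valid <- filter_valid_phenotypes(sc)
  expect_setequal(valid$phenotypes$phenotype, c("Height", "Weight"))
  expect_equal(valid$denominator, 8)
  reasons <- valid$audit$reason[match(c("enrolled",
                                        "whole-genome sequencing data",
                                        "Rare trait"),
                                      valid$audit$phenotype)]
  expect_equal(reasons, c("administrative", "genotype", "low_score"))

  # T1 with defaults: only Height (score 2) survives
  v1 <- filter_valid_phenotypes(score_phenotypes(cohort_t1()))
  expect_equal(v1$phenotypes$phenotype, "Height")
  expect_equal(v1$denominator, 2)

  expect_error(filter_valid_phenotypes(
    tibble::tibble(phenotype = "x", score = 1L)), "denominator")
  expect_error(exclusion_config(min_share = 1), "min_share")
})

test_that("P-index matches the hand-enumerated fixtures", {
  v1 <- filter_valid_phenotypes(score_phenotypes(cohort_t1()))
  p1 <- compute_p_index(cohort_t1(), v1)
  expect_equal(p1$p_index[match(c("A", "B", "C"), p1$participant_id)],
               c(100, 100, 0))

  v2 <- filter_valid_phenotypes(score_phenotypes(cohort_t2()))
  expect_equal(v2$denominator, 5)
  p2 <- compute_p_index(cohort_t2(), v2)
  expect_equal(p2$p_index[match(c("A", "B", "C"), p2$participant_id)],
               c(100, 100, 60))

  # all indexes stay in [0, 100]; a full reporter hits exactly 100
  expect_true(all(p2$p_index >= 0 & p2$p_index <= 100))
})

test_that("ranking is descending with deterministic id tie-breaks", {
  pt <- tibble::tibble(participant_id = c("hu6D1115", "hu96713F"),
                       p_index = c(96.72, 96.74))
  rk <- rank_participants(pt)
  expect_equal(rk$participant_id, c("hu96713F", "hu6D1115"))
  expect_equal(rk$rank, 1:2)

  ties <- tibble::tibble(participant_id = c("C", "A", "B"),
                         p_index = c(50, 50, 50))
  expect_equal(rank_participants(ties)$participant_id, c("A", "B", "C"))
  one <- rank_participants(tibble::tibble(participant_id = "X", p_index = 0))
  expect_equal(one$rank, 1L)
})

test_that("quantitative phenotypes are numeric-leading and well-supported", {
  rec <- rbind(
    data.frame(participant_id = sprintf("P%02d", 1:12), phenotype = "Weight",
               value = paste(60 + 1:12, c("kg", "lbs"))),
    data.frame(participant_id = sprintf("P%02d", 1:12), phenotype = "Eye Color",
               value = rep(c("blue", "brown"), 6)),
    data.frame(participant_id = sprintf("P%02d", 1:9), phenotype = "Pulse",
               value = as.character(60 + 1:9))
  )
  co <- as_cohort(rec)
  sc <- score_phenotypes(co)
  q <- select_quantitative_phenotypes(co, sc)
  expect_true("Weight" %in% q)
  expect_false("Eye Color" %in% q)   # non-numeric
  expect_false("Pulse" %in% q)       # score 9 < 10
  expect_true("Pulse" %in% select_quantitative_phenotypes(co, sc, min_score = 9L))
})

test_that("QtP-index is the P-index restricted to the quantitative list", {
  co <- cohort_t2()
  sc <- score_phenotypes(co)
  qt <- compute_qtp_index(co, "Weight", sc)
  expect_equal(qt$p_index[match(c("A", "B", "C"), qt$participant_id)],
               c(100, 100, 0))
  # in the limit of the full valid list, QtP equals P
  valid <- filter_valid_phenotypes(sc)
  full <- compute_qtp_index(co, valid$phenotypes$phenotype, sc)
  expect_equal(full$p_index, compute_p_index(co, valid)$p_index)
  expect_error(compute_qtp_index(co, character(), sc), "empty")
})

test_that("suggestions list the best missing phenotypes with their gain", {
  co <- cohort_t2()
  valid <- filter_valid_phenotypes(score_phenotypes(co))
  sg <- suggest_phenotypes(co, "C", valid, k = 3L)
  expect_equal(sg$phenotype, "Weight")
  expect_equal(sg$score, 2L)
  expect_equal(sg$p_index_gain, 40)
  # a complete reporter gets no suggestions
  expect_equal(nrow(suggest_phenotypes(co, "A", valid)), 0L)

  # applying the top suggestion (score table held fixed) raises the
  # P-index by exactly the advertised gain
  before <- compute_p_index(co, valid)
  co2 <- as_cohort(rbind(as.data.frame(co$records[, 1:3]),
                         data.frame(participant_id = "C",
                                    phenotype = "Weight", value = "75")),
                   roster = co$participants)
  after <- compute_p_index(co2, valid)
  expect_equal(after$p_index[after$participant_id == "C"],
               before$p_index[before$participant_id == "C"] + sg$p_index_gain)
})

test_that("scores and P-indexes match the brute-force oracle on random cohorts", {
  set.seed(405)
  n_done <- 0L
  while (n_done < 60L) {
    co <- random_cohort()
    sc <- score_phenotypes(co)
    oracle <- brute_scores(co)
    expect_equal(sc$score[match(names(oracle), sc$phenotype)],
                 unname(oracle))
    valid_names <- names(oracle)[oracle >= 2L]
    if (length(valid_names) == 0L) next
    valid <- filter_valid_phenotypes(sc)
    p <- compute_p_index(co, valid)
    expect_equal(p$p_index,
                 unname(brute_p_index(co, oracle, valid_names)[p$participant_id]))
    n_done <- n_done + 1L
  }
})

test_that("raw sums obey the conservation identity sum_j raw_j = sum_i S_i^2", {
  set.seed(406)
  for (i in 1:40) {
    co <- random_cohort()
    sc <- score_phenotypes(co)
    if (!any(sc$score >= 2L)) next
    valid <- filter_valid_phenotypes(sc)
    p <- compute_p_index(co, valid)
    expect_equal(sum(p$raw_sum), sum(as.numeric(valid$phenotypes$score)^2))
  }
})

test_that("adding a valid report never lowers the P-index (fixed score table)", {
  set.seed(407)
  for (i in 1:20) {
    co <- random_cohort()
    sc <- score_phenotypes(co)
    if (!any(sc$score >= 2L)) next
    valid <- filter_valid_phenotypes(sc)
    before <- compute_p_index(co, valid)
    pid <- sample(co$participants, 1L)
    phen <- sample(valid$phenotypes$phenotype, 1L)
    co2 <- as_cohort(rbind(as.data.frame(co$records[, 1:3]),
                           data.frame(participant_id = pid, phenotype = phen,
                                      value = "brand new valid value")),
                     roster = co$participants)
    after <- compute_p_index(co2, valid)
    expect_gte(after$p_index[after$participant_id == pid],
               before$p_index[before$participant_id == pid])
    expect_true(all(after$p_index >= 0 & after$p_index <= 100))
  }
})

test_that("per-phenotype weights bias the index as configured", {
  co <- cohort_t2()
  valid <- filter_valid_phenotypes(score_phenotypes(co))
  # doubling Weight's weight: denominator 3 + 2*2 = 7, C holds Height only
  p <- compute_p_index(co, valid, weights = c(Weight = 2))
  expect_equal(p$p_index[p$participant_id == "C"], 100 * 3 / 7)
})

test_that("score tail shares summarize the upper score distribution", {
  ts <- score_tail_share(c(5, 20, 200, 1500), 100)
  expect_equal(ts$n_above, 2L)
  expect_equal(ts$pct, 50)
  expect_equal(score_tail_share(tibble::tibble(score = c(1, 2, 3)), 2)$pct,
               100 / 3)
})
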