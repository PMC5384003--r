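make_ptable <- function(p) {
  tibble::tibble(participant_id = sprintf("P%04d", seq_along(p)), p_index = p)
}

test_that("prevalence is the yes share among yes/no respondents", {
  rec <- data.frame(
    participant_id = sprintf("P%04d", 1:1845),
    phenotype = "Diabetes mellitus, type 2",
    value = c(rep("yes", 16), rep("no", 1829))
  )
  pv <- prevalence_table(as_cohort(rec))
  expect_equal(pv$n_yes, 16L)
  expect_equal(pv$n_no, 1829L)
  expect_equal(round(pv$prevalence_percent, 2), 0.87)

  small <- as_cohort(data.frame(
    participant_id = sprintf("A%d", 1:4),
    phenotype = "Trait",
    value = c("yes", rep("no", 3))
  ))
  expect_equal(prevalence_table(small)$prevalence_percent, 25)

  zero <- as_cohort(data.frame(participant_id = sprintf("C%d", 1:10),
                               phenotype = "Trait", value = "no"))
  expect_equal(prevalence_table(zero)$prevalence_percent, 0)

  # respondents are bounded by the cohort size
  expect_lte(pv$n_yes + pv$n_no, n_participants(as_cohort(rec)))
})

test_that("distribution summary counts strict tails, zeros and medians", {
  d <- pindex_distribution(make_ptable(c(0, 0, 95)))
  expect_equal(d$n_above_hi, 1L)
  expect_equal(d$n_below_lo, 2L)
  expect_equal(d$n_zero, 2L)
  expect_equal(d$median_all, 0)
  expect_equal(d$median_nonzero, 95)

  d2 <- pindex_distribution(make_ptable(c(5, 15)))
  expect_equal(d2$median_all, 10)
  expect_equal(d2$n_above_hi, 0L)
  expect_equal(d2$n_below_lo, 1L)

  d3 <- pindex_distribution(make_ptable(rep(100, 7)))
  expect_equal(d3$n_above_hi, 7L)
  expect_equal(d3$n_below_lo, 0L)
  expect_true(is.na(pindex_distribution(make_ptable(c(0, 0)))$median_nonzero))
  expect_error(pindex_distribution(make_ptable(numeric())), "empty")
})

test_that("binomial sex test matches exact tail arithmetic", {
  expect_equal(binomial_sex_test(5, 5), 1)
  # P(X >= 8 | n = 10, p = 1/2) = 56/1024
  expect_equal(binomial_sex_test(8, 2, sided = "one"), 56 / 1024)
  expect_error(binomial_sex_test(-1, 2), "non-negative")
  expect_error(binomial_sex_test(0, 0), "at least one")
  # two-sided p is symmetric in its arguments
  set.seed(408)
  for (i in 1:20) {
    k <- sample(0:30, 1L); m <- sample(0:30, 1L)
    if (k + m == 0L) next
    expect_equal(binomial_sex_test(k, m), binomial_sex_test(m, k))
  }
})

test_that("rank-sum exact path equals full enumeration; ties fall back", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical groups (all ties) take the approximation path at p = 1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")

  set.seed(409)
  for (m in 1:5) {
    for (n in m:(10 - m)) {
      vals <- sample(seq(0.5, 99.5, by = 0.5), m + n)
      a <- vals[1:m]; b <- vals[-(1:m)]
      expect_equal(wilcoxon_rank_sum(a, b), enum_wilcox_p(a, b),
                   info = sprintf("m=%d n=%d", m, n))
    }
  }
})

test_that("stratification groups by field value with a minimum group size", {
  ids <- sprintf("P%04d", 1:61)
  rec <- data.frame(participant_id = ids, phenotype = "State",
                    value = c(rep("South Carolina", 31), rep("Utah", 29),
                              "unsure"))
  co <- as_cohort(rec)
  pt <- tibble::tibble(participant_id = ids,
                       p_index = c(rep(95, 9), rep(50, 22), rep(20, 29), 10))
  st <- stratify_by_field(pt, co, "State", min_group = 30L)
  expect_equal(st$label, "South Carolina")
  expect_equal(st$n, 31L)
  expect_equal(round(st$pct_above_90), 29)
  # Utah (29 < 30) dropped but accounted for; the invalid "unsure"
  # reporter is excluded entirely
  dropped <- attr(st, "dropped")
  expect_equal(dropped$label, "Utah")
  expect_equal(sum(st$n) + sum(dropped$n), 60L)

  # hand-computed medians for two clean groups
  rec2 <- data.frame(participant_id = sprintf("Q%02d", 1:6),
                     phenotype = "Sex/Gender",
                     value = rep(c("Male", "Female"), each = 3))
  pt2 <- tibble::tibble(participant_id = sprintf("Q%02d", 1:6),
                        p_index = c(10, 20, 30, 40, 50, 60))
  st2 <- stratify_by_field(pt2, as_cohort(rec2), "Sex/Gender", min_group = 1L)
  expect_equal(st2$median_p_index[st2$label == "Male"], 20)
  expect_equal(st2$median_p_index[st2$label == "Female"], 50)

  # dual-listed values form their own stratum
  rec3 <- rbind(rec2, data.frame(participant_id = "Q07",
                                 phenotype = "Sex/Gender",
                                 value = c("Male", "Female")))
  pt3 <- rbind(pt2, tibble::tibble(participant_id = "Q07", p_index = 0))
  st3 <- stratify_by_field(pt3, as_cohort(rec3), "Sex/Gender", min_group = 1L)
  expect_true("Female + Male" %in% st3$label)
  expect_equal(st3$n[st3$label == "Male"], 3L)
})

test_that("geocoding normalizes zips against the gazetteer", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("zip,latitude,longitude", "02144,42.40,-71.12",
               "63101,38.63,-90.19"), csv)
  gaz <- load_gazetteer(csv)
  co <- as_cohort(data.frame(
    participant_id = c("A", "B", "C", "D"),
    phenotype = "Zip code",
    value = c("02144", "2144", "ABCDE", "99999")
  ))
  pts <- geocode_participants(co, gaz)
  expect_setequal(pts$participant_id, c("A", "B"))
  expect_equal(pts$zip[pts$participant_id == "B"], "02144")
  expect_equal(attr(pts, "n_unmatched"), 2L)
})

test_that("degree cells use floor latitude and ceiling longitude", {
  pts <- tibble::tibble(
    participant_id = c("A", "B", "C"),
    zip = "x",
    latitude = c(42.3, 42.7, 42.0),
    longitude = c(-71.1, -71.9, -71.0)
  )
  pt <- tibble::tibble(participant_id = c("A", "B", "C"),
                       p_index = c(10, 30, 50))
  cl <- cluster_geopoints(pts, pt)
  expect_equal(nrow(cl), 1L)   # all in cell (42, -71), incl. the boundary
  expect_equal(cl$cell_lat, 42)
  expect_equal(cl$cell_lon, -71)
  # plot coordinates are medians of the unrounded member coordinates
  expect_equal(cl$plot_lat, 42.3)
  expect_equal(cl$plot_lon, -71.1)
  expect_equal(cl$median_p_index, 30)

  two <- cluster_geopoints(pts[1:2, ], pt)
  expect_equal(two$plot_lat, 42.5)
  expect_equal(two$plot_lon, -71.5)

  expect_error(cluster_geopoints(pts[0, ], pt), "no geocoded")
})

test_that("clusters partition the geocoded points", {
  set.seed(410)
  pts <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:200),
    zip = "x",
    latitude = runif(200, 25, 48),
    longitude = runif(200, -124, -67)
  )
  pt <- tibble::tibble(participant_id = pts$participant_id,
                       p_index = runif(200, 0, 100))
  cl <- cluster_geopoints(pts, pt)
  expect_equal(sum(cl$n), 200L)
  expect_setequal(unlist(cl$member_ids), pts$participant_id)
  for (i in seq_len(nrow(cl))) {
    members <- pts[pts$participant_id %in% cl$member_ids[[i]], ]
    expect_true(all(floor(members$latitude) == cl$cell_lat[i]))
    expect_true(all(ceiling(members$longitude) == cl$cell_lon[i]))
  }
})
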