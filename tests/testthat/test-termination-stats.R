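# a tiny hand-buildable endpoint table against the phantom label table
phantom_ids <- function() {
  tbl <- fixture_atlas()$table
  id_of <- function(name, hemi) tbl$id[tbl$name == name & tbl$hemisphere == hemi]
  list(ifg_r = id_of("IFG", "right"), ifg_l = id_of("IFG", "left"),
       stg_r = id_of("STG", "right"), ins_r = id_of("INS", "right"),
       dwm_r = id_of("DWM", "right"), subc_r = id_of("SUBC", "right"))
}

test_that("tally_terminations categorizes, sides and conserves endpoints", {
  ids <- phantom_ids()
  tbl <- fixture_atlas()$table
  ep <- tibble::tibble(
    id = 1:5,
    label_1 = c(ids$ifg_r, ids$ifg_r, ids$ifg_l, ids$dwm_r, 0L),
    label_2 = c(ids$stg_r, ids$ins_r, ids$dwm_r, ids$subc_r, 0L),
    broken_1 = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    broken_2 = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    excluded_1 = FALSE,
    excluded_2 = c(FALSE, TRUE, FALSE, FALSE, FALSE),
    y_1 = c(0, 0, 0, 0, 30),     # both-broken streamline: larger y is anterior
    y_2 = c(0, 0, 0, 0, -30))
  tal <- tally_terminations(ep, tbl)
  counts <- tal$counts
  g <- function(region, hemi) counts$count[counts$region == region &
                                             counts$hemisphere == hemi]
  expect_equal(g("IFG", "right"), 2)
  expect_equal(g("IFG", "left"), 1)
  expect_equal(g("STG", "right"), 1)
  # insula/subcortical endpoints are recorded as excluded, not counted
  expect_false("INS" %in% counts$region)
  expect_equal(sum(tal$excluded$count), 2)
  # both exclusions sit on the posterior side: INS is posterior-set, and the
  # sideless SUBC endpoint falls back to the y rule (its partner wins anterior)
  expect_identical(unique(tal$excluded$side), "posterior")
  # broken ends: s3's DWM end is the complement of its anterior IFG partner
  # (posterior); s4's DWM end gets anterior by the y fallback; the doubly
  # broken s5 contributes one anterior and one posterior end by y
  expect_equal(unname(tal$broken), c(anterior = 2, posterior = 2),
               ignore_attr = TRUE)
  cons <- tally_conservation(tal)
  expect_true(all(cons$ok))
  expect_equal(unique(cons$total), 5)
  # all analyzable regions appear, zeros included
  analyzable <- tbl[tbl$tissue == "CGM" & !(tbl$lobe %in%
                                              c("insula", "subcortical")), ]
  expect_equal(nrow(counts), nrow(analyzable))
})

test_that("NTDS, threshold, adjustment and presence follow their formulas", {
  # two subjects, one region pair, constructed counts
  mk <- function(c_ifg_r, total) {
    tbl <- fixture_atlas()$table
    ids <- phantom_ids()
    ep <- tibble::tibble(
      id = seq_len(total),
      label_1 = rep(ids$ifg_r, total),
      label_2 = c(rep(ids$stg_r, c_ifg_r), rep(0L, total - c_ifg_r)),
      broken_1 = FALSE, broken_2 = c(rep(FALSE, c_ifg_r),
                                     rep(TRUE, total - c_ifg_r)),
      excluded_1 = FALSE, excluded_2 = FALSE, y_1 = 1, y_2 = 0)
    tally_terminations(ep, tbl)
  }
  cohort <- compute_ntds(list(mk(8, 10), mk(5, 10)))
  expect_equal(sort(unique(cohort$subject)), 1:2)
  expect_equal(cohort$ntds[cohort$region == "IFG" &
                             cohort$hemisphere == "right"], c(1.0, 1.0))
  expect_equal(cohort$ntds[cohort$region == "STG" &
                             cohort$hemisphere == "right"], c(0.8, 0.5))
  expect_true(all(cohort$ntds >= 0 & cohort$ntds <= 1))

  # pooled threshold uses the FP region's values from both hemispheres
  thr <- fp_threshold(cohort, "STG")
  fp_vals <- c(0.8, 0.5, 0, 0)   # right: 0.8, 0.5; left: 0, 0
  expect_equal(thr$threshold, mean(fp_vals) + 2 * sd(fp_vals))
  adj <- adjust_ntds(cohort, thr)
  # identity: adjusted + threshold == NTDS, negatives retained
  expect_equal(adj$adj + thr$threshold, adj$ntds)
  expect_true(any(adj$adj < 0))
  # with an all-zero FP region the threshold is 0 and presence is direct
  thr0 <- fp_threshold(cohort, "SPG")
  expect_equal(thr0$threshold, 0)
  pres <- presence_percentages(adjust_ntds(cohort, thr0))
  expect_equal(pres$percent[pres$region == "IFG" &
                              pres$hemisphere == "right"], 100)
  expect_equal(pres$percent[pres$region == "SPG" &
                              pres$hemisphere == "right"], 0)
  # per-hemisphere thresholds line up by hemisphere
  thr2 <- fp_threshold(cohort, "STG", per_hemisphere = TRUE)
  expect_true(all(c("left", "right") %in% thr2$hemisphere))
  adj2 <- adjust_ntds(cohort, thr2)
  i <- match(adj2$hemisphere, thr2$hemisphere)
  expect_equal(adj2$adj, adj2$ntds - thr2$threshold[i])
})

test_that("territory_test: degenerate regions, Bonferroni divisor and small-n guard", {
  set.seed(31)
  subjects <- 1:12
  adj <- dplyr::bind_rows(
    tibble::tibble(subject = subjects, region = "A", hemisphere = "right",
                   side = "anterior", adj = abs(rnorm(12)) + 0.01),
    tibble::tibble(subject = subjects, region = "B", hemisphere = "right",
                   side = "anterior", adj = 0),
    tibble::tibble(subject = subjects, region = "C", hemisphere = "right",
                   side = "posterior", adj = rnorm(12, 0, 0.05)))
  res <- territory_test(adj, alpha = 0.05)
  expect_true(res$degenerate[res$region == "B"])
  expect_equal(res$p_value[res$region == "B"], 1)
  # divisor counts only the non-degenerate tests (A and C)
  expect_equal(unique(res$cutoff), 0.05 / 2)
  expect_true(res$territory[res$region == "A"])
  expect_false(res$territory[res$region == "B"])
  expect_error(territory_test(adj[adj$subject <= 4, ]), "at least 5")
})

test_that("asymmetry index and tests: formula, antisymmetry, NA and degenerate guards", {
  expect_equal(asymmetry_index(0.19, 0.26), 7 / 45)
  expect_equal(asymmetry_index(c(1, 0), c(0, 2)), c(-1, 1))
  expect_true(is.na(asymmetry_index(0, 0)))
  x <- runif(20); y <- runif(20)
  expect_equal(asymmetry_index(x, y), -asymmetry_index(y, x))
  expect_error(asymmetry_index(-0.1, 0.2))

  set.seed(8)
  ai <- dplyr::bind_rows(
    tibble::tibble(subject = 1:30, region = "MOG", side = "posterior",
                   left = NA, right = NA, ai = rnorm(30, 0.3, 0.1)),
    tibble::tibble(subject = 1:30, region = "PRC", side = "anterior",
                   left = NA, right = NA, ai = 0),
    tibble::tibble(subject = 1:30, region = "SFG", side = "anterior",
                   left = NA, right = NA, ai = rnorm(30, 0, 0.1)))
  res <- asymmetry_test(ai, alpha = 0.05)
  expect_true(res$significant[res$region == "MOG"])
  expect_false(res$significant[res$region == "SFG"])
  # identically-zero AI is degenerate, untested, never significant
  prc <- res[res$region == "PRC", ]
  expect_true(prc$degenerate); expect_false(prc$tested)
  expect_false(prc$significant)
  expect_equal(unique(res$cutoff), 0.05 / 2)
  # t and Wilcoxon agree on the strong effect
  res_w <- asymmetry_test(ai, method = "wilcoxon")
  expect_true(res_w$significant[res_w$region == "MOG"])
  # regions below min_n are reported but not tested
  small <- ai[ai$subject <= 3 | ai$region != "MOG", ]
  res_s <- asymmetry_test(small, min_n = 5)
  expect_false(res_s$tested[res_s$region == "MOG"])
})
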