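#' Termination tally objects
#'
#' Per-subject, per-tract endpoint bookkeeping: counts of streamline
#' endpoints per cortical region and hemisphere (split into the anterior
#' and posterior end-sets), the total number of tract streamlines (left +
#' right — the denominator of the normalized termination density score),
#' per-side broken-endpoint counts, and endpoints recorded but excluded
#' from analysis (insula, subcortical nuclei).
#'
#' @param counts Tibble `region`, `hemisphere`, `side`, `count`.
#' @param total_streamlines Total tract streamlines (both hemispheres).
#' @param broken Named numeric `c(anterior =, posterior =)`.
#' @param excluded Tibble like `counts` for excluded terminations.
#' @return An object of class `termination_tally`.
#' @keywords internal
new_termination_tally <- function(counts, total_streamlines, broken, excluded) {
  stopifnot(all(counts$count >= 0),
            sum(counts$count) <= 2 * total_streamlines)
  structure(list(counts = counts,
                 total_streamlines = as.integer(total_streamlines),
                 broken = broken, excluded = excluded),
            class = "termination_tally")
}

#' @export
print.termination_tally <- function(x, ...) {
  cat("<termination_tally>", x$total_streamlines, "streamlines;",
      sum(x$counts$count), "cortical endpoints;",
      sum(x$broken), "broken;", sum(x$excluded$count), "excluded\n")
  invisible(x)
}

#' Tally tract terminations per region
#'
#' Turns the endpoint table of [extract_tract()] into a
#' [new_termination_tally()]: every endpoint in an analyzable cortical
#' gray-matter region increments that region's count on its end-set side;
#' endpoints in excluded lobes (insula, subcortical by default) go to the
#' excluded tally; endpoints that are background, SWM or DWM are broken.
#' The side of a non-cortical endpoint is the complement of the other
#' endpoint's side when known, otherwise the endpoint with the larger y
#' coordinate is called anterior. All analyzable regions appear in the
#' counts (with zeros) so cohort statistics see complete tables.
#'
#' @param endpoints Endpoint tibble from [extract_tract()] (left and right
#'   extractions may be row-bound to pool hemispheres).
#' @param table Label table of the volume used for endpoint lookup.
#' @param excluded_lobes Lobes excluded from the analysis.
#' @return A `termination_tally`.
#' @export
tally_terminations <- function(endpoints, table,
                               excluded_lobes = c("insula", "subcortical")) {
  tbl_by_id <- table
  side_of_label <- function(lab) {
    i <- match(lab, tbl_by_id$id)
    ts <- tbl_by_id$terminal_side[i]
    out <- rep(NA_character_, length(lab))
    out[!is.na(ts) & ts == "anterior_set"] <- "anterior"
    out[!is.na(ts) & ts == "posterior_set"] <- "posterior"
    out
  }
  category <- function(lab) {
    i <- match(lab, tbl_by_id$id)
    lobe <- tbl_by_id$lobe[i]
    tissue <- tbl_by_id$tissue[i]
    out <- rep("broken", length(lab))
    excl <- !is.na(lobe) & lobe %in% excluded_lobes
    counted <- !excl & !is.na(tissue) & tissue == "CGM"
    out[excl] <- "excluded"
    out[counted] <- "counted"
    out
  }
  lab1 <- endpoints$label_1; lab2 <- endpoints$label_2
  cat1 <- category(lab1); cat2 <- category(lab2)
  side1 <- side_of_label(lab1); side2 <- side_of_label(lab2)
  # complement / geometric fallback for endpoints without an anatomical side
  flip <- c(anterior = "posterior", posterior = "anterior")
  fix1 <- is.na(side1)
  side1[fix1 & !is.na(side2)] <- flip[side2[fix1 & !is.na(side2)]]
  fix2 <- is.na(side2)
  side2[fix2 & !is.na(side1)] <- flip[side1[fix2 & !is.na(side1)]]
  both <- is.na(side1) & is.na(side2)
  if (any(both)) {
    y1 <- if ("y_1" %in% names(endpoints)) endpoints$y_1 else rep(0, nrow(endpoints))
    y2 <- if ("y_2" %in% names(endpoints)) endpoints$y_2 else rep(0, nrow(endpoints))
    side1[both] <- ifelse(y1[both] >= y2[both], "anterior", "posterior")
    side2[both] <- flip[side1[both]]
  }

  long <- tibble::tibble(
    label = c(lab1, lab2), category = c(cat1, cat2), side = c(side1, side2))
  i <- match(long$label, tbl_by_id$id)
  long$region <- tbl_by_id$name[i]
  long$hemisphere <- tbl_by_id$hemisphere[i]

  analyzable <- tbl_by_id[tbl_by_id$tissue == "CGM" &
                            !(tbl_by_id$lobe %in% excluded_lobes), ]
  base <- tibble::tibble(
    region = analyzable$name, hemisphere = analyzable$hemisphere,
    side = ifelse(analyzable$terminal_side == "anterior_set",
                  "anterior", "posterior"))
  counted <- long[long$category == "counted", c("region", "hemisphere", "side")]
  counts <- dplyr::count(counted, .data$region, .data$hemisphere, .data$side,
                         name = "count")
  counts <- dplyr::left_join(base, counts,
                             by = c("region", "hemisphere", "side"))
  counts$count <- as.integer(tidyr::replace_na(counts$count, 0L))

  excl <- long[long$category == "excluded", ]
  excluded <- dplyr::count(excl, .data$region, .data$hemisphere, .data$side,
                           name = "count")
  broken_side <- table(factor(long$side[long$category == "broken"],
                              levels = c("anterior", "posterior")))
  new_termination_tally(
    counts = counts,
    total_streamlines = nrow(endpoints),
    broken = c(anterior = as.integer(broken_side[["anterior"]]),
               posterior = as.integer(broken_side[["posterior"]])),
    excluded = excluded)
}

#' Endpoint conservation check of a tally
#'
#' On each side, counted + broken + excluded endpoints must equal the total
#' number of tract streamlines (each streamline has one endpoint per side).
#'
#' @param tally A `termination_tally`.
#' @return Tibble with per-side totals and an `ok` flag.
#' @export
tally_conservation <- function(tally) {
  per_side <- function(side) {
    counted <- sum(tally$counts$count[tally$counts$side == side])
    excl <- sum(tally$excluded$count[tally$excluded$side == side])
    broken <- unname(tally$broken[[side]])
    tibble::tibble(side = side, counted = counted, broken = broken,
                   excluded = excl,
                   total = counted + broken + excl,
                   ok = counted + broken + excl == tally$total_streamlines)
  }
  dplyr::bind_rows(per_side("anterior"), per_side("posterior"))
}

#' Normalized termination density scores
#'
#' The NTDS of a region is the number of tract streamlines ending in it
#' divided by the total number of left and right tract streamlines. Accepts
#' one tally or a per-subject list (a cohort).
#'
#' @param t A `termination_tally` or a list of them.
#' @return Tibble `subject`, `region`, `hemisphere`, `side`, `ntds`.
#' @export
compute_ntds <- function(t) {
  one <- function(tally, subject) {
    if (tally$total_streamlines <= 0L) stop("tally has zero total streamlines")
    out <- tally$counts
    out$ntds <- out$count / tally$total_streamlines
    out$subject <- subject
    out[, c("subject", "region", "hemisphere", "side", "ntds")]
  }
  if (inherits(t, "termination_tally")) return(one(t, 1L))
  dplyr::bind_rows(purrr::imap(t, function(tl, i) one(tl, as.integer(i))))
}

#' False-positive-region threshold
#'
#' The presence threshold for a tract is the mean plus twice the sample
#' standard deviation (n - 1 denominator) of the NTDS of a designated
#' false-positive region across the cohort; hemispheres are pooled by
#' default.
#'
#' @param cohort NTDS tibble from [compute_ntds()].
#' @param fp_region Region name assumed to contain only false positives.
#' @param per_hemisphere Compute a separate threshold per hemisphere.
#' @return An object of class `fp_threshold`: tibble `hemisphere`, `mean`,
#'   `sd`, `threshold` (hemisphere `"pooled"` unless `per_hemisphere`).
#' @export
fp_threshold <- function(cohort, fp_region, per_hemisphere = FALSE) {
  vals <- cohort[cohort$region == fp_region, ]
  if (nrow(vals) == 0L) stop("fp_region not present in NTDS table: ", fp_region)
  if (dplyr::n_distinct(vals$subject) < 2L) {
    stop("fp_threshold needs at least 2 subjects")
  }
  summarize <- function(x, hemisphere) {
    m <- mean(x); s <- stats::sd(x)
    if (is.na(s)) s <- 0
    tibble::tibble(hemisphere = hemisphere, mean = m, sd = s,
                   threshold = m + 2 * s)
  }
  out <- if (per_hemisphere) {
    dplyr::bind_rows(lapply(unique(vals$hemisphere), function(h) {
      summarize(vals$ntds[vals$hemisphere == h], h)
    }))
  } else {
    summarize(vals$ntds, "pooled")
  }
  structure(out, class = c("fp_threshold", class(out)), fp_region = fp_region)
}

#' Adjusted termination scores
#'
#' Subtracts the false-positive threshold from every subject's NTDS in
#' every region. Negative values are retained so downstream location tests
#' have a complete paired sample; "presence" is `adj > 0`.
#'
#' @param cohort NTDS tibble from [compute_ntds()].
#' @param thr An [fp_threshold()].
#' @return The input tibble with an `adj` column.
#' @export
adjust_ntds <- function(cohort, thr) {
  stopifnot(inherits(thr, "fp_threshold"))
  out <- cohort
  if (identical(thr$hemisphere, "pooled")) {
    out$adj <- out$ntds - thr$threshold[1]
  } else {
    i <- match(out$hemisphere, thr$hemisphere)
    if (anyNA(i)) stop("threshold missing for some hemisphere")
    out$adj <- out$ntds - thr$threshold[i]
  }
  out
}

#' Percentage of subjects with terminations present per region
#'
#' @param adj Adjusted-score tibble from [adjust_ntds()].
#' @return Tibble `region`, `hemisphere`, `side`, `n_subjects`, `n_present`,
#'   `percent` (presence = adjusted score > 0).
#' @export
presence_percentages <- function(adj) {
  adj |>
    dplyr::group_by(.data$region, .data$hemisphere, .data$side) |>
    dplyr::summarise(n_subjects = dplyr::n(),
                     n_present = sum(.data$adj > 0),
                     percent = 100 * sum(.data$adj > 0) / dplyr::n(),
                     .groups = "drop")
}

# one-sided (greater) Wilcoxon signed-rank against 0; zeros dropped; exact
# null for n <= 25 without ties, else normal approximation with continuity
# and tie correction
signed_rank_greater <- function(x, max_exact_n = 25L) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0L) {
    return(list(n = 0L, statistic = NA_real_, p = 1, degenerate = TRUE))
  }
  exact <- n <= max_exact_n && !any(duplicated(abs(x)))
  ht <- stats::wilcox.test(x, mu = 0, alternative = "greater",
                           exact = exact, correct = TRUE)
  list(n = n, statistic = unname(ht$statistic), p = ht$p.value,
       degenerate = FALSE)
}

#' Termination-territory test
#'
#' One region at a time, tests whether the adjusted termination scores are
#' located above zero (one-sided Wilcoxon signed-rank, null: location <= 0;
#' zeros dropped; exact null distribution up to n = 25, normal
#' approximation with tie/continuity correction beyond). Regions whose
#' adjusted scores are identically zero are flagged degenerate with p = 1.
#' The Bonferroni cutoff is `alpha` divided by the number of non-degenerate
#' tests actually performed; regions surviving it are the tract's
#' termination territories.
#'
#' @param adj Adjusted-score tibble from [adjust_ntds()].
#' @param alpha Family-wise error level.
#' @return Tibble `region`, `hemisphere`, `side`, `n`, `statistic`,
#'   `p_value`, `degenerate`, `cutoff`, `territory`.
#' @export
territory_test <- function(adj, alpha = 0.05) {
  if (dplyr::n_distinct(adj$subject) < 5L) {
    stop("territory_test needs at least 5 subjects")
  }
  res <- adj |>
    dplyr::group_by(.data$region, .data$hemisphere, .data$side) |>
    dplyr::summarise(test = list(signed_rank_greater(.data$adj)),
                     .groups = "drop")
  res$n <- vapply(res$test, function(t) t$n, integer(1))
  res$statistic <- vapply(res$test, function(t) as.numeric(t$statistic),
                          numeric(1))
  res$p_value <- vapply(res$test, function(t) t$p, numeric(1))
  res$degenerate <- vapply(res$test, function(t) t$degenerate, logical(1))
  res$test <- NULL
  m <- sum(!res$degenerate)
  res$cutoff <- if (m > 0) alpha / m else NA_real_
  res$territory <- !res$degenerate & res$p_value < res$cutoff
  res
}

#' Hemispheric asymmetry index
#'
#' `(right - left) / (right + left)`: +1 is fully right-lateralized, -1
#' fully left-lateralized. Undefined (NA) when both sides are zero.
#'
#' @param left,right Non-negative scores (vectorized).
#' @return Numeric in `[-1, 1]`, `NA` where `left + right == 0`.
#' @export
asymmetry_index <- function(left, right) {
  stopifnot(all(left >= 0, na.rm = TRUE), all(right >= 0, na.rm = TRUE))
  out <- (right - left) / (right + left)
  out[(left + right) == 0] <- NA_real_
  out
}

#' Per-subject asymmetry indexes of termination densities
#'
#' @param cohort NTDS tibble from [compute_ntds()].
#' @return Tibble `subject`, `region`, `side`, `left`, `right`, `ai`.
#' @export
asymmetry_table <- function(cohort) {
  wide <- tidyr::pivot_wider(
    cohort[cohort$hemisphere %in% c("left", "right"), ],
    id_cols = c("subject", "region", "side"),
    names_from = "hemisphere", values_from = "ntds", values_fill = 0)
  wide$ai <- asymmetry_index(wide$left, wide$right)
  wide
}

# one-sample location test of x against 0 with degenerate-data guards
location_test <- function(x, method) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(list(n = 0L, statistic = NA_real_, p = NA_real_,
                           degenerate = TRUE))
  if (stats::sd(x) == 0) {
    # constant sample: identically 0 is uninformative, constant != 0 is a
    # sure rejection in the limit
    return(list(n = n, statistic = if (mean(x) == 0) 0 else Inf * sign(mean(x)),
                p = if (mean(x) == 0) 1 else 0, degenerate = TRUE))
  }
  ht <- if (method == "t") {
    stats::t.test(x, mu = 0, alternative = "two.sided")
  } else {
    exact <- n <= 25 && !any(duplicated(abs(x[x != 0]))) && all(x != 0)
    stats::wilcox.test(x, mu = 0, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  }
  list(n = n, statistic = unname(ht$statistic), p = ht$p.value,
       degenerate = FALSE)
}

#' Asymmetry tests per region
#'
#' Two-sided one-sample location test of the asymmetry indexes against 0
#' for every region, with Bonferroni correction over the regions tested.
#' Regions with fewer than `min_n` non-missing indexes are skipped.
#'
#' @param ai Asymmetry tibble from [asymmetry_table()].
#' @param alpha Family-wise error level.
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @param min_n Minimum non-missing sample size per region.
#' @return Tibble `region`, `side`, `n`, `mean_ai`, `statistic`, `p_value`,
#'   `degenerate`, `tested`, `cutoff`, `significant`.
#' @export
asymmetry_test <- function(ai, alpha = 0.05, method = c("t", "wilcoxon"),
                           min_n = 5L) {
  method <- match.arg(method)
  res <- ai |>
    dplyr::group_by(.data$region, .data$side) |>
    dplyr::summarise(
      n = sum(!is.na(.data$ai)),
      mean_ai = mean(.data$ai, na.rm = TRUE),
      test = list(location_test(.data$ai, method)),
      .groups = "drop")
  res$statistic <- vapply(res$test, function(t) as.numeric(t$statistic),
                          numeric(1))
  res$p_value <- vapply(res$test, function(t) as.numeric(t$p), numeric(1))
  res$degenerate <- vapply(res$test, function(t) t$degenerate, logical(1))
  res$test <- NULL
  res$tested <- res$n >= min_n & !res$degenerate
  m <- sum(res$tested)
  res$cutoff <- if (m > 0) alpha / m else NA_real_
  res$significant <- res$tested & res$p_value < res$cutoff
  res
}
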