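#' Summarize a stem ROI
#'
#' Stem volume (nonzero voxel count times voxel volume) and center of mass
#' (unweighted mean of the nonzero voxels' world center coordinates, the
#' mask being binary), optionally mapped through an affine to a standard
#' space.
#'
#' @param stem A [stem_roi()].
#' @param voxel_volume Voxel volume in mm^3; defaults to the mask affine's
#'   determinant.
#' @param to_standard Optional 4x4 affine applied to the center of mass
#'   (native-to-standard spatial normalization stand-in).
#' @return One-row tibble `tract`, `hemisphere`, `operator`, `n_voxels`,
#'   `volume_mm3`, `com_x`, `com_y`, `com_z`.
#' @export
stem_summary <- function(stem, voxel_volume = NULL, to_standard = NULL) {
  if (nrow(stem$voxels) == 0L) stop("stem mask is empty")
  vox_vol <- voxel_volume %||% abs(det(stem$affine[1:3, 1:3]))
  centers <- voxel_to_world(stem$voxels, stem$affine)
  com <- colMeans(centers)
  if (!is.null(to_standard)) {
    stopifnot(all(dim(to_standard) == c(4, 4)))
    com <- drop(to_standard %*% c(com, 1))[1:3]
  }
  tibble::tibble(tract = stem$tract_tag, hemisphere = stem$hemisphere,
                 operator = stem$operator, n_voxels = nrow(stem$voxels),
                 volume_mm3 = nrow(stem$voxels) * vox_vol,
                 com_x = com[1], com_y = com[2], com_z = com[3])
}

#' Distance between two centers of mass
#'
#' @param a,b Length-3 world coordinates (mm).
#' @return `list(euclidean =, per_axis =)` — the Euclidean distance and the
#'   absolute per-axis differences `(|dx|, |dy|, |dz|)` in mm.
#' @export
com_distance <- function(a, b) {
  stopifnot(length(a) == 3, length(b) == 3)
  d <- abs(as.numeric(a) - as.numeric(b))
  list(euclidean = sqrt(sum(d^2)),
       per_axis = stats::setNames(d, c("dx", "dy", "dz")))
}

# paired t test with constant-difference guards
paired_t_guarded <- function(d) {
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(statistic = 0, p = 1))
    return(list(statistic = Inf * sign(mean(d)), p = 0))
  }
  ht <- stats::t.test(d, mu = 0)
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Inter-operator reliability of stem delineation
#'
#' Compares the stems drawn by two operators, matched by subject, tract and
#' hemisphere: per tract and hemisphere, the mean and SD of the volume
#' differences (operator 1 minus operator 2), a paired two-sided t-test on
#' the volumes, and the mean and SD of the Euclidean distances between the
#' operators' stem centers of mass.
#'
#' @param stems_op1,stems_op2 Tibbles of stem summaries with columns
#'   `subject`, `tract`, `hemisphere`, `volume_mm3`, `com_x`, `com_y`,
#'   `com_z` (e.g. row-bound [stem_summary()] outputs).
#' @return Tibble per tract x hemisphere: `n`, `mean_volume_diff`,
#'   `sd_volume_diff`, `t_statistic`, `p_value`, `mean_com_distance`,
#'   `sd_com_distance`.
#' @export
interoperator_report <- function(stems_op1, stems_op2) {
  keys <- c("subject", "tract", "hemisphere")
  merged <- dplyr::inner_join(stems_op1, stems_op2, by = keys,
                              suffix = c("_1", "_2"))
  k1 <- do.call(paste, stems_op1[keys])
  k2 <- do.call(paste, stems_op2[keys])
  unmatched <- c(setdiff(k1, k2), setdiff(k2, k1))
  if (length(unmatched) > 0) {
    stop("unmatched operator pairs: ", paste(unique(unmatched), collapse = "; "))
  }
  merged$vol_diff <- merged$volume_mm3_1 - merged$volume_mm3_2
  merged$com_dist <- sqrt((merged$com_x_1 - merged$com_x_2)^2 +
                            (merged$com_y_1 - merged$com_y_2)^2 +
                            (merged$com_z_1 - merged$com_z_2)^2)
  merged |>
    dplyr::group_by(.data$tract, .data$hemisphere) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_volume_diff = mean(.data$vol_diff),
      sd_volume_diff = if (dplyr::n() > 1) stats::sd(.data$vol_diff) else 0,
      t_statistic = paired_t_guarded(.data$vol_diff)$statistic,
      p_value = paired_t_guarded(.data$vol_diff)$p,
      mean_com_distance = mean(.data$com_dist),
      sd_com_distance = if (dplyr::n() > 1) stats::sd(.data$com_dist) else 0,
      .groups = "drop")
}

#' Repeated-measures ANOVA on stem volumes
#'
#' Tract (IFOF, UF) and Hemisphere (left, right) and their interaction as
#' within-subject factors and sex as a between-subjects factor, using the
#' standard within-subject error decomposition (`Error(subject/...)`
#' strata; both within factors have two levels, so sphericity corrections
#' do not apply). F is defined as 0 when an effect's sum of squares is 0
#' and Inf when the effect is nonzero but its error stratum has zero
#' residual variance.
#'
#' @param volumes Tibble with columns `subject`, `sex`, `tract`,
#'   `hemisphere`, `volume` — one row per subject x tract x hemisphere
#'   (complete crossed design).
#' @return An object of class `stem_anova`; see [tidy.stem_anova()].
#' @export
stem_volume_anova <- function(volumes) {
  needed <- c("subject", "sex", "tract", "hemisphere", "volume")
  miss <- setdiff(needed, names(volumes))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cells <- dplyr::count(volumes, .data$subject, .data$tract, .data$hemisphere)
  n_cells <- dplyr::n_distinct(volumes$tract) * dplyr::n_distinct(volumes$hemisphere)
  per_subject <- dplyr::count(cells, .data$subject)
  if (any(cells$n != 1L) || any(per_subject$n != n_cells)) {
    stop("design must be complete and crossed: one volume per subject x tract x hemisphere")
  }
  d <- data.frame(subject = factor(volumes$subject), sex = factor(volumes$sex),
                  tract = factor(volumes$tract),
                  hemisphere = factor(volumes$hemisphere),
                  volume = volumes$volume)
  with_sex <- nlevels(d$sex) > 1L
  form <- if (with_sex) {
    volume ~ sex * tract * hemisphere + Error(subject / (tract * hemisphere))
  } else {
    volume ~ tract * hemisphere + Error(subject / (tract * hemisphere))
  }
  fit <- stats::aov(form, data = d)
  strata <- summary(fit)
  rows <- list()
  for (stratum in strata) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid <- terms == "Residuals"
    if (!any(resid)) next
    ss_err <- tab[resid, "Sum Sq"]; df_err <- tab[resid, "Df"]
    for (i in which(!resid)) {
      ss <- tab[i, "Sum Sq"]; df <- tab[i, "Df"]
      if (ss <= 1e-12) {
        f <- 0; p <- 1
      } else if (ss_err <= 1e-12) {
        f <- Inf; p <- 0
      } else {
        f <- (ss / df) / (ss_err / df_err)
        p <- stats::pf(f, df, df_err, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        effect = terms[i], df = df, sum_sq = ss, df_error = df_err,
        sum_sq_error = ss_err, statistic = f, p_value = p)
    }
  }
  structure(list(table = dplyr::bind_rows(rows),
                 n_subjects = nlevels(d$subject), with_sex = with_sex),
            class = "stem_anova")
}

#' @export
print.stem_anova <- function(x, ...) {
  cat("Repeated-measures ANOVA on stem volumes (", x$n_subjects,
      " subjects)\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Tidy a stem-volume ANOVA
#' @param x A `stem_anova`.
#' @param ... Unused.
#' @return Tibble of effects with `df`, sums of squares, `statistic` (F)
#'   and `p_value`.
#' @method tidy stem_anova
#' @export
tidy.stem_anova <- function(x, ...) x$table

#' One-row summary of a stem-volume ANOVA
#' @param x A `stem_anova`.
#' @param ... Unused.
#' @return Tibble with subject count, effect count and the smallest effect
#'   p-value.
#' @method glance stem_anova
#' @export
glance.stem_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_effects = nrow(x$table),
                 min_p_value = min(x$table$p_value))
}
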