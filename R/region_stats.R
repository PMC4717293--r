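#' Summarize a map over anatomical regions
#'
#' Per-region statistic (mean by default, median via `statistic`) over
#' non-NaN voxels. Regions with fewer than `min_voxels` valid voxels are
#' flagged; empty regions produce no row.
#'
#' @param map 3D array or [volume_image()] on the label grid.
#' @param regions A [region_set()].
#' @param animal_id,genotype,age_group,map_name Metadata attached to rows.
#' @param statistic `"mean"` or `"median"`.
#' @param min_voxels Minimum valid voxels before a region is flagged.
#' @param include Region names to summarize (default: the six gray-matter
#'   ROIs, artery excluded).
#' @return A data.frame with one row per region: `animal_id`, `genotype`,
#'   `age_group`, `region`, `map`, `value`, `n_voxels`, `flagged`.
#' @export
summarize_regions <- function(map, regions, animal_id = "a1",
                              genotype = "control", age_group = "24mo",
                              map_name = "map",
                              statistic = c("mean", "median"),
                              min_voxels = 10, include = REGION_NAMES) {
  statistic <- match.arg(statistic)
  if (inherits(map, "volume_image")) map <- map$values
  if (!identical(dim(map), dim(regions$labels)))
    stop("map and region labels must share one grid")
  stat_fn <- if (statistic == "mean") mean else stats::median
  rows <- lapply(include, function(r) {
    lab <- regions$names[[r]]
    if (is.null(lab)) stop("unknown region: ", r)
    vals <- map[regions$labels == lab]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0) {
      warning("region ", r, " has no valid voxels; row omitted")
      return(NULL)
    }
    data.frame(animal_id = animal_id, genotype = genotype,
               age_group = age_group, region = r, map = map_name,
               value = stat_fn(vals), n_voxels = length(vals),
               flagged = length(vals) < min_voxels)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Percent change between group means
#'
#' `100 * (mean(tg) - mean(ctrl)) / mean(ctrl)`.
#'
#' @param ctrl,tg Numeric vectors of per-animal values.
#' @return Percent change (positive = higher in `tg`).
#' @export
percent_change <- function(ctrl, tg) {
  if (length(ctrl) == 0 || length(tg) == 0) stop("both groups must be nonempty")
  m <- mean(ctrl)
  if (m == 0) stop("control mean is zero; percent change undefined")
  100 * (mean(tg) - m) / m
}

#' Two-group permutation test on the difference of means
#'
#' Two-sided permutation p-value
#' `p = (1 + #\{|D_perm| >= |D_obs|\}) / (1 + n_perm)` over random
#' relabelings of group membership. Seeded and reproducible.
#'
#' @param ctrl,tg Per-animal values for the two groups.
#' @param n_perm Number of permutations (>= 1000).
#' @param seed RNG seed, or `NULL` to use the current stream.
#' @return A `group_contrast` list: `percent_change`, `p_perm`, `n_ctrl`,
#'   `n_tg`, `mean_ctrl`, `mean_tg`.
#' @export
permutation_contrast <- function(ctrl, tg, n_perm = 2000, seed = NULL) {
  if (length(ctrl) + length(tg) < 4) stop("need at least 4 animals in total")
  if (n_perm < 1000) stop("n_perm must be >= 1000")
  if (!is.null(seed)) set.seed(seed)
  pooled <- c(ctrl, tg)
  n1 <- length(ctrl)
  obs <- mean(tg) - mean(ctrl)
  if (all(pooled == pooled[1])) {
    p <- 1
  } else {
    total <- sum(pooled)
    perm_stats <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), n1)
      s1 <- sum(pooled[idx])
      (total - s1) / (length(pooled) - n1) - s1 / n1
    }, numeric(1))
    p <- (1 + sum(abs(perm_stats) >= abs(obs) - 1e-12)) / (1 + n_perm)
  }
  structure(list(percent_change = percent_change(ctrl, tg), p_perm = p,
                 n_ctrl = length(ctrl), n_tg = length(tg),
                 mean_ctrl = mean(ctrl), mean_tg = mean(tg)),
            class = "group_contrast")
}

#' Genotype contrast report from region summaries
#'
#' One row per age group x region x map: group means, percent change and
#' permutation p-value. Rows needing a missing group are omitted with a
#' warning.
#'
#' @param summaries Data.frame of [summarize_regions()] rows over all
#'   animals.
#' @param n_perm,seed Passed to [permutation_contrast()].
#' @return Data.frame with columns `age_group`, `region`, `map`, `n_ctrl`,
#'   `n_tg`, `mean_ctrl`, `mean_tg`, `percent_change`, `p_perm`.
#' @export
build_report <- function(summaries, n_perm = 2000, seed = NULL) {
  cols <- c("age_group", "region", "map", "n_ctrl", "n_tg",
            "mean_ctrl", "mean_tg", "percent_change", "p_perm")
  empty <- stats::setNames(
    data.frame(matrix(ncol = length(cols), nrow = 0)), cols)
  if (is.null(summaries) || nrow(summaries) == 0) return(empty)
  if (!is.null(seed)) set.seed(seed)
  groups <- unique(summaries[c("age_group", "region", "map")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- summaries[summaries$age_group == g$age_group &
                       summaries$region == g$region &
                       summaries$map == g$map, ]
    ctrl <- sub$value[sub$genotype == "control"]
    tg <- sub$value[sub$genotype == "transgenic"]
    if (length(ctrl) < 2 || length(tg) < 2) {
      warning("age ", g$age_group, " region ", g$region, " map ", g$map,
              ": a genotype group is missing; row omitted")
      return(NULL)
    }
    ct <- permutation_contrast(ctrl, tg, n_perm = n_perm, seed = NULL)
    data.frame(age_group = g$age_group, region = g$region, map = g$map,
               n_ctrl = ct$n_ctrl, n_tg = ct$n_tg,
               mean_ctrl = ct$mean_ctrl, mean_tg = ct$mean_tg,
               percent_change = ct$percent_change, p_perm = ct$p_perm)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Analyze a synthetic cohort end to end
#'
#' Runs the steady-state mapping pathway ([process_qmap()]) and/or the DSC
#' perfusion pathway ([process_dsc()]) for every animal of a
#' [make_cohort()] cohort and returns the tidy per-animal region summary
#' table for the maps `q`, `n_density`, `rcbv_ss`, `rcbv_dsc`, `rcbf`.
#'
#' @param cohort A [make_cohort()] result.
#' @param modalities Which pathways to run (defaults to those present).
#' @param r_trunc,aif_m,aif_candidates,statistic Processing options.
#' @return Data.frame of region summaries (one row per animal x region x
#'   map).
#' @export
analyze_cohort <- function(cohort, modalities = NULL, r_trunc = 0.2,
                           aif_m = 10, aif_candidates = NULL,
                           statistic = "mean") {
  spec <- cohort$spec
  modalities <- modalities %||% spec$modalities
  out <- list()
  for (an in cohort$animals) {
    if ("steady_state" %in% modalities && !is.null(an$steady)) {
      maps <- process_qmap(an$steady$ge_pre, an$steady$ge_post,
                           an$steady$se_pre, an$steady$se_post)
      for (mn in c("q", "n_density", "rcbv_ss"))
        out[[length(out) + 1L]] <- summarize_regions(
          maps[[mn]], cohort$phantom, animal_id = an$id,
          genotype = an$genotype, age_group = spec$age_group,
          map_name = mn, statistic = statistic)
    }
    if ("dsc" %in% modalities && !is.null(an$dsc)) {
      pm <- process_dsc(an$dsc, r_trunc = r_trunc, aif_m = aif_m,
                        aif_candidates = aif_candidates)
      for (mn in c("rcbv", "rcbf"))
        out[[length(out) + 1L]] <- summarize_regions(
          pm[[mn]], cohort$phantom, animal_id = an$id,
          genotype = an$genotype, age_group = spec$age_group,
          map_name = if (mn == "rcbv") "rcbv_dsc" else mn,
          statistic = statistic)
    }
  }
  do.call(rbind, out)
}
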