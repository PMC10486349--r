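#' Hit rate by target size
#'
#' `hits / (hits + failures)` per size value; ignored trials are excluded
#' from the denominator by default (an ignored trial carries no touch), a
#' behavior switchable via `include_ignored`. Sizes with no qualifying
#' trials are missing, not zero.
#'
#' @param records Trial records of one task (e.g. the static task).
#' @param sizes Size grid to report over.
#' @param include_ignored Count ignored trials in the denominator.
#' @return Named numeric vector (names = sizes); `NA` for empty cells.
#' @export
hit_rate_by_size <- function(records, sizes = 5:10, include_ignored = FALSE) {
  out <- stats::setNames(rep(NA_real_, length(sizes)), sizes)
  keep <- if (include_ignored) records$outcome %in% c("hit", "failure", "ignored")
          else records$outcome %in% c("hit", "failure")
  records <- records[keep, , drop = FALSE]
  for (d in sizes) {
    sub <- records[records$target_size_deg == d, , drop = FALSE]
    if (nrow(sub) > 0)
      out[as.character(d)] <- mean(sub$outcome == "hit")
  }
  out
}

#' Chance-adjusted hit rate
#'
#' Subtracts the size-dependent chance level from the hit rate, giving a
#' performance measure comparable across target sizes (0 = chance).
#'
#' @param hit_rate Hit rate(s) in `[0, 1]`.
#' @param d Target diameter(s), degrees.
#' @param geometry An [screen_geometry()] object (used when no table given).
#' @param table Optional per-size chance table (see [xbi_chance_table()]).
#' @return `hit_rate - chance_level(d)`.
#' @export
adjusted_hit_rate <- function(hit_rate, d, geometry = screen_geometry(),
                              table = NULL) {
  hit_rate - chance_level(d, geometry, table)
}

#' Pearson correlation between speed and adjusted hit rate
#'
#' For one animal: correlates the speed values with that animal's mean
#' adjusted hit rate at each speed, with the 95% confidence interval from
#' the Fisher z-transform and a two-sided p-value. Cells with fewer than 3
#' speed values with data, or zero variance, are flagged as insufficient.
#'
#' @param speeds Speed values (deg/s).
#' @param adj_rates Mean adjusted hit rate at each speed.
#' @param alpha Per-test significance threshold (Bonferroni-adjusted
#'   family-wise level; see [bonferroni_alpha()]).
#' @return List with `r`, `ci` (length-2), `p`, `n`, `significant`,
#'   `insufficient`.
#' @export
speed_correlation <- function(speeds, adj_rates, alpha = 0.003) {
  ok <- !is.na(adj_rates)
  speeds <- speeds[ok]; adj_rates <- adj_rates[ok]
  n <- length(speeds)
  if (n < 3 || stats::sd(adj_rates) == 0 || stats::sd(speeds) == 0) {
    return(list(r = NA_real_, ci = c(NA_real_, NA_real_), p = NA_real_,
                n = n, significant = FALSE, insufficient = TRUE))
  }
  ct <- stats::cor.test(speeds, adj_rates, method = "pearson",
                        conf.level = 0.95)
  r <- unname(ct$estimate)
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int)
        else c(NA_real_, NA_real_)
  list(r = r, ci = ci, p = ct$p.value, n = n,
       significant = is.finite(ct$p.value) && ct$p.value < alpha,
       insufficient = FALSE)
}

#' Bonferroni-adjusted per-test alpha
#'
#' Family-wise level divided by the number of animals analyzed (one
#' correlation test per animal).
#'
#' @param n_animals Number of animals in the analysis family.
#' @param family_alpha Family-wise error rate.
#' @return Per-test alpha.
#' @export
bonferroni_alpha <- function(n_animals, family_alpha = 0.05) {
  stopifnot(n_animals >= 1)
  family_alpha / n_animals
}

#' Mean adjusted hit rate per size-speed cell
#'
#' Aggregates dynamic-task records into a size x speed grid of mean
#' adjusted hit rates; cells with fewer than `min_trials` scored trials
#' are masked (`NA`). Trial counts are returned alongside.
#'
#' @param records Dynamic-task trial records.
#' @param sizes,speeds Grid values.
#' @param geometry,table Chance source, as in [adjusted_hit_rate()].
#' @param min_trials Minimum scored trials per cell.
#' @param include_ignored Count ignored trials in the denominator.
#' @return List with matrices `adj_rate` and `n` (rows = sizes,
#'   cols = speeds).
#' @export
size_speed_heatmap <- function(records, sizes = 5:10, speeds = 10:30,
                               geometry = screen_geometry(), table = NULL,
                               min_trials = 5, include_ignored = FALSE) {
  keep <- if (include_ignored) records$outcome %in% c("hit", "failure", "ignored")
          else records$outcome %in% c("hit", "failure")
  records <- records[keep, , drop = FALSE]
  adj <- matrix(NA_real_, length(sizes), length(speeds),
                dimnames = list(sizes, speeds))
  n <- matrix(0L, length(sizes), length(speeds),
              dimnames = list(sizes, speeds))
  for (i in seq_along(sizes)) {
    ch <- chance_level(sizes[i], geometry, table)
    for (j in seq_along(speeds)) {
      sub <- records[records$target_size_deg == sizes[i] &
                     records$target_speed_deg_s == speeds[j], , drop = FALSE]
      n[i, j] <- nrow(sub)
      if (nrow(sub) >= min_trials)
        adj[i, j] <- mean(sub$outcome == "hit") - ch
    }
  }
  list(adj_rate = adj, n = n)
}

#' Best size-speed combination
#'
#' The unmasked heatmap cell with the highest adjusted hit rate; ties are
#' broken toward the smaller size, then the smaller speed.
#'
#' @param heatmap Output of [size_speed_heatmap()].
#' @return List with `size`, `speed`, `adj_rate`; or `NULL` when all cells
#'   are masked.
#' @export
best_combo <- function(heatmap) {
  adj <- heatmap$adj_rate
  if (all(is.na(adj))) return(NULL)
  best <- max(adj, na.rm = TRUE)
  hits <- which(adj == best, arr.ind = TRUE)
  # row/col order in `which` already scans rows fastest; sort explicitly
  hits <- hits[order(hits[, "row"], hits[, "col"]), , drop = FALSE]
  list(size = as.integer(rownames(adj)[hits[1, "row"]]),
       speed = as.integer(colnames(adj)[hits[1, "col"]]),
       adj_rate = best)
}

#' Per-animal proficiency analysis of a trial log
#'
#' For each animal: the static-task hit rate by size; the dynamic-task
#' mean adjusted hit rate at each speed (per-size adjusted rates averaged
#' with trial-count weights); the Pearson correlation between speed and
#' adjusted hit rate at the Bonferroni-adjusted threshold (family size =
#' number of animals analyzed); the size x speed heatmap and its best
#' cell. Animals whose speed curve has under 3 informative speed values
#' are flagged `insufficient`.
#'
#' @param log Trial-log data frame (labeled).
#' @param geometry,table Chance source, as in [adjusted_hit_rate()].
#' @param min_trials Minimum scored trials per heatmap cell.
#' @param min_trials_speed Minimum scored trials for a per-speed mean.
#' @param family_alpha Family-wise error rate for the correlation tests.
#' @param include_ignored Count ignored trials in hit-rate denominators.
#' @return Object of class `mci_proficiency`: list with `animals` (data
#'   frame, one row per animal), `static_by_size`, `speed_curves`,
#'   `heatmaps` (per-animal lists), `pooled_heatmap`, and `alpha`.
#' @export
analyze_proficiency <- function(log, geometry = screen_geometry(),
                                table = NULL, min_trials = 5,
                                min_trials_speed = 5,
                                family_alpha = 0.05,
                                include_ignored = FALSE) {
  log <- log[!is.na(log$animal_id), , drop = FALSE]
  animals <- sort(unique(log$animal_id))
  alpha <- bonferroni_alpha(length(animals), family_alpha)
  sizes <- sort(unique(stats::na.omit(log$target_size_deg)))
  speeds <- sort(unique(log$target_speed_deg_s[log$chosen_task == "dynamic" &
                                               !is.na(log$target_speed_deg_s)]))
  if (length(sizes) == 0) sizes <- 5:10
  if (length(speeds) == 0) speeds <- 10:30
  static_by_size <- list(); speed_curves <- list(); heatmaps <- list()
  rows <- list()
  for (a in animals) {
    da <- log[log$animal_id == a, , drop = FALSE]
    stat <- da[da$chosen_task == "static", , drop = FALSE]
    dyn <- da[da$chosen_task == "dynamic", , drop = FALSE]
    static_by_size[[a]] <- hit_rate_by_size(stat, sizes, include_ignored)
    hm <- size_speed_heatmap(dyn, sizes, speeds, geometry, table,
                             min_trials, include_ignored)
    heatmaps[[a]] <- hm
    curve <- speed_adjusted_curve(dyn, sizes, speeds, geometry, table,
                                  min_trials_speed, include_ignored)
    speed_curves[[a]] <- curve
    sc <- speed_correlation(speeds, curve$adj_rate, alpha)
    bc <- best_combo(hm)
    rows[[a]] <- data.frame(
      animal_id = a,
      n_static = sum(stat$outcome %in% c("hit", "failure")),
      n_dynamic = sum(dyn$outcome %in% c("hit", "failure")),
      speed_r = sc$r, speed_ci_lo = sc$ci[1], speed_ci_hi = sc$ci[2],
      speed_p = sc$p, n_speed_values = sc$n,
      significant = sc$significant, insufficient = sc$insufficient,
      best_size = if (is.null(bc)) NA_integer_ else bc$size,
      best_speed = if (is.null(bc)) NA_integer_ else bc$speed,
      stringsAsFactors = FALSE)
  }
  pooled <- size_speed_heatmap(log[log$chosen_task == "dynamic", , drop = FALSE],
                               sizes, speeds, geometry, table,
                               min_trials, include_ignored)
  out <- list(animals = do.call(rbind, c(rows, list(make.row.names = FALSE))),
              static_by_size = static_by_size,
              speed_curves = speed_curves, heatmaps = heatmaps,
              pooled_heatmap = pooled, alpha = alpha,
              sizes = sizes, speeds = speeds)
  class(out) <- "mci_proficiency"
  out
}

#' Per-speed mean adjusted hit rate
#'
#' For each speed value, the per-size adjusted hit rates are averaged with
#' trial-count weights, giving the speed curve the correlation stage
#' consumes. Speeds with fewer than `min_trials_speed` scored trials are
#' missing.
#'
#' @param dyn Dynamic-task trial records.
#' @param sizes,speeds Grid values.
#' @param geometry,table Chance source, as in [adjusted_hit_rate()].
#' @param min_trials_speed Minimum scored trials per speed.
#' @param include_ignored Count ignored trials in the denominator.
#' @return List with `speed`, `adj_rate` (named numeric) and `n` (trial
#'   counts).
#' @export
speed_adjusted_curve <- function(dyn, sizes = 5:10, speeds = 10:30,
                                 geometry = screen_geometry(), table = NULL,
                                 min_trials_speed = 5,
                                 include_ignored = FALSE) {
  keep <- if (include_ignored) dyn$outcome %in% c("hit", "failure", "ignored")
          else dyn$outcome %in% c("hit", "failure")
  dyn <- dyn[keep, , drop = FALSE]
  adj <- stats::setNames(rep(NA_real_, length(speeds)), speeds)
  n <- stats::setNames(integer(length(speeds)), speeds)
  for (j in seq_along(speeds)) {
    sub <- dyn[dyn$target_speed_deg_s == speeds[j], , drop = FALSE]
    n[j] <- nrow(sub)
    if (nrow(sub) < min_trials_speed) next
    per_size <- vapply(unique(sub$target_size_deg), function(d) {
      cell <- sub[sub$target_size_deg == d, , drop = FALSE]
      c(adj = mean(cell$outcome == "hit") - chance_level(d, geometry, table),
        w = nrow(cell))
    }, c(adj = 0, w = 0))
    adj[j] <- sum(per_size["adj", ] * per_size["w", ]) / sum(per_size["w", ])
  }
  list(speed = speeds, adj_rate = adj, n = n)
}

#' @method print mci_proficiency
#' @export
print.mci_proficiency <- function(x, ...) {
  cat("Proficiency summary\n")
  cat(sprintf("  %d animals, per-test alpha %.4g (Bonferroni)\n",
              nrow(x$animals), x$alpha))
  cat(sprintf("  significant speed modulation: %d; insufficient data: %d\n",
              sum(x$animals$significant, na.rm = TRUE),
              sum(x$animals$insufficient)))
  bc <- best_combo(x$pooled_heatmap)
  if (!is.null(bc))
    cat(sprintf("  pooled best cell: size %d deg at %d deg/s (adj. rate %.3f)\n",
                bc$size, bc$speed, bc$adj_rate))
  invisible(x)
}
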