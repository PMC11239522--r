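# ---- group statistics over region tables ----------------------------------
#
# Group-wise comparison of per-region cell densities: two-sided unpaired
# t-tests per region (Welch by default) with Benjamini-Hochberg correction
# at q = 0.1 applied within each structure level, fiber tracts excluded.

#' Group design
#'
#' @param samples data.frame with columns sample_id, group.
#' @return A `group_design`.
#' @export
group_design <- function(samples) {
  stopifnot(all(c("sample_id", "group") %in% names(samples)))
  if (anyDuplicated(samples$sample_id))
    stop("every sample must appear in exactly one group")
  if (length(unique(samples$group)) < 2)
    stop("need at least two groups")
  structure(list(samples = as.data.frame(samples)), class = "group_design")
}

#' Sample-by-region density matrix at a structure level
#'
#' Aggregates every sample's region table to `level`, drops fiber-tract
#' regions (they are excluded from neuronal statistics, but their cells
#' still count toward each sample's total for normalization) and returns
#' densities.
#'
#' @param tables named list of region tables (names = sample ids), all from
#'   the same ontology.
#' @param ont the shared [ontology()].
#' @param level structure level to aggregate to.
#' @param normalization "per_mm3" (cells per region volume) or
#'   "per_mm3_per_total" (additionally divided by the sample's total
#'   detected cells).
#' @return numeric matrix, rows = samples, columns = region ids at
#'   `level`.
#' @export
density_matrix <- function(tables, ont, level,
                           normalization = c("per_mm3",
                                             "per_mm3_per_total")) {
  normalization <- match.arg(normalization)
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list (sample ids)")
  rows <- lapply(names(tables), function(sid) {
    tab <- tables[[sid]]
    total <- sum(tab$n_cells)   # includes fiber tracts and unassigned
    agg <- aggregate_to_level(tab, ont, level)
    agg <- agg[agg$region_id != 0, , drop = FALSE]
    fib <- ontology_is_fiber(ont, agg$region_id)
    agg <- agg[!fib, , drop = FALSE]
    dens <- agg$density_cells_per_mm3
    if (normalization == "per_mm3_per_total")
      dens <- dens / max(total, 1)
    stats::setNames(dens, agg$region_id)
  })
  ids <- sort(unique(as.integer(unlist(lapply(rows, names)))))
  m <- matrix(0, nrow = length(tables), ncol = length(ids),
              dimnames = list(names(tables), as.character(ids)))
  for (i in seq_along(rows)) m[i, names(rows[[i]])] <- rows[[i]]
  m
}

# Welch (or pooled) two-sided t-test that tolerates zero variance
safe_t_test <- function(a, b, pooled = FALSE) {
  if (stats::sd(c(a, b)) < .Machine$double.eps * max(1, abs(mean(c(a, b))))) {
    return(list(statistic = 0, p.value = 1))
  }
  tryCatch({
    ht <- stats::t.test(a, b, var.equal = pooled)
    list(statistic = unname(ht$statistic), p.value = ht$p.value)
  }, error = function(e) {
    # essentially-constant groups with different means: call it separated
    if (abs(mean(a) - mean(b)) > 0) list(statistic = Inf, p.value = 0)
    else list(statistic = 0, p.value = 1)
  })
}

#' Compare two groups region by region
#'
#' Per-region two-sided unpaired t-test (Welch by default) on densities,
#' log2 fold change of group means (means are floored at a pseudo-density
#' of half the smallest nonzero entry of the matrix, so empty regions stay
#' finite while nonzero ratios are exact), and Benjamini-Hochberg
#' adjustment across the tested regions.
#'
#' @param matrix sample-by-region density matrix from [density_matrix()].
#' @param design a [group_design()].
#' @param group_a,group_b group labels; fold change is a over b.
#' @param alpha adjusted-p significance threshold (default 0.1).
#' @param pooled use the pooled-variance Student test instead of Welch.
#' @return data.frame: region_id, mean_a, mean_b, log2_fold_change,
#'   t_statistic, p_value, p_adjusted, significant.
#' @export
compare_groups <- function(matrix, design, group_a, group_b, alpha = 0.1,
                           pooled = FALSE) {
  stopifnot(inherits(design, "group_design"))
  ds <- design$samples
  if (!all(c(group_a, group_b) %in% ds$group))
    stop("group not present in the design")
  sa <- intersect(rownames(matrix), ds$sample_id[ds$group == group_a])
  sb <- intersect(rownames(matrix), ds$sample_id[ds$group == group_b])
  if (length(sa) < 2 || length(sb) < 2)
    stop("both groups need >= 2 samples with tables")
  nz <- matrix[matrix > 0]
  eps <- if (length(nz)) min(nz) / 2 else 1
  out <- lapply(colnames(matrix), function(rid) {
    a <- matrix[sa, rid]; b <- matrix[sb, rid]
    ht <- safe_t_test(a, b, pooled)
    data.frame(region_id = as.integer(rid),
               mean_a = mean(a), mean_b = mean(b),
               log2_fold_change = log2(max(mean(a), eps) /
                                         max(mean(b), eps)),
               t_statistic = ht$statistic, p_value = ht$p.value)
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out
}

#' Level-aware group comparison sweep
#'
#' Runs [compare_groups()] at each requested structure level, applying the
#' BH correction within each level independently, and returns one long
#' table tagged by level.
#'
#' @param tables named list of per-sample region tables.
#' @param ont shared [ontology()].
#' @param design a [group_design()].
#' @param group_a,group_b group labels.
#' @param levels integer vector of structure levels (default: all in the
#'   ontology).
#' @param alpha significance threshold on adjusted p (default 0.1).
#' @param normalization passed to [density_matrix()].
#' @return data.frame with a `level` column prepended.
#' @export
level_sweep <- function(tables, ont, design, group_a, group_b,
                        levels = NULL, alpha = 0.1,
                        normalization = "per_mm3") {
  levels <- levels %||% seq_len(max(ont$nodes$level))
  if (any(levels < 1 | levels > max(ont$nodes$level)))
    stop("levels outside the ontology's depth")
  res <- lapply(levels, function(lv) {
    m <- density_matrix(tables, ont, lv, normalization)
    cmp <- compare_groups(m, design, group_a, group_b, alpha)
    cbind(level = lv, cmp)
  })
  do.call(rbind, res)
}
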