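# ranks with ties sharing a rank ("min" convention); optional secondary key
rank_stat <- function(primary, secondary = NULL) {
  if (is.null(secondary)) return(rank(primary, ties.method = "min"))
  ord <- order(primary, secondary)
  key <- paste(primary, secondary)
  ranks <- integer(length(primary))
  pos <- 1L
  for (i in seq_along(ord)) {
    if (i > 1 && key[ord[i]] != key[ord[i - 1]]) pos <- i
    ranks[ord[i]] <- pos
  }
  ranks
}

#' Delta-CT stability statistic
#'
#' For every ordered gene pair (i, j) the per-sample CT difference
#' dCT_ij(s) = CT_i(s) - CT_j(s) is formed; a gene's statistic is the mean,
#' over all partner genes j, of the sample SD of dCT_ij across samples.
#' Genes whose CT tracks every other gene (stable expression) have low
#' values; the statistic is in cycles. Technical replicates are collapsed
#' to their mean CT first.
#'
#' @param ds A single-group CT dataset (long tibble).
#' @return A tibble `gene_id`, `method` ("deltaCT"), `statistic` (cycles),
#'   `rank` (1 = most stable, ties share a rank).
#' @examples
#' ds <- tidyr::crossing(gene_id = c("a", "b", "c"), sample = paste0("s", 1:4))
#' ds$replicate <- 1L
#' ds$ct <- c(20, 21, 22, 23, 20, 21, 22, 23, 20, 23, 20, 23)
#' delta_ct_stability(ds)
#' @export
delta_ct_stability <- function(ds) {
  m <- ct_matrix(ds)
  g <- nrow(m); n <- ncol(m)
  if (g < 2) abort("delta-CT needs at least 2 genes")
  if (n < 2) abort("delta-CT needs at least 2 samples (SD undefined)")
  stat <- vapply(seq_len(g), function(i) {
    mean(vapply(setdiff(seq_len(g), i),
                function(j) sd(m[i, ] - m[j, ]), numeric(1)))
  }, numeric(1))
  tibble(gene_id = rownames(m), method = "deltaCT", statistic = stat,
         rank = rank_stat(stat))
}

#' Per-gene CT summary by priming group
#'
#' Mean and sample SD of the raw CT values (all samples and replicates)
#' per gene and group. When the dataset holds exactly two groups (e.g.
#' oligo-dT vs random priming), the per-gene between-group difference of
#' mean CT is attached as attribute `"group_diff"` — small absolute
#' differences indicate genes robust to priming chemistry.
#'
#' @param ds A CT dataset (one or more groups; replicates allowed).
#' @return A tibble `gene_id`, `group`, `mean_ct`, `sd_ct`, `n`; attribute
#'   `group_diff` (tibble `gene_id`, `mean_diff`) when two groups are
#'   present.
#' @export
ct_summary <- function(ds) {
  ds <- as_tibble(ds)
  if (!"group" %in% names(ds)) ds$group <- "all"
  out <- ds |>
    group_by(.data$gene_id, .data$group) |>
    summarise(mean_ct = mean(.data$ct),
              sd_ct = if (dplyr::n() > 1) sd(.data$ct) else NA_real_,
              n = dplyr::n(), .groups = "drop")
  groups <- sort(unique(out$group))
  if (length(groups) == 2) {
    wide <- tidyr::pivot_wider(out[, c("gene_id", "group", "mean_ct")],
                               names_from = "group", values_from = "mean_ct")
    diff <- tibble(gene_id = wide$gene_id,
                   mean_diff = wide[[groups[1]]] - wide[[groups[2]]])
    attr(out, "group_diff") <- diff
  }
  out
}

#' Rank candidate stability with all methods and aggregate
#'
#' Runs the delta-CT, geNorm, BestKeeper and NormFinder statistics on a CT
#' dataset — separately per priming group when more than one group is
#' present — and aggregates them per group into a consensus: the geometric
#' mean of a gene's four per-method ranks, re-ranked ascending (ties share
#' a rank). A method whose preconditions the dataset does not meet is
#' omitted with a warning and the aggregate covers the remaining methods.
#'
#' @param ds A CT dataset (one or more groups).
#' @param config A [pipeline_config()]; supplies the quantification base
#'   for geNorm.
#' @param methods Character subset of
#'   `c("deltaCT", "geNorm", "BestKeeper", "NormFinder")`.
#' @return An object of class `stability_ranking`: list with `scores`
#'   (tibble `group`, `gene_id`, `method`, `statistic`, `rank`),
#'   `aggregate` (tibble `group`, `gene_id`, `geo_mean_rank`, `rank`),
#'   `genorm` / `bestkeeper` / `normfinder` (per-group result objects) and
#'   `methods` (those that ran).
#' @examples
#' sim <- simulate_rpkm(generator_config(n_stable = 2, n_variable = 4,
#'                                       seed = 7))
#' ct <- simulate_ct(sim$matrix, sim$truth, generator_config(seed = 7))
#' rk <- rank_stability(ct)
#' rk$aggregate
#' @export
rank_stability <- function(ds, config = pipeline_config(),
                           methods = c("deltaCT", "geNorm", "BestKeeper",
                                       "NormFinder")) {
  ds <- as_tibble(ds)
  if (!"group" %in% names(ds)) ds$group <- "all"
  methods <- match.arg(methods, several.ok = TRUE)
  runners <- list(
    deltaCT = function(d) delta_ct_stability(d)[, c("gene_id", "statistic", "rank")],
    geNorm = function(d) {
      r <- genorm(d, base = config$efficiency_base)
      r$m_values[, c("gene_id", "statistic", "rank")]
    },
    BestKeeper = function(d) {
      r <- bestkeeper(d)
      r$gene_stats[, c("gene_id", "statistic", "rank")]
    },
    NormFinder = function(d) {
      r <- normfinder(d)
      r$gene_stats[, c("gene_id", "statistic", "rank")]
    }
  )
  details <- list(genorm = list(), bestkeeper = list(), normfinder = list())
  scores <- list()
  for (grp in unique(ds$group)) {
    sub <- ds[ds$group == grp, ]
    for (meth in methods) {
      res <- tryCatch(runners[[meth]](sub), error = function(e) {
        warn(sprintf("method %s omitted for group '%s': %s",
                     meth, grp, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) next
      scores[[length(scores) + 1]] <-
        mutate(res, group = grp, method = meth, .before = 1)
      if (meth == "geNorm") {
        details$genorm[[grp]] <- genorm(sub, base = config$efficiency_base)
      }
      if (meth == "BestKeeper") details$bestkeeper[[grp]] <- bestkeeper(sub)
      if (meth == "NormFinder") details$normfinder[[grp]] <- normfinder(sub)
    }
  }
  if (!length(scores)) abort("no stability method could run on this dataset")
  scores <- bind_rows(scores)
  aggregate <- scores |>
    group_by(.data$group, .data$gene_id) |>
    summarise(geo_mean_rank = exp(mean(log(.data$rank))),
              n_methods = dplyr::n(), .groups = "drop") |>
    group_by(.data$group) |>
    mutate(rank = rank_stat(.data$geo_mean_rank)) |>
    ungroup() |>
    arrange(.data$group, .data$rank)
  structure(
    list(scores = scores, aggregate = aggregate,
         genorm = details$genorm, bestkeeper = details$bestkeeper,
         normfinder = details$normfinder,
         methods = unique(scores$method)),
    class = "stability_ranking"
  )
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("Stability ranking (", paste(x$methods, collapse = ", "), ")\n", sep = "")
  for (grp in unique(x$aggregate$group)) {
    sub <- x$aggregate[x$aggregate$group == grp, ]
    cat(sprintf("group %s: %s\n", grp,
                paste(sprintf("%s (%d)", sub$gene_id, sub$rank),
                      collapse = ", ")))
  }
  invisible(x)
}
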