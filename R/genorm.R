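#' geNorm expression-stability M value and pairwise variation
#'
#' CT values are converted to relative quantities
#' `q_i(s) = base^(min_s CT_i - CT_i(s))` (each gene calibrated to its own
#' lowest-CT sample; any per-gene affine calibrator gives identical
#' results). A gene's M value is the mean, over all other genes j, of the
#' SD across samples of `log_base(q_i / q_j)`; low M means the gene keeps
#' a constant ratio to its partners. The gene with the highest M is
#' removed and M recomputed until two genes remain — the most stable pair,
#' which by construction cannot be resolved further and shares rank 1.
#'
#' The pairwise-variation series V_n/n+1 compares normalization factors
#' (per-sample geometric means of quantities) built from the n vs n + 1
#' most stable genes, genes added in stability order:
#' `V_n = SD_s(log_base(NF_n(s) / NF_{n+1}(s)))`. A small V_n indicates
#' that adding the (n+1)-th reference changes the normalization little.
#'
#' @param ds A single-group CT dataset with at least 3 genes.
#' @param base Quantification base (2 = perfect doubling per cycle).
#' @return An object of class `genorm_result`: list with
#'   * `m_values`: tibble `gene_id`, `method`, `statistic` (the gene's M
#'     at its exclusion step; the final pair carries the common two-gene
#'     M), `rank` (pair shares rank 1, next gene rank 3);
#'   * `full_m`: tibble of full-set M values before any exclusion;
#'   * `exclusion_order`: gene ids in removal order (least stable first);
#'   * `stable_pair`: the final two gene ids;
#'   * `v`: tibble `n`, `v` for n = 2 .. g - 1;
#'   * `base`.
#' @examples
#' ds <- tidyr::crossing(gene_id = c("a", "b", "c"), sample = paste0("s", 1:4))
#' ds$replicate <- 1L
#' ds$ct <- c(20, 21, 22, 23, 20, 21, 22, 23, 20, 23, 20, 23)
#' genorm(ds)$stable_pair
#' @export
genorm <- function(ds, base = 2) {
  m <- ct_matrix(ds)
  g <- nrow(m); n <- ncol(m)
  if (g < 3) abort("geNorm needs at least 3 genes to start stepwise exclusion")
  if (n < 2) abort("geNorm needs at least 2 samples")
  # log-base quantities; q = base^(minCT - CT) so log_base(q) = minCT - CT
  logq <- sweep(-m, 1, apply(m, 1, min), `+`)

  m_of <- function(rows) {
    vapply(rows, function(i) {
      mean(vapply(setdiff(rows, i),
                  function(j) sd(logq[i, ] - logq[j, ]), numeric(1)))
    }, numeric(1)) |> setNames(rownames(m)[rows])
  }

  full_m <- m_of(seq_len(g))
  remaining <- seq_len(g)
  exclusion <- character(0)
  m_at_exclusion <- numeric(0)
  while (length(remaining) > 2) {
    mv <- m_of(remaining)
    worst <- names(mv)[mv == max(mv)]
    # tie on the highest M: exclude the lexicographically last gene id
    worst <- sort(worst)[length(worst)]
    m_at_exclusion[worst] <- mv[[worst]]
    exclusion <- c(exclusion, worst)
    remaining <- setdiff(remaining, which(rownames(m) == worst))
  }
  pair <- rownames(m)[remaining]
  pair_m <- sd(logq[remaining[1], ] - logq[remaining[2], ])
  stability_order <- c(sort(pair), rev(exclusion))

  stat <- c(setNames(rep(pair_m, 2), sort(pair)), rev(m_at_exclusion))
  ranks <- c(1L, 1L, seq.int(3L, length.out = length(exclusion)))
  m_values <- tibble(gene_id = stability_order, method = "geNorm",
                     statistic = unname(stat[stability_order]),
                     rank = ranks)

  # V_n/n+1 on normalization factors, genes added in stability order
  idx <- match(stability_order, rownames(m))
  v <- tibble(n = integer(0), v = numeric(0))
  if (g >= 3) {
    vn <- vapply(2:(g - 1), function(k) {
      nf_k <- colMeans(logq[idx[1:k], , drop = FALSE])
      nf_k1 <- colMeans(logq[idx[1:(k + 1)], , drop = FALSE])
      sd(nf_k - nf_k1)
    }, numeric(1))
    v <- tibble(n = 2:(g - 1), v = vn)
  }

  structure(
    list(m_values = m_values, full_m = tibble(gene_id = rownames(m),
                                              m = unname(full_m)),
         exclusion_order = exclusion, stable_pair = sort(pair),
         v = v, base = base),
    class = "genorm_result"
  )
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability (base", x$base, ")\n")
  cat("most stable pair:", paste(x$stable_pair, collapse = " / "), "\n")
  print(x$m_values, n = Inf)
  invisible(x)
}
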