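# Independent brute-force implementations used as oracles. They work on a
# plain genes x samples CT matrix and deliberately share no code with the
# package (direct formula enumeration with loops).

# long CT tibble from a genes x samples matrix (replicate depth 1)
ct_tbl <- function(m, group = "all") {
  tidyr::crossing(gene_id = rownames(m), sample = colnames(m)) |>
    dplyr::mutate(replicate = 1L,
                  ct = mapply(function(g, s) m[g, s], gene_id, sample),
                  group = group) |>
    dplyr::arrange(match(gene_id, rownames(m)))
}

rand_ct_matrix <- function(g, n, lo = 18, hi = 30) {
  m <- matrix(runif(g * n, lo, hi), g, n,
              dimnames = list(paste0("g", seq_len(g)),
                              paste0("s", seq_len(n))))
  m
}

oracle_delta_ct <- function(m) {
  g <- nrow(m)
  out <- numeric(g)
  for (i in seq_len(g)) {
    sds <- c()
    for (j in seq_len(g)) {
      if (j == i) next
      sds <- c(sds, sd(m[i, ] - m[j, ]))
    }
    out[i] <- mean(sds)
  }
  names(out) <- rownames(m)
  out
}

# full-set geNorm M via explicit quantities
oracle_genorm_m <- function(m, base = 2) {
  g <- nrow(m)
  q <- matrix(NA_real_, g, ncol(m), dimnames = dimnames(m))
  for (i in seq_len(g)) q[i, ] <- base^(min(m[i, ]) - m[i, ])
  out <- numeric(g)
  for (i in seq_len(g)) {
    sds <- c()
    for (j in seq_len(g)) {
      if (j == i) next
      sds <- c(sds, sd(log(q[i, ] / q[j, ], base = base)))
    }
    out[i] <- mean(sds)
  }
  names(out) <- rownames(m)
  out
}

oracle_bestkeeper <- function(m) {
  g <- nrow(m); n <- ncol(m)
  index <- numeric(n)
  for (s in seq_len(n)) index[s] <- prod(m[, s])^(1 / g)
  res <- data.frame(gene_id = rownames(m), mean_ct = NA, geo_mean_ct = NA,
                    sd = NA, cv = NA, r = NA)
  for (i in seq_len(g)) {
    res$mean_ct[i] <- mean(m[i, ])
    res$geo_mean_ct[i] <- prod(m[i, ])^(1 / n)
    res$sd[i] <- sd(m[i, ])
    res$cv[i] <- 100 * sd(m[i, ]) / mean(m[i, ])
    res$r[i] <- if (sd(m[i, ]) == 0) NA_real_ else cor(m[i, ], index)
  }
  list(gene_stats = res, index = index)
}

# NormFinder oracle: raw per-gene residual variances, then solve the g x g
# expectation system E[v_i] = sigma2_i (g-2)/g + sum(sigma2)/g^2
oracle_normfinder_sigma2 <- function(m) {
  g <- nrow(m); n <- ncol(m)
  y <- -m
  v <- numeric(g)
  for (i in seq_len(g)) {
    ssq <- 0
    for (j in seq_len(n)) {
      r <- y[i, j] - mean(y[i, ]) - mean(y[, j]) + mean(y)
      ssq <- ssq + r^2
    }
    v[i] <- ssq / (n - 1)
  }
  A <- diag((g - 2) / g, g) + matrix(1 / g^2, g, g)
  sigma2 <- solve(A, v)
  names(sigma2) <- rownames(m)
  sigma2
}

# brute-force screening cascade by direct predicate application
oracle_screen <- function(rpkm, cfg) {
  ids <- rpkm$gene_id
  v <- as.matrix(rpkm[, -1])
  keep1 <- keep2 <- keep3 <- logical(length(ids))
  ratio <- cv <- numeric(length(ids))
  for (i in seq_along(ids)) {
    x <- v[i, ]
    keep1[i] <- min(x) >= cfg$expressed_threshold
    ratio[i] <- if (min(x) > 0) max(x) / min(x) else NA
    cv[i] <- sd(x) / mean(x)
    keep2[i] <- keep1[i] && !is.na(ratio[i]) &&
      ratio[i] < cfg$max_min_ratio_limit && cv[i] < cfg$cv_limit
    keep3[i] <- keep2[i] && min(x) > cfg$min_rpkm
  }
  surv <- data.frame(gene_id = ids, ratio = ratio, cv = cv)[keep3, ]
  surv <- surv[order(surv$ratio, surv$cv, surv$gene_id), ]
  list(expressed = ids[keep1], stable = ids[keep2], abundant = ids[keep3],
       top = head(surv$gene_id, cfg$top_n))
}
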