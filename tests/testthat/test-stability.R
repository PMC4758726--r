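# 3 genes x 4 samples worked example: A and B share a profile, C alternates
example_ct3 <- function() {
  m <- rbind(A = c(20, 21, 22, 23),
             B = c(20, 21, 22, 23),
             C = c(20, 23, 20, 23))
  colnames(m) <- paste0("s", 1:4)
  m
}

test_that("delta-CT statistic matches hand-computed pairwise SDs", {
  m <- example_ct3()
  res <- delta_ct_stability(ct_tbl(m))
  # SD(A - C) = SD([0,-2,2,0]) = sqrt(8/3); A pairs with B (0) and C
  expect_equal(res$statistic[res$gene_id == "A"], 0.5 * sqrt(8 / 3))
  expect_equal(res$statistic[res$gene_id == "B"], 0.5 * sqrt(8 / 3))
  expect_equal(res$statistic[res$gene_id == "C"], sqrt(8 / 3))
  expect_equal(res$rank[res$gene_id == "C"], 3L)
  expect_equal(sort(res$rank[res$gene_id != "C"]), c(1L, 1L))
})

test_that("delta-CT is zero for shared or shifted profiles", {
  m <- rbind(A = c(20, 22, 24), B = c(20, 22, 24), C = c(25, 27, 29))
  colnames(m) <- paste0("s", 1:3)
  res <- delta_ct_stability(ct_tbl(m))
  expect_equal(res$statistic, rep(0, 3)) # B = A, C = A + 5
  expect_error(delta_ct_stability(ct_tbl(m[, 1, drop = FALSE])),
               "at least 2 samples")
})

test_that("full-set geNorm M equals the delta-CT statistic at base 2", {
  set.seed(41)
  for (i in 1:10) {
    m <- rand_ct_matrix(6, 9)
    gn <- genorm(ct_tbl(m), base = 2)
    dc <- delta_ct_stability(ct_tbl(m))
    expect_equal(gn$full_m$m[match(dc$gene_id, gn$full_m$gene_id)],
                 dc$statistic, tolerance = 1e-12)
  }
})

test_that("geNorm on perfectly proportional quantities gives all-zero M and V", {
  base_profile <- c(20, 21.5, 19, 22, 20.5)
  m <- rbind(A = base_profile, B = base_profile + 2, C = base_profile - 1,
             D = base_profile + 0.5)
  colnames(m) <- paste0("s", 1:5)
  gn <- genorm(ct_tbl(m))
  expect_equal(gn$m_values$statistic, rep(0, 4))
  expect_equal(gn$v$v, rep(0, 2))
})

test_that("geNorm excludes an obviously noisy gene first and ranks the pair", {
  set.seed(42)
  prof <- runif(8, 19, 25)
  m <- rbind(A = prof, B = prof + 1, C = prof - 2,
             D = prof + rnorm(8, 0, 2))
  colnames(m) <- paste0("s", 1:8)
  gn <- genorm(ct_tbl(m))
  expect_equal(gn$exclusion_order[1], "D")
  expect_equal(gn$m_values$rank[1:3], c(1L, 1L, 3L)) # pair ties at rank 1
  expect_setequal(gn$stable_pair, gn$m_values$gene_id[1:2])
  expect_error(genorm(ct_tbl(m[1:2, ])), "at least 3 genes")
})

test_that("geNorm statistics match the brute-force oracle", {
  set.seed(43)
  for (i in 1:5) {
    m <- rand_ct_matrix(sample(4:6, 1), sample(5:10, 1))
    gn <- genorm(ct_tbl(m))
    or <- oracle_genorm_m(m)
    expect_equal(gn$full_m$m, unname(or[gn$full_m$gene_id]),
                 tolerance = 1e-10)
  }
})

test_that("BestKeeper reproduces the two-gene worked example", {
  m <- rbind(A = c(20, 21, 22), B = c(22, 23, 24))
  colnames(m) <- paste0("s", 1:3)
  bk <- bestkeeper(ct_tbl(m))
  expect_equal(bk$index$index, sqrt(c(20 * 22, 21 * 23, 22 * 24)),
               tolerance = 1e-12)
  # the index is almost collinear with each gene here
  expect_equal(bk$gene_stats$r, c(1, 1), tolerance = 1e-6)
  expect_equal(bk$gene_stats$statistic, c(1, 1)) # SD in cycles
  expect_equal(bk$gene_stats$cv_pct, 100 * c(1 / 21, 1 / 23))
})

test_that("BestKeeper handles constant genes and matches the oracle", {
  m <- rbind(A = c(20, 20, 20), B = c(21, 23, 25), C = c(19, 20, 21))
  colnames(m) <- paste0("s", 1:3)
  bk <- bestkeeper(ct_tbl(m))
  a <- bk$gene_stats[bk$gene_stats$gene_id == "A", ]
  expect_equal(a$statistic, 0)
  expect_equal(a$cv_pct, 0)
  expect_true(is.na(a$r))
  expect_equal(a$rank, 1L) # ranked by SD alone

  set.seed(44)
  for (i in 1:5) {
    m <- rand_ct_matrix(6, 9)
    bk <- bestkeeper(ct_tbl(m))
    or <- oracle_bestkeeper(m)
    expect_equal(bk$gene_stats$statistic, or$gene_stats$sd, tolerance = 1e-12)
    expect_equal(bk$gene_stats$cv_pct, or$gene_stats$cv, tolerance = 1e-12)
    expect_equal(bk$gene_stats$r, or$gene_stats$r, tolerance = 1e-12)
    expect_equal(bk$index$index, or$index, tolerance = 1e-12)
    expect_equal(bk$gene_stats$geo_mean_ct, or$gene_stats$geo_mean_ct,
                 tolerance = 1e-12)
  }
})

test_that("NormFinder is exactly zero on purely additive data", {
  alpha <- c(A = 20, B = 22, C = 25, D = 19)
  beta <- c(0, 1.5, -1, 2, 0.5)
  m <- outer(alpha, beta, `+`)
  colnames(m) <- paste0("s", 1:5)
  nf <- normfinder(ct_tbl(m))
  expect_equal(nf$gene_stats$statistic, rep(0, 4))
  expect_error(normfinder(ct_tbl(m[1:2, ])), "at least 3 genes")
})

test_that("NormFinder variance estimates solve the expectation system", {
  set.seed(45)
  for (i in 1:5) {
    m <- rand_ct_matrix(sample(4:6, 1), sample(5:10, 1))
    nf <- normfinder(ct_tbl(m))
    or <- oracle_normfinder_sigma2(m)
    expect_equal(nf$gene_stats$sigma2, unname(or[nf$gene_stats$gene_id]),
                 tolerance = 1e-10)
  }
})

test_that("NormFinder estimates converge to the true sigma as n grows", {
  sigma <- seq(0.1, 0.8, length.out = 8)
  err_at <- function(n, seed) {
    set.seed(seed)
    beta <- rnorm(n, 0, 1)
    m <- t(vapply(seq_along(sigma), function(i) {
      25 + beta + rnorm(n, 0, sigma[i])
    }, numeric(n)))
    rownames(m) <- paste0("g", seq_along(sigma))
    colnames(m) <- paste0("s", seq_len(n))
    est <- normfinder(ct_tbl(m))$gene_stats
    mean(abs(est$statistic[match(rownames(m), est$gene_id)] - sigma) / sigma)
  }
  errs50 <- vapply(1:5, function(s) err_at(50, s), numeric(1))
  errs500 <- vapply(1:5, function(s) err_at(500, 100 + s), numeric(1))
  expect_lt(mean(errs500), mean(errs50))
  expect_lt(mean(errs500), 0.15)
})

test_that("per-gene statistics are invariant to shifting one gene's CT", {
  set.seed(46)
  m <- rand_ct_matrix(5, 8)
  m2 <- m
  m2["g3", ] <- m2["g3", ] + 4 # constant shift
  dc1 <- delta_ct_stability(ct_tbl(m)); dc2 <- delta_ct_stability(ct_tbl(m2))
  expect_equal(dc1$statistic, dc2$statistic, tolerance = 1e-12)
  gn1 <- genorm(ct_tbl(m)); gn2 <- genorm(ct_tbl(m2))
  expect_equal(gn1$full_m$m, gn2$full_m$m, tolerance = 1e-12)
  nf1 <- normfinder(ct_tbl(m)); nf2 <- normfinder(ct_tbl(m2))
  expect_equal(nf1$gene_stats$statistic, nf2$gene_stats$statistic,
               tolerance = 1e-12)
  bk1 <- bestkeeper(ct_tbl(m)); bk2 <- bestkeeper(ct_tbl(m2))
  expect_equal(bk1$gene_stats$statistic, bk2$gene_stats$statistic,
               tolerance = 1e-12) # SD unchanged
  cv1 <- bk1$gene_stats$cv_pct[bk1$gene_stats$gene_id == "g3"]
  cv2 <- bk2$gene_stats$cv_pct[bk2$gene_stats$gene_id == "g3"]
  expect_false(isTRUE(all.equal(cv1, cv2))) # CV depends on the mean CT
})

test_that("rank aggregation takes the geometric mean of method ranks", {
  set.seed(47)
  # flat stage profile: every method then sees only the per-gene noise
  m <- rbind(best = 22 + rnorm(9, 0, 0.01),
             mid1 = 22 + rnorm(9, 0, 0.3),
             mid2 = 22 + rnorm(9, 0, 0.5),
             worst = 22 + rnorm(9, 0, 3))
  colnames(m) <- paste0("s", 1:9)
  rk <- rank_stability(ct_tbl(m))
  agg <- rk$aggregate
  expect_equal(agg$gene_id[agg$rank == 1], "best")
  # recompute the aggregate from the per-method ranks
  manual <- tapply(rk$scores$rank, rk$scores$gene_id,
                   function(r) exp(mean(log(r))))
  expect_equal(agg$geo_mean_rank, as.numeric(manual[agg$gene_id]),
               tolerance = 1e-12)
  expect_setequal(rk$methods,
                  c("deltaCT", "geNorm", "BestKeeper", "NormFinder"))
})

test_that("methods whose preconditions fail are omitted with a warning", {
  m <- rbind(A = c(20, 21, 22, 23), B = c(21, 22, 23.2, 24))
  colnames(m) <- paste0("s", 1:4)
  ws <- capture_warnings(rk <- rank_stability(ct_tbl(m)))
  expect_match(ws, "geNorm omitted", all = FALSE)
  expect_match(ws, "NormFinder omitted", all = FALSE)
  expect_false("geNorm" %in% rk$methods)
  expect_false("NormFinder" %in% rk$methods) # needs >= 3 genes too
  expect_setequal(rk$methods, c("deltaCT", "BestKeeper"))
  expect_equal(nrow(rk$aggregate), 2)
})

test_that("two-group datasets are ranked per group", {
  set.seed(48)
  build <- function(grp, shift) {
    m <- rbind(stab = 22 + rnorm(9, 0, 0.05),
               mid = 22 + rnorm(9, 0, 0.4),
               bad = 22 + rnorm(9, 0, 2))
    colnames(m) <- paste0("s", 1:9)
    ct_tbl(m + shift, group = grp)
  }
  ds <- dplyr::bind_rows(build("OP", 0), build("RP", 1))
  rk <- rank_stability(ds)
  expect_setequal(unique(rk$aggregate$group), c("OP", "RP"))
  for (grp in c("OP", "RP")) {
    sub <- rk$aggregate[rk$aggregate$group == grp, ]
    expect_equal(sub$gene_id[sub$rank == 1], "stab")
  }
})

test_that("ct_summary reports group means, SDs and OP-RP differences", {
  ds <- tibble::tibble(gene_id = "g", sample = "s", replicate = 1:3,
                       ct = c(19, 20, 21), group = "OP")
  out <- ct_summary(ds)
  expect_equal(out$mean_ct, 20)
  expect_equal(out$sd_ct, 1)

  ds2 <- dplyr::bind_rows(ds, dplyr::mutate(ds, group = "RP"))
  out2 <- ct_summary(ds2)
  diff <- attr(out2, "group_diff")
  expect_equal(diff$mean_diff, 0) # identical OP and RP data
})
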