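#' Comparative-CT relative expression
#'
#' Normalizes target-gene CT values against a set of reference genes under
#' the equal-efficiency assumption (base 2). Per sample s the reference
#' level is the arithmetic mean of the reference genes' CTs — equivalently
#' the log of the geometric mean of their quantities, the conventional way
#' to combine multiple references — and the relative expression of target
#' t is `2^-(CT_t(s) - CT_ref(s))`. With a calibrator sample, every value
#' is further divided by the calibrator's, making the calibrator exactly
#' 1. Technical replicates are collapsed to mean CT first.
#'
#' @param targets CT dataset of target genes (single group).
#' @param refs CT dataset of reference genes measured on the same samples
#'   (single group; may be the same tibble as `targets`).
#' @param ref_set Character vector of reference gene ids in `refs`.
#' @param calibrator Optional sample label to rescale to.
#' @param base Quantification base; default 2.
#' @return A tibble `gene_id` (target), `sample`, `rel_expr`
#'   (dimensionless), `ref_set` (collapsed label), `calibrator`.
#' @examples
#' ct <- tidyr::crossing(gene_id = c("t", "r1", "r2"), sample = c("s1", "s2"))
#' ct$replicate <- 1L
#' ct$ct <- c(21, 23, 20, 21, 22, 21) # r1, r2, t by gene order
#' comparative_ct(ct, ct, ref_set = c("r1", "r2"))
#' @export
comparative_ct <- function(targets, refs, ref_set, calibrator = NULL,
                           base = 2) {
  if (!length(ref_set)) abort("`ref_set` must name at least one reference gene")
  tm <- ct_matrix(targets)
  rm_ <- ct_matrix(refs)
  missing_refs <- setdiff(ref_set, rownames(rm_))
  if (length(missing_refs)) {
    abort(paste0("reference gene(s) not in `refs`: ",
                 paste(missing_refs, collapse = ", ")))
  }
  if (!setequal(colnames(tm), colnames(rm_))) {
    d <- union(setdiff(colnames(tm), colnames(rm_)),
               setdiff(colnames(rm_), colnames(tm)))
    abort(paste0("sample labels differ between targets and refs: ",
                 paste(d, collapse = ", ")))
  }
  rm_ <- rm_[, colnames(tm), drop = FALSE]
  ref_ct <- colMeans(rm_[ref_set, , drop = FALSE])
  targets_only <- setdiff(rownames(tm), ref_set)
  if (!length(targets_only)) targets_only <- rownames(tm)
  out <- purrr::map_dfr(targets_only, function(t) {
    rel <- base^(-(tm[t, ] - ref_ct))
    tibble(gene_id = t, sample = colnames(tm), rel_expr = unname(rel))
  })
  if (!is.null(calibrator)) {
    if (!calibrator %in% colnames(tm)) {
      abort(paste0("calibrator sample '", calibrator, "' not found"))
    }
    out <- out |>
      group_by(.data$gene_id) |>
      mutate(rel_expr = .data$rel_expr /
               .data$rel_expr[.data$sample == calibrator]) |>
      ungroup()
  }
  out$ref_set <- paste(ref_set, collapse = "+")
  out$calibrator <- calibrator %||% NA_character_
  out
}

#' Concordance between a normalized qPCR profile and RNA-seq
#'
#' Pearson correlation between a target's comparative-CT expression
#' profile and its RPKM profile across matched stages, on the log2 scale
#' by default so that multiplicative rescaling of either profile leaves r
#' unchanged (the profiles carry arbitrary units). Requires at least 3
#' matched stages; zero variance on either side yields `r = NA` with an
#' explanatory message.
#'
#' @param profile Output of [comparative_ct()] (one or more targets; the
#'   `sample` labels must match stage columns of `m`).
#' @param m An expression matrix containing the target gene rows.
#' @param transform `"log2"` (default) or `"linear"`.
#' @return A tibble `gene_id`, `ref_set`, `r`, `transform`, `n_stages`.
#' @export
concordance <- function(profile, m, transform = c("log2", "linear")) {
  transform <- match.arg(transform)
  m <- validate_expression_matrix(m)
  stages <- names(m)[-1]
  purrr::map_dfr(unique(profile$gene_id), function(gid) {
    p <- profile[profile$gene_id == gid, ]
    matched <- intersect(p$sample, stages)
    if (length(matched) < 3) {
      abort(sprintf("gene '%s': only %d matched stage(s); need >= 3",
                    gid, length(matched)))
    }
    if (!gid %in% m$gene_id) {
      abort(paste0("gene '", gid, "' not in the expression matrix"))
    }
    x <- p$rel_expr[match(matched, p$sample)]
    y <- as.numeric(m[m$gene_id == gid, matched])
    if (transform == "log2") {
      if (any(x <= 0) || any(y <= 0)) {
        abort(sprintf("gene '%s': non-positive values block the log2 transform",
                      gid))
      }
      x <- log2(x); y <- log2(y)
    }
    r <- if (sd(x) == 0 || sd(y) == 0) {
      inform(sprintf("gene '%s': zero variance on one side, r undefined", gid))
      NA_real_
    } else {
      cor(x, y)
    }
    tibble(gene_id = gid, ref_set = p$ref_set[1], r = r,
           transform = transform, n_stages = length(matched))
  })
}

#' Primer-efficiency fit from a dilution series
#'
#' Least-squares line `CT = a + b * log2(dilution)` over a serial dilution
#' of template, via `stats::lm()`. A perfect twofold chemistry gains one
#' cycle per twofold dilution (b = 1); the amplification efficiency is
#' `E = 2^(1/b) - 1` (1 = 100%, perfect doubling). A fit passes QC when
#' R^2 > 0.99. A non-positive slope (CT failing to rise with dilution)
#' leaves the efficiency undefined.
#'
#' @param series A data frame with columns `dilution` (> 0 factors, e.g.
#'   1, 2, 4, 8, 16) and `ct`; at least 3 points. An optional `gene_id`
#'   column fits each gene separately.
#' @param r2_pass R^2 threshold for the pass flag (strict >). Default
#'   0.99.
#' @return A tibble of class `efficiency_fit` with one row per gene:
#'   `gene_id`, `slope` (cycles per log2 dilution), `intercept`,
#'   `efficiency` (fraction; NA when slope <= 0), `r_squared`, `n_points`,
#'   `pass`.
#' @examples
#' fit_efficiency(data.frame(dilution = c(1, 2, 4, 8, 16),
#'                           ct = c(20, 21, 22, 23, 24)))
#' @export
fit_efficiency <- function(series, r2_pass = 0.99) {
  series <- as_tibble(series)
  if (!"gene_id" %in% names(series)) series$gene_id <- "series"
  if (any(series$dilution <= 0)) abort("dilution factors must be > 0")
  out <- purrr::map_dfr(unique(series$gene_id), function(gid) {
    s <- series[series$gene_id == gid, ]
    if (nrow(s) < 3) {
      abort(sprintf("gene '%s': need >= 3 dilution points, got %d",
                    gid, nrow(s)))
    }
    fit <- lm(ct ~ log2(dilution), data = s)
    b <- unname(coef(fit)[2]); a <- unname(coef(fit)[1])
    ss_tot <- sum((s$ct - mean(s$ct))^2)
    if (ss_tot == 0) abort(sprintf("gene '%s': constant CT across dilutions",
                                   gid))
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
    eff <- if (b <= 0) NA_real_ else 2^(1 / b) - 1
    if (b <= 0) {
      warn(sprintf("gene '%s': slope %.3g <= 0, efficiency undefined", gid, b))
    }
    tibble(gene_id = gid, slope = b, intercept = a, efficiency = eff,
           r_squared = r2, n_points = nrow(s),
           pass = is.finite(eff) & r2 > r2_pass)
  })
  class(out) <- c("efficiency_fit", class(out))
  out
}
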