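#' Per-gene screening statistics
#'
#' Computes, for every gene of a stage-wise RPKM matrix, the quantities the
#' screening cascade filters on: minimum and maximum RPKM, the max/min
#' ratio (the primary stability screen; `NA` when the minimum is 0, where
#' the ratio is undefined), the mean, the sample SD and the coefficient of
#' variation CV = SD / mean.
#'
#' @param m An expression matrix (see [validate_expression_matrix()]).
#' @return A tibble with one row per gene: `gene_id`, `min_rpkm`,
#'   `max_rpkm`, `max_min_ratio`, `mean_rpkm`, `sd_rpkm`, `cv`.
#' @examples
#' m <- tibble::tibble(gene_id = "g1", s1 = 40, s2 = 60)
#' screen_stats(m) # ratio 1.5, cv ~ 0.283
#' @export
screen_stats <- function(m) {
  m <- validate_expression_matrix(m)
  v <- as.matrix(m[, -1, drop = FALSE])
  mins <- apply(v, 1, min)
  maxs <- apply(v, 1, max)
  mus <- rowMeans(v)
  sds <- apply(v, 1, sd)
  tibble(
    gene_id = m$gene_id,
    min_rpkm = mins,
    max_rpkm = maxs,
    max_min_ratio = ifelse(mins > 0, maxs / mins, NA_real_),
    mean_rpkm = mus,
    sd_rpkm = sds,
    cv = ifelse(mus > 0, sds / mus, NA_real_)
  )
}

#' Screening cascade filters
#'
#' The four tabular filters of the reference-gene screen, each taking the
#' [screen_stats()] tibble (or a previously filtered subset) and returning
#' the surviving rows. Boundary conventions follow the screen as printed:
#' the expression call is inclusive (min RPKM >= threshold), the stability
#' limits are strict (ratio < limit, CV < limit), the abundance floor is
#' strict (min RPKM > limit).
#'
#' `filter_expressed()` keeps genes expressed at every stage;
#' `filter_stable()` keeps genes with a defined max/min ratio below
#' `ratio_limit` and CV below `cv_limit`; `filter_abundant()` keeps genes
#' whose minimum RPKM exceeds `min_rpkm`; `select_top_candidates()` orders
#' survivors by ascending max/min ratio (ties: ascending CV, then
#' lexicographic gene id) and keeps the first `top_n`.
#'
#' @param stats A [screen_stats()] tibble (possibly already filtered).
#' @param threshold,ratio_limit,cv_limit,min_rpkm,top_n Filter parameters;
#'   defaults are the [pipeline_config()] values.
#' @return The surviving rows, as a tibble; `select_top_candidates()`
#'   returns them in rank order.
#' @name screen_filters
NULL

#' @rdname screen_filters
#' @export
filter_expressed <- function(stats, threshold = 0.17) {
  stopifnot(threshold > 0)
  filter(stats, .data$min_rpkm >= threshold)
}

#' @rdname screen_filters
#' @export
filter_stable <- function(stats, ratio_limit = 2, cv_limit = 0.3) {
  stopifnot(ratio_limit > 0, cv_limit > 0)
  filter(stats,
         !is.na(.data$max_min_ratio), .data$max_min_ratio < ratio_limit,
         !is.na(.data$cv), .data$cv < cv_limit)
}

#' @rdname screen_filters
#' @export
filter_abundant <- function(stats, min_rpkm = 40) {
  stopifnot(min_rpkm > 0)
  limit <- min_rpkm
  filter(stats, .data$min_rpkm > .env$limit)
}

#' @rdname screen_filters
#' @export
select_top_candidates <- function(stats, top_n = 5) {
  if (nrow(stats) == 0) abort("no survivors to rank")
  ord <- arrange(stats, .data$max_min_ratio, .data$cv, .data$gene_id)
  if (top_n > nrow(ord)) {
    warn(sprintf("top_n = %d exceeds the %d survivors; returning all",
                 top_n, nrow(ord)))
    return(ord)
  }
  head(ord, top_n)
}

#' Annotation filter for candidate reference genes
#'
#' Keeps candidates whose transcript structure permits unambiguous primer
#' design: genes with exactly one annotated transcript, or with two
#' transcripts that overlap. Genes with more isoforms are dropped by
#' default (primer specificity is doubtful); `allow_multi_isoform = TRUE`
#' keeps them. Candidates without an annotation row are dropped with a
#' warning unless `missing = "keep"`.
#'
#' @param candidates A tibble with a `gene_id` column (e.g. the output of
#'   [select_top_candidates()]).
#' @param annotation A data frame with columns `gene_id`,
#'   `transcript_count` (non-negative integer) and
#'   `two_transcripts_overlap` (logical; meaningful when
#'   `transcript_count == 2`).
#' @param allow_multi_isoform Keep genes with > 2 transcripts? Default
#'   FALSE.
#' @param missing `"drop"` (default) or `"keep"` for candidates without
#'   an annotation row.
#' @return The retained candidate rows, annotation columns appended.
#' @export
filter_annotation <- function(candidates, annotation,
                              allow_multi_isoform = FALSE,
                              missing = c("drop", "keep")) {
  missing <- match.arg(missing)
  annotation <- as_tibble(annotation)
  if (any(annotation$transcript_count < 0)) {
    abort("transcript_count must be >= 0")
  }
  if (any(annotation$transcript_count == 2 &
          is.na(annotation$two_transcripts_overlap))) {
    abort("two_transcripts_overlap must be set when transcript_count == 2")
  }
  joined <- left_join(candidates, annotation, by = "gene_id")
  unannotated <- joined$gene_id[is.na(joined$transcript_count)]
  if (length(unannotated)) {
    warn(paste0("no annotation for: ", paste(unannotated, collapse = ", "),
                if (missing == "drop") " (dropped)" else " (kept)"))
  }
  keep <- ifelse(
    is.na(joined$transcript_count),
    missing == "keep",
    joined$transcript_count == 1 |
      (joined$transcript_count == 2 &
         !is.na(joined$two_transcripts_overlap) &
         joined$two_transcripts_overlap) |
      (allow_multi_isoform & joined$transcript_count > 2)
  )
  joined[keep, , drop = FALSE]
}

#' Run the full reference-gene screening cascade
#'
#' Applies, in order: the expression call (min RPKM >= threshold at every
#' stage), the stability screen (max/min ratio and CV below their limits),
#' the abundance floor (min RPKM above the floor), top-N selection by
#' ascending max/min ratio, and (when an annotation table is supplied) the
#' transcript-structure filter. Survivor sets are strictly nested; the
#' report records the survivors and parameters of every stage.
#'
#' @param m An expression matrix.
#' @param annotation Optional gene annotation table (see
#'   [filter_annotation()]); when `NULL` the annotation stage is skipped.
#' @param config A [pipeline_config()].
#' @param allow_multi_isoform Passed to [filter_annotation()].
#' @return An object of class `screening_report`: a list with `stages`
#'   (tibble: `stage`, `parameters`, `n_in`, `n_out`, `survivors`
#'   list-column), `candidates` (final candidate tibble in rank order) and
#'   `stats` (the full [screen_stats()] table).
#' @examples
#' sim <- simulate_rpkm(generator_config(n_stable = 4, n_variable = 20,
#'                                       seed = 1))
#' rep <- run_screen(sim$matrix, sim$annotation,
#'                   config = pipeline_config(top_n = 4))
#' rep$candidates$gene_id
#' @export
run_screen <- function(m, annotation = NULL, config = pipeline_config(),
                       allow_multi_isoform = FALSE) {
  stats <- screen_stats(m)
  stages <- list()
  log_stage <- function(name, parameters, before, after) {
    stages[[length(stages) + 1]] <<- tibble(
      stage = name, parameters = parameters,
      n_in = nrow(before), n_out = nrow(after),
      survivors = list(after$gene_id)
    )
    inform(sprintf("%-12s %5d -> %5d survivors", name,
                   nrow(before), nrow(after)))
  }

  s1 <- filter_expressed(stats, config$expressed_threshold)
  log_stage("expressed", sprintf("min RPKM >= %g", config$expressed_threshold),
            stats, s1)
  s2 <- filter_stable(s1, config$max_min_ratio_limit, config$cv_limit)
  log_stage("stability", sprintf("ratio < %g & CV < %g",
                                 config$max_min_ratio_limit, config$cv_limit),
            s1, s2)
  s3 <- filter_abundant(s2, config$min_rpkm)
  log_stage("abundance", sprintf("min RPKM > %g", config$min_rpkm), s2, s3)
  s4 <- if (nrow(s3)) select_top_candidates(s3, config$top_n) else s3
  log_stage("top_n", sprintf("top %d by ascending ratio", config$top_n),
            s3, s4)
  if (!is.null(annotation) && nrow(s4)) {
    s5 <- filter_annotation(s4, annotation,
                            allow_multi_isoform = allow_multi_isoform)
    log_stage("annotation", "1 transcript, or 2 overlapping", s4, s5)
  } else {
    s5 <- s4
  }
  structure(
    list(stages = bind_rows(stages), candidates = s5, stats = stats),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Reference-gene screening cascade\n")
  st <- x$stages
  for (i in seq_len(nrow(st))) {
    cat(sprintf("  %-12s (%s): %d -> %d\n", st$stage[i], st$parameters[i],
                st$n_in[i], st$n_out[i]))
  }
  cat("Final candidates:",
      if (nrow(x$candidates)) paste(x$candidates$gene_id, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
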