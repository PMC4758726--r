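#' Validate a stage-wise expression matrix
#'
#' An expression matrix is a wide data frame whose first column (`gene_id`)
#' holds unique gene identifiers and whose remaining columns hold
#' non-negative RPKM values, one column per developmental stage in
#' chronological (file) order. No chronology is inferred: stage order is
#' the column order.
#'
#' @param m A data frame in the wide layout described above.
#' @return The validated matrix as a tibble, unchanged in content.
#' @examples
#' m <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4))
#' validate_expression_matrix(m)
#' @export
validate_expression_matrix <- function(m) {
  m <- as_tibble(m)
  if (ncol(m) < 3) {
    abort("an expression matrix needs a gene_id column and at least 2 stages")
  }
  if (names(m)[1] != "gene_id") names(m)[1] <- "gene_id"
  m$gene_id <- as.character(m$gene_id)
  dup <- m$gene_id[duplicated(m$gene_id)]
  if (length(dup)) {
    abort(paste0("duplicate gene id(s): ", paste(unique(dup), collapse = ", ")))
  }
  stages <- names(m)[-1]
  if (anyDuplicated(stages)) abort("duplicate stage labels")
  for (s in stages) {
    v <- m[[s]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf("non-numeric value at gene row %s, stage '%s'",
                    if (length(bad)) bad else "?", s))
    }
    if (any(!is.finite(v))) {
      abort(sprintf("non-finite value at gene '%s', stage '%s'",
                    m$gene_id[which(!is.finite(v))[1]], s))
    }
    if (any(v < 0)) {
      abort(sprintf("negative RPKM at gene '%s', stage '%s'",
                    m$gene_id[which(v < 0)[1]], s))
    }
  }
  m
}

#' Read / write an expression matrix (TSV)
#'
#' TSV dialect: UTF-8, `.` decimal separator, no thousands separators; the
#' first column is `gene_id` (opaque strings), the header row carries the
#' stage labels. `write_expression_matrix()` emits files that round-trip
#' bitwise through `read_expression_matrix()`.
#'
#' @param path File path.
#' @return `read_expression_matrix()` returns a validated wide tibble.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- tibble::tibble(gene_id = "g1", s1 = 1.5, s2 = 2.5)
#' write_expression_matrix(m, f)
#' read_expression_matrix(f)
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  m <- read_tsv_exact(path)
  for (col in names(m)[-1]) {
    v <- suppressWarnings(as.numeric(m[[col]]))
    if (anyNA(v) && !all(is.na(m[[col]]) == is.na(v))) {
      abort(sprintf("non-numeric cell at row %d, column '%s' of %s",
                    which(is.na(v) & !is.na(m[[col]]))[1], col, path))
    }
    m[[col]] <- v
  }
  validate_expression_matrix(m)
}

# base-R TSV reader: glibc strtod parses %.17g output back bitwise-exactly
read_tsv_exact <- function(path) {
  as_tibble(utils::read.delim(path, colClasses = "character",
                              check.names = FALSE, na.strings = "NA"))
}

#' @rdname read_expression_matrix
#' @param m A validated expression matrix.
#' @export
write_expression_matrix <- function(m, path) {
  m <- validate_expression_matrix(m)
  readr::write_tsv(fmt_doubles(m), path, progress = FALSE)
  invisible(path)
}

# 17 significant digits: doubles survive the text round trip bitwise
fmt_doubles <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      df[[col]] <- sprintf("%.17g", df[[col]])
    }
  }
  df
}

#' Validate a CT dataset
#'
#' A CT dataset is a long tibble with columns `gene_id`, `sample`,
#' `replicate`, `ct` and `group` (a priming-chemistry tag such as `"OP"`
#' or `"RP"`). Within each group the replicate structure must be complete:
#' every (gene, sample) cell carries the same number of technical
#' replicates. CT values outside the plausible range are flagged in the
#' returned `flagged` attribute, never dropped; validation is loss-free.
#'
#' @param ds A data frame with the columns above (`group` optional,
#'   defaults to `"all"`).
#' @param ct_range Plausible CT range in cycles; values outside are
#'   reported via a warning and recorded in `attr(, "flagged")`.
#' @return The validated tibble; attribute `flagged` holds the rows whose
#'   CT fell outside `ct_range`.
#' @examples
#' ds <- tidyr::crossing(gene_id = c("a", "b"), sample = c("s1", "s2"),
#'                       replicate = 1:2)
#' ds$ct <- 20 + seq_len(nrow(ds)) / 10
#' validate_ct_dataset(ds)
#' @export
validate_ct_dataset <- function(ds, ct_range = c(5, 40)) {
  ds <- as_tibble(ds)
  need <- c("gene_id", "sample", "replicate", "ct")
  miss <- setdiff(need, names(ds))
  if (length(miss)) {
    abort(paste0("CT dataset lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (!"group" %in% names(ds)) ds$group <- "all"
  ds$gene_id <- as.character(ds$gene_id)
  ds$sample <- as.character(ds$sample)
  ds$replicate <- as.integer(ds$replicate)
  if (any(!is.finite(ds$ct))) {
    bad <- ds[!is.finite(ds$ct), ]
    abort(sprintf("non-finite CT at gene '%s', sample '%s'",
                  bad$gene_id[1], bad$sample[1]))
  }
  dupcell <- ds |>
    dplyr::count(.data$group, .data$gene_id, .data$sample, .data$replicate) |>
    filter(.data$n > 1)
  if (nrow(dupcell)) {
    abort(sprintf("duplicated replicate %d for gene '%s', sample '%s'",
                  dupcell$replicate[1], dupcell$gene_id[1], dupcell$sample[1]))
  }
  # uniform replicate depth per group: complete grid gene x sample x replicate
  for (g in unique(ds$group)) {
    sub <- ds[ds$group == g, ]
    depth <- sub |>
      dplyr::count(.data$gene_id, .data$sample, name = "depth")
    if (length(unique(depth$depth)) > 1 ||
        nrow(depth) != length(unique(sub$gene_id)) * length(unique(sub$sample))) {
      expected <- max(depth$depth)
      full <- tidyr::crossing(gene_id = unique(sub$gene_id),
                              sample = unique(sub$sample))
      short <- dplyr::left_join(full, depth, by = c("gene_id", "sample")) |>
        mutate(depth = dplyr::coalesce(.data$depth, 0L)) |>
        filter(.data$depth < expected)
      abort(paste0(
        "incomplete replicate structure in group '", g, "' for (gene, sample): ",
        paste(sprintf("(%s, %s)", short$gene_id, short$sample)[
          seq_len(min(5, nrow(short)))], collapse = ", ")
      ))
    }
  }
  flagged <- ds[ds$ct < ct_range[1] | ds$ct > ct_range[2], ]
  if (nrow(flagged)) {
    warn(sprintf("%d CT value(s) outside [%g, %g] cycles (flagged, kept)",
                 nrow(flagged), ct_range[1], ct_range[2]))
  }
  attr(ds, "flagged") <- flagged
  ds
}

#' Read / write a CT dataset (TSV)
#'
#' Long layout: columns `gene_id`, `sample`, `replicate`, `ct`; wide
#' layout: `gene_id`, `sample`, then one `ct` column per replicate named
#' `rep1`, `rep2`, ... The group tag is supplied at read time (one dataset
#' per priming chemistry).
#'
#' @param path File path.
#' @param group Group label attached to every row (e.g. `"OP"`, `"RP"`).
#' @param format `"long"` (default) or `"wide"`.
#' @param ct_range Passed to [validate_ct_dataset()].
#' @return `read_ct_dataset()` returns a validated long tibble with a
#'   `group` column.
#' @export
read_ct_dataset <- function(path, group = "all",
                            format = c("long", "wide"), ct_range = c(5, 40)) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read_tsv_exact(path)
  num_cols <- setdiff(names(raw), c("gene_id", "sample"))
  for (col in num_cols) raw[[col]] <- as.numeric(raw[[col]])
  if (format == "wide") {
    raw <- tidyr::pivot_longer(raw, dplyr::starts_with("rep"),
                               names_to = "replicate", names_prefix = "rep",
                               values_to = "ct")
    raw$replicate <- as.integer(raw$replicate)
  }
  raw$group <- group
  validate_ct_dataset(raw, ct_range = ct_range)
}

#' @rdname read_ct_dataset
#' @param ds A validated CT dataset (its `group` column is not written;
#'   one file per group).
#' @export
write_ct_dataset <- function(ds, path) {
  ds <- as_tibble(ds)
  readr::write_tsv(fmt_doubles(ds[, c("gene_id", "sample", "replicate", "ct")]),
                   path, progress = FALSE)
  invisible(path)
}

#' Collapse technical replicates to per-sample mean CT
#'
#' Averages the technical replicates of each (gene, sample, group) cell
#' arithmetically on the CT scale and keeps the replicate sample SD as a
#' `ct_sd` column. Idempotent: depth-1 input passes through with
#' `ct_sd = NA` preserved (or 0 where a previous collapse recorded it).
#'
#' @param ds A CT dataset (long tibble, any replicate depth >= 1).
#' @return A tibble with one row per (group, gene, sample): columns
#'   `gene_id`, `sample`, `replicate` (= 1), `ct` (replicate mean),
#'   `ct_sd` (replicate sample SD; NA at depth 1), `group`.
#' @examples
#' ds <- tibble::tibble(gene_id = "g", sample = "s",
#'                      replicate = 1:2, ct = c(19, 21), group = "OP")
#' collapse_replicates(ds)
#' @export
collapse_replicates <- function(ds) {
  ds <- as_tibble(ds)
  if (!"group" %in% names(ds)) ds$group <- "all"
  if (all(ds$replicate == 1L) && "ct_sd" %in% names(ds)) {
    return(ds) # already collapsed
  }
  ds |>
    group_by(.data$group, .data$gene_id, .data$sample) |>
    summarise(ct_sd = if (dplyr::n() > 1) sd(.data$ct) else NA_real_,
              ct = mean(.data$ct), .groups = "drop") |>
    mutate(replicate = 1L) |>
    select("gene_id", "sample", "replicate", "ct", "ct_sd", "group")
}

# internal: collapsed genes x samples CT matrix for one group
# rows = gene_ids (sorted stable by first appearance), cols = samples
ct_matrix <- function(ds) {
  ds <- collapse_replicates(ds)
  if (length(unique(ds$group)) > 1) {
    abort("expected a single-group CT dataset; split by group first")
  }
  genes <- unique(ds$gene_id)
  samples <- unique(ds$sample)
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(ds$gene_id, genes), match(ds$sample, samples))] <- ds$ct
  if (anyNA(m)) abort("CT matrix has missing cells after collapse")
  m
}
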