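#' Generator configuration for synthetic benchmark data
#'
#' Describes a synthetic developmental expression study: a desk-scale
#' transcriptome (default 2,000 genes over 9 stages) containing a small
#' set of designed-stable genes — flat expression with mild log-normal
#' noise, placed above the abundance floor so the screening cascade can
#' recover them — among variable genes carrying stage-trend profiles
#' (monotone ramps, maternal decays and transient pulses, drawn
#' independently per gene and spanning at least 1.5 log2 units, so their
#' max/min ratio exceeds 2 by design). The matching CT
#' model is `CT = intercept - log2(RPKM) + group offset + instability +
#' replicate noise`, with technical triplicates and two priming groups
#' whose per-gene offsets mimic priming-chemistry bias.
#'
#' @param n_stable Number of designed-stable genes. Default 4.
#' @param n_variable Number of designed-variable genes. Default 1996.
#' @param n_stages Number of developmental stages. Default 9.
#' @param mean_range_stable RPKM range (log-uniform) for stable genes;
#'   default c(64, 512), above the abundance floor of 40.
#' @param mean_range_variable RPKM range (log-uniform) for variable
#'   genes; default c(0.05, 1000), spanning unexpressed to abundant.
#' @param sigma_stable SD of log2 expression noise on stable genes;
#'   default 0.1 (CV about 0.07, max/min ratio well under 2).
#' @param sigma_variable_range Range of the per-gene extra CT instability
#'   SD (cycles) given to variable genes; default c(0.4, 1).
#' @param trend_span_range Range of the log2 span of variable genes'
#'   stage trends; default c(2.6, 3.1), i.e. max/min ratios of about 6 to
#'   8.5 — the contrast classic actin-family comparators show against
#'   candidate reference genes in early zebrafish development.
#' @param ct_intercept CT of a 1-RPKM transcript; default 30 cycles.
#' @param replicates Technical replicates per well; default 3.
#' @param sigma_tech Replicate noise SD; default 0.15 cycles.
#' @param groups Priming-group labels; default c("OP", "RP").
#' @param group_offset_sd SD of per-gene group offsets (cycles) for every
#'   group after the first; default 0.5.
#' @param seed Integer seed; same config + seed gives identical output.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_stable = 4, n_variable = 1996, n_stages = 9,
                             mean_range_stable = c(64, 512),
                             mean_range_variable = c(0.05, 1000),
                             sigma_stable = 0.1,
                             sigma_variable_range = c(0.4, 1),
                             trend_span_range = c(2.6, 3.1),
                             ct_intercept = 30, replicates = 3,
                             sigma_tech = 0.15,
                             groups = c("OP", "RP"), group_offset_sd = 0.5,
                             seed = NULL) {
  stopifnot(n_stable >= 0, n_variable >= 0, n_stages >= 2, replicates >= 1,
            sigma_stable >= 0, sigma_tech >= 0, group_offset_sd >= 0)
  structure(as.list(environment()), class = "generator_config")
}

log_uniform <- function(n, range) exp(runif(n, log(range[1]), log(range[2])))

#' Simulate a stage-wise RPKM matrix with known ground truth
#'
#' Stable genes get `RPKM_g(s) = mu_g * 2^eps`, `eps ~ N(0, sigma_stable)`;
#' variable genes additionally carry a stage-trend profile in log2 space,
#' drawn independently per gene from monotone ramps (up or down),
#' maternal-decay shapes (high early expression decaying exponentially)
#' and transient pulses (a zygotic wave peaking at a random interior
#' stage), whose span guarantees a max/min ratio of at least 2. Ground-truth labels, the per-gene extra CT
#' instability later used by [simulate_ct()], per-group CT offsets, and a
#' transcript annotation table (stable genes annotated so they survive the
#' annotation filter) are emitted alongside.
#'
#' @param cfg A [generator_config()].
#' @return A list: `matrix` (wide expression tibble), `truth` (tibble
#'   `gene_id`, `label`, `sigma`, `shape`, `mu`, one `delta_<group>`
#'   column per group), `annotation` (tibble `gene_id`,
#'   `transcript_count`, `two_transcripts_overlap`), `config`.
#' @examples
#' sim <- simulate_rpkm(generator_config(n_stable = 2, n_variable = 10,
#'                                       seed = 1))
#' screen_stats(sim$matrix)
#' @export
simulate_rpkm <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  S <- cfg$n_stages
  stages <- sprintf("stage%02d", seq_len(S))
  ids_s <- sprintf("stab%04d", seq_len(cfg$n_stable))
  ids_v <- sprintf("var%05d", seq_len(cfg$n_variable))

  rows <- list(); truth <- list()
  for (i in seq_along(ids_s)) {
    mu <- log_uniform(1, cfg$mean_range_stable)
    rpkm <- mu * 2^rnorm(S, 0, cfg$sigma_stable)
    rows[[ids_s[i]]] <- rpkm
    truth[[ids_s[i]]] <- tibble(gene_id = ids_s[i], label = "designed-stable",
                                sigma = 0, shape = "flat", mu = mu)
  }
  for (i in seq_along(ids_v)) {
    mu <- log_uniform(1, cfg$mean_range_variable)
    span <- runif(1, cfg$trend_span_range[1], cfg$trend_span_range[2])
    shape <- sample(c("ramp", "decay", "pulse"), 1)
    trend <- switch(
      shape,
      # monotone ramp, direction random
      ramp = sample(c(-1, 1), 1) * span * seq(0, 1, length.out = S),
      # maternal transcript: high early, exponential clearance
      decay = span * exp(-runif(1, 0.5, 1.5) * (seq_len(S) - 1)) - span / 2,
      # transient zygotic wave peaking at a random interior stage
      pulse = {
        peak <- sample(seq(3, max(3, S - 2)), 1)
        w <- runif(1, 1, 1.5)
        span * exp(-(seq_len(S) - peak)^2 / (2 * w^2)) - span / 2
      }
    )
    rpkm <- mu * 2^(trend + rnorm(S, 0, cfg$sigma_stable))
    rows[[ids_v[i]]] <- rpkm
    truth[[ids_v[i]]] <- tibble(gene_id = ids_v[i],
                                label = "designed-variable",
                                sigma = runif(1, cfg$sigma_variable_range[1],
                                              cfg$sigma_variable_range[2]),
                                shape = shape, mu = mu)
  }
  ids <- c(ids_s, ids_v)
  m <- as_tibble(do.call(rbind, rows[ids]), .name_repair = "minimal")
  names(m) <- stages
  m <- dplyr::bind_cols(tibble(gene_id = ids), m)
  truth <- bind_rows(truth[ids])

  # per-gene CT offsets per priming group (first group is the baseline)
  for (g in seq_along(cfg$groups)) {
    col <- paste0("delta_", cfg$groups[g])
    truth[[col]] <- if (g == 1) 0 else rnorm(nrow(truth), 0,
                                             cfg$group_offset_sd)
  }

  n_s <- length(ids_s)
  annotation <- tibble(
    gene_id = ids,
    transcript_count = c(sample(1:2, n_s, replace = TRUE),
                         sample(1:7, length(ids_v), replace = TRUE))
  )
  annotation$two_transcripts_overlap <- ifelse(
    annotation$transcript_count == 2,
    c(rep(TRUE, n_s), sample(c(TRUE, FALSE), length(ids_v),
                             replace = TRUE))[seq_len(nrow(annotation))],
    NA
  )
  list(matrix = validate_expression_matrix(m), truth = truth,
       annotation = annotation, config = cfg)
}

#' Simulate qRT-PCR CT datasets from an expression matrix
#'
#' Converts RPKM to CT through the log2 link
#' `CT_g(s, rep) = intercept - log2(RPKM_g(s)) + delta_group,g + tau_g(s)
#' + eta`, where `delta` is the per-gene priming-group offset (from the
#' truth table; cancels in within-group stability statistics by shift
#' invariance), `tau_g(s) ~ N(0, sigma_g)` is extra instability drawn per
#' group for designed-variable genes (sigma from the truth table), and
#' `eta ~ N(0, sigma_tech)` is replicate noise. All groups share the
#' underlying expression signal. Noise-free, the CT of a 1024-RPKM gene
#' at intercept 30 is exactly 20.
#'
#' @param m An expression matrix (strictly positive for the genes used).
#' @param truth Truth table from [simulate_rpkm()] (columns `gene_id`,
#'   `sigma`, optional `delta_<group>`); genes absent from it get
#'   sigma = 0 and offset 0. May be a hand-built tibble for custom noise
#'   designs.
#' @param cfg A [generator_config()] (supplies intercept, replicates,
#'   noise SDs, groups; its seed, offset by a fixed constant so the draws
#'   are independent of [simulate_rpkm()]'s, makes the output
#'   deterministic).
#' @param genes Optional subset of gene ids to convert (default: all rows
#'   of `m`).
#' @return A long CT tibble: `gene_id`, `sample`, `replicate`, `ct`,
#'   `group` — all groups stacked.
#' @export
simulate_ct <- function(m, truth = NULL, cfg = generator_config(),
                        genes = NULL) {
  m <- validate_expression_matrix(m)
  if (!is.null(genes)) {
    miss <- setdiff(genes, m$gene_id)
    if (length(miss)) abort(paste0("gene(s) not in matrix: ",
                                   paste(miss, collapse = ", ")))
    m <- m[m$gene_id %in% genes, , drop = FALSE]
  }
  v <- as.matrix(m[, -1, drop = FALSE])
  rownames(v) <- m$gene_id
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf("non-positive RPKM at gene '%s', stage '%s'",
                  rownames(v)[bad[1]], colnames(v)[bad[2]]))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed + 1000003L)
  sigma <- setNames(rep(0, nrow(v)), rownames(v))
  if (!is.null(truth)) {
    hit <- intersect(rownames(v), truth$gene_id)
    sigma[hit] <- truth$sigma[match(hit, truth$gene_id)]
  }
  S <- ncol(v); R <- cfg$replicates
  out <- list()
  for (grp in cfg$groups) {
    delta <- setNames(rep(0, nrow(v)), rownames(v))
    dcol <- paste0("delta_", grp)
    if (!is.null(truth) && dcol %in% names(truth)) {
      hit <- intersect(rownames(v), truth$gene_id)
      delta[hit] <- truth[[dcol]][match(hit, truth$gene_id)]
    }
    for (g in rownames(v)) {
      tau <- rnorm(S, 0, sigma[g])
      base_ct <- cfg$ct_intercept - log2(v[g, ]) + delta[g] + tau
      for (r in seq_len(R)) {
        eta <- rnorm(S, 0, cfg$sigma_tech)
        out[[length(out) + 1]] <- tibble(
          gene_id = g, sample = colnames(v), replicate = r,
          ct = unname(base_ct + eta), group = grp
        )
      }
    }
  }
  bind_rows(out)
}

#' Simulate a primer-efficiency dilution series
#'
#' CT at dilution d is `a + log_(1+E)(d) + noise`: with perfect doubling
#' (E = 1) the series gains exactly one cycle per twofold dilution, so
#' [fit_efficiency()] recovers E and R^2 = 1 on noiseless input.
#'
#' @param true_efficiency Amplification efficiency E in (0, 1.2].
#' @param dilutions Dilution factors; default the twofold series
#'   c(1, 2, 4, 8, 16).
#' @param intercept CT of the undiluted sample; default 20.
#' @param noise_sd SD of CT noise; default 0.
#' @param gene_id Label for the series; default "series".
#' @param seed Optional integer seed.
#' @return A tibble `gene_id`, `dilution`, `ct`.
#' @examples
#' fit_efficiency(simulate_dilution(0.9))$efficiency # 0.9
#' @export
simulate_dilution <- function(true_efficiency = 1,
                              dilutions = c(1, 2, 4, 8, 16),
                              intercept = 20, noise_sd = 0,
                              gene_id = "series", seed = NULL) {
  if (true_efficiency <= 0 || true_efficiency > 1.2) {
    abort("`true_efficiency` must be in (0, 1.2]")
  }
  stopifnot(all(dilutions > 0))
  if (!is.null(seed)) set.seed(seed)
  ct <- intercept + log(dilutions, base = 1 + true_efficiency) +
    rnorm(length(dilutions), 0, noise_sd)
  tibble(gene_id = gene_id, dilution = dilutions, ct = ct)
}
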