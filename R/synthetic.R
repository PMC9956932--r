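#' Specification for the two-strain count simulator
#'
#' Describes a synthetic bulk RNA-seq experiment shaped like a two-strain
#' mouse comparison: 10 + 11 replicates, a few thousand genes with
#' log-normal baselines, negative-binomial counts, a small fraction of
#' genes with a strain-shifted mean, a small fraction with equal means but
#' inflated dispersion in one strain, and a few genes forced to contain a
#' zero so the zero filter has work to do.
#'
#' @param n_genes number of genes.
#' @param n_samples_1,n_samples_2 replicates per strain (defaults 10, 11).
#' @param frac_mean_de fraction of genes with a strain-shifted mean.
#' @param mean_lfc log2 fold-change magnitude planted in mean-DE genes
#'   (applied to strain 2, sign random per gene).
#' @param frac_std_de fraction of genes with equal means but dispersion
#'   multiplied by `dispersion_ratio` in one randomly chosen strain.
#' @param dispersion_ratio dispersion inflation factor for std-DE genes.
#' @param baseline_log_mean,baseline_log_sd mean and sd of the per-gene
#'   baseline on the log2 scale (baselines are log-normal).
#' @param nb_dispersion negative-binomial dispersion phi, so that
#'   `Var = mu + phi * mu^2` (`size = 1/phi` in [stats::rnbinom()]).
#' @param zero_gene_frac fraction of (otherwise null) genes that get one
#'   randomly chosen sample zeroed out.
#' @param seed integer seed; the whole draw is reproducible from it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_genes = 2000L, n_samples_1 = 10L,
                           n_samples_2 = 11L,
                           frac_mean_de = 0.025, mean_lfc = 2.0,
                           frac_std_de = 0.015, dispersion_ratio = 4,
                           baseline_log_mean = 6, baseline_log_sd = 1.25,
                           nb_dispersion = 0.1, zero_gene_frac = 0.05,
                           seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_1 = as.integer(n_samples_1),
               n_samples_2 = as.integer(n_samples_2),
               frac_mean_de = frac_mean_de, mean_lfc = mean_lfc,
               frac_std_de = frac_std_de, dispersion_ratio = dispersion_ratio,
               baseline_log_mean = baseline_log_mean,
               baseline_log_sd = baseline_log_sd,
               nb_dispersion = nb_dispersion,
               zero_gene_frac = zero_gene_frac, seed = as.integer(seed))
  fracs <- c(spec$frac_mean_de, spec$frac_std_de, spec$zero_gene_frac)
  if (any(fracs < 0) || any(fracs > 1) || sum(fracs) > 1)
    stop("validation error: fractions must lie in [0,1] and sum to <= 1")
  if (spec$n_genes < 1L) stop("validation error: n_genes must be >= 1")
  if (spec$n_samples_1 < 2L || spec$n_samples_2 < 2L)
    stop("validation error: each strain needs >= 2 samples")
  if (spec$mean_lfc < 0) stop("validation error: mean_lfc must be >= 0")
  if (spec$dispersion_ratio <= 0 || spec$nb_dispersion <= 0)
    stop("validation error: dispersions must be > 0")
  structure(spec, class = "synthetic_spec")
}

#' Simulate a two-strain count matrix with known DE truth
#'
#' Gene baselines are drawn log-normally on the log2 scale; counts are
#' negative-binomial per sample. Mean-DE genes have strain 2's mean
#' multiplied by `2^(s * mean_lfc)` with a random sign `s`; std-DE genes
#' keep equal means but one strain's dispersion is multiplied by
#' `dispersion_ratio`; zeroed genes get exactly one sample set to 0 so the
#' zero filter removes them. Fully reproducible from `spec$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `counts` (raw [expression_matrix()]),
#'   `design` ([strain_design()] with labels "strainA"/"strainB") and
#'   `truth` (data.frame: `gene_id`, `class` in null/mean_de/std_de/zeroed,
#'   `lfc` signed planted log2 fold change, `inflated_strain`).
#' @export
simulate_counts <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  restore <- local_rng(spec$seed)
  on.exit(restore())

  n <- spec$n_genes
  n1 <- spec$n_samples_1
  n2 <- spec$n_samples_2
  gene_id <- sprintf("gene%05d", seq_len(n))
  sid <- c(sprintf("A%02d", seq_len(n1)), sprintf("B%02d", seq_len(n2)))
  strain <- rep(c("strainA", "strainB"), c(n1, n2))

  n_mean <- round(spec$frac_mean_de * n)
  n_std <- round(spec$frac_std_de * n)
  n_zero <- round(spec$zero_gene_frac * n)
  cls <- rep("null", n)
  picked <- sample.int(n, n_mean + n_std + n_zero)
  cls[picked[seq_len(n_mean)]] <- "mean_de"
  cls[picked[n_mean + seq_len(n_std)]] <- "std_de"
  cls[picked[n_mean + n_std + seq_len(n_zero)]] <- "zeroed"

  base_log2 <- stats::rnorm(n, spec$baseline_log_mean, spec$baseline_log_sd)
  mu1 <- 2^base_log2
  lfc <- numeric(n)
  is_mean <- cls == "mean_de"
  lfc[is_mean] <- spec$mean_lfc * sample(c(-1, 1), sum(is_mean), replace = TRUE)
  mu2 <- mu1 * 2^lfc

  phi1 <- rep(spec$nb_dispersion, n)
  phi2 <- rep(spec$nb_dispersion, n)
  inflated <- rep(NA_character_, n)
  is_std <- cls == "std_de"
  if (any(is_std)) {
    which_strain <- sample(c("strainA", "strainB"), sum(is_std), replace = TRUE)
    inflated[is_std] <- which_strain
    phi1[is_std][which_strain == "strainA"] <-
      spec$nb_dispersion * spec$dispersion_ratio
    phi2[is_std][which_strain == "strainB"] <-
      spec$nb_dispersion * spec$dispersion_ratio
  }

  counts <- matrix(0, nrow = n, ncol = n1 + n2, dimnames = list(gene_id, sid))
  for (j in seq_len(n1))
    counts[, j] <- stats::rnbinom(n, size = 1 / phi1, mu = mu1)
  for (j in seq_len(n2))
    counts[, n1 + j] <- stats::rnbinom(n, size = 1 / phi2, mu = mu2)
  # zeroed genes: force one zero; everything else strictly positive so the
  # planted truth classes and the zero filter coincide exactly
  counts[counts == 0] <- 1
  is_zeroed <- cls == "zeroed"
  if (any(is_zeroed))
    counts[cbind(which(is_zeroed),
                 sample.int(n1 + n2, sum(is_zeroed), replace = TRUE))] <- 0

  list(counts = expression_matrix(counts, scale = "raw"),
       design = strain_design(sid, strain),
       truth = data.frame(gene_id = gene_id, class = cls, lfc = lfc,
                          inflated_strain = inflated,
                          stringsAsFactors = FALSE))
}

#' Recovery metrics of a call set against simulation truth
#'
#' Sensitivity is the fraction of true-effect genes (classes `mean_de` and
#' `std_de`) that were called, computed among genes that survived the zero
#' filter; the false-positive rate is the fraction of surviving null genes
#' that were called.
#'
#' @param calls a `de_calls` object whose `gene_ids_retained` attribute
#'   records the post-filter gene universe (as set by [run_pipeline()]),
#'   or any data.frame with a `gene_id` column plus an explicit `retained`
#'   argument.
#' @param truth truth table from [simulate_counts()].
#' @param retained character vector of genes surviving the zero filter;
#'   defaults to `attr(calls, "gene_ids_retained")`.
#' @return A list with `sensitivity`, `fpr`, and `by_class` (data.frame
#'   with per-class totals, retained and flagged counts).
#' @export
truth_metrics <- function(calls, truth,
                          retained = attr(calls, "gene_ids_retained")) {
  if (is.null(retained))
    stop("`retained` gene universe missing; pass the pipeline's call set or supply it")
  flagged <- unique(calls$gene_id)
  if (!all(flagged %in% truth$gene_id))
    stop("mismatched gene ids: calls contain genes absent from the truth table")
  tr <- truth
  tr$retained <- tr$gene_id %in% retained
  tr$flagged <- tr$gene_id %in% flagged
  eff <- tr$class %in% c("mean_de", "std_de") & tr$retained
  null_ret <- tr$class == "null" & tr$retained
  by_class <- do.call(rbind, lapply(split(tr, tr$class), function(d)
    data.frame(class = d$class[1L], n_total = nrow(d),
               n_retained = sum(d$retained), n_flagged = sum(d$flagged),
               stringsAsFactors = FALSE)))
  rownames(by_class) <- NULL
  list(sensitivity = if (any(eff)) sum(tr$flagged[eff]) / sum(eff) else NA_real_,
       fpr = if (any(null_ret)) sum(tr$flagged[null_ret]) / sum(null_ret) else NA_real_,
       by_class = by_class)
}
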