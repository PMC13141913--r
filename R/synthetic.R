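#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generators with the defaults
#' the test fixtures use: a miniature longitudinal cohort (8 infants x 10
#' samples) and a small bacterial database with planted prophages. All
#' generators are pure functions of this object: the same config yields
#' byte-identical output.
#'
#' @param seed Integer RNG seed.
#' @param n_bacterial_contigs Number of bacterial contigs to simulate.
#' @param prophage_rate Fraction of contigs carrying a planted prophage.
#' @param contig_length_range Length range (bp) of bacterial contigs.
#' @param prophage_length_range Length range (bp) of planted prophages.
#' @param planted_identity Percent identity reported for planted hits.
#' @param planted_coverage Query-coverage fraction reported for planted hits.
#' @param classifier_error \code{c(false_pos_rate, false_neg_rate)} for the
#'   score generators.
#' @param degenerate_scores Use degenerate 1.0/0.0 scores instead of Beta
#'   draws (for exact-recovery fixtures).
#' @param n_infants Number of infant time series.
#' @param samples_per_infant Samples per infant.
#' @param effect_sizes Named list of fixed effects on the log (Gaussian) or
#'   log-odds (binomial) scale: \code{treatment}, \code{delivery},
#'   \code{age}.
#' @param random_intercept_sd SD of the per-infant random intercept.
#' @param residual_sd Residual SD of the Gaussian response.
#' @param intercept Fixed intercept b0.
#' @return Named list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1,
                       n_bacterial_contigs = 100L,
                       prophage_rate = 0.4,
                       contig_length_range = c(5000L, 20000L),
                       prophage_length_range = c(1000L, 5000L),
                       planted_identity = 95,
                       planted_coverage = 1.0,
                       classifier_error = c(false_pos_rate = 0.05,
                                            false_neg_rate = 0.05),
                       degenerate_scores = FALSE,
                       n_infants = 8L,
                       samples_per_infant = 10L,
                       effect_sizes = list(treatment = 0.8, delivery = 0.5,
                                           age = 1.0),
                       random_intercept_sd = 0.5,
                       residual_sd = 0.5,
                       intercept = 0) {
  stopifnot(prophage_rate >= 0, prophage_rate <= 1,
            all(classifier_error >= 0), all(classifier_error <= 1),
            n_infants >= 2, samples_per_infant >= 2,
            contig_length_range[1] > 0,
            prophage_length_range[1] > 0)
  cfg <- list(seed = as.integer(seed),
              n_bacterial_contigs = as.integer(n_bacterial_contigs),
              prophage_rate = prophage_rate,
              contig_length_range = as.integer(contig_length_range),
              prophage_length_range = as.integer(prophage_length_range),
              planted_identity = planted_identity,
              planted_coverage = planted_coverage,
              classifier_error = classifier_error,
              degenerate_scores = degenerate_scores,
              n_infants = as.integer(n_infants),
              samples_per_infant = as.integer(samples_per_infant),
              effect_sizes = effect_sizes,
              random_intercept_sd = random_intercept_sd,
              residual_sd = residual_sd,
              intercept = intercept)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Introduce uniform random substitutions into a sequence
#'
#' Mutation operator for dereplication fixtures: each position is
#' substituted with probability \code{rate} by one of the three other bases.
#'
#' @param seq Character sequence or \code{DNAString}.
#' @param rate Per-base substitution probability.
#' @return Mutated character sequence.
#' @export
mutate_sequence <- function(seq, rate) {
  s <- strsplit(as.character(seq), "")[[1]]
  hit <- which(stats::runif(length(s)) < rate)
  for (i in hit) {
    s[i] <- sample(setdiff(c("A", "C", "G", "T"), s[i]), 1)
  }
  paste(s, collapse = "")
}

#' Simulate a bacterial database with planted prophages
#'
#' Random bacterial contigs; a configured fraction receives one planted
#' prophage insertion at a recorded coordinate. The generator also emits the
#' matching BLAST-style hit table at the configured planted identity and
#' query coverage, so the unphaging threshold behaviour is testable: hits
#' planted below the 70/0.70 thresholds must excise nothing.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{contigs} (\code{DNAStringSet}, prophages included in
#'   the sequences), \code{hits} (data.frame in \code{\link{read_blast_tab}}
#'   layout), \code{truth} (data.frame \code{contig_id}, \code{start},
#'   \code{end} 0-based half-open, \code{query_id}).
#' @export
simulate_database <- function(config) {
  set.seed(config$seed)
  n <- config$n_bacterial_contigs
  lr <- config$contig_length_range
  pr <- config$prophage_length_range
  seqs <- character(n)
  truth <- vector("list", n)
  hits <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("bact_%03d", i)
    blen <- sample(lr[1]:lr[2], 1)
    seq <- random_dna(blen)
    if (stats::runif(1) < config$prophage_rate) {
      plen <- sample(pr[1]:pr[2], 1)
      pseq <- random_dna(plen)
      at <- sample(0:blen, 1)                       # 0-based insertion point
      seq <- paste0(substr(seq, 1, at), pseq,
                    substr(seq, at + 1, blen))
      q <- sprintf("uhgv_%03d", i)
      truth[[i]] <- data.frame(contig_id = id, start = at, end = at + plen,
                               query_id = q, stringsAsFactors = FALSE)
      qlen <- round(plen / config$planted_coverage)
      hits[[i]] <- data.frame(
        query_id = q, subject_id = id,
        pct_identity = config$planted_identity,
        aln_length = plen,
        q_start = 1L, q_end = plen,
        s_start = at + 1L, s_end = at + plen,
        e_value = 0, query_length = qlen, query_length_known = TRUE,
        stringsAsFactors = FALSE)
    }
    seqs[i] <- seq
  }
  contigs <- Biostrings::DNAStringSet(seqs)
  names(contigs) <- sprintf("bact_%03d", seq_len(n))
  truth <- if (any(!vapply(truth, is.null, logical(1)))) do.call(rbind, truth) else
    data.frame(contig_id = character(0), start = integer(0),
               end = integer(0), query_id = character(0))
  hits <- if (any(!vapply(hits, is.null, logical(1)))) do.call(rbind, hits) else empty_hits()
  rownames(truth) <- rownames(hits) <- NULL
  list(contigs = contigs, hits = hits, truth = truth)
}

#' Simulate classifier score tables with planted truth
#'
#' True phages draw their PhaMer-like and MetaPhaPred-like scores from a
#' high Beta distribution, non-phages from a low one; with the configured
#' false-negative (false-positive) rate a true (non-) phage draws from the
#' wrong class instead. With \code{degenerate_scores} the distributions
#' collapse to 1.0 and 0.0 so zero error rates recover the truth exactly.
#'
#' @param contig_ids Character vector of contig IDs.
#' @param is_phage Logical planted-truth vector aligned with
#'   \code{contig_ids}.
#' @param config A \code{\link{sim_config}}.
#' @param shape_hi,shape_lo Beta shape pairs for the high and low score
#'   classes.
#' @return data.frame in \code{\link{read_scores_table}} layout plus an
#'   \code{is_phage} truth column.
#' @export
simulate_scores <- function(contig_ids, is_phage, config,
                            shape_hi = c(30, 1), shape_lo = c(1, 30)) {
  stopifnot(length(contig_ids) == length(is_phage))
  set.seed(config$seed + 1L)
  n <- length(contig_ids)
  fpr <- config$classifier_error[[1]]
  fnr <- config$classifier_error[[2]]
  # effective class after the flip
  flip <- stats::runif(n) < ifelse(is_phage, fnr, fpr)
  hi <- xor(is_phage, flip)
  draw <- function() {
    if (config$degenerate_scores) as.numeric(hi)
    else ifelse(hi, stats::rbeta(n, shape_hi[1], shape_hi[2]),
                stats::rbeta(n, shape_lo[1], shape_lo[2]))
  }
  data.frame(
    contig_id = contig_ids,
    phamer = draw(),
    metaphapred = draw(),
    deepvirfinder = draw(),
    virsorter2_viral = hi,
    kraken_bacterial = !hi,
    prophage_regions = I(replicate(n, matrix(integer(0), ncol = 2,
                                             dimnames = list(NULL, c("start", "end"))),
                                   simplify = FALSE)),
    is_phage = is_phage,
    stringsAsFactors = FALSE
  )
}

#' Simulate per-contig depth summaries for one sample
#'
#' Log-normal mean depths and Beta-distributed covered fractions, the raw
#' material of VRU computation.
#'
#' @param contig_ids Character vector.
#' @param seed Integer seed.
#' @param zero_rate Fraction of contigs with no mapped reads.
#' @return data.frame in \code{\link{depth_summary}} layout.
#' @export
simulate_depths <- function(contig_ids, seed = 1, zero_rate = 0.2) {
  set.seed(seed)
  n <- length(contig_ids)
  zero <- stats::runif(n) < zero_rate
  mdepth <- ifelse(zero, 0, stats::rlnorm(n, meanlog = 1, sdlog = 1))
  coverage <- ifelse(zero, 0, stats::rbeta(n, 5, 2))
  data.frame(contig_id = contig_ids, mdepth = mdepth, coverage = coverage,
             contig_length = sample(2000:50000, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate a longitudinal infant cohort
#'
#' Miniature version of the study design: each infant time series carries a
#' delivery mode (between infants, balanced), samples split across the two
#' age windows, and the phage-enrichment treatment applied to a subset of
#' each infant's samples (within infant, as in the study where a subset of
#' each series was enriched). The linear predictor is
#' b0 + b_treatment*PE + b_delivery*vaginal + b_age*age12 + R_j with
#' R_j ~ N(0, random_intercept_sd^2); the Gaussian response adds
#' N(0, residual_sd^2) noise on the log scale, the binomial response is
#' Bernoulli through the logistic link.
#'
#' @param config A \code{\link{sim_config}}.
#' @param family \code{"gaussian"} (log-abundance) or \code{"binomial"}
#'   (presence).
#' @return List: \code{meta} (validated sample metadata), \code{response}
#'   (numeric or 0/1 vector), \code{linear_predictor}, \code{truth} (the
#'   effect sizes used).
#' @export
simulate_cohort <- function(config, family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  set.seed(config$seed + 2L)
  ni <- config$n_infants
  ns <- config$samples_per_infant
  infant <- rep(sprintf("infant_%02d", seq_len(ni)), each = ns)
  delivery <- rep(rep(c("cesarean", "vaginal"), length.out = ni), each = ns)
  age <- unlist(lapply(seq_len(ni), function(i)
    rep(c("6", "12"), length.out = ns)))
  treatment <- unlist(lapply(seq_len(ni), function(i)
    sample(rep(c("control", "PE"), length.out = ns))))
  meta <- validate_sample_meta(data.frame(
    sample_id = sprintf("s%03d", seq_len(ni * ns)),
    infant_id = infant, age_months = age, delivery = delivery,
    treatment = treatment, stringsAsFactors = FALSE))
  es <- config$effect_sizes
  ri <- stats::rnorm(ni, 0, config$random_intercept_sd)
  eta <- config$intercept +
    es$treatment * (meta$treatment == "PE") +
    es$delivery * (meta$delivery == "vaginal") +
    es$age * (meta$age_months == "12") +
    ri[match(meta$infant_id, unique(meta$infant_id))]
  response <- if (family == "gaussian") {
    eta + stats::rnorm(nrow(meta), 0, config$residual_sd)
  } else {
    as.integer(stats::runif(nrow(meta)) < stats::plogis(eta))
  }
  list(meta = meta, response = response, linear_predictor = eta,
       truth = es)
}

#' Write a full fixture set to disk
#'
#' Emits the synthetic database, hits, scores, one depth table and the
#' cohort metadata in the exact file dialects the readers consume.
#'
#' @param config A \code{\link{sim_config}}.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_fixtures <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  db <- simulate_database(config)
  p <- c(
    fasta = file.path(dir, "database.fasta"),
    hits = file.path(dir, "hits.tsv"),
    qlens = file.path(dir, "query_lengths.tsv"),
    scores = file.path(dir, "scores.tsv"),
    depths = file.path(dir, "depths.tsv"),
    meta = file.path(dir, "meta.tsv")
  )
  write_fasta(db$contigs, p[["fasta"]])
  h <- db$hits
  out6 <- data.frame(h$query_id, h$subject_id, h$pct_identity, h$aln_length,
                     0L, 0L, h$q_start, h$q_end, h$s_start, h$s_end,
                     h$e_value, 100)
  utils::write.table(out6, p[["hits"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(unique(data.frame(query_id = h$query_id,
                                       length = h$query_length)),
                     p[["qlens"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_phage <- names(db$contigs) %in% db$truth$contig_id
  sc <- simulate_scores(names(db$contigs), truth_phage, config)
  sc$prophage_regions <- vapply(sc$prophage_regions, format_region_spec, character(1))
  utils::write.table(sc[setdiff(names(sc), "is_phage")], p[["scores"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dp <- simulate_depths(names(db$contigs), seed = config$seed + 3L)
  # sparse per-base depth table consistent with the summaries is large;
  # fixtures carry the summary layout instead
  utils::write.table(dp, p[["depths"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  co <- simulate_cohort(config)
  utils::write.table(co$meta, p[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p
}
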