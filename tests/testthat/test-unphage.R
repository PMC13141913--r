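mk_hit <- function(query_id = "v", subject_id = "b", pct_identity = 95,
                   aln_length = 800L, s_start = 1L, s_end = 800L,
                   query_length = 1000) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity, aln_length = aln_length,
             q_start = 1L, q_end = aln_length, s_start = s_start,
             s_end = s_end, e_value = 0, query_length = query_length,
             query_length_known = TRUE, stringsAsFactors = FALSE)
}

test_that("filter_hits applies inclusive identity and query-coverage thresholds", {
  expect_equal(nrow(filter_hits(mk_hit(pct_identity = 85, aln_length = 800L,
                                       query_length = 1000), 70, 0.70)), 1L)
  expect_equal(nrow(filter_hits(mk_hit(pct_identity = 69.9, aln_length = 900L,
                                       query_length = 1000), 70, 0.70)), 0L)
  # exact boundary: 70.0 identity and coverage exactly 0.70 both pass
  expect_equal(nrow(filter_hits(mk_hit(pct_identity = 70, aln_length = 700L,
                                       query_length = 1000), 70, 0.70)), 1L)
  # missing query length errors with the query name
  h <- mk_hit(); h$query_length_known <- FALSE
  expect_error(filter_hits(h, 70, 0.7), "v")
})

test_that("merge_intervals unions overlaps and adjacency", {
  iv <- data.frame(contig_id = "c", start = c(100L, 150L), end = c(200L, 300L),
                   source_query = c("q1", "q2"))
  m <- merge_intervals(iv)
  expect_equal(m$start, 100L)
  expect_equal(m$end, 300L)

  adj <- data.frame(contig_id = "c", start = c(100L, 200L), end = c(200L, 250L),
                    source_query = c("q1", "q2"))
  m2 <- merge_intervals(adj)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$end, 250L)
})

test_that("merge_intervals matches the per-base mask union oracle", {
  set.seed(101)
  for (rep in 1:10) {
    len <- 5000L
    n <- 50L
    s <- sample(0:(len - 10), n, replace = TRUE)
    e <- pmin(len, s + sample(5:400, n, replace = TRUE))
    iv <- data.frame(contig_id = "c", start = s, end = e,
                     source_query = sprintf("q%d", seq_len(n)))
    m <- merge_intervals(iv)
    expect_equal(mask_oracle(len, m), mask_oracle(len, iv))
    # pairwise disjoint and sorted
    expect_true(all(diff(m$start) > 0))
    expect_true(all(m$start[-1] > m$end[-nrow(m)]))
  }
})

test_that("excise_and_split conserves bases and drops short fragments", {
  ctg <- dss(c(big = rand_dna(10000)))
  res <- excise_and_split(ctg, data.frame(start = 2000L, end = 3000L),
                          min_fragment_len = 1L)
  expect_equal(sort(Biostrings::width(res$fragments)), c(2000L, 7000L))
  expect_equal(Biostrings::width(res$prophages), 1000L)
  expect_equal(as.character(res$prophages[[1]]),
               substr(as.character(ctg[[1]]), 2001, 3000))

  # no intervals: identity
  res0 <- excise_and_split(ctg, data.frame(start = integer(0), end = integer(0)),
                           min_fragment_len = 1L)
  expect_equal(as.character(res0$fragments[[1]]), as.character(ctg[[1]]))
  expect_equal(length(res0$prophages), 0L)

  # middle fragment of 100 bp dropped under a 2000 bp floor
  res2 <- excise_and_split(ctg, data.frame(start = c(0L, 4100L),
                                           end = c(4000L, 10000L)),
                           min_fragment_len = 2000L)
  expect_equal(length(res2$prophages), 2L)
  expect_equal(length(res2$fragments), 0L)
  expect_equal(res2$dropped_bp, 100L)

  expect_error(excise_and_split(ctg, data.frame(start = 0L, end = 10001L), 1L),
               "out of bounds")
})

test_that("unphage_database excises every planted base on a synthetic DB", {
  cfg <- sim_config(seed = 13, n_bacterial_contigs = 100, prophage_rate = 0.4,
                    planted_identity = 95)
  db <- simulate_database(cfg)
  res <- suppressMessages(unphage_database(db$contigs, db$hits,
                                           min_fragment_len = 1L))
  expect_equal(res$removed_count, nrow(db$truth))
  # every planted base is excised: fragments contain no planted positions
  for (id in db$truth$contig_id) {
    iv <- db$truth[db$truth$contig_id == id, ]
    expect_equal(res$per_contig_log$bp_removed[res$per_contig_log$contig_id == id],
                 sum(iv$end - iv$start))
  }
  # base conservation
  expect_equal(sum(Biostrings::width(res$fragments)) +
                 sum(Biostrings::width(res$prophages)) +
                 sum(res$per_contig_log$bp_dropped),
               sum(Biostrings::width(db$contigs)))
})

test_that("hits below threshold leave the database unchanged", {
  cfg <- sim_config(seed = 17, n_bacterial_contigs = 30, prophage_rate = 0.5,
                    planted_identity = 60)
  db <- simulate_database(cfg)
  res <- suppressMessages(unphage_database(db$contigs, db$hits,
                                           min_fragment_len = 1L))
  expect_equal(res$removed_count, 0L)
  expect_equal(as.character(res$fragments), as.character(db$contigs))
})

test_that("a fully covered contig yields one prophage and no fragments", {
  ctg <- dss(c(allviral = rand_dna(3000)))
  hit <- mk_hit(subject_id = "allviral", s_start = 1L, s_end = 3000L,
                aln_length = 3000L, query_length = 3000)
  res <- suppressMessages(unphage_database(ctg, hit, min_fragment_len = 1L))
  expect_equal(length(res$prophages), 1L)
  expect_equal(sum(res$per_contig_log$n_fragments), 0L)
})

test_that("unphaging an unphaged database removes nothing more", {
  cfg <- sim_config(seed = 19, n_bacterial_contigs = 20, prophage_rate = 0.5)
  db <- simulate_database(cfg)
  res <- suppressMessages(unphage_database(db$contigs, db$hits,
                                           min_fragment_len = 1L))
  again <- suppressMessages(unphage_database(res$fragments, empty_hits_df(),
                                             min_fragment_len = 1L))
  expect_equal(again$removed_count, 0L)
  expect_equal(sum(Biostrings::width(again$fragments)),
               sum(Biostrings::width(res$fragments)))
})

test_that("unphage report has the documented columns", {
  cfg <- sim_config(seed = 23, n_bacterial_contigs = 10)
  db <- simulate_database(cfg)
  res <- suppressMessages(unphage_database(db$contigs, db$hits))
  out <- tempfile(fileext = ".tsv")
  unphage_report(res, out)
  rep <- read.delim(out)
  expect_equal(names(rep), c("contig_id", "n_intervals", "bp_removed",
                             "n_fragments"))
  expect_equal(nrow(rep), 10L)
})
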