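test_that("length filter keeps the 2000 bp boundary inclusive", {
  ctgs <- dss(c(a = rand_dna(1999), b = rand_dna(2000), c = rand_dna(2001)))
  kept <- suppressMessages(length_filter(ctgs, 2000L))
  expect_equal(sort(names(kept)), c("b", "c"))
  expect_equal(length(suppressMessages(length_filter(dss(character(0))))), 0L)
})

test_that("length filter equals the comparison oracle on random lengths", {
  set.seed(7)
  lens <- sample(500:4000, 1000, replace = TRUE)
  ctgs <- Biostrings::DNAStringSet(vapply(lens, function(n)
    paste(rep("A", n), collapse = ""), character(1)))
  names(ctgs) <- sprintf("c%04d", seq_along(ctgs))
  kept <- suppressMessages(length_filter(ctgs, 2000L))
  expect_equal(names(kept), names(ctgs)[lens >= 2000])
})

test_that("extract_prophages excises predicted regions as candidates", {
  ctg <- dss(c(host = rand_dna(20000)))
  sc <- data.frame(contig_id = "host", stringsAsFactors = FALSE)
  sc$prophage_regions <- list(matrix(c(5000L, 15000L), ncol = 2,
                                     dimnames = list(NULL, c("start", "end"))))
  ex <- extract_prophages(ctg, sc, min_fragment_len = 1L)
  expect_equal(length(ex$candidates), 1L)
  expect_equal(Biostrings::width(ex$candidates), 10000L)
  expect_equal(as.character(ex$candidates[[1]]),
               substr(as.character(ctg[[1]]), 5001, 15000))
  expect_equal(unname(ex$parent["host_pp1"]), "host")

  # no regions: contig passes unchanged
  sc0 <- data.frame(contig_id = "host", stringsAsFactors = FALSE)
  sc0$prophage_regions <- list(matrix(integer(0), ncol = 2))
  ex0 <- extract_prophages(ctg, sc0, min_fragment_len = 1L)
  expect_equal(length(ex0$candidates), 0L)
  expect_equal(as.character(ex0$host_fragments[[1]]), as.character(ctg[[1]]))
})

test_that("overlapping predictor regions are merged before excision", {
  ctg <- dss(c(host = rand_dna(20000)))
  sc <- data.frame(contig_id = "host", stringsAsFactors = FALSE)
  # CheckV-style and PhageBoost-style overlapping calls
  sc$prophage_regions <- list(matrix(c(4000L, 12000L, 10000L, 15000L),
                                     ncol = 2, byrow = TRUE))
  ex <- extract_prophages(ctg, sc, min_fragment_len = 1L)
  expect_equal(length(ex$candidates), 1L)
  expect_equal(Biostrings::width(ex$candidates), 11000L)
  # mask oracle: candidate covers exactly the union
  expect_equal(as.character(ex$candidates[[1]]),
               substr(as.character(ctg[[1]]), 4001, 15000))
})

test_that("bacterial parents are dropped while their candidates survive", {
  ctgs <- dss(c(bac = rand_dna(3000), vir = rand_dna(3000),
                bac_pp1 = rand_dna(2500)))
  sc <- data.frame(contig_id = c("bac", "vir", "bac_pp1"),
                   kraken_bacterial = c(TRUE, FALSE, FALSE))
  kept <- suppressMessages(remove_bacterial(ctgs, sc))
  expect_equal(sort(names(kept)), c("bac_pp1", "vir"))
})

test_that("remove_bacterial survivor set equals planted truth on 200 contigs", {
  set.seed(31)
  n <- 200
  ids <- sprintf("c%03d", 1:n)
  bact <- runif(n) < 0.5
  ctgs <- Biostrings::DNAStringSet(rep("ACGT", n))
  names(ctgs) <- ids
  sc <- data.frame(contig_id = ids, kraken_bacterial = bact)
  kept <- suppressMessages(remove_bacterial(ctgs, sc))
  expect_equal(names(kept), ids[!bact])
})

test_that("consensus rule: phamer threshold AND strict score-sum agreement", {
  sc <- data.frame(contig_id = c("a", "b", "c"),
                   phamer = c(0.95, 0.95, 0.60),
                   metaphapred = c(0.20, 0.05, 0.60))
  dec <- consensus_classify(sc)
  expect_equal(dec$verdict, c("phage", "non_phage", "non_phage"))
  # missing metaphapred treated as 0
  sc2 <- data.frame(contig_id = "d", phamer = 0.95, metaphapred = NA_real_)
  expect_equal(consensus_classify(sc2)$verdict, "non_phage")
  sc3 <- data.frame(contig_id = "e", phamer = NA_real_, metaphapred = 0.9)
  expect_error(consensus_classify(sc3), "e")
})

test_that("consensus decision is monotone in both scores", {
  set.seed(11)
  for (i in 1:200) {
    ph <- runif(1); mp <- runif(1)
    d1 <- consensus_classify(data.frame(contig_id = "x", phamer = ph,
                                        metaphapred = mp))$verdict
    d2 <- consensus_classify(data.frame(contig_id = "x",
                                        phamer = min(1, ph + runif(1) * (1 - ph)),
                                        metaphapred = min(1, mp + runif(1) * (1 - mp))))$verdict
    expect_false(d1 == "phage" && d2 == "non_phage")
  }
})

test_that("supplementary classifiers annotate but do not flip by default", {
  sc <- data.frame(contig_id = "a", phamer = 0.5, metaphapred = 0.9,
                   deepvirfinder = 0.99, virsorter2_viral = TRUE)
  dec <- consensus_classify(sc)
  expect_equal(dec$verdict, "non_phage")
  expect_match(dec$reason, "dvf=0.990")
  dec2 <- consensus_classify(sc, dvf_rescue = TRUE)
  expect_equal(dec2$verdict, "phage")
  expect_match(dec2$reason, "rescued")
})

test_that("mining cascade order does not matter for per-contig predicates", {
  set.seed(41)
  n <- 60
  ids <- sprintf("c%02d", 1:n)
  lens <- sample(1000:4000, n, replace = TRUE)
  ctgs <- Biostrings::DNAStringSet(vapply(lens, function(k)
    paste(rep("A", k), collapse = ""), character(1)))
  names(ctgs) <- ids
  sc <- data.frame(contig_id = ids, phamer = runif(n), metaphapred = runif(n))
  dec <- consensus_classify(sc)
  phage_ids <- dec$contig_id[dec$verdict == "phage"]
  a <- names(suppressMessages(length_filter(ctgs[names(ctgs) %in% phage_ids], 2000L)))
  after <- suppressMessages(length_filter(ctgs, 2000L))
  b <- intersect(names(after), phage_ids)
  expect_equal(sort(a), sort(b))
})

test_that("consensus recall/precision match the rule's closed-form expectation", {
  cfg <- sim_config(seed = 47, classifier_error = c(0, 0))
  n <- 4000
  truth <- rep(c(TRUE, FALSE), n / 2)
  sc <- simulate_scores(sprintf("c%04d", 1:n), truth, cfg)
  dec <- consensus_classify(sc)
  called <- dec$verdict == "phage"
  # closed-form expectation by direct Monte Carlo integration of the rule
  # over the generator's Beta score distributions (independent oracle)
  set.seed(99)
  m <- 2e5
  hi1 <- rbeta(m, 30, 1); hi2 <- rbeta(m, 30, 1)
  lo1 <- rbeta(m, 1, 30); lo2 <- rbeta(m, 1, 30)
  p_call_phage <- mean(hi1 >= 0.9 & (hi1 + hi2) > 1)
  p_call_nonphage <- mean(lo1 >= 0.9 & (lo1 + lo2) > 1)
  recall <- mean(called[truth])
  fpr <- mean(called[!truth])
  expect_lt(abs(recall - p_call_phage), 3 * sqrt(p_call_phage * (1 - p_call_phage) / (n / 2)) + 0.01)
  expect_lt(abs(fpr - p_call_nonphage), 0.01)
})

test_that("mine_phages runs the full cascade on a planted fixture", {
  cfg <- sim_config(seed = 53, n_bacterial_contigs = 40, prophage_rate = 0.5,
                    degenerate_scores = TRUE, classifier_error = c(0, 0),
                    contig_length_range = c(4000L, 8000L),
                    prophage_length_range = c(2500L, 4000L))
  db <- simulate_database(cfg)
  truth_phage <- names(db$contigs) %in% db$truth$contig_id
  sc <- simulate_scores(names(db$contigs), truth_phage, cfg)
  # contigs with planted prophages carry the predicted region coordinates
  sc$prophage_regions <- lapply(names(db$contigs), function(id) {
    t <- db$truth[db$truth$contig_id == id, ]
    if (nrow(t) == 0) return(matrix(integer(0), ncol = 2))
    matrix(c(t$start, t$end), ncol = 2)
  })
  # parents are bacterial; their excised candidates are the phages
  sc$kraken_bacterial <- TRUE
  res <- suppressMessages(mine_phages(db$contigs, sc, default_config()))
  # every kept contig is an excised prophage candidate
  expect_true(all(grepl("_pp\\d+$", names(res$phage_contigs))))
  # the candidates recover the planted prophages that meet the length floor
  big <- db$truth[db$truth$end - db$truth$start >= 2000, ]
  expect_equal(sum(grepl("_pp", names(res$phage_contigs))), nrow(big))
})
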