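# Contig post-processing: N-splitting, N50, assembly selection, cereal
# contig removal, domain classification.

test_that("scaffolds split at N runs and keep only pieces over 500 bp", {
  sc <- tibble::tibble(
    id = c("sc1", "sc2", "sc3"),
    sequence = c(
      paste0(strrep("A", 600), "N", strrep("C", 599)),  # two ~600 bp pieces
      strrep("G", 400),                                  # too short
      paste0(strrep("T", 500), "NN", strrep("A", 501))   # 500 exact dropped
    )
  )
  out <- split_and_filter(sc)
  expect_equal(out$contig_id, c("sc1_1", "sc1_2", "sc3_2"))
  expect_equal(out$length, c(600, 599, 501))
  expect_false(any(grepl("N", out$sequence)))
  # named-vector input works too
  v <- c(x = paste0(strrep("A", 501), "NNN", strrep("C", 502)))
  expect_equal(split_and_filter(v)$length, c(501, 502))
})

test_that("N50 follows the cumulative-sum definition", {
  expect_equal(n50(1000), 1000)
  expect_equal(n50(c(500, 600, 700, 800)), 700)
  expect_equal(n50(tibble::tibble(length = c(500, 600, 700, 800))), 700)
  expect_error(n50(numeric(0)), "empty")
  set.seed(41)
  for (i in 1:100) {
    lens <- sample(100:5000, sample(1:40, 1), replace = TRUE)
    got <- n50(lens)
    # brute force over candidate lengths
    cands <- sort(unique(lens))
    ok <- cands[vapply(cands, function(L) {
      sum(lens[lens >= L]) >= sum(lens) / 2
    }, logical(1))]
    expect_equal(got, max(ok))
    expect_gte(got, min(lens))
    expect_lte(got, max(lens))
    expect_equal(n50(lens[sample.int(length(lens))]), got)  # order invariant
  }
})

test_that("assembly selection maximises N50 with declared tie-breaks", {
  c1 <- list(kmer = 39, contig_lengths = c(10000, 500))
  c2 <- list(kmer = 43, contig_lengths = c(12000, 400))
  expect_equal(select_best_assembly(list(c1, c2))$kmer, 43)
  expect_equal(select_best_assembly(list(c1))$kmer, 39)
  # N50 tie -> larger total length wins
  t1 <- list(kmer = 47, contig_lengths = c(1000, 1000))
  t2 <- list(kmer = 51, contig_lengths = c(1000, 1000, 900))
  expect_equal(select_best_assembly(list(t1, t2))$kmer, 51)
  # full tie -> smaller k-mer
  t3 <- list(kmer = 55, contig_lengths = c(1000, 1000, 900))
  expect_equal(select_best_assembly(list(t3, t2))$kmer, 51)
  expect_error(select_best_assembly(list()), "no assembly")
})

test_that("cereal contigs are removed at >=90% coverage and >=95% identity", {
  contigs <- tibble::tibble(contig_id = c("k1", "k2", "k3"),
                            length = c(1000, 1000, 1000))
  aln <- tibble::tibble(
    query = c("k1", "k2", "k3"),
    subject = "rice|chr1",
    identity = c(0.99, 0.99, 0.94),
    length = c(1000, 890, 950),
    qstart = c(1, 1, 1), qend = c(1000, 890, 950)
  )
  res <- remove_cereal_contigs(contigs, aln)
  expect_equal(res$contigs$contig_id, c("k2", "k3"))  # 89% cov / 94% id kept
  expect_equal(res$removed$contig_id, "k1")
  # monotone: adding a qualifying hit can only remove
  more <- dplyr::bind_rows(aln, tibble::tibble(
    query = "k2", subject = "rice|chr1", identity = 0.99,
    length = 200, qstart = 801, qend = 1000
  ))
  res2 <- remove_cereal_contigs(contigs, more)
  expect_true(all(res2$contigs$contig_id %in% res$contigs$contig_id))
  expect_setequal(res2$removed$contig_id, c("k1", "k2"))
})

test_that("hit coverage merges overlapping intervals like a brute-force union", {
  set.seed(43)
  for (i in 1:30) {
    k <- sample(1:6, 1)
    starts <- sample(1:900, k, replace = TRUE)
    ends <- pmin(starts + sample(10:300, k, replace = TRUE), 1000)
    aln <- tibble::tibble(query = "c", subject = "g|x", identity = 1,
                          length = ends - starts + 1,
                          qstart = starts, qend = ends)
    res <- remove_cereal_contigs(
      tibble::tibble(contig_id = "c", length = 1000), aln,
      min_coverage = 0, min_identity = 0
    )
    covered <- logical(1000)
    for (j in seq_len(k)) covered[starts[j]:ends[j]] <- TRUE
    expect_equal(res$removed$coverage, sum(covered) / 1000)
  }
})

test_that("domain classification follows the three-step procedure", {
  # step 1: predictable by exactly one predictor
  fungal_only <- tibble::tibble(gene_id = c("a", "b"),
                                predictable_by = "fungal_predictor",
                                nr_domain = NA, nr_evalue = NA, m8_score = NA)
  expect_equal(classify_contig_domain(fungal_only), "fungi")
  both <- tibble::tibble(
    gene_id = "a", predictable_by = "bacterial_predictor,fungal_predictor",
    nr_domain = NA_character_, nr_evalue = NA_real_, m8_score = NA_real_
  )
  # step 2: qualifying genome hit, best bit score wins
  hits <- tibble::tibble(
    domain = c("bacteria", "fungi"),
    identity = c(0.96, 0.99), coverage = c(0.95, 0.2),
    overlap = c(500, 90), bitscore = c(300, 800)
  )
  expect_equal(classify_contig_domain(both, hits), "bacteria")
  hits2 <- hits
  hits2$overlap[2] <- 150  # fungi now qualifies via overlap > 100, higher score
  expect_equal(classify_contig_domain(both, hits2), "fungi")
  none <- hits
  none$identity <- 0.90    # nothing qualifies -> fall through to step 3
  expect_equal(classify_contig_domain(both, none), "unclassified")
})

test_that("step-3 voting uses the 40% rule with mean-score tie-break", {
  mk_genes <- function(domains, scores, evalues = 1e-20) {
    n <- length(domains)
    tibble::tibble(
      gene_id = sprintf("g%02d", 1:n),
      predictable_by = "bacterial_predictor,fungal_predictor",
      nr_domain = domains, nr_evalue = evalues, m8_score = scores
    )
  }
  # 4 bacterial vs 3 fungal labels (10 genes, 3 unlabeled): unique max >= 40%
  g <- mk_genes(c(rep("bacteria", 4), rep("fungi", 3), rep(NA, 3)),
                scores = 50)
  expect_equal(classify_contig_domain(g), "bacteria")
  # balanced 4 vs 4: mean m8 score decides
  tie <- mk_genes(rep(c("bacteria", "fungi"), each = 4),
                  scores = c(rep(80, 4), rep(60, 4)))
  expect_equal(classify_contig_domain(tie), "bacteria")
  tie2 <- mk_genes(rep(c("bacteria", "fungi"), each = 4),
                   scores = c(rep(60, 4), rep(90, 4)))
  expect_equal(classify_contig_domain(tie2), "fungi")
  # NR labels above the E-value cutoff are ignored
  weak <- mk_genes(rep("fungi", 3), scores = 50, evalues = 1e-8)
  expect_equal(classify_contig_domain(weak), "unclassified")
  # counting unlabeled genes in the denominator is configurable: under the
  # "all" base neither domain reaches 40% here, so the score fallback flips
  # the call to the better-scoring minority
  sparse <- mk_genes(c(rep("bacteria", 3), rep("fungi", 2), rep(NA, 5)),
                     scores = c(rep(50, 3), rep(90, 2), rep(NA, 5)))
  expect_equal(classify_contig_domain(sparse, vote_base = "labeled"),
               "bacteria")
  expect_equal(classify_contig_domain(sparse, vote_base = "all"), "fungi")
  empty <- mk_genes("bacteria", 50)[0, ]
  expect_equal(classify_contig_domain(empty), "unclassified")
})

test_that("planted contig domains are recovered in all unambiguous fixtures", {
  set.seed(47)
  truth <- tibble::tibble(
    contig_id = sprintf("ctg%02d", 1:20),
    domain = sample(c("bacteria", "fungi"), 20, replace = TRUE)
  )
  gene_evidence <- purrr::map_dfr(seq_len(20), function(i) {
    d <- truth$domain[i]
    n_genes <- sample(3:8, 1)
    tibble::tibble(
      contig_id = truth$contig_id[i],
      gene_id = sprintf("g%d_%d", i, seq_len(n_genes)),
      predictable_by = "bacterial_predictor,fungal_predictor",
      nr_domain = d, nr_evalue = 10^-runif(n_genes, 11, 40),
      m8_score = runif(n_genes, 50, 500)
    )
  })
  got <- classify_contigs(gene_evidence)
  expect_equal(dplyr::arrange(got, contig_id)$domain,
               dplyr::arrange(truth, contig_id)$domain)
})
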