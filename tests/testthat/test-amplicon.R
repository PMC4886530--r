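# Amplicon profiling: QC boundaries, dereplication, clustering, chimera
# screening, tag mapping, rarefaction and genus profiling.

make_tag <- function(seq, mean_q = 35, sample_id = "S1", id = "t1") {
  tibble::tibble(tag_id = id, sample_id = sample_id, sequence = seq,
                 quality = strrep(intToUtf8(mean_q + 33), nchar(seq)))
}

test_that("tag QC applies the marker length window, Q20 mean and N cap", {
  seq350 <- strrep("A", 350)
  expect_equal(nrow(qc_filter_tags(make_tag(strrep("A", 349)), "16S")), 0)
  expect_equal(nrow(qc_filter_tags(make_tag(seq350), "16S")), 1)
  expect_equal(nrow(qc_filter_tags(make_tag(strrep("A", 500)), "16S")), 1)
  expect_equal(nrow(qc_filter_tags(make_tag(strrep("A", 501)), "16S")), 0)
  # ITS window differs
  expect_equal(nrow(qc_filter_tags(make_tag(strrep("A", 310)), "ITS")), 1)
  expect_equal(nrow(qc_filter_tags(make_tag(strrep("A", 310)), "16S")), 0)
  # N cap: 3 kept, 4 removed
  with_n <- function(k) paste0(strrep("N", k), strrep("A", 360 - k))
  expect_equal(nrow(qc_filter_tags(make_tag(with_n(3)), "16S")), 1)
  expect_equal(nrow(qc_filter_tags(make_tag(with_n(4)), "16S")), 0)
  # mean Phred boundary: exactly 20 kept, below removed
  expect_equal(nrow(qc_filter_tags(make_tag(seq350, mean_q = 20), "16S")), 1)
  expect_equal(nrow(qc_filter_tags(make_tag(seq350, mean_q = 19), "16S")), 0)
  empty <- make_tag(seq350)[0, ]
  expect_equal(nrow(qc_filter_tags(empty, "16S")), 0)
  expect_error(qc_filter_tags(make_tag(seq350), "18S"))
})

test_that("tag QC agrees with an independent per-criterion filter", {
  set.seed(42)
  n <- 400
  lens <- sample(330:520, n, replace = TRUE)
  tags <- tibble::tibble(
    tag_id = sprintf("t%03d", 1:n), sample_id = "S1",
    sequence = vapply(lens, function(l) {
      s <- rand_seq(l)
      k <- sample(0:5, 1)
      if (k > 0) {
        pos <- sample(l, k)
        s <- paste(replace(strsplit(s, "")[[1]], pos, "N"), collapse = "")
      }
      s
    }, character(1)),
    quality = vapply(lens, function(l) {
      intToUtf8(sample(10:40, l, replace = TRUE) + 33L)
    }, character(1))
  )
  kept <- qc_filter_tags(tags, "16S")
  oracle_keep <- vapply(seq_len(n), function(i) {
    s <- tags$sequence[i]
    q <- utf8ToInt(tags$quality[i]) - 33L
    nchar(s) >= 350 && nchar(s) <= 500 &&
      mean(q) >= 20 &&
      lengths(regmatches(s, gregexpr("N", s))) <= 3
  }, logical(1))
  expect_identical(kept$tag_id, tags$tag_id[oracle_keep])
})

test_that("dereplication conserves counts and flags singletons", {
  tags <- tibble::tibble(sequence = c("AAA", "AAA", "CCC"))
  u <- dereplicate_tags(tags)
  expect_equal(u$count[u$sequence == "AAA"], 2)
  expect_true(u$singleton[u$sequence == "CCC"])
  expect_false(u$singleton[u$sequence == "AAA"])
  set.seed(1)
  pool <- replicate(30, rand_seq(20))
  tags <- tibble::tibble(sequence = sample(pool, 200, replace = TRUE))
  u <- dereplicate_tags(tags)
  expect_equal(sum(u$count), 200)
  expect_identical(sort(u$sequence), sort(unique(tags$sequence)))
  all_distinct <- tibble::tibble(sequence = replicate(10, rand_seq(25)))
  u2 <- dereplicate_tags(all_distinct)
  expect_true(all(u2$singleton))
})

test_that("greedy OTU clustering matches the declared rule", {
  two_same <- tibble::tibble(sequence = rep(strrep("ACGT", 15), 2),
                             count = c(3L, 2L), singleton = FALSE)
  # identical sequences dereplicate upstream, but the rule still merges them
  expect_equal(nrow(cluster_otus(dplyr::distinct(two_same))), 1)
  set.seed(3)
  a <- rand_seq(60)
  b <- mutate_seq(a, 6)  # ~90% identity
  far <- tibble::tibble(sequence = c(a, b), count = c(5L, 4L))
  expect_equal(nrow(cluster_otus(far, 0.97)), 2)
  near <- tibble::tibble(sequence = c(a, mutate_seq(a, 1)), count = c(5L, 4L))
  expect_equal(nrow(cluster_otus(near, 0.97)), 1)
  expect_error(cluster_otus(far, 0), "0, 1")
})

test_that("clustering partition equals a brute-force greedy oracle and is order-invariant", {
  set.seed(7)
  templates <- replicate(4, rand_seq(50))
  seqs <- unique(unlist(lapply(templates, function(t) {
    c(t, replicate(4, mutate_seq(t, sample(0:1, 1))))
  })))
  counts <- sample(2:40, length(seqs), replace = TRUE)
  tags <- tibble::tibble(sequence = seqs, count = counts)
  got <- cluster_otus(tags, 0.97)
  # brute-force reimplementation with the independent DP aligner
  ord <- order(-counts, seqs)
  reps <- character(0)
  members <- list()
  for (i in ord) {
    hit <- 0L
    for (k in seq_along(reps)) {
      if (oracle_global_identity(reps[k], seqs[i]) >= 0.97) {
        hit <- k
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, seqs[i])
      members <- c(members, list(seqs[i]))
    } else {
      members[[hit]] <- c(members[[hit]], seqs[i])
    }
  }
  expect_equal(got$representative, reps)
  expect_equal(got$n_members, lengths(members))
  # input order must not matter
  shuf <- tags[sample(nrow(tags)), ]
  expect_identical(cluster_otus(shuf, 0.97), got)
})

test_that("chimeric representatives are flagged and whole OTUs dropped", {
  set.seed(11)
  a <- rand_seq(120)
  b <- mutate_seq(a, 60)  # far from a
  chim <- paste0(substr(a, 1, 60), substr(b, 61, 120))
  otus <- tibble::tibble(
    otu_id = c("OTU_1", "OTU_2", "OTU_3"),
    representative = c(a, b, chim),
    count = c(50L, 40L, 5L), n_members = c(1L, 1L, 1L)
  )
  res <- flag_chimeras(otus)
  expect_equal(res$chimeras$representative, chim)
  expect_equal(sort(res$otus$representative), sort(c(a, b)))
  # single OTU: nothing can be flagged
  one <- flag_chimeras(otus[1, ])
  expect_equal(nrow(one$chimeras), 0)
  # unrelated clean representatives: zero flags
  clean <- tibble::tibble(otu_id = c("O1", "O2"),
                          representative = c(a, b),
                          count = c(9L, 5L), n_members = c(1L, 1L))
  expect_equal(nrow(flag_chimeras(clean)$chimeras), 0)
})

test_that("tag mapping picks the best representative at 97% and drops the rest", {
  set.seed(13)
  r1 <- rand_seq(80)
  r2 <- mutate_seq(r1, 20)
  otus <- tibble::tibble(otu_id = c("O1", "O2"), representative = c(r1, r2),
                         count = c(10L, 8L))
  tags <- tibble::tibble(
    tag_id = c("a", "b", "c"), sample_id = "S1",
    sequence = c(r1, mutate_seq(r2, 1), mutate_seq(r1, 15)),
    quality = strrep("I", 80)
  )
  counts <- map_tags_to_otus(tags, otus)
  expect_equal(counts$O1, 1)
  expect_equal(counts$O2, 1)  # the 15-sub tag matches neither at 97%
  # brute-force best-hit oracle on a larger fixture
  tags2 <- tibble::tibble(
    tag_id = sprintf("t%02d", 1:30), sample_id = rep(c("S1", "S2"), 15),
    sequence = vapply(1:30, function(i) {
      mutate_seq(sample(c(r1, r2), 1), sample(0:3, 1))
    }, character(1)),
    quality = strrep("I", 80)
  )
  got <- map_tags_to_otus(tags2, otus) |>
    tidyr::pivot_longer(-sample_id, names_to = "otu_id", values_to = "n") |>
    dplyr::filter(n > 0) |>
    dplyr::arrange(sample_id, otu_id)
  reps <- c(O1 = r1, O2 = r2)
  best <- vapply(seq_len(30), function(i) {
    ids <- vapply(reps, function(r) {
      oracle_global_identity(tags2$sequence[i], r)
    }, numeric(1))
    ok <- ids >= 0.97
    if (!any(ok)) return(NA_character_)
    names(reps)[order(-ids, -c(10, 8))][1]
  }, character(1))
  oracle <- tibble::tibble(sample_id = tags2$sample_id, otu_id = best) |>
    dplyr::filter(!is.na(otu_id)) |>
    dplyr::count(sample_id, otu_id, name = "n") |>
    dplyr::arrange(sample_id, otu_id)
  expect_equal(as.data.frame(got), as.data.frame(oracle))
})

test_that("rarefaction subsamples to depth, drops shallow samples, keeps support", {
  counts <- tibble::tibble(sample_id = c("A", "B", "C"),
                           O1 = c(30L, 5L, 0L), O2 = c(20L, 3L, 60L),
                           O3 = c(0L, 2L, 40L))
  expect_warning(r <- rarefy(counts, depth = 50, seed = 1), "B")
  expect_equal(r$sample_id, c("A", "C"))
  expect_true(all(rowSums(abundance_matrix(r)) == 50))
  # depth equal to a sample total leaves it unchanged
  expect_equal(unlist(r[r$sample_id == "A", c("O1", "O2", "O3")]),
               c(O1 = 30, O2 = 20, O3 = 0))
  # support: absent OTUs stay absent
  expect_equal(r$O1[r$sample_id == "C"], 0)
  expect_identical(rarefy(counts[3, ], 50, seed = 9),
                   rarefy(counts[3, ], 50, seed = 9))
  expect_error(rarefy(counts, 0), "positive")
})

test_that("rarefaction is hypergeometric on average", {
  counts <- tibble::tibble(sample_id = "A", O1 = 60L, O2 = 30L, O3 = 10L)
  draws <- vapply(1:1000, function(s) {
    unlist(rarefy(counts, depth = 20, seed = s)[1, c("O1", "O2", "O3")])
  }, numeric(3))
  expect_equal(rowMeans(draws), 20 * c(O1 = 0.6, O2 = 0.3, O3 = 0.1),
               tolerance = 0.05)
})

test_that("genus profiling sums counts per lowest rank and normalises", {
  counts <- tibble::tibble(sample_id = "S1", O1 = 10L, O2 = 30L, O3 = 60L)
  tax <- tibble::tibble(
    otu_id = c("O1", "O2", "O3"),
    taxonomy = c("k__Bacteria;p__Firmicutes;g__Lactobacillus",
                 "k__Bacteria;p__Firmicutes;g__Lactobacillus",
                 "k__Bacteria;p__Firmicutes;g__Bacillus")
  )
  gp <- genus_profile(counts, tax)
  expect_equal(gp$Lactobacillus, 0.4)
  expect_equal(gp$Bacillus, 0.6)
  # above-genus assignment keeps its rank prefix
  tax2 <- tax
  tax2$taxonomy[3] <- "k__Bacteria;p__Firmicutes;f__Bacillaceae;g__"
  gp2 <- genus_profile(counts, tax2)
  expect_equal(gp2$f__Bacillaceae, 0.6)
  expect_true(abs(sum(abundance_matrix(gp2)) - 1) < 1e-12)
  expect_error(genus_profile(counts, tax[1:2, ]), "O3")
})

test_that("deep no-noise tag simulation recovers the generating profile", {
  prof <- c(Lactobacillus = 0.55, Bacillus = 0.25, Weissella = 0.2)
  tmpl <- genus_templates(names(prof), "16S", seed = 17)
  tags <- simulate_tags(prof, depth = 10000, templates = tmpl, seed = 18)
  est <- table(tags$true_genus) / nrow(tags)
  expect_lt(max(abs(est[names(prof)] - prof)), 0.02)
})
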