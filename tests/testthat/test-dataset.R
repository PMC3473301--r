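test_that("bitscore distance follows the reciprocal-score formula", {
  expect_equal(pairwise_distance(100, 100, 100, 100), 0)
  expect_equal(pairwise_distance(0, 0, 80, 48), 1)
  expect_equal(pairwise_distance(30, 34, 80, 48), 0.5)
  # symmetric in (i, j)
  expect_equal(pairwise_distance(30, 34, 80, 48),
               pairwise_distance(34, 30, 48, 80))
  expect_error(pairwise_distance(1, 1, 0, 0), "positive")
  expect_error(pairwise_distance(-1, 1, 2, 2), ">= 0")
})

test_that("bitscore tables handle missing reciprocal hits as score 0", {
  bs <- data.frame(
    query = c("a", "b", "a"), subject = c("a", "b", "b"),
    score = c(80, 48, 64), stringsAsFactors = FALSE
  )
  d <- bitscore_distances(bs)
  expect_equal(nrow(d), 1L)
  expect_equal(d$d, 1 - 64 / 128)  # only one direction scored
  expect_error(bitscore_distances(bs[-1, ]), "self-scores")
})

test_that("graph edges appear exactly at or below the threshold", {
  dists <- data.frame(orf_i = c("A", "A", "B"), orf_j = c("B", "C", "C"),
                      d = c(0.2, 0.9, 0.9), stringsAsFactors = FALSE)
  genomes <- c(A = "g1", B = "g2", C = "g3")
  g <- build_graph(dists, genomes, t = 0.3)
  expect_equal(igraph::ecount(g$graph), 1L)
  expect_equal(igraph::vcount(g$graph), 3L)
  expect_equal(igraph::ecount(build_graph(dists, genomes, t = 0)$graph), 0L)
  expect_equal(igraph::ecount(build_graph(dists, genomes, t = 1)$graph), 3L)
  # boundary: d == t keeps the edge
  expect_equal(igraph::ecount(build_graph(dists, genomes, t = 0.2)$graph), 1L)
})

test_that("HCO extraction keeps only all-genome components and picks medoids", {
  dists <- data.frame(
    orf_i = c("A", "A", "B", "D"), orf_j = c("B", "C", "C", "E"),
    d = c(0.1, 0.2, 0.25, 0.1), stringsAsFactors = FALSE
  )
  genomes <- c(A = "g1", B = "g2", C = "g3", D = "g1", E = "g2")
  g <- build_graph(dists, genomes, t = 0.3)
  hcos <- extract_hcos(g, c("g1", "g2", "g3"))
  # {D,E} misses g3 and is discarded; {A,B,C} covers all genomes
  expect_equal(nrow(hcos), 1L)
  expect_equal(sort(hcos$members[[1L]]), c("A", "B", "C"))
  # medoid minimizes the distance sum: A has 0.1+0.2 < B < C
  expect_equal(hcos$medoid_id, "A")
  expect_true(hcos$medoid_id %in% hcos$members[[1L]])
  # a two-genome species: both components qualify and are disjoint
  dists2 <- dists[dists$orf_i != "A" | dists$orf_j != "C", , drop = FALSE]
  dists2 <- dists2[dists2$orf_i != "B" | dists2$orf_j != "C", , drop = FALSE]
  g2 <- build_graph(dists2, genomes[c("A", "B", "D", "E")], t = 0.3)
  hcos2 <- extract_hcos(g2, c("g1", "g2"))
  expect_equal(nrow(hcos2), 2L)
  expect_length(intersect(hcos2$members[[1L]], hcos2$members[[2L]]), 0L)
  expect_error(extract_hcos(g, character(0)), "non-empty")
})

test_that("positives are capped by seeded subsampling and stripped", {
  orfs <- data.frame(
    species_id = "s", genome_id = "g",
    orf_id = sprintf("o%02d", 1:30),
    seq = replicate(30, toy_orf(sample(alphabet("codon")$symbols, 10, TRUE))),
    stringsAsFactors = FALSE
  )
  hcos <- data.frame(cluster_id = 1:30, medoid_id = orfs$orf_id,
                     n_members = 1L, members = I(as.list(orfs$orf_id)),
                     stringsAsFactors = FALSE)
  all_pos <- sample_positives(hcos, orfs, cap = 400)
  expect_equal(nrow(all_pos), 30L)
  expect_true(all(all_pos$label == 1L))
  expect_true(all(nchar(all_pos$seq) == 30))  # ATG and TAA removed
  capped <- sample_positives(hcos, orfs, cap = 10, seed = 9)
  expect_equal(nrow(capped), 10L)
  expect_identical(capped, sample_positives(hcos, orfs, cap = 10, seed = 9))
  expect_error(sample_positives(hcos[0, ], orfs), "no HCO")
})

test_that("every positive yields 5 stop-free out-of-frame negatives", {
  set.seed(7)
  for (i in 1:10) {
    orf <- toy_orf(sample(alphabet("codon")$symbols, 40, TRUE))
    neg <- make_negatives(orf, "s", "g", paste0("o", i))
    expect_equal(nrow(neg), 5L)
    expect_true(all(neg$label == -1L))
    expect_true(all(nchar(neg$seq) %% 3 == 0))
    for (s in neg$seq) {
      codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
    }
  }
  # the +1 frame starts one base in
  neg <- make_negatives("ATGGCAGATTAG")
  fwd1 <- neg$raw[neg$orf_id == "orf:fwd1"]
  expect_equal(substr(fwd1, 1, 3), "TGG")
})

test_that("fold assignment is a stratified partition", {
  f <- split_folds(rep(c(1L, -1L), each = 10), folds = 10, seed = 1)
  expect_true(all(table(f) == 2))
  labels <- rep(c(1L, -1L), c(60, 300))
  f <- split_folds(labels, folds = 10, seed = 2)
  expect_true(all(table(f[labels == 1L]) == 6))
  expect_true(all(table(f[labels == -1L]) == 30))
  expect_equal(sort(unique(f)), 1:10)
  expect_error(split_folds(rep(c(1L, -1L), c(5, 100)), folds = 10),
               "fewer than")
})

test_that("ORF FASTA and bitscore TSV round-trip, including CRLF input", {
  orfs <- data.frame(
    species_id = "sp1", genome_id = "g1",
    orf_id = c("x1", "x2"),
    seq = c(strrep("ACGT", 40), "ATGGCATAA"),  # first wraps at 70 cols
    label = c(1L, -1L), stringsAsFactors = FALSE
  )
  path <- tempfile(fileext = ".fasta")
  write_orf_fasta(orfs, path)
  back <- read_orf_fasta(path)
  expect_equal(back, orfs)
  # CRLF + wrapped lines
  crlf <- tempfile(fileext = ".fasta")
  writeLines(c(">a|b|c\r", "ACGTAC\r", "GT\r"), crlf, sep = "\n")
  rec <- read_orf_fasta(crlf)
  expect_equal(rec$seq, "ACGTACGT")

  bs <- data.frame(query = "a", subject = "b", score = 12.5,
                   stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  write_bitscores(bs, tsv)
  expect_equal(read_bitscores(tsv), bs)
})
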