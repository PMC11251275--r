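test_that("pairwise identity handles the textbook cases", {
  expect_equal(as.numeric(pairwise_identity("MKVLAT", "MKVLAT")), 1.0)
  expect_equal(as.numeric(pairwise_identity("AAAA", "AAAT")), 0.75)
  expect_error(pairwise_identity("", "AAA"), "non-empty")
  expect_error(pairwise_identity("AaA", "AAA"), "uppercase")
})

test_that("identity is symmetric and bounded", {
  set.seed(31)
  for (i in 1:10) {
    a <- random_protein(sample(40:80, 1))
    b <- random_protein(sample(40:80, 1))
    ab <- as.numeric(pairwise_identity(a, b))
    ba <- as.numeric(pairwise_identity(b, a))
    expect_identical(ab, ba)
    expect_gte(ab, 0); expect_lte(ab, 1)
  }
})

test_that("alignment agrees with the independent DP oracle", {
  set.seed(42)
  for (i in 1:30) {
    n <- sample(30:70, 1)
    a <- random_protein(n)
    # related sequence with substitutions and a small indel
    bb <- strsplit(a, "")[[1]]
    sub <- runif(n) < 0.2
    bb[sub] <- vapply(bb[sub], function(x)
      sample(setdiff(LETTERS[1:20], x), 1), character(1))
    if (i %% 2 == 0) bb <- bb[-sample(n, sample(1:3, 1))]
    b <- paste(bb, collapse = "")
    got <- pairwise_identity(a, b)
    want <- nw_oracle(a, b)
    expect_equal(attr(got, "score"), want$score)
    expect_equal(attr(got, "matches"), want$matches)
    expect_equal(attr(got, "align_length"), want$align_length)
    expect_equal(as.numeric(got), want$identity)
  }
})

test_that("shorter-sequence denominator is available and documented in output", {
  a <- "MKVLATMKVLAT" # 12
  b <- "MKVLAT"       # 6, perfect prefix
  full <- pairwise_identity(a, b, denominator = "alignment")
  short <- pairwise_identity(a, b, denominator = "shorter")
  expect_equal(as.numeric(short), 1.0)
  expect_lt(as.numeric(full), 1.0)
})

test_that("greedy clustering covers the trivial cases", {
  same <- setNames(rep("MKVLATWYPR", 5), paste0("s", 1:5))
  ca <- greedy_cluster(same, 0.9)
  expect_equal(length(attr(ca, "centroids")), 1L)

  set.seed(7)
  distinct <- setNames(vapply(1:6, function(i) random_protein(60),
                              character(1)), paste0("d", 1:6))
  ca2 <- greedy_cluster(distinct, 1.0)
  expect_equal(length(attr(ca2, "centroids")), 6L)
  expect_error(greedy_cluster(distinct, 0), "threshold")
})

test_that("three synthetic families are recovered intact at 0.8", {
  fam <- simulate_sequence_family(3, 5, within_identity = 0.95,
                                  between_identity = 0.6, length = 120,
                                  seed = 9)
  ca <- greedy_cluster(fam, 0.8)
  expect_equal(length(attr(ca, "centroids")), 3L)
  # families intact: members of one true cluster share one centroid
  merged <- merge(ca, fam[, c("id", "cluster")],
                  by.x = "member_id", by.y = "id")
  expect_equal(unname(tapply(merged$centroid_id, merged$cluster,
                             function(x) length(unique(x)))),
               c(1L, 1L, 1L), ignore_attr = TRUE)
})

test_that("members satisfy the threshold to their centroid", {
  fam <- simulate_sequence_family(2, 6, 0.92, 0.55, length = 100,
                                  seed = 13)
  ca <- greedy_cluster(fam, 0.75)
  expect_true(all(ca$identity >= 0.75))
  # centroids map to themselves
  cents <- attr(ca, "centroids")
  self <- ca$member_id %in% cents
  expect_equal(ca$centroid_id[self], ca$member_id[self])
})

test_that("clustering is stable under input permutation", {
  fam <- simulate_sequence_family(3, 4, 0.93, 0.6, length = 90, seed = 21)
  ca1 <- greedy_cluster(fam, 0.8)
  set.seed(2); perm <- sample(nrow(fam))
  ca2 <- greedy_cluster(fam[perm, ], 0.8)
  expect_identical(ca1, ca2)
})

test_that("representative counts are non-decreasing in threshold", {
  fam <- simulate_sequence_family(4, 4, 0.9, 0.55, length = 90, seed = 33)
  counts <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.97, 1.0), function(th)
    length(attr(greedy_cluster(fam, th), "centroids")), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("iterative selection reduces to greedy clustering for one stage", {
  fam <- simulate_sequence_family(3, 4, 0.95, 0.6, length = 90, seed = 14)
  sel <- iterative_select(fam, data.frame(tag = "all", threshold = 0.8))
  expect_setequal(sel$representatives,
                  attr(greedy_cluster(fam, 0.8), "centroids"))
})

test_that("multi-stage union equals per-stage counts minus overlaps", {
  fam <- simulate_sequence_family(3, 5, 0.95, 0.6, length = 100, seed = 15)
  fam$subset_tags <- ifelse(fam$cluster <= 2, "formIA,all", "all")
  scheme <- data.frame(tag = c("all", "formIA"),
                       threshold = c(0.75, 0.9))
  sel <- iterative_select(fam, scheme)
  a1 <- attr(sel$assignments[[1]], "centroids")
  a2 <- attr(sel$assignments[[2]], "centroids")
  expect_setequal(sel$representatives, union(a1, a2))
  expect_equal(length(sel$representatives),
               length(a1) + length(a2) - length(intersect(a1, a2)))
})

test_that("the published six-stage scheme shape runs and reports counts", {
  fam <- simulate_sequence_family(4, 5, 0.96, 0.6, length = 100, seed = 16)
  fam$subset_tags <- c("formIA", "formIB", "cyano", "ccm_proteo")[fam$cluster]
  fam$subset_tags <- paste0(fam$subset_tags, ",all")
  scheme <- data.frame(
    tag = c("all", "formIA", "cyano", "formIB", "cyano", "ccm_proteo"),
    threshold = c(0.75, 0.85, 0.88, 0.91, 0.975, 0.90))
  sel <- iterative_select(fam, scheme)
  expect_equal(nrow(sel$stages), 6L)
  expect_true(all(sel$stages$n_centroids >= 1))
  expect_true(length(sel$representatives) >= max(sel$stages$n_centroids))
  # a tag with no members is skipped with a warning
  expect_warning(
    iterative_select(fam, data.frame(tag = "missing", threshold = 0.8)),
    "skipped")
})

test_that("FASTA round trip preserves ids and residues at 60 columns", {
  fam <- simulate_sequence_family(2, 3, 0.9, 0.6, length = 130, seed = 17)
  path <- withr::local_tempfile(fileext = ".faa")
  write_fasta_set(fam, path)
  lines <- readLines(path)
  expect_true(all(nchar(lines[!startsWith(lines, ">")]) <= 60))
  back <- read_fasta_set(path)
  expect_equal(back$id, fam$id)
  expect_equal(back$residues, fam$residues)
})

test_that("length filtering drops out-of-range sequences", {
  seqs <- setNames(c(random_protein(100), random_protein(350),
                     random_protein(800)), c("a", "b", "c"))
  kept <- filter_sequence_length(seqs)
  expect_equal(kept$id, "b")
})
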