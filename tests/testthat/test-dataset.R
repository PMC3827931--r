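test_that("least atom distance is a symmetric brute-force minimum", {
  a <- matrix(c(0, 0, 0), 1, 3)
  b <- matrix(c(3, 4, 0), 1, 3)
  expect_equal(least_atom_distance(a, b), 5)
  expect_equal(least_atom_distance(a, a), 0)
  set.seed(13)
  for (rep in 1:10) {
    A <- matrix(rnorm(9, sd = 5), 3, 3)
    B <- matrix(rnorm(9, sd = 5), 3, 3)
    brute <- min(vapply(seq_len(3), function(i)
      min(sqrt(colSums((t(B) - A[i, ])^2))), numeric(1)))
    expect_equal(least_atom_distance(A, B), brute, tolerance = 1e-12)
    expect_equal(least_atom_distance(A, B), least_atom_distance(B, A))
  }
  expect_error(least_atom_distance(A[0, , drop = FALSE], B), "empty")
})

test_that("interactivity labeling is strict and monotone in the cutoff", {
  near <- list(atoms = matrix(c(0, 0, 0), 1, 3))
  at <- function(d) list(atoms = matrix(c(d, 0, 0), 1, 3))
  expect_identical(label_interactivity(near, at(4.9), 5), "interactive")
  expect_identical(label_interactivity(near, at(5.0), 5),
                   "non-interactive")   # boundary: strict "less than"
  # the 7 A regime flips pairs between 5 and 7 A, and labeling is monotone
  expect_identical(label_interactivity(near, at(6.0), 7), "interactive")
  for (d in c(1, 4.99, 5, 6.5, 8)) {
    l5 <- label_interactivity(near, at(d), 5)
    l7 <- label_interactivity(near, at(d), 7)
    if (l5 == "interactive") expect_identical(l7, "interactive")
  }
})

test_that("pair extraction dedups identical chains and uses ANY-copy labels", {
  cx <- toy_2ftc()
  expect_length(cx$chains, 18)
  expect_message(pairs <- extract_pairs(cx), "ANY-copy")
  rna <- attr(pairs, "rna"); prot <- attr(pairs, "protein")
  expect_length(rna, 1)
  expect_length(prot, 16)                 # 18 chains -> 17 kept
  expect_identical(nrow(pairs), 16L)      # 1 RNA x 16 proteins
  expect_identical(sum(pairs$label == "interactive"), 8L)
  # the duplicated chain (copies at 4 A and 20 A) is interactive
  dup <- pairs[pairs$protein_id == "T2F_E", ]
  expect_identical(dup$label, "interactive")
})

test_that("a complex without both polymer kinds yields an empty warning set", {
  cx <- toy_complex(list(list(chain_id = "A", kind = "rna",
                              sequence = "ACGUACGU", pos = c(0, 0))))
  expect_warning(pairs <- extract_pairs(cx), "lacks")
  expect_identical(nrow(pairs), 0L)
})

test_that("RNA length filter is strict at both bounds and idempotent", {
  rna <- rpi_seqs(c(short = strrep("A", 100), keep = strrep("A", 101),
                    long = strrep("A", 120)), "rna")
  pairs <- rpi_pairs(c("short", "keep", "long"), rep("p", 3),
                     rep("interactive", 3))
  out <- filter_rna_length(pairs, rna, min_len = 100, max_len = 110)
  expect_identical(out$rna_id, "keep")    # 100 removed, 101 kept, 120 cut
  expect_identical(filter_rna_length(out, rna, 100, 110), out)
})

test_that("sequence identity matches hand-aligned fractions", {
  expect_equal(sequence_identity("ACGU", "ACGU"), 1)
  expect_equal(sequence_identity("AAAA", "TTTT"), 0)
  expect_equal(sequence_identity("ACGU", "ACGA"), 0.75)
  expect_equal(sequence_identity("MKVLA", "MKVLA"), 1)
})

test_that("redundancy removal needs both identities and is idempotent", {
  rna <- rpi_seqs(c(r1 = "ACGUACGUAC", r2 = "ACGUACGUAC",
                    r3 = "GGGGGGCCCC"), "rna")
  prot <- rpi_seqs(c(p1 = "MKVLAWYERT", p2 = "MKVLAWYERT",
                     p3 = "GGGGGGGGGG"), "protein")
  pairs <- rpi_pairs(c("r1", "r2", "r3"), c("p1", "p2", "p1"),
                     rep("interactive", 3))
  out <- remove_redundancy(pairs, rna, prot)
  # exact duplicate pair removed; pair sharing only the protein kept
  expect_identical(out$rna_id, c("r1", "r3"))
  expect_identical(remove_redundancy(out, rna, prot), out)
})

test_that("cluster-file identity lookup reproduces external clustering", {
  seqs <- rpi_seqs(c(s1 = "AAAA", s2 = "AAAC", s3 = "GGGG"), "rna")
  clstr <- tempfile(fileext = ".clstr")
  writeLines(c(">Cluster 0", "0\t4nt, >s1... *", "1\t4nt, >s2... at 75%",
               ">Cluster 1", "0\t4nt, >s3... *"), clstr)
  idf <- read_cdhit_clusters(clstr, seqs)
  expect_identical(idf("AAAA", "AAAC"), 1)
  expect_identical(idf("AAAA", "GGGG"), 0)
})

test_that("evidence codes split into direct {1,5,6} and indirect", {
  expect_identical(classify_npinter_evidence(1), "direct")
  expect_identical(classify_npinter_evidence(c(5, 6)),
                   c("direct", "direct"))
  expect_identical(classify_npinter_evidence(c(2, 3, 4, 7, 8)),
                   rep("indirect", 5))
  expect_error(classify_npinter_evidence(9), "1..8")
  expect_error(classify_npinter_evidence(0), "1..8")
})

test_that("pair shuffling preserves the count, seed and avoids originals", {
  pairs <- rpi_pairs(paste0("r", 1:8), paste0("p", 1:8),
                     rep("non-interactive", 8))
  s1 <- shuffle_pairs(pairs, seed = 3)
  s2 <- shuffle_pairs(pairs, seed = 3)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 8L)
  expect_false(any(paste(s1$rna_id, s1$protein_id) %in%
                     paste(pairs$rna_id, pairs$protein_id)))
  one <- pairs[1, ]
  expect_warning(shuffle_pairs(one, seed = 1), "unavoidable")
})

test_that("toy complexes round-trip through the PDB writer/reader", {
  cx <- toy_complex(list(
    list(chain_id = "A", kind = "rna", sequence = "GGGAUUCCC",
         pos = c(0, 0)),
    list(chain_id = "B", kind = "protein", sequence = "MKVLAWYERT",
         pos = c(4, 0)),
    list(chain_id = "C", kind = "protein", sequence = "GASDE",
         pos = c(3, 4))))
  expect_equal(least_atom_distance(cx$chains[[1]]$atoms,
                                   cx$chains[[2]]$atoms), 4, tolerance = 1e-9)
  expect_equal(least_atom_distance(cx$chains[[1]]$atoms,
                                   cx$chains[[3]]$atoms), 5, tolerance = 1e-9)
  f <- tempfile(fileext = ".pdb")
  write_pdb(cx, f)
  back <- read_pdb(f)
  expect_identical(vapply(back$chains, `[[`, character(1), "kind"),
                   c("rna", "protein", "protein"))
  expect_identical(vapply(back$chains, `[[`, character(1), "sequence"),
                   vapply(cx$chains, `[[`, character(1), "sequence"))
  p1 <- extract_pairs(cx); p2 <- extract_pairs(back)
  expect_identical(p1$label, p2$label)    # labels survive the round trip
})

test_that("build_dataset bookkeeping matches hand counts on toy input", {
  dir <- tempfile(); dir.create(dir)
  write_pdb(toy_2ftc(), file.path(dir, "t2f.pdb"))
  # second complex: RNA exactly 100 nt (filtered by the strict rule)
  rna100 <- unclass(random_sequences(1, c(100L, 100L), "rna",
                                     seed = 31))[[1]]
  cx2 <- toy_complex(list(
    list(chain_id = "A", kind = "rna", sequence = rna100, pos = c(0, 0)),
    list(chain_id = "B", kind = "protein",
         sequence = unclass(random_sequences(1, c(30L, 30L), "protein",
                                             seed = 32))[[1]],
         pos = c(2, 0))), id = "TOY2")
  write_pdb(cx2, file.path(dir, "toy2.pdb"))
  suppressMessages(ds <- build_dataset(dir))
  # 16 + 1 extracted; the 100-nt RNA pair dies at the length filter;
  # nothing is redundant among the remaining 16
  expect_identical(ds$stats$pairs, c(17L, 16L, 16L))
  expect_identical(ds$stats$interactive, c(9L, 8L, 8L))
  expect_identical(nrow(ds$pairs), 16L)
})
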