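test_that("propensity encoding is a positional lookup with ambiguity means", {
  sc <- toy_rna_scale()
  expect_equal(as.numeric(encode_propensity("ACGU", sc)), c(1, 2, 3, 4))
  expect_equal(as.numeric(encode_propensity("AN", sc)), c(1, 2.5))
  expect_error(propensity_scale(numeric(0), "empty", "rna"), "empty")
  expect_error(encode_propensity("ACGU", structure(1, class = "foo")),
               "propensity_scale")

  kd <- default_scales()$kd
  expect_equal(as.numeric(encode_propensity("IR", kd)), c(4.5, -4.5))
  expect_equal(as.numeric(encode_propensity("X", kd)),
               mean(unclass(kd)))
  expect_equal(as.numeric(encode_propensity("B", kd)),
               mean(unclass(kd)[c("D", "N")]))
})

test_that("propensity encoding commutes with concatenation and reversal", {
  sc <- toy_protein_scale()
  set.seed(3)
  for (rep in 1:5) {
    s1 <- unclass(random_sequences(1, c(5L, 30L), "protein",
                                   seed = rep))[[1]]
    s2 <- unclass(random_sequences(1, c(5L, 30L), "protein",
                                   seed = rep + 100))[[1]]
    expect_equal(as.numeric(encode_propensity(paste0(s1, s2), sc)),
                 c(as.numeric(encode_propensity(s1, sc)),
                   as.numeric(encode_propensity(s2, sc))))
    rev_s <- paste(rev(strsplit(s1, "")[[1]]), collapse = "")
    expect_equal(as.numeric(encode_propensity(rev_s, sc)),
                 rev(as.numeric(encode_propensity(s1, sc))))
  }
})

test_that("structure channel counts pairedness across folded structures", {
  # no pairing possible: all-A sequence gives an all-zero profile
  expect_equal(as.numeric(encode_rna_structure("AAAAAAAA", n = 6)),
               rep(0, 8))
  # the built-in maximum-pairing folder on a perfect stem, n = 2:
  # stems paired in both (repeated) structures, loop positions unpaired
  expect_equal(as.numeric(encode_rna_structure("GGGGAAAACCCC", n = 2)),
               c(2, 2, 2, 2, 0, 0, 0, 0, 2, 2, 2, 2))
  # a residue paired in all n structures reaches exactly n
  hairpin <- mock_folder("((((....))))")
  prof <- encode_rna_structure("GGGGAAAACCCC", folder = hairpin, n = 6)
  expect_equal(max(prof), 6)
  expect_true(all(prof %in% c(0, 6)))
})

test_that("structure profile is bounded by n and monotone for nested lists", {
  nested <- mock_folder(c("........", "((....))", "((....))"))
  for (n in 1:3) {
    prof <- encode_rna_structure("GGAAAACC", folder = nested, n = n)
    expect_true(all(prof >= 0 & prof <= n))
  }
  p1 <- encode_rna_structure("GGAAAACC", folder = nested, n = 2)
  p2 <- encode_rna_structure("GGAAAACC", folder = nested, n = 3)
  expect_true(all(p2 >= p1))
})

test_that("folding backend contract violations are caught", {
  expect_error(encode_rna_structure("ACGU", mock_folder("..."), n = 1),
               "length")
  expect_error(encode_rna_structure("ACGU", mock_folder("(..."), n = 1),
               "unbalanced")
  expect_error(encode_rna_structure("ACGU", mock_folder("(.x)"), n = 1),
               "invalid character")
  expect_error(encode_rna_structure("ACGU", mock_folder(character(0)),
                                    n = 1), "no structures")
})

test_that("built-in folder emits balanced structures with loop length >= 3", {
  for (s in unclass(random_sequences(8, c(15L, 60L), "rna", seed = 9))) {
    structs <- rna_folder_nussinov()(s, 6)
    expect_true(length(structs) >= 1)
    for (db in structs) {
      ch <- strsplit(db, "")[[1]]
      depth <- cumsum((ch == "(") - (ch == ")"))
      expect_true(all(depth >= 0) && depth[length(depth)] == 0)
      # recover pairs with a stack and check the hairpin constraint
      stack <- integer(0)
      for (i in seq_along(ch)) {
        if (ch[i] == "(") stack <- c(stack, i)
        else if (ch[i] == ")") {
          j <- stack[length(stack)]
          stack <- stack[-length(stack)]
          expect_true(i - j - 1 >= 3)
        }
      }
    }
  }
})

test_that("long-RNA policy mirrors the 4095-nt folder limit", {
  long_seq <- strrep("A", 30)
  expect_error(rna_folder_nussinov(max_len = 20)(long_seq, 1), "20 nt")
  trunc <- rna_folder_nussinov(max_len = 20, policy = "truncate")
  expect_identical(nchar(trunc(long_seq, 1)[1]), 20L)
})

test_that("protein structure channel selects the per-state table", {
  cf <- default_scales()$chou_fasman
  # all-helix prediction on Ala: the classic helix propensity 1.42
  prof <- encode_protein_structure("AA", mock_predictor("HH"), cf)
  expect_equal(as.numeric(prof), c(1.42, 1.42))
  # mixed states pick different tables for identical residues
  prof2 <- encode_protein_structure("AA", mock_predictor("HC"), cf)
  expect_equal(as.numeric(prof2), c(1.42, 0.66))
  expect_error(encode_protein_structure("AAA", mock_predictor("HH"), cf),
               "length")
  expect_error(encode_protein_structure("AA", mock_predictor("HQ"), cf),
               "outside")
})

test_that("channel counts and determinism of the full encoders", {
  rna <- unclass(random_sequences(1, c(25L, 25L), "rna", seed = 4))[[1]]
  prot <- unclass(random_sequences(1, c(30L, 30L), "protein",
                                   seed = 4))[[1]]
  er1 <- encode_rna(rna); er2 <- encode_rna(rna)
  expect_identical(names(er1), c("structure", "hbond", "vdw"))
  expect_identical(er1, er2)
  ep1 <- encode_protein(prot); ep2 <- encode_protein(prot)
  expect_identical(names(ep1),
                   c("structure", "grantham", "zimmerman", "kd", "bb"))
  expect_identical(ep1, ep2)
  # single-residue sequences still yield full-width vectors
  ep_min <- encode_protein("M")
  expect_true(all(lengths(ep_min) == 10))
  er_min <- encode_rna("G")
  expect_true(all(lengths(er_min) == 10))
  # profile length equals sequence length before compression
  expect_length(encode_propensity(rna, default_scales()$rna_hbond),
                nchar(rna))
  expect_length(encode_rna_structure(rna), nchar(rna))
})
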