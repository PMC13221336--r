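# Fingerprints and similarity.

test_that("pubchem881 reproduces the frozen reference bit sets", {
  oracle <- read_pubchem_oracle()
  # the nine panel compounds plus a structurally diverse battery (fused and
  # bridged rings, heteroaromatics, charged species, halogens, sulfonamide)
  for (entry in oracle) {
    fp <- fingerprint(entry$smiles, "pubchem881")
    expect_identical(fp$on_bits, entry$bits, label = entry$smiles)
  }
})

test_that("fingerprint lengths and determinism", {
  kinds <- c("pubchem881", "maccs166", "circular_r2_1024", "path_d7_2048")
  lens <- c(881L, 166L, 1024L, 2048L)
  for (i in seq_along(kinds)) {
    f1 <- fingerprint("CCO", kinds[i])
    f2 <- fingerprint("CCO", kinds[i])
    expect_equal(f1$length, lens[i])
    expect_identical(f1$on_bits, f2$on_bits)
    expect_true(all(f1$on_bits >= 0 & f1$on_bits < lens[i]))
  }
  expect_error(fingerprint("CCO", "morgan_foo"))
})

test_that("maccs166 matches the public key semantics on reference molecules", {
  # frozen from an independent implementation of the same public key set
  expect_identical(fingerprint("c1ccccc1", "maccs166")$on_bits + 1L,
                   c(162L, 163L, 165L))
  expect_identical(fingerprint("CCO", "maccs166")$on_bits + 1L,
                   c(82L, 109L, 114L, 139L, 153L, 155L, 157L, 160L, 164L))
  expect_identical(fingerprint("CC(=O)O", "maccs166")$on_bits + 1L,
                   c(123L, 139L, 154L, 157L, 159L, 160L, 164L))
  expect_identical(
    fingerprint("C1=CC=C(C=C1)C=C[N+](=O)[O-]", "maccs166")$on_bits + 1L,
    c(24L, 45L, 49L, 56L, 63L, 70L, 71L, 94L, 99L, 102L, 119L, 122L, 124L,
      130L, 148L, 158L, 159L, 161L, 162L, 163L, 164L, 165L))
})

test_that("hashed fingerprints are invariant to atom input order", {
  pairs <- list(
    c("C1=CC=C(C=C1)C=C[N+](=O)[O-]", "[O-][N+](=O)C=Cc1ccccc1"),
    c("CC(=O)OC1=CC=CC=C1C(=O)O", "OC(=O)c1ccccc1OC(C)=O"))
  for (kind in c("circular_r2_1024", "path_d7_2048")) {
    for (p in pairs) {
      expect_identical(fingerprint(p[1], kind)$on_bits,
                       fingerprint(p[2], kind)$on_bits,
                       label = paste(kind, p[1]))
    }
  }
})

test_that("tanimoto agrees with brute-force set arithmetic", {
  set.seed(11)
  mkfp <- function(bits) {
    structure(list(kind = "pubchem881", length = 881L,
                   on_bits = sort(unique(as.integer(bits)))),
              class = "nv_fingerprint")
  }
  for (rep in 1:25) {
    a <- sample(0:880, sample(0:60, 1))
    b <- sample(0:880, sample(0:60, 1))
    brute <- if (!length(a) && !length(b)) 1
             else if (!length(a) || !length(b)) 0
             else length(intersect(a, b)) / length(union(a, b))
    expect_equal(tanimoto(mkfp(a), mkfp(b)), brute)
  }
})

test_that("tanimoto identity, disjoint and error cases", {
  fa <- fingerprint("CCO", "maccs166")
  expect_equal(tanimoto(fa, fa), 1)
  da <- structure(list(kind = "maccs166", length = 166L, on_bits = c(0L, 1L)),
                  class = "nv_fingerprint")
  db <- structure(list(kind = "maccs166", length = 166L, on_bits = c(5L, 9L)),
                  class = "nv_fingerprint")
  expect_equal(tanimoto(da, db), 0)
  fb <- fingerprint("CCO", "pubchem881")
  expect_error(tanimoto(fa, fb), "kind mismatch")
})

test_that("similarity matrix invariants", {
  m <- test_simmatrix()
  expect_true(isSymmetric(m$values))
  expect_true(all(diag(m$values) == 1))
  expect_true(all(m$values >= 0 & m$values <= 1))
  two <- parse_compound_table(
    "id,name,cas,smiles\n1,a,0,CCO\n2,b,0,OCC\n")
  m2 <- similarity_matrix(two, "maccs166")
  expect_equal(unname(m2$values), matrix(1, 2, 2))
  expect_error(similarity_matrix(two[1], "maccs166"), "at least 2")
})

test_that("rank_by_reference ordering and tie rule", {
  m <- test_simmatrix()
  r <- rank_by_reference(m, 1)
  expect_equal(r$id[1], 1)            # reference first, Tc 1.0
  expect_equal(r$tc[1], 1.0)
  expect_equal(r$id, c(1:7, 8, 9))    # 8 and 9 tie at 0.5776; id breaks it
  expect_true(all(diff(r$tc) <= 0))
  expect_error(rank_by_reference(m, 99), "unknown reference")
  # explicit duplicate-of-reference tie case
  three <- parse_compound_table(
    "id,name,cas,smiles\n5,a,0,CCO\n2,b,0,CCO\n9,c,0,CCN\n")
  r3 <- rank_by_reference(similarity_matrix(three, "maccs166"), 5)
  expect_equal(r3$id[1:2], c(2, 5))   # both Tc 1, ascending id
})

test_that("selection report reproduces the panel's structural logic", {
  rep <- selection_report(test_panel(), ref_id = 1)
  by_id <- rep[order(rep$id), ]
  expect_equal(by_id$nitrovinyl, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE,
                                   FALSE, TRUE, TRUE))
  expect_false(by_id$nitrovinyl[by_id$id == 2])  # saturated linker
  expect_true(by_id$nitro[by_id$id == 2])
  expect_false(by_id$nitro[by_id$id == 4])       # styrene: no nitro group
  expect_false(by_id$vinyl[by_id$id == 6])       # nitrobenzene: no vinyl
  expect_true(by_id$carboxyl[by_id$id == 7])
  expect_true(all(by_id$phenyl))
  expect_error(selection_report(test_panel(), rules = c(bad = "C((")),
               "invalid SMARTS")
})
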