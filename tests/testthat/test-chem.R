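# Compound table parsing and descriptor profiles.

test_that("parse_compound_table reads the packaged panel", {
  panel <- test_panel()
  expect_s3_class(panel, "nv_panel")
  expect_length(panel, 9L)
  expect_equal(vapply(panel, function(c) c$id, integer(1)), 1:9)
  expect_equal(heavy_atom_count(panel[[1]]), 11L)  # C8 + N + O2
})

test_that("parse_compound_table error handling", {
  expect_length(parse_compound_table("id,name,cas,smiles\n"), 0L)
  expect_error(parse_compound_table("id,name,cas,smiles\n1,x,0-0-0,C1CC\n"),
               "compound id 1")
  expect_error(
    parse_compound_table(
      "id,name,cas,smiles\n1,a,0,C\n1,b,0,CC\n"),
    "duplicate")
  expect_error(parse_compound_table("id,name\n1,x\n"), "lacks column")
  # disconnected SMILES rejected
  expect_error(parse_compound_table("id,name,cas,smiles\n1,salt,0,CC.O\n"),
               "connected")
  # column order is free
  p <- parse_compound_table("smiles,cas,id,name\nCC,0-0-0,7,ethane\n")
  expect_equal(p[[1]]$id, 7L)
})

test_that("heavy atom counts match hand counts", {
  expect_equal(heavy_atom_count("C=CC1=CC=CC=C1"), 8L)       # styrene
  expect_equal(heavy_atom_count("COC1=C(C=C(C=C1)C=C[N+](=O)[O-])O"), 14L)
  expect_equal(heavy_atom_count("C"), 1L)
})

test_that("Crippen LogP reproduces the published endpoint values", {
  expect_equal(crippen_logp("C1=CC=C(C=C1)CCN"), 1.1878, tolerance = 1e-6)
  expect_equal(crippen_logp("C=CC1=CC=CC=C1"), 2.3296, tolerance = 1e-6)
  # simple hand-computable case: methane = C1 + 4 x H1
  expect_equal(crippen_logp("C"), 0.1441 + 4 * 0.123, tolerance = 1e-12)
  # benzene: 6 x C18 + 6 x H1
  expect_equal(crippen_logp("c1ccccc1"), 6 * 0.1581 + 6 * 0.123,
               tolerance = 1e-12)
})

test_that("Ertl TPSA: polar fragment sums", {
  expect_equal(ertl_tpsa("C=CC1=CC=CC=C1"), 0)
  # charged nitro written [N+](=O)[O-]: 3.01 + 17.07 + 23.06
  expect_equal(ertl_tpsa("C1=CC=C(C=C1)[N+](=O)[O-]"), 43.14,
               tolerance = 1e-9)
  # compound 9: nitro + aromatic ether O + phenol OH
  expect_equal(ertl_tpsa("COC1=C(C=C(C=C1)C=C[N+](=O)[O-])O"),
               43.14 + 9.23 + 20.23, tolerance = 1e-9)
  # amine, acid, pyridine spot values from the published table
  expect_equal(ertl_tpsa("CCN"), 26.02)
  expect_equal(ertl_tpsa("CC(=O)O"), 17.07 + 20.23)
  expect_equal(ertl_tpsa("c1ccncc1"), 12.89)
  # zero iff no N/O
  expect_equal(ertl_tpsa("CCCl"), 0)
  expect_gt(ertl_tpsa("CCO"), 0)
})

test_that("descriptor_profile: rule-of-five logic", {
  prof <- descriptor_profile("C1=CC=C(C=C1)C=C[N+](=O)[O-]")
  expect_equal(prof$ro5_violations, 0L)
  expect_false(prof$ghose_atoms_ok)
  expect_equal(prof$hbd, 0L)
  expect_equal(prof$hba, 3L)
  expect_equal(prof$mw, 149.15, tolerance = 1e-3)
})

test_that("panel-wide descriptor claims", {
  desc <- test_descriptors()
  expect_equal(range(desc$heavy_atoms), c(8L, 14L))
  expect_equal(min(desc$logp), 1.1878, tolerance = 1e-3)
  expect_equal(max(desc$logp), 2.3296, tolerance = 1e-3)
  expect_true(all(desc$ro5_violations == 0L))
  expect_true(all(!desc$ghose_atoms_ok))
  expect_true(all(desc$tpsa >= 0))
  expect_equal(max(desc$tpsa), 86.28, tolerance = 1e-9)
  expect_equal(names(desc),
               c("id", "mw", "heavy_atoms", "hbd", "hba", "logp", "tpsa",
                 "ro5_violations", "ghose_atoms_ok"))
})

test_that("profiles are canonical: atom order does not matter", {
  a <- descriptor_profile("C1=CC=C(C=C1)C=C[N+](=O)[O-]")
  b <- descriptor_profile("[O-][N+](=O)C=Cc1ccccc1")
  expect_equal(a, b)
})
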