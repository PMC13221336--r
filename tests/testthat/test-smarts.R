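# SMARTS engine semantics.

test_that("element, aromaticity and wildcard primitives", {
  benz <- nv_parse_smiles("c1ccccc1")
  hex <- nv_parse_smiles("C1CCCCC1")
  expect_true(nitrotox:::nv_has_substructure(benz, "c"))
  expect_false(nitrotox:::nv_has_substructure(benz, "C"))
  expect_true(nitrotox:::nv_has_substructure(hex, "C"))
  expect_true(nitrotox:::nv_has_substructure(benz, "[#6]"))
  expect_true(nitrotox:::nv_has_substructure(benz, "a"))
  expect_false(nitrotox:::nv_has_substructure(hex, "a"))
  expect_true(nitrotox:::nv_has_substructure(hex, "*"))
})

test_that("bond primitives: single vs aromatic vs double", {
  benz <- nv_parse_smiles("c1ccccc1")
  sty <- nv_parse_smiles("C=CC1=CC=CC=C1")
  expect_true(nitrotox:::nv_has_substructure(benz, "c:c"))
  expect_false(nitrotox:::nv_has_substructure(benz, "[#6]-[#6]"))
  expect_true(nitrotox:::nv_has_substructure(benz, "[#6]~[#6]"))
  expect_true(nitrotox:::nv_has_substructure(sty, "C=C"))
  expect_false(nitrotox:::nv_has_substructure(benz, "C=C"))  # aromatic != double
  # default bond matches single or aromatic
  expect_true(nitrotox:::nv_has_substructure(benz, "cc"))
  expect_true(nitrotox:::nv_has_substructure(sty, "[#6][#6]"))
})

test_that("H-count, charge, connectivity, degree primitives", {
  eth <- nv_parse_smiles("CCO")
  expect_true(nitrotox:::nv_has_substructure(eth, "[CH3]"))
  expect_true(nitrotox:::nv_has_substructure(eth, "[OX2H1]"))
  expect_false(nitrotox:::nv_has_substructure(eth, "[CH4]"))
  nitro <- nv_parse_smiles("C1=CC=C(C=C1)[N+](=O)[O-]")
  expect_true(nitrotox:::nv_has_substructure(nitro, "[N+]"))
  expect_true(nitrotox:::nv_has_substructure(nitro, "[O-]"))
  expect_false(nitrotox:::nv_has_substructure(nitro, "[N+0]"))
  expect_true(nitrotox:::nv_has_substructure(nitro, "[#7+1](=[#8])[#8-]"))
  iso <- nv_parse_smiles("CC(C)C")
  expect_true(nitrotox:::nv_has_substructure(iso, "[CX4D3]"))
})

test_that("ring primitives and logic operators", {
  naph <- nv_parse_smiles("c1ccc2ccccc2c1")
  expect_true(nitrotox:::nv_has_substructure(naph, "[cR2]"))  # fusion atoms
  expect_true(nitrotox:::nv_has_substructure(naph, "[c;r6]"))
  tol <- nv_parse_smiles("Cc1ccccc1")
  expect_true(nitrotox:::nv_has_substructure(tol, "[C!R]"))
  expect_true(nitrotox:::nv_has_substructure(tol, "[CH3,NH2]"))
  expect_false(nitrotox:::nv_has_substructure(tol, "[!#6;!#1]"))
  # ring-bond primitive
  expect_true(nitrotox:::nv_has_substructure(naph, "c@c"))
  expect_false(nitrotox:::nv_has_substructure(tol, "C@c"))
})

test_that("recursive SMARTS", {
  phenol <- nv_parse_smiles("Oc1ccccc1")
  anisole <- nv_parse_smiles("COc1ccccc1")
  expect_true(nitrotox:::nv_has_substructure(phenol, "[$([OH]c)]"))
  expect_false(nitrotox:::nv_has_substructure(anisole, "[$([OH]c)]"))
  expect_true(nitrotox:::nv_has_substructure(anisole, "[c$(c[OX2])]"))
})

test_that("unique match counting dedupes atom-set permutations", {
  benz <- nv_parse_smiles("c1ccccc1")
  # a single benzene ring: one unique 6-atom embedding, 12 raw automorphisms
  expect_equal(nitrotox:::nv_count_unique_matches(benz, "c1ccccc1"), 1L)
  hexane <- nv_parse_smiles("CCCCCC")
  expect_equal(nitrotox:::nv_count_unique_matches(hexane, "CC"), 5L)
})

test_that("invalid SMARTS raise errors", {
  expect_error(nitrotox:::nv_parse_smarts("C(("), "unbalanced")
  expect_error(nitrotox:::nv_parse_smarts("C1CC"), "unclosed ring")
  expect_error(nitrotox:::nv_parse_smarts("[Zz]"), "unexpected|unknown")
  expect_error(nitrotox:::nv_parse_smarts(""), "non-empty")
})
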