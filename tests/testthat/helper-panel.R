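# Shared, lazily computed objects: the packaged nine-compound panel and its
# PubChem similarity matrix are used by several test files and are the most
# expensive objects in the suite, so compute them once.

.test_cache <- new.env(parent = emptyenv())

test_panel <- function() {
  if (is.null(.test_cache$panel)) .test_cache$panel <- nitrostyrene_panel()
  .test_cache$panel
}

test_simmatrix <- function() {
  if (is.null(.test_cache$simmat)) {
    .test_cache$simmat <- similarity_matrix(test_panel(), "pubchem881")
  }
  .test_cache$simmat
}

test_descriptors <- function() {
  if (is.null(.test_cache$desc)) {
    .test_cache$desc <- descriptor_report(test_panel())
  }
  .test_cache$desc
}

# parse the frozen reference fingerprints (computed with an independent
# cheminformatics toolkit implementing the same public 881-bit specification)
read_pubchem_oracle <- function() {
  lines <- readLines(test_path("pubchem_oracle_bits.txt"))
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, " | ", fixed = TRUE)[[1]]
    list(smiles = trimws(parts[1]),
         bits = sort(as.integer(strsplit(trimws(parts[2]), ",")[[1]])))
  })
  out
}
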