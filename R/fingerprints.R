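# Bit-string molecular fingerprints.
#
# Four kinds are implemented:
#   pubchem881      - the public PubChem/CACTVS 881-bit substructure keys
#                     (element counts, ESSSR ring counts, atom pairs and
#                     SMARTS features), bit-compatible with the reference
#                     CDK implementation of the public specification.
#   maccs166        - the public 166-key MACCS definitions.
#   circular_r2_1024 - radius-2 hashed circular fingerprint, 1024 bits.
#   path_d7_2048    - hashed linear-path fingerprint, paths of 1..7 bonds,
#                     2048 bits.
#
# The hash used by the two hashed kinds is a package-versioned polynomial
# string hash (see nv_hash_string) so bit positions are stable across
# platforms and R versions.

NV_FP_KINDS <- c(pubchem881 = 881L, maccs166 = 166L,
                 circular_r2_1024 = 1024L, path_d7_2048 = 2048L)

#' Compute a bit-string molecular fingerprint
#'
#' @param x a compound, molecule, or SMILES string.
#' @param kind one of `"pubchem881"`, `"maccs166"`, `"circular_r2_1024"`,
#'   `"path_d7_2048"`.
#' @return an object of class `nv_fingerprint` with fields `kind`, `length`
#'   and `on_bits` (sorted 0-based bit indices).
#' @examples
#' fp <- fingerprint("c1ccccc1", "maccs166")
#' fp$on_bits
#' @export
fingerprint <- function(x, kind = c("pubchem881", "maccs166",
                                    "circular_r2_1024", "path_d7_2048")) {
  kind <- match.arg(kind)
  mol <- nv_mol_of(x)
  bits <- switch(kind,
    pubchem881 = nv_fp_pubchem(mol),
    maccs166 = nv_fp_maccs(mol),
    circular_r2_1024 = nv_fp_circular(mol, radius = 2L, nbits = 1024L),
    path_d7_2048 = nv_fp_path(mol, max_depth = 7L, nbits = 2048L)
  )
  structure(list(kind = kind, length = NV_FP_KINDS[[kind]],
                 on_bits = sort(unique(as.integer(bits)))),
            class = "nv_fingerprint")
}

#' @export
print.nv_fingerprint <- function(x, ...) {
  cat("<nv_fingerprint> ", x$kind, ": ", length(x$on_bits), "/", x$length,
      " bits on\n", sep = "")
  invisible(x)
}

# -- PubChem 881 --------------------------------------------------------------

nv_pubchem_tables <- function() {
  tabs <- .nv_env[["pubchem_tables"]]
  if (is.null(tabs)) {
    ext <- function(f) system.file("extdata", f, package = "nitrotox",
                                   mustWork = TRUE)
    tabs <- list(
      elements = utils::read.delim(ext("pubchem_element_bits.tsv")),
      rings = utils::read.delim(ext("pubchem_ring_bits.tsv")),
      smarts = utils::read.delim(ext("pubchem_smarts_bits.tsv"))
    )
    assign("pubchem_tables", tabs, envir = .nv_env)
  }
  tabs
}

nv_fp_pubchem <- function(mol) {
  tabs <- nv_pubchem_tables()
  bits <- integer(0)

  # section 1: hierarchic element counts (hydrogens include implicit ones)
  zc <- table(factor(mol$Z, levels = 1:104))
  counts <- as.integer(zc)
  counts[1] <- counts[1] + sum(mol$nh)
  el <- tabs$elements
  on <- counts[el$z] >= el$threshold
  bits <- c(bits, el$bit[on])

  # section 2: ESSSR ring counts
  rings <- nv_esssr(mol)
  if (length(rings)) {
    info <- lapply(rings, function(r) nv_ring_class(mol, r))
    sizes <- vapply(info, `[[`, integer(1), "size")
    sat <- vapply(info, `[[`, logical(1), "sat")
    carbon <- vapply(info, `[[`, logical(1), "carbon_only")
    nitro <- vapply(info, `[[`, logical(1), "has_n")
    hetero <- vapply(info, `[[`, logical(1), "has_hetero")
    arom <- vapply(info, `[[`, logical(1), "aromatic")
    rt <- tabs$rings
    for (i in seq_len(nrow(rt))) {
      cnt <- switch(rt$class[i],
        any = sum(sizes == rt$size[i]),
        sat_carbon = sum(sizes == rt$size[i] & sat & carbon),
        sat_nitrogen = sum(sizes == rt$size[i] & sat & nitro),
        sat_hetero = sum(sizes == rt$size[i] & sat & hetero),
        unsat_carbon = sum(sizes == rt$size[i] & !sat & carbon),
        unsat_nitrogen = sum(sizes == rt$size[i] & !sat & nitro),
        unsat_hetero = sum(sizes == rt$size[i] & !sat & hetero),
        aromatic = sum(arom),
        hetero_aromatic = sum(arom & hetero)
      )
      if (cnt >= rt$threshold[i]) bits <- c(bits, rt$bit[i])
    }
  }

  # sections 3-7: substructure presence
  st <- tabs$smarts
  for (i in seq_len(nrow(st))) {
    if (nv_has_substructure(mol, st$smarts[i])) bits <- c(bits, st$bit[i])
  }
  bits
}

nv_ring_class <- function(mol, ring) {
  m <- length(ring)
  bond_ids <- integer(m)
  for (i in seq_len(m)) {
    bond_ids[i] <- nv_mol_bond_between(mol, ring[i],
                                       ring[if (i == m) 1L else i + 1L])
  }
  barom <- mol$bonds$aromatic[bond_ids]
  bord <- mol$bonds$order[bond_ids]
  z <- mol$Z[ring]
  list(
    size = m,
    sat = all(barom | bord == 1),
    carbon_only = all(z == 6),
    has_n = any(z == 7),
    has_hetero = any(z != 6 & z != 1),
    aromatic = all(barom)
  )
}

# ESSSR: the SSSR plus, for every atom triple u-v-w (u,w neighbours of v),
# the shortest cycle through that triple (= u-v-w closed by the shortest
# path u->w avoiding v). This reproduces the envelope rings of fused bicyclic
# systems (e.g. the 9-ring of benzodioxole, the 10-ring of naphthalene) that
# the PubChem ring section counts.
nv_esssr <- function(mol) {
  rings <- mol$rings
  keys <- vapply(rings, function(r) paste(sort(r), collapse = ","),
                 character(1))
  for (v in seq_len(mol$n)) {
    nbs <- mol$adj[[v]]
    if (length(nbs) < 2) next
    for (i in seq_len(length(nbs) - 1)) {
      for (j in (i + 1):length(nbs)) {
        u <- nbs[i]; w <- nbs[j]
        p <- nv_shortest_path_avoiding(mol$adj, u, w, avoid_atoms = v)
        if (is.null(p)) next
        ring <- c(v, p)
        if (length(ring) > 10L) next
        key <- paste(sort(ring), collapse = ",")
        if (!key %in% keys) {
          rings[[length(rings) + 1L]] <- ring
          keys <- c(keys, key)
        }
      }
    }
  }
  rings
}

# -- MACCS 166 ----------------------------------------------------------------

nv_maccs_table <- function() {
  tab <- .nv_env[["maccs"]]
  if (is.null(tab)) {
    path <- system.file("extdata", "maccs_keys.tsv", package = "nitrotox",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    assign("maccs", tab, envir = .nv_env)
  }
  tab
}

nv_fp_maccs <- function(mol) {
  tab <- nv_maccs_table()
  bits <- integer(0)
  for (i in seq_len(nrow(tab))) {
    key <- tab$key[i]; patt <- tab$smarts[i]; cnt <- tab$count[i]
    on <- if (key == 125L) {
      # >= 2 aromatic rings (SSSR rings whose bonds are all aromatic)
      n_arom <- sum(vapply(mol$rings, function(r) {
        nv_ring_class(mol, r)$aromatic
      }, logical(1)))
      n_arom >= 2L
    } else if (key == 166L) {
      length(unique(nv_components(mol))) >= 2L
    } else if (patt == "?") {
      FALSE
    } else if (cnt == 0L) {
      nv_has_substructure(mol, patt)
    } else {
      nv_count_unique_matches(mol, patt) > cnt
    }
    if (on) bits <- c(bits, key - 1L)  # key k -> bit k-1
  }
  bits
}

# -- hashed fingerprints ------------------------------------------------------

# 31-ary polynomial string hash modulo 2^31-1; exact in double arithmetic.
# Versioned: changing this function changes every hashed fingerprint, so it
# must stay fixed within a package major version.
nv_hash_string <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 7
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  h
}

nv_atom_invariant <- function(mol, a) {
  paste(mol$Z[a], mol$charge[a], mol$nh[a], mol$degree[a],
        as.integer(mol$aromatic[a]), as.integer(mol$ring_count[a] > 0),
        sep = ",")
}

nv_bond_code <- function(mol, k) {
  if (mol$bonds$aromatic[k]) "a" else as.character(mol$bonds$order[k])
}

# radius-limited circular environments (ECFP-style, string invariants)
nv_fp_circular <- function(mol, radius = 2L, nbits = 1024L) {
  inv <- vapply(seq_len(mol$n), function(a) nv_atom_invariant(mol, a),
                character(1))
  bits <- vapply(inv, nv_hash_string, numeric(1)) %% nbits
  for (r in seq_len(radius)) {
    nxt <- character(mol$n)
    for (a in seq_len(mol$n)) {
      nbs <- mol$adj[[a]]
      if (length(nbs)) {
        parts <- vapply(seq_along(nbs), function(i) {
          k <- mol$badj[[a]][i]
          paste0(nv_bond_code(mol, k), "(", inv[nbs[i]], ")")
        }, character(1))
        nxt[a] <- paste0(inv[a], "|", paste(sort(parts), collapse = ";"))
      } else {
        nxt[a] <- inv[a]
      }
    }
    inv <- nxt
    bits <- c(bits, vapply(inv, nv_hash_string, numeric(1)) %% nbits)
  }
  as.integer(bits)
}

# linear paths of 1..max_depth bonds, canonicalized by direction
nv_fp_path <- function(mol, max_depth = 7L, nbits = 2048L) {
  atom_code <- function(a) {
    paste0(mol$elem[a], if (mol$aromatic[a]) "ar" else "",
           if (mol$charge[a] != 0) sprintf("%+d", mol$charge[a]) else "")
  }
  codes <- vapply(seq_len(mol$n), atom_code, character(1))
  paths <- new.env(parent = emptyenv())

  walk <- function(path_atoms, path_bonds) {
    a <- path_atoms[length(path_atoms)]
    for (i in seq_along(mol$adj[[a]])) {
      nb <- mol$adj[[a]][i]
      if (nb %in% path_atoms) next
      k <- mol$badj[[a]][i]
      atoms2 <- c(path_atoms, nb)
      bonds2 <- c(path_bonds, nv_bond_code(mol, k))
      fwd <- paste(codes[atoms2], c(bonds2, ""), sep = "", collapse = "")
      rev_ <- paste(codes[rev(atoms2)], c(rev(bonds2), ""), sep = "",
                    collapse = "")
      assign(min(fwd, rev_), TRUE, envir = paths)
      if (length(bonds2) < max_depth) walk(atoms2, bonds2)
    }
  }
  for (a in seq_len(mol$n)) walk(a, character(0))
  keys <- ls(paths)
  if (!length(keys)) return(integer(0))
  as.integer(vapply(keys, nv_hash_string, numeric(1)) %% nbits)
}
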