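# Minimal molecular graph engine: SMILES in, perceived molecule out.
#
# The panel chemistry this package targets is small neutral/zwitterionic
# organics (C/H/N/O aromatics, charged nitro groups), but the parser and
# perception code below implement the general organic-subset SMILES rules so
# arbitrary small molecules round-trip correctly.

NV_VALENCES <- list(
  B = 3L, C = 4L, N = c(3L, 5L), O = 2L, P = c(3L, 5L), S = c(2L, 4L, 6L),
  F = 1L, Cl = 1L, Br = 1L, I = 1L
)

NV_ATOMIC_NUMBERS <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40, Nb = 41, Mo = 42,
  Tc = 43, Ru = 44, Rh = 45, Pd = 46, Ag = 47, Cd = 48, In = 49, Sn = 50,
  Sb = 51, Te = 52, I = 53, Xe = 54, Cs = 55, Ba = 56, La = 57, Ce = 58,
  Pr = 59, Nd = 60, Pm = 61, Sm = 62, Eu = 63, Gd = 64, Tb = 65, Dy = 66,
  Ho = 67, Er = 68, Tm = 69, Yb = 70, Lu = 71, Hf = 72, Ta = 73, W = 74,
  Re = 75, Os = 76, Ir = 77, Pt = 78, Au = 79, Hg = 80, Tl = 81, Pb = 82,
  Bi = 83, Po = 84, At = 85, Rn = 86, Fr = 87, Ra = 88, Ac = 89, Th = 90,
  Pa = 91, U = 92, Np = 93, Pu = 94, Am = 95, Cm = 96, Bk = 97, Cf = 98,
  Es = 99, Fm = 100, Md = 101, No = 102, Lr = 103, Rf = 104
)

# Standard atomic weights (IUPAC 2021, conventional values) for the elements
# a small-molecule panel can realistically contain.
NV_ATOMIC_WEIGHTS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.99, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  As = 74.922, Se = 78.971, Br = 79.904, I = 126.904
)

#' Parse a SMILES string into a molecule object
#'
#' Builds a molecular graph from a SMILES string: atoms (element, formal
#' charge, hydrogen count), bonds (order, aromaticity), ring perception
#' (SSSR), kekulization of aromatic input and aromaticity perception of
#' kekulized input (Hueckel 4n+2 on SSSR rings and fused-ring perimeters).
#'
#' Supported syntax: the organic subset (`B C N O P S F Cl Br I` and their
#' aromatic lowercase forms), bracket atoms with isotope, charge and explicit
#' hydrogen counts, branches, ring-closure digits and `%nn` labels, bond
#' symbols `- = # : / \` and disconnected components separated by `.`.
#' Stereochemistry markers are accepted and ignored.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `nv_mol`: a list with element vectors `elem`,
#'   `Z`, `charge`, `nh` (total attached hydrogens), `aromatic`, a bond table
#'   (`a1`, `a2`, `order`, `aromatic`), the SSSR ring list and derived ring
#'   membership tables.
#' @examples
#' m <- nv_parse_smiles("C1=CC=C(C=C1)C=C[N+](=O)[O-]")
#' sum(m$Z > 1) # heavy atoms
#' @export
nv_parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("smiles must be a single non-empty string", call. = FALSE)
  }
  raw <- nv_scan_smiles(smiles)
  mol <- nv_perceive(raw)
  mol$smiles <- smiles
  mol
}

# -- tokenizer / graph builder -----------------------------------------------

nv_scan_smiles <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  i <- 1L

  elem <- character(0); arom_in <- logical(0); charge <- integer(0)
  hcount <- integer(0)   # NA = organic subset (compute implicit H)
  isotope <- integer(0)

  b_a1 <- integer(0); b_a2 <- integer(0); b_sym <- character(0)

  prev <- NA_integer_          # previous atom index for next bond
  stack <- integer(0)          # branch stack
  pend_bond <- ""              # bond symbol awaiting next atom
  ring_open <- list()          # label -> list(atom, bond)

  add_atom <- function(sym, aromatic, chg, hc, iso) {
    elem[[length(elem) + 1L]] <<- sym
    arom_in[[length(arom_in) + 1L]] <<- aromatic
    charge[[length(charge) + 1L]] <<- chg
    hcount[[length(hcount) + 1L]] <<- hc
    isotope[[length(isotope) + 1L]] <<- iso
    idx <- length(elem)
    if (!is.na(prev)) {
      b_a1[[length(b_a1) + 1L]] <<- prev
      b_a2[[length(b_a2) + 1L]] <<- idx
      b_sym[[length(b_sym) + 1L]] <<- pend_bond
    }
    prev <<- idx
    pend_bond <<- ""
    idx
  }

  close_ring <- function(label) {
    if (is.null(ring_open[[label]])) {
      ring_open[[label]] <<- list(atom = prev, bond = pend_bond)
    } else {
      opened <- ring_open[[label]]
      bsym <- pend_bond
      if (!nzchar(bsym)) bsym <- opened$bond
      if (nzchar(opened$bond) && nzchar(pend_bond) &&
          opened$bond != pend_bond) {
        stop("conflicting ring-closure bond symbols for label ", label,
             call. = FALSE)
      }
      if (opened$atom == prev) stop("ring bond to self", call. = FALSE)
      b_a1[[length(b_a1) + 1L]] <<- opened$atom
      b_a2[[length(b_a2) + 1L]] <<- prev
      b_sym[[length(b_sym) + 1L]] <<- bsym
      ring_open[[label]] <<- NULL
    }
    pend_bond <<- ""
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", "=", "#", ":", "/", "\\", "$")) {
      pend_bond <- ch; i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMILES", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pend_bond <- ""; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring label", call. = FALSE)
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed '[' in SMILES", call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      at <- nv_parse_bracket_atom(body)
      add_atom(at$elem, at$aromatic, at$charge, at$hcount, at$isotope)
      i <- j + 1L
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(two, FALSE, 0L, NA_integer_, 0L); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(ch, FALSE, 0L, NA_integer_, 0L); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(toupper(ch), TRUE, 0L, NA_integer_, 0L); i <- i + 1L
      } else if (ch == "*") {
        stop("wildcard atoms are not valid in molecule SMILES", call. = FALSE)
      } else {
        stop("unexpected character '", ch, "' in SMILES at position ", i,
             call. = FALSE)
      }
    }
  }
  if (length(stack)) stop("unbalanced '(' in SMILES", call. = FALSE)
  open_labels <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_labels)) {
    stop("unclosed ring bond label(s): ", paste(open_labels, collapse = ", "),
         call. = FALSE)
  }
  if (!length(elem)) stop("SMILES contains no atoms", call. = FALSE)
  list(elem = elem, arom_in = arom_in, charge = charge, hcount = hcount,
       isotope = isotope,
       bonds = data.frame(a1 = b_a1, a2 = b_a2, sym = b_sym,
                          stringsAsFactors = FALSE))
}

nv_parse_bracket_atom <- function(body) {
  # [isotope? symbol chirality? Hn? charge? :class?]
  m <- regmatches(body, regexec(
    "^([0-9]*)(se|as|[A-Z][a-z]?|[bcnops])((?:@{1,2}(?:TH|AL|SP|TB|OH)?[0-9]*)?)(H[0-9]*)?((?:\\+[0-9+]*|-[0-9-]*))?(:[0-9]+)?$",
    body, perl = TRUE))[[1]]
  if (!length(m)) stop("cannot parse bracket atom [", body, "]", call. = FALSE)
  iso <- if (nzchar(m[2])) as.integer(m[2]) else 0L
  sym <- m[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  if (aromatic) sym <- paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  if (!sym %in% names(NV_ATOMIC_NUMBERS)) {
    stop("unknown element '", sym, "' in bracket atom", call. = FALSE)
  }
  hc <- 0L
  if (!is.na(m[5]) && nzchar(m[5])) {
    hc <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
  }
  chg <- 0L
  if (!is.na(m[6]) && nzchar(m[6])) {
    cs <- m[6]
    if (grepl("^\\++$", cs)) chg <- nchar(cs)
    else if (grepl("^-+$", cs)) chg <- -nchar(cs)
    else chg <- as.integer(cs)
  }
  list(elem = sym, aromatic = aromatic, charge = chg, hcount = hc,
       isotope = iso)
}

# -- perception ---------------------------------------------------------------

nv_perceive <- function(raw) {
  n <- length(raw$elem)
  bonds <- raw$bonds
  arom_atom <- raw$arom_in

  # resolve bond symbols -> order + aromatic flag
  nb <- nrow(bonds)
  order <- rep(1, nb)
  barom <- rep(FALSE, nb)
  for (k in seq_len(nb)) {
    s <- bonds$sym[k]
    if (s == "=") order[k] <- 2
    else if (s == "#") order[k] <- 3
    else if (s == "$") order[k] <- 4
    else if (s == ":") barom[k] <- TRUE
    else if (s == "") {
      if (arom_atom[bonds$a1[k]] && arom_atom[bonds$a2[k]]) barom[k] <- TRUE
    }
  }

  mol <- list(
    n = n, elem = raw$elem,
    Z = unname(NV_ATOMIC_NUMBERS[raw$elem]),
    charge = raw$charge, isotope = raw$isotope,
    aromatic = arom_atom,
    bonds = data.frame(a1 = bonds$a1, a2 = bonds$a2, order = order,
                       aromatic = barom)
  )
  class(mol) <- "nv_mol"
  mol <- nv_index_bonds(mol)

  # implicit hydrogens (organic subset); bracket atoms use their H count
  mol$nh <- integer(n)
  for (a in seq_len(n)) {
    if (!is.na(raw$hcount[a])) {
      mol$nh[a] <- raw$hcount[a]
    } else {
      mol$nh[a] <- nv_implicit_h(mol, a)
    }
  }

  # rings are needed both for kekulization sanity and aromaticity
  mol$rings <- nv_sssr(mol)
  mol <- nv_ring_tables(mol)

  # demote "aromatic" bonds that are not in any ring (e.g. bare biphenyl
  # linker bonds between two lowercase atoms): they are plain single bonds
  if (any(mol$bonds$aromatic & !mol$bond_in_ring)) {
    mol$bonds$aromatic[mol$bonds$aromatic & !mol$bond_in_ring] <- FALSE
  }

  if (any(mol$aromatic)) mol <- nv_kekulize(mol)
  mol <- nv_perceive_aromaticity(mol)
  mol
}

nv_index_bonds <- function(mol) {
  adj <- vector("list", mol$n)
  badj <- vector("list", mol$n)
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
      adj[[a1]] <- c(adj[[a1]], a2); adj[[a2]] <- c(adj[[a2]], a1)
      badj[[a1]] <- c(badj[[a1]], k); badj[[a2]] <- c(badj[[a2]], k)
    }
  }
  mol$adj <- adj
  mol$badj <- badj
  mol$degree <- lengths(adj)
  mol
}

nv_implicit_h <- function(mol, a) {
  vals <- NV_VALENCES[[mol$elem[a]]]
  if (is.null(vals)) return(0L)
  bk <- mol$badj[[a]]
  s <- 0
  for (k in bk) s <- s + if (mol$bonds$aromatic[k]) 1.5 else mol$bonds$order[k]
  s <- ceiling(s)
  for (v in vals) if (v >= s) return(as.integer(v - s))
  0L
}

# -- ring perception (SSSR + helper tables) ----------------------------------

nv_shortest_path_avoiding <- function(adj, from, to, avoid_atoms = integer(0),
                                      avoid_bond = NULL, bonds = NULL) {
  # BFS shortest path from -> to; avoid_atoms excluded; optionally one bond
  n <- length(adj)
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  seen[avoid_atoms] <- TRUE
  seen[from] <- TRUE
  queue <- from
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!is.null(avoid_bond) &&
          ((cur == bonds$a1[avoid_bond] && nb == bonds$a2[avoid_bond]) ||
           (cur == bonds$a2[avoid_bond] && nb == bonds$a1[avoid_bond]))) next
      if (!seen[nb]) {
        seen[nb] <- TRUE
        prev[nb] <- cur
        if (nb == to) {
          path <- nb
          while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
          return(path)
        }
        queue <- c(queue, nb)
      }
    }
  }
  NULL
}

nv_sssr <- function(mol) {
  nb <- nrow(mol$bonds)
  if (!nb) return(list())
  comp <- nv_components(mol)
  dim_cycles <- nb - mol$n + length(unique(comp))
  if (dim_cycles <= 0) return(list())

  # candidate rings: shortest cycle through every bond
  cands <- list()
  for (k in seq_len(nb)) {
    p <- nv_shortest_path_avoiding(mol$adj, mol$bonds$a1[k], mol$bonds$a2[k],
                                   avoid_bond = k, bonds = mol$bonds)
    if (!is.null(p)) cands[[length(cands) + 1L]] <- p
  }
  if (!length(cands)) return(list())
  cands <- cands[order(lengths(cands))]

  # greedy GF(2) independence over bond incidence vectors
  ring_bond_vec <- function(ring) {
    v <- logical(nb)
    m <- length(ring)
    for (i in seq_len(m)) {
      a <- ring[i]; b <- ring[if (i == m) 1L else i + 1L]
      hit <- which((mol$bonds$a1 == a & mol$bonds$a2 == b) |
                   (mol$bonds$a1 == b & mol$bonds$a2 == a))
      v[hit[1]] <- TRUE
    }
    v
  }
  basis <- list(); rings <- list()
  seen_sets <- character(0)
  for (ring in cands) {
    key <- paste(sort(ring), collapse = ",")
    if (key %in% seen_sets) next
    v <- ring_bond_vec(ring)
    red <- v
    for (b in basis) {
      pivot <- which(b)[1]
      if (red[pivot]) red <- xor(red, b)
    }
    if (any(red)) {
      basis[[length(basis) + 1L]] <- red
      rings[[length(rings) + 1L]] <- ring
      seen_sets <- c(seen_sets, key)
      if (length(rings) == dim_cycles) break
    }
  }
  rings
}

nv_components <- function(mol) {
  comp <- rep(NA_integer_, mol$n)
  cid <- 0L
  for (s in seq_len(mol$n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (nb in mol$adj[[cur]]) if (is.na(comp[nb])) {
        comp[nb] <- cid; queue <- c(queue, nb)
      }
    }
  }
  comp
}

nv_ring_tables <- function(mol) {
  n <- mol$n
  rc <- integer(n)
  sizes <- vector("list", n)
  bond_ring <- rep(FALSE, nrow(mol$bonds))
  for (ring in mol$rings) {
    rc[ring] <- rc[ring] + 1L
    for (a in ring) sizes[[a]] <- c(sizes[[a]], length(ring))
    m <- length(ring)
    for (i in seq_len(m)) {
      a <- ring[i]; b <- ring[if (i == m) 1L else i + 1L]
      hit <- which((mol$bonds$a1 == a & mol$bonds$a2 == b) |
                   (mol$bonds$a1 == b & mol$bonds$a2 == a))
      bond_ring[hit] <- TRUE
    }
  }
  mol$ring_count <- rc
  mol$ring_sizes <- sizes
  mol$bond_in_ring <- bond_ring
  mol
}

# -- kekulization -------------------------------------------------------------

nv_kekulize <- function(mol) {
  # Atoms written aromatic that still need one double bond within the
  # aromatic system (sp2 atoms whose sigma skeleton leaves valence short).
  needs <- rep(FALSE, mol$n)
  for (a in which(mol$aromatic)) {
    has_double <- any(mol$bonds$order[mol$badj[[a]]] >= 2)
    sig <- mol$degree[a] + mol$nh[a]
    el <- mol$elem[a]; ch <- mol$charge[a]
    needs[a] <- if (has_double) FALSE
      else if (el == "C" && ch == 0) sig == 3
      else if (el == "C" && ch == -1) FALSE
      else if (el == "C" && ch == 1) FALSE
      else if (el == "N" && ch == 0) sig == 2
      else if (el == "N" && ch == 1) sig == 3
      else if (el == "P" && ch == 0) sig == 2
      else if (el %in% c("O", "S", "Se")) ch == 1
      else FALSE
  }
  arom_bonds <- which(mol$bonds$aromatic)
  # backtracking perfect matching on 'needs' atoms over aromatic bonds
  match_edges <- nv_match_doubles(which(needs), arom_bonds, mol$bonds)
  if (is.null(match_edges)) {
    stop("kekulization failed for SMILES aromatic system", call. = FALSE)
  }
  mol$bonds$order[match_edges] <- 2
  mol
}

nv_match_doubles <- function(need_atoms, cand_bonds, bonds) {
  if (!length(need_atoms)) return(integer(0))
  need <- rep(FALSE, max(c(bonds$a1, bonds$a2, 1)))
  need[need_atoms] <- TRUE
  chosen <- integer(0)
  recurse <- function(remaining, need) {
    if (!any(need)) return(integer(0))
    a <- which(need)[1]
    for (k in remaining) {
      a1 <- bonds$a1[k]; a2 <- bonds$a2[k]
      if ((a1 == a && need[a2]) || (a2 == a && need[a1])) {
        need2 <- need; need2[c(a1, a2)] <- FALSE
        res <- recurse(setdiff(remaining, k), need2)
        if (!is.null(res)) return(c(k, res))
      }
    }
    NULL
  }
  recurse(cand_bonds, need)
}

# -- aromaticity perception ---------------------------------------------------

nv_pi_contribution <- function(mol, a, ring) {
  # electrons atom a contributes to the pi system of 'ring';
  # NA = atom cannot take part in an aromatic ring
  el <- mol$elem[a]; ch <- mol$charge[a]
  dbl_partners <- integer(0)
  for (k in mol$badj[[a]]) {
    if (mol$bonds$order[k] == 2) {
      other <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
      dbl_partners <- c(dbl_partners, other)
    }
    if (mol$bonds$order[k] >= 3) return(NA_real_)
  }
  if (length(dbl_partners) > 1) return(NA_real_)
  if (length(dbl_partners) == 1) {
    return(if (dbl_partners %in% ring) 1 else 0)  # exocyclic double: 0
  }
  # sigma-only atom
  sig <- mol$degree[a] + mol$nh[a]
  if (el == "C") {
    if (ch == -1 && sig == 3) return(2)
    if (ch == 1 && sig == 3) return(0)
    return(NA_real_)  # sp3 carbon
  }
  if (el %in% c("N", "P")) {
    if (ch == 0 && sig == 3) return(2)   # pyrrole-type
    if (ch == -1 && sig == 2) return(2)
    return(NA_real_)
  }
  if (el %in% c("O", "S", "Se")) {
    if (ch == 0 && sig == 2) return(2)
    return(NA_real_)
  }
  if (el == "B" && ch == 0 && sig == 3) return(0)
  NA_real_
}

nv_cycle_is_aromatic <- function(mol, ring) {
  total <- 0
  for (a in ring) {
    pi <- nv_pi_contribution(mol, a, ring)
    if (is.na(pi)) return(FALSE)
    total <- total + pi
  }
  total %% 4 == 2
}

nv_mark_aromatic_cycle <- function(mol, ring) {
  mol$aromatic[ring] <- TRUE
  m <- length(ring)
  for (i in seq_len(m)) {
    a <- ring[i]; b <- ring[if (i == m) 1L else i + 1L]
    hit <- which((mol$bonds$a1 == a & mol$bonds$a2 == b) |
                 (mol$bonds$a1 == b & mol$bonds$a2 == a))
    mol$bonds$aromatic[hit] <- TRUE
  }
  mol
}

nv_perceive_aromaticity <- function(mol) {
  mol$aromatic <- rep(FALSE, mol$n)
  mol$bonds$aromatic <- rep(FALSE, nrow(mol$bonds))
  if (!length(mol$rings)) return(mol)
  for (ring in mol$rings) {
    if (nv_cycle_is_aromatic(mol, ring)) mol <- nv_mark_aromatic_cycle(mol, ring)
  }
  # fused-ring perimeters (naphthalene-type systems where a single SSSR ring
  # fails Hueckel in the chosen Kekule structure)
  nr <- length(mol$rings)
  if (nr >= 2) {
    for (i in seq_len(nr - 1)) {
      for (j in (i + 1):nr) {
        shared <- intersect(mol$rings[[i]], mol$rings[[j]])
        if (length(shared) < 2) next
        if (all(mol$aromatic[mol$rings[[i]]]) &&
            all(mol$aromatic[mol$rings[[j]]])) next
        per <- nv_perimeter_cycle(mol, mol$rings[[i]], mol$rings[[j]])
        if (is.null(per)) next
        if (nv_cycle_is_aromatic(mol, per)) mol <- nv_mark_aromatic_cycle(mol, per)
      }
    }
  }
  mol
}

nv_perimeter_cycle <- function(mol, r1, r2) {
  # symmetric difference of the two ring edge sets, if it forms one cycle
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  edges_of <- function(ring) {
    m <- length(ring)
    vapply(seq_len(m), function(i) {
      edge_key(ring[i], ring[if (i == m) 1L else i + 1L])
    }, character(1))
  }
  e1 <- edges_of(r1); e2 <- edges_of(r2)
  keep <- c(setdiff(e1, e2), setdiff(e2, e1))
  if (!length(keep)) return(NULL)
  pairs <- do.call(rbind, lapply(strsplit(keep, " "), as.integer))
  verts <- unique(as.vector(pairs))
  deg <- table(factor(as.vector(pairs), levels = verts))
  if (any(deg != 2)) return(NULL)
  # walk the cycle
  adj <- lapply(verts, function(v) {
    setdiff(unique(as.vector(pairs[pairs[, 1] == v | pairs[, 2] == v, ])), v)
  })
  names(adj) <- as.character(verts)
  start <- verts[1]; cyc <- start
  prev <- NA_integer_; cur <- start
  repeat {
    nbs <- adj[[as.character(cur)]]
    nxt <- if (is.na(prev)) nbs[1] else setdiff(nbs, prev)[1]
    if (is.na(nxt)) return(NULL)
    if (nxt == start) break
    cyc <- c(cyc, nxt); prev <- cur; cur <- nxt
    if (length(cyc) > length(verts)) return(NULL)
  }
  if (length(cyc) != length(verts)) return(NULL)
  cyc
}

# -- derived quantities -------------------------------------------------------

#' @export
print.nv_mol <- function(x, ...) {
  cat("<nv_mol> ", x$smiles, "\n  atoms: ", x$n, " (",
      sum(x$aromatic), " aromatic), bonds: ", nrow(x$bonds),
      ", rings: ", length(x$rings), "\n", sep = "")
  invisible(x)
}

# total connectivity (heavy neighbours + hydrogens)
nv_connectivity <- function(mol) mol$degree + mol$nh

# add explicit hydrogen atoms (used for Crippen atom typing)
nv_add_hydrogens <- function(mol) {
  nh <- mol$nh
  n0 <- mol$n
  extra <- sum(nh)
  if (!extra) return(mol)
  elem <- c(mol$elem, rep("H", extra))
  Z <- c(mol$Z, rep(1L, extra))
  charge <- c(mol$charge, rep(0L, extra))
  isotope <- c(mol$isotope, rep(0L, extra))
  aromatic <- c(mol$aromatic, rep(FALSE, extra))
  a1 <- mol$bonds$a1; a2 <- mol$bonds$a2
  order <- mol$bonds$order; barom <- mol$bonds$aromatic
  idx <- n0
  for (a in seq_len(n0)) {
    if (nh[a] > 0) {
      for (i in seq_len(nh[a])) {
        idx <- idx + 1L
        a1 <- c(a1, a); a2 <- c(a2, idx)
        order <- c(order, 1); barom <- c(barom, FALSE)
      }
    }
  }
  out <- list(
    n = n0 + extra, elem = elem, Z = Z, charge = charge, isotope = isotope,
    aromatic = aromatic,
    bonds = data.frame(a1 = a1, a2 = a2, order = order, aromatic = barom),
    smiles = mol$smiles
  )
  class(out) <- "nv_mol"
  out <- nv_index_bonds(out)
  out$nh <- c(integer(n0), rep(0L, extra))
  # hydrogens attached to heavies are now explicit neighbours; keep the
  # total-H bookkeeping consistent: nh counts H neighbours + implicit
  out$nh[seq_len(n0)] <- nh[seq_len(n0)]  # total H attached, now explicit
  out$implicit_h <- rep(0L, out$n)
  out$rings <- lapply(mol$rings, identity)
  out <- nv_ring_tables(out)
  out$explicit_h <- TRUE
  out
}
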