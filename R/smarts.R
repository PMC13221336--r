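# SMARTS subset engine.
#
# Implements the pattern language needed by the fingerprint/descriptor tables
# shipped with the package: atom primitives *, A, a, element symbols
# (aliphatic/aromatic), #n, Hn, Xn, Dn, R/Rn, r/rn, charge, isotope,
# recursive $(...), with !, & (or juxtaposition), ',' and ';' logic at the
# usual precedences; bond primitives - = # : ~ @ with the same logic
# operators; branches and ring closures. Unspecified bonds match
# single-or-aromatic, per the Daylight convention.

.nv_env <- new.env(parent = emptyenv())

nv_smarts <- function(smarts) {
  key <- paste0("pat:", smarts)
  pat <- .nv_env[[key]]
  if (is.null(pat)) {
    pat <- nv_parse_smarts(smarts)
    assign(key, pat, envir = .nv_env)
  }
  pat
}

# -- parser -------------------------------------------------------------------

nv_parse_smarts <- function(smarts) {
  if (!is.character(smarts) || length(smarts) != 1L || !nzchar(smarts)) {
    stop("smarts must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(smarts, "")[[1]]
  n <- length(chars)
  i <- 1L

  atoms <- list()
  b_a1 <- integer(0); b_a2 <- integer(0); b_expr <- list()
  prev <- NA_integer_
  stack <- integer(0)
  pend_bond <- NULL
  ring_open <- list()

  bond_chars <- c("-", "=", "#", ":", "~", "@", "!", "&", ";", ",", "/", "\\")

  add_atom <- function(expr) {
    atoms[[length(atoms) + 1L]] <<- expr
    idx <- length(atoms)
    if (!is.na(prev)) {
      b_a1[[length(b_a1) + 1L]] <<- prev
      b_a2[[length(b_a2) + 1L]] <<- idx
      b_expr[length(b_expr) + 1L] <<- list(pend_bond)
    }
    prev <<- idx
    pend_bond <<- NULL
    idx
  }
  close_ring <- function(label) {
    if (is.null(ring_open[[label]])) {
      ring_open[[label]] <<- list(atom = prev, bond = pend_bond)
    } else {
      opened <- ring_open[[label]]
      bexpr <- if (!is.null(pend_bond)) pend_bond else opened$bond
      b_a1[[length(b_a1) + 1L]] <<- opened$atom
      b_a2[[length(b_a2) + 1L]] <<- prev
      b_expr[length(b_expr) + 1L] <<- list(bexpr)
      ring_open[[label]] <<- NULL
    }
    pend_bond <<- NULL
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop("unbalanced ')' in SMARTS", call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch); i <- i + 1L
    } else if (ch == "%") {
      close_ring(paste0(chars[i + 1L], chars[i + 2L])); i <- i + 3L
    } else if (ch %in% bond_chars) {
      j <- i
      while (j <= n && chars[j] %in% bond_chars) j <- j + 1L
      pend_bond <- nv_parse_bond_expr(paste(chars[i:(j - 1L)], collapse = ""))
      i <- j
    } else if (ch == "[") {
      depth <- 1L; j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) stop("unclosed '[' in SMARTS", call. = FALSE)
      body <- paste(chars[(i + 1L):(j - 2L)], collapse = "")
      add_atom(nv_parse_atom_expr(body))
      i <- j
    } else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(nv_prim("elem_aliph", unname(NV_ATOMIC_NUMBERS[two])))
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        add_atom(nv_prim("elem_aliph", unname(NV_ATOMIC_NUMBERS[ch])))
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        add_atom(nv_prim("elem_arom", unname(NV_ATOMIC_NUMBERS[toupper(ch)])))
        i <- i + 1L
      } else if (ch == "*") {
        add_atom(nv_prim("any", 0L)); i <- i + 1L
      } else if (ch == "A") {
        add_atom(nv_prim("aliph", 0L)); i <- i + 1L
      } else if (ch == "a") {
        add_atom(nv_prim("arom", 0L)); i <- i + 1L
      } else {
        stop("unexpected character '", ch, "' in SMARTS '", smarts, "'",
             call. = FALSE)
      }
    }
  }
  if (!length(atoms)) stop("SMARTS contains no atoms", call. = FALSE)
  if (length(stack)) stop("unbalanced '(' in SMARTS", call. = FALSE)
  open_ring <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_ring)) {
    stop("unclosed ring label(s) in SMARTS: ",
         paste(open_ring, collapse = ", "), call. = FALSE)
  }

  np <- length(atoms)
  adj <- vector("list", np)
  eadj <- vector("list", np)
  if (length(b_a1)) {
    for (k in seq_along(b_a1)) {
      adj[[b_a1[k]]] <- c(adj[[b_a1[k]]], b_a2[k])
      adj[[b_a2[k]]] <- c(adj[[b_a2[k]]], b_a1[k])
      eadj[[b_a1[k]]] <- c(eadj[[b_a1[k]]], k)
      eadj[[b_a2[k]]] <- c(eadj[[b_a2[k]]], k)
    }
  }
  # BFS order for the matcher, each atom anchored to an earlier neighbour
  order <- 1L
  anchor <- list(NULL)
  seen <- rep(FALSE, np); seen[1] <- TRUE
  queue <- 1L
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (idx in seq_along(adj[[cur]])) {
      nb <- adj[[cur]][idx]
      if (!seen[nb]) {
        seen[nb] <- TRUE
        order <- c(order, nb)
        anchor[[length(anchor) + 1L]] <- c(cur, eadj[[cur]][idx])
        queue <- c(queue, nb)
      }
    }
  }
  if (!all(seen)) stop("disconnected SMARTS pattern unsupported", call. = FALSE)

  structure(list(
    smarts = smarts, atoms = atoms, natoms = np,
    b_a1 = b_a1, b_a2 = b_a2, b_expr = b_expr,
    order = order, anchor = anchor
  ), class = "nv_smarts")
}

nv_prim <- function(kind, value) list(op = "prim", kind = kind, value = value)

# atom expression: ';' (lowest) > ',' > '&'/juxtaposition > '!'
nv_parse_atom_expr <- function(body) {
  toks <- nv_tokenize_atom(body)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }

  parse_low <- function() {
    args <- list(parse_or())
    while (!is.null(peek()) && identical(peek()$t, ";")) {
      take(); args[[length(args) + 1L]] <- parse_or()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.null(peek()) && identical(peek()$t, ",")) {
      take(); args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_not())
    repeat {
      p <- peek()
      if (is.null(p) || p$t %in% c(",", ";")) break
      if (identical(p$t, "&")) take()
      args[[length(args) + 1L]] <- parse_not()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_not <- function() {
    if (!is.null(peek()) && identical(peek()$t, "!")) {
      take(); return(list(op = "not", args = list(parse_not())))
    }
    p <- take()
    if (is.null(p) || is.null(p$prim)) {
      stop("malformed atom expression [", body, "]", call. = FALSE)
    }
    p$prim
  }
  out <- parse_low()
  if (pos <= length(toks)) {
    stop("trailing tokens in atom expression [", body, "]", call. = FALSE)
  }
  out
}

nv_tokenize_atom <- function(body) {
  chars <- strsplit(body, "")[[1]]
  n <- length(chars); i <- 1L
  toks <- list()
  push_op <- function(t) toks[[length(toks) + 1L]] <<- list(t = t)
  push_prim <- function(kind, value) {
    toks[[length(toks) + 1L]] <<- list(t = "p", prim = nv_prim(kind, value))
  }
  read_digits <- function() {
    j <- i
    while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
    if (j == i) return(NA_integer_)
    v <- as.integer(paste(chars[i:(j - 1L)], collapse = ""))
    i <<- j
    v
  }
  first <- TRUE
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("!", "&", ",", ";")) { push_op(ch); i <- i + 1L; next }
    if (ch == "$") {
      if (i + 1L > n || chars[i + 1L] != "(") {
        stop("expected '(' after '$' in [", body, "]", call. = FALSE)
      }
      depth <- 1L; j <- i + 2L
      while (j <= n && depth > 0L) {
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
        j <- j + 1L
      }
      inner <- paste(chars[(i + 2L):(j - 2L)], collapse = "")
      push_prim("recursive", nv_parse_smarts(inner))
      i <- j; next
    }
    if (grepl("[0-9]", ch)) {  # isotope
      v <- read_digits()
      push_prim("isotope", v); next
    }
    if (ch == "#") {
      i <- i + 1L
      v <- read_digits()
      if (is.na(v)) stop("expected digits after '#' in [", body, "]",
                         call. = FALSE)
      push_prim("elem_any", v); next
    }
    if (ch == "*") { push_prim("any", 0L); i <- i + 1L; next }
    if (ch == "+" || ch == "-") {
      sign <- if (ch == "+") 1L else -1L
      j <- i + 1L
      reps <- 1L
      while (j <= n && chars[j] == ch) { reps <- reps + 1L; j <- j + 1L }
      if (reps > 1L) { push_prim("charge", sign * reps); i <- j; next }
      i <- i + 1L
      v <- read_digits()
      push_prim("charge", if (is.na(v)) sign else sign * v)
      next
    }
    # two-letter element symbols take priority (e.g. Cl, Br, Na, Sc, Se)
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% names(NV_ATOMIC_NUMBERS) && grepl("^[A-Z][a-z]$", two) &&
        !(two %in% c("Hf", "Ho"))) {
      push_prim("elem_aliph", unname(NV_ATOMIC_NUMBERS[two])); i <- i + 2L
      next
    }
    if (two %in% c("Hf", "Ho")) {  # avoid clashing with H-count
      push_prim("elem_aliph", unname(NV_ATOMIC_NUMBERS[two])); i <- i + 2L
      next
    }
    if (two %in% c("se", "as")) {
      sym <- paste0(toupper(substr(two, 1, 1)), substring(two, 2))
      push_prim("elem_arom", unname(NV_ATOMIC_NUMBERS[sym])); i <- i + 2L
      next
    }
    if (ch == "H") {
      i <- i + 1L
      v <- read_digits()
      push_prim("hcount", if (is.na(v)) 1L else v); next
    }
    if (ch == "X") {
      i <- i + 1L
      v <- read_digits()
      push_prim("connectivity", if (is.na(v)) 1L else v); next
    }
    if (ch == "D") {
      i <- i + 1L
      v <- read_digits()
      push_prim("degree", if (is.na(v)) 1L else v); next
    }
    if (ch == "R") {
      i <- i + 1L
      v <- read_digits()
      push_prim("ring_count", if (is.na(v)) -1L else v); next  # -1 = any ring
    }
    if (ch == "r") {
      i <- i + 1L
      v <- read_digits()
      push_prim("ring_size", if (is.na(v)) -1L else v); next
    }
    if (ch == "a") { push_prim("arom", 0L); i <- i + 1L; next }
    if (ch == "A") { push_prim("aliph", 0L); i <- i + 1L; next }
    if (ch == "@") { i <- i + 1L; next }  # chirality: ignore
    if (grepl("[A-Z]", ch) && ch %in% names(NV_ATOMIC_NUMBERS)) {
      push_prim("elem_aliph", unname(NV_ATOMIC_NUMBERS[ch])); i <- i + 1L
      next
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      push_prim("elem_arom", unname(NV_ATOMIC_NUMBERS[toupper(ch)]))
      i <- i + 1L; next
    }
    stop("unexpected character '", ch, "' in atom expression [", body, "]",
         call. = FALSE)
  }
  toks
}

# bond expression with the same logic precedences over - = # : ~ @
nv_parse_bond_expr <- function(txt) {
  chars <- strsplit(txt, "")[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(chars)) chars[pos] else NULL
  take <- function() { c <- chars[pos]; pos <<- pos + 1L; c }
  parse_low <- function() {
    args <- list(parse_or())
    while (identical(peek(), ";")) { take(); args[[length(args) + 1L]] <- parse_or() }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), ",")) { take(); args[[length(args) + 1L]] <- parse_and() }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_not())
    repeat {
      p <- peek()
      if (is.null(p) || p %in% c(",", ";")) break
      if (identical(p, "&")) take()
      args[[length(args) + 1L]] <- parse_not()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_not <- function() {
    if (identical(peek(), "!")) {
      take(); return(list(op = "not", args = list(parse_not())))
    }
    ch <- take()
    kind <- switch(ch,
      "-" = "single", "/" = "single", "\\" = "single",
      "=" = "double", "#" = "triple", "$" = "quad",
      ":" = "aromatic", "~" = "anybond", "@" = "ringbond",
      stop("unexpected bond character '", ch, "'", call. = FALSE))
    nv_prim(kind, 0L)
  }
  out <- parse_low()
  if (pos <= length(chars)) stop("trailing bond tokens in '", txt, "'",
                                 call. = FALSE)
  out
}

# -- evaluation ---------------------------------------------------------------

nv_mol_h_neighbors <- function(mol, a) {
  if (is.null(mol$explicit_h)) return(0L)
  sum(mol$elem[mol$adj[[a]]] == "H")
}

nv_eval_atom <- function(expr, mol, a) {
  switch(expr$op,
    prim = {
      k <- expr$kind; v <- expr$value
      switch(k,
        any = TRUE,
        aliph = !mol$aromatic[a],
        arom = mol$aromatic[a],
        elem_any = mol$Z[a] == v,
        elem_aliph = mol$Z[a] == v && !mol$aromatic[a],
        elem_arom = mol$Z[a] == v && mol$aromatic[a],
        hcount = mol$nh[a] == v,
        connectivity = (mol$degree[a] - nv_mol_h_neighbors(mol, a) +
                          mol$nh[a]) == v,
        degree = mol$degree[a] == v,
        ring_count = if (v < 0L) mol$ring_count[a] > 0L
                     else mol$ring_count[a] == v,
        ring_size = if (v < 0L) mol$ring_count[a] > 0L
                    else v %in% mol$ring_sizes[[a]],
        charge = mol$charge[a] == v,
        isotope = mol$isotope[a] == v,
        recursive = length(nv_match(mol, v, anchor = a, first_only = TRUE)) > 0L,
        stop("unknown atom primitive ", k)
      )
    },
    and = {
      for (e in expr$args) if (!nv_eval_atom(e, mol, a)) return(FALSE)
      TRUE
    },
    or = {
      for (e in expr$args) if (nv_eval_atom(e, mol, a)) return(TRUE)
      FALSE
    },
    not = !nv_eval_atom(expr$args[[1L]], mol, a),
    stop("unknown op ", expr$op)
  )
}

nv_eval_bond <- function(expr, mol, k) {
  if (is.null(expr)) {  # unspecified: single or aromatic
    return(mol$bonds$aromatic[k] ||
             (mol$bonds$order[k] == 1 && !mol$bonds$aromatic[k]))
  }
  switch(expr$op,
    prim = switch(expr$kind,
      single = mol$bonds$order[k] == 1 && !mol$bonds$aromatic[k],
      double = mol$bonds$order[k] == 2 && !mol$bonds$aromatic[k],
      triple = mol$bonds$order[k] == 3,
      quad = mol$bonds$order[k] == 4,
      aromatic = mol$bonds$aromatic[k],
      anybond = TRUE,
      ringbond = mol$bond_in_ring[k],
      stop("unknown bond primitive ", expr$kind)),
    and = {
      for (e in expr$args) if (!nv_eval_bond(e, mol, k)) return(FALSE)
      TRUE
    },
    or = {
      for (e in expr$args) if (nv_eval_bond(e, mol, k)) return(TRUE)
      FALSE
    },
    not = !nv_eval_bond(expr$args[[1L]], mol, k),
    stop("unknown op ", expr$op)
  )
}

nv_mol_bond_between <- function(mol, a, b) {
  for (k in mol$badj[[a]]) {
    if (mol$bonds$a1[k] == b || mol$bonds$a2[k] == b) return(k)
  }
  NA_integer_
}

# Find matches of a parsed pattern in a molecule.
#  anchor: if given, pattern atom 1 must map to this molecule atom.
#  first_only: stop at the first embedding.
# Returns a list of integer vectors (pattern atom i -> molecule atom).
nv_match <- function(mol, pat, anchor = NULL, first_only = FALSE,
                     max_matches = 100000L) {
  np <- pat$natoms
  matches <- list()
  mapping <- rep(NA_integer_, np)
  used <- rep(FALSE, mol$n)

  extend <- function(step) {
    if (length(matches) >= max_matches) return(TRUE)
    if (step > np) {
      matches[[length(matches) + 1L]] <<- mapping
      return(first_only)
    }
    pa <- pat$order[step]
    if (step == 1L) {
      cands <- if (is.null(anchor)) seq_len(mol$n) else anchor
    } else {
      anc <- pat$anchor[[step]]
      cands <- mol$adj[[mapping[anc[1L]]]]
    }
    for (ma in cands) {
      if (used[ma]) next
      if (!nv_eval_atom(pat$atoms[[pa]], mol, ma)) next
      ok <- TRUE
      if (length(pat$b_a1)) {
        for (k in seq_along(pat$b_a1)) {
          p1 <- pat$b_a1[k]; p2 <- pat$b_a2[k]
          other <- if (p1 == pa) p2 else if (p2 == pa) p1 else next
          mo <- mapping[other]
          if (is.na(mo)) next
          bk <- nv_mol_bond_between(mol, ma, mo)
          if (is.na(bk) || !nv_eval_bond(pat$b_expr[[k]], mol, bk)) {
            ok <- FALSE; break
          }
        }
      }
      if (!ok) next
      mapping[pa] <<- ma; used[ma] <<- TRUE
      done <- extend(step + 1L)
      mapping[pa] <<- NA_integer_; used[ma] <<- FALSE
      if (done) return(TRUE)
    }
    FALSE
  }
  extend(1L)
  matches
}

# does the molecule contain the SMARTS pattern at all?
nv_has_substructure <- function(mol, smarts) {
  length(nv_match(mol, nv_smarts(smarts), first_only = TRUE)) > 0L
}

# number of distinct embeddings, unique by the set of matched atoms
nv_count_unique_matches <- function(mol, smarts) {
  m <- nv_match(mol, nv_smarts(smarts))
  if (!length(m)) return(0L)
  length(unique(vapply(m, function(v) paste(sort(v), collapse = ","),
                       character(1))))
}
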